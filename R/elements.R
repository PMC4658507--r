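# Element handling: symbol inference from PDB fields and standard atomic masses.

# Standard atomic weights (amu), IUPAC 2021 abridged values.
.ELEMENT_MASSES <- c(
  H = 1.008, D = 2.014, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, SE = 78.971, FE = 55.845, MG = 24.305, MN = 54.938,
  ZN = 65.38, "NA" = 22.990, K = 39.098, CL = 35.45, CA = 40.078,
  CU = 63.546, F = 18.998, BR = 79.904, I = 126.904, MO = 95.95,
  CO = 58.933, NI = 58.693, B = 10.81, LI = 6.94
)

#' Atomic mass for an element symbol
#'
#' @param element character vector of element symbols (case-insensitive).
#' @return numeric vector of masses in atomic mass units.
#' @keywords internal
element_mass <- function(element) {
  key <- toupper(trimws(element))
  m <- .ELEMENT_MASSES[key]
  if (anyNA(m)) {
    bad <- unique(key[is.na(m)])
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  unname(m)
}

# Infer an element symbol from a PDB atom name when the element column is
# absent.  Strategy: strip digits and apostrophes, take the leading letters;
# two-letter symbols are only accepted if the full candidate is a known
# element (so "CA" as an atom name stays carbon, calcium must come from the
# element column).
infer_element <- function(atom_name) {
  vapply(atom_name, function(nm) {
    s <- gsub("[0-9']", "", trimws(nm))
    if (!nzchar(s)) {
      stop("cannot infer element from atom name '", nm, "'", call. = FALSE)
    }
    first <- toupper(substr(s, 1L, 1L))
    if (first %in% names(.ELEMENT_MASSES)) first
    else stop("cannot infer element from atom name '", nm, "'", call. = FALSE)
  }, character(1), USE.NAMES = FALSE)
}

is_hydrogen <- function(element) toupper(trimws(element)) %in% c("H", "D")
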