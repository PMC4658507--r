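# Nucleosome-aware annotation: chain roles, named regions, dimer groupings,
# and the basepair / superhelix-location coordinate system.

.NUC_ROLES <- c("H3-like", "H3-like'", "H4", "H4'", "H2A", "H2A'",
                "H2B", "H2B'", "DNA-I", "DNA-J")

#' Built-in region presets
#'
#' Residue ranges in the numbering used for tailless H3/CENP-A nucleosome
#' systems: loop 1 (78-84), the CENP-A targeting domain CATD (75-114), the
#' span covering the H2A acidic-patch C-terminal extension (87-100), and the
#' H4 alpha-N helix (26-29).  The acidic patch itself is formally defined by
#' H2A E56, E61, E64, D90, E91, E92 and H2B E102, E110.
#'
#' @param variant `"H3"` or `"CENP-A"` (same numbering for these presets).
#' @return data.frame with columns name, role, start, end.
#' @export
region_presets <- function(variant = c("H3", "CENP-A")) {
  variant <- match.arg(variant)
  data.frame(
    name = c("loop1", "loop1_prime", "CATD", "CATD_prime",
             "acidic_patch_span", "acidic_patch_span_prime",
             "H4_alphaN", "H4_alphaN_prime"),
    role = c("H3-like", "H3-like'", "H3-like", "H3-like'",
             "H2A", "H2A'", "H4", "H4'"),
    start = c(78L, 78L, 75L, 75L, 87L, 87L, 26L, 26L),
    end = c(84L, 84L, 114L, 114L, 100L, 100L, 29L, 29L),
    stringsAsFactors = FALSE
  )
}

#' Annotate a system as a nucleosome
#'
#' Maps chains to nucleosome roles (the two heterotypic halves use the primed
#' / unprimed convention), validates named regions, builds dimer groupings,
#' and constructs the basepair coordinate system: basepair 0 sits at the
#' pseudo-dyad, negative indices run toward the entry DNA and positive toward
#' the exit, and strand-I nucleotide `i` (1-based) pairs with strand-J
#' nucleotide `L + 1 - i`.
#'
#' @param system a `MolecularSystem`.
#' @param chain_roles named character vector `chain_id -> role`; roles from
#'   `H3-like, H3-like', H4, H4', H2A, H2A', H2B, H2B', DNA-I, DNA-J`.
#' @param regions data.frame (name, role, start, end); default
#'   [region_presets()] filtered to roles present.
#' @param dyad_bp_offset 1-based position of basepair 0 within strand I;
#'   default the middle nucleotide.
#' @return object of class `NucleosomeAnnotation`.
#' @export
annotate_nucleosome <- function(system, chain_roles, regions = NULL,
                                dyad_bp_offset = NULL) {
  stopifnot(inherits(system, "MolecularSystem"))
  chain_roles <- unlist(chain_roles)
  bad_role <- setdiff(chain_roles, .NUC_ROLES)
  if (length(bad_role)) stop("unknown role(s): ", paste(bad_role, collapse = ", "))
  if (anyDuplicated(chain_roles)) {
    stop("each role may be assigned to at most one chain")
  }
  present <- unique(system$atoms$chain_id)
  absent <- setdiff(names(chain_roles), present)
  if (length(absent)) {
    stop("config names chain(s) absent from the system: ",
         paste(absent, collapse = ", "))
  }

  role_of <- stats::setNames(names(chain_roles), chain_roles)  # role -> chain

  # residues per chain, in order of first appearance
  chain_residues <- lapply(stats::setNames(present, present), function(ch) {
    a <- system$atoms[system$atoms$chain_id == ch, ]
    unique(a$residue_number)
  })

  # DNA basepair system
  bp <- NULL
  if (any(c("DNA-I", "DNA-J") %in% chain_roles)) {
    if (!all(c("DNA-I", "DNA-J") %in% chain_roles)) {
      stop("both DNA strands (roles DNA-I and DNA-J) are required")
    }
    resI <- chain_residues[[role_of["DNA-I"]]]
    resJ <- chain_residues[[role_of["DNA-J"]]]
    L <- length(resI)
    if (length(resJ) != L) {
      stop("DNA strands differ in length: ", L, " vs ", length(resJ))
    }
    if (is.null(dyad_bp_offset)) dyad_bp_offset <- (L + 1L) %/% 2L
    dyad_bp_offset <- as.integer(dyad_bp_offset)
    if (dyad_bp_offset < 1L || dyad_bp_offset > L) {
      stop("dyad_bp_offset outside strand I (1..", L, ")")
    }
    idx <- seq_len(L)
    bp <- data.frame(
      bp = idx - dyad_bp_offset,
      strandI_pos = idx,
      strandJ_pos = L + 1L - idx,
      strandI_res = resI[idx],
      strandJ_res = resJ[L + 1L - idx]
    )
    bp$shl <- bp$bp / 10
  }

  if (is.null(regions)) {
    # default presets: keep only those whose role is assigned and whose
    # range the chain actually covers (explicit regions are validated
    # strictly below instead)
    regions <- region_presets()
    regions <- regions[regions$role %in% chain_roles, , drop = FALSE]
    covers <- vapply(seq_len(nrow(regions)), function(i) {
      res <- chain_residues[[role_of[[regions$role[i]]]]]
      all(seq.int(regions$start[i], regions$end[i]) %in% res)
    }, logical(1))
    regions <- regions[covers, , drop = FALSE]
  }
  if (nrow(regions)) {
    for (k in seq_len(nrow(regions))) {
      r <- regions[k, ]
      if (!r$role %in% chain_roles) {
        stop("region '", r$name, "' references unassigned role ", r$role)
      }
      res <- chain_residues[[role_of[[r$role]]]]
      span <- seq.int(r$start, r$end)
      if (!all(span %in% res)) {
        stop("region '", r$name, "' (", r$start, "-", r$end,
             ") outside residues of chain ", role_of[[r$role]])
      }
    }
  }

  dimers <- list()
  dimer_defs <- list(
    "homodimer-1" = c("H3-like", "H4"),
    "homodimer-2" = c("H3-like'", "H4'"),
    "hetdimer-1" = c("H2A", "H2B"),
    "hetdimer-2" = c("H2A'", "H2B'")
  )
  for (nm in names(dimer_defs)) {
    if (all(dimer_defs[[nm]] %in% chain_roles)) dimers[[nm]] <- dimer_defs[[nm]]
  }

  structure(list(chain_roles = chain_roles, role_chain = role_of,
                 regions = regions, dimers = dimers, basepairs = bp,
                 chain_residues = chain_residues),
            class = "NucleosomeAnnotation")
}

#' @export
print.NucleosomeAnnotation <- function(x, ...) {
  cat("<NucleosomeAnnotation> roles:",
      paste(sprintf("%s=%s", x$chain_roles, names(x$chain_roles)),
            collapse = " "), "\n")
  if (!is.null(x$basepairs)) {
    cat("  basepairs ", min(x$basepairs$bp), "..", max(x$basepairs$bp),
        " (bp 0 at the pseudo-dyad)\n", sep = "")
  }
  invisible(x)
}

#' Strand partner of a strand-I nucleotide position
#' @param annotation a `NucleosomeAnnotation`.
#' @param pos 1-based strand-I position(s).
#' @return 1-based strand-J position(s).
#' @export
basepair_partner <- function(annotation, pos) {
  L <- nrow(annotation$basepairs)
  if (is.null(L)) stop("annotation has no DNA strands")
  L + 1L - pos
}

#' Select atom sites from an annotated system
#'
#' Builds a grouped atom selection: one group per residue (atom classes
#' `"CA"`, `"heavy"`, `"all"`), one group per basepair (class `"basepair"`:
#' heavy atoms of both paired nucleotides; `"phosphate"`: P atoms only), or
#' whatever residue subset a region / residue query restricts to.
#'
#' @param system a `MolecularSystem`.
#' @param annotation a `NucleosomeAnnotation`.
#' @param role role name (e.g. `"H3-like"`), a character vector of roles, or
#'   `NULL` with `region`.
#' @param region named region from the annotation (overrides `role`).
#' @param residues optional integer vector restricting residue numbers.
#' @param atom_class one of `"CA"`, `"heavy"`, `"all"`, `"basepair"`,
#'   `"phosphate"`.
#' @param bp_range for basepair classes, integer vector of basepair indices
#'   (default: all).
#' @param pooled if `TRUE`, collapse all groups into a single pooled group.
#' @return object of class `SiteSelection`: list with `label`, `groups`
#'   (named list of atom-index vectors) and `grouping`.
#' @export
select_sites <- function(system, annotation, role = NULL, region = NULL,
                         residues = NULL,
                         atom_class = c("CA", "heavy", "all", "basepair",
                                        "phosphate"),
                         bp_range = NULL, pooled = FALSE) {
  atom_class <- match.arg(atom_class)
  a <- system$atoms
  heavy <- !is_hydrogen(a$element)

  if (atom_class %in% c("basepair", "phosphate")) {
    bp <- annotation$basepairs
    if (is.null(bp)) stop("selection query 'basepair': no DNA annotated")
    if (is.null(bp_range)) bp_range <- bp$bp
    rows <- bp[match(bp_range, bp$bp), , drop = FALSE]
    if (anyNA(rows$bp)) stop("basepair index out of range: ",
                             paste(bp_range[is.na(rows$bp)], collapse = ", "))
    chI <- annotation$role_chain[["DNA-I"]]
    chJ <- annotation$role_chain[["DNA-J"]]
    groups <- lapply(seq_len(nrow(rows)), function(k) {
      keep <- (a$chain_id == chI & a$residue_number == rows$strandI_res[k]) |
        (a$chain_id == chJ & a$residue_number == rows$strandJ_res[k])
      if (atom_class == "phosphate") keep <- keep & a$element == "P"
      else keep <- keep & heavy
      which(keep)
    })
    names(groups) <- sprintf("bp%+d", rows$bp)
    label <- sprintf("basepair[%+d..%+d]", min(rows$bp), max(rows$bp))
  } else {
    if (!is.null(region)) {
      reg <- annotation$regions[annotation$regions$name == region, ]
      if (nrow(reg) != 1L) stop("unknown region: ", region)
      role <- reg$role
      residues <- seq.int(reg$start, reg$end)
      label <- region
    } else if (!is.null(role)) {
      label <- paste(role, collapse = "+")
    } else {
      stop("query needs a role, region or residue set")
    }
    chains <- annotation$role_chain[role]
    if (anyNA(chains)) stop("role(s) not annotated: ",
                            paste(role[is.na(chains)], collapse = ", "))
    keep <- a$chain_id %in% chains
    if (!is.null(residues)) keep <- keep & a$residue_number %in% residues
    if (atom_class == "CA") keep <- keep & trimws(a$atom_name) == "CA"
    if (atom_class == "heavy") keep <- keep & heavy
    idx <- which(keep)
    if (length(idx) == 0L) {
      stop("empty selection for query: ", label, " [", atom_class, "]")
    }
    resid_key <- paste(a$chain_id[idx], a$residue_number[idx], sep = ":")
    groups <- split(idx, factor(resid_key, levels = unique(resid_key)))
    label <- paste0(label, "[", atom_class, "]")
  }

  groups <- Filter(length, groups)
  if (length(groups) == 0L) stop("empty selection for query: ", label)
  if (pooled) {
    groups <- list(pooled = sort(unique(unlist(groups))))
  }
  structure(list(label = label, groups = groups,
                 grouping = if (pooled) "pooled"
                            else if (atom_class %in% c("basepair", "phosphate"))
                              "per_basepair" else "per_residue"),
            class = "SiteSelection")
}

#' @export
print.SiteSelection <- function(x, ...) {
  cat("<SiteSelection> ", x$label, ": ", length(x$groups), " group(s), ",
      length(unlist(x$groups)), " atoms (", x$grouping, ")\n", sep = "")
  invisible(x)
}

# All atom indices of a selection, sorted and unique.
selection_atoms <- function(selection) sort(unique(unlist(selection$groups)))

#' Write a selection as TSV
#' @param system the owning `MolecularSystem`.
#' @param selection a `SiteSelection`.
#' @param path output path.
#' @export
write_selection_tsv <- function(system, selection, path) {
  a <- system$atoms
  rows <- do.call(rbind, lapply(names(selection$groups), function(g) {
    idx <- selection$groups[[g]]
    data.frame(chain = a$chain_id[idx], resnum = a$residue_number[idx],
               atomname = a$atom_name[idx], group = g)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Echo an annotation as JSON
#' @param annotation a `NucleosomeAnnotation`.
#' @param path output path.
#' @export
write_annotation_json <- function(annotation, path) {
  obj <- list(
    chain_roles = as.list(stats::setNames(unname(annotation$chain_roles),
                                          names(annotation$chain_roles))),
    regions = annotation$regions,
    dimers = annotation$dimers,
    n_basepairs = if (is.null(annotation$basepairs)) 0L
                  else nrow(annotation$basepairs)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
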