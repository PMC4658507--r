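# PDB reading/writing and trajectory ingestion (multi-model PDB, DCD).
#
# Fixed-column PDB parsing per the wwPDB format v3.3.  Alternate locations:
# keep altloc ' ' or 'A', drop the rest; insertion codes are folded into the
# residue key so selections stay unambiguous on real crystal structures.

parse_pdb_models <- function(path) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  is_atom <- startsWith(lines, "ATOM  ") | startsWith(lines, "HETATM")
  is_endmdl <- startsWith(lines, "ENDMDL")
  if (!any(is_atom)) {
    stop("no ATOM/HETATM records in ", path, " (line 1: '",
         if (length(lines)) lines[1] else "", "')", call. = FALSE)
  }
  # model id per line: cumulative ENDMDL count before the line
  model_id <- cumsum(c(0L, utils::head(is_endmdl, -1L))) + 1L
  keep <- which(is_atom)
  al <- lines[keep]
  # pad short lines so substr() on optional columns is safe
  al <- formatC(al, width = 80L, flag = "-")
  altloc <- substr(al, 17L, 17L)
  ok <- altloc %in% c(" ", "A")
  al <- al[ok]
  mid <- model_id[keep][ok]

  fields <- data.frame(
    atom_name = trimws(substr(al, 13L, 16L)),
    residue_name = trimws(substr(al, 18L, 20L)),
    chain_id = substr(al, 22L, 22L),
    residue_number = as.integer(substr(al, 23L, 26L)),
    icode = substr(al, 27L, 27L),
    x = as.numeric(substr(al, 31L, 38L)),
    y = as.numeric(substr(al, 39L, 46L)),
    z = as.numeric(substr(al, 47L, 54L)),
    element = trimws(substr(al, 77L, 78L)),
    stringsAsFactors = FALSE
  )
  if (anyNA(fields$x) || anyNA(fields$y) || anyNA(fields$z) ||
      anyNA(fields$residue_number)) {
    bad <- which(is.na(fields$x) | is.na(fields$y) | is.na(fields$z) |
                   is.na(fields$residue_number))[1L]
    stop("unparseable ATOM record (coordinate line ", bad, ") in ", path,
         call. = FALSE)
  }
  # fold insertion codes into the residue number key (rare in practice;
  # keeps (chain, resnum, atomname) unique)
  has_icode <- fields$icode != " "
  if (any(has_icode)) {
    idx <- ifelse(has_icode, match(fields$icode, LETTERS), 0L)
    fields$residue_number <- fields$residue_number * 100L + idx
  }
  fields$icode <- NULL
  split(fields, mid)
}

#' Read a PDB structure
#'
#' Parses ATOM/HETATM records; for multi-model files, model 1 provides the
#' reference coordinates.  Element symbols come from the element column when
#' present, otherwise from the leading letters of the atom name; masses are
#' assigned from a standard atomic-weight table.
#'
#' @param path path to a PDB file.
#' @return a [molecular_system()].
#' @export
read_structure <- function(path) {
  models <- parse_pdb_models(path)
  m1 <- models[[1L]]
  molecular_system(
    atoms = m1[, c("atom_name", "element", "residue_number", "residue_name",
                   "chain_id")],
    ref_coords = as.matrix(m1[, c("x", "y", "z")])
  )
}

#' Write a MolecularSystem (or trajectory) as PDB
#'
#' @param system a `MolecularSystem`.
#' @param path output path.
#' @param coords optional coordinates to write instead of the reference set: a
#'   matrix (one model) or a `frames x atoms x 3` array / `TrajectorySegment`
#'   (multi-model output).
#' @export
write_structure <- function(system, path, coords = NULL) {
  if (is.null(coords)) coords <- system$ref_coords
  if (inherits(coords, "TrajectorySegment")) coords <- coords$coords
  if (is.matrix(coords)) {
    coords <- array(coords, dim = c(1L, nrow(coords), 3L))
  }
  nf <- dim(coords)[1]
  a <- system$atoms
  con <- file(path, "w")
  on.exit(close(con))
  multi <- nf > 1L
  for (f in seq_len(nf)) {
    if (multi) writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- coords[f, , , drop = TRUE]
    if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3L)
    nm <- ifelse(nchar(a$atom_name) <= 3L,
                 sprintf(" %-3s", a$atom_name), a$atom_name)
    writeLines(sprintf(
      "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      a$atom_id %% 100000L, nm, a$residue_name, a$chain_id,
      a$residue_number %% 10000L, xyz[, 1], xyz[, 2], xyz[, 3], 1, 0,
      a$element), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a coordinate trajectory
#'
#' Accepts a multi-model PDB or a binary DCD file (dispatch on extension).
#' Frames are ordered as stored; the default analysis window covers all
#' frames and can be restricted afterwards (`window_fraction` keeps the final
#' fraction, mirroring analysis of the equilibrated tail).
#'
#' @param system the owning `MolecularSystem` (atom counts must match).
#' @param path trajectory file (.pdb or .dcd).
#' @param times optional frame times in ns.
#' @param window_fraction if non-`NULL`, keep only this final fraction.
#' @return a `TrajectorySegment`.
#' @export
read_trajectory <- function(system, path, times = NULL,
                            window_fraction = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "dcd") {
    coords <- read_dcd_coords(path)
  } else {
    models <- parse_pdb_models(path)
    if (length(models) == 0L) stop("empty trajectory: ", path)
    coords <- lapply(models, function(m) as.matrix(m[, c("x", "y", "z")]))
    coords <- aperm(simplify2array(coords), c(3L, 1L, 2L))
  }
  traj <- trajectory_segment(coords, times = times, system = system)
  if (!is.null(window_fraction)) {
    traj <- window_final_fraction(traj, window_fraction)
  }
  traj
}

# --- DCD (CHARMM/NAMD Fortran-unformatted) -------------------------------

read_fortran_record <- function(con, what, size, endian) {
  len <- readBin(con, "integer", 1L, size = 4L, endian = endian)
  if (length(len) == 0L) return(NULL)
  n <- len %/% size
  dat <- readBin(con, what, n, size = size, endian = endian)
  tail <- readBin(con, "integer", 1L, size = 4L, endian = endian)
  if (length(tail) == 0L || tail != len) stop("corrupt DCD record")
  dat
}

# Returns frames x atoms x 3 array of coordinates from a DCD file.
read_dcd_coords <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  # detect endianness from the first record marker (must be 84)
  marker <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  endian <- if (identical(marker, 84L)) "little" else "big"
  seek(con, 0L)
  hdr_len <- readBin(con, "integer", 1L, size = 4L, endian = endian)
  if (!identical(hdr_len, 84L)) stop("not a DCD file: ", path)
  magic <- readChar(con, 4L, useBytes = TRUE)
  if (magic != "CORD") stop("not a coordinate DCD file: ", path)
  icntrl <- readBin(con, "integer", 20L, size = 4L, endian = endian)
  invisible(readBin(con, "integer", 1L, size = 4L, endian = endian))
  nframes <- icntrl[1]
  has_cell <- icntrl[11] == 1L
  invisible(read_fortran_record_raw(con, endian))  # title block
  natoms <- read_fortran_record(con, "integer", 4L, endian)[1]
  frames <- vector("list", max(nframes, 0L))
  f <- 0L
  repeat {
    if (has_cell) {
      cell <- read_fortran_record(con, "double", 8L, endian)
      if (is.null(cell)) break
    }
    x <- read_fortran_record(con, "double", 4L, endian)
    if (is.null(x)) break
    y <- read_fortran_record(con, "double", 4L, endian)
    z <- read_fortran_record(con, "double", 4L, endian)
    f <- f + 1L
    frames[[f]] <- cbind(x, y, z)
  }
  if (f == 0L) stop("empty DCD trajectory: ", path)
  frames <- frames[seq_len(f)]
  if (any(vapply(frames, nrow, 1L) != natoms)) stop("corrupt DCD frames")
  aperm(simplify2array(frames), c(3L, 1L, 2L))
}

# Record reader for opaque payloads (title block): returns raw bytes.
read_fortran_record_raw <- function(con, endian) {
  len <- readBin(con, "integer", 1L, size = 4L, endian = endian)
  if (length(len) == 0L) return(NULL)
  dat <- readBin(con, "raw", len)
  invisible(readBin(con, "integer", 1L, size = 4L, endian = endian))
  dat
}

#' Write a trajectory as DCD
#'
#' Minimal single-precision CHARMM-style DCD writer (no unit cell); used so
#' synthetic trajectories can exercise the binary reader path.
#'
#' @param traj a `TrajectorySegment` (all frames written, window ignored).
#' @param path output path.
#' @export
write_dcd <- function(traj, path) {
  coords <- traj$coords
  nf <- dim(coords)[1]; na <- dim(coords)[2]
  con <- file(path, "wb")
  on.exit(close(con))
  wrec <- function(writer) {
    # writer(con) must return the byte length it wrote
    len <- attr(writer, "bytes")
    writeBin(len, con, size = 4L, endian = "little")
    writer(con)
    writeBin(len, con, size = 4L, endian = "little")
  }
  icntrl <- integer(20L); icntrl[1] <- nf; icntrl[2] <- 1L; icntrl[3] <- 1L
  icntrl[4] <- nf; icntrl[20] <- 24L
  hdr <- function(con) {
    writeChar("CORD", con, nchars = 4L, eos = NULL)
    writeBin(icntrl, con, size = 4L, endian = "little")
  }
  attr(hdr, "bytes") <- 84L
  wrec(hdr)
  title <- function(con) {
    writeBin(1L, con, size = 4L, endian = "little")
    writeChar(formatC("synthetic trajectory", width = 80L, flag = "-"), con,
              nchars = 80L, eos = NULL)
  }
  attr(title, "bytes") <- 84L
  wrec(title)
  natrec <- function(con) writeBin(na, con, size = 4L, endian = "little")
  attr(natrec, "bytes") <- 4L
  wrec(natrec)
  for (f in seq_len(nf)) {
    for (d in 1:3) {
      vec <- as.numeric(coords[f, , d])
      w <- function(con) writeBin(vec, con, size = 4L, endian = "little")
      attr(w, "bytes") <- 4L * na
      wrec(w)
    }
  }
  invisible(path)
}
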