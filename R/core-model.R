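# Core containers: MolecularSystem and TrajectorySegment.
#
# Coordinates are Angstrom throughout; frame times are ns.  Frame windows are
# 1-based inclusive [start, end] (idiomatic R; every analysis restricts itself
# to the window).

#' Construct a MolecularSystem
#'
#' A `MolecularSystem` holds the topology every analysis selects against: one
#' row per atom (name, element, mass, residue and chain identity) plus a
#' single reference coordinate set.
#'
#' @param atoms data.frame with columns `atom_name`, `residue_number`,
#'   `residue_name`, `chain_id`, and optionally `element` (inferred from
#'   `atom_name` when absent or blank) and `mass` (looked up from the element
#'   when absent).
#' @param ref_coords numeric matrix, one row per atom, columns x/y/z in
#'   Angstrom.
#' @return object of class `MolecularSystem`.
#' @export
molecular_system <- function(atoms, ref_coords) {
  stopifnot(is.data.frame(atoms))
  req <- c("atom_name", "residue_number", "residue_name", "chain_id")
  miss <- setdiff(req, names(atoms))
  if (length(miss)) stop("atoms lacks column(s): ", paste(miss, collapse = ", "))
  n <- nrow(atoms)
  if (n == 0L) stop("a MolecularSystem needs at least one atom")
  ref_coords <- as_coord_matrix(ref_coords)
  if (nrow(ref_coords) != n) {
    stop("reference_coords has ", nrow(ref_coords), " rows for ", n, " atoms")
  }

  if (is.null(atoms$element)) atoms$element <- ""
  blank <- !nzchar(trimws(atoms$element))
  if (any(blank)) atoms$element[blank] <- infer_element(atoms$atom_name[blank])
  atoms$element <- toupper(trimws(atoms$element))
  if (is.null(atoms$mass)) atoms$mass <- element_mass(atoms$element)
  if (any(atoms$mass <= 0)) stop("all atomic masses must be positive")

  key <- paste(atoms$chain_id, atoms$residue_number, trimws(atoms$atom_name),
               sep = "|")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    stop("duplicate (chain, residue, atom name) key: ", dup)
  }
  atoms$atom_id <- seq_len(n)
  rownames(ref_coords) <- NULL
  structure(list(atoms = atoms[, c("atom_id", req[1], "element",
                                   req[2], req[3], req[4], "mass")],
                 ref_coords = ref_coords),
            class = "MolecularSystem")
}

as_coord_matrix <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) != 3L) stop("coordinates must have 3 columns (x, y, z)")
  storage.mode(x) <- "double"
  colnames(x) <- c("x", "y", "z")
  x
}

#' @export
print.MolecularSystem <- function(x, ...) {
  cat("<MolecularSystem> ", n_atoms(x), " atoms, ",
      length(unique(x$atoms$chain_id)), " chain(s): ",
      paste(unique(x$atoms$chain_id), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Number of atoms in a system
#' @param system a `MolecularSystem`.
#' @export
n_atoms <- function(system) nrow(system$atoms)

#' Construct a TrajectorySegment
#'
#' An ordered stack of coordinate frames with times and an analysis window.
#' The window defaults to all frames; [set_window()] restricts it, e.g. to the
#' equilibrated tail of a production run.
#'
#' @param coords numeric array `frames x atoms x 3` (Angstrom), or a list of
#'   per-frame coordinate matrices.
#' @param times numeric vector of frame times in ns (default `0, 1, ...`).
#' @param system optional `MolecularSystem` used to check the atom count.
#' @param window integer length-2 vector, 1-based inclusive frame window.
#' @return object of class `TrajectorySegment`.
#' @export
trajectory_segment <- function(coords, times = NULL, system = NULL,
                               window = NULL) {
  if (is.list(coords)) {
    coords <- simplify2array(lapply(coords, as_coord_matrix))
    coords <- aperm(coords, c(3L, 1L, 2L))
  }
  if (length(dim(coords)) != 3L || dim(coords)[3] != 3L) {
    stop("coords must be a frames x atoms x 3 array")
  }
  nf <- dim(coords)[1]
  if (nf < 1L) stop("trajectory has no frames")
  if (!is.null(system) && dim(coords)[2] != n_atoms(system)) {
    stop("atom-count mismatch: trajectory has ", dim(coords)[2],
         " atoms, system has ", n_atoms(system))
  }
  if (is.null(times)) times <- as.numeric(seq_len(nf) - 1L)
  if (length(times) != nf) stop("times length must equal frame count")
  if (nf > 1L && any(diff(times) <= 0)) {
    stop("frame_times must be strictly increasing")
  }
  traj <- structure(list(coords = coords, times = times,
                         window = c(1L, nf), aligned = FALSE),
                    class = "TrajectorySegment")
  if (!is.null(window)) traj <- set_window(traj, window[1], window[2])
  traj
}

#' @export
print.TrajectorySegment <- function(x, ...) {
  cat("<TrajectorySegment> ", dim(x$coords)[1], " frames x ",
      dim(x$coords)[2], " atoms; window [", x$window[1], ", ", x$window[2],
      "]", if (isTRUE(x$aligned)) "; aligned" else "", "\n", sep = "")
  invisible(x)
}

#' Number of frames (total, ignoring the window)
#' @param traj a `TrajectorySegment`.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' Restrict the analysis window of a trajectory
#'
#' @param traj a `TrajectorySegment`.
#' @param start,end 1-based inclusive frame bounds.
#' @export
set_window <- function(traj, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  nf <- n_frames(traj)
  if (is.na(start) || is.na(end) || start < 1L || end > nf || start > end) {
    stop("window [", start, ", ", end, "] invalid for ", nf, " frames")
  }
  traj$window <- c(start, end)
  traj
}

#' Restrict the window to the final fraction of frames
#'
#' Mirrors the common practice of analysing only the equilibrated tail of a
#' production trajectory (the default elsewhere in the package is the final
#' 40 percent, e.g. the last 400 ns of a 1 us run).
#'
#' @param traj a `TrajectorySegment`.
#' @param fraction final fraction of frames to keep, in (0, 1].
#' @export
window_final_fraction <- function(traj, fraction = 0.4) {
  stopifnot(fraction > 0, fraction <= 1)
  nf <- n_frames(traj)
  keep <- max(1L, as.integer(floor(nf * fraction)))
  set_window(traj, nf - keep + 1L, nf)
}

# Integer vector of frame indices inside the analysis window.
window_frames <- function(traj) {
  if (traj$window[2] < traj$window[1]) return(integer(0))
  seq.int(traj$window[1], traj$window[2])
}

# Coordinates restricted to the window: frames x atoms x 3.
window_coords <- function(traj) {
  traj$coords[window_frames(traj), , , drop = FALSE]
}
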