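# Rigid-body superposition and global-fluctuation measurements.

#' Kabsch superposition
#'
#' Finds the proper rotation and translation minimising the (weighted) RMSD
#' of `mobile` onto `reference`, via the SVD of the weighted cross-covariance
#' with the usual determinant correction so a reflection is never returned.
#'
#' @param mobile,reference coordinate matrices (same atom count, >= 3 atoms).
#' @param weights per-atom non-negative weights (default uniform).
#' @return object of class `Superposition`: list with `rotation` (3x3,
#'   det +1), `translation` (applied after rotation), and `rmsd` (Angstrom).
#'   The fitted coordinates are `mobile %*% rotation + translation`.
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as_coord_matrix(mobile); reference <- as_coord_matrix(reference)
  n <- nrow(mobile)
  if (nrow(reference) != n) stop("atom counts differ")
  if (n < 3L) stop("superposition needs at least 3 atoms")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0) || sum(weights) <= 0) {
    stop("weights must be non-negative with positive sum")
  }
  w <- weights / sum(weights)
  cm <- colSums(mobile * w); cr <- colSums(reference * w)
  A <- sweep(mobile, 2L, cm); B <- sweep(reference, 2L, cr)
  H <- t(A * w) %*% B
  sv <- svd(H)
  if (sv$d[2] < 1e-12 * max(sv$d[1], 1e-300)) {
    stop("degenerate (collinear) geometry: superposition is ill-defined")
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)  # mobile %*% R aligns onto reference
  fitted <- A %*% R
  rmsd <- sqrt(sum(w * rowSums((fitted - B)^2)))
  structure(list(rotation = R, translation = as.numeric(cr - cm %*% R),
                 rmsd = rmsd, weights = weights),
            class = "Superposition")
}

#' @export
print.Superposition <- function(x, ...) {
  cat(sprintf("<Superposition> rmsd = %.4f A\n", x$rmsd))
  invisible(x)
}

apply_superposition <- function(coords, sp) {
  sweep(coords %*% sp$rotation, 2L, -sp$translation)
}

#' Root-mean-square deviation between two coordinate sets
#' @param a,b coordinate matrices of equal size.
#' @param weights optional per-atom weights.
#' @export
coord_rmsd <- function(a, b, weights = NULL) {
  a <- as_coord_matrix(a); b <- as_coord_matrix(b)
  if (is.null(weights)) weights <- rep(1, nrow(a))
  w <- weights / sum(weights)
  sqrt(sum(w * rowSums((a - b)^2)))
}

#' Superpose every frame of a trajectory onto a reference
#'
#' The fit is computed on the selection atoms and the resulting rigid
#' transform applied to all atoms of the frame, removing overall
#' translational and rotational motion.
#'
#' @param traj a `TrajectorySegment`.
#' @param selection a `SiteSelection` providing the fit atoms.
#' @param reference coordinate matrix covering all atoms (only the selection
#'   rows are used in the fit).  Defaults to a converged window average:
#'   align onto frame 1, average, re-align onto that average (2 iterations).
#' @return the aligned `TrajectorySegment` (`aligned = TRUE`); per-frame fit
#'   RMSDs in attribute `fit_rmsd`.
#' @export
fit_trajectory <- function(traj, selection, reference = NULL) {
  idx <- selection_atoms(selection)
  if (is.null(reference)) {
    ref <- traj$coords[window_frames(traj)[1L], , , drop = TRUE]
    for (it in 1:2) {
      tmp <- fit_trajectory(traj, selection, reference = ref)
      ref <- average_structure(tmp, selection = NULL)
    }
    reference <- ref
  }
  reference <- as_coord_matrix(reference)
  out <- traj
  nf <- n_frames(traj)
  rmsds <- numeric(nf)
  refsel <- reference[idx, , drop = FALSE]
  for (f in seq_len(nf)) {
    fr <- traj$coords[f, , , drop = TRUE]
    sp <- tryCatch(kabsch_superpose(fr[idx, , drop = FALSE], refsel),
                   error = function(e) {
                     stop("superposition failed at frame ", f, ": ",
                          conditionMessage(e), call. = FALSE)
                   })
    out$coords[f, , ] <- apply_superposition(fr, sp)
    rmsds[f] <- sp$rmsd
  }
  out$aligned <- TRUE
  attr(out, "fit_rmsd") <- rmsds
  out
}

#' Average structure over the analysis window
#'
#' Unweighted per-atom arithmetic mean of the window frames (the "geometric
#' average"); meaningful only for an aligned trajectory.
#'
#' @param traj a `TrajectorySegment`.
#' @param selection optional `SiteSelection`; if given, only those atoms are
#'   returned (rows ordered as in the system).
#' @return coordinate matrix; attribute `aligned` records the input flag.
#' @export
average_structure <- function(traj, selection = NULL) {
  wc <- window_coords(traj)
  if (dim(wc)[1] == 0L) stop("empty analysis window")
  avg <- apply(wc, c(2L, 3L), mean)
  if (!is.null(selection)) {
    avg <- avg[selection_atoms(selection), , drop = FALSE]
  }
  avg <- as_coord_matrix(avg)
  attr(avg, "aligned") <- isTRUE(traj$aligned)
  avg
}

#' Mass-weighted center of mass
#' @param coords coordinate matrix.
#' @param masses per-atom masses (amu).
#' @param group optional atom-index vector restricting the computation.
#' @export
center_of_mass <- function(coords, masses, group = NULL) {
  coords <- as_coord_matrix(coords)
  if (!is.null(group)) {
    if (length(group) == 0L) stop("empty group")
    coords <- coords[group, , drop = FALSE]
    masses <- masses[group]
  }
  M <- sum(masses)
  if (M <= 0) stop("zero total mass")
  unname(colSums(coords * masses) / M)
}

#' Center-of-mass distance series between two groups
#'
#' Per-frame distance between the mass-weighted centers of two disjoint atom
#' groups over the analysis window, with mean and standard deviation — the
#' global-fluctuation measure used for histone dimer pairings (homotetramer
#' and the two heterotetramers) and for the intra-dimer alpha1-alpha2
#' compactness.
#'
#' @param traj a `TrajectorySegment`.
#' @param system the owning `MolecularSystem` (masses).
#' @param groupA,groupB `SiteSelection`s or atom-index vectors; must be
#'   disjoint.
#' @param label optional label for the series.
#' @return object of class `DistanceSeries`: `values` (Angstrom per window
#'   frame), `times`, `mean`, `sd`, `label`, `n_frames`.
#' @export
com_distance_series <- function(traj, system, groupA, groupB, label = NULL) {
  ga <- if (inherits(groupA, "SiteSelection")) selection_atoms(groupA) else as.integer(groupA)
  gb <- if (inherits(groupB, "SiteSelection")) selection_atoms(groupB) else as.integer(groupB)
  if (length(intersect(ga, gb))) stop("groups overlap: COM distance undefined")
  if (is.null(label)) {
    la <- if (inherits(groupA, "SiteSelection")) groupA$label else "groupA"
    lb <- if (inherits(groupB, "SiteSelection")) groupB$label else "groupB"
    label <- paste(la, lb, sep = " <-> ")
  }
  m <- system$atoms$mass
  wf <- window_frames(traj)
  vals <- vapply(wf, function(f) {
    fr <- traj$coords[f, , , drop = TRUE]
    sqrt(sum((center_of_mass(fr, m, ga) - center_of_mass(fr, m, gb))^2))
  }, numeric(1))
  distance_series(vals, traj$times[wf], label)
}

distance_series <- function(values, times, label) {
  structure(list(label = label, values = values, times = times,
                 mean = mean(values),
                 sd = if (length(values) > 1L) stats::sd(values) else 0,
                 n_frames = length(values)),
            class = "DistanceSeries")
}

#' @export
print.DistanceSeries <- function(x, ...) {
  cat(sprintf("<DistanceSeries> %s: %.3f +/- %.3f A over %d frames\n",
              x$label, x$mean, x$sd, x$n_frames))
  invisible(x)
}

#' Write a DistanceSeries as TSV plus JSON summary
#' @param series a `DistanceSeries`.
#' @param path TSV output path; the JSON summary goes to `<path>.json`.
#' @export
write_distance_series <- function(series, path) {
  utils::write.table(
    data.frame(frame = seq_along(series$values), time_ns = series$times,
               distance_A = series$values),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(label = series$label, mean = series$mean, sd = series$sd,
         n_frames = series$n_frames),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
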