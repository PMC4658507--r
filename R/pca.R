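# Essential dynamics: C-alpha Cartesian PCA, projections, representative
# structures, and mode animations.
#
# The 3N x 3N covariance of the aligned C-alpha coordinate vector is
# diagonalised with a full symmetric eigendecomposition (fine up to
# nucleosome-scale N); eigenvalues are variances in Angstrom^2 and the top
# eigenvectors are the dominant collective motions.

#' Fit a PCA model on the C-alpha coordinates
#'
#' @param traj an aligned `TrajectorySegment`.
#' @param selection a `SiteSelection` of the PCA sites (typically one
#'   C-alpha per residue).
#' @param unaligned one of `"warn"` (default) or `"error"`: reaction when
#'   the trajectory is not flagged as aligned.
#' @return object of class `PCAModel`: `mean_coords` (sites x 3),
#'   `eigenvectors` (3N x 3N, columns, descending eigenvalue order),
#'   `eigenvalues` (Angstrom^2, sample covariance with the n-1 divisor),
#'   `n_frames`, `atom_indices`.
#' @export
fit_pca <- function(traj, selection, unaligned = c("warn", "error")) {
  unaligned <- match.arg(unaligned)
  if (!isTRUE(traj$aligned)) {
    msg <- "trajectory is not flagged as aligned; PCA assumes prior superposition"
    if (unaligned == "error") stop(msg) else warning(msg)
  }
  idx <- selection_atoms(selection)
  wf <- window_frames(traj)
  if (length(wf) < 2L) stop("PCA needs at least 2 frames")
  # frames x 3N matrix, coordinate order (x1, y1, z1, x2, ...)
  X <- matrix(aperm(traj$coords[wf, idx, , drop = FALSE], c(1L, 3L, 2L)),
              nrow = length(wf))
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  C <- crossprod(Xc) / (length(wf) - 1L)
  ed <- eigen(C, symmetric = TRUE)
  vals <- pmax(ed$values, 0)
  vecs <- ed$vectors
  # deterministic sign: largest-magnitude component of each vector positive
  for (k in seq_len(ncol(vecs))) {
    p <- which.max(abs(vecs[, k]))
    if (vecs[p, k] < 0) vecs[, k] <- -vecs[, k]
  }
  mean_coords <- matrix(mu, ncol = 3L, byrow = TRUE)
  colnames(mean_coords) <- c("x", "y", "z")
  structure(list(mean_coords = mean_coords, eigenvectors = vecs,
                 eigenvalues = vals, n_frames = length(wf),
                 atom_indices = idx, label = selection$label),
            class = "PCAModel")
}

#' @export
print.PCAModel <- function(x, ...) {
  tot <- sum(x$eigenvalues)
  k <- min(3L, length(x$eigenvalues))
  cat(sprintf("<PCAModel> %s: %d sites, %d frames; top %d eigenvalues (A^2): %s (%.1f%% of variance)\n",
              x$label, nrow(x$mean_coords), x$n_frames, k,
              paste(sprintf("%.3f", x$eigenvalues[seq_len(k)]), collapse = ", "),
              100 * sum(x$eigenvalues[seq_len(k)]) / max(tot, 1e-300)))
  invisible(x)
}

# frame coordinates on the model's sites flattened to 3N (x1, y1, z1, ...)
.flatten_frames <- function(traj, model) {
  wf <- window_frames(traj)
  matrix(aperm(traj$coords[wf, model$atom_indices, , drop = FALSE],
               c(1L, 3L, 2L)), nrow = length(wf))
}

#' Project trajectory frames onto principal components
#'
#' @param traj a `TrajectorySegment` over the same sites as the model.
#' @param model a `PCAModel`.
#' @param k number of components (default 2).
#' @return matrix of window frames x k projections (Angstrom).
#' @export
project_frames <- function(traj, model, k = 2L) {
  nv <- ncol(model$eigenvectors)
  if (k > nv) stop("k = ", k, " exceeds the ", nv, " available modes")
  X <- .flatten_frames(traj, model)
  if (ncol(X) != nv) {
    stop("selection mismatch: trajectory provides ", ncol(X),
         " coordinates, model expects ", nv)
  }
  mu <- as.numeric(t(model$mean_coords))
  P <- sweep(X, 2L, mu) %*% model$eigenvectors[, seq_len(k), drop = FALSE]
  colnames(P) <- paste0("PC", seq_len(k))
  P
}

#' Representative frame of a trajectory
#'
#' The window frame with the lowest selection RMSD to the window-average
#' structure; ties break to the earliest frame.
#'
#' @param traj an aligned `TrajectorySegment`.
#' @param selection a `SiteSelection`.
#' @return the frame index (1-based, into the full trajectory); attribute
#'   `rmsd` gives its RMSD to the average.
#' @export
representative_frame <- function(traj, selection) {
  wf <- window_frames(traj)
  idx <- selection_atoms(selection)
  avg <- average_structure(traj)[idx, , drop = FALSE]
  r <- vapply(wf, function(f) {
    coord_rmsd(traj$coords[f, idx, , drop = TRUE], avg)
  }, numeric(1))
  best <- wf[which.min(r)]  # which.min takes the first minimum: earliest frame
  attr(best, "rmsd") <- min(r)
  best
}

#' Mode-animation coordinate sets
#'
#' Displaces a base structure along one principal component:
#' `frame(s) = base + s * sqrt(eigenvalue) * eigenvector`, for an array of
#' unitless scalars (default 21 values spanning -5..+5), optionally written
#' as a multi-model PDB on the C-alpha sites.
#'
#' @param model a `PCAModel`.
#' @param component mode index.
#' @param scalars numeric vector of unitless multipliers.
#' @param base base coordinates on the model's sites (default: the model
#'   mean; typically the representative structure).
#' @param system,path if both given, the animation is written as a
#'   multi-model PDB on the selection sites.
#' @return array `length(scalars) x sites x 3`.
#' @export
mode_animation <- function(model, component = 1L,
                           scalars = seq(-5, 5, length.out = 21L),
                           base = NULL, system = NULL, path = NULL) {
  if (component > length(model$eigenvalues)) stop("no such mode: ", component)
  lam <- model$eigenvalues[component]
  if (lam <= 0) stop("mode ", component, " has zero eigenvalue: no motion to animate")
  if (is.null(base)) base <- model$mean_coords
  base <- as_coord_matrix(base)
  v <- matrix(model$eigenvectors[, component], ncol = 3L, byrow = TRUE)
  out <- array(NA_real_, dim = c(length(scalars), nrow(base), 3L))
  for (i in seq_along(scalars)) {
    out[i, , ] <- base + scalars[i] * sqrt(lam) * v
  }
  if (!is.null(system) && !is.null(path)) {
    sub <- subset_system(system, model$atom_indices)
    write_structure(sub, path, coords = out)
  }
  out
}

# Restrict a MolecularSystem to an atom subset (atom ids renumbered).
subset_system <- function(system, atom_indices) {
  molecular_system(system$atoms[atom_indices,
                                c("atom_name", "element", "residue_number",
                                  "residue_name", "chain_id", "mass")],
                   system$ref_coords[atom_indices, , drop = FALSE])
}

#' Persist a PCA model as JSON (+ plain-text array sidecar)
#'
#' @param model a `PCAModel`.
#' @param path JSON output path; eigenvectors go to `<path>.vectors.tsv`.
#' @param k number of modes to persist (default 10).
#' @export
write_pca_json <- function(model, path, k = 10L) {
  k <- min(k, length(model$eigenvalues))
  jsonlite::write_json(
    list(n_sites = nrow(model$mean_coords), n_frames = model$n_frames,
         eigenvalues = model$eigenvalues[seq_len(k)],
         total_variance = sum(model$eigenvalues),
         mean_coords = model$mean_coords),
    path, auto_unbox = TRUE, digits = NA)
  utils::write.table(model$eigenvectors[, seq_len(k), drop = FALSE],
                     paste0(path, ".vectors.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = paste0("PC", seq_len(k)))
  invisible(path)
}
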