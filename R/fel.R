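# Free-energy landscapes over the top principal components, with basin
# segmentation and bottleneck (minimax) barrier estimation.
#
# F = -ln(count / max_count) in kBT, so the deepest occupied bin sits at 0;
# only relative free energies are meaningful.  Basins are found by a
# watershed-style ascending flood fill on the occupied-bin grid
# (8-connectivity); barriers come from the union-find merge height of the
# same ascending sweep, which equals the max F along the minimax path.

#' 2D free-energy landscape from projections
#'
#' @param projections 2-column matrix (e.g. from [project_frames()]).
#' @param bins number of bins per axis (scalar or length 2), or a list of
#'   two explicit bin-edge vectors.  Default 50x50 spanning the data range
#'   padded by 5 percent.
#' @param temperature_kT energy scale multiplier (landscape reported in kBT;
#'   default 1).
#' @return object of class `FreeEnergyLandscape`: `counts` and `F` matrices
#'   (x index by y index; unsampled bins have `F = Inf`), `xmid`/`ymid` bin
#'   centers, `edges`, `n_frames`.
#' @export
free_energy_landscape <- function(projections, bins = 50L,
                                  temperature_kT = 1) {
  P <- as.matrix(projections)
  if (ncol(P) != 2L) stop("projections must have exactly 2 columns")
  n <- nrow(P)
  if (n < 100L) warning("fewer than 100 frames; the landscape will be noisy")
  if (is.list(bins)) {
    ex <- bins[[1]]; ey <- bins[[2]]
  } else {
    if (length(bins) == 1L) bins <- rep(bins, 2L)
    pad <- function(r) {
      w <- diff(r); if (w == 0) w <- 1
      r + c(-0.05, 0.05) * w
    }
    rx <- pad(range(P[, 1])); ry <- pad(range(P[, 2]))
    ex <- seq(rx[1], rx[2], length.out = bins[1] + 1L)
    ey <- seq(ry[1], ry[2], length.out = bins[2] + 1L)
  }
  ix <- findInterval(P[, 1], ex, rightmost.closed = TRUE)
  iy <- findInterval(P[, 2], ey, rightmost.closed = TRUE)
  ok <- ix >= 1L & ix <= length(ex) - 1L & iy >= 1L & iy <= length(ey) - 1L
  counts <- matrix(0L, length(ex) - 1L, length(ey) - 1L)
  tab <- table(factor(ix[ok], levels = seq_len(nrow(counts))),
               factor(iy[ok], levels = seq_len(ncol(counts))))
  counts[] <- as.integer(tab)
  if (sum(counts > 0) < 2L) stop("fewer than 2 occupied bins")
  F <- matrix(Inf, nrow(counts), ncol(counts))
  occ <- counts > 0
  F[occ] <- -temperature_kT * log(counts[occ] / max(counts))
  structure(list(counts = counts, F = F,
                 xmid = (ex[-1] + ex[-length(ex)]) / 2,
                 ymid = (ey[-1] + ey[-length(ey)]) / 2,
                 edges = list(x = ex, y = ey),
                 n_frames = sum(counts), temperature_kT = temperature_kT),
            class = "FreeEnergyLandscape")
}

#' @export
print.FreeEnergyLandscape <- function(x, ...) {
  cat(sprintf("<FreeEnergyLandscape> %dx%d bins, %d occupied, %d frames, F up to %.2f kBT\n",
              nrow(x$F), ncol(x$F), sum(is.finite(x$F)), x$n_frames,
              max(x$F[is.finite(x$F)])))
  invisible(x)
}

# 8-neighbourhood offsets
.NBR8 <- cbind(dx = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
               dy = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L))

#' Segment a free-energy landscape into basins and estimate barriers
#'
#' Occupied bins are swept in ascending F.  A bin with no previously assigned
#' 8-neighbour seeds a new basin (a local minimum); otherwise it joins its
#' lowest neighbouring basin.  When the sweep first connects two basins, the
#' current F is their bottleneck (minimax-path) saddle.  Basins whose depth
#' below their lowest saddle is less than `min_depth` are merged into the
#' neighbour across that saddle.  The reported barrier is
#' `saddle - min(F_i*, F_j*)` (both basin minima and the saddle itself are
#' returned so other conventions are recoverable); basin pairs in different
#' connected components of the occupied grid are reported as not accessible.
#'
#' @param fel a `FreeEnergyLandscape`.
#' @param min_depth minimum basin depth in kBT before merging (default 1).
#' @param min_count bins with fewer observations are ignored during
#'   segmentation (default 3): single-observation outliers are sampling
#'   noise, not landscape features.  Occupied area still counts all
#'   occupied bins.
#' @return object of class `BasinSet`: `basins` (data.frame: label, n_bins,
#'   min_F, x, y), `barriers` (data.frame: basin_i, basin_j, saddle_F,
#'   barrier, accessible), `assignment` (bin matrix of basin labels),
#'   `occupied_area` (occupied-bin count x bin area).
#' @export
find_basins <- function(fel, min_depth = 1, min_count = 3L) {
  F <- fel$F
  min_count <- min(min_count, max(fel$counts))  # degrade, never empty out
  F[fel$counts < min_count] <- Inf
  occ <- which(is.finite(F), arr.ind = TRUE)
  ord <- order(F[occ])
  occ <- occ[ord, , drop = FALSE]
  nb <- nrow(occ)
  lab <- matrix(0L, nrow(F), ncol(F))   # 0 = unassigned
  basin_min <- numeric(0)
  basin_pos <- list()

  # union-find over basins for saddle bookkeeping
  parent <- integer(0)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  saddles <- list()  # list of c(i, j, F) at first connection of root basins

  for (k in seq_len(nb)) {
    x <- occ[k, 1]; y <- occ[k, 2]
    nx <- x + .NBR8[, 1]; ny <- y + .NBR8[, 2]
    inb <- nx >= 1L & nx <= nrow(F) & ny >= 1L & ny <= ncol(F)
    nl <- lab[cbind(nx[inb], ny[inb])]
    nl <- nl[nl > 0L]
    if (!length(nl)) {
      bid <- length(basin_min) + 1L
      basin_min[bid] <- F[x, y]
      basin_pos[[bid]] <- c(x, y)
      parent[bid] <- bid
      lab[x, y] <- bid
    } else {
      # join the basin whose minimum is lowest among neighbours
      uniq <- unique(nl)
      lab[x, y] <- uniq[which.min(basin_min[uniq])]
      if (length(uniq) > 1L) {
        roots <- unique(vapply(uniq, find, integer(1)))
        if (length(roots) > 1L) {
          for (r in roots[-1]) {
            saddles[[length(saddles) + 1L]] <- c(roots[1], r, F[x, y])
            parent[r] <- roots[1]
          }
        }
      }
    }
  }

  n_basin <- length(basin_min)
  # saddle matrix between original basin seeds via the recorded merges:
  # bottleneck saddle between i and j = the height at which their union-find
  # components first met, maximised along the merge chain.  Recover by
  # replaying merges as a dendrogram.
  saddle <- matrix(NA_real_, n_basin, n_basin)
  if (length(saddles)) {
    comp <- as.list(seq_len(n_basin))
    cid <- seq_len(n_basin)
    for (s in saddles) {
      a <- cid[s[1]]; b <- cid[s[2]]
      if (a == b) next
      for (i in comp[[a]]) for (j in comp[[b]]) {
        saddle[i, j] <- saddle[j, i] <- s[3]
      }
      comp[[a]] <- c(comp[[a]], comp[[b]])
      cid[cid == b] <- a
      comp[[b]] <- integer(0)
    }
  }

  # merge shallow basins: depth = lowest saddle - basin minimum
  keep <- rep(TRUE, n_basin)
  merged_into <- seq_len(n_basin)
  repeat {
    depths <- vapply(seq_len(n_basin), function(i) {
      if (!keep[i]) return(Inf)
      s <- saddle[i, keep & seq_len(n_basin) != i]
      s <- s[!is.na(s)]
      if (!length(s)) return(Inf)
      min(s) - basin_min[i]
    }, numeric(1))
    # never merge the globally deepest basin of a component
    cand <- which(depths < min_depth)
    if (!length(cand)) break
    i <- cand[which.max(basin_min[cand])]  # absorb the shallowest first
    s <- saddle[i, ]; s[!keep] <- NA; s[i] <- NA
    j <- which.min(s)
    keep[i] <- FALSE
    merged_into[merged_into == i] <- j
    # absorbed basin: neighbours inherit the better (lower) saddle
    for (kk in seq_len(n_basin)) {
      if (kk == i || kk == j) next
      s2 <- c(saddle[j, kk], saddle[i, kk])
      s2 <- s2[!is.na(s2)]
      saddle[j, kk] <- saddle[kk, j] <- if (length(s2)) min(s2) else NA
    }
  }

  # prominence rule for disconnected basins: a basin with no accessible
  # saddle to any other kept basin must span at least min_depth within its
  # own bins, else it is a sampling island, not a landscape feature.  The
  # globally deepest basin is always kept.
  relab0 <- match(merged_into, which(keep))
  lab_tmp <- lab
  lab_tmp[lab > 0L] <- relab0[lab[lab > 0L]]
  kept_ids <- which(keep)
  global_best <- kept_ids[which.min(basin_min[kept_ids])]
  for (i in kept_ids) {
    if (i == global_best) next
    others <- setdiff(kept_ids, i)
    has_saddle <- length(others) && any(!is.na(saddle[i, others]))
    if (!has_saddle) {
      own <- F[lab_tmp == match(i, kept_ids)]
      if (length(own) == 0L || max(own) - basin_min[i] < min_depth) {
        keep[i] <- FALSE
        merged_into[merged_into == i] <- 0L
      }
    }
  }

  final_ids <- which(keep)
  relab <- ifelse(merged_into == 0L, 0L, match(merged_into, final_ids))
  relab[is.na(relab)] <- 0L
  lab2 <- lab
  lab2[lab > 0L] <- relab[lab[lab > 0L]]

  basins <- data.frame(
    label = seq_along(final_ids),
    n_bins = vapply(seq_along(final_ids), function(i) sum(lab2 == i), 1L),
    min_F = basin_min[final_ids],
    x = fel$xmid[vapply(final_ids, function(i) basin_pos[[i]][1], 1L)],
    y = fel$ymid[vapply(final_ids, function(i) basin_pos[[i]][2], 1L)]
  )
  barriers <- NULL
  if (length(final_ids) > 1L) {
    cmb <- utils::combn(seq_along(final_ids), 2L)
    barriers <- data.frame(
      basin_i = cmb[1, ], basin_j = cmb[2, ],
      saddle_F = saddle[cbind(final_ids[cmb[1, ]], final_ids[cmb[2, ]])]
    )
    barriers$accessible <- !is.na(barriers$saddle_F)
    barriers$barrier <- barriers$saddle_F -
      pmin(basins$min_F[barriers$basin_i], basins$min_F[barriers$basin_j])
    barriers$barrier_from_shallower <- barriers$saddle_F -
      pmax(basins$min_F[barriers$basin_i], basins$min_F[barriers$basin_j])
  }
  bin_area <- diff(fel$edges$x[1:2]) * diff(fel$edges$y[1:2])
  structure(list(basins = basins, barriers = barriers, assignment = lab2,
                 occupied_area = sum(is.finite(fel$F)) * bin_area,
                 min_depth = min_depth, min_count = min_count),
            class = "BasinSet")
}

#' @export
print.BasinSet <- function(x, ...) {
  cat(sprintf("<BasinSet> %d basin(s), occupied area %.2f A^2\n",
              nrow(x$basins), x$occupied_area))
  if (!is.null(x$barriers)) {
    for (k in seq_len(nrow(x$barriers))) {
      b <- x$barriers[k, ]
      cat(sprintf("  barrier %d-%d: %s kBT\n", b$basin_i, b$basin_j,
                  if (b$accessible) sprintf("%.2f", b$barrier)
                  else "not accessible"))
    }
  }
  invisible(x)
}

#' Write a landscape as TSV and its basin report as JSON
#' @param fel a `FreeEnergyLandscape`.
#' @param basins optional `BasinSet`.
#' @param path TSV output path; basins go to `<path>.basins.json`.
#' @export
write_fel_tsv <- function(fel, path, basins = NULL) {
  grid <- expand.grid(ix = seq_along(fel$xmid), iy = seq_along(fel$ymid))
  df <- data.frame(
    bin_x_center = fel$xmid[grid$ix], bin_y_center = fel$ymid[grid$iy],
    count = fel$counts[cbind(grid$ix, grid$iy)],
    F_kT = fel$F[cbind(grid$ix, grid$iy)]
  )
  df$F_kT[is.infinite(df$F_kT)] <- NA
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(basins)) {
    jsonlite::write_json(
      list(basins = basins$basins, barriers = basins$barriers,
           occupied_area = basins$occupied_area,
           min_depth = basins$min_depth),
      paste0(path, ".basins.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
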