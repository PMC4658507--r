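# Local-fluctuation stage: per-site RMSF, the trajectory-thirds significance
# procedure, pairwise system comparison, and DNA basepair RMSF.

# RMSF of one site group: sqrt(mean over frames of mean over atoms of squared
# displacement from the reference).  coords: frames x atoms x 3 (already
# restricted to the group's atoms); ref: atoms x 3.
.group_rmsf <- function(coords, ref) {
  nf <- dim(coords)[1]
  disp2 <- 0
  for (d in 1:3) {
    disp2 <- disp2 + sweep(coords[, , d, drop = FALSE], 2L, ref[, d])^2
  }
  sqrt(mean(rowMeans(array(disp2, dim = dim(coords)[1:2]))))
}

#' Per-site root-mean-square fluctuations with the thirds procedure
#'
#' For each site group (typically one C-alpha per residue, or one pooled
#' basepair) the RMSF about the window-average structure is computed, then
#' recomputed on each third of the window (contiguous equal frame blocks,
#' remainder dropped at the end, each third re-centred on its own average).
#' The per-site standard deviation across thirds yields the significance
#' threshold: twice the maximum per-third SD over all sites.  With a maximum
#' SD of ~0.3 Angstrom this reproduces the familiar rule of treating RMSF
#' differences above 0.6 Angstrom as highly significant.
#'
#' @param traj an aligned `TrajectorySegment`.
#' @param selection a `SiteSelection` (groups define the sites).
#' @param reference optional reference coordinates for the full-window RMSF
#'   (default: the window average structure).
#' @param thirds compute the per-third profile (needs >= 9 window frames).
#' @return object of class `RMSFProfile`: `sites`, `rmsf`, `third_rmsf`
#'   (sites x 3), `third_sd`, `threshold`.
#' @export
site_rmsf <- function(traj, selection, reference = NULL, thirds = TRUE) {
  wf <- window_frames(traj)
  if (length(wf) < 2L) stop("RMSF needs at least 2 frames in the window")
  if (!isTRUE(traj$aligned)) {
    warning("trajectory is not flagged as aligned; RMSF assumes prior superposition")
  }
  if (is.null(reference)) reference <- average_structure(traj)
  reference <- as_coord_matrix(reference)

  groups <- selection$groups
  sites <- names(groups)
  wc <- window_coords(traj)
  rmsf <- vapply(groups, function(g) {
    .group_rmsf(wc[, g, , drop = FALSE], reference[g, , drop = FALSE])
  }, numeric(1))

  third_rmsf <- NULL; third_sd <- NULL; threshold <- NA_real_
  if (thirds) {
    nt <- length(wf) %/% 3L
    if (nt < 3L) stop("thirds procedure needs at least 3 frames per third")
    third_rmsf <- matrix(NA_real_, length(groups), 3L,
                         dimnames = list(sites, paste0("third", 1:3)))
    for (t in 1:3) {
      block <- wc[seq.int((t - 1L) * nt + 1L, t * nt), , , drop = FALSE]
      bavg <- apply(block, c(2L, 3L), mean)
      third_rmsf[, t] <- vapply(groups, function(g) {
        .group_rmsf(block[, g, , drop = FALSE], bavg[g, , drop = FALSE])
      }, numeric(1))
    }
    third_sd <- apply(third_rmsf, 1L, stats::sd)
    threshold <- 2 * max(third_sd)
  }
  structure(list(sites = sites, rmsf = unname(rmsf),
                 third_rmsf = third_rmsf,
                 third_sd = if (is.null(third_sd)) NULL else unname(third_sd),
                 threshold = threshold, label = selection$label),
            class = "RMSFProfile")
}

#' @export
print.RMSFProfile <- function(x, ...) {
  cat(sprintf("<RMSFProfile> %s: %d sites, rmsf %.3f..%.3f A%s\n",
              x$label, length(x$sites), min(x$rmsf), max(x$rmsf),
              if (!is.na(x$threshold))
                sprintf(", significance threshold %.3f A", x$threshold)
              else ""))
  invisible(x)
}

#' Compare two RMSF profiles
#'
#' Per-site delta (B minus A) with a significance flag: `|delta|` must exceed
#' the larger of the two profiles' thresholds (2 x max per-third SD).  For
#' chains of unequal length (e.g. a 2-residue loop-1 insertion) an alignment
#' map of site-index pairs puts the profiles in register; unmapped sites are
#' reported, never silently dropped.
#'
#' @param profileA,profileB `RMSFProfile`s.
#' @param alignment optional 2-column integer matrix of (site index in A,
#'   site index in B) pairs; default: positional identity (requires equal
#'   lengths).
#' @param regions optional named list of site-index vectors (in B's indexing
#'   after alignment) for which signed extrema of delta are reported.
#' @return object of class `RMSFComparison`.
#' @export
compare_rmsf <- function(profileA, profileB, alignment = NULL,
                         regions = NULL) {
  nA <- length(profileA$sites); nB <- length(profileB$sites)
  if (is.null(alignment)) {
    if (nA != nB) {
      stop("profiles have ", nA, " vs ", nB,
           " sites; supply an alignment map")
    }
    alignment <- cbind(seq_len(nA), seq_len(nB))
  }
  alignment <- as.matrix(alignment)
  delta <- profileB$rmsf[alignment[, 2]] - profileA$rmsf[alignment[, 1]]
  thr <- max(profileA$threshold, profileB$threshold, na.rm = TRUE)
  significant <- abs(delta) > thr
  unmappedA <- setdiff(seq_len(nA), alignment[, 1])
  unmappedB <- setdiff(seq_len(nB), alignment[, 2])

  extrema <- NULL
  if (!is.null(regions)) {
    extrema <- lapply(regions, function(rows) {
      rows <- rows[rows %in% seq_along(delta)]
      if (!length(rows)) return(NULL)
      k <- rows[which.max(abs(delta[rows]))]
      list(site = profileB$sites[alignment[k, 2]], delta = delta[k],
           significant = significant[k])
    })
  }
  structure(list(siteA = profileA$sites[alignment[, 1]],
                 siteB = profileB$sites[alignment[, 2]],
                 delta = delta, significant = significant, threshold = thr,
                 unmapped_A = profileA$sites[unmappedA],
                 unmapped_B = profileB$sites[unmappedB],
                 extrema = extrema),
            class = "RMSFComparison")
}

#' @export
print.RMSFComparison <- function(x, ...) {
  cat(sprintf(
    "<RMSFComparison> %d shared sites, %d significant (threshold %.3f A)\n",
    length(x$delta), sum(x$significant), x$threshold))
  if (length(x$unmapped_A) || length(x$unmapped_B)) {
    cat("  unmapped: A{", paste(x$unmapped_A, collapse = ","), "} B{",
        paste(x$unmapped_B, collapse = ","), "}\n", sep = "")
  }
  invisible(x)
}

#' DNA basepair RMSF
#'
#' One site per basepair: the pooled heavy atoms of both paired nucleotides
#' (phosphate-only available).  The trajectory must be aligned on the protein
#' core so DNA motion is measured relative to the core; output is ordered by
#' basepair index, `per_strand = TRUE` returns the two strands separately.
#'
#' @param traj an aligned `TrajectorySegment`.
#' @param system the owning `MolecularSystem`.
#' @param annotation a `NucleosomeAnnotation` with both DNA strands.
#' @param atom_class `"basepair"` (heavy atoms, default) or `"phosphate"`.
#' @param per_strand return a list of two per-strand profiles instead.
#' @param thirds as in [site_rmsf()].
#' @export
basepair_rmsf <- function(traj, system, annotation, atom_class = "basepair",
                          per_strand = FALSE, thirds = TRUE) {
  if (is.null(annotation$basepairs)) stop("annotation has no DNA strands")
  if (!per_strand) {
    sel <- select_sites(system, annotation, atom_class = atom_class)
    return(site_rmsf(traj, sel, thirds = thirds))
  }
  bp <- annotation$basepairs
  a <- system$atoms
  heavy <- !is_hydrogen(a$element)
  out <- lapply(c(I = "DNA-I", J = "DNA-J"), function(role) {
    ch <- annotation$role_chain[[role]]
    resn <- if (role == "DNA-I") bp$strandI_res else bp$strandJ_res
    groups <- lapply(resn, function(r) {
      which(a$chain_id == ch & a$residue_number == r & heavy)
    })
    names(groups) <- sprintf("bp%+d", bp$bp)
    sel <- structure(list(label = paste0(role, "[", atom_class, "]"),
                          groups = groups, grouping = "per_basepair"),
                     class = "SiteSelection")
    site_rmsf(traj, sel, thirds = thirds)
  })
  out
}

#' Write an RMSF profile as TSV
#' @param profile an `RMSFProfile`.
#' @param path output path.
#' @export
write_rmsf_tsv <- function(profile, path) {
  df <- data.frame(site = profile$sites, rmsf_A = profile$rmsf)
  if (!is.null(profile$third_rmsf)) {
    df$third1 <- profile$third_rmsf[, 1]
    df$third2 <- profile$third_rmsf[, 2]
    df$third3 <- profile$third_rmsf[, 3]
    df$sd <- profile$third_sd
    df$threshold <- profile$threshold
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
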