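# Event detection and coincidence scoring: DNA-segment detachment episodes
# and residue side-chain swings, temporally associated within a frame window.
#
# All thresholds are qualitative conventions (detachment has no published
# quantitative definition) and are therefore config-exposed and echoed in
# every output.

#' Build an event series from an active-flag vector
#' @param active logical per frame.
#' @param label series label.
#' @param definition list describing the generating rule (echoed in output).
#' @return object of class `EventSeries` with `episodes` as a 2-column
#'   matrix of 1-based inclusive `start`/`end` frame bounds.
#' @export
event_series <- function(active, label = "events", definition = list()) {
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  structure(list(label = label, active = active,
                 episodes = cbind(start = starts[keep], end = ends[keep]),
                 definition = definition),
            class = "EventSeries")
}

#' @export
print.EventSeries <- function(x, ...) {
  cat(sprintf("<EventSeries> %s: %d episode(s) over %d frames\n",
              x$label, nrow(x$episodes), length(x$active)))
  invisible(x)
}

# hysteresis thresholding: activate when value > on for >= min_duration
# consecutive frames; deactivate when value < off.
.hysteresis_episodes <- function(values, on, off, min_duration) {
  n <- length(values)
  active <- logical(n)
  state <- FALSE
  run <- 0L
  for (i in seq_len(n)) {
    if (!state) {
      run <- if (values[i] > on) run + 1L else 0L
      if (run >= min_duration) {
        state <- TRUE
        active[seq.int(i - run + 1L, i)] <- TRUE
        run <- 0L
      }
    } else {
      if (values[i] < off) state <- FALSE else active[i] <- TRUE
    }
  }
  active
}

#' Detect DNA-segment detachment episodes
#'
#' Tracks the per-frame minimum heavy-atom distance between a basepair range
#' and the protein core; the segment is detached while that distance exceeds
#' `threshold` for at least `min_duration` consecutive frames, and
#' re-attaches when it falls back below `threshold - hysteresis`.
#'
#' @param traj a `TrajectorySegment`.
#' @param system the owning `MolecularSystem`.
#' @param annotation a `NucleosomeAnnotation` with DNA strands.
#' @param bp_range integer vector of basepair indices defining the segment.
#' @param core_selection `SiteSelection` of the reference core (default: all
#'   protein heavy atoms).
#' @param threshold detachment distance in Angstrom (default 8).
#' @param min_duration minimum episode length in frames (default 1 percent
#'   of the window, at least 1).
#' @param hysteresis re-attachment margin in Angstrom (default 1).
#' @return an `EventSeries`; the distance series is in attribute `distance`.
#' @export
segment_detachment_series <- function(traj, system, annotation, bp_range,
                                      core_selection = NULL, threshold = 8,
                                      min_duration = NULL, hysteresis = 1) {
  if (!length(bp_range)) stop("empty basepair range")
  seg <- select_sites(system, annotation, atom_class = "basepair",
                      bp_range = bp_range, pooled = TRUE)
  if (is.null(core_selection)) {
    protein_roles <- intersect(
      c("H3-like", "H3-like'", "H4", "H4'", "H2A", "H2A'", "H2B", "H2B'"),
      annotation$chain_roles)
    if (!length(protein_roles)) stop("no protein chains annotated")
    core_selection <- select_sites(system, annotation, role = protein_roles,
                                   atom_class = "heavy", pooled = TRUE)
  }
  wf <- window_frames(traj)
  if (is.null(min_duration)) min_duration <- max(1L, length(wf) %/% 100L)
  ia <- selection_atoms(seg); ib <- selection_atoms(core_selection)
  vals <- vapply(wf, function(f) {
    fr <- traj$coords[f, , , drop = TRUE]
    A <- fr[ia, , drop = FALSE]; B <- fr[ib, , drop = FALSE]
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
    sqrt(max(min(d2), 0))
  }, numeric(1))
  active <- .hysteresis_episodes(vals, threshold, threshold - hysteresis,
                                 min_duration)
  es <- event_series(
    active,
    label = sprintf("detachment bp[%+d..%+d]", min(bp_range), max(bp_range)),
    definition = list(rule = "min heavy-atom distance to core",
                      threshold_A = threshold, min_duration = min_duration,
                      hysteresis_A = hysteresis))
  attr(es, "distance") <- distance_series(vals, traj$times[wf], es$label)
  es
}

#' Minimum-distance series between a residue and a site
#'
#' Convenience wrapper over [min_distance_series()] with basepair targets
#' enabled (e.g. a side-chain swing toward a superhelix location).
#'
#' @param traj,system,annotation as elsewhere.
#' @param residue `"chain:resnum"`.
#' @param target `"chain:resnum"` or `"bp:+k"`.
#' @param atom_class `"heavy"` or `"all"`.
#' @export
residue_site_distance_series <- function(traj, system, residue, target,
                                         annotation = NULL,
                                         atom_class = "heavy") {
  min_distance_series(traj, system, residue, target, annotation = annotation,
                      atom_class = atom_class)
}

#' Threshold a distance series into a contact-style event series
#' @param series a `DistanceSeries`.
#' @param cutoff contact cutoff in Angstrom (default 3.6, strict less-than).
#' @export
contact_event_series <- function(series, cutoff = 3.6) {
  event_series(series$values < cutoff,
               label = paste0(series$label, " < ", cutoff, " A"),
               definition = list(rule = "distance below cutoff",
                                 cutoff_A = cutoff))
}

#' Score the temporal coincidence of two event series
#'
#' An A-episode is coincident when some B-episode starts within
#' `+/- window` frames of the A-episode start.  The rate is the fraction of
#' coincident A-episodes; signed lags are B start minus A start (nearest B
#' episode).
#'
#' @param seriesA,seriesB `EventSeries` over the same frame count.
#' @param window matching half-width in frames (default 2 percent of the
#'   series length, at least 1).
#' @return object of class `CoincidenceReport`; `rate` is `NA` (undefined,
#'   not 0) when A has no episodes.
#' @export
event_coincidence <- function(seriesA, seriesB, window = NULL) {
  nA <- length(seriesA$active); nB <- length(seriesB$active)
  if (nA != nB) stop("series cover different frame counts: ", nA, " vs ", nB)
  if (is.null(window)) window <- max(1L, nA %/% 50L)
  sa <- seriesA$episodes[, "start"]
  sb <- seriesB$episodes[, "start"]
  lags <- rep(NA_integer_, length(sa))
  coincident <- logical(length(sa))
  for (i in seq_along(sa)) {
    if (!length(sb)) break
    d <- sb - sa[i]
    j <- which.min(abs(d))
    lags[i] <- d[j]
    coincident[i] <- abs(d[j]) <= window
  }
  rate <- if (!length(sa)) NA_real_ else mean(coincident)
  structure(list(labelA = seriesA$label, labelB = seriesB$label,
                 window = window, n_A = length(sa), n_B = length(sb),
                 coincident = sum(coincident), rate = rate,
                 lags = lags[coincident],
                 median_lag = if (any(coincident))
                   stats::median(lags[coincident]) else NA_real_),
            class = "CoincidenceReport")
}

#' @export
print.CoincidenceReport <- function(x, ...) {
  cat(sprintf("<CoincidenceReport> %s ~ %s: rate %s (%d/%d, window +/-%d, median lag %s)\n",
              x$labelA, x$labelB,
              if (is.na(x$rate)) "undefined (no A episodes)"
              else sprintf("%.3f", x$rate),
              x$coincident, x$n_A, x$window,
              if (is.na(x$median_lag)) "-" else sprintf("%+d", as.integer(x$median_lag))))
  invisible(x)
}

#' Write an event series as TSV and a coincidence report as JSON
#' @param series an `EventSeries`.
#' @param path output path.
#' @export
write_event_series_tsv <- function(series, path) {
  utils::write.table(
    data.frame(frame = seq_along(series$active), active = series$active),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_event_series_tsv
#' @param report a `CoincidenceReport`.
#' @export
write_coincidence_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
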