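# Two-system comparison pipeline: align -> average -> RMSF / COM / contacts
# -> PCA -> FEL -> events, aggregated into a machine-readable report.

#' Bundle one system for comparison
#'
#' @param system a `MolecularSystem` or path to a PDB file.
#' @param trajectory a `TrajectorySegment` or path to a trajectory file
#'   (multi-model PDB or DCD).
#' @param annotation a `NucleosomeAnnotation`, or a named chain-role vector
#'   to build one.
#' @param label system label used in the report.
#' @param window_fraction if non-`NULL`, restrict the analysis window to
#'   this final fraction of frames (default 0.4 when the trajectory is read
#'   from file, untouched when passed as an object).
#' @return object of class `CompareConfig`.
#' @export
compare_config <- function(system, trajectory, annotation, label,
                           window_fraction = NULL) {
  if (is.character(system)) system <- read_structure(system)
  if (is.character(trajectory)) {
    trajectory <- read_trajectory(system, trajectory,
                                  window_fraction = window_fraction %||% 0.4)
  } else if (!is.null(window_fraction)) {
    trajectory <- window_final_fraction(trajectory, window_fraction)
  }
  if (!inherits(annotation, "NucleosomeAnnotation")) {
    annotation <- annotate_nucleosome(system, annotation)
  }
  structure(list(system = system, trajectory = trajectory,
                 annotation = annotation, label = label),
            class = "CompareConfig")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.protein_roles <- function(annotation) {
  intersect(c("H3-like", "H3-like'", "H4", "H4'", "H2A", "H2A'",
              "H2B", "H2B'"), annotation$chain_roles)
}

# site-index alignment map between two per-residue CA profiles, built from
# per-role global sequence alignment (handles e.g. a loop-1 insertion)
rmsf_alignment_map <- function(cfgA, cfgB) {
  rolesA <- .protein_roles(cfgA$annotation)
  rolesB <- .protein_roles(cfgB$annotation)
  roles <- intersect(rolesA, rolesB)
  offA <- 0L; offB <- 0L
  pairs <- NULL
  for (r in rolesA) {
    chA <- cfgA$annotation$role_chain[[r]]
    nA <- length(cfgA$annotation$chain_residues[[chA]])
    if (r %in% roles) {
      chB <- cfgB$annotation$role_chain[[r]]
      nB <- length(cfgB$annotation$chain_residues[[chB]])
      if (nA == nB) {
        al <- cbind(seq_len(nA), seq_len(nA))
      } else {
        sa <- chain_sequence(cfgA$system, chA)
        sb <- chain_sequence(cfgB$system, chB)
        al <- align_sequences(sa, sb)$pairs
      }
      pairs <- rbind(pairs, cbind(al[, 1] + offA, al[, 2] + offB))
      offB <- offB + nB
    }
    offA <- offA + nA
  }
  pairs
}

#' Run the full two-system comparison
#'
#' Executes the requested stages in dependency order on both systems and
#' aggregates a `ComparisonReport`.  Stage outputs (TSV/JSON) are written to
#' `out_dir` when given, with a manifest.
#'
#' @param configA,configB [compare_config()] bundles (A is the baseline,
#'   e.g. the canonical H3 system; B the variant).
#' @param stages subset of `c("rmsf", "com", "contacts", "pca", "fel",
#'   "events")`.
#' @param out_dir optional output directory.
#' @param fel_bins bins per axis for the free-energy landscape.
#' @param detachment_bp_range basepair range scanned by the events stage
#'   (default the pseudo-dyad-proximal +10..+30).
#' @param seed seed recorded in provenance (the pipeline itself is
#'   deterministic).
#' @return object of class `ComparisonReport` (a nested list); `$failed`
#'   lists stages that errored.
#' @export
run_compare <- function(configA, configB,
                        stages = c("rmsf", "com", "contacts", "pca", "fel",
                                   "events"),
                        out_dir = NULL, fel_bins = 50L,
                        detachment_bp_range = 10:30, seed = NULL) {
  stages <- match.arg(stages, several.ok = TRUE)
  report <- list(labels = c(A = configA$label, B = configB$label),
                 stages = stages, failed = character(0),
                 provenance = list(seed = seed,
                                   version = as.character(utils::packageVersion("nucdyn")),
                                   date = format(Sys.time(), "%Y-%m-%d")))
  cfgs <- list(A = configA, B = configB)

  # alignment + averages (always run; everything downstream needs them)
  prep <- lapply(cfgs, function(cfg) {
    ca <- select_sites(cfg$system, cfg$annotation,
                       role = .protein_roles(cfg$annotation), atom_class = "CA")
    traj <- fit_trajectory(cfg$trajectory, ca)
    list(cfg = cfg, ca = ca, traj = traj)
  })

  run_stage <- function(name, fun) {
    if (!name %in% stages) return(NULL)
    tryCatch(fun(), error = function(e) {
      report$failed <<- c(report$failed, name)
      list(error = conditionMessage(e))
    })
  }

  report$rmsf <- run_stage("rmsf", function() {
    profs <- lapply(prep, function(p) site_rmsf(p$traj, p$ca))
    map <- rmsf_alignment_map(configA, configB)
    regions <- NULL
    regB <- configB$annotation$regions
    if (!is.null(regB) && nrow(regB)) {
      # map named regions to row indices of the aligned site list
      sitesB <- profs$B$sites[map[, 2]]
      regions <- lapply(seq_len(nrow(regB)), function(i) {
        ch <- configB$annotation$role_chain[[regB$role[i]]]
        keys <- paste0(ch, ":", seq.int(regB$start[i], regB$end[i]))
        which(sitesB %in% keys)
      })
      names(regions) <- regB$name
      regions <- Filter(length, regions)
    }
    cmp <- compare_rmsf(profs$A, profs$B, alignment = map, regions = regions)
    list(profiles = profs, comparison = cmp,
         summary = list(
           threshold_A = cmp$threshold,
           n_significant = sum(cmp$significant),
           extrema = cmp$extrema))
  })

  report$com <- run_stage("com", function() {
    pairings <- list(homotetramer = c("homodimer-1", "homodimer-2"),
                     heterotetramer_1 = c("homodimer-1", "hetdimer-1"),
                     heterotetramer_2 = c("homodimer-2", "hetdimer-2"))
    res <- lapply(prep, function(p) {
      ann <- p$cfg$annotation
      sapply(pairings, function(pr) {
        if (!all(pr %in% names(ann$dimers))) return(c(mean = NA, sd = NA))
        g1 <- select_sites(p$cfg$system, ann, role = ann$dimers[[pr[1]]],
                           atom_class = "all", pooled = TRUE)
        g2 <- select_sites(p$cfg$system, ann, role = ann$dimers[[pr[2]]],
                           atom_class = "all", pooled = TRUE)
        ds <- com_distance_series(p$traj, p$cfg$system, g1, g2)
        c(mean = ds$mean, sd = ds$sd)
      })
    })
    res
  })

  report$contacts <- run_stage("contacts", function() {
    maps <- lapply(prep, function(p) {
      ann <- p$cfg$annotation
      gA <- select_sites(p$cfg$system, ann, role = "H3-like",
                         atom_class = "heavy")
      gB <- select_sites(p$cfg$system, ann, role = "H3-like'",
                         atom_class = "heavy")
      list(map = contact_map(p$traj, p$cfg$system, gA, gB),
           count = interface_contact_count(p$traj, p$cfg$system, gA, gB))
    })
    # pair labels are chain:resnum; map across systems by residue number
    # (works when the two systems share numbering, as the presets do)
    relabel <- function(m, cfg) {
      ann <- cfg$annotation
      chain2role <- stats::setNames(unname(ann$chain_roles),
                                    names(ann$chain_roles))
      p <- m$pairs
      fix <- function(s) {
        parts <- do.call(rbind, strsplit(s, ":", fixed = TRUE))
        paste0(chain2role[parts[, 1]], ":", parts[, 2])
      }
      paste(fix(p$resA), fix(p$resB), sep = "|")
    }
    keyA <- relabel(maps$A$map, configA); keyB <- relabel(maps$B$map, configB)
    keys <- union(keyA, keyB)
    cmpdf <- {
      fa <- maps$A$map$pairs$fraction[match(keys, keyA)]
      fb <- maps$B$map$pairs$fraction[match(keys, keyB)]
      fa[is.na(fa)] <- 0; fb[is.na(fb)] <- 0
      status <- rep("kept", length(keys))
      status[fa >= 0.5 & fb < 0.05] <- "lost"
      status[fb >= 0.5 & fa < 0.05] <- "gained"
      status[status == "kept" & fb >= 0.05 & (fa - fb) >= 0.25] <- "weakened"
      data.frame(pair = keys, fraction_A = fa, fraction_B = fb,
                 status = status, stringsAsFactors = FALSE)
    }
    list(maps = maps, comparison = cmpdf,
         summary = list(
           mean_count_A = maps$A$count$mean, mean_count_B = maps$B$count$mean,
           n_lost = sum(cmpdf$status == "lost"),
           n_weakened = sum(cmpdf$status == "weakened"),
           n_gained = sum(cmpdf$status == "gained")))
  })

  pca_models <- NULL
  report$pca <- run_stage("pca", function() {
    pca_models <<- lapply(prep, function(p) fit_pca(p$traj, p$ca))
    lapply(pca_models, function(m) {
      k <- min(5L, length(m$eigenvalues))
      list(eigenvalues = m$eigenvalues[seq_len(k)],
           total_variance = sum(m$eigenvalues))
    })
  })

  report$fel <- run_stage("fel", function() {
    if (is.null(pca_models)) {
      pca_models <<- lapply(prep, function(p) fit_pca(p$traj, p$ca))
    }
    res <- lapply(names(prep), function(nm) {
      p <- prep[[nm]]
      proj <- project_frames(p$traj, pca_models[[nm]], k = 2L)
      # keep bins commensurate with sampling so occupied bins are meaningful
      bins <- max(5L, min(fel_bins, as.integer(floor(sqrt(nrow(proj))))))
      fel <- suppressWarnings(free_energy_landscape(proj, bins = bins))
      basins <- find_basins(fel)
      list(fel = fel, basins = basins,
           summary = list(n_basins = nrow(basins$basins),
                          occupied_area = basins$occupied_area,
                          barriers = if (is.null(basins$barriers)) NULL
                                     else basins$barriers$barrier))
    })
    names(res) <- names(prep)
    res
  })

  report$events <- run_stage("events", function() {
    res <- lapply(prep, function(p) {
      ann <- p$cfg$annotation
      if (is.null(ann$basepairs)) return(list(skipped = "no DNA annotated"))
      rng <- intersect(detachment_bp_range, ann$basepairs$bp)
      if (!length(rng)) return(list(skipped = "bp range not in annotation"))
      es <- segment_detachment_series(p$traj, p$cfg$system, ann, rng)
      list(series = es, n_episodes = nrow(es$episodes),
           definition = es$definition)
    })
    res
  })

  class(report) <- "ComparisonReport"
  if (!is.null(out_dir)) write_comparison_report(report, out_dir)
  report
}

#' @export
print.ComparisonReport <- function(x, ...) {
  cat("<ComparisonReport> ", x$labels["A"], " vs ", x$labels["B"], "\n",
      sep = "")
  cat("  stages:", paste(x$stages, collapse = ", "), "\n")
  if (length(x$failed)) cat("  FAILED:", paste(x$failed, collapse = ", "), "\n")
  if (!is.null(x$rmsf$summary)) {
    cat(sprintf("  rmsf: %d significant site(s) at threshold %.3f A\n",
                x$rmsf$summary$n_significant, x$rmsf$summary$threshold_A))
  }
  if (!is.null(x$contacts$summary)) {
    s <- x$contacts$summary
    cat(sprintf("  contacts: mean %.1f -> %.1f; %d lost, %d weakened, %d gained\n",
                s$mean_count_A, s$mean_count_B, s$n_lost, s$n_weakened,
                s$n_gained))
  }
  if (!is.null(x$fel) && is.null(x$fel$error)) {
    cat(sprintf("  fel: %d vs %d basin(s)\n",
                x$fel$A$summary$n_basins, x$fel$B$summary$n_basins))
  }
  invisible(x)
}

#' Write a comparison report (JSON + Markdown summary)
#' @param report a `ComparisonReport`.
#' @param out_dir output directory (created if needed).
#' @export
write_comparison_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  slim <- list(labels = as.list(report$labels), stages = report$stages,
               failed = report$failed, provenance = report$provenance)
  fmt <- function(x, digits) if (is.null(x)) NULL else round(x, digits)
  if (!is.null(report$rmsf$summary)) {
    slim$rmsf <- list(
      threshold_A = fmt(report$rmsf$summary$threshold_A, 3),
      n_significant = report$rmsf$summary$n_significant,
      extrema = lapply(report$rmsf$summary$extrema, function(e)
        if (is.null(e)) NULL
        else list(site = e$site, delta = fmt(e$delta, 3),
                  significant = e$significant)))
  }
  if (!is.null(report$com) && is.null(report$com$error)) {
    slim$com <- lapply(report$com, function(m) round(m, 3))
  }
  if (!is.null(report$contacts$summary)) slim$contacts <- report$contacts$summary
  if (!is.null(report$pca) && is.null(report$pca$error)) {
    slim$pca <- lapply(report$pca, function(p)
      list(eigenvalues = fmt(p$eigenvalues, 3),
           total_variance = fmt(p$total_variance, 3)))
  }
  if (!is.null(report$fel) && is.null(report$fel$error)) {
    slim$fel <- lapply(report$fel, function(f)
      list(n_basins = f$summary$n_basins,
           occupied_area = fmt(f$summary$occupied_area, 3),
           barriers_kT = fmt(f$summary$barriers, 2)))
  }
  if (!is.null(report$events) && is.null(report$events$error)) {
    slim$events <- lapply(report$events, function(e)
      if (!is.null(e$skipped)) list(skipped = e$skipped)
      else list(n_episodes = e$n_episodes, definition = e$definition))
  }
  jsonlite::write_json(slim, file.path(out_dir, "comparison.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)

  md <- c(sprintf("# Comparison: %s vs %s", report$labels["A"],
                  report$labels["B"]),
          "",
          sprintf("Stages: %s%s", paste(report$stages, collapse = ", "),
                  if (length(report$failed))
                    paste0(" (FAILED: ",
                           paste(report$failed, collapse = ", "), ")")
                  else ""))
  if (!is.null(slim$rmsf)) {
    md <- c(md, "", "## RMSF",
            sprintf("- significance threshold: %.3f A", slim$rmsf$threshold_A),
            sprintf("- significant sites: %d", slim$rmsf$n_significant))
  }
  if (!is.null(slim$contacts)) {
    s <- slim$contacts
    md <- c(md, "", "## Interface contacts",
            sprintf("- mean contacts: %.2f (A) vs %.2f (B)",
                    s$mean_count_A, s$mean_count_B),
            sprintf("- lost %d, weakened %d, gained %d",
                    s$n_lost, s$n_weakened, s$n_gained))
  }
  if (!is.null(slim$fel)) {
    md <- c(md, "", "## Free-energy landscape",
            sprintf("- basins: %d (A) vs %d (B)",
                    slim$fel$A$n_basins, slim$fel$B$n_basins))
  }
  writeLines(md, file.path(out_dir, "comparison.md"))

  manifest <- data.frame(file = c("comparison.json", "comparison.md"))
  utils::write.table(manifest, file.path(out_dir, "MANIFEST.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(report)
}
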