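# Synthetic toy nucleosomes and trajectories with planted ground truth.
#
# The generator plants statistics, not physics: isotropic Gaussian site
# noise, low-rank collective modes, Markov two-state switching, and scripted
# DNA-segment detachment with a lagged side-chain swing.  Geometry mimics the
# nucleosome architecture (protein core inside a DNA superhelix: radius
# ~41.8 A, pitch ~23.9 A, ~89 bp per superhelical turn) closely enough for
# distance-based analyses to behave realistically.

# one root seed expands into independent per-stream seeds so adding a stream
# never perturbs another
stream_seed <- function(seed, stream) {
  offsets <- c(geometry = 101L, sequence = 211L, noise = 307L, modes = 401L,
               switching = 503L, events = 601L)
  if (!stream %in% names(offsets)) stop("unknown seed stream: ", stream)
  (as.integer(seed) * 1009L + offsets[[stream]]) %% 2147483587L
}

.TOY_PROTEIN_CHAINS <- list(
  list(role = "H3-like",  chain = "A", start = 40L, end = 135L),
  list(role = "H4",       chain = "B", start = 24L, end = 102L),
  list(role = "H2A",      chain = "C", start = 13L, end = 117L),
  list(role = "H2B",      chain = "D", start = 27L, end = 122L),
  list(role = "H3-like'", chain = "E", start = 40L, end = 135L),
  list(role = "H4'",      chain = "F", start = 24L, end = 102L),
  list(role = "H2A'",     chain = "G", start = 13L, end = 117L),
  list(role = "H2B'",     chain = "H", start = 27L, end = 122L)
)

.AA20 <- names(.AA3TO1)[!names(.AA3TO1) %in% "MSE"]

#' Specify a toy nucleosome
#'
#' @param chains list of chain specs `list(role, chain, start, end)` for
#'   protein chains (C-alpha only), or `NULL` for the default eight-chain
#'   histone core with tailless-construct residue ranges.
#' @param sequences optional named list `chain ->` character vector of
#'   3-letter residue names (length must match the residue range); default
#'   pseudo-random sequences drawn per chain from the seed.
#' @param n_basepairs DNA length in basepairs (0 = no DNA).
#' @param superhelix_radius,superhelix_pitch,bp_per_turn DNA superhelix
#'   geometry (Angstrom / Angstrom per turn / basepairs per turn).
#' @param protein_radius radius of the inner protein cylinder (Angstrom).
#' @param seed root seed; every stream below derives from it.
#' @return object of class `ToySpec`.
#' @export
toy_nucleosome_spec <- function(chains = NULL, sequences = NULL,
                                n_basepairs = 147L,
                                superhelix_radius = 41.8,
                                superhelix_pitch = 23.9,
                                bp_per_turn = 89,
                                protein_radius = 34,
                                seed = 1L) {
  if (is.null(chains)) chains <- .TOY_PROTEIN_CHAINS
  if (!length(chains)) stop("at least one protein chain is required")
  structure(list(chains = chains, sequences = sequences,
                 n_basepairs = as.integer(n_basepairs),
                 superhelix_radius = superhelix_radius,
                 superhelix_pitch = superhelix_pitch,
                 bp_per_turn = bp_per_turn, protein_radius = protein_radius,
                 seed = as.integer(seed)),
            class = "ToySpec")
}

#' Build a toy nucleosome system and its annotation
#'
#' Protein chains are C-alpha-only traces on an inner cylinder; DNA is two
#' antiparallel strands of pseudo-nucleotides (3 heavy-atom proxies each:
#' P, C1', N1) on an outer superhelix, base-paired across strands with the
#' pseudo-dyad at the DNA midpoint.  Deterministic given the spec seed.
#'
#' @param spec a [toy_nucleosome_spec()].
#' @return list with `system` (a `MolecularSystem`) and `annotation` (a
#'   `NucleosomeAnnotation`).
#' @export
build_toy_nucleosome <- function(spec) {
  stopifnot(inherits(spec, "ToySpec"))
  rows <- list(); coords <- list()
  set.seed(stream_seed(spec$seed, "geometry"))
  seq_rng_seed <- stream_seed(spec$seed, "sequence")

  nch <- length(spec$chains)
  for (k in seq_len(nch)) {
    ch <- spec$chains[[k]]
    resnums <- seq.int(ch$start, ch$end)
    n <- length(resnums)
    if (!is.null(spec$sequences) && !is.null(spec$sequences[[ch$chain]])) {
      resnames <- spec$sequences[[ch$chain]]
      if (length(resnames) != n) {
        stop("sequence for chain ", ch$chain, " has length ",
             length(resnames), ", expected ", n)
      }
    } else {
      set.seed(seq_rng_seed + k)
      resnames <- sample(.AA20, n, replace = TRUE)
      set.seed(stream_seed(spec$seed, "geometry") + k)
    }
    # compact helical trace on the inner cylinder; chains staggered in angle
    # and height so dimer partners sit adjacently
    ang0 <- 2 * pi * (k - 1) / nch
    t <- seq_len(n)
    ang <- ang0 + 0.25 * t / sqrt(n)
    z <- -15 + 30 * (k %% 2) * 0.5 + 8 * sin(t / 6) + 0.15 * t
    r <- spec$protein_radius + 3 * cos(t / 5)
    xyz <- cbind(r * cos(ang), r * sin(ang), z) +
      matrix(stats::rnorm(3 * n, sd = 0.3), n, 3)
    rows[[length(rows) + 1L]] <- data.frame(
      atom_name = "CA", element = "C", residue_number = resnums,
      residue_name = resnames, chain_id = ch$chain,
      stringsAsFactors = FALSE)
    coords[[length(coords) + 1L]] <- xyz
  }

  chain_roles <- stats::setNames(
    vapply(spec$chains, `[[`, "", "role"),
    vapply(spec$chains, `[[`, "", "chain"))

  L <- spec$n_basepairs
  if (L > 0L) {
    dyad <- (L + 1L) %/% 2L
    step <- 2 * pi / spec$bp_per_turn
    bp_center <- function(i) {
      th <- (i - dyad) * step
      c(spec$superhelix_radius * cos(th), spec$superhelix_radius * sin(th),
        spec$superhelix_pitch * th / (2 * pi))
    }
    nt_atoms <- function(center, side) {
      # 3 heavy-atom proxies per nucleotide: backbone P (outer), sugar C1'
      # (center), base N1 (toward the paired strand)
      radial <- center / sqrt(sum(center[1:2]^2) + 1e-9)
      radial[3] <- 0
      rbind(center + 1.5 * radial + c(0, 0, side * 2),
            center + c(0, 0, side * 2),
            center - 1.0 * radial + c(0, 0, side * 0.8))
    }
    dna_names <- c("P", "C1'", "N1")
    dna_elems <- c("P", "C", "N")
    bases_I <- sample(c("DA", "DT", "DG", "DC"), L, replace = TRUE)
    comp <- c(DA = "DT", DT = "DA", DG = "DC", DC = "DG")
    for (strand in c("I", "J")) {
      ch <- if (strand == "I") "I" else "J"
      xyz <- matrix(NA_real_, 3L * L, 3L)
      for (p in seq_len(L)) {
        bp_i <- if (strand == "I") p else L + 1L - p  # strand-I bp position
        xyz[(3L * p - 2L):(3L * p), ] <-
          nt_atoms(bp_center(bp_i), side = if (strand == "I") 1 else -1)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        atom_name = rep(dna_names, L), element = rep(dna_elems, L),
        residue_number = rep(seq_len(L), each = 3L),
        residue_name = rep(if (strand == "I") bases_I
                           else unname(comp[bases_I[L:1]]), each = 3L),
        chain_id = ch, stringsAsFactors = FALSE)
      coords[[length(coords) + 1L]] <- xyz
    }
    chain_roles <- c(chain_roles, c(I = "DNA-I", J = "DNA-J"))
  }

  atoms <- do.call(rbind, rows)
  system <- molecular_system(atoms, do.call(rbind, coords))
  annotation <- annotate_nucleosome(system, chain_roles)
  list(system = system, annotation = annotation)
}

.check_nframes <- function(n_frames) {
  if (n_frames < 2L) stop("n_frames must be at least 2")
}

#' Isotropic Gaussian fluctuation trajectory
#'
#' Frames are the reference coordinates plus iid isotropic Gaussian noise
#' per atom; no rigid-body drift is injected.  A site with per-coordinate
#' standard deviation sigma has expected RMSF sigma * sqrt(3).
#'
#' @param system a `MolecularSystem`.
#' @param sigma per-coordinate standard deviation in Angstrom: scalar or
#'   one value per atom.
#' @param n_frames number of frames.
#' @param seed RNG seed.
#' @param times optional frame times.
#' @return a `TrajectorySegment` (flagged aligned: no rigid-body motion was
#'   added).
#' @export
gaussian_fluctuation_traj <- function(system, sigma, n_frames, seed = 1L,
                                      times = NULL) {
  .check_nframes(n_frames)
  na <- n_atoms(system)
  if (length(sigma) == 1L) sigma <- rep(sigma, na)
  if (length(sigma) != na) stop("sigma must be scalar or one value per atom")
  if (any(sigma < 0)) stop("sigma must be non-negative")
  set.seed(stream_seed(seed, "noise"))
  coords <- array(NA_real_, dim = c(n_frames, na, 3L))
  ref <- system$ref_coords
  for (f in seq_len(n_frames)) {
    coords[f, , ] <- ref + matrix(stats::rnorm(3L * na, sd = sigma), na, 3L)
  }
  traj <- trajectory_segment(coords, times = times, system = system)
  traj$aligned <- TRUE
  traj
}

#' Planted low-rank collective-mode trajectory
#'
#' Frames are the reference plus a sum of a few collective displacements
#' `a[i, t] * v_i`, with mode amplitudes drawn `Normal(0, variance_i)` and
#' the mode vectors orthonormalized internally, plus an optional isotropic
#' noise floor.  The planted modes are returned for verification.
#'
#' @param system a `MolecularSystem`.
#' @param modes list of `list(vector, variance)`: `vector` is a 3N
#'   displacement (or N x 3 matrix), `variance` in Angstrom^2.  Pass an
#'   integer instead of a vector to seed a random direction.
#' @param n_frames,seed as elsewhere.
#' @param floor_sd isotropic per-coordinate noise floor (Angstrom).
#' @return a `TrajectorySegment`; planted orthonormal modes in attribute
#'   `modes` (3N x k), variances in `variances`, amplitudes in `amplitudes`.
#' @export
planted_mode_traj <- function(system, modes, n_frames, seed = 1L,
                              floor_sd = 0) {
  .check_nframes(n_frames)
  na <- n_atoms(system)
  dof <- 3L * na
  k <- length(modes)
  if (k > dof) stop("more modes (", k, ") than degrees of freedom (", dof, ")")
  set.seed(stream_seed(seed, "modes"))
  V <- matrix(NA_real_, dof, k)
  lam <- numeric(k)
  for (i in seq_len(k)) {
    m <- modes[[i]]
    v <- m$vector
    if (is.null(v)) v <- stats::rnorm(dof)
    if (is.matrix(v)) v <- as.numeric(t(v))  # N x 3 -> (x1,y1,z1,...)
    if (length(v) != dof) stop("mode ", i, " has length ", length(v),
                               ", expected ", dof)
    V[, i] <- v
    lam[i] <- m$variance
  }
  if (any(lam < 0)) stop("mode variances must be non-negative")
  V <- qr.Q(qr(V))[, seq_len(k), drop = FALSE]  # orthonormalize
  amps <- matrix(stats::rnorm(n_frames * k), n_frames, k) %*% diag(sqrt(lam), k)
  ref_flat <- as.numeric(t(system$ref_coords))
  coords <- array(NA_real_, dim = c(n_frames, na, 3L))
  for (f in seq_len(n_frames)) {
    x <- ref_flat + as.numeric(V %*% amps[f, ])
    if (floor_sd > 0) x <- x + stats::rnorm(dof, sd = floor_sd)
    coords[f, , ] <- matrix(x, na, 3L, byrow = TRUE)
  }
  traj <- trajectory_segment(coords, system = system)
  traj$aligned <- TRUE
  attr(traj, "modes") <- V
  attr(traj, "variances") <- lam
  attr(traj, "amplitudes") <- amps
  traj
}

#' Two-state Markov switching trajectory
#'
#' Frames alternate between the reference conformation and a displaced
#' conformation under a symmetric two-state Markov chain (switch probability
#' per frame), plus an isotropic noise floor.  The true state labels are
#' returned for verification — this is the planted ground truth for basin
#' recovery on a free-energy landscape.
#'
#' @param system a `MolecularSystem`.
#' @param offset_coords displacement of state 2 relative to the reference:
#'   N x 3 matrix or 3N vector.
#' @param p_switch per-frame switching probability, in (0, 1).
#' @param n_frames,seed as elsewhere.
#' @param floor_sd isotropic per-coordinate noise floor (Angstrom).
#' @return a `TrajectorySegment` with attribute `states` (1/2 per frame).
#' @export
two_state_traj <- function(system, offset_coords, p_switch, n_frames,
                           seed = 1L, floor_sd = 0.1) {
  .check_nframes(n_frames)
  if (p_switch <= 0 || p_switch >= 1) stop("p_switch must be in (0, 1)")
  na <- n_atoms(system)
  off <- offset_coords
  if (is.matrix(off)) {
    if (nrow(off) != na) stop("offset_coords must cover all atoms")
  } else {
    off <- matrix(off, na, 3L, byrow = TRUE)
  }
  if (all(off == 0)) warning("zero offset: the two states are degenerate")
  set.seed(stream_seed(seed, "switching"))
  flips <- stats::runif(n_frames) < p_switch
  states <- integer(n_frames)
  s <- 1L
  for (f in seq_len(n_frames)) {
    if (flips[f]) s <- 3L - s
    states[f] <- s
  }
  ref <- system$ref_coords
  coords <- array(NA_real_, dim = c(n_frames, na, 3L))
  for (f in seq_len(n_frames)) {
    base <- if (states[f] == 2L) ref + off else ref
    coords[f, , ] <- base + matrix(stats::rnorm(3L * na, sd = floor_sd),
                                   na, 3L)
  }
  traj <- trajectory_segment(coords, system = system)
  traj$aligned <- TRUE
  attr(traj, "states") <- states
  traj
}

#' Scripted DNA-detachment scenario with a lagged residue swing
#'
#' During `event_frames` the basepair segment is displaced radially outward
#' (away from the superhelix axis) by `displacement`; `lag` frames after
#' event start, the swing residue is moved to within contact range of its
#' target site.  Ground truth (event frames, swing frames) is returned for
#' verification.
#'
#' @param system a `MolecularSystem`.
#' @param annotation a `NucleosomeAnnotation` with DNA.
#' @param bp_range basepair indices of the detaching segment.
#' @param event_frames integer vector of detached frames (one contiguous
#'   episode).
#' @param displacement outward displacement in Angstrom.
#' @param swing `list(residue = "chain:resnum", target = "bp:+k", lag)` or
#'   `NULL`.
#' @param n_frames,seed as elsewhere.
#' @param floor_sd isotropic noise floor (Angstrom).
#' @return a `TrajectorySegment` with attribute `truth` (list of
#'   `event_frames`, `swing_frames`).
#' @export
detachment_scenario_traj <- function(system, annotation, bp_range,
                                     event_frames, displacement,
                                     swing = NULL, n_frames, seed = 1L,
                                     floor_sd = 0.1) {
  .check_nframes(n_frames)
  if (any(event_frames < 1L | event_frames > n_frames)) {
    stop("event_frames outside 1..", n_frames)
  }
  seg <- select_sites(system, annotation, atom_class = "basepair",
                      bp_range = bp_range, pooled = TRUE)
  seg_atoms <- selection_atoms(seg)
  swing_atoms <- integer(0); swing_frames <- integer(0); target_pos <- NULL
  if (!is.null(swing)) {
    if (swing$lag < 0) stop("swing lag must be non-negative")
    swing_atoms <- .residue_atoms(system, swing$residue, heavy_only = FALSE)
    if (length(intersect(swing_atoms, seg_atoms))) {
      stop("scripted events overlap on the same sites")
    }
    tsel <- select_sites(system, annotation, atom_class = "basepair",
                         bp_range = as.integer(sub("^bp:", "", swing$target)),
                         pooled = TRUE)
    target_pos <- colMeans(system$ref_coords[selection_atoms(tsel), ,
                                             drop = FALSE])
    swing_frames <- event_frames + swing$lag
    swing_frames <- swing_frames[swing_frames <= n_frames]
  }
  set.seed(stream_seed(seed, "events"))
  ref <- system$ref_coords
  na <- n_atoms(system)
  # outward = radial in the xy-plane (the superhelix axis is z)
  seg_xyz <- ref[seg_atoms, , drop = FALSE]
  radial <- seg_xyz / sqrt(rowSums(seg_xyz[, 1:2, drop = FALSE]^2) + 1e-9)
  radial[, 3] <- 0
  coords <- array(NA_real_, dim = c(n_frames, na, 3L))
  for (f in seq_len(n_frames)) {
    fr <- ref + matrix(stats::rnorm(3L * na, sd = floor_sd), na, 3L)
    if (f %in% event_frames) {
      fr[seg_atoms, ] <- fr[seg_atoms, ] + displacement * radial
    }
    if (f %in% swing_frames) {
      # move the swing residue to ~2.5 A from the target site center
      ctr <- colMeans(fr[swing_atoms, , drop = FALSE])
      dirv <- target_pos - ctr
      dl <- sqrt(sum(dirv^2))
      if (dl > 2.5) {
        shift <- dirv * (dl - 2.5) / dl
        fr[swing_atoms, ] <- sweep(fr[swing_atoms, , drop = FALSE], 2L,
                                   -shift)
      }
    }
    coords[f, , ] <- fr
  }
  traj <- trajectory_segment(coords, system = system)
  traj$aligned <- TRUE
  attr(traj, "truth") <- list(event_frames = sort(unique(event_frames)),
                              swing_frames = sort(unique(swing_frames)))
  traj
}
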