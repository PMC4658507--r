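# Shared fixtures and independent oracles.  Everything is generated in code;
# no binary fixtures.

`%||%` <- function(a, b) if (is.null(a)) b else a

# a minimal hand-built protein system: n_res CA atoms per chain, arbitrary
# but non-degenerate coordinates
tiny_protein <- function(chains = c(A = 5L), spread = 4, seed = 1L) {
  set.seed(seed)
  rows <- list(); xyz <- list()
  for (ch in names(chains)) {
    n <- chains[[ch]]
    rows[[ch]] <- data.frame(
      atom_name = "CA", element = "C", residue_number = seq_len(n),
      residue_name = "ALA", chain_id = ch, stringsAsFactors = FALSE)
    xyz[[ch]] <- matrix(stats::runif(3 * n, -spread, spread), n, 3)
  }
  molecular_system(do.call(rbind, rows), do.call(rbind, xyz))
}

# trajectory from an explicit list of per-frame coordinate matrices
traj_from_frames <- function(frames, system = NULL, aligned = TRUE) {
  tr <- trajectory_segment(frames, system = system)
  tr$aligned <- aligned
  tr
}

# brute-force RMSF by the definition: per group g,
# sqrt(mean_f mean_{a in g} |x_{f,a} - ref_a|^2)
brute_rmsf <- function(coords, groups, ref) {
  vapply(groups, function(g) {
    acc <- 0
    for (f in seq_len(dim(coords)[1])) {
      s <- 0
      for (a in g) s <- s + sum((coords[f, a, ] - ref[a, ])^2)
      acc <- acc + s / length(g)
    }
    sqrt(acc / dim(coords)[1])
  }, numeric(1))
}

# brute-force per-frame contact count between residue groups (double loop)
brute_contact_count <- function(fr, groupsA, groupsB, cutoff) {
  n <- 0L
  for (ga in groupsA) for (gb in groupsB) {
    dmin <- Inf
    for (i in ga) for (j in gb) {
      dmin <- min(dmin, sqrt(sum((fr[i, ] - fr[j, ])^2)))
    }
    if (dmin < cutoff) n <- n + 1L
  }
  n
}

# brute-force minimum distance between two atom sets
brute_min_dist <- function(fr, ia, ib) {
  dmin <- Inf
  for (i in ia) for (j in ib) {
    dmin <- min(dmin, sqrt(sum((fr[i, ] - fr[j, ]) ^ 2)))
  }
  dmin
}

# brute-force 3N x 3N covariance by explicit double loop (n-1 divisor)
brute_covariance <- function(X) {
  n <- nrow(X); p <- ncol(X)
  mu <- colMeans(X)
  C <- matrix(0, p, p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    C[i, j] <- sum((X[, i] - mu[i]) * (X[, j] - mu[j])) / (n - 1)
  }
  C
}

# rotation matrix about an axis
rot_z <- function(theta) {
  matrix(c(cos(theta), sin(theta), 0,
           -sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3)
}
rot_x <- function(theta) {
  matrix(c(1, 0, 0,
           0, cos(theta), sin(theta),
           0, -sin(theta), cos(theta)), 3, 3)
}

# dense rotation grid for the superposition oracle: minimum RMSD over a grid
# of Euler-like rotations (coarse by design; used only as a lower-accuracy
# cross-check that the analytic optimum is not beaten)
grid_min_rmsd <- function(mobile, reference, n = 24L) {
  cm <- colMeans(mobile); cr <- colMeans(reference)
  A <- sweep(mobile, 2, cm); B <- sweep(reference, 2, cr)
  best <- Inf
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  ph <- seq(0, pi, length.out = n %/% 2L)
  for (a in th) for (b in ph) for (c in th) {
    R <- rot_z(a) %*% rot_x(b) %*% rot_z(c)
    r <- sqrt(mean(rowSums((A %*% R - B)^2)))
    if (r < best) best <- r
  }
  best
}

# principal angle (degrees) between the column spaces of two matrices
subspace_angle_deg <- function(U, V) {
  qu <- qr.Q(qr(U)); qv <- qr.Q(qr(V))
  s <- svd(crossprod(qu, qv))$d
  s <- pmin(pmax(s, -1), 1)
  max(acos(s)) * 180 / pi
}

# --- synthetic crystal-structure stand-ins --------------------------------
# The real reference structures (a 147-bp canonical-H3 nucleosome and a
# 121-bp CENP-A nucleosome) cannot be downloaded in this environment, so
# these SYNTHETIC stand-ins encode the documented facts instead: 147 vs 121
# resolved basepairs, a 2-residue loop-1 insertion in the CENP-A-like chain,
# and near-identical core geometry (small Gaussian perturbation + a rigid
# transform).  Tests against them verify the pipeline machinery on planted
# ground truth, not real crystallographic data.

standin_h3_sequence <- function(seed = 11L) {
  set.seed(seed)
  aa <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")
  sample(aa, 96, replace = TRUE)  # residues 40..135 of the H3-like chain
}

make_crystal_standins <- function(seed = 11L) {
  h3_seq <- standin_h3_sequence(seed)
  spec147 <- toy_nucleosome_spec(
    n_basepairs = 147L,
    sequences = list(A = h3_seq, E = h3_seq),
    seed = seed)
  kx5 <- build_toy_nucleosome(spec147)

  # CENP-A-like: drop 13 bp from each DNA end (121 resolved bp), insert two
  # loop-1 residues (TRP TRP after residue 80) into both H3-like chains,
  # perturb coordinates (sd 0.5 A) and apply a rigid transform
  sys <- kx5$system
  a <- sys$atoms
  keep <- rep(TRUE, nrow(a))
  for (ch in c("I", "J")) {
    keep[a$chain_id == ch & (a$residue_number <= 13 | a$residue_number > 134)] <- FALSE
  }
  a2 <- a[keep, ]
  xyz <- sys$ref_coords[keep, , drop = FALSE]
  # renumber trimmed DNA 1..121
  for (ch in c("I", "J")) {
    sel <- a2$chain_id == ch
    a2$residue_number[sel] <- a2$residue_number[sel] - 13L
  }
  # loop-1 insertion into chains A and E: new residues 200/201 placed midway,
  # then renumber the chain 40.. so numbering stays contiguous
  ins_rows <- list(); ins_xyz <- list()
  for (ch in c("A", "E")) {
    i80 <- which(a2$chain_id == ch & a2$residue_number == 80L)
    i81 <- which(a2$chain_id == ch & a2$residue_number == 81L)
    p <- (xyz[i80, ] + xyz[i81, ]) / 2
    ins_rows[[ch]] <- data.frame(
      atom_name = "CA", element = "C", residue_number = c(9980L, 9981L),
      residue_name = "TRP", chain_id = ch, stringsAsFactors = FALSE)
    ins_xyz[[ch]] <- rbind(p + c(0.5, 0, 0), p + c(-0.5, 0, 0))
  }
  a2 <- rbind(a2[, c("atom_name", "element", "residue_number", "residue_name",
                     "chain_id")],
              do.call(rbind, ins_rows))
  xyz <- rbind(xyz, do.call(rbind, ins_xyz))
  # reorder within chains: insertions go between 80 and 81
  ord <- order(match(a2$chain_id, c("A", "B", "C", "D", "E", "F", "G", "H",
                                    "I", "J")),
               ifelse(a2$residue_number %in% c(9980L, 9981L),
                      80.25 + 0.25 * (a2$residue_number - 9980L),
                      a2$residue_number))
  a2 <- a2[ord, ]; xyz <- xyz[ord, , drop = FALSE]
  # contiguous renumbering of the variant chains (start 40, now 98 residues)
  for (ch in c("A", "E")) {
    sel <- a2$chain_id == ch
    res <- a2$residue_number[sel]
    a2$residue_number[sel] <- 39L + as.integer(factor(res, levels = unique(res)))
  }
  set.seed(seed + 1L)
  xyz <- xyz + matrix(rnorm(length(xyz), sd = 0.5), nrow(xyz), 3)
  R <- rot_z(0.7) %*% rot_x(0.3)
  xyz <- xyz %*% R + matrix(c(5, -3, 2), nrow(xyz), 3, byrow = TRUE)
  an2_sys <- molecular_system(a2, xyz)

  roles <- c(A = "H3-like", B = "H4", C = "H2A", D = "H2B",
             E = "H3-like'", F = "H4'", G = "H2A'", H = "H2B'",
             I = "DNA-I", J = "DNA-J")
  list(
    kx5_like = list(system = kx5$system, annotation = kx5$annotation),
    an2_like = list(system = an2_sys,
                    annotation = annotate_nucleosome(
                      an2_sys, roles,
                      regions = region_presets()))
  )
}
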