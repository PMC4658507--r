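# C-alpha PCA, projections, representative frames, mode animation,
# free-energy landscapes, basins and barriers

ca_sel <- function(sys) {
  ann <- annotate_nucleosome(sys, c(A = "H3-like"))
  select_sites(sys, ann, role = "H3-like", atom_class = "CA")
}

test_that("static trajectory gives all-zero eigenvalues; trace identity holds", {
  sys <- tiny_protein(c(A = 6L), seed = 1)
  static <- traj_from_frames(rep(list(sys$ref_coords), 5), sys)
  m <- fit_pca(static, ca_sel(sys))
  expect_equal(m$eigenvalues, rep(0, 18))

  traj <- gaussian_fluctuation_traj(sys, 0.5, 200, seed = 2)
  m2 <- fit_pca(traj, ca_sel(sys))
  X <- nucdyn:::.flatten_frames(traj, m2)
  total_var <- sum(apply(X, 2, var))
  expect_equal(sum(m2$eigenvalues), total_var, tolerance = 1e-6)
  # orthonormality
  G <- crossprod(m2$eigenvectors)
  expect_lt(max(abs(G - diag(ncol(G)))), 1e-8)
  # eigenvalues non-increasing
  expect_true(all(diff(m2$eigenvalues) <= 1e-12))
})

test_that("planted rank-1 and rank-2 modes are recovered", {
  sys <- tiny_protein(c(A = 10L), seed = 3)
  dof <- 3L * 10L
  set.seed(4)
  v <- rnorm(dof); v <- v / sqrt(sum(v^2))
  tr1 <- planted_mode_traj(sys, list(list(vector = v, variance = 4)),
                           n_frames = 3000, seed = 5)
  m1 <- fit_pca(tr1, ca_sel(sys))
  amps <- attr(tr1, "amplitudes")
  expect_equal(m1$eigenvalues[1], var(amps[, 1]), tolerance = 1e-8)
  planted <- attr(tr1, "modes")[, 1]
  expect_gt(abs(sum(m1$eigenvectors[, 1] * planted)), 0.999)
  expect_lt(m1$eigenvalues[2], 1e-10)

  tr2 <- planted_mode_traj(sys, list(list(variance = 4), list(variance = 1)),
                           n_frames = 4000, seed = 6, floor_sd = 0.02)
  m2 <- fit_pca(tr2, ca_sel(sys))
  expect_equal(m2$eigenvalues[1] / m2$eigenvalues[2], 4, tolerance = 0.2)
  expect_lt(subspace_angle_deg(attr(tr2, "modes"),
                               m2$eigenvectors[, 1:2]), 2)
})

test_that("covariance matches the brute-force double loop on toys", {
  for (rep in 1:3) {
    sys <- tiny_protein(c(A = 5L), seed = rep + 10)
    traj <- gaussian_fluctuation_traj(sys, 0.6, 40, seed = rep)
    m <- fit_pca(traj, ca_sel(sys))
    X <- nucdyn:::.flatten_frames(traj, m)
    C <- brute_covariance(X)
    ed <- eigen(C, symmetric = TRUE)
    expect_equal(m$eigenvalues, pmax(ed$values, 0), tolerance = 1e-8)
  }
})

test_that("projections: zero at the mean, orthonormal pull-back, variances", {
  sys <- tiny_protein(c(A = 8L), seed = 12)
  traj <- gaussian_fluctuation_traj(sys, 0.5, 500, seed = 13)
  m <- fit_pca(traj, ca_sel(sys))

  # a frame equal to the mean projects to zero; mean + 2 e1 projects to (2, 0)
  mk_frame <- function(flat) {
    tr <- traj
    tr$coords[1, , ] <- matrix(flat, n_atoms(sys), 3, byrow = TRUE)
    set_window(tr, 1L, 1L)
  }
  mu_flat <- as.numeric(t(m$mean_coords))
  expect_equal(as.numeric(project_frames(mk_frame(mu_flat), m, k = 2)),
               c(0, 0), tolerance = 1e-10)
  shifted <- mu_flat + 2 * m$eigenvectors[, 1]
  p <- as.numeric(project_frames(mk_frame(shifted), m, k = 3))
  expect_equal(p, c(2, 0, 0), tolerance = 1e-10)

  # variance of projection i equals eigenvalue i
  P <- project_frames(traj, m, k = 4)
  expect_equal(apply(P, 2, var), m$eigenvalues[1:4], tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(colMeans(P), rep(0, 4), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("representative_frame: exact hit, tie-break, brute-force scan", {
  sys <- tiny_protein(c(A = 5L), seed = 14)
  sel <- ca_sel(sys)
  c0 <- sys$ref_coords
  d <- matrix(0.5, 5, 3)
  # average of {c0+d, c0-d, c0} is c0, present as frame 3
  traj <- traj_from_frames(list(c0 + d, c0 - d, c0), sys)
  expect_equal(as.integer(representative_frame(traj, sel)), 3L)

  # two frames at +d / -d: tie -> earliest
  tie <- traj_from_frames(list(c0 + d, c0 - d), sys)
  expect_equal(as.integer(representative_frame(tie, sel)), 1L)

  set.seed(15)
  rnd <- gaussian_fluctuation_traj(sys, 0.8, 30, seed = 16)
  avg <- average_structure(rnd)
  oracle <- which.min(vapply(seq_len(30), function(f)
    coord_rmsd(rnd$coords[f, , ], avg), numeric(1)))
  expect_equal(as.integer(representative_frame(rnd, sel)), oracle)
})

test_that("mode_animation: base at s=0, sqrt(lambda) step, antisymmetry", {
  sys <- tiny_protein(c(A = 6L), seed = 17)
  v <- rnorm(18); v <- v / sqrt(sum(v^2))
  tr <- planted_mode_traj(sys, list(list(vector = v, variance = 2.25)),
                          n_frames = 500, seed = 18)
  m <- fit_pca(tr, ca_sel(sys))
  anim <- mode_animation(m, 1, scalars = c(-1, 0, 1))
  expect_equal(anim[2, , ], unname(m$mean_coords), ignore_attr = TRUE)
  disp <- anim[3, , ] - m$mean_coords
  expect_equal(sqrt(sum(disp^2)), sqrt(m$eigenvalues[1]), tolerance = 1e-10)
  expect_equal(anim[3, , ] - m$mean_coords,
               -(anim[1, , ] - m$mean_coords), ignore_attr = TRUE)
  expect_error(mode_animation(m, 10, scalars = 0), "zero eigenvalue")

  # multi-model PDB output has one MODEL per scalar
  path <- withr::local_tempfile(fileext = ".pdb")
  mode_animation(m, 1, scalars = seq(-5, 5, length.out = 21), system = sys,
                 path = path)
  expect_equal(sum(grepl("^MODEL", readLines(path))), 21L)
})

test_that("free_energy_landscape: degenerate, single-bin and density rules", {
  # all frames in one bin -> error (fewer than 2 occupied bins)
  one <- matrix(0, 500, 2)
  expect_error(free_energy_landscape(one), "fewer than 2")

  set.seed(19)
  P <- matrix(rnorm(2 * 5000), ncol = 2)
  fel <- free_energy_landscape(P, bins = 30)
  expect_equal(sum(fel$counts), 5000)
  expect_equal(min(fel$F[is.finite(fel$F)]), 0)
  expect_true(all(is.infinite(fel$F[fel$counts == 0])))

  # duplicating every frame leaves F unchanged
  fel2 <- free_energy_landscape(rbind(P, P),
                                bins = list(fel$edges$x, fel$edges$y))
  expect_equal(fel2$F, fel$F)
  expect_warning(free_energy_landscape(matrix(rnorm(80), ncol = 2)),
                 "fewer than 100")
})

test_that("basins: single Gaussian 1 basin; merging threshold behaviour", {
  set.seed(20)
  P <- matrix(rnorm(2 * 20000), ncol = 2)
  fel <- free_energy_landscape(P, bins = 25)
  bs <- find_basins(fel)
  expect_equal(nrow(bs$basins), 1L)
  expect_null(bs$barriers)
  expect_equal(bs$occupied_area,
               sum(is.finite(fel$F)) * diff(fel$edges$x[1:2]) *
                 diff(fel$edges$y[1:2]))

  # balanced two-Gaussian mixture: 2 basins at default depth, 1 when the
  # merge threshold exceeds the planted depth
  set.seed(21)
  x <- c(rnorm(30000, -3), rnorm(30000, 3))
  P2 <- cbind(x, rnorm(60000))
  fel2 <- free_energy_landscape(P2, bins = c(40, 12))
  bs2 <- find_basins(fel2, min_depth = 1)
  expect_equal(nrow(bs2$basins), 2L)
  expect_true(bs2$barriers$accessible[1])
  expect_gt(bs2$barriers$barrier[1], 1)
  bs_merged <- find_basins(fel2, min_depth = 99)
  expect_equal(nrow(bs_merged$basins), 1L)

  # barrier symmetry comes from construction: barrier(i,j) recorded once per
  # unordered pair, and it is non-negative
  expect_true(all(bs2$barriers$barrier >= 0))
})

test_that("FEL barriers are invariant to frame reordering", {
  set.seed(22)
  x <- c(rnorm(5000, -2.5), rnorm(5000, 2.5))
  P <- cbind(x, rnorm(10000))
  fel_a <- free_energy_landscape(P, bins = c(30, 10))
  perm <- sample(nrow(P))
  fel_b <- free_energy_landscape(P[perm, ],
                                 bins = list(fel_a$edges$x, fel_a$edges$y))
  expect_equal(fel_a$F, fel_b$F)
  ba <- find_basins(fel_a); bb <- find_basins(fel_b)
  expect_equal(ba$barriers$barrier, bb$barriers$barrier)
})

test_that("two-state trajectory maps to two basins on its top-2 PCs", {
  sys <- tiny_protein(c(A = 8L), seed = 23)
  off <- matrix(0, 8, 3); off[, 1] <- 1.2   # collective x shift
  tr <- two_state_traj(sys, off, p_switch = 0.15, n_frames = 4000,
                       seed = 24, floor_sd = 0.1)
  m <- fit_pca(tr, ca_sel(sys))
  P <- project_frames(tr, m, k = 2)
  fel <- free_energy_landscape(P, bins = c(40, 10))
  bs <- find_basins(fel, min_depth = 1)
  expect_equal(nrow(bs$basins), 2L)
  # PC1 captures the planted offset direction
  offdir <- as.numeric(t(off)); offdir <- offdir / sqrt(sum(offdir^2))
  expect_gt(abs(sum(m$eigenvectors[, 1] * offdir)), 0.99)
})
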