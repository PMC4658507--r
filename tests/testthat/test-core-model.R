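# structure/trajectory ingestion, annotation, selection

test_that("read_structure parses a hand-written PDB and assigns masses", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C",
    "ATOM      3  C   ALA A   1      10.729   6.817  -4.175  1.00  0.00           C",
    "ATOM      4  O   ALA A   1       9.580   7.113  -4.492  1.00  0.00           O",
    "END"), path)
  sys <- read_structure(path)
  expect_equal(n_atoms(sys), 4L)
  expect_equal(sys$atoms$mass, c(14.007, 12.011, 12.011, 15.999))
  expect_equal(sys$ref_coords[2, ], c(x = 11.639, y = 6.071, z = -5.147))
  expect_equal(sys$atoms$element, c("N", "C", "C", "O"))
})

test_that("element inference works without an element column", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00",
    "ATOM      3  P    DA I   1       0.000   0.000   0.000  1.00  0.00",
    "END"), path)
  sys <- read_structure(path)
  expect_equal(sys$atoms$element, c("N", "C", "P"))
})

test_that("duplicate (chain, resnum, atomname) is a uniqueness error", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  ALA A   1       1.000   0.000   0.000  1.00  0.00           C",
    "END"), path)
  expect_error(read_structure(path), "duplicate")
})

test_that("unreadable input and unknown elements produce informative errors", {
  expect_error(read_structure(tempfile(fileext = ".pdb")), "cannot read")
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines("REMARK nothing here", path)
  expect_error(read_structure(path), "no ATOM")
  expect_error(nucdyn:::element_mass("Xx"), "unknown element")
})

test_that("PDB write/read round-trip preserves identity and coordinates", {
  sys <- tiny_protein(c(A = 6L, B = 4L), seed = 3)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(sys, path)
  back <- read_structure(path)
  expect_equal(back$atoms$atom_name, sys$atoms$atom_name)
  expect_equal(back$atoms$chain_id, sys$atoms$chain_id)
  expect_equal(back$atoms$residue_number, sys$atoms$residue_number)
  expect_lt(max(abs(back$ref_coords - sys$ref_coords)), 1e-3)
})

test_that("multi-model PDB and DCD trajectories read back identically", {
  sys <- tiny_protein(c(A = 5L), seed = 4)
  frames <- lapply(1:3, function(f) sys$ref_coords + f)
  traj <- traj_from_frames(frames, sys)
  pdb <- withr::local_tempfile(fileext = ".pdb")
  write_structure(sys, pdb, coords = traj)
  tr_pdb <- read_trajectory(sys, pdb)
  expect_equal(n_frames(tr_pdb), 3L)
  expect_lt(max(abs(tr_pdb$coords - traj$coords)), 1e-3)

  dcd <- withr::local_tempfile(fileext = ".dcd")
  write_dcd(traj, dcd)
  tr_dcd <- read_trajectory(sys, dcd)
  expect_equal(n_frames(tr_dcd), 3L)
  expect_lt(max(abs(tr_dcd$coords - traj$coords)), 1e-5)  # float32 precision
})

test_that("trajectory windows: final-fraction arithmetic and error cases", {
  sys <- tiny_protein(c(A = 4L))
  frames <- lapply(1:10, function(f) sys$ref_coords + f)
  traj <- trajectory_segment(frames, system = sys)
  w <- window_final_fraction(traj, 0.4)
  expect_equal(w$window, c(7L, 10L))  # frames 6..9 zero-based
  expect_error(set_window(traj, 0, 5), "invalid")
  expect_error(set_window(traj, 3, 11), "invalid")
  expect_error(trajectory_segment(array(0, c(0, 4, 3))), "no frames")
  # atom-count mismatch names both counts
  expect_error(trajectory_segment(array(0, c(2, 3, 3)), system = sys),
               "3 atoms, system has 4")
  expect_error(trajectory_segment(array(0, c(2, 4, 3)), times = c(1, 1),
                                  system = sys), "strictly increasing")
})

test_that("basepair map: symmetric indices, pairing, involution", {
  toy <- build_toy_nucleosome(toy_nucleosome_spec(n_basepairs = 21L))
  bp <- toy$annotation$basepairs
  expect_equal(range(bp$bp), c(-10L, 10L))
  expect_equal(bp$bp[bp$strandI_pos == 11L], 0L)       # dyad at the midpoint
  # bp +1 -> strand-I nt 12 (1-based) paired with strand-J nt 10 (1-based)
  row <- bp[bp$bp == 1L, ]
  expect_equal(row$strandI_pos, 12L)
  expect_equal(row$strandJ_pos, 10L)
  # involution: partner(partner(i)) == i
  for (i in bp$strandI_pos) {
    expect_equal(basepair_partner(toy$annotation,
                                  basepair_partner(toy$annotation, i)), i)
  }
  # SHL is a derived label: bp / 10
  expect_equal(bp$shl[bp$bp == 10L], 1)
})

test_that("annotation rejects absent chains, bad regions, single DNA strand", {
  toy <- build_toy_nucleosome(toy_nucleosome_spec(n_basepairs = 0L))
  sys <- toy$system
  expect_error(annotate_nucleosome(sys, c(Z = "H3-like")), "absent")
  expect_error(
    annotate_nucleosome(sys, c(A = "H3-like"),
                        regions = data.frame(name = "x", role = "H3-like",
                                             start = 1L, end = 500L)),
    "outside")
  expect_error(annotate_nucleosome(sys, c(A = "DNA-I")), "both DNA strands")
  expect_error(annotate_nucleosome(sys, c(A = "H3-like", B = "H3-like")),
               "at most one")
})

test_that("select_sites: per-residue CA groups, heavy atoms, basepairs", {
  toy <- build_toy_nucleosome(toy_nucleosome_spec(n_basepairs = 21L))
  sys <- toy$system; ann <- toy$annotation
  ca <- select_sites(sys, ann, role = "H3-like", atom_class = "CA")
  expect_equal(length(ca$groups), 96L)            # residues 40..135
  expect_true(all(lengths(ca$groups) == 1L))

  bp2 <- select_sites(sys, ann, atom_class = "basepair", bp_range = 2L)
  expect_equal(length(bp2$groups), 1L)
  # group = heavy atoms of strand-I nt dyad+2 and its strand-J partner
  a <- sys$atoms
  row <- ann$basepairs[ann$basepairs$bp == 2L, ]
  expected <- which((a$chain_id == "I" & a$residue_number == row$strandI_res) |
                    (a$chain_id == "J" & a$residue_number == row$strandJ_res))
  expect_setequal(bp2$groups[[1]], expected)

  expect_error(select_sites(sys, ann, role = "H3-like", atom_class = "CA",
                            residues = 9999L), "empty selection")
  # region query
  loop <- select_sites(sys, ann, region = "loop1", atom_class = "CA")
  expect_equal(length(loop$groups), 7L)  # residues 78..84
})

test_that("selections are stable under atom reordering when keys survive", {
  toy <- build_toy_nucleosome(toy_nucleosome_spec(n_basepairs = 0L))
  sys <- toy$system
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(sys, path)
  lines <- readLines(path)
  atom_lines <- grep("^ATOM", lines, value = TRUE)
  set.seed(9)
  shuffled <- sample(atom_lines)
  path2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(shuffled, "END"), path2)
  sys2 <- read_structure(path2)
  ann1 <- annotate_nucleosome(sys, c(A = "H3-like"), regions = NULL)
  ann2 <- annotate_nucleosome(sys2, c(A = "H3-like"), regions = NULL)
  s1 <- select_sites(sys, ann1, role = "H3-like", atom_class = "CA")
  s2 <- select_sites(sys2, ann2, role = "H3-like", atom_class = "CA")
  key <- function(sys, sel) {
    idx <- nucdyn:::selection_atoms(sel)
    sort(paste(sys$atoms$chain_id[idx], sys$atoms$residue_number[idx],
               sys$atoms$atom_name[idx]))
  }
  expect_equal(key(sys2, s2), key(sys, s1))
})

test_that("altloc handling keeps A/blank and drops others", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA BALA A   1       9.000   9.000   9.000  1.00  0.00           C",
    "ATOM      3  CB  ALA A   1       1.000   0.000   0.000  1.00  0.00           C",
    "END"), path)
  sys <- read_structure(path)
  expect_equal(n_atoms(sys), 2L)
  expect_equal(sys$ref_coords[1, "x"], c(x = 0))
})
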