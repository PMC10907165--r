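test_that("a minimal hand-written PDB is echoed exactly", {
  m <- read_structure(write_lines_tmp(minimal_pdb_text(), ".pdb"))
  expect_equal(nrow(m$atoms), 3L)
  expect_equal(unique(m$atoms$chain), "A")
  expect_equal(m$atoms$elety, c("N", "CA", "C"))
  expect_equal(m$atoms$x, c(1.000, 2.458, 3.009))
  expect_equal(m$atoms$resid, rep("GLY", 3))
})

test_that("the same content parses identically from PDB and mmCIF", {
  m1 <- read_structure(write_lines_tmp(minimal_pdb_text(), ".pdb"))
  m2 <- read_structure(write_lines_tmp(minimal_cif_text(), ".cif"))
  expect_equal(m1$atoms, m2$atoms)
})

test_that("alternate locations resolve to the highest occupancy", {
  m <- read_structure(write_lines_tmp(altloc_pdb_text(), ".pdb"))
  natom <- m$atoms[m$atoms$elety == "N", ]
  expect_equal(nrow(natom), 1L)
  expect_equal(natom$alt, "B")
  expect_equal(natom$x, 5.0)
})

test_that("PDB writer round-trips models built in code", {
  fx <- cached_beta_pair("antiparallel", 5)
  p <- tempfile(fileext = ".pdb")
  write_structure_pdb(fx$model, p)
  back <- read_structure(p)
  expect_equal(nrow(back$atoms), nrow(fx$model$atoms))
  expect_equal(back$atoms$x, fx$model$atoms$x, tolerance = 1e-3)
  expect_equal(back$atoms$resno, fx$model$atoms$resno)
  expect_equal(sort(unique(back$atoms$chain)), c("A", "B"))
})

test_that("malformed and missing structure input is rejected with context", {
  expect_error(read_structure(tempfile(fileext = ".pdb")), "not found")
  empty <- write_lines_tmp("END", ".pdb")
  expect_error(read_structure(empty), "parse|empty")
})

test_that("kabsch_superpose is exact on identical and rigidly moved sets", {
  set.seed(31)
  X <- matrix(stats::rnorm(30, sd = 5), ncol = 3)
  sp <- kabsch_superpose(X, X)
  expect_equal(sp$rmsd, 0, tolerance = 1e-9)
  expect_equal(sp$rotation, diag(3), tolerance = 1e-9)
  for (k in 1:10) {
    tf <- random_rigid_transform()
    sp <- kabsch_superpose(X, apply_rigid(X, tf))
    expect_lt(sp$rmsd, 1e-6)
    expect_equal(det(sp$rotation), 1, tolerance = 1e-9)
  }
})

test_that("kabsch_superpose never returns a reflection even when one fits better", {
  set.seed(5)
  X <- matrix(stats::rnorm(24, sd = 4), ncol = 3)
  Y <- X %*% diag(c(1, 1, -1))       # mirrored set
  sp <- kabsch_superpose(X, Y)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-9)
  expect_gt(sp$rmsd, 0.1)
})

test_that("kabsch rmsd matches a brute-force rotation-grid oracle", {
  set.seed(13)
  X <- matrix(stats::rnorm(15, sd = 3), ncol = 3)
  Y <- X + matrix(stats::rnorm(15, sd = 0.5), ncol = 3)
  sp <- kabsch_superpose(X, Y)
  grid <- grid_superpose_rmsd(X, Y, n_steps = 36)
  # the optimum can never beat Kabsch; the 10-degree grid gets close to it
  expect_lte(sp$rmsd, grid + 1e-9)
  expect_lt(grid - sp$rmsd, 0.08)
})

test_that("kabsch input validation catches mismatch and degeneracy", {
  X <- matrix(stats::rnorm(12), ncol = 3)
  expect_error(kabsch_superpose(X, X[1:3, ]), "differ in length")
  expect_error(kabsch_superpose(X[1:2, ], X[1:2, ]), "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_warning(kabsch_superpose(line, line), "collinear")
})

test_that("complex_ca_rmsd is zero against itself and invariant to chain relabeling", {
  fx <- cached_recruitment_complex(7)
  m <- fx$model
  expect_lt(complex_ca_rmsd(m, m)$rmsd, 1e-9)

  # swap the two partner chain labels and rigidly move the copy
  m2 <- m
  m2$atoms$chain <- c(P = "P", A = "B", B = "A")[m2$atoms$chain]
  tf <- local({set.seed(8); random_rigid_transform()})
  m2 <- dboxr:::transform_model(m2, tf$R, tf$t)
  sp <- complex_ca_rmsd(m, m2)
  expect_lt(sp$rmsd, 1e-6)
  # chains A and B have identical sequences, so the mapping search must have
  # considered both assignments
  expect_gte(sp$mappings_tried, 2)
})

test_that("complex_ca_rmsd recovers a known deformation magnitude", {
  fx <- cached_beta_pair("antiparallel", 8)
  m <- fx$model
  m2 <- m
  set.seed(21)
  jit <- matrix(stats::rnorm(nrow(m2$atoms) * 3, sd = 0.3), ncol = 3)
  m2$atoms$x <- m2$atoms$x + jit[, 1]
  m2$atoms$y <- m2$atoms$y + jit[, 2]
  m2$atoms$z <- m2$atoms$z + jit[, 3]
  sp <- complex_ca_rmsd(m, m2)
  # rmsd ~ sigma * sqrt(3), reduced slightly by the 6 fitted dof
  expect_gt(sp$rmsd, 0.25)
  expect_lt(sp$rmsd, 0.3 * sqrt(3))
})

test_that("waters and hydrogens are retained but flagged on input", {
  pdb <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  H   ALA A   1       0.500   0.800   0.000  1.00  0.00           H",
    "ATOM      3  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "HETATM    4  O   HOH A 101       8.000   0.000   0.000  1.00  0.00           O",
    "END")
  m <- read_structure(write_lines_tmp(pdb, ".pdb"))
  expect_equal(nrow(m$atoms), 4L)
  expect_equal(sum(m$atoms$is_water), 1L)
  expect_equal(sum(m$atoms$is_hydrogen), 1L)
  # waters and hydrogens are excluded from SASA by default
  s <- compute_sasa(m)
  expect_equal(nrow(s$atoms), 2L)
  # residue table drops waters by default but can keep them
  expect_equal(nrow(residue_table(m)), 1L)
  expect_equal(nrow(residue_table(m, include_water = TRUE)), 2L)
})

test_that("structure_model validates its inputs", {
  expect_error(structure_model(data.frame(chain = "A")), "missing column")
  bad <- data.frame(chain = "A", resno = 1, resid = "ALA", elety = "CA",
                    x = NaN, y = 0, z = 0)
  expect_error(structure_model(bad), "non-finite")
  dup <- data.frame(chain = "A", resno = c(1, 1), resid = "ALA",
                    elety = c("CA", "CA"), x = c(0, 1), y = 0, z = 0)
  expect_error(structure_model(dup), "duplicate")
})
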