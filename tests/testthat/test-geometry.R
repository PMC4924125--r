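# Centers of mass, normalized distances, frame-averaged adjacency, grade.

test_that("center of mass matches hand-summed mass weighting", {
  path <- withr::local_tempfile(fileext = ".pdb")
  atoms <- data.frame(
    elety = c("N", "CA", "C", "O"),
    resid = "GLY", chain = "A", resno = 1L
  )
  coords <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(2.2, 1.3, 0), c(1.8, 2.4, 0.5))
  write_toy_pdb(path, atoms, list(coords))
  ens <- read_ensemble(path)

  m <- c(14.007, 12.011, 12.011, 15.999)
  expected <- colSums(coords * m) / sum(m)
  expect_equal(drop(node_com(ens, 1)), expected, tolerance = 1e-9)

  # equal masses at (0,0,0) and (2,0,0) -> midpoint
  path2 <- withr::local_tempfile(fileext = ".pdb")
  atoms2 <- data.frame(elety = c("C1", "C2"), resid = "GLY", chain = "A", resno = 1L)
  write_toy_pdb(path2, atoms2, list(rbind(c(0, 0, 0), c(2, 0, 0))))
  expect_equal(drop(node_com(read_ensemble(path2), 1)), c(1, 0, 0))
})

test_that("normalized distance follows the definition", {
  expect_equal(normalized_distance(c(0, 0, 0), c(7, 0, 0), 3, 4), 1.0)
  expect_equal(normalized_distance(c(1, 1, 1), c(1, 1, 1), 2, 2), 0)

  withr::with_seed(11, {
    for (rep in 1:20) {
      a <- rnorm(3); b <- rnorm(3); r1 <- runif(1, 1, 4); r2 <- runif(1, 1, 4)
      expect_equal(normalized_distance(a, b, r1, r2),
                   sqrt(sum((a - b)^2)) / (r1 + r2), tolerance = 1e-12)
    }
  })
})

test_that("two-frame adjacency arithmetic distinguishes the weight modes", {
  # one pair of single-atom nodes at normalized distances 1.0 and 3.0
  path <- withr::local_tempfile(fileext = ".pdb")
  atoms <- data.frame(elety = c("CA", "CA"), resid = c("GLY", "GLY"),
                      chain = "A", resno = c(1L, 2L))
  r2 <- 2 * vdw_radii()$radius[vdw_radii()$name == "GLY"]
  f1 <- rbind(c(0, 0, 0), c(r2 * 1.0, 0, 0))
  f2 <- rbind(c(0, 0, 0), c(r2 * 3.0, 0, 0))
  write_toy_pdb(path, atoms, list(f1, f2))
  ens <- read_ensemble(path)

  a_iom <- node_adjacency(ens, round_decimals = NULL)
  expect_equal(a_iom[1, 2], 1 / mean(c(1, 3)), tolerance = 1e-6)
  a_moi <- node_adjacency(ens, weight_mode = "mean-of-inverse",
                          round_decimals = NULL)
  expect_equal(a_moi[1, 2], mean(c(1, 1 / 3)), tolerance = 1e-6)
  # default rounding to 4 decimals, matching the weight construction
  a_round <- node_adjacency(ens)
  expect_equal(a_round[1, 2], round(a_iom[1, 2], 4))
})

test_that("adjacency equals the brute-force oracle on a random ensemble", {
  ens <- make_ensemble(5, "lattice", amplitudes = 1.0, n_frames = 10, seed = 21)
  for (mode in c("inverse-of-mean", "mean-of-inverse")) {
    a <- node_adjacency(ens, weight_mode = mode, round_decimals = NULL)
    o <- adjacency_oracle(ens, weight_mode = mode)
    expect_lt(max(abs(a - o)), 1e-9)
  }
})

test_that("adjacency is symmetric, zero-diagonal, and scales as 1/c under coordinate scaling", {
  ens <- make_ensemble(8, "helix", amplitudes = 0.6, n_frames = 6, seed = 5)
  a <- node_adjacency(ens, round_decimals = NULL)
  expect_equal(a, t(a))
  expect_equal(diag(a), rep(0, 8))
  expect_true(all(a[upper.tri(a)] > 0))

  scaled <- ens
  scaled$xyz <- ens$xyz * 2
  a2 <- node_adjacency(scaled, round_decimals = NULL)
  expect_equal(a2, a / 2, tolerance = 1e-10)
})

test_that("uniform geometry gives equal off-diagonal weights", {
  # equilateral triangle of identical single-atom nodes
  path <- withr::local_tempfile(fileext = ".pdb")
  atoms <- data.frame(elety = rep("CA", 3), resid = "GLY", chain = "A",
                      resno = 1:3)
  tri <- rbind(c(0, 0, 0), c(6, 0, 0), c(3, 3 * sqrt(3), 0))
  write_toy_pdb(path, atoms, list(tri, tri))
  a <- node_adjacency(read_ensemble(path), round_decimals = NULL)
  off <- a[upper.tri(a)]
  # PDB columns carry 3 decimals, so equality holds to that precision
  expect_lt(max(off) - min(off), 1e-4)
})

test_that("coincident centers of mass are a geometry error", {
  path <- withr::local_tempfile(fileext = ".pdb")
  atoms <- data.frame(elety = c("CA", "CA"), resid = "GLY", chain = "A",
                      resno = c(1L, 2L))
  same <- rbind(c(1, 1, 1), c(1, 1, 1))
  write_toy_pdb(path, atoms, list(same, same))
  expect_error(node_adjacency(read_ensemble(path)), "coincident")
})

test_that("grade honors the 5 A heavy-atom boundary inclusively", {
  atoms <- data.frame(elety = c("CA", "CA"), resid = c("GLY", "ALA"),
                      chain = "A", resno = c(1L, 2L))
  grade_at <- function(d) {
    path <- withr::local_tempfile(fileext = ".pdb")
    write_toy_pdb(path, atoms, list(rbind(c(0, 0, 0), c(d, 0, 0))))
    node_grade(read_ensemble(path))$grade
  }
  expect_equal(grade_at(4.99), c(1L, 1L))
  expect_equal(grade_at(5.00), c(1L, 1L))
  expect_equal(grade_at(5.01), c(0L, 0L))
  expect_error(node_grade(make_ensemble(4, "lattice", n_frames = 2, seed = 1),
                          cutoff = -1), "positive")
})

test_that("grade ignores hydrogens", {
  path <- withr::local_tempfile(fileext = ".pdb")
  # heavy atoms 6 A apart; hydrogens bridge at 2 A -- must not create an edge
  lines <- c(
    pdb_atom_line(1, "CA", "GLY", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "HA", "GLY", "A", 1, 2, 0, 0, elesy = "H"),
    pdb_atom_line(3, "CA", "ALA", "A", 2, 6, 0, 0),
    pdb_atom_line(4, "HA", "ALA", "A", 2, 4, 0, 0, elesy = "H"),
    "END"
  )
  writeLines(lines, path)
  expect_equal(node_grade(read_ensemble(path))$grade, c(0L, 0L))
})

test_that("grade matches the all-pairs brute-force oracle and is permutation-equivariant", {
  ens <- make_ensemble(30, "two-domain", n_frames = 3, seed = 13)
  g <- node_grade(ens, cutoff = 5)
  expect_identical(g$grade, as.integer(grade_oracle(ens, cutoff = 5)))

  # relabeling nodes (reversing the atom order residue-wise) permutes K
  rev_atoms_idx <- order(-ens$atoms$node, ens$atoms$eleno)
  atoms2 <- ens$atoms[rev_atoms_idx, c("type", "eleno", "elety", "alt", "resid",
                                       "chain", "resno", "insert", "o", "b",
                                       "element", "is_hydrogen")]
  xyz2 <- ens$xyz[, bio3d::atom2xyz(rev_atoms_idx), drop = FALSE]
  ens2 <- sdri:::new_ensemble(atoms2, xyz2)
  g2 <- node_grade(ens2, cutoff = 5)
  expect_identical(g2$grade, rev(g$grade))
})
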