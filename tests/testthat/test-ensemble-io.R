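# Reading, validating and writing multi-model ensembles.

test_that("a 2-model file yields the right nodes, frames and renumbering", {
  path <- withr::local_tempfile(fileext = ".pdb")
  coords1 <- rbind(c(0, 0, 0), c(4, 0, 0), c(8, 0, 0))
  coords2 <- coords1 + 0.5
  write_toy_pdb(path, toy_atoms_3res(resno = c(19L, 20L, 21L)),
                list(coords1, coords2))

  ens <- read_ensemble(path)
  expect_s3_class(ens, "sdri_ensemble")
  expect_equal(nrow(ens$nodes), 3L)
  expect_equal(ens$frame_count, 2L)
  # author numbering starting at 19 maps onto continuous indices 1..3
  expect_equal(ens$nodes$node, 1:3)
  expect_equal(ens$nodes$original_number, c(19L, 20L, 21L))
  expect_equal(ens$nodes$kind, rep("amino-acid", 3))

  mapping <- attr(renumber_nodes(ens), "renumbering")
  expect_equal(mapping$node, 1:3)
  expect_equal(mapping$original_number, c(19L, 20L, 21L))
})

test_that("waters are excluded and hetero entities obey the flag", {
  path <- withr::local_tempfile(fileext = ".pdb")
  atoms <- rbind(
    toy_atoms_3res(),
    data.frame(elety = "O", resid = "HOH", chain = "A", resno = 100L),
    data.frame(elety = "ZN", resid = "ZN", chain = "A", resno = 200L)
  )
  atoms$record <- c("ATOM  ", "ATOM  ", "ATOM  ", "HETATM", "HETATM")
  coords <- rbind(c(0, 0, 0), c(4, 0, 0), c(8, 0, 0), c(20, 0, 0), c(12, 0, 0))
  write_toy_pdb(path, atoms, list(coords, coords + 0.1))

  ens <- read_ensemble(path)
  expect_equal(nrow(ens$nodes), 3L)
  expect_false(any(ens$nodes$name %in% c("HOH", "ZN")))

  with_ions <- read_ensemble(path, include_hetero = TRUE)
  expect_equal(nrow(with_ions$nodes), 4L)
  expect_true("ZN" %in% with_ions$nodes$name)
  expect_false("HOH" %in% with_ions$nodes$name)
  expect_equal(with_ions$nodes$kind[with_ions$nodes$name == "ZN"], "hetero")
})

test_that("mismatched model topology is rejected with model and residue named", {
  path <- withr::local_tempfile(fileext = ".pdb")
  coords <- rbind(c(0, 0, 0), c(4, 0, 0), c(8, 0, 0))
  lines <- c(
    "MODEL        1",
    pdb_atom_line(1, "CA", "GLY", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CA", "ALA", "A", 2, 4, 0, 0),
    "ENDMDL",
    "MODEL        2",
    pdb_atom_line(1, "CA", "GLY", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CA", "SER", "A", 2, 4, 0, 0),
    "ENDMDL", "END"
  )
  writeLines(lines, path)
  expect_error(read_ensemble(path), "model 2.*SER|model 2.*atom 2")

  empty <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("MODEL        1", "ENDMDL", "END"), empty)
  expect_error(read_ensemble(empty), "no ATOM/HETATM records")
})

test_that("write/read round trip preserves topology and coordinates to 3 decimals", {
  ens <- make_ensemble(12, "lattice", amplitudes = 0.8, n_frames = 20, seed = 7)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble_pdb(ens, path)
  back <- read_ensemble(path)

  expect_equal(back$nodes$name, ens$nodes$name)
  expect_equal(back$nodes$node, ens$nodes$node)
  expect_equal(back$frame_count, ens$frame_count)
  expect_equal(back$atoms$elety, ens$atoms$elety)
  expect_lt(max(abs(back$xyz - ens$xyz)), 5e-4 + 1e-12)
})

test_that("altloc reduction keeps the highest-occupancy conformer", {
  path <- withr::local_tempfile(fileext = ".pdb")
  mk <- function(alt, occ, x) {
    sprintf("ATOM  %5d  %-3s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            1L, "CA", alt, "GLY", "A", 1L, x, 0, 0, occ, 0, "C")
  }
  writeLines(c(
    mk("A", 0.4, 1.0), mk("B", 0.6, 2.0),
    pdb_atom_line(2, "CA", "ALA", "A", 2, 9, 0, 0),
    "END"
  ), path)
  ens <- read_ensemble(path)
  expect_equal(nrow(ens$atoms), 2L)
  expect_equal(frame_coords(ens, 1)[1, 1], 2.0)  # occupancy 0.6 conformer wins
})

test_that("score tables round-trip and refuse degenerate input", {
  prof <- run_score(make_ensemble(10, "lattice", amplitudes = 0.5,
                                  n_frames = 10, seed = 3))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_score_table(prof, path)
  back <- read_score_table(path)
  expect_equal(nrow(back), 10L)
  expect_equal(back$sdri, prof$sdri, tolerance = 1e-12)
  expect_equal(back$rank, prof$rank)
  # metadata header is present as comments
  expect_true(any(grepl("^# weight_mode", readLines(path))))

  expect_error(write_score_table(prof[0, ], withr::local_tempfile()), "empty")
})

test_that("B-factor PDB carries scores scaled to 0-100 and round-trips coordinates", {
  ens <- make_ensemble(5, "lattice", amplitudes = 0.5, n_frames = 4, seed = 9)
  scores <- c(1, 0, 0.25, 0.5, 0.75)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_bfactor_pdb(ens, scores, frame = 2, path = path)

  back <- suppressWarnings(bio3d::read.pdb(path))
  expect_equal(unique(back$atom$b[back$atom$resno == 1]), 100.00)
  expect_equal(unique(back$atom$b[back$atom$resno == 2]), 0.00)
  expect_equal(unique(back$atom$b[back$atom$resno == 4]), 50.00)
  ref <- frame_coords(ens, 2)
  expect_lt(max(abs(as.matrix(back$atom[, c("x", "y", "z")]) - ref)), 5e-4 + 1e-12)

  expect_error(write_bfactor_pdb(ens, scores, frame = 99, path = path), "out of range")
  expect_error(write_bfactor_pdb(ens, scores * 2, frame = 1, path = path), "\\[0, 1\\]")
  expect_error(write_bfactor_pdb(ens, scores[-1], frame = 1, path = path), "does not match")
})

test_that("chain filtering rebuilds a continuously numbered sub-assembly", {
  path <- withr::local_tempfile(fileext = ".pdb")
  atoms <- data.frame(
    elety = rep("CA", 4),
    resid = rep("GLY", 4),
    chain = c("A", "A", "B", "B"),
    resno = c(1L, 2L, 1L, 2L)
  )
  coords <- rbind(c(0, 0, 0), c(4, 0, 0), c(0, 6, 0), c(4, 6, 0))
  write_toy_pdb(path, atoms, list(coords, coords + 0.2))
  ens <- read_ensemble(path)
  expect_equal(ens$nodes$node, 1:4)  # two chains concatenate into 1..4

  b_only <- filter_chains(ens, "B")
  expect_equal(b_only$nodes$node, 1:2)
  expect_equal(b_only$nodes$chain, c("B", "B"))
  expect_error(filter_chains(ens, "Z"), "no atoms")
})
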