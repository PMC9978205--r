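test_that("a single ATOM record parses into one chain, residue and atom", {
  line <- "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C"
  s <- parse_structure(line)
  atoms <- structure_atoms(s)
  expect_equal(nrow(atoms), 1L)
  expect_equal(atoms$name, "CA")
  expect_equal(atoms$resname, "ALA")
  expect_equal(atoms$chain, "A")
  expect_equal(unname(chain_lengths(s)), 1L)
  expect_equal(length(s$models), 1L)
})

test_that("multi-model files keep every model; model 1 is the default", {
  atom <- "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C"
  atom2 <- "ATOM      1  CA  ALA A   1       4.000   5.000   6.000  1.00  0.00           C"
  text <- paste(c("MODEL        1", atom, "ENDMDL",
                  "MODEL        2", atom2, "ENDMDL", "END"), collapse = "\n")
  s <- parse_structure(text)
  expect_equal(length(s$models), 2L)
  expect_equal(structure_atoms(s, model = 1)$x, 1)
  expect_equal(structure_atoms(s, model = 2)$x, 4)
})

test_that("parsing is the identity under write/reparse on all id fields", {
  s <- make_synthetic_complex(15, 6, seed = 7)
  s2 <- parse_structure(write_structure(s))
  a1 <- s$models[[1]]
  a2 <- s2$models[[1]]
  expect_equal(a2$chain, a1$chain)
  expect_equal(a2$resseq, a1$resseq)
  expect_equal(a2$name, a1$name)
  expect_equal(a2$resname, a1$resname)
  expect_equal(a2$element, a1$element)
  expect_equal(a2$x, round(a1$x, 3))
  expect_equal(a2$y, round(a1$y, 3))
  expect_equal(a2$z, round(a1$z, 3))
  # second write/parse cycle is exactly stable
  s3 <- parse_structure(write_structure(s2))
  expect_identical(s3$models[[1]], s2$models[[1]])
  expect_equal(s2$experiment, "xray")
  expect_equal(s2$resolution, 1.8)
})

test_that("chain selection emits only requested chains and conserves atoms", {
  s <- make_synthetic_complex(10, 4, seed = 3)
  only_a <- parse_structure(write_structure(s, chains = "A"))
  expect_equal(unique(structure_atoms(only_a)$chain), "A")
  n_a <- nrow(structure_atoms(only_a))
  n_b <- nrow(structure_atoms(parse_structure(write_structure(s, chains = "B"))))
  n_all <- nrow(structure_atoms(parse_structure(write_structure(s))))
  expect_equal(n_a + n_b, n_all)
  expect_error(write_structure(s, chains = character(0)), "empty")
  expect_error(write_structure(s, chains = "Z"), "not present")
})

test_that("zero parsable atoms is a hard error", {
  expect_error(parse_structure("HEADER    NOTHING\nEND"), "no ATOM/HETATM")
  expect_error(suppressWarnings(parse_structure("ATOM  truncated")), "no parsable")
})

test_that("waters are excluded and hydrogens retained but flagged", {
  text <- paste(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  H   ALA A   1       0.500   0.000   0.000  1.00  0.00           H",
    "HETATM    3  O   HOH A 101       5.000   5.000   5.000  1.00  0.00           O"
  ), collapse = "\n")
  s <- parse_structure(text)
  all_atoms <- structure_atoms(s, heavy_only = FALSE)
  expect_equal(nrow(all_atoms), 2L)
  expect_false(any(all_atoms$resname == "HOH"))
  expect_equal(sum(all_atoms$hydrogen), 1L)
  expect_equal(nrow(structure_atoms(s, heavy_only = TRUE)), 1L)
})

test_that("synthetic complexes are deterministic per seed with plausible geometry", {
  s1 <- make_synthetic_complex(60, 10, seed = 1)
  s2 <- make_synthetic_complex(60, 10, seed = 1)
  expect_identical(write_structure(s1), write_structure(s2))
  s3 <- make_synthetic_complex(60, 10, seed = 2)
  expect_false(identical(write_structure(s1), write_structure(s3)))

  a <- structure_atoms(s1, chains = "A")
  ca <- a[a$name == "CA", c("x", "y", "z")]
  steps <- sqrt(rowSums((ca[-1, ] - ca[-nrow(ca), ])^2))
  expect_true(all(steps >= 3.7 & steps <= 3.9))

  # peptide placed at the requested minimum distance from the protein
  b <- structure_atoms(s1, chains = "B")
  d <- min(as.matrix(dist(rbind(as.matrix(a[, c("x", "y", "z")]),
                                as.matrix(b[, c("x", "y", "z")]))))[
    seq_len(nrow(a)), nrow(a) + seq_len(nrow(b))])
  expect_lt(abs(d - 4), 0.25)
})

test_that("parsed atom tables agree with an independent PDB reader", {
  s <- make_synthetic_complex(12, 5, seed = 11)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s, path = path)
  ours <- structure_atoms(parse_structure(readLines(path)), heavy_only = FALSE)
  ref <- bio3d::read.pdb(path, verbose = FALSE)$atom
  expect_equal(nrow(ours), nrow(ref))
  expect_equal(ours$name, ref$elety)
  expect_equal(ours$resname, ref$resid)
  expect_equal(ours$chain, ref$chain)
  expect_equal(ours$resseq, ref$resno)
  expect_equal(ours$x, ref$x)
  expect_equal(ours$y, ref$y)
  expect_equal(ours$z, ref$z)
})

test_that("altloc duplicates collapse to the highest-occupancy conformer", {
  mk <- function(alt, occ, x) sprintf(
    "ATOM      1  CA %sALA A   1    %8.3f   0.000   0.000%6.2f  0.00           C",
    alt, x, occ)
  text <- paste(c(mk("A", 0.4, 1), mk("B", 0.6, 2)), collapse = "\n")
  s <- parse_structure(text)
  atoms <- structure_atoms(s)
  expect_equal(nrow(atoms), 1L)
  expect_equal(atoms$x, 2)  # occupancy 0.6 wins
  # tie broken alphabetically
  text2 <- paste(c(mk("B", 0.5, 2), mk("A", 0.5, 1)), collapse = "\n")
  expect_equal(structure_atoms(parse_structure(text2))$x, 1)
})
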