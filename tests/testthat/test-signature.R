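test_that("feature schema size follows 36 pairs x bin count", {
  expect_length(feature_schema(signature_params(0.2, 20)), 3600L)
  expect_length(feature_schema(signature_params(1, 5)), 180L)
  expect_length(feature_schema(signature_params(5, 5)), 36L)
  expect_error(signature_params(0.3, 20), "whole number")
  expect_error(signature_params(-1, 20))
  # pair order: alphabetical categories, cutoffs inner
  sch <- feature_schema(signature_params(1, 2))
  expect_equal(sch[1:2], c("acceptor:acceptor@1", "acceptor:acceptor@2"))
  expect_equal(sch[71:72], c("sulfide:sulfide@1", "sulfide:sulfide@2"))
})

test_that("distance matrix is Euclidean, symmetric and zero-diagonal", {
  d <- distance_matrix(rbind(c(0, 0, 0), c(3, 4, 0)))
  expect_equal(d, matrix(c(0, 5, 5, 0), 2))
  expect_equal(distance_matrix(matrix(c(1, 2, 3), 1)), matrix(0, 1, 1))
  ta <- random_typed_atoms(50, seed = 5)
  d50 <- distance_matrix(ta)
  coords <- as.matrix(ta$atoms[, c("x", "y", "z")])
  naive <- matrix(0, 50, 50)
  for (i in 1:50) for (j in 1:50) naive[i, j] <- sqrt(sum((coords[i, ] - coords[j, ])^2))
  expect_equal(d50, naive)
  expect_equal(d50, t(d50))
})

test_that("a single hydrophobic pair lands in the right cumulative bins", {
  cats <- atom_categories()
  m <- matrix(FALSE, 2, 8, dimnames = list(NULL, cats))
  m[, "hydrophobic"] <- TRUE
  ta <- random_typed_atoms(2, seed = 1)
  ta$categories <- m
  ta$atoms[, c("x", "y", "z")] <- rbind(c(0, 0, 0), c(2.5, 0, 0))
  sig <- compute_signature(ta, signature_params(1, 5))
  hh <- sig[paste0("hydrophobic:hydrophobic@", 1:5)]
  expect_equal(unname(hh), c(0L, 0L, 1L, 1L, 1L))
  expect_equal(sum(sig), 3L)  # nothing else anywhere
})

test_that("single-atom and empty inputs yield zero vectors", {
  ta <- random_typed_atoms(1, seed = 1)
  sig <- compute_signature(ta)
  expect_length(sig, 3600L)
  expect_true(all(sig == 0L))
  ta0 <- random_typed_atoms(2, seed = 1)
  ta0$atoms <- ta0$atoms[0, ]
  ta0$categories <- ta0$categories[0, , drop = FALSE]
  expect_warning(sig0 <- compute_signature(ta0), "empty")
  expect_true(all(sig0 == 0L))
})

test_that("signatures agree feature-for-feature with the naive triple-loop oracle", {
  params <- signature_params(1.5, 15)
  for (seed in c(2, 9)) {
    ta <- random_typed_atoms(30, seed = seed)
    coords <- as.matrix(ta$atoms[, c("x", "y", "z")])
    sig <- compute_signature(ta, params)
    oracle <- naive_signature(coords, ta$categories, 1.5, 15, "cumulative")
    expect_equal(as.integer(oracle[names(sig)]), as.integer(sig))
    sig_int <- compute_signature(ta, signature_params(1.5, 15, mode = "interval"))
    oracle_int <- naive_signature(coords, ta$categories, 1.5, 15, "interval")
    expect_equal(as.integer(oracle_int[names(sig_int)]), as.integer(sig_int))
  }
})

test_that("interval series accumulate to the cumulative series", {
  ta <- random_typed_atoms(40, seed = 4)
  cum <- compute_signature(ta, signature_params(0.5, 10))
  itv <- compute_signature(ta, signature_params(0.5, 10, mode = "interval"))
  nb <- 20L
  for (p in seq_len(36L)) {
    idx <- ((p - 1L) * nb + 1L):(p * nb)
    expect_equal(cumsum(as.integer(itv[idx])), as.integer(cum[idx]))
  }
})

test_that("signatures are invariant under rigid motions", {
  s <- make_synthetic_complex(30, 10, seed = 6)
  typed <- assign_types(s, chains = "B")
  ref <- compute_signature(typed, signature_params())
  for (seed in 1:5) {
    moved <- apply_rigid_motion(typed, random_rotation(seed),
                                runif(3, -50, 50))
    expect_identical(as.integer(compute_signature(moved, signature_params())),
                     as.integer(ref))
  }
})

test_that("cumulative series are monotone and bounded by n(n-1)/2", {
  ta <- random_typed_atoms(25, seed = 8)
  sig <- compute_signature(ta, signature_params(0.5, 10))
  nb <- 20L
  n <- 25
  for (p in seq_len(36L)) {
    series <- as.integer(sig[((p - 1L) * nb + 1L):(p * nb)])
    expect_true(all(diff(series) >= 0))
  }
  expect_true(all(sig <= n * (n - 1) / 2))
})

test_that("signature CSV round-trips exactly with the id + features layout", {
  s <- make_synthetic_complex(25, 8, seed = 12)
  rows <- list(chain_signature(s, "B"),
               chain_signature(s, "A"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_signature_csv(rows, path)
  header <- strsplit(readLines(path, n = 1), ",")[[1]]
  expect_length(header, 3601L)
  expect_equal(header[1], "id")
  back <- read_signature_csv(path)
  expect_equal(back$ids, c("SYNT_B", "SYNT_A"))
  expect_equal(back$values[1, ], setNames(as.integer(rows[[1]]), names(rows[[1]])))
  expect_equal(unname(back$values[2, ]), as.integer(rows[[2]]))

  # empty dataset: header-only file
  write_signature_csv(list(), path)
  expect_length(readLines(path), 1L)

  # mixed schemas refuse to serialize
  bad <- list(rows[[1]], compute_signature(random_typed_atoms(3, 1),
                                           signature_params(1, 5)))
  expect_error(write_signature_csv(bad, path), "mixed")
})
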