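# Independent oracles and small builders shared across test files.
# The oracles deliberately re-derive everything from first principles
# (explicit loops, no reuse of package internals beyond public builders).

# Naive triple-loop cutoff-scan signature: for every atom pair, every
# category pair and every bin, test the membership condition directly.
# Returns a named vector; names follow the "c1:c2@cutoff" convention so
# comparisons are order-independent.
naive_signature <- function(coords, catmat, step, limit,
                            mode = c("cumulative", "interval")) {
  mode <- match.arg(mode)
  cats <- sort(colnames(catmat))
  nb <- round(limit / step)
  out <- c()
  for (a in seq_along(cats)) {
    for (b in a:length(cats)) {
      c1 <- cats[a]; c2 <- cats[b]
      for (k in 1:nb) {
        cnt <- 0L
        n <- nrow(coords)
        if (n >= 2) {
          for (i in 1:(n - 1)) {
            for (j in (i + 1):n) {
              d <- sqrt(sum((coords[i, ] - coords[j, ])^2))
              match_cat <- (catmat[i, c1] && catmat[j, c2]) ||
                (catmat[i, c2] && catmat[j, c1])
              in_bin <- if (mode == "cumulative") d <= k * step
                else d <= k * step && d > (k - 1) * step
              if (match_cat && in_bin) cnt <- cnt + 1L
            }
          }
        }
        out[paste0(c1, ":", c2, "@", as.character(round(k * step, 9)))] <- cnt
      }
    }
  }
  out
}

# A typed_atoms object with random coordinates and random multi-label
# categories (1-3 categories per atom), built directly.
random_typed_atoms <- function(n, seed, box = 15) {
  set.seed(seed)
  coords <- matrix(runif(n * 3, 0, box), n, 3)
  cats <- atom_categories()
  m <- matrix(FALSE, n, length(cats), dimnames = list(NULL, cats))
  for (i in seq_len(n)) m[i, sample(cats, sample(1:3, 1))] <- TRUE
  atoms <- data.frame(
    serial = seq_len(n), name = "CA", altloc = " ", resname = "ALA",
    chain = "B", resseq = seq_len(n), icode = " ",
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    occupancy = 1, element = "C", het = FALSE, hydrogen = FALSE
  )
  structure(list(atoms = atoms, categories = m, n_untyped = 0L),
            class = "typed_atoms")
}

# Uniform random rotation matrix (QR of a gaussian matrix, det +1).
random_rotation <- function(seed) {
  set.seed(seed)
  qr_dec <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_dec)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

apply_rigid_motion <- function(typed, rotation, translation) {
  coords <- as.matrix(typed$atoms[, c("x", "y", "z")])
  moved <- sweep(coords %*% t(rotation), 2, translation, "+")
  typed$atoms[, c("x", "y", "z")] <- moved
  typed
}

# Minimal single-chain atom data.frame (for interface tests).
point_chain <- function(chain, coords, name = "CA", resname = "ALA") {
  coords <- matrix(coords, ncol = 3)
  data.frame(
    serial = seq_len(nrow(coords)), name = name, altloc = " ",
    resname = resname, chain = chain, resseq = seq_len(nrow(coords)),
    icode = " ", x = coords[, 1], y = coords[, 2], z = coords[, 3],
    occupancy = 1, element = substr(name, 1, 1), het = FALSE, hydrogen = FALSE
  )
}
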