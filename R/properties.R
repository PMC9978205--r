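# Per-entry physicochemical metadata: sequence statistics, isoelectric
# point, and solvent-accessible / buried surface areas.

check_sequence <- function(seq, min_len = 1L) {
  stopifnot(is.character(seq), length(seq) == 1L)
  letters <- strsplit(seq, "")[[1]]
  if (length(letters) < min_len) {
    stop(sprintf("sequence must have at least %d residue(s)", min_len))
  }
  bad <- which(!(letters %in% names(.RESIDUE_MASS)))
  if (length(bad)) {
    stop(sprintf("unknown residue letter '%s' at position %d", letters[bad[1]], bad[1]))
  }
  letters
}

#' Molecular weight of a peptide sequence
#'
#' Sum of average residue masses plus one water (the free peptide).
#'
#' @param seq One-letter sequence over the 20 standard residues.
#' @return Mass in daltons.
#' @export
molecular_weight <- function(seq) {
  letters <- check_sequence(seq)
  sum(.RESIDUE_MASS[letters]) + .WATER_MASS
}

#' Aromaticity of a peptide sequence
#'
#' Relative frequency of Phe, Trp and Tyr (the Lobry-Gautier definition).
#'
#' @inheritParams molecular_weight
#' @return Fraction in \[0, 1\].
#' @export
aromaticity <- function(seq) {
  letters <- check_sequence(seq)
  mean(letters %in% c("F", "W", "Y"))
}

#' Fraction of hydrophobic residues
#'
#' @inheritParams molecular_weight
#' @param hydrophobic_set Residues counted as hydrophobic; the default
#'   \{A, V, L, I, P, F, M, W\} is the Kyte-Doolittle positive set.
#' @return Fraction in \[0, 1\].
#' @export
hydrophobic_fraction <- function(seq, hydrophobic_set = c("A", "V", "L", "I",
                                                          "P", "F", "M", "W")) {
  letters <- check_sequence(seq)
  mean(letters %in% hydrophobic_set)
}

load_diwv <- function() {
  cached <- get0("diwv", envir = .pepsigna_cache)
  if (!is.null(cached)) return(cached)
  path <- system.file("extdata", "diwv.tsv", package = "pepsigna", mustWork = TRUE)
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  assign("diwv", m, envir = .pepsigna_cache)
  m
}

#' Guruprasad instability index
#'
#' `(10 / L) * sum of DIWV(x_i, x_{i+1})` over consecutive residue pairs,
#' with the published dipeptide instability weights shipped as package
#' data. Values above 40 predict in-vitro instability.
#'
#' @inheritParams molecular_weight
#' @return Dimensionless index.
#' @export
instability_index <- function(seq) {
  letters <- check_sequence(seq, min_len = 2L)
  diwv <- load_diwv()
  L <- length(letters)
  i <- seq_len(L - 1L)
  (10 / L) * sum(diwv[cbind(letters[i], letters[i + 1L])])
}

load_pka <- function() {
  cached <- get0("pka", envir = .pepsigna_cache)
  if (!is.null(cached)) return(cached)
  path <- system.file("extdata", "pka_emboss.tsv", package = "pepsigna", mustWork = TRUE)
  df <- utils::read.delim(path, comment.char = "#")
  assign("pka", df, envir = .pepsigna_cache)
  df
}

#' Net charge of a peptide at a given pH
#'
#' Henderson-Hasselbalch over the free termini and the ionizable side
#' chains (D, E, C, Y, H, K, R) with the EMBOSS pKa set (packaged data).
#'
#' @inheritParams molecular_weight
#' @param pH pH value (scalar or vector).
#' @return Net charge in elementary units, vectorized over `pH`.
#' @export
net_charge <- function(seq, pH) {
  letters <- check_sequence(seq)
  pka <- load_pka()
  counts <- structure(numeric(nrow(pka)), names = pka$group)
  counts[c("Nterm", "Cterm")] <- 1
  side <- table(letters)
  shared <- intersect(names(side), pka$group)
  counts[shared] <- counts[shared] + as.numeric(side[shared])
  vapply(pH, function(p) {
    pos <- pka$sign == 1
    sum(counts[pos] / (1 + 10^(p - pka$pka[pos]))) -
      sum(counts[!pos] / (1 + 10^(pka$pka[!pos] - p)))
  }, numeric(1))
}

#' Isoelectric point
#'
#' pH at which [net_charge()] is zero, found by bisection on \[0, 14\] to
#' a charge tolerance of 1e-3.
#'
#' @inheritParams molecular_weight
#' @return pH units.
#' @export
isoelectric_point <- function(seq) {
  lo <- 0; hi <- 14
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (net_charge(seq, mid) > 0) lo <- mid else hi <- mid
  }
  mid
}

# Van der Waals radii (angstroms) by element for SASA.
.VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20,
                D = 1.20, SE = 1.90)
.VDW_DEFAULT <- 1.70

# Deterministic quasi-uniform points on the unit sphere (Fibonacci lattice).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Numeric SASA over heavy atoms: each atom's solvent-accessible sphere
#' (van der Waals radius + probe) is sampled on a fixed Fibonacci lattice
#' and the accessible fraction is the share of lattice points outside all
#' neighbouring spheres. Deterministic for a fixed `n_points`.
#'
#' @param s A `pdb_structure` or an atom data.frame.
#' @param probe Probe radius in angstroms (default 1.4, water).
#' @param n_points Lattice points per atom (default 960).
#' @param chains Optional chain restriction.
#' @param model Model number (default 1).
#' @return Numeric vector of per-atom areas in square angstroms (sums to
#'   the total SASA).
#' @export
sasa <- function(s, probe = 1.4, n_points = 960L, chains = NULL, model = 1L) {
  atoms <- if (inherits(s, "pdb_structure")) {
    structure_atoms(s, model, chains = chains, heavy_only = TRUE)
  } else {
    a <- s
    if (!is.null(chains)) a <- a[a$chain %in% chains, , drop = FALSE]
    a[!a$hydrogen, , drop = FALSE]
  }
  n <- nrow(atoms)
  stopifnot(n >= 1)
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  radii <- .VDW_RADII[atoms$element]
  radii[is.na(radii)] <- .VDW_DEFAULT
  rs <- radii + probe
  sphere <- fibonacci_sphere(n_points)
  d <- cross_distances(coords, coords)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(d[i, ] < rs[i] + rs & seq_len(n) != i)
    pts <- sweep(sphere * rs[i], 2, coords[i, ], "+")
    if (length(nb)) {
      buried <- rep(FALSE, n_points)
      for (j in nb) {
        dj <- sqrt(colSums((t(pts) - coords[j, ])^2))
        buried <- buried | dj < rs[j]
        if (all(buried)) break
      }
      acc <- sum(!buried)
    } else {
      acc <- n_points
    }
    out[i] <- 4 * pi * rs[i]^2 * acc / n_points
  }
  out
}

#' Buried surface area of a peptide-protein complex
#'
#' `SASA(protein alone) + SASA(peptide alone) - SASA(complex)`: the
#' solvent-accessible area lost on complex formation. Reported as the
#' total and as the conventional per-side value (half the total).
#'
#' @param complex A `pdb_structure` containing both chains.
#' @param protein_chain,peptide_chain Chain ids.
#' @inheritParams sasa
#' @return List with `bsa_total` and `bsa_per_side` (square angstroms).
#' @export
binding_area <- function(complex, protein_chain, peptide_chain,
                         probe = 1.4, n_points = 960L, model = 1L) {
  a_prot <- sum(sasa(complex, probe, n_points, chains = protein_chain, model = model))
  a_pept <- sum(sasa(complex, probe, n_points, chains = peptide_chain, model = model))
  a_both <- sum(sasa(complex, probe, n_points,
                     chains = c(protein_chain, peptide_chain), model = model))
  total <- a_prot + a_pept - a_both
  list(bsa_total = total, bsa_per_side = total / 2)
}

#' All peptide properties of a complex entry
#'
#' @param complex A `pdb_structure`.
#' @param entry A `complex_entry` (see [enumerate_entries()]).
#' @inheritParams sasa
#' @return One-row data.frame with columns entry_id, sequence, length,
#'   mw, aromaticity, instability, pi, hydrophobic_frac, bsa_total,
#'   bsa_per_side.
#' @export
peptide_properties <- function(complex, entry, probe = 1.4, n_points = 960L,
                               model = 1L) {
  seq <- chain_sequence(complex, entry$peptide_chain, model)
  bsa <- binding_area(complex, entry$protein_chain, entry$peptide_chain,
                      probe, n_points, model)
  data.frame(
    entry_id = entry$entry_id,
    sequence = seq,
    length = nchar(seq),
    mw = molecular_weight(seq),
    aromaticity = aromaticity(seq),
    instability = if (nchar(seq) >= 2) instability_index(seq) else NA_real_,
    pi = isoelectric_point(seq),
    hydrophobic_frac = hydrophobic_fraction(seq),
    bsa_total = bsa$bsa_total,
    bsa_per_side = bsa$bsa_per_side,
    stringsAsFactors = FALSE
  )
}
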