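# Synthetic-input generators: labeled signature datasets with controllable
# class separation, boundary-case structure corpora, malformed-file corpora.

#' Specification of a labeled signature fixture
#'
#' @param n_classes Number of classes.
#' @param peptides_per_class Members per class (scalar or vector of length
#'   `n_classes`).
#' @param length_range Peptide length bounds (residues); each class draws
#'   one template length from this range.
#' @param sigma Isotropic Gaussian coordinate noise (angstroms) applied to
#'   each member around its class template.
#' @param seed Integer seed; generation is fully deterministic per seed.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_classes = 3L, peptides_per_class = 20L,
                         length_range = c(8L, 16L), sigma = 0.1, seed = 1L) {
  stopifnot(n_classes >= 1, sigma >= 0, length_range[1] >= 2,
            length_range[2] >= length_range[1])
  sizes <- rep_len(as.integer(peptides_per_class), n_classes)
  structure(
    list(n_classes = as.integer(n_classes), class_sizes = sizes,
         length_range = as.integer(length_range), sigma = sigma,
         seed = as.integer(seed)),
    class = "fixture_spec"
  )
}

# One template peptide structure per class: distinct random sequence,
# length and backbone wander, so class signal lives in both the geometry
# and the atom-category channels.
make_class_templates <- function(spec) {
  lapply(seq_len(spec$n_classes), function(cl) {
    make_synthetic_structure(
      list(list(chain = "B",
                n_res = sample(seq(spec$length_range[1], spec$length_range[2]), 1))),
      seed = spec$seed * 1000L + cl,
      pdb_id = sprintf("SY%02d", cl %% 100)
    )
  })
}

#' Generate a labeled signature dataset
#'
#' Builds one template peptide conformation per class, derives each class
#' member by adding isotropic Gaussian coordinate noise (`sigma`) to the
#' template, computes every member's aCSM-ALL signature and attaches the
#' class labels. With `sigma = 0` all members of a class share one
#' signature; increasing `sigma` degrades class separability.
#'
#' @param spec A `fixture_spec`.
#' @param params Signature parameters (default: package defaults).
#' @return List with `dataset` (a `labeled_dataset`) and `templates`
#'   (the per-class template `pdb_structure`s).
#' @export
make_labeled_signature_dataset <- function(spec = fixture_spec(),
                                           params = signature_params()) {
  stopifnot(inherits(spec, "fixture_spec"))
  templates <- make_class_templates(spec)
  ids <- character(0); labels <- character(0); rows <- list()
  with_seed(spec$seed, {
    for (cl in seq_len(spec$n_classes)) {
      tmpl <- templates[[cl]]
      typed0 <- assign_types(tmpl, chains = "B")
      coords <- as.matrix(typed0$atoms[, c("x", "y", "z")])
      for (m in seq_len(spec$class_sizes[cl])) {
        typed <- typed0
        noise <- matrix(stats::rnorm(length(coords), sd = spec$sigma),
                        nrow(coords), 3)
        typed$atoms[, c("x", "y", "z")] <- coords + noise
        id <- sprintf("%s%03d_B", tmpl$pdb_id, m)
        rows[[length(rows) + 1L]] <- compute_signature(typed, params, id = id)
        ids <- c(ids, id)
        labels <- c(labels, sprintf("C%d", cl))
      }
    }
  })
  x <- do.call(rbind, lapply(rows, as.integer))
  colnames(x) <- names(rows[[1]])
  list(dataset = labeled_dataset(ids, x, labels), templates = templates)
}

#' Case-study fixture presets
#'
#' `"case-study-1"` emulates, at desk scale, a five-class size-imbalanced
#' sequence-cluster dataset: class sizes proportional to
#' 503:183:161:142:122 scaled to about `n_total` peptides, coordinate
#' noise 0.1 angstroms around well-separated class templates.
#'
#' @param preset Preset name (only `"case-study-1"`).
#' @param seed Integer seed.
#' @param n_total Approximate total number of peptides (default 250).
#' @return A `fixture_spec`.
#' @export
case_study_fixture <- function(preset = "case-study-1", seed = 1L,
                               n_total = 250L) {
  preset <- match.arg(preset)
  proportions <- c(503, 183, 161, 142, 122)
  sizes <- pmax(2L, as.integer(round(proportions * n_total / sum(proportions))))
  fixture_spec(n_classes = 5L, peptides_per_class = sizes,
               length_range = c(8L, 16L), sigma = 0.1, seed = seed)
}

#' Deterministic corpus of malformed and edge-case PDB files
#'
#' Covers truncated atom records, blank element columns, altloc
#' duplicates, interleaved garbage lines and multi-model files. The
#' parser must handle every member with at most record-level warnings.
#'
#' @param seed Integer seed.
#' @return Named list of PDB-format strings.
#' @export
make_malformed_corpus <- function(seed = 1L) {
  base <- write_structure(make_synthetic_complex(5, 3, seed = seed))
  lines <- strsplit(base, "\n")[[1]]
  atom_idx <- grep("^ATOM", lines)

  truncate_line <- function(ls, i, at) {
    ls[i] <- substr(ls[i], 1, at)
    ls
  }
  no_element <- vapply(lines, function(l) {
    if (startsWith(l, "ATOM")) substr(l, 1, 66) else l
  }, character(1), USE.NAMES = FALSE)

  altloc_dup <- lines
  first_atom <- altloc_dup[atom_idx[1]]
  a_conf <- first_atom
  substr(a_conf, 17, 17) <- "A"
  substr(a_conf, 55, 60) <- "  0.60"
  b_conf <- first_atom
  substr(b_conf, 17, 17) <- "B"
  substr(b_conf, 55, 60) <- "  0.40"
  altloc_dup <- append(altloc_dup[-atom_idx[1]], c(a_conf, b_conf),
                       after = atom_idx[1] - 1L)

  model_lines <- c("MODEL        1", lines[atom_idx], "ENDMDL",
                   "MODEL        2", lines[atom_idx], "ENDMDL", "END")

  garbage <- append(lines, c("JUNK RECORD", "ATOM  bad"), after = atom_idx[2])

  list(
    truncated = paste(truncate_line(lines, atom_idx[1], 40), collapse = "\n"),
    no_element = paste(no_element, collapse = "\n"),
    altloc_duplicates = paste(altloc_dup, collapse = "\n"),
    multi_model = paste(model_lines, collapse = "\n"),
    garbage_records = paste(garbage, collapse = "\n")
  )
}

#' Corpus of structures spanning the collection-criteria boundaries
#'
#' Fifty deterministic synthetic structures crossing the filter
#' boundaries: shortest-chain lengths 1, 2, 50 and 51, single- versus
#' two-chain files, X-ray resolutions on both sides of the threshold and
#' NMR entries, each annotated with the ground-truth filter outcome.
#'
#' @param seed Integer seed.
#' @param n Corpus size (default 50).
#' @return List of records: `structure`, `expect_pass` (logical),
#'   `expect_kinds` (named character vector of ground-truth chain kinds).
#' @export
make_criteria_corpus <- function(seed = 1L, n = 50L) {
  boundary_lens <- c(1L, 2L, 50L, 51L)
  corpus <- vector("list", n)
  for (i in seq_len(n)) {
    len <- boundary_lens[(i - 1L) %% 4L + 1L]
    two_chain <- (i %% 2L) == 0L
    variant <- ((i - 1L) %/% 8L) %% 3L
    experiment <- c("xray", "xray", "nmr")[variant + 1L]
    resolution <- c(1.8, 3.2, NA_real_)[variant + 1L]

    chain_spec <- list(list(chain = "B", n_res = len, origin = c(0, 12, 0)))
    if (two_chain) {
      chain_spec <- c(list(list(chain = "A", n_res = 60L)), chain_spec)
    }
    s <- make_synthetic_structure(chain_spec, seed = seed * 100L + i,
                                  experiment = experiment,
                                  resolution = resolution)

    kind_b <- if (len >= 2L && len <= 50L) "peptide"
      else if (len > 50L) "protein" else "other"
    expect_kinds <- if (two_chain) c(A = "protein", B = kind_b)
      else c(B = kind_b)
    has_peptide <- any(expect_kinds == "peptide")
    exp_ok <- experiment == "nmr" || (!is.na(resolution) && resolution <= 2.5)
    corpus[[i]] <- list(
      structure = s,
      expect_pass = two_chain && has_peptide && exp_ok,
      expect_kinds = expect_kinds
    )
  }
  corpus
}

#' Materialize a fixture preset on disk
#'
#' Writes one PDB file per peptide (template plus noise) and a
#' tab-separated label table (`peptide_id<TAB>class`), plus the signature
#' CSV of the whole set.
#'
#' @param spec A `fixture_spec` (e.g. from [case_study_fixture()]).
#' @param outdir Output directory.
#' @param params Signature parameters.
#' @return Paths of the signature CSV and label table, invisibly.
#' @export
write_fixture_files <- function(spec, outdir, params = signature_params()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  made <- make_labeled_signature_dataset(spec, params)
  d <- made$dataset
  sig_rows <- lapply(seq_along(d$ids), function(i) {
    structure(as.integer(d$x[i, ]), names = colnames(d$x), id = d$ids[i],
              params = params, class = "signature_vector")
  })
  sig_path <- file.path(outdir, "signatures.csv")
  write_signature_csv(sig_rows, sig_path)
  lab_path <- file.path(outdir, "labels.tsv")
  utils::write.table(
    data.frame(peptide_id = d$ids, class = as.character(d$y)),
    lab_path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(list(signatures = sig_path, labels = lab_path))
}
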