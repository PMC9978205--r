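# Cutoff-scanning (aCSM-ALL) structural signatures: counts of atom pairs,
# stratified by unordered pharmacophore category pair, at each distance
# cutoff k * step up to the cutoff limit.

#' Signature parameters
#'
#' @param cutoff_step Distance increment in angstroms (default 0.2).
#' @param cutoff_limit Maximum distance in angstroms (default 20).
#' @param mode `"cumulative"` (feature at cutoff c counts all pairs with
#'   distance <= c; the cutoff-scanning default) or `"interval"` (pairs in
#'   the half-open band ((k-1)*step, k*step]). The two encodings are
#'   linearly inter-convertible.
#' @return A `signature_params` list with an `algorithm` label `"acsm_all"`.
#' @export
signature_params <- function(cutoff_step = 0.2, cutoff_limit = 20,
                             mode = c("cumulative", "interval")) {
  mode <- match.arg(mode)
  stopifnot(cutoff_step > 0, cutoff_step <= cutoff_limit)
  nb <- cutoff_limit / cutoff_step
  if (abs(nb - round(nb)) > 1e-9) {
    stop("cutoff_limit must be a whole number of cutoff_step bins")
  }
  structure(
    list(cutoff_step = cutoff_step, cutoff_limit = cutoff_limit,
         mode = mode, algorithm = "acsm_all", n_bins = as.integer(round(nb))),
    class = "signature_params"
  )
}

# The 36 unordered category pairs (with repetition) over the 8 ordered
# categories, as a 2-column character matrix.
category_pairs <- function() {
  cats <- atom_categories()
  idx <- which(upper.tri(diag(length(cats)), diag = TRUE), arr.ind = TRUE)
  idx <- idx[order(idx[, "row"], idx[, "col"]), , drop = FALSE]
  cbind(cats[idx[, "row"]], cats[idx[, "col"]])
}

#' Ordered feature names of a signature
#'
#' Category pairs (36 unordered pairs over the alphabetically ordered
#' 8 categories) vary in the outer loop, cutoffs in the inner loop:
#' `"acceptor:acceptor@0.2"`, `"acceptor:acceptor@0.4"`, ...
#' With the default parameters this yields 3,600 names.
#'
#' @param params A `signature_params` (default: package defaults).
#' @return Character vector of length `36 * cutoff_limit / cutoff_step`.
#' @export
feature_schema <- function(params = signature_params()) {
  stopifnot(inherits(params, "signature_params"))
  cutoffs <- round(seq_len(params$n_bins) * params$cutoff_step, 9)
  pairs <- category_pairs()
  as.vector(t(outer(
    paste0(pairs[, 1], ":", pairs[, 2]),
    as.character(cutoffs),
    function(p, c) paste0(p, "@", c)
  )))
}

#' Euclidean distance matrix over typed atoms
#'
#' @param atoms A `typed_atoms` object or a numeric coordinate matrix
#'   (rows = atoms, columns = x, y, z).
#' @return Symmetric zero-diagonal matrix of distances in angstroms.
#' @export
distance_matrix <- function(atoms) {
  coords <- if (inherits(atoms, "typed_atoms")) {
    as.matrix(atoms$atoms[, c("x", "y", "z")])
  } else {
    as.matrix(atoms)
  }
  stopifnot(nrow(coords) >= 1, ncol(coords) == 3)
  d <- as.matrix(stats::dist(coords))
  dimnames(d) <- NULL
  d
}

#' Compute the aCSM-ALL structural signature
#'
#' For each of the 36 unordered category pairs \{c1, c2\} and each cutoff
#' k * step (k = 1 .. limit/step), counts the unordered atom pairs (i < j)
#' whose distance falls in the bin and where one atom carries c1 and the
#' other c2 (both carry it when c1 = c2). A multi-labelled atom pair
#' contributes at most once to each category-pair feature, so every
#' feature is bounded by n(n-1)/2. All atom pairs are counted, including
#' intra-residue and covalently bonded ones.
#'
#' @param atoms A `typed_atoms` object (see [assign_types()]).
#' @param params A `signature_params`.
#' @param id Identifier stored with the vector (conventionally
#'   `"PDBID_CHAIN"`).
#' @return A `signature_vector`: named integer vector (names from
#'   [feature_schema()]) with attributes `id` and `params`. An empty atom
#'   set yields an all-zero vector with a warning.
#' @export
compute_signature <- function(atoms, params = signature_params(), id = NA_character_) {
  stopifnot(inherits(atoms, "typed_atoms"), inherits(params, "signature_params"))
  schema <- feature_schema(params)
  n <- nrow(atoms$atoms)
  values <- integer(length(schema))
  if (n == 0L) {
    warning("empty atom set: all-zero signature")
  } else if (n >= 2L) {
    d <- distance_matrix(atoms)
    ut <- upper.tri(d)
    dv <- d[ut]
    # closed right bin edges: distance d lands in bin ceiling(d / step),
    # with a small epsilon so d == k*step stays in bin k despite rounding
    bin <- ceiling(dv / params$cutoff_step - 1e-9)
    inside <- bin >= 1L & bin <= params$n_bins
    pairs <- category_pairs()
    nb <- params$n_bins
    cm <- atoms$categories
    for (p in seq_len(nrow(pairs))) {
      c1 <- cm[, pairs[p, 1]]
      c2 <- cm[, pairs[p, 2]]
      match_mat <- (outer(c1, c2) | outer(c2, c1))[ut]
      sel <- match_mat & inside
      counts <- tabulate(bin[sel], nbins = nb)
      if (params$mode == "cumulative") counts <- cumsum(counts)
      values[((p - 1L) * nb + 1L):(p * nb)] <- counts
    }
  }
  structure(as.integer(values), names = schema, id = id, params = params,
            class = "signature_vector")
}

#' @export
print.signature_vector <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("<signature_vector> id=%s  %d features (%s, step %g A, limit %g A), %d non-zero\n",
              attr(x, "id"), length(x), p$mode, p$cutoff_step, p$cutoff_limit,
              sum(x != 0)))
  invisible(x)
}

#' Signature of one peptide chain of a structure
#'
#' Convenience wrapper: types the heavy atoms of `chain` and computes its
#' signature, with id `"PDBID_CHAIN"`.
#'
#' @param s A `pdb_structure`.
#' @param chain Chain id.
#' @param params A `signature_params`.
#' @param table Typing table.
#' @param model Model number (default 1; for NMR ensembles the working
#'   model).
#' @return A `signature_vector`.
#' @export
chain_signature <- function(s, chain, params = signature_params(),
                            table = default_typing_table(), model = 1L) {
  typed <- assign_types(s, table = table, chains = chain, model = model)
  compute_signature(typed, params, id = paste0(s$pdb_id, "_", chain))
}

#' Write a signature dataset as CSV
#'
#' One row per peptide: the peptide id followed by the integer signature
#' vector, under a header of `id` plus the feature names. All rows must
#' share one schema.
#'
#' @param rows A list of `signature_vector` objects.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_signature_csv <- function(rows, path) {
  stopifnot(length(rows) >= 0, all(vapply(rows, inherits, logical(1), "signature_vector")))
  if (length(rows)) {
    schemas <- lapply(rows, names)
    if (!all(vapply(schemas, identical, logical(1), schemas[[1]]))) {
      stop("signature rows have mixed feature schemas")
    }
    df <- as.data.frame(do.call(rbind, lapply(rows, as.integer)))
    names(df) <- names(rows[[1]])
    df <- cbind(id = vapply(rows, function(r) attr(r, "id"), character(1)), df)
  } else {
    df <- as.data.frame(matrix(nrow = 0, ncol = 1 + length(feature_schema())))
    names(df) <- c("id", feature_schema())
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a signature dataset written by [write_signature_csv()]
#'
#' @param path CSV path.
#' @return List with `ids` (character) and `values` (integer matrix, one
#'   row per peptide, feature names as column names).
#' @export
read_signature_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "id") stop("not a signature CSV: first column must be 'id'")
  values <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(values) <- "integer"
  rownames(values) <- NULL
  list(ids = as.character(df$id), values = values)
}
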