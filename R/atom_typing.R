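# Pharmacophore atom typing: the 8-category scheme behind the aCSM-ALL
# signature. The mapping (residue, atom) -> categories is data, shipped as
# an editable TSV, so alternative typing schemes are a file swap.

#' The eight aCSM-ALL atom categories
#'
#' Fixed, alphabetically ordered category universe: acceptor, aromatic,
#' donor, hydrophobic, negative, neutral, positive, sulfide. The ordering
#' defines the feature-name order of signature vectors.
#'
#' @return Character vector of length 8.
#' @export
atom_categories <- function() {
  c("acceptor", "aromatic", "donor", "hydrophobic",
    "negative", "neutral", "positive", "sulfide")
}

#' Read a pharmacophore typing table
#'
#' Format: tab-separated `residue<TAB>atom<TAB>category[,category...]`,
#' `#` comments allowed. Categories must come from [atom_categories()].
#'
#' @param path Path to the TSV table.
#' @return A `typing_table`: named list mapping `"RES ATOM"` to a character
#'   vector of categories, with the source path as an attribute.
#' @export
read_typing_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) < 3
  if (any(bad)) stop("malformed typing-table line(s): ", which(bad)[1])
  keys <- vapply(parts, function(p) paste(toupper(trimws(p[1])), toupper(trimws(p[2]))),
                 character(1))
  vals <- lapply(parts, function(p) trimws(strsplit(p[3], ",", fixed = TRUE)[[1]]))
  if (anyDuplicated(keys)) {
    stop("duplicate typing-table entries: ", keys[duplicated(keys)][1])
  }
  tab <- structure(vals, names = keys, class = "typing_table")
  attr(tab, "source") <- path
  tab
}

#' The packaged default typing table
#'
#' A reconstruction of the aCSM-ALL typing from standard pharmacophore
#' chemistry (the original assignment table is unpublished): charged
#' side-chain nitrogens are positive donors, carboxylate oxygens negative
#' acceptors, backbone N/O donor/acceptor, ring atoms aromatic (carbons
#' also hydrophobic), aliphatic carbons hydrophobic, CYS/MET sulfurs
#' sulfide, carbonyl/amide carbons neutral. Multi-label assignments are
#' intentional (e.g. TYR OH is both donor and acceptor).
#'
#' @return A validated `typing_table`.
#' @export
default_typing_table <- function() {
  cached <- get0("typing_table", envir = .pepsigna_cache)
  if (!is.null(cached)) return(cached)
  path <- system.file("extdata", "acsm_typing.tsv", package = "pepsigna", mustWork = TRUE)
  tab <- read_typing_table(path)
  rep <- validate_table(tab)
  if (!rep$valid) stop("packaged typing table failed validation")
  assign("typing_table", tab, envir = .pepsigna_cache)
  tab
}

.pepsigna_cache <- new.env(parent = emptyenv())

#' Validate a typing table against the canonical heavy-atom dictionary
#'
#' Checks that every heavy atom of the 20 standard residues has an entry,
#' that no value is empty, and that all categories belong to the 8-member
#' universe. Out-of-universe categories are a hard error; missing entries
#' are reported (they degrade to `neutral` at assignment time).
#'
#' @param table A `typing_table`.
#' @return List with `valid` (logical), `missing` (data.frame of absent
#'   residue/atom pairs) and `extra_keys` (entries outside the dictionary,
#'   informational).
#' @export
validate_table <- function(table) {
  stopifnot(inherits(table, "typing_table"))
  cats <- unique(unlist(table, use.names = FALSE))
  out_of_enum <- setdiff(cats, atom_categories())
  if (length(out_of_enum)) {
    stop("typing table uses categories outside the 8-member universe: ",
         paste(out_of_enum, collapse = ", "))
  }
  if (any(!vapply(table, length, integer(1)))) stop("typing table has empty category sets")
  dict <- canonical_heavy_atoms()
  want <- paste(dict$residue, dict$atom)
  missing <- dict[!(want %in% names(table)), , drop = FALSE]
  rownames(missing) <- NULL
  list(
    valid = nrow(missing) == 0L,
    missing = missing,
    extra_keys = setdiff(names(table), want)
  )
}

#' Assign pharmacophore categories to the atoms of a structure
#'
#' Every heavy atom of the selected chains receives the category set of
#' its (residue, atom) table entry. Hydrogens are excluded. The terminal
#' carboxylate OXT is negative + acceptor for any residue. Heavy atoms
#' without a table entry fall back to `{neutral}` and are tallied in a
#' warning. Typing is a pure function of residue and atom names; it never
#' looks at coordinates.
#'
#' @param structure A `pdb_structure`, or an atom data.frame as returned
#'   by [structure_atoms()].
#' @param table A `typing_table` (default: the packaged table).
#' @param chains Optional chain ids to restrict to.
#' @param model Model number when `structure` is a `pdb_structure`.
#' @return A `typed_atoms` object: list with `atoms` (the heavy-atom
#'   table), `categories` (logical matrix, atoms x 8 categories) and
#'   `n_untyped` (atoms that fell back to neutral).
#' @export
assign_types <- function(structure, table = default_typing_table(),
                         chains = NULL, model = 1L) {
  atoms <- if (inherits(structure, "pdb_structure")) {
    structure_atoms(structure, model = model, chains = chains, heavy_only = TRUE)
  } else {
    a <- structure
    if (!is.null(chains)) a <- a[a$chain %in% chains, , drop = FALSE]
    a[!a$hydrogen, , drop = FALSE]
  }
  cats <- atom_categories()
  m <- matrix(FALSE, nrow(atoms), length(cats), dimnames = list(NULL, cats))
  keys <- paste(atoms$resname, atoms$name)
  hit <- keys %in% names(table)
  for (i in which(hit)) m[i, table[[keys[i]]]] <- TRUE
  oxt <- !hit & atoms$name == "OXT"
  m[oxt, c("acceptor", "negative")] <- TRUE
  untyped <- which(!hit & !oxt)
  if (length(untyped)) {
    m[untyped, "neutral"] <- TRUE
    warning(sprintf("%d atom(s) without a typing entry assigned {neutral}",
                    length(untyped)))
  }
  structure(
    list(atoms = atoms, categories = m, n_untyped = length(untyped)),
    class = "typed_atoms"
  )
}

#' @export
print.typed_atoms <- function(x, ...) {
  cat(sprintf("<typed_atoms> %d heavy atoms, %d untyped; categories in use: %s\n",
              nrow(x$atoms), x$n_untyped,
              paste(colnames(x$categories)[colSums(x$categories) > 0], collapse = ", ")))
  invisible(x)
}
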