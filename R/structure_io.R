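# PDB-format structure I/O and synthetic-structure generation.

#' Parse a PDB-format structure from text
#'
#' Reads ATOM/HETATM records using the PDB v3.3 fixed-column layout. Waters
#' are excluded; hydrogens are retained but flagged; alternate locations are
#' collapsed to the highest-occupancy conformer (ties broken alphabetically
#' by altloc). Multi-model files (NMR ensembles) keep every model; model 1
#' is the working model downstream. Malformed atom records are skipped with
#' a warning; a file with no parsable atom is an error.
#'
#' @param text A single string (or character vector of lines) holding a
#'   PDB-format structure.
#' @return A `pdb_structure`: list with `pdb_id`, `models` (list of atom
#'   data.frames with columns serial, name, altloc, resname, chain, resseq,
#'   icode, x, y, z, occupancy, element, het, hydrogen), `experiment`
#'   (`"xray"`, `"nmr"`, `"other"` or `NA` when the file carries no EXPDTA
#'   record) and `resolution` (angstroms, `NA` if absent).
#' @seealso [write_structure()], [make_synthetic_complex()]
#' @export
parse_structure <- function(text) {
  stopifnot(is.character(text))
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text

  rec <- substr(lines, 1, 6)
  pdb_id <- "XXXX"
  hdr <- lines[rec == "HEADER"]
  if (length(hdr)) {
    id <- trimws(substr(hdr[1], 63, 66))
    if (nzchar(id)) pdb_id <- id
  }

  experiment <- NA_character_
  exp_line <- lines[rec == "EXPDTA"]
  if (length(exp_line)) {
    experiment <- if (grepl("X-RAY", exp_line[1])) "xray"
      else if (grepl("NMR", exp_line[1])) "nmr" else "other"
  }

  resolution <- NA_real_
  res_line <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
  if (length(res_line)) {
    tail_part <- substr(res_line[1], 23, 80)
    m <- regmatches(tail_part, regexpr("[0-9]+\\.?[0-9]*", tail_part))
    if (length(m)) resolution <- as.numeric(m)
  }

  model_no <- pmax(cumsum(startsWith(lines, "MODEL")), 1L)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom)) stop("no ATOM/HETATM records found")

  at_lines <- lines[is_atom]
  at_model <- model_no[is_atom]

  ok <- nchar(at_lines) >= 54
  x <- suppressWarnings(as.numeric(substr(at_lines, 31, 38)))
  y <- suppressWarnings(as.numeric(substr(at_lines, 39, 46)))
  z <- suppressWarnings(as.numeric(substr(at_lines, 47, 54)))
  ok <- ok & is.finite(x) & is.finite(y) & is.finite(z)
  n_bad <- sum(!ok)
  if (n_bad > 0) {
    warning(sprintf("skipped %d malformed atom record(s)", n_bad))
    at_lines <- at_lines[ok]; at_model <- at_model[ok]
    x <- x[ok]; y <- y[ok]; z <- z[ok]
  }
  if (!length(at_lines)) stop("no parsable ATOM/HETATM records")

  raw_name <- substr(at_lines, 13, 16)
  atoms <- data.frame(
    serial = suppressWarnings(as.integer(substr(at_lines, 7, 11))),
    name = trimws(raw_name),
    altloc = substr(at_lines, 17, 17),
    resname = trimws(substr(at_lines, 18, 20)),
    chain = substr(at_lines, 22, 22),
    resseq = suppressWarnings(as.integer(substr(at_lines, 23, 26))),
    icode = substr(at_lines, 27, 27),
    x = x, y = y, z = z,
    occupancy = suppressWarnings(as.numeric(substr(at_lines, 55, 60))),
    element = trimws(substr(at_lines, 77, 78)),
    het = substr(at_lines, 1, 6) == "HETATM",
    stringsAsFactors = FALSE
  )
  atoms$occupancy[!is.finite(atoms$occupancy)] <- 1.0
  atoms$resseq[is.na(atoms$resseq)] <- 0L

  blank <- !nzchar(atoms$element)
  if (any(blank)) atoms$element[blank] <- infer_element(raw_name[blank])
  atoms$hydrogen <- atoms$element %in% c("H", "D")

  keep <- !(atoms$resname %in% .WATER_NAMES)
  atoms <- atoms[keep, , drop = FALSE]
  at_model <- at_model[keep]
  if (!nrow(atoms)) stop("no non-water atoms in structure")

  models <- lapply(sort(unique(at_model)), function(m) {
    resolve_altlocs(atoms[at_model == m, , drop = FALSE])
  })

  structure(
    list(pdb_id = pdb_id, models = models,
         experiment = experiment, resolution = resolution),
    class = "pdb_structure"
  )
}

#' Read a PDB-format structure from a file
#' @param path Path to a PDB file.
#' @return A `pdb_structure`; see [parse_structure()].
#' @export
read_structure <- function(path) {
  parse_structure(readLines(path, warn = FALSE))
}

# Infer the element symbol from the raw 4-character atom-name field.
# Names starting in column 13 (no leading blank) may carry 2-letter
# elements (FE, ZN, calcium CA); otherwise strip digits and take the
# first letter (1HB2 -> H).
infer_element <- function(raw_name) {
  two_letter <- c("FE", "ZN", "MG", "MN", "CU", "NA", "CL", "CA", "CO",
                  "NI", "BR", "SE", "CD", "HG")
  vapply(raw_name, function(nm) {
    first2 <- toupper(substr(nm, 1, 2))
    if (substr(nm, 1, 1) != " " && first2 %in% two_letter) return(first2)
    letters_only <- gsub("[^A-Za-z]", "", nm)
    if (!nzchar(letters_only)) return("X")
    toupper(substr(letters_only, 1, 1))
  }, character(1), USE.NAMES = FALSE)
}

# Collapse alternate locations: within each (chain, resseq, icode, name)
# group carrying >1 altloc, keep the highest-occupancy conformer, ties
# broken alphabetically (blank sorts before 'A').
resolve_altlocs <- function(atoms) {
  key <- paste(atoms$chain, atoms$resseq, atoms$icode, atoms$name, sep = "\r")
  if (!anyDuplicated(key)) return(atoms)
  multi <- key %in% key[duplicated(key)]
  has_alt <- multi & ave(atoms$altloc, key, FUN = function(a) length(unique(a)))[] > 1
  if (!any(has_alt)) return(atoms)
  ord <- order(key, -atoms$occupancy, atoms$altloc)
  sorted <- atoms[ord, , drop = FALSE]
  skey <- key[ord]
  drop <- duplicated(skey) & skey %in% key[has_alt]
  out <- sorted[!drop, , drop = FALSE]
  out[order(match(paste(out$chain, out$resseq, out$icode, out$name, sep = "\r"),
                  unique(key))), , drop = FALSE]
}

#' Write a structure (or a chain subset) as PDB-format text
#'
#' Emits fixed-column PDB v3.3 ATOM/HETATM records for the selected chains
#' of one model, a TER record after each chain, and a terminating END.
#'
#' @param s A `pdb_structure`.
#' @param chains Character vector of chain ids to emit; `NULL` (default)
#'   emits all chains.
#' @param model Model number (1-based); defaults to 1.
#' @param path Optional file path; when given the text is also written there.
#' @return The PDB-format text, invisibly when `path` is given.
#' @export
write_structure <- function(s, chains = NULL, model = 1L, path = NULL) {
  stopifnot(inherits(s, "pdb_structure"))
  atoms <- s$models[[model]]
  all_chains <- unique(atoms$chain)
  if (is.null(chains)) chains <- all_chains
  if (!length(chains)) stop("empty chain selection")
  if (!all(chains %in% all_chains)) {
    stop("chains not present in structure: ",
         paste(setdiff(chains, all_chains), collapse = ", "))
  }

  header <- sprintf("%-62s%4s", "HEADER    PEPTIDE-PROTEIN COMPLEX", s$pdb_id)
  out <- header
  if (!is.na(s$experiment)) {
    out <- c(out, sprintf("EXPDTA    %s",
      switch(s$experiment, xray = "X-RAY DIFFRACTION", nmr = "SOLUTION NMR", "OTHER")))
  }
  if (!is.na(s$resolution)) {
    out <- c(out, sprintf("REMARK   2 RESOLUTION. %7.2f ANGSTROMS.", s$resolution))
  }

  serial <- 0L
  for (ch in chains) {
    a <- atoms[atoms$chain == ch, , drop = FALSE]
    for (i in seq_len(nrow(a))) {
      serial <- serial + 1L
      nm <- a$name[i]
      nm4 <- if (nchar(nm) >= 4 || nchar(a$element[i]) > 1) {
        sprintf("%-4s", nm)
      } else {
        sprintf(" %-3s", nm)
      }
      out <- c(out, sprintf(
        "%-6s%5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        if (a$het[i]) "HETATM" else "ATOM", serial, nm4, a$altloc[i],
        a$resname[i], ch, a$resseq[i], a$icode[i],
        a$x[i], a$y[i], a$z[i], a$occupancy[i], 0, a$element[i]))
    }
    out <- c(out, "TER")
  }
  out <- c(out, "END")
  text <- paste0(paste(out, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(text))
  }
  text
}

#' Atom table of one model, optionally restricted
#'
#' @param s A `pdb_structure`.
#' @param model Model number (default 1).
#' @param chains Optional chain ids to keep.
#' @param heavy_only Drop hydrogens/deuteriums (default TRUE).
#' @return Atom data.frame (see [parse_structure()]).
#' @export
structure_atoms <- function(s, model = 1L, chains = NULL, heavy_only = TRUE) {
  stopifnot(inherits(s, "pdb_structure"))
  a <- s$models[[model]]
  if (!is.null(chains)) a <- a[a$chain %in% chains, , drop = FALSE]
  if (heavy_only) a <- a[!a$hydrogen, , drop = FALSE]
  a
}

#' Chain ids present in a structure model
#' @inheritParams structure_atoms
#' @return Character vector of chain ids in file order.
#' @export
chain_ids <- function(s, model = 1L) unique(s$models[[model]]$chain)

#' Amino-acid residue count per chain
#'
#' A residue counts toward chain length when it carries a CA atom, so
#' modified amino acids deposited as HETATM within a polymer chain are
#' included while ions and small-molecule ligands are not.
#'
#' @inheritParams structure_atoms
#' @return Named integer vector (names = chain ids).
#' @export
chain_lengths <- function(s, model = 1L) {
  a <- structure_atoms(s, model)
  ca <- a[a$name == "CA" & a$element == "C", , drop = FALSE]
  if (!nrow(ca)) {
    return(structure(integer(length(chain_ids(s, model))), names = chain_ids(s, model)))
  }
  tab <- tapply(paste(ca$resseq, ca$icode), ca$chain, function(v) length(unique(v)))
  out <- structure(integer(length(chain_ids(s, model))), names = chain_ids(s, model))
  out[names(tab)] <- as.integer(tab)
  out
}

#' One-letter sequence of a chain
#'
#' Standard residues map to their one-letter code; non-standard residues
#' are skipped with a warning (they still contribute atoms elsewhere).
#'
#' @param s A `pdb_structure`.
#' @param chain Chain id.
#' @param model Model number (default 1).
#' @return Single string over the 20 standard letters.
#' @export
chain_sequence <- function(s, chain, model = 1L) {
  a <- structure_atoms(s, model, chains = chain)
  ca <- a[a$name == "CA" & a$element == "C", , drop = FALSE]
  ca <- ca[!duplicated(paste(ca$resseq, ca$icode)), , drop = FALSE]
  known <- ca$resname %in% names(.AA321)
  if (any(!known)) {
    warning(sprintf("chain %s: skipped %d non-standard residue(s) in sequence",
                    chain, sum(!known)))
  }
  paste(.AA321[ca$resname[known]], collapse = "")
}

# ---- synthetic structures -------------------------------------------------

# Run code with a private RNG stream seeded by `seed`, restoring the
# caller's RNG state afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

normalize <- function(v) v / sqrt(sum(v^2))

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

# Build the atom table of one chain as a gently wandering extended backbone:
# consecutive CA atoms exactly 3.8 A apart, N/C/O in a local frame, side-chain
# heavy atoms extending perpendicular to the chain axis. Plausible, not
# energy-minimized; signatures only need realistic distance scales.
build_chain_atoms <- function(chain_id, sequence, origin, direction, wobble = 0.08) {
  seq3 <- unname(.AA123[strsplit(sequence, "")[[1]]])
  n <- length(seq3)
  dir <- normalize(direction)
  ca <- matrix(0, n, 3)
  ca[1, ] <- origin
  dirs <- matrix(0, n, 3)
  dirs[1, ] <- dir
  for (i in seq_len(n - 1)) {
    dir <- normalize(dir + wobble * stats::rnorm(3))
    ca[i + 1, ] <- ca[i, ] + 3.8 * dir
    dirs[i + 1, ] <- dir
  }
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    d <- dirs[i, ]
    up <- c(0, 0, 1)
    if (abs(sum(d * up)) > 0.95) up <- c(0, 1, 0)
    p <- normalize(cross3(d, up))     # side-chain direction
    q <- normalize(cross3(d, p))      # carbonyl direction
    names_i <- c("N", "CA", "C", "O")
    coords <- rbind(
      ca[i, ] - 1.2 * d - 0.5 * p,
      ca[i, ],
      ca[i, ] + 1.2 * d - 0.5 * p,
      ca[i, ] + 1.2 * d - 0.5 * p + 1.23 * q
    )
    sc <- .SIDE_CHAIN_ATOMS[[seq3[i]]]
    for (j in seq_along(sc)) {
      zig <- if (j %% 2 == 0) 0.45 else -0.45
      coords <- rbind(coords, ca[i, ] + (0.9 + 0.75 * j) * p + zig * d +
                        0.1 * stats::rnorm(3))
      names_i <- c(names_i, sc[j])
    }
    el <- substr(names_i, 1, 1)
    rows[[i]] <- data.frame(
      serial = 0L, name = names_i, altloc = " ", resname = seq3[i],
      chain = chain_id, resseq = i, icode = " ",
      x = coords[, 1], y = coords[, 2], z = coords[, 3],
      occupancy = 1.0, element = el, het = FALSE, hydrogen = FALSE,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  out$serial <- seq_len(nrow(out))
  out
}

random_sequence <- function(n) paste(sample(names(.AA123), n, replace = TRUE), collapse = "")

#' Generate a synthetic multi-chain structure
#'
#' Deterministic for a fixed seed. Each chain is specified by id, a
#' sequence (or a length, in which case residues are drawn at random),
#' an origin and an initial direction.
#'
#' @param chain_spec List of lists with elements `chain`, and either
#'   `sequence` (1-letter string) or `n_res`, plus optional `origin`
#'   (3-vector, angstroms) and `direction` (3-vector).
#' @param seed Integer RNG seed.
#' @param experiment,resolution Metadata stamped on the structure
#'   (defaults: `"xray"`, 1.8 angstroms).
#' @param pdb_id 4-character identifier.
#' @return A `pdb_structure`.
#' @export
make_synthetic_structure <- function(chain_spec, seed,
                                     experiment = "xray", resolution = 1.8,
                                     pdb_id = "SYNT") {
  with_seed(seed, {
    tabs <- lapply(chain_spec, function(cs) {
      sequence <- cs$sequence
      if (is.null(sequence)) sequence <- random_sequence(cs$n_res)
      origin <- if (is.null(cs$origin)) c(0, 0, 0) else cs$origin
      direction <- if (is.null(cs$direction)) c(1, 0, 0) else cs$direction
      build_chain_atoms(cs$chain, sequence, origin, direction)
    })
    atoms <- do.call(rbind, tabs)
    atoms$serial <- seq_len(nrow(atoms))
    structure(
      list(pdb_id = pdb_id, models = list(atoms),
           experiment = experiment, resolution = resolution),
      class = "pdb_structure"
    )
  })
}

#' Generate a synthetic two-chain peptide-protein complex
#'
#' Chain A is the protein, chain B the peptide. The peptide is translated
#' so that the minimum inter-chain heavy-atom distance is approximately
#' `min_distance` (within ~0.2 angstroms), guaranteeing (or excluding)
#' interface contacts by construction.
#'
#' @param n_protein_res,n_peptide_res Residue counts (protein chain A,
#'   peptide chain B).
#' @param seed Integer RNG seed; fixed seed gives byte-identical output.
#' @param min_distance Target minimum distance between the chains
#'   (angstroms, default 4).
#' @inheritParams make_synthetic_structure
#' @return A `pdb_structure` with chains A and B.
#' @export
make_synthetic_complex <- function(n_protein_res, n_peptide_res, seed,
                                   min_distance = 4,
                                   experiment = "xray", resolution = 1.8,
                                   pdb_id = "SYNT") {
  stopifnot(n_protein_res >= 1, n_peptide_res >= 1)
  s <- make_synthetic_structure(
    list(
      list(chain = "A", n_res = n_protein_res, origin = c(0, 0, 0)),
      list(chain = "B", n_res = n_peptide_res, origin = c(0, 30, 0))
    ),
    seed = seed, experiment = experiment, resolution = resolution,
    pdb_id = pdb_id
  )
  atoms <- s$models[[1]]
  ia <- atoms$chain == "A"
  ib <- atoms$chain == "B"
  pa <- as.matrix(atoms[ia, c("x", "y", "z")])
  pb <- as.matrix(atoms[ib, c("x", "y", "z")])
  for (iter in 1:30) {
    cd <- cross_distances(pa, pb)
    m <- min(cd)
    if (abs(m - min_distance) < 0.1) break
    idx <- which(cd == m, arr.ind = TRUE)[1, ]
    shift_dir <- normalize(pa[idx[1], ] - pb[idx[2], ])
    pb <- sweep(pb, 2, shift_dir * (m - min_distance), "+")
  }
  atoms[ib, c("x", "y", "z")] <- pb
  s$models[[1]] <- atoms
  s
}

# Euclidean distances between two coordinate matrices (rows = atoms).
cross_distances <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}
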