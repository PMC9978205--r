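# Collection criteria, peptide/protein chain classification, entry
# enumeration and contact-interface extraction.

#' Collection criteria for peptide-protein complexes
#'
#' Defaults mirror the database-construction filter: a peptide is a chain
#' of 2-50 amino-acid residues, the structure must have at least two
#' chains, and must be solved by X-ray crystallography or NMR. For X-ray
#' entries a resolution rule applies; the default keeps structures with
#' resolution <= 2.5 angstroms (the conventional quality direction) and
#' the comparator is explicit so the opposite reading can be configured.
#'
#' @param min_peptide_len,max_peptide_len Peptide length bounds in
#'   residues (defaults 2 and 50, both inclusive).
#' @param min_chains Minimum chain count (default 2).
#' @param allowed_experiments Admissible experiment kinds.
#' @param xray_resolution_threshold Resolution threshold in angstroms
#'   (default 2.5).
#' @param xray_resolution_comparator `"le"` (resolution <= threshold
#'   passes, default) or `"gt"` (resolution > threshold passes).
#' @return A `collection_criteria` list.
#' @export
collection_criteria <- function(min_peptide_len = 2L, max_peptide_len = 50L,
                                min_chains = 2L,
                                allowed_experiments = c("xray", "nmr"),
                                xray_resolution_threshold = 2.5,
                                xray_resolution_comparator = c("le", "gt")) {
  stopifnot(min_peptide_len >= 1, min_peptide_len <= max_peptide_len,
            xray_resolution_threshold > 0)
  structure(
    list(min_peptide_len = as.integer(min_peptide_len),
         max_peptide_len = as.integer(max_peptide_len),
         min_chains = as.integer(min_chains),
         allowed_experiments = allowed_experiments,
         xray_resolution_threshold = xray_resolution_threshold,
         xray_resolution_comparator = match.arg(xray_resolution_comparator)),
    class = "collection_criteria"
  )
}

#' Test a structure against the collection criteria
#'
#' Passes iff the chain count meets the minimum, at least one chain has a
#' peptide-range length, and the experiment is admissible (NMR always;
#' X-ray subject to the resolution rule). Absent experiment metadata is a
#' failure, not an error.
#'
#' @param s A `pdb_structure`.
#' @param criteria A `collection_criteria`.
#' @return List with `pass` (logical) and `reasons` (character vector of
#'   failed criteria, empty on pass).
#' @export
passes_criteria <- function(s, criteria = collection_criteria()) {
  stopifnot(inherits(s, "pdb_structure"), inherits(criteria, "collection_criteria"))
  reasons <- character(0)
  lens <- chain_lengths(s)
  if (length(lens) < criteria$min_chains) {
    reasons <- c(reasons, sprintf("chain count %d < %d", length(lens), criteria$min_chains))
  }
  in_range <- lens >= criteria$min_peptide_len & lens <= criteria$max_peptide_len
  if (!any(in_range)) {
    reasons <- c(reasons, sprintf("peptide length: no chain with %d-%d residues",
                                  criteria$min_peptide_len, criteria$max_peptide_len))
  }
  if (is.na(s$experiment)) {
    reasons <- c(reasons, "experiment metadata absent")
  } else if (!(s$experiment %in% criteria$allowed_experiments)) {
    reasons <- c(reasons, sprintf("experiment '%s' not admissible", s$experiment))
  } else if (s$experiment == "xray") {
    res_ok <- !is.na(s$resolution) &&
      switch(criteria$xray_resolution_comparator,
             le = s$resolution <= criteria$xray_resolution_threshold,
             gt = s$resolution > criteria$xray_resolution_threshold)
    if (!res_ok) {
      reasons <- c(reasons, sprintf("x-ray resolution rule (%s %g A) failed",
                                    criteria$xray_resolution_comparator,
                                    criteria$xray_resolution_threshold))
    }
  }
  list(pass = length(reasons) == 0L, reasons = reasons)
}

#' Classify chains as peptide, protein or other
#'
#' A chain whose amino-acid length lies in the peptide range (bounds
#' inclusive) is a peptide; longer chains are proteins; shorter or
#' non-polypeptide chains are `other`.
#'
#' @inheritParams passes_criteria
#' @param model Model number (default 1).
#' @return Named character vector (`"peptide"`, `"protein"` or `"other"`)
#'   over chain ids.
#' @export
classify_chains <- function(s, criteria = collection_criteria(), model = 1L) {
  lens <- chain_lengths(s, model)
  kind <- ifelse(lens > criteria$max_peptide_len, "protein",
                 ifelse(lens >= criteria$min_peptide_len, "peptide", "other"))
  structure(as.character(kind), names = names(lens))
}

#' Extract the contact interface between two chains
#'
#' All inter-chain heavy-atom pairs within `contact_cutoff` angstroms,
#' plus the per-side sets of atoms participating in at least one contact.
#'
#' @param protein,peptide Atom data.frames (one chain each, as from
#'   [structure_atoms()]).
#' @param contact_cutoff Distance cutoff in angstroms (default 5).
#' @return An `interface_record`: list with `contact_pairs` (data.frame:
#'   serials, atom names, residue numbers of both sides, `distance`),
#'   `protein_atoms` / `peptide_atoms` (serial sets) and `contact_cutoff`.
#' @export
extract_interface <- function(protein, peptide, contact_cutoff = 5) {
  protein <- protein[!protein$hydrogen, , drop = FALSE]
  peptide <- peptide[!peptide$hydrogen, , drop = FALSE]
  stopifnot(nrow(protein) >= 1, nrow(peptide) >= 1)
  d <- cross_distances(as.matrix(protein[, c("x", "y", "z")]),
                       as.matrix(peptide[, c("x", "y", "z")]))
  hit <- which(d <= contact_cutoff, arr.ind = TRUE)
  pairs <- data.frame(
    protein_serial = protein$serial[hit[, 1]],
    protein_atom = protein$name[hit[, 1]],
    protein_res = protein$resseq[hit[, 1]],
    peptide_serial = peptide$serial[hit[, 2]],
    peptide_atom = peptide$name[hit[, 2]],
    peptide_res = peptide$resseq[hit[, 2]],
    distance = d[hit],
    stringsAsFactors = FALSE
  )
  pairs <- pairs[order(pairs$protein_serial, pairs$peptide_serial), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(
    list(contact_pairs = pairs,
         protein_atoms = sort(unique(pairs$protein_serial)),
         peptide_atoms = sort(unique(pairs$peptide_serial)),
         contact_cutoff = contact_cutoff),
    class = "interface_record"
  )
}

#' Enumerate peptide-protein complex entries
#'
#' Forms the Cartesian product of protein chains and peptide chains and
#' keeps every pair with at least one heavy-atom contact at
#' `contact_cutoff`. A four-chain structure with proteins \{A, B\} and
#' peptides \{C, D\}, all mutually in contact, therefore yields the four
#' entries A-C, A-D, B-C and B-D.
#'
#' @inheritParams passes_criteria
#' @param contact_cutoff Heavy-atom contact cutoff in angstroms (default 5).
#' @param model Model number (default 1).
#' @return List of `complex_entry` objects: `entry_id`
#'   (`"PDBID_PROTEIN_PEPTIDE"`), chain ids, chain lengths, `n_contacts`
#'   and the `interface_record`.
#' @export
enumerate_entries <- function(s, criteria = collection_criteria(),
                              contact_cutoff = 5, model = 1L) {
  kinds <- classify_chains(s, criteria, model)
  prot <- names(kinds)[kinds == "protein"]
  pept <- names(kinds)[kinds == "peptide"]
  lens <- chain_lengths(s, model)
  entries <- list()
  for (p in prot) {
    pa <- structure_atoms(s, model, chains = p)
    for (q in pept) {
      qa <- structure_atoms(s, model, chains = q)
      iface <- extract_interface(pa, qa, contact_cutoff)
      n <- nrow(iface$contact_pairs)
      if (n >= 1L) {
        entries[[length(entries) + 1L]] <- structure(
          list(entry_id = paste(s$pdb_id, p, q, sep = "_"),
               protein_chain = p, peptide_chain = q,
               protein_length = unname(lens[p]), peptide_length = unname(lens[q]),
               n_contacts = n, interface = iface),
          class = "complex_entry"
        )
      }
    }
  }
  entries
}

#' @export
print.complex_entry <- function(x, ...) {
  cat(sprintf("<complex_entry> %s  protein %s (%d res) / peptide %s (%d res), %d contacts <= %g A\n",
              x$entry_id, x$protein_chain, x$protein_length,
              x$peptide_chain, x$peptide_length, x$n_contacts,
              x$interface$contact_cutoff))
  invisible(x)
}

#' Write per-entry PDB and interface files
#'
#' For each enumerated entry, writes the two-chain complex as
#' `ENTRYID.pdb` and the contact pairs as `ENTRYID.interface.tsv`
#' (protein/peptide atom serials, names, residue numbers, distance to
#' three decimals).
#'
#' @param s A `pdb_structure`.
#' @param outdir Output directory (created if needed).
#' @inheritParams enumerate_entries
#' @return The list of entries, invisibly, with file paths attached.
#' @export
write_entry_files <- function(s, outdir, criteria = collection_criteria(),
                              contact_cutoff = 5, model = 1L) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  entries <- enumerate_entries(s, criteria, contact_cutoff, model)
  for (i in seq_along(entries)) {
    e <- entries[[i]]
    pdb_path <- file.path(outdir, paste0(e$entry_id, ".pdb"))
    write_structure(s, chains = c(e$protein_chain, e$peptide_chain),
                    model = model, path = pdb_path)
    tsv_path <- file.path(outdir, paste0(e$entry_id, ".interface.tsv"))
    tab <- e$interface$contact_pairs
    tab$distance <- sprintf("%.3f", tab$distance)
    utils::write.table(tab, tsv_path, sep = "\t", row.names = FALSE, quote = FALSE)
    entries[[i]]$pdb_path <- pdb_path
    entries[[i]]$interface_path <- tsv_path
  }
  invisible(entries)
}
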