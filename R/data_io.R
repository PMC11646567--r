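# Dataset container and file I/O: pair tables (CSV/TSV), RNA FASTA,
# SMILES (.smi or CSV), and prediction tables.

#' Construct an RNA-small molecule affinity dataset
#'
#' Validates and assembles the three tables that define a dataset: RNA
#' records, molecule records, and (RNA, molecule, pKd) affinity pairs. The
#' pair table is the source of truth: orphan RNA/molecule records (never
#' referenced by a pair) are allowed but reported with a message.
#'
#' @param rnas Tibble with columns `id`, `sequence` (A/C/G/U alphabet).
#' @param molecules Tibble with columns `id`, `smiles`.
#' @param pairs Tibble with columns `rna_id`, `mol_id`, `affinity` (pKd).
#' @param validate_smiles Parse every SMILES and fail on invalid ones
#'   (default `TRUE`).
#' @return An object of class `rsma_dataset`: a list with tibbles `rnas`
#'   (id, sequence, p), `molecules` (id, smiles, q), and `pairs`.
#' @export
rsma_dataset <- function(rnas, molecules, pairs, validate_smiles = TRUE) {
  rnas <- tibble::as_tibble(rnas)
  molecules <- tibble::as_tibble(molecules)
  pairs <- tibble::as_tibble(pairs)

  stopifnot(all(c("id", "sequence") %in% names(rnas)),
            all(c("id", "smiles") %in% names(molecules)),
            all(c("rna_id", "mol_id", "affinity") %in% names(pairs)))
  if (nrow(pairs) == 0L) stop("no pairs", call. = FALSE)
  if (anyDuplicated(rnas$id)) stop("duplicate RNA ids", call. = FALSE)
  if (anyDuplicated(molecules$id)) stop("duplicate molecule ids", call. = FALSE)
  dup <- duplicated(pairs[, c("rna_id", "mol_id")])
  if (any(dup)) {
    stop("duplicate (rna_id, mol_id) pairs: ",
         paste(utils::head(paste(pairs$rna_id[dup], pairs$mol_id[dup], sep = "/"), 5L),
               collapse = ", "), call. = FALSE)
  }

  rnas$sequence <- normalize_rna_sequence(rnas$sequence, ids = rnas$id)
  rnas$p <- nchar(rnas$sequence)
  if (any(rnas$p == 0L)) {
    stop("empty RNA sequence: ", paste(rnas$id[rnas$p == 0L], collapse = ", "),
         call. = FALSE)
  }

  if (validate_smiles) {
    bad <- vapply(molecules$smiles, function(s) !is_valid_smiles(s), logical(1L))
    if (any(bad)) {
      stop("invalid SMILES for molecule ids: ",
           paste(molecules$id[bad], collapse = ", "), call. = FALSE)
    }
    molecules$q <- vapply(molecules$smiles, function(s) parse_smiles(s)$q,
                          integer(1L), USE.NAMES = FALSE)
  } else if (!"q" %in% names(molecules)) {
    molecules$q <- NA_integer_
  }

  miss_r <- setdiff(pairs$rna_id, rnas$id)
  if (length(miss_r)) stop("pair table references unknown rna_id: ",
                           paste(utils::head(miss_r, 5L), collapse = ", "), call. = FALSE)
  miss_m <- setdiff(pairs$mol_id, molecules$id)
  if (length(miss_m)) stop("pair table references unknown mol_id: ",
                           paste(utils::head(miss_m, 5L), collapse = ", "), call. = FALSE)
  if (any(!is.finite(pairs$affinity))) stop("non-finite affinity values", call. = FALSE)

  orphan_r <- setdiff(rnas$id, pairs$rna_id)
  orphan_m <- setdiff(molecules$id, pairs$mol_id)
  if (length(orphan_r) || length(orphan_m)) {
    message("orphan records not referenced by any pair: ",
            length(orphan_r), " RNA(s), ", length(orphan_m), " molecule(s)")
  }

  structure(list(rnas = rnas, molecules = molecules, pairs = pairs),
            class = "rsma_dataset")
}

#' @export
print.rsma_dataset <- function(x, ...) {
  cat("<rsma_dataset> ", nrow(x$pairs), " pairs | ", nrow(x$rnas), " RNAs | ",
      nrow(x$molecules), " molecules\n", sep = "")
  cat("  pKd range: [", round(min(x$pairs$affinity), 2), ", ",
      round(max(x$pairs$affinity), 2), "]\n", sep = "")
  invisible(x)
}

#' Normalize RNA sequences to the A/C/G/U alphabet
#'
#' Uppercases, maps DNA-style T to U (with a warning, since real sources mix
#' alphabets), and rejects any other character.
#'
#' @param sequences Character vector of sequences.
#' @param ids Optional ids used in error messages.
#' @return Normalized character vector.
#' @export
normalize_rna_sequence <- function(sequences, ids = NULL) {
  out <- toupper(sequences)
  has_t <- grepl("T", out, fixed = TRUE)
  if (any(has_t)) {
    who <- if (is.null(ids)) sum(has_t) else paste(ids[has_t], collapse = ", ")
    warning("DNA letter T normalized to U in: ", who, call. = FALSE)
    out <- gsub("T", "U", out, fixed = TRUE)
  }
  bad <- grepl("[^ACGU]", out)
  if (any(bad)) {
    who <- if (is.null(ids)) which(bad) else ids[bad]
    stop("non-ACGU characters after T->U normalization in: ",
         paste(who, collapse = ", "), call. = FALSE)
  }
  out
}

.read_pair_table <- function(path) {
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  tb <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  need <- c("rna_id", "mol_id", "affinity")
  if (!all(need %in% names(tb))) {
    stop("pair table must have columns rna_id, mol_id, affinity; found: ",
         paste(names(tb), collapse = ", "), call. = FALSE)
  }
  tb$rna_id <- as.character(tb$rna_id)
  tb$mol_id <- as.character(tb$mol_id)
  tb$affinity <- as.numeric(tb$affinity)
  tb[need]
}

.read_smiles_file <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    tb <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    if (!all(c("id", "smiles") %in% names(tb))) {
      stop("SMILES CSV must have columns id, smiles", call. = FALSE)
    }
    tibble::tibble(id = as.character(tb$id), smiles = as.character(tb$smiles))
  } else {
    ln <- readLines(path)
    ln <- ln[nzchar(trimws(ln))]
    parts <- strsplit(trimws(ln), "\\s+")
    tibble::tibble(
      id = vapply(parts, function(x) if (length(x) > 1L) x[2L] else x[1L], character(1L)),
      smiles = vapply(parts, `[[`, character(1L), 1L)
    )
  }
}

#' Load a dataset from a pair table, an RNA FASTA, and a SMILES file
#'
#' @param pairs_path CSV/TSV with header columns `rna_id`, `mol_id`,
#'   `affinity` (pKd).
#' @param fasta_path FASTA of RNA sequences; DNA-style T is normalized to U
#'   with a warning.
#' @param smiles_path `.smi` file (`SMILES id` per line) or CSV with columns
#'   `id`, `smiles`.
#' @return An [rsma_dataset()].
#' @examples
#' \dontrun{
#' ds <- load_dataset("pairs.csv", "rnas.fasta", "mols.smi")
#' }
#' @export
load_dataset <- function(pairs_path, fasta_path, smiles_path) {
  for (p in c(pairs_path, fasta_path, smiles_path)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  pairs <- .read_pair_table(pairs_path)
  if (nrow(pairs) == 0L) stop("no pairs", call. = FALSE)
  seqs <- Biostrings::readBStringSet(fasta_path)
  rnas <- tibble::tibble(id = names(seqs),
                         sequence = unname(as.character(seqs)))
  molecules <- .read_smiles_file(smiles_path)
  rsma_dataset(rnas, molecules, pairs)
}

#' Write predicted affinities next to their pairs
#'
#' @param pairs Tibble with columns `rna_id`, `mol_id` and optionally
#'   `affinity` (written as `affinity_true`).
#' @param scores Numeric vector of predictions, same length and order as
#'   `pairs` rows.
#' @param path Output CSV path.
#' @return The written tibble, invisibly.
#' @export
write_predictions <- function(pairs, scores, path) {
  pairs <- tibble::as_tibble(pairs)
  if (nrow(pairs) != length(scores)) {
    stop("length mismatch: ", nrow(pairs), " pairs vs ", length(scores),
         " scores", call. = FALSE)
  }
  out <- tibble::tibble(rna_id = pairs$rna_id, mol_id = pairs$mol_id)
  if ("affinity" %in% names(pairs)) out$affinity_true <- pairs$affinity
  out$affinity_pred <- as.numeric(scores)
  readr::write_csv(out, path, progress = FALSE)
  invisible(out)
}

#' Write a dataset to the on-disk formats the loaders consume
#'
#' Emits `pairs.csv`, `rnas.fasta`, `mols.smi`, and optionally one
#' whitespace-delimited contact-map matrix file per RNA under
#' `contact_maps/`, plus one embedding matrix file per RNA under
#' `embeddings/`.
#'
#' @param dataset An [rsma_dataset()].
#' @param dir Output directory (created if needed).
#' @param contact_maps Optional named list of p x p 0/1 matrices.
#' @param embeddings Optional named list of p x d matrices.
#' @return `dir`, invisibly.
#' @export
write_dataset_files <- function(dataset, dir, contact_maps = NULL,
                                embeddings = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(dataset$pairs, file.path(dir, "pairs.csv"), progress = FALSE)
  fasta <- Biostrings::BStringSet(stats::setNames(dataset$rnas$sequence,
                                                  dataset$rnas$id))
  Biostrings::writeXStringSet(fasta, file.path(dir, "rnas.fasta"))
  writeLines(paste(dataset$molecules$smiles, dataset$molecules$id),
             file.path(dir, "mols.smi"))
  if (!is.null(contact_maps)) {
    cdir <- file.path(dir, "contact_maps")
    dir.create(cdir, showWarnings = FALSE)
    for (id in names(contact_maps)) {
      utils::write.table(contact_maps[[id]], file.path(cdir, paste0(id, ".txt")),
                         row.names = FALSE, col.names = FALSE)
    }
  }
  if (!is.null(embeddings)) {
    edir <- file.path(dir, "embeddings")
    dir.create(edir, showWarnings = FALSE)
    for (id in names(embeddings)) {
      utils::write.table(embeddings[[id]], file.path(edir, paste0(id, ".txt")),
                         row.names = FALSE, col.names = FALSE)
    }
  }
  invisible(dir)
}
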