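#' Construct a proteome
#'
#' A proteome is the complete protein complement of one genome assembly: an
#' ordered set of amino-acid sequences plus the metadata used for redundancy
#' ranking. It is the node type of the redundancy graph.
#'
#' @param proteome_id Single non-empty string identifying the proteome.
#' @param proteins A data frame (or tibble) with columns `protein_id` and
#'   `sequence`; a `length` column is derived. Row order is preserved.
#' @param species_group_id Taxonomic grouping key; only proteomes sharing a
#'   `species_group_id` are ever compared.
#' @param is_reference Is this a curator-designated reference proteome?
#'   Reference proteomes are protected from removal and carry priority
#'   score 2 (all others 1).
#' @param annotation_level Number of curator-reviewed entries (integer >= 0).
#' @param previous_state 1 if the proteome was non-redundant in the previous
#'   run (or has never been processed), 0 if it was redundant.
#'
#' @return An object of class `proteome`: a list with elements `proteome_id`,
#'   `species_group_id`, `proteins` (tibble with `protein_id`, `sequence`,
#'   `length`) and `metadata` (list with `is_reference`, `priority_score`,
#'   `annotation_level`, `previous_state`).
#' @examples
#' p <- proteome("UP1", tibble::tibble(protein_id = "a", sequence = "MKV"))
#' p$proteins$length
#' @export
proteome <- function(proteome_id, proteins, species_group_id = "default",
                     is_reference = FALSE, annotation_level = 0L,
                     previous_state = 1L) {
  if (!is.character(proteome_id) || length(proteome_id) != 1 ||
      !nzchar(proteome_id)) {
    abort("`proteome_id` must be a single non-empty string.")
  }
  proteins <- tibble::as_tibble(proteins)
  if (!all(c("protein_id", "sequence") %in% names(proteins))) {
    abort("`proteins` must have columns `protein_id` and `sequence`.")
  }
  if (nrow(proteins) == 0) {
    abort(sprintf("Proteome '%s' has no proteins.", proteome_id))
  }
  proteins$sequence <- toupper(proteins$sequence)
  proteins$sequence <- sub("\\*+$", "", proteins$sequence)
  dup <- proteins$protein_id[duplicated(proteins$protein_id)]
  if (length(dup) > 0) {
    abort(sprintf("Duplicate protein id(s) in proteome '%s': %s",
                  proteome_id, paste(unique(dup), collapse = ", ")))
  }
  validate_sequences(proteins$protein_id, proteins$sequence, proteome_id)
  proteins$length <- nchar(proteins$sequence)
  if (any(proteins$length < 1)) {
    abort(sprintf("Proteome '%s' contains an empty sequence.", proteome_id))
  }
  structure(
    list(
      proteome_id = proteome_id,
      species_group_id = as.character(species_group_id),
      proteins = proteins[, c("protein_id", "sequence", "length")],
      metadata = proteome_metadata(is_reference, annotation_level,
                                   previous_state)
    ),
    class = "proteome"
  )
}

# Ranking metadata for one proteome; priority score is derived, not free.
proteome_metadata <- function(is_reference, annotation_level, previous_state,
                              priority_score = NULL) {
  is_reference <- as.logical(is_reference)
  derived <- if (is_reference) 2L else 1L
  if (!is.null(priority_score) && as.integer(priority_score) != derived) {
    abort(sprintf(
      "priority_score must be %d for %s proteomes, got %s.",
      derived, if (is_reference) "reference" else "non-reference",
      priority_score))
  }
  previous_state <- as.integer(previous_state)
  if (!previous_state %in% c(0L, 1L)) {
    abort("`previous_state` must be 0 (redundant) or 1 (non-redundant).")
  }
  annotation_level <- as.integer(annotation_level)
  if (is.na(annotation_level) || annotation_level < 0) {
    abort("`annotation_level` must be a non-negative integer.")
  }
  list(is_reference = is_reference, priority_score = derived,
       annotation_level = annotation_level, previous_state = previous_state)
}

validate_sequences <- function(ids, seqs, proteome_id) {
  bad <- !grepl(paste0("^[", paste(aa_extended, collapse = ""), "]+$"), seqs)
  if (any(bad)) {
    i <- which(bad)[1]
    pos <- regexpr(paste0("[^", paste(aa_extended, collapse = ""), "]"),
                   seqs[i])
    abort(sprintf(
      "Invalid residue '%s' at position %d of record '%s' in proteome '%s'.",
      substr(seqs[i], pos, pos), pos, ids[i], proteome_id))
  }
  invisible(TRUE)
}

#' @export
print.proteome <- function(x, ...) {
  cat(sprintf("<proteome> %s  (species group: %s)\n", x$proteome_id,
              x$species_group_id))
  cat(sprintf("  %d proteins, %d residues total\n", nrow(x$proteins),
              sum(x$proteins$length)))
  cat(sprintf("  reference: %s, annotation level: %d, previous state: %d\n",
              x$metadata$is_reference, x$metadata$annotation_level,
              x$metadata$previous_state))
  invisible(x)
}

#' Read a proteome from a protein FASTA file
#'
#' The first whitespace-delimited token of each header is taken as the
#' protein id. Sequences are upper-cased and terminal stop symbols (`*`)
#' stripped; residues outside the 20 standard amino acids plus B, Z, X, U, O
#' are rejected.
#'
#' @param path Path to a protein FASTA file.
#' @param proteome_id Identifier assigned to the proteome.
#' @inheritParams proteome
#' @return A [proteome] with records in file order.
#' @export
read_proteome_fasta <- function(path, proteome_id,
                                species_group_id = "default",
                                is_reference = FALSE, annotation_level = 0L,
                                previous_state = 1L) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  # read as raw byte strings so invalid residues reach our validator
  # instead of being silently dropped
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0) abort(sprintf("FASTA file is empty: %s", path))
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1)
  proteome(
    proteome_id = proteome_id,
    proteins = tibble::tibble(protein_id = ids,
                              sequence = unname(as.character(seqs))),
    species_group_id = species_group_id,
    is_reference = is_reference,
    annotation_level = annotation_level,
    previous_state = previous_state
  )
}

#' Write a proteome to a protein FASTA file
#'
#' Round-trips losslessly with [read_proteome_fasta()]: ids, sequences and
#' record order are preserved.
#'
#' @param x A [proteome].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_proteome_fasta <- function(x, path) {
  stopifnot(inherits(x, "proteome"))
  seqs <- Biostrings::AAStringSet(x$proteins$sequence)
  names(seqs) <- x$proteins$protein_id
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a proteome metadata table
#'
#' Tab-separated with a header row; required columns `proteome_id`,
#' `species_group_id`, `is_reference`, `priority_score`, `annotation_level`.
#' The `previous_state` column may be omitted, in which case every proteome
#' defaults to 1 (previously non-redundant) so that a first run treats all
#' proteomes as never-before-removed.
#'
#' @param path Path to the TSV file.
#' @return A tibble with one row per proteome: `proteome_id`,
#'   `species_group_id`, `is_reference` (logical), `priority_score`,
#'   `annotation_level`, `previous_state` (all integer).
#' @export
read_metadata_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("Metadata file not found: %s", path))
  md <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = "c"))
  required <- c("proteome_id", "species_group_id", "is_reference",
                "priority_score", "annotation_level")
  missing <- setdiff(required, names(md))
  if (length(missing) > 0) {
    abort(sprintf("Metadata table is missing column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  if (!"previous_state" %in% names(md)) md$previous_state <- "1"
  md$previous_state[is.na(md$previous_state)] <- "1"
  out <- tibble::tibble(
    proteome_id = md$proteome_id,
    species_group_id = md$species_group_id,
    is_reference = parse_flag(md$is_reference, "is_reference"),
    priority_score = as.integer(md$priority_score),
    annotation_level = as.integer(md$annotation_level),
    previous_state = as.integer(md$previous_state)
  )
  validate_metadata(out)
  out
}

parse_flag <- function(x, what) {
  v <- tolower(trimws(x))
  out <- v %in% c("1", "true", "t", "yes")
  bad <- !v %in% c("1", "true", "t", "yes", "0", "false", "f", "no")
  if (any(bad)) {
    abort(sprintf("Cannot parse %s value '%s' as a boolean.",
                  what, x[which(bad)[1]]))
  }
  out
}

validate_metadata <- function(md) {
  dup <- md$proteome_id[duplicated(md$proteome_id)]
  if (length(dup) > 0) {
    abort(sprintf("Duplicate proteome id(s) in metadata: %s",
                  paste(unique(dup), collapse = ", ")))
  }
  expected <- ifelse(md$is_reference, 2L, 1L)
  bad <- which(md$priority_score != expected)
  if (length(bad) > 0) {
    abort(sprintf(
      "Proteome '%s': priority_score %d inconsistent with is_reference=%s (reference proteomes score 2, others 1).",
      md$proteome_id[bad[1]], md$priority_score[bad[1]],
      md$is_reference[bad[1]]))
  }
  if (!all(md$previous_state %in% c(0L, 1L))) {
    abort("previous_state must be 0 or 1.")
  }
  if (any(is.na(md$annotation_level)) || any(md$annotation_level < 0)) {
    abort("annotation_level must be a non-negative integer.")
  }
  invisible(md)
}

#' Write a metadata table
#'
#' Inverse of [read_metadata_table()]; the round trip is lossless.
#'
#' @param md Metadata tibble as returned by [read_metadata_table()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_metadata_table <- function(md, path) {
  validate_metadata(md)
  out <- md
  out$is_reference <- as.integer(out$is_reference)
  readr::write_tsv(out, path)
  invisible(path)
}

#' Write a redundancy results table
#'
#' One row per proteome, tab-separated: `proteome_id`, `status`
#' (`redundant` or `non-redundant`) and the semicolon-joined ids of its
#' surviving representatives (empty for non-redundant proteomes). Rows are
#' sorted by `proteome_id` for deterministic output.
#'
#' @param statuses A data frame with columns `proteome_id`, `status` and
#'   `representatives` (a list-column of character vectors, or a character
#'   column of semicolon-joined ids).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(statuses, path) {
  statuses <- tibble::as_tibble(statuses)
  stopifnot(all(c("proteome_id", "status", "representatives") %in%
                  names(statuses)))
  if (!all(statuses$status %in% c("redundant", "non-redundant"))) {
    abort("status must be 'redundant' or 'non-redundant'.")
  }
  reps <- statuses$representatives
  if (is.list(reps)) {
    reps_chr <- vapply(reps, function(r) paste(r, collapse = ";"),
                       character(1))
  } else {
    reps_chr <- ifelse(is.na(reps), "", as.character(reps))
  }
  empty_red <- statuses$status == "redundant" & !nzchar(reps_chr)
  if (any(empty_red)) {
    abort(sprintf(
      "Redundant proteome(s) without a representative: %s",
      paste(statuses$proteome_id[empty_red], collapse = ", ")))
  }
  out <- tibble::tibble(
    proteome_id = statuses$proteome_id,
    status = statuses$status,
    representatives = reps_chr
  )
  out <- out[order(out$proteome_id), ]
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read a redundancy results table written by [write_results_table()]
#'
#' @param path Path to the results TSV.
#' @return A tibble with `proteome_id`, `status` and a `representatives`
#'   list-column of character vectors.
#' @export
read_results_table <- function(path) {
  res <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  stopifnot(all(c("proteome_id", "status", "representatives") %in% names(res)))
  res$representatives <- lapply(res$representatives, function(r) {
    if (is.na(r) || !nzchar(r)) character(0) else strsplit(r, ";")[[1]]
  })
  tibble::as_tibble(res)
}

# Extract the per-proteome metadata tibble from a list of proteome objects.
proteomes_metadata <- function(proteomes) {
  purrr::map_dfr(proteomes, function(p) {
    tibble::tibble(
      proteome_id = p$proteome_id,
      species_group_id = p$species_group_id,
      is_reference = p$metadata$is_reference,
      priority_score = p$metadata$priority_score,
      annotation_level = p$metadata$annotation_level,
      previous_state = p$metadata$previous_state
    )
  })
}
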