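#' Length-weighted proteome similarity score
#'
#' The similarity of a query proteome B to a subject proteome A is the
#' length-weighted mean of the per-protein identities:
#' `S(A, B) = sum(length(b) * AS90(A, b)) / sum(length(b))` over all
#' proteins b of B, where `AS90(A, b)` is the identity of b to the longest
#' seed of A reaching the identity threshold, and 0 when no seed qualifies.
#' Unmatched proteins therefore contribute nothing to the numerator but
#' their full length to the denominator.
#'
#' @param weighted_matches A data frame with columns `query_length` (residue
#'   counts, >= 1) and `identity` (fractions in \[0, 1\]), one row per query
#'   protein — the shape returned by [match_sequences()].
#' @return The similarity fraction in \[0, 1\].
#' @examples
#' # two phage-sized proteomes of four proteins
#' similarity_score(data.frame(
#'   query_length = c(545, 393, 130, 75),
#'   identity = c(0.9853, 0.9975, 1, 1)))  # 0.9921
#' @export
similarity_score <- function(weighted_matches) {
  m <- tibble::as_tibble(weighted_matches)
  if (!all(c("query_length", "identity") %in% names(m))) {
    abort("`weighted_matches` needs columns `query_length` and `identity`.")
  }
  if (nrow(m) == 0) abort("A proteome has at least one protein.")
  if (any(m$query_length < 1)) abort("Protein lengths must be >= 1.")
  if (any(m$identity < 0 | m$identity > 1)) {
    abort("Identities must be in [0, 1].")
  }
  sum(m$query_length * m$identity) / sum(m$query_length)
}

#' Proteome size heuristic
#'
#' Pre-filter applied before a full comparison: testing proteome B (the
#' query) for redundancy against subject A is only worthwhile when A is not
#' much smaller than B — a small subject cannot cover a much larger query at
#' high similarity. The comparison is performed iff
#' `factor * query_count <= subject_count`. With the default factor 0.9, a
#' 10 000-protein query is never tested against a 1000-protein subject
#' (10 000 x 0.9 > 1000), while the opposite direction is performed
#' (1000 x 0.9 < 10 000: the small proteome can still be redundant to the
#' large one).
#'
#' @param query_count Number of proteins in the proteome tested for
#'   redundancy.
#' @param subject_count Number of proteins in the subject proteome.
#' @param factor Size factor in (0, 1\] (default 0.9).
#' @return `TRUE` if the full comparison should be performed.
#' @export
size_heuristic <- function(query_count, subject_count, factor = 0.9) {
  stopifnot(query_count >= 1, subject_count >= 1, factor > 0, factor <= 1)
  factor * query_count <= subject_count
}

#' Partition proteomes by species group
#'
#' The taxonomy heuristic: only proteomes of the same species (including
#' strains, sub-strains and isolates) are ever compared, so the comparison
#' space is partitioned by `species_group_id` and no cross-group pair is
#' evaluated.
#'
#' @param proteomes A list of [proteome] objects.
#' @return A named list mapping each `species_group_id` to the character
#'   vector of its proteome ids (in input order).
#' @export
group_by_species <- function(proteomes) {
  ids <- unname(vapply(proteomes, function(p) p$proteome_id, character(1)))
  groups <- unname(vapply(proteomes, function(p) p$species_group_id,
                          character(1)))
  split(ids, groups)
}

#' Compare all ordered proteome pairs within one species group
#'
#' For every ordered pair (subject A, query B) with A != B: if the size
#' heuristic passes, the query's proteins are greedily matched against the
#' subject's seeds and the length-weighted similarity `S(A, B)` computed;
#' otherwise the pair is recorded as skipped. Each subject's seed index is
#' built at most once. Both orientations of a pair are evaluated
#' independently — proteome similarity is non-symmetric, and mutual
#' redundancy yields two graph edges.
#'
#' @param group A list of [proteome] objects from one species group.
#' @param identity_threshold Per-protein identity cut-off (default 0.9).
#' @param size_factor Size-heuristic factor (default 0.9).
#' @param word_size Word filter k-mer length (default 5).
#' @return A tibble of comparison records: `subject_id`, `query_id`,
#'   `similarity` (`NA` when skipped) and `performed`.
#' @export
compare_group <- function(group, identity_threshold = 0.9,
                          size_factor = 0.9, word_size = 5L) {
  stopifnot(all(vapply(group, inherits, logical(1), "proteome")))
  n <- length(group)
  if (n < 2) {
    return(tibble::tibble(subject_id = character(0), query_id = character(0),
                          similarity = numeric(0), performed = logical(0)))
  }
  sgid <- unique(vapply(group, function(p) p$species_group_id, character(1)))
  if (length(sgid) > 1) {
    abort(sprintf("compare_group expects a single species group, got: %s",
                  paste(sgid, collapse = ", ")))
  }
  counts <- vapply(group, function(p) nrow(p$proteins), integer(1))
  indexes <- vector("list", n)
  out <- vector("list", n * (n - 1))
  k <- 0
  for (ai in seq_len(n)) {
    for (bi in seq_len(n)) {
      if (ai == bi) next
      k <- k + 1
      subject <- group[[ai]]
      query <- group[[bi]]
      if (!size_heuristic(counts[bi], counts[ai], size_factor)) {
        out[[k]] <- tibble::tibble(subject_id = subject$proteome_id,
                                   query_id = query$proteome_id,
                                   similarity = NA_real_, performed = FALSE)
        next
      }
      if (is.null(indexes[[ai]])) {
        indexes[[ai]] <- build_seed_index(subject, word_size)
      }
      matches <- match_sequences(query, indexes[[ai]], identity_threshold)
      out[[k]] <- tibble::tibble(subject_id = subject$proteome_id,
                                 query_id = query$proteome_id,
                                 similarity = similarity_score(matches),
                                 performed = TRUE)
    }
  }
  dplyr::bind_rows(out[seq_len(k)])
}

#' Compare one ordered proteome pair
#'
#' Convenience wrapper computing `S(subject, query)` directly, bypassing the
#' size heuristic. Useful for inspecting a single comparison (including a
#' self-comparison, for which the score is 1).
#'
#' @inheritParams compare_group
#' @param subject,query [proteome] objects.
#' @return The similarity fraction `S(subject, query)`.
#' @export
compare_proteomes <- function(subject, query, identity_threshold = 0.9,
                              word_size = 5L) {
  index <- build_seed_index(subject, word_size)
  similarity_score(match_sequences(query, index, identity_threshold))
}
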