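# Shared fixture builders. Everything is generated in code; no data files.

# deterministic random amino-acid sequence over the 20 standard residues
random_seq <- function(n, seed = NULL) {
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  if (!is.null(seed)) set.seed(seed)
  paste(sample(aa, n, replace = TRUE), collapse = "")
}

# substitute exactly n_sub positions; replacement defaults to a residue
# guaranteed absent from the original so the identity is exactly
# (L - n_sub) / L with no realignment gain
substitute_positions <- function(seq, n_sub, replacement = NULL,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  chars <- strsplit(seq, "")[[1]]
  pos <- sample(length(chars), n_sub)
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  for (p in pos) {
    chars[p] <- if (is.null(replacement)) {
      sample(setdiff(aa, chars[p]), 1)
    } else replacement
  }
  paste(chars, collapse = "")
}

toy_proteome <- function(id, seqs, group = "g", ...) {
  proteome(id, tibble::tibble(
    protein_id = sprintf("%s_p%d", id, seq_along(seqs)),
    sequence = seqs), species_group_id = group, ...)
}

# metadata tibble for a set of ids with per-id overrides
toy_metadata <- function(ids, group = "g", is_reference = FALSE,
                         annotation_level = 0L, previous_state = 1L) {
  tibble::tibble(
    proteome_id = ids,
    species_group_id = group,
    is_reference = rep_len(is_reference, length(ids)),
    priority_score = ifelse(rep_len(is_reference, length(ids)), 2L, 1L),
    annotation_level = rep_len(as.integer(annotation_level), length(ids)),
    previous_state = rep_len(as.integer(previous_state), length(ids))
  )
}

# graph straight from an edge data frame (similarities default 0.95)
toy_graph <- function(edges, ids = NULL, metadata = NULL, threshold = 0.9) {
  edges <- as.data.frame(edges)
  if (is.null(edges$similarity)) {
    edges$similarity <- rep(0.95, nrow(edges))
  }
  if (is.null(metadata)) {
    ids <- unique(c(ids, edges$from, edges$to))
    metadata <- toy_metadata(ids)
  }
  comparisons <- tibble::tibble(
    subject_id = edges$to, query_id = edges$from,
    similarity = edges$similarity, performed = TRUE)
  build_graph(comparisons, metadata, threshold = threshold)
}

# seeded random digraph with uniform edge probability and similarities
# uniform in [0.9, 1]; annotation levels and previous states vary so rank
# comparisons exercise every component
random_digraph <- function(n, density, seed) {
  set.seed(seed)
  ids <- sprintf("P%02d", seq_len(n))
  md <- tibble::tibble(
    proteome_id = ids, species_group_id = "g",
    is_reference = FALSE, priority_score = 1L,
    annotation_level = sample(0:5, n, replace = TRUE),
    previous_state = sample(0:1, n, replace = TRUE)
  )
  pairs <- expand.grid(from = ids, to = ids, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  keep <- stats::runif(nrow(pairs)) < density
  edges <- pairs[keep, ]
  edges$similarity <- stats::runif(nrow(edges), 0.9, 1)
  comparisons <- tibble::tibble(
    subject_id = edges$to, query_id = edges$from,
    similarity = edges$similarity, performed = TRUE)
  build_graph(comparisons, md, threshold = 0.9)
}

# independent identity oracle: Biostrings global alignment with match +1,
# mismatch 0, free gaps — maximizes identical aligned columns
oracle_identity <- function(a, b) {
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
          "M", "F", "P", "S", "T", "W", "Y", "V", "B", "Z", "X", "U", "O")
  mat <- matrix(0L, length(aa), length(aa), dimnames = list(aa, aa))
  diag(mat) <- 1L
  pa <- Biostrings::pairwiseAlignment(
    a, b, type = "global", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = 0)
  as.numeric(Biostrings::score(pa)) / min(nchar(a), nchar(b))
}
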