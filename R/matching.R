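#' Build a seed index over a subject proteome
#'
#' Orders the subject's proteins as cluster seeds — descending length, ties
#' by ascending protein id so runs are reproducible — and builds an inverted
#' k-mer index used to skip hopeless query/seed pairs before alignment.
#'
#' @param subject A [proteome] (dataset A of the asymmetric comparison).
#' @param word_size k-mer length for the word filter (default 5, the CD-HIT
#'   default for identity thresholds of 0.7 and above).
#' @return An object of class `seed_index` with elements
#'   `subject_proteome_id`, `seeds` (tibble: `protein_id`, `sequence`,
#'   `length`, in seed order), `seed_kmers` (list of per-seed k-mer
#'   vectors), `word_index` (hashed environment mapping k-mer to integer
#'   seed positions) and `word_size`.
#' @export
build_seed_index <- function(subject, word_size = 5L) {
  stopifnot(inherits(subject, "proteome"))
  word_size <- as.integer(word_size)
  if (word_size < 2) abort("`word_size` must be >= 2.")
  ord <- order(-subject$proteins$length, subject$proteins$protein_id)
  seeds <- subject$proteins[ord, ]
  seed_kmers <- lapply(seeds$sequence, kmers, w = word_size)
  word_index <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(nrow(seeds))) {
    for (k in unique(seed_kmers[[i]])) {
      word_index[[k]] <- c(word_index[[k]], i)
    }
  }
  structure(
    list(subject_proteome_id = subject$proteome_id, seeds = seeds,
         seed_kmers = seed_kmers, word_index = word_index,
         word_size = word_size),
    class = "seed_index"
  )
}

kmers <- function(seq, w) {
  n <- nchar(seq)
  if (n < w) return(character(0))
  substring(seq, 1:(n - w + 1), w:n)
}

#' Greedily match query proteins against a subject's seeds
#'
#' CD-HIT-2D-style asymmetric clustering: each query protein is compared
#' against the subject's seeds in descending-length order until the first
#' seed reaching the identity threshold is found; being first in that order,
#' it is the longest qualifying seed. Seeds whose shared k-mer count cannot
#' support the threshold are skipped without alignment. A query protein with
#' no qualifying seed is recorded with identity 0.
#'
#' @param query A [proteome] (dataset B, the one tested for redundancy).
#' @param index A `seed_index` from [build_seed_index()].
#' @param identity_threshold Minimum identity for a match (default 0.9).
#' @param use_word_filter Disable only to cross-check that the filter is
#'   lossless; results must be identical either way.
#' @return A tibble with one row per query protein: `query_protein_id`,
#'   `query_length`, `matched_seed_id` (`NA` when unmatched) and `identity`
#'   (0 when unmatched).
#' @export
match_sequences <- function(query, index, identity_threshold = 0.9,
                            use_word_filter = TRUE) {
  stopifnot(inherits(query, "proteome"), inherits(index, "seed_index"))
  if (!(identity_threshold > 0 && identity_threshold <= 1)) {
    abort("`identity_threshold` must be in (0, 1].")
  }
  seeds <- index$seeds
  n_seeds <- nrow(seeds)
  w <- index$word_size
  res_seed <- character(nrow(query$proteins))
  res_ident <- numeric(nrow(query$proteins))
  for (qi in seq_len(nrow(query$proteins))) {
    qseq <- query$proteins$sequence[qi]
    qlen <- query$proteins$length[qi]
    qk <- NULL
    shared_q <- NULL
    if (use_word_filter) {
      qk <- kmers(qseq, w)
      # per query position, each seed containing that k-mer counts once:
      # shared_q[si] = number of query k-mer positions preserved in seed si
      hits <- unlist(mget(qk, envir = index$word_index,
                          ifnotfound = list(integer(0))),
                     use.names = FALSE)
      shared_q <- tabulate(hits, nbins = n_seeds)
    }
    best <- NA_character_
    ident <- 0
    for (si in seq_len(n_seeds)) {
      if (use_word_filter) {
        slen <- seeds$length[si]
        L <- min(qlen, slen)
        bound <- kmer_lower_bound(L, w, identity_threshold)
        if (bound > 0) {
          # the bound counts preserved k-mers of the *shorter* sequence
          shared <- if (qlen <= slen) shared_q[si]
                    else sum(index$seed_kmers[[si]] %in% qk)
          if (shared < bound) next
        }
      }
      id_frac <- pairwise_identity(qseq, seeds$sequence[si])
      if (id_frac >= identity_threshold) {
        best <- seeds$protein_id[si]
        ident <- id_frac
        break
      }
    }
    res_seed[qi] <- best
    res_ident[qi] <- ident
  }
  tibble::tibble(
    query_protein_id = query$proteins$protein_id,
    query_length = query$proteins$length,
    matched_seed_id = res_seed,
    identity = res_ident
  )
}
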