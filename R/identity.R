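#' Percent identity of two protein sequences
#'
#' Global (end-to-end) alignment maximizing the number of identical aligned
#' columns, with free gaps; identity is the match count divided by the
#' length of the *shorter* sequence (the CD-HIT convention). The measure is
#' symmetric, equals 1 for identical sequences, and equals 1 whenever one
#' sequence is an exact subsequence of the other.
#'
#' @param seq_a,seq_b Non-empty amino-acid strings.
#' @return Identity fraction in \[0, 1\].
#' @examples
#' pairwise_identity("AAAA", "AAAT")  # 0.75
#' @export
pairwise_identity <- function(seq_a, seq_b) {
  if (!is.character(seq_a) || !is.character(seq_b) ||
      length(seq_a) != 1 || length(seq_b) != 1 ||
      !nzchar(seq_a) || !nzchar(seq_b)) {
    abort("Both sequences must be single non-empty strings.")
  }
  matches <- .align_match_count(seq_a, seq_b)
  matches / min(nchar(seq_a), nchar(seq_b))
}

#' Word filter: can a sequence pair possibly reach an identity threshold?
#'
#' A fast k-mer screen applied before alignment. A pair at identity `c` over
#' shorter length `L` (substitution divergence) must share at least
#' `L - word_size * ceiling((1 - c) * L) - word_size + 1` k-mers: each of the
#' at most `ceiling((1 - c) * L)` differing positions destroys at most
#' `word_size` of the shorter sequence's `L - word_size + 1` k-mers. When the
#' observed shared k-mer count falls below that bound the pair provably
#' cannot reach the threshold and `FALSE` is returned; the filter never
#' rejects a pair that meets the threshold under substitution divergence.
#'
#' @param query,seed Either [proteome] protein rows (lists/one-row data
#'   frames with a `sequence` field) or plain sequence strings.
#' @param word_size k-mer length (integer >= 2; default 5).
#' @param identity_threshold The identity the pair would need to reach.
#' @return `TRUE` if the pair may reach the threshold, `FALSE` if it
#'   provably cannot.
#' @export
word_filter_passes <- function(query, seed, word_size = 5L,
                               identity_threshold = 0.9) {
  qs <- as_sequence(query)
  ss <- as_sequence(seed)
  word_size <- as.integer(word_size)
  if (word_size < 2) abort("`word_size` must be >= 2.")
  L <- min(nchar(qs), nchar(ss))
  bound <- kmer_lower_bound(L, word_size, identity_threshold)
  if (bound <= 0) return(TRUE)
  shorter <- if (nchar(qs) <= nchar(ss)) qs else ss
  longer <- if (nchar(qs) <= nchar(ss)) ss else qs
  .shared_kmer_count(shorter, longer, word_size) >= bound
}

# Minimum number of shorter-sequence k-mers that must be preserved for a
# pair to reach identity `threshold` over shorter length L.
kmer_lower_bound <- function(L, word_size, threshold) {
  max(0, L - word_size * ceiling((1 - threshold) * L) - word_size + 1)
}

as_sequence <- function(x) {
  if (is.character(x) && length(x) == 1) return(x)
  if (!is.null(x$sequence)) return(as.character(x$sequence)[1])
  abort("Expected a sequence string or a record with a `sequence` field.")
}
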