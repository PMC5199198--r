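#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>

// Number of identical aligned columns in an optimal global alignment with
// match +1, mismatch 0, gap 0 (free end gaps included). With that scoring
// the optimum equals the longest common subsequence, computed here with a
// two-row dynamic programme: O(m*n) time, O(min(m,n)) memory.
// [[Rcpp::export(name = ".align_match_count")]]
int align_match_count(const std::string &a, const std::string &b) {
  const std::string &s = (a.size() <= b.size()) ? a : b;
  const std::string &t = (a.size() <= b.size()) ? b : a;
  const size_t n = s.size(), m = t.size();
  if (n == 0) Rcpp::stop("sequences must be non-empty");
  std::vector<int> prev(n + 1, 0), cur(n + 1, 0);
  for (size_t i = 1; i <= m; ++i) {
    const char ti = t[i - 1];
    for (size_t j = 1; j <= n; ++j) {
      if (s[j - 1] == ti)
        cur[j] = prev[j - 1] + 1;
      else
        cur[j] = std::max(prev[j], cur[j - 1]);
    }
    std::swap(prev, cur);
  }
  return prev[n];
}

// Count of k-mer start positions in `query` whose k-mer occurs anywhere in
// `seed`. Upper-bounds the number of query k-mers preserved in an alignment,
// which is what the word filter's lower bound is compared against.
// [[Rcpp::export(name = ".shared_kmer_count")]]
int shared_kmer_count(const std::string &query, const std::string &seed,
                      const int word_size) {
  if (word_size < 2) Rcpp::stop("word_size must be >= 2");
  const size_t w = (size_t)word_size;
  if (seed.size() < w || query.size() < w) return 0;
  std::vector<std::string> kmers;
  kmers.reserve(seed.size() - w + 1);
  for (size_t i = 0; i + w <= seed.size(); ++i)
    kmers.push_back(seed.substr(i, w));
  std::sort(kmers.begin(), kmers.end());
  int shared = 0;
  for (size_t i = 0; i + w <= query.size(); ++i) {
    if (std::binary_search(kmers.begin(), kmers.end(), query.substr(i, w)))
      ++shared;
  }
  return shared;
}
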