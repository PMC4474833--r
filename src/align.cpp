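// Modification-aware semi-global alignment of small-RNA reads to tRNA
// references.  The read must be explained end to end; both reference ends
// are free.  Reference positions carrying modified nucleotides match any
// read base at zero cost (reverse transcription misreads them), and all
// edit operations (mismatch, insertion, deletion) cost one error.

#include <Rcpp.h>
#include <algorithm>
#include <climits>
#include <string>
#include <vector>
using namespace Rcpp;

static inline bool base_match(char a, char b) {
  return a == b || a == 'N' || b == 'N';
}

// Fill the DP table row by row (rows = read positions).  Row 0 is all zero
// (free start anywhere on the reference); column 0 costs i (read bases
// hanging off the reference 5' end).  Abandons once the row minimum exceeds
// `threshold` and returns threshold + 1.  On success returns the minimum of
// the last row and sets best_j to its rightmost column (1-based).
static int dp_fill(const std::string& read, const std::string& ref,
                   const std::vector<char>& wild, int threshold,
                   std::vector<int>& D, int& best_j) {
  const int m = (int)read.size(), n = (int)ref.size();
  for (int j = 0; j <= n; ++j) D[j] = 0;
  for (int i = 1; i <= m; ++i) {
    const int* prev = &D[(size_t)(i - 1) * (n + 1)];
    int* cur = &D[(size_t)i * (n + 1)];
    cur[0] = i;
    int rowmin = cur[0];
    const char rc = read[i - 1];
    for (int j = 1; j <= n; ++j) {
      const int cost = (wild[j - 1] || base_match(rc, ref[j - 1])) ? 0 : 1;
      int v = prev[j - 1] + cost;
      const int v2 = prev[j] + 1;
      if (v2 < v) v = v2;
      const int v3 = cur[j - 1] + 1;
      if (v3 < v) v = v3;
      cur[j] = v;
      if (v < rowmin) rowmin = v;
    }
    if (rowmin > threshold) { best_j = -1; return threshold + 1; }
  }
  const int* last = &D[(size_t)m * (n + 1)];
  int best = INT_MAX;
  best_j = 0;
  for (int j = 0; j <= n; ++j)
    if (last[j] <= best) { best = last[j]; best_j = j; }  // rightmost tie
  return best;
}

// Walk back from (m, end_j), preferring diagonal moves; counts alignment
// columns and finds the first aligned reference position.
static void dp_traceback(const std::string& read, const std::string& ref,
                         const std::vector<char>& wild,
                         const std::vector<int>& D, int end_j,
                         int& start_j, int& aligned_len) {
  const int n = (int)ref.size();
  int i = (int)read.size(), j = end_j, len = 0;
  while (i > 0) {
    const int cur = D[(size_t)i * (n + 1) + j];
    if (j > 0) {
      const int cost =
          (wild[j - 1] || base_match(read[i - 1], ref[j - 1])) ? 0 : 1;
      if (D[(size_t)(i - 1) * (n + 1) + (j - 1)] + cost == cur) {
        --i; --j; ++len;
        continue;
      }
    }
    if (D[(size_t)(i - 1) * (n + 1) + j] + 1 == cur) { --i; ++len; continue; }
    --j; ++len;  // deletion from the reference
  }
  start_j = j;
  aligned_len = len;
}

// Cheap upper bound on the semi-global error count: gapless alignment of
// the read to the reference 5' end (reads are 3'-truncated copies of the
// reference, so this diagonal is where true hits live).
static int ham_bound(const std::string& read, const std::string& ref,
                     const std::vector<char>& wild, int cap) {
  const int m = (int)read.size(), n = (int)ref.size();
  int e = m > n ? m - n : 0;
  const int L = std::min(m, n);
  for (int i = 0; i < L && e <= cap; ++i)
    if (!wild[i] && !base_match(read[i], ref[i])) ++e;
  return e;
}

// [[Rcpp::export(name = ".align_read_cpp")]]
List align_read_cpp(std::string read, std::string ref, IntegerVector mask) {
  if (read.empty() || ref.empty()) stop("empty sequence");
  const int m = (int)read.size(), n = (int)ref.size();
  std::vector<char> wild(n, 0);
  for (int t = 0; t < mask.size(); ++t)
    if (mask[t] >= 0 && mask[t] < n) wild[mask[t]] = 1;
  std::vector<int> D((size_t)(m + 1) * (n + 1));
  int ej = 0;
  const int e = dp_fill(read, ref, wild, INT_MAX - 1, D, ej);
  int sj = 0, len = 0;
  dp_traceback(read, ref, wild, D, ej, sj, len);
  return List::create(_["errors"] = e, _["ref_start"] = sj,
                      _["ref_end"] = ej - 1, _["aligned_length"] = len);
}

// Strictly local (Smith-Waterman-style) variant: +1 match, -1 mismatch/gap,
// modified positions score as matches.  Errors are counted on the traceback
// of the maximal-scoring local path.
// [[Rcpp::export(name = ".align_local_cpp")]]
List align_local_cpp(std::string read, std::string ref, IntegerVector mask) {
  if (read.empty() || ref.empty()) stop("empty sequence");
  const int m = (int)read.size(), n = (int)ref.size();
  std::vector<char> wild(n, 0);
  for (int t = 0; t < mask.size(); ++t)
    if (mask[t] >= 0 && mask[t] < n) wild[mask[t]] = 1;
  std::vector<int> S((size_t)(m + 1) * (n + 1), 0);
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      const bool ok = wild[j - 1] || base_match(read[i - 1], ref[j - 1]);
      int v = S[(size_t)(i - 1) * (n + 1) + (j - 1)] + (ok ? 1 : -1);
      v = std::max(v, S[(size_t)(i - 1) * (n + 1) + j] - 1);
      v = std::max(v, S[(size_t)i * (n + 1) + (j - 1)] - 1);
      v = std::max(v, 0);
      S[(size_t)i * (n + 1) + j] = v;
      if (v > best) { best = v; bi = i; bj = j; }
    }
  }
  int i = bi, j = bj, errors = 0, len = 0;
  while (i > 0 && j > 0 && S[(size_t)i * (n + 1) + j] > 0) {
    const int cur = S[(size_t)i * (n + 1) + j];
    const bool ok = wild[j - 1] || base_match(read[i - 1], ref[j - 1]);
    if (S[(size_t)(i - 1) * (n + 1) + (j - 1)] + (ok ? 1 : -1) == cur) {
      if (!ok) ++errors;
      --i; --j; ++len;
    } else if (S[(size_t)(i - 1) * (n + 1) + j] - 1 == cur) {
      ++errors; --i; ++len;
    } else {
      ++errors; --j; ++len;
    }
  }
  return List::create(_["errors"] = errors, _["ref_start"] = j,
                      _["ref_end"] = bj - 1, _["aligned_length"] = len,
                      _["read_start"] = i, _["read_end"] = bi - 1,
                      _["score"] = best);
}

// Best accepted alignment per read across all references.  References must
// arrive sorted by species id so that index order implements the
// deterministic lexicographic tie-break (fewest errors, then longest
// alignment, then first species id).
// [[Rcpp::export(name = ".align_batch_cpp")]]
List align_batch_cpp(CharacterVector reads, CharacterVector refs, List masks,
                     int max_errors, int min_length) {
  const int R = reads.size(), K = refs.size();
  if (K == 0) stop("empty reference set");
  std::vector<std::string> refv(K);
  std::vector<std::vector<char> > wildv(K);
  for (int k = 0; k < K; ++k) {
    refv[k] = as<std::string>(refs[k]);
    std::vector<char> w(refv[k].size(), 0);
    IntegerVector mk = masks[k];
    for (int t = 0; t < mk.size(); ++t)
      if (mk[t] >= 0 && mk[t] < (int)w.size()) w[mk[t]] = 1;
    wildv[k] = w;
  }
  IntegerVector best_ref(R, NA_INTEGER), errors(R, NA_INTEGER),
      alen(R, NA_INTEGER), rstart(R, NA_INTEGER), rend(R, NA_INTEGER);
  LogicalVector too_short(R, false);
  std::vector<int> D;
  std::vector<std::pair<int, int> > order(K);
  for (int r = 0; r < R; ++r) {
    const std::string rd = as<std::string>(reads[r]);
    const int m = (int)rd.size();
    if (m < min_length) { too_short[r] = true; continue; }
    int best_e = max_errors + 1, best_len = -1, best_k = -1, best_s = -1,
        best_end = -1;
    for (int k = 0; k < K; ++k)
      order[k] = std::make_pair(
          ham_bound(rd, refv[k], wildv[k], max_errors + 1), k);
    std::sort(order.begin(), order.end());
    for (int o = 0; o < K; ++o) {
      const int k = order[o].second;
      const int n = (int)refv[k].size();
      const int thr = std::min(best_e, max_errors);
      const size_t need = (size_t)(m + 1) * (n + 1);
      if (D.size() < need) D.resize(need);
      int ej = 0;
      const int e = dp_fill(rd, refv[k], wildv[k], thr, D, ej);
      if (e > thr) continue;
      int sj = 0, len = 0;
      dp_traceback(rd, refv[k], wildv[k], D, ej, sj, len);
      if (len < min_length) continue;
      const bool better =
          (e < best_e) || (e == best_e && len > best_len) ||
          (e == best_e && len == best_len && (best_k < 0 || k < best_k));
      if (better) {
        best_e = e; best_len = len; best_k = k; best_s = sj;
        best_end = ej - 1;
      }
    }
    if (best_k >= 0) {
      best_ref[r] = best_k + 1;  // 1-based for R
      errors[r] = best_e;
      alen[r] = best_len;
      rstart[r] = best_s;
      rend[r] = best_end;
    }
  }
  return List::create(_["best_ref"] = best_ref, _["errors"] = errors,
                      _["aligned_length"] = alen, _["ref_start"] = rstart,
                      _["ref_end"] = rend, _["too_short"] = too_short);
}
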