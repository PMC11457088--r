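#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Maximal exact matches on the forward strands of ref and qry.
//
// Seeds on shared k-mers (2-bit encoded; any k-mer containing a non-ACGT
// character is skipped) and extends each seed in both directions.  A base
// matches only if the two characters are equal and neither is an ambiguity
// code, so N never matches anything, including another N; extension
// therefore stops at N and the reported matches are maximal under that
// rule.  Seeds falling inside a match already emitted on the same diagonal
// are skipped, which de-duplicates co-extended seeds.
//
// Coordinates are half-open, 0-based.  Strand handling (searching the
// reverse complement and mapping coordinates back) lives in R.

static inline int code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default: return -1;
  }
}

// [[Rcpp::export(name = ".mem_sense")]]
DataFrame mem_sense(std::string ref, std::string qry, int k, int min_match) {
  if (k < 1 || k > 31) stop("seed k must be in [1, 31]");
  if (min_match < k) stop("min_match must be >= seed k");
  const int rn = (int) ref.size(), qn = (int) qry.size();

  std::vector<int> ref_starts, ref_ends, qry_starts, qry_ends, lens;

  if (rn >= k && qn >= k) {
    // index ref k-mers
    std::unordered_map<uint64_t, std::vector<int> > idx;
    idx.reserve((size_t) rn * 2);
    const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    uint64_t h = 0;
    int run = 0; // valid consecutive coded bases ending at i
    for (int i = 0; i < rn; ++i) {
      int c = code(ref[i]);
      if (c < 0) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t) c) & mask;
      if (++run >= k) idx[h].push_back(i - k + 1);
    }

    // per-diagonal end of the last emitted/extended match (qry coordinate,
    // exclusive); diagonal = rpos - qpos, shifted non-negative by qn
    std::unordered_map<int64_t, int> diag_end;
    diag_end.reserve(1024);

    h = 0; run = 0;
    for (int j = 0; j < qn; ++j) {
      int c = code(qry[j]);
      if (c < 0) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t) c) & mask;
      if (++run < k) continue;
      auto it = idx.find(h);
      if (it == idx.end()) continue;
      const int q0 = j - k + 1;
      for (int r0 : it->second) {
        int64_t d = (int64_t) r0 - q0 + qn;
        auto de = diag_end.find(d);
        if (de != diag_end.end() && q0 < de->second) continue; // co-extended
        // extend left
        int rs = r0, qs = q0;
        while (rs > 0 && qs > 0) {
          char a = ref[rs - 1], b = qry[qs - 1];
          if (a != b || code(a) < 0) break;
          --rs; --qs;
        }
        // extend right (seed itself is k matching bases)
        int re = r0 + k, qe = q0 + k;
        while (re < rn && qe < qn) {
          char a = ref[re], b = qry[qe];
          if (a != b || code(a) < 0) break;
          ++re; ++qe;
        }
        diag_end[d] = qe;
        if (re - rs >= min_match) {
          ref_starts.push_back(rs); ref_ends.push_back(re);
          qry_starts.push_back(qs); qry_ends.push_back(qe);
          lens.push_back(re - rs);
        }
      }
    }
  }

  return DataFrame::create(
      Named("ref_start") = ref_starts, Named("ref_end") = ref_ends,
      Named("qry_start") = qry_starts, Named("qry_end") = qry_ends,
      Named("match_len") = lens);
}
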