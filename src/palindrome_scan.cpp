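#include <Rcpp.h>
using namespace Rcpp;

// Bases are encoded 0=A, 1=C, 2=G, 3=T, 4=N. N never pairs.
static inline bool base_pairs(int a, int b) {
  return (a == 0 && b == 3) || (a == 3 && b == 0) ||
         (a == 1 && b == 2) || (a == 2 && b == 1);
}

// Maximal inverted-repeat scan over one linear string.
//
// A hit is a pair of equal-length arms around a loop: pairs lie on the
// anti-diagonal c = p + q (p left-arm index, q right-arm index). For each
// anti-diagonal and each admissible innermost pair (which fixes the loop
// length), arms are grown outward greedily while the mismatch budget,
// max_stem and the span cap allow; the resulting hit is kept only if it is
// not inward-extendable (so each reported hit is maximal in both
// directions). One hit per distinct maximal span.
//
// keep_lo/keep_hi restrict reported left-arm starts; the circular wrapper
// scans an unrolled extension of the circle and keeps starts in [1, n] to
// de-duplicate origin-crossing hits.
// [[Rcpp::export]]
DataFrame scan_palindromes_cpp(IntegerVector s, int min_stem, int max_stem,
                               int max_loop, int max_mismatch,
                               int keep_lo, int keep_hi, int span_cap) {
  const int n = s.size();
  std::vector<int> v_left, v_stem, v_loop, v_mm;

  for (int c = 1; c <= 2 * n - 3; ++c) {
    // innermost admissible pair indices: loop g = c - 2p - 1 in [0, max_loop]
    int p_hi = (c - 1) / 2;
    int tmp = c - 1 - max_loop;
    int p_lo = (tmp <= 0) ? 0 : (tmp + 1) / 2;
    int p_out_min = std::max(0, c - n + 1);  // q = c - p must be <= n - 1
    if (p_hi < p_lo) continue;

    for (int p_in = std::max(p_lo, p_out_min); p_in <= p_hi; ++p_in) {
      int g = c - 2 * p_in - 1;
      int q_in = c - p_in;
      if (q_in >= n) continue;
      int mm = base_pairs(s[p_in], s[q_in]) ? 0 : 1;
      if (mm > max_mismatch) continue;
      int L = 1;
      int p_out = p_in;
      while (L < max_stem && p_out - 1 >= p_out_min &&
             2 * (L + 1) + g <= span_cap) {
        int add = base_pairs(s[p_out - 1], s[c - p_out + 1]) ? 0 : 1;
        if (mm + add > max_mismatch) break;
        mm += add;
        --p_out;
        ++L;
      }
      if (L < min_stem) continue;
      // inward extension: consume two loop bases, gaining the pair at p_in+1
      if (p_in + 1 <= p_hi && L < max_stem) {
        int add = base_pairs(s[p_in + 1], s[c - p_in - 1]) ? 0 : 1;
        if (mm + add <= max_mismatch) continue;  // not maximal inward
      }
      if (p_out < keep_lo || p_out > keep_hi) continue;
      v_left.push_back(p_out);
      v_stem.push_back(L);
      v_loop.push_back(g);
      v_mm.push_back(mm);
    }
  }

  return DataFrame::create(
    _["left_start"] = wrap(v_left),
    _["stem_len"] = wrap(v_stem),
    _["loop_len"] = wrap(v_loop),
    _["mismatches"] = wrap(v_mm)
  );
}

// Wraparound alignment of a region against a cyclic consensus.
//
// H[i][j] = best score aligning the first i region bases with an alignment
// ending at consensus position j. The start phase on the consensus is free
// (row 0 is all zero) and the score is the maximum over the final row.
// Wraparound between the last and first consensus column is handled with a
// second sweep per row.
// [[Rcpp::export]]
double wrap_align_cpp(IntegerVector region, IntegerVector consensus,
                      double match, double mismatch, double indel) {
  const int m = region.size();
  const int d = consensus.size();
  if (m == 0 || d == 0) return 0.0;
  std::vector<double> prev(d, 0.0), cur(d, 0.0);
  const double NEG = -1e18;
  for (int i = 1; i <= m; ++i) {
    for (int j = 0; j < d; ++j) cur[j] = NEG;
    for (int sweep = 0; sweep < 2; ++sweep) {
      for (int j = 0; j < d; ++j) {
        int jm1 = (j == 0) ? d - 1 : j - 1;
        double sub = (region[i - 1] == consensus[j] && region[i - 1] != 4)
                         ? match : -mismatch;
        double best = prev[jm1] + sub;            // align region[i-1] to cons[j]
        double del = prev[j] - indel;             // consensus char skipped
        if (del > best) best = del;
        double ins = cur[jm1] - indel;            // region char inserted
        if (ins > best) best = ins;
        if (best > cur[j]) cur[j] = best;
      }
    }
    std::swap(prev, cur);
  }
  double out = NEG;
  for (int j = 0; j < d; ++j) out = std::max(out, prev[j]);
  return out;
}
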