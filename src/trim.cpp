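// Quality/adapter trimming core. Steps per read, in order:
//   1. adapter clip (earliest suffix match of an adapter prefix with
//      overlap >= ad_min_overlap and <= ad_max_mismatch mismatches, or a
//      full internal occurrence),
//   2. leading/trailing base clip below lead_q/trail_q,
//   3. left-to-right sliding window cut at the first window whose mean
//      Phred falls below window_minq (cut at window start),
//   4. discard if shorter than min_len.
// Qualities are Phred+33 strings.
#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export]]
List cpp_trim_reads(CharacterVector seqs, CharacterVector quals,
                    CharacterVector adapters, int window, double window_minq,
                    int lead_q, int trail_q, int min_len,
                    int ad_min_overlap, int ad_max_mismatch) {
  const int n = seqs.size();
  std::vector<std::string> ads(adapters.size());
  for (int i = 0; i < adapters.size(); ++i)
    ads[i] = as<std::string>(adapters[i]);
  CharacterVector oseq(n), oqual(n);
  LogicalVector keep(n);
  for (int r = 0; r < n; ++r) {
    std::string s = as<std::string>(seqs[r]);
    std::string q = as<std::string>(quals[r]);
    if (s.size() != q.size())
      stop("read %d: sequence and quality lengths differ", r + 1);
    int L = (int) s.size();
    // 1. adapter clip at the earliest matching position
    int cut = L;
    for (int i = 0; i < L && i < cut; ++i) {
      for (const std::string& ad : ads) {
        int alen = (int) ad.size();
        int m = std::min(alen, L - i);
        if (m < ad_min_overlap && m < alen) continue;
        int mm = 0;
        for (int x = 0; x < m && mm <= ad_max_mismatch; ++x)
          if (s[i + x] != ad[x]) ++mm;
        if (mm <= ad_max_mismatch) { cut = i; break; }
      }
    }
    L = cut;
    // 2. leading / trailing low-quality clip
    int lo = 0, hi = L;
    while (lo < hi && (int) q[lo] - 33 < lead_q) ++lo;
    while (hi > lo && (int) q[hi - 1] - 33 < trail_q) --hi;
    // 3. sliding window; a cut can expose a low-quality final base, so
    // the trailing clip is re-applied until stable (keeps trimming
    // idempotent)
    for (;;) {
      int before = hi;
      if (hi - lo >= window) {
        long sum = 0;
        for (int i = lo; i < lo + window; ++i) sum += (int) q[i] - 33;
        int end = hi;
        for (int st = lo; st + window <= hi; ++st) {
          if (st > lo) sum += ((int) q[st + window - 1] - 33) -
                              ((int) q[st - 1] - 33);
          if ((double) sum / window < window_minq) { end = st; break; }
        }
        // past the failing window's start, keep individually good bases
        while (end < hi && (int) q[end] - 33 >= window_minq) ++end;
        hi = end;
      }
      while (hi > lo && (int) q[hi - 1] - 33 < trail_q) --hi;
      if (hi == before) break;
    }
    int len = hi - lo;
    if (len < min_len) {
      oseq[r] = ""; oqual[r] = ""; keep[r] = false;
    } else {
      oseq[r] = s.substr(lo, len);
      oqual[r] = q.substr(lo, len);
      keep[r] = true;
    }
  }
  return List::create(_["seq"] = oseq, _["qual"] = oqual, _["keep"] = keep);
}
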