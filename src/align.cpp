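// Protein local alignment (affine-gap Smith-Waterman) and the translated
// seed-and-extend read scorer used for recruitment.
#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>
#include <string>
using namespace Rcpp;

// 256x256 score lookup built from a named substitution matrix.
struct ScoreLut {
  int lut[256][256];
  bool known[256];
  ScoreLut(const IntegerMatrix& mat) {
    CharacterVector rn = rownames(mat);
    std::vector<unsigned char> letters(rn.size());
    for (int i = 0; i < 256; ++i) known[i] = false;
    for (int i = 0; i < rn.size(); ++i) {
      std::string s = as<std::string>(rn[i]);
      letters[i] = (unsigned char) s[0];
      known[letters[i]] = true;
    }
    for (int i = 0; i < rn.size(); ++i)
      for (int j = 0; j < rn.size(); ++j)
        lut[letters[i]][letters[j]] = mat(i, j);
  }
  inline int score(unsigned char a, unsigned char b) const {
    if (!known[a]) a = 'X';
    if (!known[b]) b = 'X';
    return lut[a][b];
  }
};

// Optimal local alignment under affine gaps (a k-long gap costs
// open + k*extend). Among equal-scoring cells the first in row-major
// order wins, giving a deterministic smallest-end tie break; the
// traceback prefers substitution over gaps.
// [[Rcpp::export]]
List cpp_smith_waterman(std::string a, std::string b, IntegerMatrix mat,
                        int gap_open, int gap_extend) {
  const int n = (int) a.size(), m = (int) b.size();
  if (n == 0 || m == 0) stop("empty sequence in alignment");
  ScoreLut lut(mat);
  const int NEG = -1000000000;
  std::vector<int> H(m + 1, 0), E(m + 1, NEG);
  std::vector<int> Hprev(m + 1, 0);
  std::vector<int> F(m + 1, NEG);
  // traceback codes per cell: 0 stop, 1 diag, 2 gap-in-a (E), 3 gap-in-b (F)
  std::vector<unsigned char> tbH((size_t)(n + 1) * (m + 1), 0);
  std::vector<unsigned char> tbE((size_t)(n + 1) * (m + 1), 0); // 1 = extend
  std::vector<unsigned char> tbF((size_t)(n + 1) * (m + 1), 0);
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    std::swap(H, Hprev);
    std::fill(H.begin(), H.end(), 0);
    std::fill(E.begin(), E.end(), NEG);
    // E is gap in query a (consumes b); recomputed per row left-to-right.
    int Erow = NEG;
    for (int j = 1; j <= m; ++j) {
      size_t at = (size_t) i * (m + 1) + j;
      int eopen = H[j - 1] - gap_open - gap_extend;
      int eext = Erow - gap_extend;
      Erow = std::max(eopen, eext);
      tbE[at] = (unsigned char) (eext > eopen);
      int fopen = Hprev[j] - gap_open - gap_extend;
      int fext = F[j] - gap_extend;
      F[j] = std::max(fopen, fext);
      tbF[at] = (unsigned char) (fext > fopen);
      int diag = Hprev[j - 1] +
                 lut.score((unsigned char) a[i - 1], (unsigned char) b[j - 1]);
      int h = 0;
      unsigned char tb = 0;
      if (diag > h) { h = diag; tb = 1; }
      if (Erow > h) { h = Erow; tb = 2; }
      if (F[j] > h) { h = F[j]; tb = 3; }
      H[j] = h;
      tbH[at] = tb;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  if (best <= 0)
    return List::create(_["score"] = 0, _["q_start"] = 0, _["q_end"] = 0,
                        _["t_start"] = 0, _["t_end"] = 0, _["matches"] = 0,
                        _["columns"] = 0);
  // traceback
  int i = bi, j = bj, matches = 0, columns = 0;
  int state = 0; // 0 = in H, 2 = in E, 3 = in F
  while (i > 0 && j > 0) {
    size_t at = (size_t) i * (m + 1) + j;
    if (state == 0) {
      unsigned char tb = tbH[at];
      if (tb == 0) break;
      if (tb == 1) {
        ++columns;
        if (a[i - 1] == b[j - 1]) ++matches;
        --i; --j;
      } else state = tb;
    } else if (state == 2) {
      ++columns;
      if (!tbE[at]) state = 0;
      --j;
    } else {
      ++columns;
      if (!tbF[at]) state = 0;
      --i;
    }
  }
  return List::create(_["score"] = best, _["q_start"] = i, _["q_end"] = bi,
                      _["t_start"] = j, _["t_end"] = bj,
                      _["matches"] = matches, _["columns"] = columns);
}

static inline int nt2(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

struct CodonLut {
  char aa[64];
  CodonLut(const CharacterVector& codons, const CharacterVector& aas) {
    for (int i = 0; i < 64; ++i) aa[i] = 'X';
    for (int i = 0; i < codons.size(); ++i) {
      std::string c = as<std::string>(codons[i]);
      int b0 = nt2(c[0]), b1 = nt2(c[1]), b2 = nt2(c[2]);
      if (b0 < 0 || b1 < 0 || b2 < 0) continue;
      aa[(b0 << 4) | (b1 << 2) | b2] = as<std::string>(aas[i])[0];
    }
  }
  inline char translate(char c0, char c1, char c2) const {
    int b0 = nt2(c0), b1 = nt2(c1), b2 = nt2(c2);
    if (b0 < 0 || b1 < 0 || b2 < 0) return 'X';
    return aa[(b0 << 4) | (b1 << 2) | b2];
  }
};

static std::string translate_frame(const std::string& s, int frame,
                                   const CodonLut& lut) {
  const int n = (int) s.size();
  std::string out;
  out.reserve((n - frame) / 3);
  for (int i = frame; i + 2 < n; i += 3)
    out.push_back(lut.translate(s[i], s[i + 1], s[i + 2]));
  return out;
}

static std::string rc_nt(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (char& c : r) {
    switch (c) {
      case 'A': c = 'T'; break; case 'C': c = 'G'; break;
      case 'G': c = 'C'; break; case 'T': c = 'A'; break;
      default: c = 'N';
    }
  }
  return r;
}

// Best ungapped x-drop extension score of each read against the query
// set: every exact aa-word hit in any of the read's six frame
// translations is extended both ways without gaps, stopping when the
// running score drops x_drop below the running maximum.
// [[Rcpp::export]]
IntegerVector cpp_score_reads(CharacterVector seqs, CharacterVector queries,
                              int word, int x_drop, IntegerMatrix mat,
                              CharacterVector codons, CharacterVector aas) {
  ScoreLut lut(mat);
  CodonLut clut(codons, aas);
  std::vector<std::string> qs(queries.size());
  std::unordered_map<std::string, std::vector<std::pair<int, int>>> index;
  for (int qi = 0; qi < queries.size(); ++qi) {
    qs[qi] = as<std::string>(queries[qi]);
    const std::string& q = qs[qi];
    if ((int) q.size() < word) continue;
    for (int o = 0; o + word <= (int) q.size(); ++o) {
      std::string w = q.substr(o, word);
      if (w.find('X') != std::string::npos ||
          w.find('*') != std::string::npos) continue;
      index[w].push_back(std::make_pair(qi, o));
    }
  }
  IntegerVector out(seqs.size());
  for (int ri = 0; ri < seqs.size(); ++ri) {
    std::string fwd = as<std::string>(seqs[ri]);
    std::string rev = rc_nt(fwd);
    int best = 0;
    for (int strand = 0; strand < 2; ++strand) {
      const std::string& nt = strand ? rev : fwd;
      for (int frame = 0; frame < 3; ++frame) {
        std::string aa = translate_frame(nt, frame, clut);
        const int alen = (int) aa.size();
        if (alen < word) continue;
        for (int p = 0; p + word <= alen; ++p) {
          auto it = index.find(aa.substr(p, word));
          if (it == index.end()) continue;
          for (auto& occ : it->second) {
            const std::string& q = qs[occ.first];
            const int qlen = (int) q.size();
            const int qo = occ.second;
            int core = 0;
            for (int x = 0; x < word; ++x)
              core += lut.score(aa[p + x], q[qo + x]);
            // right extension
            int run = 0, mx = 0;
            for (int x = word; p + x < alen && qo + x < qlen; ++x) {
              run += lut.score(aa[p + x], q[qo + x]);
              if (run > mx) mx = run;
              if (mx - run > x_drop) break;
            }
            int right = mx;
            // left extension
            run = 0; mx = 0;
            for (int x = 1; p - x >= 0 && qo - x >= 0; ++x) {
              run += lut.score(aa[p - x], q[qo - x]);
              if (run > mx) mx = run;
              if (mx - run > x_drop) break;
            }
            int total = core + right + mx;
            if (total > best) best = total;
          }
        }
      }
    }
    out[ri] = best;
  }
  return out;
}
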