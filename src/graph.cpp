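// De Bruijn graph over canonical k-mers: construction is implicit (an edge
// exists when two stored k-mers overlap by k-1 with consistent orientation),
// so the graph state is just the surviving k-mer set and its counts.
// Provides degree queries, unitig extraction, iterative tip clipping and
// coverage-guided bubble popping.
#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <map>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

static inline int b2(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}

static inline uint64_t rc_code(uint64_t code, int k) {
  uint64_t rc = 0;
  for (int i = 0; i < k; ++i) {
    rc = (rc << 2) | (3ULL - (code & 3ULL));
    code >>= 2;
  }
  return rc;
}

static std::string dec(uint64_t code, int k) {
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) { s[i] = bases[code & 3ULL]; code >>= 2; }
  return s;
}

struct DBG {
  int k;
  uint64_t mask;
  std::vector<uint64_t> nodes;
  std::vector<double> counts;
  std::unordered_map<uint64_t, int> idx;

  DBG(const CharacterVector& kmers, const NumericVector& cnt, int k_,
      const std::vector<bool>* keep = nullptr) : k(k_) {
    mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    std::vector<std::pair<uint64_t, double>> tmp;
    for (int i = 0; i < kmers.size(); ++i) {
      if (keep && !(*keep)[i]) continue;
      std::string s = as<std::string>(kmers[i]);
      if ((int) s.size() != k) stop("k-mer length != k");
      uint64_t c = 0;
      for (char ch : s) {
        int b = b2(ch);
        if (b < 0) stop("invalid k-mer '%s'", s);
        c = (c << 2) | (uint64_t) b;
      }
      tmp.push_back(std::make_pair(c, cnt[i]));
    }
    std::sort(tmp.begin(), tmp.end());
    nodes.reserve(tmp.size());
    counts.reserve(tmp.size());
    for (size_t i = 0; i < tmp.size(); ++i) {
      nodes.push_back(tmp[i].first);
      counts.push_back(tmp[i].second);
      idx[tmp[i].first] = (int) i;
    }
  }

  inline uint64_t ocode(int i, int o) const {
    return o ? rc_code(nodes[i], k) : nodes[i];
  }

  std::vector<std::pair<int, int>> succs(uint64_t code) const {
    std::vector<std::pair<int, int>> out;
    for (uint64_t b = 0; b < 4; ++b) {
      uint64_t c2 = ((code << 2) | b) & mask;
      uint64_t rc = rc_code(c2, k);
      uint64_t canon = std::min(c2, rc);
      auto it = idx.find(canon);
      if (it != idx.end())
        out.push_back(std::make_pair(it->second, canon == c2 ? 0 : 1));
    }
    return out;
  }

  std::vector<std::pair<int, int>> preds(uint64_t code) const {
    std::vector<std::pair<int, int>> out;
    for (uint64_t b = 0; b < 4; ++b) {
      uint64_t c2 = (code >> 2) | (b << (2 * (k - 1)));
      uint64_t rc = rc_code(c2, k);
      uint64_t canon = std::min(c2, rc);
      auto it = idx.find(canon);
      if (it != idx.end())
        out.push_back(std::make_pair(it->second, canon == c2 ? 0 : 1));
    }
    return out;
  }
};

struct Unitig {
  std::vector<std::pair<int, int>> path; // (node index, orientation)
  std::string seq;
  double cov;
};

static std::vector<Unitig> unitigs_of(const DBG& g) {
  const int n = (int) g.nodes.size();
  std::vector<bool> visited(n, false);
  std::vector<Unitig> out;
  auto walk = [&](int i, int o) {
    Unitig u;
    u.path.push_back(std::make_pair(i, o));
    visited[i] = true;
    int ci = i, co = o;
    for (;;) {
      auto sv = g.succs(g.ocode(ci, co));
      if (sv.size() != 1) break;
      int ni = sv[0].first, no = sv[0].second;
      if (visited[ni]) break;
      if (g.preds(g.ocode(ni, no)).size() != 1) break;
      u.path.push_back(sv[0]);
      visited[ni] = true;
      ci = ni; co = no;
    }
    u.seq = dec(g.ocode(u.path[0].first, u.path[0].second), g.k);
    double tot = g.counts[u.path[0].first];
    for (size_t p = 1; p < u.path.size(); ++p) {
      uint64_t c = g.ocode(u.path[p].first, u.path[p].second);
      u.seq.push_back("ACGT"[c & 3ULL]);
      tot += g.counts[u.path[p].first];
    }
    u.cov = tot / u.path.size();
    out.push_back(u);
  };
  for (int i = 0; i < n; ++i) {
    if (visited[i]) continue;
    for (int o = 0; o < 2; ++o) {
      uint64_t code = g.ocode(i, o);
      auto pv = g.preds(code);
      bool start = pv.size() != 1;
      if (!start &&
          g.succs(g.ocode(pv[0].first, pv[0].second)).size() != 1)
        start = true;
      if (start) { walk(i, o); break; }
    }
  }
  for (int i = 0; i < n; ++i)  // leftover perfect cycles
    if (!visited[i]) walk(i, 0);
  return out;
}

static std::string rc_seq(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (char& c : r) c = "TGCA"[std::string("ACGT").find(c)];
  return r;
}

// banded-free small edit distance; identity = 1 - dist/max(len)
static double seq_identity(const std::string& a, const std::string& b) {
  if (a == b) return 1.0;
  const int n = (int) a.size(), m = (int) b.size();
  std::vector<int> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = j;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i;
    for (int j = 1; j <= m; ++j)
      cur[j] = std::min(std::min(prev[j] + 1, cur[j - 1] + 1),
                        prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1));
    std::swap(prev, cur);
  }
  return 1.0 - (double) prev[m] / std::max(n, m);
}

// [[Rcpp::export]]
IntegerMatrix cpp_dbg_degrees(CharacterVector kmers, NumericVector counts,
                              int k) {
  DBG g(kmers, counts, k);
  IntegerMatrix deg(g.nodes.size(), 2);
  CharacterVector rn(g.nodes.size());
  for (size_t i = 0; i < g.nodes.size(); ++i) {
    deg(i, 0) = (int) g.preds(g.nodes[i]).size();
    deg(i, 1) = (int) g.succs(g.nodes[i]).size();
    rn[i] = dec(g.nodes[i], k);
  }
  rownames(deg) = rn;
  colnames(deg) = CharacterVector::create("in", "out");
  return deg;
}

// [[Rcpp::export]]
List cpp_dbg_unitigs(CharacterVector kmers, NumericVector counts, int k) {
  DBG g(kmers, counts, k);
  std::vector<Unitig> us = unitigs_of(g);
  CharacterVector seq(us.size());
  NumericVector cov(us.size());
  IntegerVector nn(us.size());
  for (size_t i = 0; i < us.size(); ++i) {
    seq[i] = us[i].seq;
    cov[i] = us[i].cov;
    nn[i] = (int) us[i].path.size();
  }
  return List::create(_["seq"] = seq, _["cov"] = cov, _["nnodes"] = nn);
}

// Remove dead-end unitigs of <= tip_len nodes attached to the rest of the
// graph, iterating to a fixed point. Returns a keep mask over the input.
// [[Rcpp::export]]
LogicalVector cpp_clip_tips(CharacterVector kmers, NumericVector counts,
                            int k, int tip_len) {
  const int n = kmers.size();
  std::vector<bool> keep(n, true);
  // map original index -> code string kept stable via rebuild each round
  bool changed = true;
  while (changed) {
    changed = false;
    DBG g(kmers, counts, k, &keep);
    if (g.nodes.empty()) break;
    // map node code -> original input index
    std::unordered_map<uint64_t, int> orig;
    for (int i = 0; i < n; ++i) {
      if (!keep[i]) continue;
      std::string s = as<std::string>(kmers[i]);
      uint64_t c = 0;
      for (char ch : s) c = (c << 2) | (uint64_t) b2(ch);
      orig[c] = i;
    }
    std::vector<Unitig> us = unitigs_of(g);
    for (auto& u : us) {
      if ((int) u.path.size() > tip_len) continue;
      bool dead_in = g.preds(g.ocode(u.path.front().first,
                                     u.path.front().second)).empty();
      bool dead_out = g.succs(g.ocode(u.path.back().first,
                                      u.path.back().second)).empty();
      if (dead_in == dead_out) continue; // isolated or internal: not a tip
      for (auto& pr : u.path) keep[orig[g.nodes[pr.first]]] = false;
      changed = true;
    }
  }
  return LogicalVector(keep.begin(), keep.end());
}

// Collapse bubbles: sets of single-entry single-exit unitigs sharing both
// junction endpoints; arms within bubble_identity of the highest-coverage
// arm are removed. Iterates until stable. Returns a keep mask.
// [[Rcpp::export]]
LogicalVector cpp_pop_bubbles(CharacterVector kmers, NumericVector counts,
                              int k, double bubble_identity) {
  const int n = kmers.size();
  std::vector<bool> keep(n, true);
  bool changed = true;
  while (changed) {
    changed = false;
    DBG g(kmers, counts, k, &keep);
    if (g.nodes.empty()) break;
    std::unordered_map<uint64_t, int> orig;
    for (int i = 0; i < n; ++i) {
      if (!keep[i]) continue;
      std::string s = as<std::string>(kmers[i]);
      uint64_t c = 0;
      for (char ch : s) c = (c << 2) | (uint64_t) b2(ch);
      orig[c] = i;
    }
    std::vector<Unitig> us = unitigs_of(g);
    typedef std::pair<uint64_t, uint64_t> Key;
    std::map<Key, std::vector<std::pair<int, bool>>> arms; // (unitig, flipped)
    for (size_t ui = 0; ui < us.size(); ++ui) {
      auto& u = us[ui];
      auto pv = g.preds(g.ocode(u.path.front().first, u.path.front().second));
      auto sv = g.succs(g.ocode(u.path.back().first, u.path.back().second));
      if (pv.size() != 1 || sv.size() != 1) continue;
      uint64_t s = ((uint64_t) pv[0].first << 1) | pv[0].second;
      uint64_t t = ((uint64_t) sv[0].first << 1) | sv[0].second;
      uint64_t sf = ((uint64_t) sv[0].first << 1) | (1 - sv[0].second);
      uint64_t tf = ((uint64_t) pv[0].first << 1) | (1 - pv[0].second);
      Key fwd(s, t), flip(sf, tf);
      bool flipped = flip < fwd;
      arms[flipped ? flip : fwd].push_back(
        std::make_pair((int) ui, flipped));
    }
    for (auto& kv : arms) {
      if (kv.second.size() < 2) continue;
      // orient arm sequences consistently with the key
      std::vector<std::pair<int, std::string>> oriented;
      for (auto& a : kv.second) {
        const std::string& s0 = us[a.first].seq;
        oriented.push_back(
          std::make_pair(a.first, a.second ? rc_seq(s0) : s0));
      }
      std::sort(oriented.begin(), oriented.end(),
                [&](const std::pair<int, std::string>& a,
                    const std::pair<int, std::string>& b) {
                  double ca = us[a.first].cov, cb = us[b.first].cov;
                  if (ca != cb) return ca > cb;
                  return a.second < b.second;
                });
      const std::string& kept = oriented[0].second;
      for (size_t a = 1; a < oriented.size(); ++a) {
        if (seq_identity(kept, oriented[a].second) < bubble_identity)
          continue;
        for (auto& pr : us[oriented[a].first].path)
          keep[orig[g.nodes[pr.first]]] = false;
        changed = true;
      }
    }
  }
  return LogicalVector(keep.begin(), keep.end());
}
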