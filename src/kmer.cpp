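// 2-bit encoded canonical k-mer machinery shared by the read classifier,
// the enrichment stage and the assembler. k is limited to 31 so that a
// k-mer fits a 64-bit word; k must be odd, which rules out reverse-complement
// palindromes and makes canonicalization unambiguous.
#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <unordered_set>
#include <algorithm>
using namespace Rcpp;

static inline int base2bits(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static inline uint64_t revcomp_code(uint64_t code, int k) {
  uint64_t rc = 0;
  for (int i = 0; i < k; ++i) {
    rc = (rc << 2) | (3ULL - (code & 3ULL));
    code >>= 2;
  }
  return rc;
}

static std::string decode_kmer(uint64_t code, int k) {
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    s[i] = bases[code & 3ULL];
    code >>= 2;
  }
  return s;
}

// Enumerate canonical k-mer codes of one sequence; k-mers containing
// non-ACGT letters are skipped. Calls f(canonical_code) per position.
template <typename F>
static void for_each_canonical(const std::string& s, int k, F f) {
  const int n = (int) s.size();
  if (n < k) return;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t fwd = 0, rev = 0;
  int valid = 0;
  for (int i = 0; i < n; ++i) {
    int b = base2bits(s[i]);
    if (b < 0) { valid = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t) b) & mask;
    rev = (rev >> 2) | ((3ULL - (uint64_t) b) << (2 * (k - 1)));
    if (++valid >= k) f(std::min(fwd, rev));
  }
}

static bool encode_kmer(const std::string& s, uint64_t& out) {
  uint64_t code = 0;
  for (char c : s) {
    int b = base2bits(c);
    if (b < 0) return false;
    code = (code << 2) | (uint64_t) b;
  }
  out = code;
  return true;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
  const int n = seqs.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    std::string r(s.rbegin(), s.rend());
    for (char& c : r) {
      switch (c) {
        case 'A': c = 'T'; break; case 'C': c = 'G'; break;
        case 'G': c = 'C'; break; case 'T': c = 'A'; break;
        case 'a': c = 't'; break; case 'c': c = 'g'; break;
        case 'g': c = 'c'; break; case 't': c = 'a'; break;
        case 'N': case 'n': break;
        default: stop("revcomp: invalid letter '%s'", std::string(1, c));
      }
    }
    out[i] = r;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_count_kmers(CharacterVector seqs, int k) {
  std::unordered_map<uint64_t, int> counts;
  for (int i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    for_each_canonical(s, k, [&](uint64_t c) { ++counts[c]; });
  }
  std::vector<uint64_t> keys;
  keys.reserve(counts.size());
  for (auto& kv : counts) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());
  CharacterVector km(keys.size());
  IntegerVector ct(keys.size());
  for (size_t i = 0; i < keys.size(); ++i) {
    km[i] = decode_kmer(keys[i], k);
    ct[i] = counts[keys[i]];
  }
  return List::create(_["kmer"] = km, _["count"] = ct);
}

// [[Rcpp::export]]
CharacterVector cpp_kmer_set(CharacterVector seqs, int k) {
  std::unordered_set<uint64_t> set;
  for (int i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    for_each_canonical(s, k, [&](uint64_t c) { set.insert(c); });
  }
  std::vector<uint64_t> keys(set.begin(), set.end());
  std::sort(keys.begin(), keys.end());
  CharacterVector out(keys.size());
  for (size_t i = 0; i < keys.size(); ++i) out[i] = decode_kmer(keys[i], k);
  return out;
}

static std::unordered_set<uint64_t> parse_set(CharacterVector kmers, int k) {
  std::unordered_set<uint64_t> set;
  set.reserve(kmers.size() * 2);
  for (int i = 0; i < kmers.size(); ++i) {
    uint64_t c;
    std::string s = as<std::string>(kmers[i]);
    if ((int) s.size() != k || !encode_kmer(s, c))
      stop("invalid k-mer in set: '%s'", s);
    set.insert(c);
  }
  return set;
}

// Number of distinct canonical k-mers of each sequence present in `set`.
// [[Rcpp::export]]
IntegerVector cpp_shared_kmer_counts(CharacterVector seqs,
                                     CharacterVector set, int k) {
  std::unordered_set<uint64_t> ref = parse_set(set, k);
  IntegerVector out(seqs.size());
  std::unordered_set<uint64_t> seen;
  for (int i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    seen.clear();
    int hits = 0;
    for_each_canonical(s, k, [&](uint64_t c) {
      if (ref.count(c) && seen.insert(c).second) ++hits;
    });
    out[i] = hits;
  }
  return out;
}

// Joint classification of reads (or read pairs when seqs2 is non-empty)
// against per-label canonical k-mer sets. hits(label) counts k-mer
// positions of the read (pair) whose canonical k-mer is in the label's
// set; the winner must be unique and reach min_frac of all k-mer
// positions, otherwise "ambiguous"/"unclassified".
// [[Rcpp::export]]
List cpp_classify(CharacterVector seqs1, CharacterVector seqs2,
                  CharacterVector labels, List kmer_sets, int k,
                  double min_frac) {
  const int nlab = labels.size();
  std::vector<std::unordered_set<uint64_t>> sets(nlab);
  for (int l = 0; l < nlab; ++l)
    sets[l] = parse_set(kmer_sets[l], k);
  const bool paired = seqs2.size() > 0;
  if (paired && seqs2.size() != seqs1.size())
    stop("mate streams differ in length");
  const int n = seqs1.size();
  CharacterVector out(n);
  NumericVector frac(n);
  std::vector<int> hits(nlab);
  for (int i = 0; i < n; ++i) {
    std::fill(hits.begin(), hits.end(), 0);
    int total = 0;
    auto count = [&](const std::string& s) {
      for_each_canonical(s, k, [&](uint64_t c) {
        ++total;
        for (int l = 0; l < nlab; ++l)
          if (sets[l].count(c)) ++hits[l];
      });
    };
    count(as<std::string>(seqs1[i]));
    if (paired) count(as<std::string>(seqs2[i]));
    if (total == 0 || nlab == 0) { out[i] = "unclassified"; frac[i] = 0; continue; }
    int best = 0;
    for (int l = 1; l < nlab; ++l) if (hits[l] > hits[best]) best = l;
    double f = (double) hits[best] / total;
    frac[i] = f;
    if (hits[best] == 0 || f < min_frac) { out[i] = "unclassified"; continue; }
    bool tied = false;
    for (int l = 0; l < nlab; ++l)
      if (l != best && hits[l] == hits[best]) { tied = true; break; }
    out[i] = tied ? String("ambiguous") : String(labels[best]);
  }
  return List::create(_["label"] = out, _["frac"] = frac);
}
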