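#include <Rcpp.h>
#include <unordered_map>
#include <string>
#include <vector>
using namespace Rcpp;

// Tiered Hamming-distance error collapse within one selection round.
//
// Sequences arrive sorted by descending count (ties lexicographic). A
// sequence s is discarded iff there is a comparison sequence t with
// count(t) > count(s) and Hamming(s,t) <= 1, or count(t) >= 100*count(s)
// and Hamming <= 2, or count(t) >= 10000*count(s) and Hamming <= 3.
// With retained_only = true (the default pipeline behaviour) only retained
// sequences act as comparators; otherwise every more prevalent sequence
// does. Radius-1 neighbours are found by exact-neighbour hash lookup;
// radius 2-3 only engage across large (>=100x) count ratios, so scanning
// the descending-ordered comparator list with an early break stays cheap.

static inline int hamming_capped(const std::string &a, const std::string &b,
                                 int cap) {
  int d = 0;
  for (size_t i = 0; i < a.size(); ++i) {
    if (a[i] != b[i] && ++d > cap) return d;
  }
  return d;
}

// [[Rcpp::export]]
LogicalVector collapse_greedy_cpp(CharacterVector seqs, NumericVector counts,
                                  bool retained_only) {
  const int n = seqs.size();
  LogicalVector keep(n);
  if (n == 0) return keep;
  std::unordered_map<std::string, double> cmp_count; // comparator -> count
  std::vector<std::string> cmp_seq;                  // desc-count order
  std::vector<double> cmp_cnt;
  cmp_count.reserve(2 * n);
  const char bases[4] = {'A', 'C', 'G', 'T'};

  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    const double c = counts[i];
    bool drop = false;
    // radius 1: probe all single-substitution neighbours
    for (size_t p = 0; p < s.size() && !drop; ++p) {
      const char orig = s[p];
      for (int b = 0; b < 4 && !drop; ++b) {
        if (bases[b] == orig) continue;
        s[p] = bases[b];
        auto it = cmp_count.find(s);
        if (it != cmp_count.end() && it->second > c) drop = true;
      }
      s[p] = orig;
    }
    // radius 2 and 3: only comparators >= 100x (resp. 10000x) more prevalent
    if (!drop) {
      for (size_t j = 0; j < cmp_seq.size(); ++j) {
        if (cmp_cnt[j] < 100.0 * c) break; // descending order
        const int d = hamming_capped(s, cmp_seq[j], 3);
        if (d <= 2 || (d == 3 && cmp_cnt[j] >= 10000.0 * c)) {
          drop = true;
          break;
        }
      }
    }
    keep[i] = !drop;
    if (!drop || !retained_only) {
      auto it = cmp_count.find(s);
      if (it == cmp_count.end() || it->second < c) cmp_count[s] = c;
      cmp_seq.push_back(s);
      cmp_cnt.push_back(c);
    }
  }
  return keep;
}
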