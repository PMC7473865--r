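#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Gibbs sampler over (cluster, core offset) assignments, maximizing the
// size-weighted Kullback-Leibler distance of pseudocount-smoothed cluster
// frequency matrices against a data-derived background.
//
// Peptides are residue-index vectors (0..19) of possibly different lengths,
// passed concatenated. Annealed sweeps decay the sampling temperature
// linearly to near-zero; the last `greedy` sweeps take argmax moves. When
// trash_threshold is finite, peptides whose best available log-odds score
// falls below it are parked in a trash cluster and excluded from counts.

struct State {
  int K, m;
  std::vector<std::vector<double>> cnt; // K x (m*20) residue counts
  std::vector<double> size;             // peptides per cluster
};

static inline double cell_logodds(const State &st, const NumericVector &bg,
                                  double beta, int k, int p, int a) {
  double f = (st.cnt[k][p * 20 + a] + beta * bg[a]) / (st.size[k] + beta);
  return std::log2(f / bg[a]);
}

static double system_kld(const State &st, const NumericVector &bg,
                         double beta) {
  double total = 0, n = 0;
  for (int k = 0; k < st.K; ++k) n += st.size[k];
  if (n == 0) return 0;
  for (int k = 0; k < st.K; ++k) {
    if (st.size[k] == 0) continue;
    double kld = 0;
    for (int p = 0; p < st.m; ++p)
      for (int a = 0; a < 20; ++a) {
        double f = (st.cnt[k][p * 20 + a] + beta * bg[a]) /
                   (st.size[k] + beta);
        kld += f * std::log2(f / bg[a]);
      }
    total += st.size[k] / n * kld;
  }
  return total;
}

// [[Rcpp::export]]
List gibbs_run_cpp(IntegerVector pep_flat, IntegerVector pep_start,
                   IntegerVector pep_len, int K, int motif_len,
                   NumericVector bg, double beta, int sweeps, int greedy,
                   double t0, double trash_threshold, bool use_trash) {
  const int n = pep_start.size();
  State st;
  st.K = K;
  st.m = motif_len;
  st.cnt.assign(K, std::vector<double>(motif_len * 20, 0.0));
  st.size.assign(K, 0.0);

  std::vector<int> cl(n), off(n);
  // random initial assignment (uses R's RNG: seeded from R)
  for (int i = 0; i < n; ++i) {
    cl[i] = (int)std::floor(unif_rand() * K);
    if (cl[i] == K) cl[i] = K - 1;
    int no = pep_len[i] - motif_len + 1;
    off[i] = (int)std::floor(unif_rand() * no);
    if (off[i] == no) off[i] = no - 1;
    for (int p = 0; p < motif_len; ++p)
      st.cnt[cl[i]][p * 20 + pep_flat[pep_start[i] + off[i] + p]] += 1.0;
    st.size[cl[i]] += 1.0;
  }
  const double init_kld = system_kld(st, bg, beta);

  // phase-shift move: try shifting every (shiftable) member of cluster k
  // by delta; keep the shift if the system KLD improves
  auto try_phase_shift = [&](int k, int delta) {
    std::vector<int> movers;
    for (int i = 0; i < n; ++i) {
      if (cl[i] != k) continue;
      int no = pep_len[i] - motif_len + 1;
      if (off[i] + delta >= 0 && off[i] + delta < no) movers.push_back(i);
    }
    if (movers.empty()) return;
    const double before = system_kld(st, bg, beta);
    for (int i : movers) {
      for (int p = 0; p < motif_len; ++p) {
        st.cnt[k][p * 20 + pep_flat[pep_start[i] + off[i] + p]] -= 1.0;
        st.cnt[k][p * 20 + pep_flat[pep_start[i] + off[i] + delta + p]] +=
            1.0;
      }
      off[i] += delta;
    }
    if (system_kld(st, bg, beta) < before) { // revert
      for (int i : movers) {
        for (int p = 0; p < motif_len; ++p) {
          st.cnt[k][p * 20 + pep_flat[pep_start[i] + off[i] + p]] -= 1.0;
          st.cnt[k][p * 20 + pep_flat[pep_start[i] + off[i] - delta + p]] +=
              1.0;
        }
        off[i] -= delta;
      }
    }
  };

  std::vector<double> score; // K * max offsets scratch
  const int total_sweeps = sweeps + greedy;
  bool any_shiftable = false;
  for (int i = 0; i < n; ++i)
    if (pep_len[i] > motif_len) any_shiftable = true;
  for (int sw = 0; sw < total_sweeps; ++sw) {
    const bool argmax = sw >= sweeps;
    const double temp =
        argmax ? 0.0 : std::max(0.05, t0 * (1.0 - (double)sw / sweeps));
    for (int i = 0; i < n; ++i) {
      // remove peptide i from its cluster (unless trashed)
      if (cl[i] >= 0) {
        for (int p = 0; p < motif_len; ++p)
          st.cnt[cl[i]][p * 20 + pep_flat[pep_start[i] + off[i] + p]] -= 1.0;
        st.size[cl[i]] -= 1.0;
      }
      const int no = pep_len[i] - motif_len + 1;
      score.assign((size_t)K * no, 0.0);
      double best = -1e300;
      int bestk = 0, besto = 0;
      for (int k = 0; k < K; ++k)
        for (int o = 0; o < no; ++o) {
          double s = 0;
          for (int p = 0; p < motif_len; ++p)
            s += cell_logodds(st, bg, beta, k, p,
                              pep_flat[pep_start[i] + o + p]);
          score[(size_t)k * no + o] = s;
          if (s > best) {
            best = s;
            bestk = k;
            besto = o;
          }
        }
      int newk, newo;
      if (use_trash && best < trash_threshold) {
        cl[i] = -1;
        continue;
      }
      if (argmax || temp <= 0.0) {
        newk = bestk;
        newo = besto;
      } else {
        // softmax draw at temperature `temp`
        double z = 0;
        for (size_t j = 0; j < score.size(); ++j) {
          score[j] = std::exp((score[j] - best) / temp);
          z += score[j];
        }
        double u = unif_rand() * z, acc = 0;
        size_t pick = score.size() - 1;
        for (size_t j = 0; j < score.size(); ++j) {
          acc += score[j];
          if (u <= acc) {
            pick = j;
            break;
          }
        }
        newk = (int)(pick / no);
        newo = (int)(pick % no);
      }
      cl[i] = newk;
      off[i] = newo;
      for (int p = 0; p < motif_len; ++p)
        st.cnt[newk][p * 20 + pep_flat[pep_start[i] + newo + p]] += 1.0;
      st.size[newk] += 1.0;
    }
    if (any_shiftable)
      for (int k = 0; k < K; ++k)
        for (int d = 1; d <= 3; ++d) {
          try_phase_shift(k, d);
          try_phase_shift(k, -d);
        }
  }

  // per-peptide final log-odds score of its assigned (cluster, offset)
  NumericVector final_score(n);
  for (int i = 0; i < n; ++i) {
    if (cl[i] < 0) {
      final_score[i] = NA_REAL;
      continue;
    }
    double s = 0;
    for (int p = 0; p < motif_len; ++p)
      s += cell_logodds(st, bg, beta, cl[i], p,
                        pep_flat[pep_start[i] + off[i] + p]);
    final_score[i] = s;
  }
  NumericMatrix mats(motif_len * 20, K);
  for (int k = 0; k < K; ++k)
    for (int j = 0; j < motif_len * 20; ++j) {
      double f = (st.cnt[k][j] + beta * bg[j % 20]) / (st.size[k] + beta);
      mats(j, k) = std::log2(f / bg[j % 20]);
    }
  return List::create(_["cluster"] = wrap(cl), _["offset"] = wrap(off),
                      _["kld"] = system_kld(st, bg, beta),
                      _["init_kld"] = init_kld, _["score"] = final_score,
                      _["logodds"] = mats);
}
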