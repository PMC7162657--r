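#include <Rcpp.h>
using namespace Rcpp;

// Rank-based weight reassignment onto a fixed binary topology.
// Greedy, re-ranked after every assignment: repeatedly pick a random
// unassigned edge, rank its residual-strength product s_i * s_j among all
// unassigned edges, and give it the weight of the same rank among the
// remaining (descending-sorted) original weights. Preserves the weight
// multiset exactly and the strength sequence approximately.
// ei, ej: 1-based edge endpoints; weights: original edge weights (any order);
// target_strength: per-node strengths to approximate. Uses the R RNG.
// After the greedy pass, a swap-refinement polish repeatedly exchanges the
// weights of random edge pairs whenever the squared strength error drops,
// for up to refine_passes sweeps (early exit on a sweep with no accepted
// swap). The weight multiset is untouched by construction.
// [[Rcpp::export(name = ".assign_weights_rank")]]
NumericVector assign_weights_rank(IntegerVector ei, IntegerVector ej,
                                  NumericVector weights,
                                  NumericVector target_strength,
                                  int refine_passes = 20) {
  int m = ei.size();
  if (ej.size() != m || weights.size() != m)
    stop("edge list and weight vector lengths differ");
  std::vector<double> wv(weights.begin(), weights.end());
  std::sort(wv.begin(), wv.end(), std::greater<double>());
  std::vector<double> resid(target_strength.begin(), target_strength.end());
  std::vector<int> un(m);
  for (int k = 0; k < m; ++k) un[k] = k;
  NumericVector out(m);

  for (int it = 0; it < m; ++it) {
    int k = un.size();
    int pick = (int)(unif_rand() * k);
    if (pick >= k) pick = k - 1;
    int o = un[pick];
    double so = resid[ei[o] - 1] * resid[ej[o] - 1];
    int r = 0;
    for (int q = 0; q < k; ++q) {
      int e = un[q];
      if (resid[ei[e] - 1] * resid[ej[e] - 1] > so) ++r;
    }
    double w = wv[r];
    wv.erase(wv.begin() + r);
    out[o] = w;
    resid[ei[o] - 1] -= w;
    resid[ej[o] - 1] -= w;
    un.erase(un.begin() + pick);
  }

  // swap-refinement polish toward the target strength sequence
  int nn = target_strength.size();
  std::vector<double> s(nn, 0.0), err(nn);
  for (int e = 0; e < m; ++e) {
    s[ei[e] - 1] += out[e];
    s[ej[e] - 1] += out[e];
  }
  for (int v = 0; v < nn; ++v) err[v] = s[v] - target_strength[v];
  for (int pass = 0; pass < refine_passes; ++pass) {
    bool improved = false;
    for (int k = 0; k < m; ++k) {
      int e = (int)(unif_rand() * m); if (e >= m) e = m - 1;
      int f = (int)(unif_rand() * m); if (f >= m) f = m - 1;
      if (e == f) continue;
      double d = out[f] - out[e];
      if (d == 0.0) continue;
      int i1 = ei[e] - 1, j1 = ej[e] - 1, i2 = ei[f] - 1, j2 = ej[f] - 1;
      double before = err[i1] * err[i1] + err[j1] * err[j1] +
                      err[i2] * err[i2] + err[j2] * err[j2];
      double n_i1 = err[i1] + d, n_j1 = err[j1] + d;
      double n_i2 = err[i2] - d, n_j2 = err[j2] - d;
      // shared endpoints: recompute jointly to stay exact
      if (i1 == i2 || i1 == j2 || j1 == i2 || j1 == j2) {
        std::vector<double> tmp(err);
        tmp[i1] += d; tmp[j1] += d; tmp[i2] -= d; tmp[j2] -= d;
        double after = tmp[i1] * tmp[i1] + tmp[j1] * tmp[j1] +
                       tmp[i2] * tmp[i2] + tmp[j2] * tmp[j2];
        double bef2 = err[i1] * err[i1] + err[j1] * err[j1] +
                      err[i2] * err[i2] + err[j2] * err[j2];
        if (after < bef2) {
          double t = out[e]; out[e] = out[f]; out[f] = t;
          err[i1] += d; err[j1] += d; err[i2] -= d; err[j2] -= d;
          improved = true;
        }
        continue;
      }
      double after = n_i1 * n_i1 + n_j1 * n_j1 + n_i2 * n_i2 + n_j2 * n_j2;
      if (after < before) {
        double t = out[e]; out[e] = out[f]; out[f] = t;
        err[i1] += d; err[j1] += d; err[i2] -= d; err[j2] -= d;
        improved = true;
      }
    }
    if (!improved) break;
  }
  return out;
}
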