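#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Gibbs-style Metropolis-Hastings sampler for the bounded-network density
//   f(x) propto exp(theta' h(x)),  x in [0,1]^m.
//
// Statistics (stat id / downweight w):
//   1 two_stars: sum over edge pairs sharing a node of (x_ik x_jk)^w
//   2 triads:    sum over node triples of (x_ij x_jk x_ik)^w
//   3 edges:     sum of x_ij^w
//
// Proposal: per-edge Gaussian random walk reflected at the [0,1]
// boundaries (symmetric), systematic sweep over edges in the canonical
// row-major upper-triangle order.  Uses R's RNG, so set.seed() on the R
// side gives reproducible chains.

static inline double reflect01(double v) {
  // fold v into [0,1]; proposal density stays symmetric
  while (v < 0.0 || v > 1.0) {
    if (v < 0.0) v = -v;
    if (v > 1.0) v = 2.0 - v;
  }
  return v;
}

// change in statistic s when edge (i,j) moves from u to v, given powered
// adjacency P (P = x^w, zero diagonal)
static double delta_stat(int id, const NumericMatrix &P, int n,
                         int i, int j, double pu, double pv) {
  double s = 0.0;
  switch (id) {
  case 1: { // two-stars: pairs through i and through j
    for (int k = 0; k < n; ++k) {
      if (k == i || k == j) continue;
      s += P(i, k) + P(j, k);
    }
    return (pv - pu) * s;
  }
  case 2: { // triads: triples containing edge (i,j)
    for (int k = 0; k < n; ++k) {
      if (k == i || k == j) continue;
      s += P(i, k) * P(j, k);
    }
    return (pv - pu) * s;
  }
  default: // edges
    return pv - pu;
  }
}

// full statistic value from scratch
static double full_stat(int id, const NumericMatrix &P, int n) {
  double s = 0.0;
  switch (id) {
  case 1:
    for (int k = 0; k < n; ++k) {
      double r = 0.0, r2 = 0.0;
      for (int i = 0; i < n; ++i) {
        r += P(k, i);
        r2 += P(k, i) * P(k, i);
      }
      s += r * r - r2;
    }
    return s / 2.0;
  case 2:
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j)
        for (int k = j + 1; k < n; ++k)
          s += P(i, j) * P(j, k) * P(i, k);
    return s;
  default:
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j)
        s += P(i, j);
    return s;
  }
}

// [[Rcpp::export]]
List mh_sample_cpp(int n_nodes, NumericVector theta, IntegerVector ids,
                   NumericVector weights, NumericVector x_init,
                   int n_samples, int burn_in, int thin,
                   double proposal_sd, bool tune, int fixed_edge) {
  const int n = n_nodes;
  const int m = n * (n - 1) / 2;
  const int p = theta.size();
  if (x_init.size() != m) stop("x_init has wrong length");
  if (ids.size() != p || weights.size() != p)
    stop("theta, ids and weights must have equal length");

  // edge list in canonical row-major upper-triangle order
  std::vector<int> ei(m), ej(m);
  {
    int e = 0;
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) { ei[e] = i; ej[e] = j; ++e; }
  }

  NumericMatrix X(n, n);
  for (int e = 0; e < m; ++e) {
    X(ei[e], ej[e]) = x_init[e];
    X(ej[e], ei[e]) = x_init[e];
  }

  // powered adjacency per statistic
  std::vector<NumericMatrix> P;
  for (int s = 0; s < p; ++s) {
    NumericMatrix Ps(n, n);
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j)
        Ps(i, j) = (i == j) ? 0.0 : std::pow(X(i, j), weights[s]);
    P.push_back(Ps);
  }

  std::vector<double> h(p);
  for (int s = 0; s < p; ++s) h[s] = full_stat(ids[s], P[s], n);

  NumericMatrix out_x(n_samples, m);
  NumericMatrix out_h(n_samples, p);

  RNGScope scope;
  double sd = proposal_sd;
  long acc = 0, tot = 0;          // post-burn-in acceptance bookkeeping
  long tune_acc = 0, tune_tot = 0;
  const int tune_block = 50;      // sweeps between tuning updates
  int stored = 0, since = 0;
  const int total_sweeps = burn_in + n_samples * thin;

  std::vector<double> pv(p), dlh(p);

  for (int sweep = 0; sweep < total_sweeps; ++sweep) {
    const bool in_burn = sweep < burn_in;
    for (int e = 0; e < m; ++e) {
      if (fixed_edge >= 0 && e != fixed_edge) continue;
      const int i = ei[e], j = ej[e];
      const double u = X(i, j);
      const double v = reflect01(u + sd * R::norm_rand());
      double lr = 0.0;
      for (int s = 0; s < p; ++s) {
        pv[s] = std::pow(v, weights[s]);
        dlh[s] = delta_stat(ids[s], P[s], n, i, j, P[s](i, j), pv[s]);
        lr += theta[s] * dlh[s];
      }
      bool accept = lr >= 0.0 || R::unif_rand() < std::exp(lr);
      if (accept) {
        X(i, j) = v; X(j, i) = v;
        for (int s = 0; s < p; ++s) {
          P[s](i, j) = pv[s]; P[s](j, i) = pv[s];
          h[s] += dlh[s];
        }
      }
      if (in_burn && tune) { tune_tot++; if (accept) tune_acc++; }
      if (!in_burn) { tot++; if (accept) acc++; }
    }
    if (in_burn && tune && ((sweep + 1) % tune_block == 0) && tune_tot > 0) {
      double rate = (double)tune_acc / (double)tune_tot;
      sd *= std::exp(rate - 0.25);          // aim at ~25% acceptance
      if (sd < 1e-3) sd = 1e-3;
      if (sd > 1.0) sd = 1.0;
      tune_acc = 0; tune_tot = 0;
    }
    if (!in_burn) {
      if (++since == thin) {
        since = 0;
        for (int e = 0; e < m; ++e) out_x(stored, e) = X(ei[e], ej[e]);
        for (int s = 0; s < p; ++s) out_h(stored, s) = h[s];
        if (++stored == n_samples) break;
      }
    }
    if ((sweep & 1023) == 0) Rcpp::checkUserInterrupt();
    for (int s = 0; s < p; ++s)
      if (!std::isfinite(h[s]))
        stop("non-finite statistic value encountered during sampling");
  }

  return List::create(_["x"] = out_x, _["stats"] = out_h,
                      _["acceptance"] = tot > 0 ? (double)acc / (double)tot : NA_REAL,
                      _["proposal_sd"] = sd);
}
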