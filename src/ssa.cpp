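#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Sparse, per-directed-reaction view of the stoichiometry used by the hot loop.
struct Rxn {
  std::vector<std::pair<int,int> > reac;   // (species, nu_minus) with nu_minus > 0
  std::vector<std::pair<int,int> > delta;  // (species, nu_plus - nu_minus) != 0, non-driven only
  double k;                                // kappa * omega^{-(|L_r|-1)}
};

static std::vector<Rxn> build_rxns(const IntegerMatrix& nu_minus,
                                   const IntegerMatrix& nu_plus,
                                   const NumericVector& kappa,
                                   const LogicalVector& driven,
                                   double omega) {
  const int M = nu_minus.nrow(), N = nu_minus.ncol();
  std::vector<Rxn> rx(M);
  for (int r = 0; r < M; ++r) {
    int nL = 0;
    for (int i = 0; i < N; ++i) {
      const int vm = nu_minus(r, i), vp = nu_plus(r, i);
      if (vm > 0) { rx[r].reac.push_back(std::make_pair(i, vm)); ++nL; }
      if (vp != vm && !driven[i]) rx[r].delta.push_back(std::make_pair(i, vp - vm));
    }
    rx[r].k = kappa[r] * std::pow(omega, -(double)(nL - 1));
  }
  return rx;
}

// Mass-action propensity kappa * prod_i C(X_i, nu-_r(i)) / omega^{|L_r|-1},
// zero when reactants are insufficient or a firing would push a non-driven
// product above its cap.
static inline double propensity_of(const Rxn& rx, const int* x, const int* xmax) {
  double a = rx.k;
  for (size_t q = 0; q < rx.reac.size(); ++q) {
    const int i = rx.reac[q].first, v = rx.reac[q].second;
    const int xi = x[i];
    if (xi < v) return 0.0;
    // falling factorial / v!  (v is small: 1 or 2 in practice)
    double c = 1.0;
    for (int j = 0; j < v; ++j) c *= (double)(xi - j) / (double)(j + 1);
    a *= c;
  }
  if (a <= 0.0) return 0.0;
  for (size_t q = 0; q < rx.delta.size(); ++q) {
    const int i = rx.delta[q].first, d = rx.delta[q].second;
    if (d > 0 && x[i] + d > xmax[i]) return 0.0;
    if (d < 0 && x[i] + d < 0) return 0.0;
  }
  return a;
}

// One Gillespie event on x in place. Returns false at an absorbing state.
static inline bool ssa_event(const std::vector<Rxn>& rx, int* x, const int* xmax,
                             std::vector<double>& eta) {
  const int M = (int)rx.size();
  double tot = 0.0;
  for (int r = 0; r < M; ++r) { eta[r] = propensity_of(rx[r], x, xmax); tot += eta[r]; }
  if (tot <= 0.0) return false;
  unif_rand();                      // u1: waiting time, kept for stream faithfulness
  const double u2 = unif_rand();
  double acc = 0.0; int r = M - 1;
  const double target = u2 * tot;
  for (int rr = 0; rr < M; ++rr) { acc += eta[rr]; if (acc > target) { r = rr; break; } }
  for (size_t q = 0; q < rx[r].delta.size(); ++q)
    x[rx[r].delta[q].first] += rx[r].delta[q].second;
  return true;
}

// Iteration-convention ensemble run: every member advances by
// `rxn_per_iter` Gillespie events per iteration, for dt_eq equilibration
// iterations followed by dt_av recorded iterations. Accumulates the
// statistics needed downstream (means, sds, sign frequencies, joint
// histograms for requested species pairs) and optionally the full buffer.
// [[Rcpp::export]]
List cpp_run_ensemble(IntegerMatrix counts,
                      IntegerMatrix nu_minus, IntegerMatrix nu_plus,
                      NumericVector kappa, LogicalVector driven,
                      IntegerVector x_max, double omega,
                      int dt_eq, int dt_av, int rxn_per_iter,
                      IntegerMatrix pairs, int n_bins,
                      NumericVector thresholds, bool keep_buffer) {
  const int n_pop = counts.nrow(), N = counts.ncol();
  const int M = nu_minus.nrow();
  std::vector<Rxn> rx = build_rxns(nu_minus, nu_plus, kappa, driven, omega);
  std::vector<double> eta(M);
  std::vector<int> xmax(N);
  for (int i = 0; i < N; ++i) xmax[i] = x_max[i];

  const int n_pairs = pairs.nrow();
  NumericVector sum(N), sumsq(N);
  NumericVector sign_pos(N);
  NumericVector joints(n_pairs * n_bins * n_bins);
  IntegerVector buffer(keep_buffer ? n_pop * N * dt_av : 0);

  IntegerMatrix out = clone(counts);
  std::vector<int> x(N);

  for (int m = 0; m < n_pop; ++m) {
    for (int i = 0; i < N; ++i) x[i] = out(m, i);
    for (int it = 0; it < dt_eq + dt_av; ++it) {
      for (int e = 0; e < rxn_per_iter; ++e)
        if (!ssa_event(rx, x.data(), xmax.data(), eta)) break;
      if (it >= dt_eq) {
        const int s = it - dt_eq;
        for (int i = 0; i < N; ++i) {
          const double xi = (double)x[i];
          sum[i] += xi; sumsq[i] += xi * xi;
          if (xi > thresholds[i]) sign_pos[i] += 1.0;
          if (keep_buffer) buffer[m + n_pop * (i + N * s)] = x[i];
        }
        for (int p = 0; p < n_pairs; ++p) {
          const int i = pairs(p, 0), j = pairs(p, 1);
          int bi = (int)((double)x[i] * n_bins / (double)(xmax[i] + 1));
          int bj = (int)((double)x[j] * n_bins / (double)(xmax[j] + 1));
          if (bi >= n_bins) bi = n_bins - 1;
          if (bj >= n_bins) bj = n_bins - 1;
          joints[p + n_pairs * (bi + n_bins * bj)] += 1.0;
        }
      }
    }
    for (int i = 0; i < N; ++i) out(m, i) = x[i];
  }

  const double n_samp = (double)n_pop * (double)dt_av;
  return List::create(_["counts"] = out,
                      _["n_samples"] = n_samp,
                      _["sum"] = sum, _["sumsq"] = sumsq,
                      _["sign_pos"] = sign_pos,
                      _["joints"] = joints,
                      _["buffer"] = buffer);
}

// Real-time SSA over independent members, recording counts at a fixed time
// grid (used for mean-field comparisons where physical time matters).
// [[Rcpp::export]]
IntegerVector cpp_ssa_timegrid(IntegerMatrix counts,
                               IntegerMatrix nu_minus, IntegerMatrix nu_plus,
                               NumericVector kappa, LogicalVector driven,
                               IntegerVector x_max, double omega,
                               NumericVector times) {
  const int n_pop = counts.nrow(), N = counts.ncol();
  const int M = nu_minus.nrow(), n_t = times.size();
  std::vector<Rxn> rx = build_rxns(nu_minus, nu_plus, kappa, driven, omega);
  std::vector<double> eta(M);
  std::vector<int> xmax(N), x(N);
  for (int i = 0; i < N; ++i) xmax[i] = x_max[i];

  IntegerVector buf(n_pop * N * n_t);
  for (int m = 0; m < n_pop; ++m) {
    for (int i = 0; i < N; ++i) x[i] = counts(m, i);
    double t = 0.0; int g = 0; bool absorbed = false;
    while (g < n_t) {
      double tot = 0.0;
      if (!absorbed) {
        for (int r = 0; r < M; ++r) { eta[r] = propensity_of(rx[r], x.data(), xmax.data()); tot += eta[r]; }
        if (tot <= 0.0) absorbed = true;
      }
      if (absorbed) {
        for (; g < n_t; ++g)
          for (int i = 0; i < N; ++i) buf[m + n_pop * (i + N * g)] = x[i];
        break;
      }
      const double u1 = unif_rand();
      const double tau = std::log(1.0 / u1) / tot;
      while (g < n_t && t + tau > times[g]) {
        for (int i = 0; i < N; ++i) buf[m + n_pop * (i + N * g)] = x[i];
        ++g;
      }
      if (g >= n_t) break;
      t += tau;
      const double u2 = unif_rand();
      double acc = 0.0; int r = M - 1;
      const double target = u2 * tot;
      for (int rr = 0; rr < M; ++rr) { acc += eta[rr]; if (acc > target) { r = rr; break; } }
      for (size_t q = 0; q < rx[r].delta.size(); ++q)
        x[rx[r].delta[q].first] += rx[r].delta[q].second;
    }
  }
  buf.attr("dim") = IntegerVector::create(n_pop, N, n_t);
  return buf;
}
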