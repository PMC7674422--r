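#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Gillespie simulation of a time-homogeneous birth-death process started from
// one lineage. Exact exponential waiting times; no time discretization.
//
// S(t) is the total lineage duration accumulated on the clade between origin
// and elapsed time t, i.e. the integral of N(u) du over [0, t]. Lineages that
// later go extinct contribute the duration they lived (fossils can be sampled
// from them), so S grows by N * dt between events.

// Saturation guard: once psi*S - log(N) exceeds this, psi*N*exp(-psi*S) is
// below ~1e-17 of any attainable maximum and only survival status matters.
static const double SAT_LOG = 40.0;
// Lineage count above which extinction of the whole clade is numerically
// impossible for turnover < 1 (prob <= eps^N).
static const int SAT_N = 50;
static const int HARD_N_CAP = 2000000;

// [[Rcpp::export]]
List bd_simulate_cpp(double lambda, double mu, double t, int n_reps,
                     double max_attempts) {
  NumericVector N_out(n_reps), S_out(n_reps);
  double attempts = 0.0;
  RNGScope scope;
  for (int r = 0; r < n_reps; ++r) {
    bool accepted = false;
    double attempts_here = 0.0;  // rejection cap applies per accepted sample
    while (!accepted) {
      attempts += 1.0;
      attempts_here += 1.0;
      if (attempts_here > max_attempts)
        stop("rejection cap reached: survival probability too small at t=%g",
             t);
      double tau = 0.0, S = 0.0;
      long N = 1;
      bool alive = true;
      while (true) {
        double total = (double)N * (lambda + mu);
        double wait = (total > 0.0) ? R::exp_rand() / total : R_PosInf;
        double te = tau + wait;
        if (te >= t) {
          S += (double)N * (t - tau);
          break;
        }
        S += (double)N * (te - tau);
        tau = te;
        if (R::unif_rand() < lambda / (lambda + mu)) {
          ++N;
          if (N > HARD_N_CAP) stop("lineage count exceeded hard cap");
        } else {
          --N;
          if (N == 0) { alive = false; break; }
        }
      }
      if (alive) {
        N_out[r] = (double)N;
        S_out[r] = S;
        accepted = true;
      }
    }
  }
  return List::create(_["N"] = N_out, _["S"] = S_out,
                      _["attempts"] = attempts);
}

// Monte-Carlo kernel for the clade-age calibration density
//   f(t) = E[ psi * N * exp(-psi * S(t - t_f)) | N >= 1 ]
// marginalised over a uniform fossil-age interval [tf_min, tf_max] and uniform
// ranges for psi, net diversification d and turnover eps. For each replicate a
// single lineage history is simulated once up to the largest elapsed time the
// grid requires and evaluated at every grid age; conditioning on survival uses
// the pooled survivor count per grid age.
//
// grid: ascending absolute ages (Ma). Returns per-grid-age sums needed to
// assemble the (unnormalised) density in R.
// [[Rcpp::export]]
List bd_density_kernel_cpp(NumericVector grid, double tf_min, double tf_max,
                           double psi_min, double psi_max, double d_min,
                           double d_max, double eps_min, double eps_max,
                           int n_reps) {
  const int G = grid.size();
  NumericVector g_sum(G), alive_cnt(G), valid_cnt(G);
  RNGScope scope;
  for (int r = 0; r < n_reps; ++r) {
    double tf = (tf_max > tf_min) ? R::runif(tf_min, tf_max) : tf_min;
    double psi = (psi_max > psi_min) ? R::runif(psi_min, psi_max) : psi_min;
    double d = (d_max > d_min) ? R::runif(d_min, d_max) : d_min;
    double eps = (eps_max > eps_min) ? R::runif(eps_min, eps_max) : eps_min;
    double lambda = d / (1.0 - eps);
    double mu = eps * d / (1.0 - eps);
    double tau_max = grid[G - 1] - tf;
    if (tau_max < 0.0) continue;  // fossil older than entire grid: no support
    // first grid index with elapsed time >= 0
    int g0 = 0;
    while (g0 < G && grid[g0] - tf < 0.0) ++g0;

    double tau = 0.0, S = 0.0;
    long N = 1;
    int g = g0;
    bool alive = true, saturated = false;
    while (g < G) {
      if (!alive) break;
      if (saturated) break;
      double total = (double)N * (lambda + mu);
      double wait = (total > 0.0) ? R::exp_rand() / total : R_PosInf;
      double te = tau + wait;
      // evaluate all grid elapsed times in [tau, te)
      while (g < G) {
        double el = grid[g] - tf;
        if (el >= te) break;
        double Sg = S + (double)N * (el - tau);
        double x = psi * Sg;
        valid_cnt[g] += 1.0;
        alive_cnt[g] += 1.0;
        if (x < 700.0) g_sum[g] += psi * (double)N * std::exp(-x);
        ++g;
      }
      if (g >= G) break;
      S += (double)N * (te - tau);
      tau = te;
      if (R::unif_rand() < lambda / (lambda + mu)) {
        ++N;
        if ((N >= SAT_N && psi * S - std::log((double)N) > SAT_LOG) ||
            N > HARD_N_CAP)
          saturated = true;
      } else {
        --N;
        if (N == 0) alive = false;
      }
    }
    // remaining grid ages after extinction or saturation
    for (; g < G; ++g) {
      valid_cnt[g] += 1.0;
      if (saturated) alive_cnt[g] += 1.0;  // contribution ~0 but clade alive
    }
  }
  return List::create(_["g_sum"] = g_sum, _["alive"] = alive_cnt,
                      _["valid"] = valid_cnt);
}
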