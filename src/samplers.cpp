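#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Target densities the samplers can traverse: a 1-D Gaussian (time
// estimation) or a 2-D Gaussian mixture (semantic plane). Inverse
// covariances and log normalizers are precomputed once per run.
struct Target {
  int type; // 1 = gaussian, 2 = mixture
  int dim;
  double mean, sd;
  int K;
  std::vector<double> logw, mux, muy;
  std::vector<double> ia, ib, ic; // inverse covariance [a b; b c]
  std::vector<double> lnorm;

  double logp(const double *x) const {
    if (type == 1) {
      double z = (x[0] - mean) / sd;
      return -0.918938533204672742 - std::log(sd) - 0.5 * z * z;
    }
    double m = R_NegInf;
    std::vector<double> lk(K);
    for (int k = 0; k < K; ++k) {
      double q;
      if (dim == 1) {
        double d1 = x[0] - mux[k];
        q = ia[k] * d1 * d1;
      } else {
        double d1 = x[0] - mux[k], d2 = x[1] - muy[k];
        q = ia[k] * d1 * d1 + 2.0 * ib[k] * d1 * d2 + ic[k] * d2 * d2;
      }
      lk[k] = logw[k] + lnorm[k] - 0.5 * q;
      if (lk[k] > m) m = lk[k];
    }
    double s = 0.0;
    for (int k = 0; k < K; ++k)
      if (lk[k] - m > -37.0) s += std::exp(lk[k] - m); // below: underflows
    return m + std::log(s);
  }

  void grad(const double *x, double *g) const {
    if (type == 1) {
      g[0] = -(x[0] - mean) / (sd * sd);
      return;
    }
    double m = R_NegInf;
    std::vector<double> lk(K), g1(K), g2(K);
    for (int k = 0; k < K; ++k) {
      if (dim == 1) {
        double d1 = x[0] - mux[k];
        lk[k] = logw[k] + lnorm[k] - 0.5 * ia[k] * d1 * d1;
        g1[k] = -ia[k] * d1;
        g2[k] = 0.0;
      } else {
        double d1 = x[0] - mux[k], d2 = x[1] - muy[k];
        double q = ia[k] * d1 * d1 + 2.0 * ib[k] * d1 * d2 + ic[k] * d2 * d2;
        lk[k] = logw[k] + lnorm[k] - 0.5 * q;
        g1[k] = -(ia[k] * d1 + ib[k] * d2);
        g2[k] = -(ib[k] * d1 + ic[k] * d2);
      }
      if (lk[k] > m) m = lk[k];
    }
    double s = 0.0;
    for (int k = 0; k < K; ++k) s += std::exp(lk[k] - m);
    for (int d = 0; d < dim; ++d) g[d] = 0.0;
    for (int k = 0; k < K; ++k) {
      double r = std::exp(lk[k] - m) / s;
      g[0] += r * g1[k];
      if (dim == 2) g[1] += r * g2[k];
    }
  }
};

static Target parse_target(const List &spec) {
  Target t;
  t.type = as<int>(spec["type"]);
  if (t.type == 1) {
    t.dim = 1;
    t.mean = as<double>(spec["mean"]);
    t.sd = as<double>(spec["sd"]);
    t.K = 0;
  } else {
    NumericVector w = spec["weights"];
    NumericMatrix mu = spec["means"];
    List covs = spec["covs"];
    t.dim = mu.ncol();
    t.K = w.size();
    t.logw.resize(t.K); t.mux.resize(t.K); t.muy.resize(t.K);
    t.ia.resize(t.K); t.ib.resize(t.K); t.ic.resize(t.K); t.lnorm.resize(t.K);
    for (int k = 0; k < t.K; ++k) {
      t.logw[k] = std::log(w[k]);
      t.mux[k] = mu(k, 0);
      NumericMatrix S = covs[k];
      if (t.dim == 1) {
        t.muy[k] = 0.0;
        t.ia[k] = 1.0 / S(0, 0);
        t.ib[k] = 0.0; t.ic[k] = 0.0;
        t.lnorm[k] = -0.918938533204672742 - 0.5 * std::log(S(0, 0));
      } else {
        t.muy[k] = mu(k, 1);
        double det = S(0, 0) * S(1, 1) - S(0, 1) * S(1, 0);
        t.ia[k] = S(1, 1) / det;
        t.ib[k] = -S(0, 1) / det;
        t.ic[k] = S(0, 0) / det;
        t.lnorm[k] = -std::log(2.0 * M_PI) - 0.5 * std::log(det);
      }
    }
  }
  return t;
}

// One Random Walk Metropolis step on the tempered density logp(x)/T.
// Consumes dim normals for the proposal and one uniform for the accept
// decision, in that order.
static bool rwm_inplace(const Target &t, double *x, double &lp,
                        double scale, double invT) {
  double prop[2];
  for (int d = 0; d < t.dim; ++d) prop[d] = x[d] + scale * norm_rand();
  double lp_new = t.logp(prop);
  double u = unif_rand();
  if (R_finite(lp_new) && std::log(u) < (lp_new - lp) * invT) {
    for (int d = 0; d < t.dim; ++d) x[d] = prop[d];
    lp = lp_new;
    return true;
  }
  return false;
}

// One HMC step: momentum refresh, `leaps` leapfrog steps of size `step`,
// Metropolis correction on the Hamiltonian error. A non-finite gradient
// or log-density along the path rejects the step.
static bool hmc_inplace(const Target &t, double *x, double &lp,
                        double step, int leaps) {
  if (leaps == 0) return true; // degenerate identity step
  double q[2], p[2], g[2];
  double ke0 = 0.0;
  for (int d = 0; d < t.dim; ++d) {
    q[d] = x[d];
    p[d] = norm_rand();
    ke0 += 0.5 * p[d] * p[d];
  }
  double h0 = -lp + ke0;
  t.grad(q, g);
  bool bad = false;
  for (int d = 0; d < t.dim; ++d) {
    if (!R_finite(g[d])) bad = true;
    p[d] += 0.5 * step * g[d];
  }
  for (int l = 0; l < leaps && !bad; ++l) {
    for (int d = 0; d < t.dim; ++d) q[d] += step * p[d];
    t.grad(q, g);
    double w = (l == leaps - 1) ? 0.5 : 1.0;
    for (int d = 0; d < t.dim; ++d) {
      if (!R_finite(g[d])) bad = true;
      p[d] += w * step * g[d];
    }
  }
  double u = unif_rand();
  if (bad) return false;
  double lp_new = t.logp(q);
  double ke1 = 0.0;
  for (int d = 0; d < t.dim; ++d) ke1 += 0.5 * p[d] * p[d];
  double h1 = -lp_new + ke1;
  if (R_finite(lp_new) && std::log(u) < h0 - h1) {
    for (int d = 0; d < t.dim; ++d) x[d] = q[d];
    lp = lp_new;
    return true;
  }
  return false;
}

// [[Rcpp::export]]
double cpp_log_density(List tspec, NumericVector point) {
  Target t = parse_target(tspec);
  return t.logp(point.begin());
}

// [[Rcpp::export]]
NumericVector cpp_grad_log_density(List tspec, NumericVector point) {
  Target t = parse_target(tspec);
  NumericVector g(t.dim);
  t.grad(point.begin(), g.begin());
  return g;
}

// [[Rcpp::export]]
List cpp_rwm_step(NumericVector state, List tspec, double scale,
                  double temperature) {
  Target t = parse_target(tspec);
  std::vector<double> x(state.begin(), state.end());
  double lp = t.logp(x.data());
  if (!R_finite(lp)) stop("log-density is not finite at the current state");
  bool acc = rwm_inplace(t, x.data(), lp, scale, 1.0 / temperature);
  return List::create(_["state"] = NumericVector(x.begin(), x.end()),
                      _["accepted"] = acc);
}

// [[Rcpp::export]]
List cpp_hmc_step(NumericVector state, List tspec, double step, int leaps) {
  Target t = parse_target(tspec);
  std::vector<double> x(state.begin(), state.end());
  double lp = t.logp(x.data());
  if (!R_finite(lp)) stop("log-density is not finite at the current state");
  bool acc = hmc_inplace(t, x.data(), lp, step, leaps);
  return List::create(_["state"] = NumericVector(x.begin(), x.end()),
                      _["accepted"] = acc);
}

// Deterministic leapfrog integration (no momentum refresh, no accept
// step); exposed for reversibility checks.
// [[Rcpp::export]]
List cpp_leapfrog(NumericVector state, NumericVector momentum, List tspec,
                  double step, int leaps) {
  Target t = parse_target(tspec);
  double q[2], p[2], g[2];
  for (int d = 0; d < t.dim; ++d) { q[d] = state[d]; p[d] = momentum[d]; }
  t.grad(q, g);
  for (int d = 0; d < t.dim; ++d) p[d] += 0.5 * step * g[d];
  for (int l = 0; l < leaps; ++l) {
    for (int d = 0; d < t.dim; ++d) q[d] += step * p[d];
    t.grad(q, g);
    double w = (l == leaps - 1) ? 0.5 : 1.0;
    for (int d = 0; d < t.dim; ++d) p[d] += w * step * g[d];
  }
  return List::create(_["state"] = NumericVector(q, q + t.dim),
                      _["momentum"] = NumericVector(p, p + t.dim));
}

// One sweep of Metropolis-coupled MCMC: every chain m takes an RWM step
// on logp/T_m with proposal scale scale*sqrt(T_m) (matching the width of
// the tempered target), then (optionally) one uniformly chosen adjacent
// pair is proposed for a state swap with probability
// min(1, exp[(logp(h_j) - logp(h_i)) (1/T_i - 1/T_j)]).
// With a single chain no swap randomness is consumed, so the sweep
// reduces exactly to one RWM step.
static void mc3_sweep_inplace(const Target &t, double *xs, double *lps,
                              const double *temps, int M, double scale,
                              bool propose_swap, int *swap_out) {
  for (int m = 0; m < M; ++m)
    rwm_inplace(t, xs + m * t.dim, lps[m], scale * std::sqrt(temps[m]),
                1.0 / temps[m]);
  swap_out[0] = -1;
  if (propose_swap && M > 1) {
    int i = (int)std::floor(unif_rand() * (M - 1));
    if (i > M - 2) i = M - 2;
    int j = i + 1;
    double lr = (lps[j] - lps[i]) * (1.0 / temps[i] - 1.0 / temps[j]);
    double u = unif_rand();
    bool acc = std::log(u) < lr;
    if (acc) {
      for (int d = 0; d < t.dim; ++d)
        std::swap(xs[i * t.dim + d], xs[j * t.dim + d]);
      std::swap(lps[i], lps[j]);
    }
    swap_out[0] = i;
    swap_out[1] = j;
    swap_out[2] = acc ? 1 : 0;
  }
}

// [[Rcpp::export]]
List cpp_mc3_sweep(NumericMatrix states, List tspec, NumericVector temps,
                   double scale, bool propose_swap) {
  Target t = parse_target(tspec);
  int M = states.nrow();
  if (temps.size() != M) stop("one temperature per chain is required");
  std::vector<double> xs(M * t.dim), lps(M);
  for (int m = 0; m < M; ++m) {
    for (int d = 0; d < t.dim; ++d) xs[m * t.dim + d] = states(m, d);
    lps[m] = t.logp(xs.data() + m * t.dim);
    if (!R_finite(lps[m])) stop("log-density is not finite at a chain state");
  }
  int sw[3] = {-1, -1, -1};
  mc3_sweep_inplace(t, xs.data(), lps.data(), temps.begin(), M, scale,
                    propose_swap, sw);
  NumericMatrix out(M, t.dim);
  for (int m = 0; m < M; ++m)
    for (int d = 0; d < t.dim; ++d) out(m, d) = xs[m * t.dim + d];
  List swap = R_NilValue;
  if (sw[0] >= 0)
    swap = List::create(_["i"] = sw[0] + 1, _["j"] = sw[1] + 1,
                        _["accepted"] = sw[2] == 1);
  return List::create(_["states"] = out, _["swap"] = swap);
}

// Fused naming-task simulator: runs a sampler over the semantic plane
// and applies the count-based Poisson readout online, stopping as soon
// as n_responses have been emitted. Per iteration the RNG consumes the
// sampler's draws, then one exponential inter-arrival time, so the
// trace is seed-reproducible. Returns IRIs, emitted name indices
// (1-based) and the iteration count used.
// [[Rcpp::export]]
List cpp_run_naming(List tspec, std::string algorithm, NumericMatrix coords,
                    double rate, int n_responses, int max_iter,
                    NumericVector init, double rwm_scale, double hmc_step,
                    int hmc_leaps, NumericVector mc3_temps, int swap_every) {
  Target t = parse_target(tspec);
  if (t.dim != 2) stop("naming simulation requires a 2-D target");
  int m = coords.nrow();
  if (m < 1) stop("semantic space is empty");
  int M = (algorithm == "mc3") ? mc3_temps.size() : 1;
  std::vector<double> xs(M * 2), lps(M);
  for (int c = 0; c < M; ++c) {
    xs[c * 2] = init[0]; xs[c * 2 + 1] = init[1];
    lps[c] = t.logp(xs.data() + c * 2);
    if (!R_finite(lps[c])) stop("log-density is not finite at the initial state");
  }
  auto nearest = [&](const double *x) {
    int best = 0; double bd = R_PosInf;
    for (int j = 0; j < m; ++j) {
      double d1 = x[0] - coords(j, 0), d2 = x[1] - coords(j, 1);
      double d = d1 * d1 + d2 * d2;
      if (d < bd) { bd = d; best = j; }
    }
    return best;
  };
  std::vector<double> iris; iris.reserve(n_responses);
  std::vector<int> labels; labels.reserve(n_responses);
  int cur = -1;
  double clock = 0.0;
  int it = 0;
  int alg = (algorithm == "rwm") ? 0 : (algorithm == "hmc") ? 1 :
            (algorithm == "mc3") ? 2 : -1;
  if (alg < 0) stop("unknown algorithm: " + algorithm);
  int nn_cache = -1; // nearest name of the current cold position
  for (; it < max_iter && (int)iris.size() < n_responses; ++it) {
    // abort chains producing far too slowly to reach n/2 responses
    // within max_iter (e.g. a frozen sampler)
    if (it == 4096 && iris.empty()) break;
    if (it == max_iter / 4 &&
        (double)iris.size() < 0.03125 * n_responses) break;
    if (it == max_iter / 2 &&
        (double)iris.size() < 0.125 * n_responses) break;
    bool cold_moved = false;
    if (alg == 0) {
      cold_moved = rwm_inplace(t, xs.data(), lps[0], rwm_scale, 1.0);
    } else if (alg == 1) {
      cold_moved = hmc_inplace(t, xs.data(), lps[0], hmc_step, hmc_leaps);
    } else {
      for (int c = 0; c < M; ++c) {
        bool acc = rwm_inplace(t, xs.data() + c * 2, lps[c],
                               rwm_scale * (c == 0 ? 1.0 : std::sqrt(mc3_temps[c])),
                               1.0 / mc3_temps[c]);
        if (c == 0) cold_moved = acc;
      }
      if (((it + 1) % swap_every) == 0 && M > 1) {
        int i = (int)std::floor(unif_rand() * (M - 1));
        if (i > M - 2) i = M - 2;
        int j = i + 1;
        double lr = (lps[j] - lps[i]) * (1.0 / mc3_temps[i] - 1.0 / mc3_temps[j]);
        double u = unif_rand();
        if (std::log(u) < lr) {
          std::swap(xs[i * 2], xs[j * 2]);
          std::swap(xs[i * 2 + 1], xs[j * 2 + 1]);
          std::swap(lps[i], lps[j]);
          if (i == 0) cold_moved = true;
        }
      }
    }
    double dt = exp_rand() / rate;
    if (cold_moved || nn_cache < 0) nn_cache = nearest(xs.data());
    int nn = nn_cache;
    if (cur < 0) {
      cur = nn;        // clock starts at the first sample's arrival
      clock = 0.0;
    } else {
      clock += dt;
      if (nn != cur) {
        iris.push_back(clock);
        labels.push_back(nn + 1);
        clock = 0.0;
        cur = nn;
      }
    }
  }
  return List::create(_["iris"] = NumericVector(iris.begin(), iris.end()),
                      _["labels"] = IntegerVector(labels.begin(), labels.end()),
                      _["n_iter"] = it);
}

// Continuous power-law tail fit: for each candidate xmin (values from
// the sorted sample), the Hill/Clauset MLE mu = 1 + m / sum log(x/xmin)
// over the m tail points, scored by the KS distance between the
// empirical tail CDF and the fitted power law; the candidate with the
// smallest KS distance wins. `x` must be sorted ascending and positive;
// `cand` holds candidate xmin values.
// [[Rcpp::export]]
List cpp_tail_fit(NumericVector x, NumericVector cand, int min_tail) {
  int n = x.size();
  std::vector<double> slog(n + 1, 0.0);
  for (int i = n - 1; i >= 0; --i) slog[i] = slog[i + 1] + std::log(x[i]);
  double best_ks = R_PosInf, best_mu = NA_REAL, best_xmin = NA_REAL;
  int best_m = 0;
  for (int c = 0; c < cand.size(); ++c) {
    double xm = cand[c];
    int i = (int)(std::lower_bound(x.begin(), x.end(), xm) - x.begin());
    int m = n - i;
    if (m < min_tail) continue;
    double denom = slog[i] - m * std::log(xm);
    if (denom <= 0) continue;
    double mu = 1.0 + m / denom;
    double ks = 0.0;
    for (int j = 0; j < m; ++j) {
      double fit = 1.0 - std::pow(x[i + j] / xm, 1.0 - mu);
      double lo = (double)j / m, hi = (double)(j + 1) / m;
      double d1 = std::fabs(lo - fit), d2 = std::fabs(hi - fit);
      if (d1 > ks) ks = d1;
      if (d2 > ks) ks = d2;
    }
    if (ks < best_ks) {
      best_ks = ks; best_mu = mu; best_xmin = xm; best_m = m;
    }
  }
  return List::create(_["mu"] = best_mu, _["xmin"] = best_xmin,
                      _["n_tail"] = best_m, _["ks"] = best_ks);
}

// Full sampler run; returns the cold-chain trace with bookkeeping.
// [[Rcpp::export]]
List cpp_run_sampler(List tspec, std::string algorithm, int n,
                     NumericVector init, double rwm_scale, double hmc_step,
                     int hmc_leaps, NumericVector mc3_temps, int swap_every) {
  Target t = parse_target(tspec);
  if ((int)init.size() != t.dim) stop("initial state dimension mismatch");
  NumericMatrix samples(n, t.dim);
  LogicalVector accepted(n);
  std::vector<int> sw_iter, sw_i, sw_j, sw_acc;

  if (algorithm == "rwm" || algorithm == "hmc") {
    std::vector<double> x(init.begin(), init.end());
    double lp = t.logp(x.data());
    if (!R_finite(lp)) stop("log-density is not finite at the initial state");
    for (int it = 0; it < n; ++it) {
      bool acc = (algorithm == "rwm")
        ? rwm_inplace(t, x.data(), lp, rwm_scale, 1.0)
        : hmc_inplace(t, x.data(), lp, hmc_step, hmc_leaps);
      for (int d = 0; d < t.dim; ++d) samples(it, d) = x[d];
      accepted[it] = acc;
    }
  } else if (algorithm == "mc3") {
    int M = mc3_temps.size();
    std::vector<double> xs(M * t.dim), lps(M);
    for (int m = 0; m < M; ++m) {
      for (int d = 0; d < t.dim; ++d) xs[m * t.dim + d] = init[d];
      lps[m] = t.logp(xs.data() + m * t.dim);
      if (!R_finite(lps[m])) stop("log-density is not finite at the initial state");
    }
    for (int it = 0; it < n; ++it) {
      double lp_cold_before = lps[0];
      double x_cold_before = xs[0];
      bool propose = ((it + 1) % swap_every) == 0;
      int sw[3] = {-1, -1, -1};
      // cold-chain acceptance flag reflects the cold chain's own RWM step
      bool acc0 = rwm_inplace(t, xs.data(), lps[0], rwm_scale,
                              1.0 / mc3_temps[0]);
      (void)lp_cold_before; (void)x_cold_before;
      for (int m = 1; m < M; ++m)
        rwm_inplace(t, xs.data() + m * t.dim, lps[m],
                    rwm_scale * std::sqrt(mc3_temps[m]),
                    1.0 / mc3_temps[m]);
      if (propose && M > 1) {
        int i = (int)std::floor(unif_rand() * (M - 1));
        if (i > M - 2) i = M - 2;
        int j = i + 1;
        double lr = (lps[j] - lps[i]) * (1.0 / mc3_temps[i] - 1.0 / mc3_temps[j]);
        double u = unif_rand();
        bool acc = std::log(u) < lr;
        if (acc) {
          for (int d = 0; d < t.dim; ++d)
            std::swap(xs[i * t.dim + d], xs[j * t.dim + d]);
          std::swap(lps[i], lps[j]);
        }
        sw[0] = i; sw[1] = j; sw[2] = acc ? 1 : 0;
        sw_iter.push_back(it + 1);
        sw_i.push_back(i + 1);
        sw_j.push_back(j + 1);
        sw_acc.push_back(sw[2]);
      }
      for (int d = 0; d < t.dim; ++d) samples(it, d) = xs[d];
      accepted[it] = acc0;
    }
  } else {
    stop("unknown algorithm: " + algorithm);
  }

  return List::create(
    _["samples"] = samples,
    _["accepted"] = accepted,
    _["swap_iter"] = IntegerVector(sw_iter.begin(), sw_iter.end()),
    _["swap_i"] = IntegerVector(sw_i.begin(), sw_i.end()),
    _["swap_j"] = IntegerVector(sw_j.begin(), sw_j.end()),
    _["swap_accepted"] = IntegerVector(sw_acc.begin(), sw_acc.end()));
}
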