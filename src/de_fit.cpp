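#include <Rcpp.h>
using namespace Rcpp;

// Piecewise plateau/ramp curve; th = (t1,t2,t3,t4,A1,A2,A3).
// Must match the R-level evaluate_piecewise() definition exactly.
static inline double eval_pw(double t, double t0, const double* th) {
  const double k1 = t0 + th[0];
  const double k2 = k1 + th[1];
  const double k3 = k2 + th[2];
  const double k4 = k3 + th[3];
  if (t <= k1) return th[4];
  if (t <  k2) return th[4] + (th[5] - th[4]) * (t - k1) / th[1];
  if (t <= k3) return th[5];
  if (t <  k4) return th[5] + (th[6] - th[5]) * (t - k3) / th[3];
  return th[6];
}

static inline double cost_pw(const double* th, double t0,
                             const NumericVector& tgrid,
                             const NumericVector& d,
                             const NumericVector& inv_var) {
  double F = 0.0;
  const int n = tgrid.size();
  for (int j = 0; j < n; ++j) {
    const double r = d[j] - eval_pw(tgrid[j], t0, th);
    F += r * r * inv_var[j];
  }
  return F;
}

// Clip to the box, then rescale the four durations proportionally if their
// sum exceeds the span of the time grid (bounded search box).
static inline void repair(double* th, const NumericVector& lower,
                          const NumericVector& upper, double tspan) {
  for (int j = 0; j < 7; ++j) {
    if (th[j] < lower[j]) th[j] = lower[j];
    if (th[j] > upper[j]) th[j] = upper[j];
  }
  const double tot = th[0] + th[1] + th[2] + th[3];
  if (tot > tspan && tot > 0.0) {
    const double f = tspan / tot;
    for (int j = 0; j < 4; ++j) th[j] *= f;
  }
}

// Differential evolution (DE/rand/1/bin, greedy selection) for the
// seven-parameter piecewise profile.  Uses R's RNG so results are
// reproducible under set.seed().  Returns the pooled final populations of
// all restarts plus the per-restart best-cost traces.
// [[Rcpp::export]]
List de_fit_cpp(NumericVector d, NumericVector sigma, NumericVector tgrid,
                double t0, NumericVector lower, NumericVector upper,
                int agents, double cr, double fmix, int max_iter,
                int restarts, double reltol, int patience) {
  const int npar = 7;
  const int n = d.size();
  if (sigma.size() != n || tgrid.size() != n)
    stop("d, sigma and tgrid must have the same length");
  for (int j = 0; j < n; ++j) {
    if (!R_finite(d[j]) || !R_finite(sigma[j]) || sigma[j] <= 0.0)
      stop("non-finite data or non-positive sigma");
  }
  if (agents < 4) stop("DE needs at least 4 agents");
  const double tspan = tgrid[n - 1] - t0;

  NumericVector inv_var(n);
  for (int j = 0; j < n; ++j) inv_var[j] = 1.0 / (sigma[j] * sigma[j]);

  const int pool_n = agents * restarts;
  NumericMatrix pool(pool_n, npar);
  NumericVector pool_cost(pool_n);
  List traces(restarts);

  RNGScope scope;
  std::vector<double> pop(agents * npar), trial(npar);
  std::vector<double> cost(agents);

  for (int r = 0; r < restarts; ++r) {
    // init uniform in the box
    for (int i = 0; i < agents; ++i) {
      double* xi = &pop[i * npar];
      for (int j = 0; j < npar; ++j)
        xi[j] = lower[j] + unif_rand() * (upper[j] - lower[j]);
      repair(xi, lower, upper, tspan);
      cost[i] = cost_pw(xi, t0, tgrid, d, inv_var);
    }
    double best = *std::min_element(cost.begin(), cost.end());
    std::vector<double> trace;
    trace.reserve(max_iter + 1);
    trace.push_back(best);

    for (int it = 0; it < max_iter; ++it) {
      for (int i = 0; i < agents; ++i) {
        int r1, r2, r3;
        do { r1 = (int)(unif_rand() * agents); } while (r1 == i);
        do { r2 = (int)(unif_rand() * agents); } while (r2 == i || r2 == r1);
        do { r3 = (int)(unif_rand() * agents); } while (r3 == i || r3 == r1 || r3 == r2);
        const double* x1 = &pop[r1 * npar];
        const double* x2 = &pop[r2 * npar];
        const double* x3 = &pop[r3 * npar];
        const double* xi = &pop[i * npar];
        const int jrand = (int)(unif_rand() * npar);
        for (int j = 0; j < npar; ++j) {
          if (unif_rand() < cr || j == jrand)
            trial[j] = x1[j] + fmix * (x2[j] - x3[j]);
          else
            trial[j] = xi[j];
        }
        repair(trial.data(), lower, upper, tspan);
        const double fc = cost_pw(trial.data(), t0, tgrid, d, inv_var);
        if (fc <= cost[i]) {
          std::copy(trial.begin(), trial.end(), &pop[i * npar]);
          cost[i] = fc;
          if (fc < best) best = fc;
        }
      }
      trace.push_back(best);
      if ((int)trace.size() > patience) {
        const double prev = trace[trace.size() - 1 - patience];
        const double scale = std::max(std::abs(prev), 1e-300);
        if ((prev - best) / scale < reltol) break;
      }
    }
    traces[r] = NumericVector(trace.begin(), trace.end());
    for (int i = 0; i < agents; ++i) {
      for (int j = 0; j < npar; ++j) pool(r * agents + i, j) = pop[i * npar + j];
      pool_cost[r * agents + i] = cost[i];
    }
  }

  return List::create(_["params"] = pool, _["cost"] = pool_cost,
                      _["traces"] = traces);
}
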