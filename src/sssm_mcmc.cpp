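// MCMC sampler for the two-state switching first-difference correlated
// random walk (DCRW) observed through irregular, heavy-tailed Argos fixes.
//
// Latent process on a regular (12-h) grid of positions x_t (lon, lat deg):
//   d_t = x_t - x_{t-1}
//   d_t = gamma[b_t] * R(theta[b_t]) * d_{t-1} + e_t,  e_t ~ N2(0, Sigma)
//   b_t in {1,2} Markov with stay probabilities alpha1, alpha2
// Observations y_i between grid points (j, j+1) with interpolation weight w:
//   y_i = (1-w) x_j + w x_{j+1} + eps_i,  eps_i ~ t_nu(0, tau_class) per axis
//
// Updates per iteration:
//   b   : forward-filter backward-sample (exact)
//   x_t : single-site random-walk Metropolis, step adapted during burn-in
//   gamma/theta (per state), Sigma (log-sd, atanh-rho): RW Metropolis
//   alpha1, alpha2 : conjugate Beta Gibbs from transition counts
//
// Uses R's RNG so results are reproducible under set.seed().

#include <Rcpp.h>
using namespace Rcpp;

static const double LOG2PI = std::log(2.0 * M_PI);

struct Params {
  double gamma[2], theta[2];
  double sig_lon, sig_lat, rho;
  double alpha1, alpha2;
};

// log N2(u, v; 0, Sigma)
static inline double ldnorm2(double u, double v, const Params &p) {
  double om = 1.0 - p.rho * p.rho;
  double su = u / p.sig_lon, sv = v / p.sig_lat;
  double q = (su * su - 2.0 * p.rho * su * sv + sv * sv) / om;
  return -LOG2PI - std::log(p.sig_lon * p.sig_lat) - 0.5 * std::log(om)
         - 0.5 * q;
}

// process innovation for step t (t >= 2) under state s (0/1)
static inline void innov(const std::vector<double> &xl,
                         const std::vector<double> &xa,
                         int t, int s, const Params &p,
                         double &u, double &v) {
  double d1l = xl[t - 1] - xl[t - 2], d1a = xa[t - 1] - xa[t - 2];
  double c = std::cos(p.theta[s]), sn = std::sin(p.theta[s]);
  double ml = p.gamma[s] * (c * d1l - sn * d1a);
  double ma = p.gamma[s] * (sn * d1l + c * d1a);
  u = (xl[t] - xl[t - 1]) - ml;
  v = (xa[t] - xa[t - 1]) - ma;
}

static inline double proc_logdens(const std::vector<double> &xl,
                                  const std::vector<double> &xa,
                                  int t, int s, const Params &p) {
  double u, v;
  innov(xl, xa, t, s, p, u, v);
  return ldnorm2(u, v, p);
}

// log t density with scale
static inline double ldt(double z, double nu, double tau) {
  return R::dt(z / tau, nu, 1) - std::log(tau);
}

// [[Rcpp::export(name = ".sssm_mcmc_cpp")]]
List sssm_mcmc_cpp(NumericVector y_lon, NumericVector y_lat,
                   IntegerVector obs_idx, NumericVector obs_w,
                   NumericVector tau_lon, NumericVector tau_lat,
                   NumericVector obs_nu,
                   int n_grid, int n_iter, int n_burn, int thin,
                   NumericVector x_init_lon, NumericVector x_init_lat,
                   NumericVector par_init, double prior_sigma_scale,
                   double anchor_lon, double anchor_lat, double anchor_sd) {
  const int T = n_grid, N = y_lon.size();
  std::vector<double> xl(x_init_lon.begin(), x_init_lon.end());
  std::vector<double> xa(x_init_lat.begin(), x_init_lat.end());
  Params p;
  p.gamma[0] = par_init[0]; p.gamma[1] = par_init[1];
  p.theta[0] = par_init[2]; p.theta[1] = par_init[3];
  p.sig_lon = par_init[4]; p.sig_lat = par_init[5];
  p.rho = par_init[6]; p.alpha1 = par_init[7]; p.alpha2 = par_init[8];

  std::vector<int> b(T, 0);            // 0 = transit, 1 = ARS
  // observations grouped by the grid points they touch
  std::vector<std::vector<int>> obs_at(T);
  for (int i = 0; i < N; ++i) {
    int j = obs_idx[i];
    obs_at[j].push_back(i);
    if (j + 1 < T) obs_at[j + 1].push_back(i);
  }

  // vague proper prior anchoring the track: x_0 near the first fix and a
  // diffuse first displacement. Dominated by any observation; makes the
  // posterior proper (and the no-data sampler well defined).
  auto anchor_logdens = [&](int t) {
    double ll = 0.0;
    if (t == 0) {
      ll += R::dnorm(xl[0] - anchor_lon, 0.0, anchor_sd, 1);
      ll += R::dnorm(xa[0] - anchor_lat, 0.0, anchor_sd, 1);
    }
    if (t <= 1 && T > 1) {
      ll += R::dnorm(xl[1] - xl[0], 0.0, anchor_sd, 1);
      ll += R::dnorm(xa[1] - xa[0], 0.0, anchor_sd, 1);
    }
    return ll;
  };

  auto obs_loglik_at = [&](int t) {
    double ll = 0.0;
    for (int i : obs_at[t]) {
      int j = obs_idx[i];
      double w = obs_w[i];
      double ml = (1.0 - w) * xl[j] + w * xl[j + 1];
      double ma = (1.0 - w) * xa[j] + w * xa[j + 1];
      ll += ldt(y_lon[i] - ml, obs_nu[i], tau_lon[i]);
      ll += ldt(y_lat[i] - ma, obs_nu[i], tau_lat[i]);
    }
    return ll;
  };

  // FFBS workspace
  std::vector<double> fwd(2 * T);

  // adaptive proposal scales
  std::vector<double> step_x(T, 0.05);
  double step_g = 0.05, step_th = 0.2, step_sig = 0.15, step_rho = 0.2;
  std::vector<int> acc_x(T, 0);
  int acc_g = 0, acc_th = 0, acc_sig = 0, n_adapt_win = 0;
  const int ADAPT_EVERY = 50;

  const int n_keep = (n_iter - n_burn) / thin;
  NumericMatrix out_par(n_keep, 9);
  IntegerMatrix out_b(n_keep, T);
  NumericMatrix out_xl(n_keep, T), out_xa(n_keep, T);
  int keep = 0;

  RNGScope scope;

  for (int it = 0; it < n_iter; ++it) {
    // ---- 1. states by FFBS --------------------------------------------
    {
      double a1 = p.alpha1, a2 = p.alpha2;
      double pi1 = (1.0 - a2) / ((1.0 - a1) + (1.0 - a2));
      double trans[2][2] = {{a1, 1.0 - a1}, {1.0 - a2, a2}};
      // forward (log-space with per-step normalization)
      double prev[2] = {std::log(pi1), std::log(1.0 - pi1)};
      for (int t = 0; t < T; ++t) {
        double cur[2];
        for (int s = 0; s < 2; ++s) {
          double e = (t >= 2) ? proc_logdens(xl, xa, t, s, p) : 0.0;
          if (t == 0) {
            cur[s] = prev[s] + e;
          } else {
            double m = std::max(fwd[2 * (t - 1)] + std::log(trans[0][s]),
                                fwd[2 * (t - 1) + 1] + std::log(trans[1][s]));
            double sum = std::exp(fwd[2 * (t - 1)] + std::log(trans[0][s]) - m)
                       + std::exp(fwd[2 * (t - 1) + 1] + std::log(trans[1][s]) - m);
            cur[s] = m + std::log(sum) + e;
          }
        }
        double m = std::max(cur[0], cur[1]);
        fwd[2 * t] = cur[0] - m - std::log(std::exp(cur[0] - m) + std::exp(cur[1] - m));
        fwd[2 * t + 1] = cur[1] - m - std::log(std::exp(cur[0] - m) + std::exp(cur[1] - m));
      }
      // backward sample
      double p1 = std::exp(fwd[2 * (T - 1)]);
      b[T - 1] = (unif_rand() < p1) ? 0 : 1;
      for (int t = T - 2; t >= 0; --t) {
        double l0 = fwd[2 * t] + std::log(trans[0][b[t + 1]]);
        double l1 = fwd[2 * t + 1] + std::log(trans[1][b[t + 1]]);
        double m = std::max(l0, l1);
        double q1 = std::exp(l0 - m) / (std::exp(l0 - m) + std::exp(l1 - m));
        b[t] = (unif_rand() < q1) ? 0 : 1;
      }
    }

    // ---- 2. latent positions, single-site MH --------------------------
    for (int t = 0; t < T; ++t) {
      double old_l = xl[t], old_a = xa[t];
      double cur = obs_loglik_at(t) + anchor_logdens(t);
      for (int k = t; k <= t + 2 && k < T; ++k)
        if (k >= 2) cur += proc_logdens(xl, xa, k, b[k], p);
      xl[t] = old_l + norm_rand() * step_x[t];
      xa[t] = old_a + norm_rand() * step_x[t];
      double prop = obs_loglik_at(t) + anchor_logdens(t);
      for (int k = t; k <= t + 2 && k < T; ++k)
        if (k >= 2) prop += proc_logdens(xl, xa, k, b[k], p);
      if (std::log(unif_rand()) < prop - cur) {
        acc_x[t]++;
      } else {
        xl[t] = old_l; xa[t] = old_a;
      }
    }

    // ---- 3. movement parameters ---------------------------------------
    auto proc_loglik_state = [&](int s, const Params &pp) {
      double ll = 0.0;
      for (int t = 2; t < T; ++t)
        if (b[t] == s) ll += proc_logdens(xl, xa, t, s, pp);
      return ll;
    };
    // gamma (per state), uniform(0,1) prior
    for (int s = 0; s < 2; ++s) {
      double gprop = p.gamma[s] + norm_rand() * step_g;
      if (gprop >= 0.0 && gprop <= 1.0) {
        Params pp = p; pp.gamma[s] = gprop;
        double lr = proc_loglik_state(s, pp) - proc_loglik_state(s, p);
        if (std::log(unif_rand()) < lr) { p = pp; acc_g++; }
      }
    }
    // theta (per state), uniform(-pi, pi] prior, wrapped
    for (int s = 0; s < 2; ++s) {
      double tprop = p.theta[s] + norm_rand() * step_th;
      tprop = std::atan2(std::sin(tprop), std::cos(tprop));
      Params pp = p; pp.theta[s] = tprop;
      double lr = proc_loglik_state(s, pp) - proc_loglik_state(s, p);
      if (std::log(unif_rand()) < lr) { p = pp; acc_th++; }
    }
    // Sigma: log-sds (half-Cauchy prior) and atanh-rho (uniform prior)
    {
      Params pp = p;
      pp.sig_lon = p.sig_lon * std::exp(norm_rand() * step_sig);
      pp.sig_lat = p.sig_lat * std::exp(norm_rand() * step_sig);
      double z = std::atanh(p.rho) + norm_rand() * step_rho;
      pp.rho = std::tanh(z);
      double cur = 0.0, prop = 0.0;
      for (int t = 2; t < T; ++t) {
        cur += proc_logdens(xl, xa, t, b[t], p);
        prop += proc_logdens(xl, xa, t, b[t], pp);
      }
      double sc = prior_sigma_scale;
      auto lhc = [&](double s) {  // half-Cauchy log density
        return -std::log(1.0 + (s / sc) * (s / sc));
      };
      // Jacobians: log-scale for sds, tanh for rho
      cur += lhc(p.sig_lon) + lhc(p.sig_lat)
           + std::log(p.sig_lon) + std::log(p.sig_lat)
           + std::log(1.0 - p.rho * p.rho);
      prop += lhc(pp.sig_lon) + lhc(pp.sig_lat)
            + std::log(pp.sig_lon) + std::log(pp.sig_lat)
            + std::log(1.0 - pp.rho * pp.rho);
      if (std::log(unif_rand()) < prop - cur) { p = pp; acc_sig++; }
    }
    // alphas: conjugate Beta(1,1) Gibbs from transition counts
    {
      int n11 = 0, n12 = 0, n21 = 0, n22 = 0;
      for (int t = 1; t < T; ++t) {
        if (b[t - 1] == 0) { if (b[t] == 0) n11++; else n12++; }
        else               { if (b[t] == 1) n22++; else n21++; }
      }
      p.alpha1 = R::rbeta(1.0 + n11, 1.0 + n12);
      p.alpha2 = R::rbeta(1.0 + n22, 1.0 + n21);
    }

    // ---- adaptation (burn-in only) ------------------------------------
    n_adapt_win++;
    if (it < n_burn && n_adapt_win == ADAPT_EVERY) {
      for (int t = 0; t < T; ++t) {
        double r = (double)acc_x[t] / ADAPT_EVERY;
        step_x[t] *= std::exp(0.6 * (r - 0.35));
        acc_x[t] = 0;
      }
      double rg = (double)acc_g / (2.0 * ADAPT_EVERY);
      step_g = std::min(0.5, step_g * std::exp(0.6 * (rg - 0.3)));
      double rt = (double)acc_th / (2.0 * ADAPT_EVERY);
      step_th = std::min(1.0, step_th * std::exp(0.6 * (rt - 0.3)));
      double rs = (double)acc_sig / ADAPT_EVERY;
      step_sig = std::min(1.0, step_sig * std::exp(0.6 * (rs - 0.3)));
      acc_g = acc_th = acc_sig = 0;
      n_adapt_win = 0;
    }
    if (n_adapt_win >= ADAPT_EVERY) { // post burn-in: just reset counters
      for (int t = 0; t < T; ++t) acc_x[t] = 0;
      acc_g = acc_th = acc_sig = 0;
      n_adapt_win = 0;
    }

    // ---- storage -------------------------------------------------------
    if (it >= n_burn && ((it - n_burn) % thin) == (thin - 1) && keep < n_keep) {
      out_par(keep, 0) = p.gamma[0]; out_par(keep, 1) = p.gamma[1];
      out_par(keep, 2) = p.theta[0]; out_par(keep, 3) = p.theta[1];
      out_par(keep, 4) = p.sig_lon; out_par(keep, 5) = p.sig_lat;
      out_par(keep, 6) = p.rho;
      out_par(keep, 7) = p.alpha1; out_par(keep, 8) = p.alpha2;
      for (int t = 0; t < T; ++t) {
        out_b(keep, t) = b[t] + 1;
        out_xl(keep, t) = xl[t];
        out_xa(keep, t) = xa[t];
      }
      keep++;
    }
  }

  return List::create(_["params"] = out_par, _["states"] = out_b,
                      _["pos_lon"] = out_xl, _["pos_lat"] = out_xa);
}
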