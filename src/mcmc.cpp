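// Metropolis-within-Gibbs core for the dynamic multistate occupancy model.
//
// Data layout: y and date are N x (2*J) matrices, column (t-1)*J + j for
// survey j in year t (0-based internally). NA_INTEGER / NA_REAL mark
// surveys that were not conducted. Parameter layout: mu[0..10] =
// {psi1, R1, psi2[1..3], R2[1..3], p[2], p[3], delta} on the logit scale,
// beta[0..4] with effective contribution gamma[k]*beta[k], V = total
// linear-predictor variance (Link-Barker prior).

#include <Rcpp.h>
using namespace Rcpp;

static const double NEGINF = -std::numeric_limits<double>::infinity();

static inline double log1pexp_(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}
// log(invlogit(x)) and log(1 - invlogit(x))
static inline double llog(double x) { return -log1pexp_(-x); }
static inline double l1m(double x) { return -log1pexp_(x); }

struct ModelData {
  int N, J;
  IntegerMatrix y;     // N x 2J
  NumericMatrix date;  // N x 2J
  NumericVector snag;  // N
};

// log observation probabilities of one cell under z = 1, 2, 3
static inline void cell_obs(int yv, double d, const double *mu,
                            const double *gb, double out[3]) {
  const double e2 = mu[8] + gb[0] * d;
  const double e3 = mu[9] + gb[1] * d;
  const double ed = mu[10] + gb[2] * d;
  out[0] = (yv == 1) ? 0.0 : NEGINF;
  if (yv == 1)      out[1] = l1m(e2);
  else if (yv == 2) out[1] = llog(e2);
  else              out[1] = NEGINF;
  if (yv == 1)      out[2] = l1m(e3);
  else if (yv == 2) out[2] = llog(e3) + l1m(ed);
  else              out[2] = llog(e3) + llog(ed);
}

// accumulate log Pr(obs in year t | z_t = s) for site i, s = 0..2
static inline void site_year_obs(const ModelData &dat, int i, int t,
                                 const double *mu, const double *gb,
                                 double out[3]) {
  out[0] = out[1] = out[2] = 0.0;
  double o[3];
  for (int j = 0; j < dat.J; ++j) {
    int yv = dat.y(i, t * dat.J + j);
    if (yv == NA_INTEGER) continue;
    double d = dat.date(i, t * dat.J + j);
    cell_obs(yv, d, mu, gb, o);
    out[0] += o[0]; out[1] += o[1]; out[2] += o[2];
  }
}

// log phi1 (3) and log phi2 (3x3, row-major) at one site's snag value
static inline void site_state(const double *mu, const double *gb,
                              double snag, double lphi1[3],
                              double lphi2[9]) {
  const double e1 = mu[0];
  const double er1 = mu[1] + gb[3] * snag;
  lphi1[0] = l1m(e1);
  lphi1[1] = llog(e1) + l1m(er1);
  lphi1[2] = llog(e1) + llog(er1);
  for (int m = 0; m < 3; ++m) {
    const double ep = mu[2 + m];
    const double er = (m == 2) ? (mu[7] + gb[4] * snag) : mu[5 + m];
    lphi2[3 * m + 0] = l1m(ep);
    lphi2[3 * m + 1] = llog(ep) + l1m(er);
    lphi2[3 * m + 2] = llog(ep) + llog(er);
  }
}

static inline void eff_coef(const double *beta, const int *gamma,
                            double *gb) {
  for (int k = 0; k < 5; ++k) gb[k] = gamma[k] ? beta[k] : 0.0;
}

static double complete_ll(const ModelData &dat, const double *mu,
                          const double *beta, const int *gamma,
                          const IntegerMatrix &z) {
  double gb[5]; eff_coef(beta, gamma, gb);
  double lphi1[3], lphi2[9], o1[3], o2[3], tot = 0.0;
  for (int i = 0; i < dat.N; ++i) {
    site_state(mu, gb, dat.snag[i], lphi1, lphi2);
    site_year_obs(dat, i, 0, mu, gb, o1);
    site_year_obs(dat, i, 1, mu, gb, o2);
    const int z1 = z(i, 0) - 1, z2 = z(i, 1) - 1;
    tot += lphi1[z1] + lphi2[3 * z1 + z2] + o1[z1] + o2[z2];
    if (tot == NEGINF) return NEGINF;
  }
  return tot;
}

static void marginal_ll_sites(const ModelData &dat, const double *mu,
                              const double *beta, const int *gamma,
                              double *out) {
  double gb[5]; eff_coef(beta, gamma, gb);
  double lphi1[3], lphi2[9], o1[3], o2[3], w[9];
  for (int i = 0; i < dat.N; ++i) {
    site_state(mu, gb, dat.snag[i], lphi1, lphi2);
    site_year_obs(dat, i, 0, mu, gb, o1);
    site_year_obs(dat, i, 1, mu, gb, o2);
    double m = NEGINF;
    for (int a = 0; a < 3; ++a)
      for (int b = 0; b < 3; ++b) {
        w[3 * a + b] = lphi1[a] + o1[a] + lphi2[3 * a + b] + o2[b];
        if (w[3 * a + b] > m) m = w[3 * a + b];
      }
    if (m == NEGINF) { out[i] = NEGINF; continue; }
    double s = 0.0;
    for (int u = 0; u < 9; ++u) s += std::exp(w[u] - m);
    out[i] = m + std::log(s);
  }
}

// Gibbs draw of (z1, z2) for every site from the exact joint full
// conditional; returns the complete-data loglik of the new configuration.
static double draw_z(const ModelData &dat, const double *mu,
                     const double *beta, const int *gamma,
                     IntegerMatrix &z) {
  double gb[5]; eff_coef(beta, gamma, gb);
  double lphi1[3], lphi2[9], o1[3], o2[3], w[9], p[9];
  double tot = 0.0;
  for (int i = 0; i < dat.N; ++i) {
    site_state(mu, gb, dat.snag[i], lphi1, lphi2);
    site_year_obs(dat, i, 0, mu, gb, o1);
    site_year_obs(dat, i, 1, mu, gb, o2);
    double m = NEGINF;
    for (int a = 0; a < 3; ++a)
      for (int b = 0; b < 3; ++b) {
        w[3 * a + b] = lphi1[a] + o1[a] + lphi2[3 * a + b] + o2[b];
        if (w[3 * a + b] > m) m = w[3 * a + b];
      }
    if (m == NEGINF)
      stop("site %d: no latent state configuration is consistent with y",
           i + 1);
    double s = 0.0;
    for (int u = 0; u < 9; ++u) { p[u] = std::exp(w[u] - m); s += p[u]; }
    double r = unif_rand() * s, acc = 0.0;
    int pick = 8;
    for (int u = 0; u < 9; ++u) { acc += p[u]; if (r <= acc) { pick = u; break; } }
    z(i, 0) = pick / 3 + 1;
    z(i, 1) = pick % 3 + 1;
    tot += w[pick];
  }
  return tot;
}

// [[Rcpp::export(name = ".complete_loglik_cpp")]]
double complete_loglik_cpp(IntegerMatrix y, NumericMatrix date,
                           NumericVector snag, int J, NumericVector mu,
                           NumericVector beta, IntegerVector gamma,
                           IntegerMatrix z) {
  ModelData dat{(int)y.nrow(), J, y, date, snag};
  return complete_ll(dat, mu.begin(), beta.begin(), gamma.begin(), z);
}

// [[Rcpp::export(name = ".marginal_loglik_cpp")]]
NumericVector marginal_loglik_cpp(IntegerMatrix y, NumericMatrix date,
                                  NumericVector snag, int J,
                                  NumericVector mu, NumericVector beta,
                                  IntegerVector gamma) {
  ModelData dat{(int)y.nrow(), J, y, date, snag};
  NumericVector out(dat.N);
  marginal_ll_sites(dat, mu.begin(), beta.begin(), gamma.begin(),
                    out.begin());
  return out;
}

// [[Rcpp::export(name = ".sample_z_cpp")]]
IntegerMatrix sample_z_cpp(IntegerMatrix y, NumericMatrix date,
                           NumericVector snag, int J, NumericVector mu,
                           NumericVector beta, IntegerVector gamma) {
  ModelData dat{(int)y.nrow(), J, y, date, snag};
  IntegerMatrix z(dat.N, 2);
  RNGScope scope;
  draw_z(dat, mu.begin(), beta.begin(), gamma.begin(), z);
  return z;
}

// logistic log-density: prior on a logit-scale intercept whose
// probability-scale prior is U(0,1)
static inline double lprior_mu(double x) { return x - 2.0 * log1pexp_(x); }

// Cached per-site likelihood tables. obs[(i)*6 + t*3 + s] = log Pr(obs in
// year t at site i | z_t = s+1); lphi1[i*3 + s], lphi2[i*9 + 3m + n].
// Each Metropolis proposal touches exactly one slice, so updates are O(N)
// instead of a full likelihood recomputation.
struct Cache {
  std::vector<double> obs, lphi1, lphi2;
  Cache(int N) : obs(6 * N), lphi1(3 * N), lphi2(9 * N) {}
};

static void cache_obs_col(const ModelData &dat, const double *mu,
                          const double *gb, int s, Cache &C) {
  double o[3];
  for (int i = 0; i < dat.N; ++i) {
    double a0 = 0.0, a1 = 0.0;
    for (int j = 0; j < dat.J; ++j) {
      int yv = dat.y(i, j);
      if (yv != NA_INTEGER) {
        cell_obs(yv, dat.date(i, j), mu, gb, o);
        a0 += o[s];
      }
      yv = dat.y(i, dat.J + j);
      if (yv != NA_INTEGER) {
        cell_obs(yv, dat.date(i, dat.J + j), mu, gb, o);
        a1 += o[s];
      }
    }
    C.obs[6 * i + s] = a0;
    C.obs[6 * i + 3 + s] = a1;
  }
}

static void cache_lphi1(const ModelData &dat, const double *mu,
                        const double *gb, Cache &C) {
  for (int i = 0; i < dat.N; ++i) {
    const double e1 = mu[0];
    const double er1 = mu[1] + gb[3] * dat.snag[i];
    C.lphi1[3 * i + 0] = l1m(e1);
    C.lphi1[3 * i + 1] = llog(e1) + l1m(er1);
    C.lphi1[3 * i + 2] = llog(e1) + llog(er1);
  }
}

static void cache_lphi2_row(const ModelData &dat, const double *mu,
                            const double *gb, int m, Cache &C) {
  const double ep = mu[2 + m];
  for (int i = 0; i < dat.N; ++i) {
    const double er = (m == 2) ? (mu[7] + gb[4] * dat.snag[i]) : mu[5 + m];
    C.lphi2[9 * i + 3 * m + 0] = l1m(ep);
    C.lphi2[9 * i + 3 * m + 1] = llog(ep) + l1m(er);
    C.lphi2[9 * i + 3 * m + 2] = llog(ep) + llog(er);
  }
}

static void cache_all(const ModelData &dat, const double *mu,
                      const double *gb, Cache &C) {
  for (int s = 0; s < 3; ++s) cache_obs_col(dat, mu, gb, s, C);
  cache_lphi1(dat, mu, gb, C);
  for (int m = 0; m < 3; ++m) cache_lphi2_row(dat, mu, gb, m, C);
}

static double cache_total_ll(const Cache &C, const IntegerMatrix &z,
                             int N) {
  double tot = 0.0;
  for (int i = 0; i < N; ++i) {
    const int z1 = z(i, 0) - 1, z2 = z(i, 1) - 1;
    tot += C.lphi1[3 * i + z1] + C.lphi2[9 * i + 3 * z1 + z2] +
           C.obs[6 * i + z1] + C.obs[6 * i + 3 + z2];
  }
  return tot;
}

// Gibbs draw of z from the cached tables; returns the new complete-data
// log-likelihood.
static double cache_draw_z(const Cache &C, IntegerMatrix &z, int N) {
  double w[9], p[9], tot = 0.0;
  for (int i = 0; i < N; ++i) {
    double m = NEGINF;
    for (int a = 0; a < 3; ++a)
      for (int b = 0; b < 3; ++b) {
        w[3 * a + b] = C.lphi1[3 * i + a] + C.obs[6 * i + a] +
                       C.lphi2[9 * i + 3 * a + b] + C.obs[6 * i + 3 + b];
        if (w[3 * a + b] > m) m = w[3 * a + b];
      }
    if (m == NEGINF)
      stop("site %d: no latent state configuration is consistent with y",
           i + 1);
    double s = 0.0;
    for (int u = 0; u < 9; ++u) { p[u] = std::exp(w[u] - m); s += p[u]; }
    double r = unif_rand() * s, acc = 0.0;
    int pick = 8;
    for (int u = 0; u < 9; ++u) { acc += p[u]; if (r <= acc) { pick = u; break; } }
    z(i, 0) = pick / 3 + 1;
    z(i, 1) = pick % 3 + 1;
    tot += w[pick];
  }
  return tot;
}

// which cache slice a parameter touches: 0..2 = obs column for z = s+1
// (column 0 depends only on y and never changes), 3 = lphi1,
// 4..6 = lphi2 row m. p[2] -> z=2 column; p[3] and delta -> z=3 column;
// snag coefficients -> lphi1 / lphi2 row 3.
static const int MU_SLICE[11] = {3, 3, 4, 5, 6, 4, 5, 6, 1, 2, 2};
static const int BETA_SLICE[5] = {1, 2, 2, 3, 6};

class SliceGuard {
  // saves one cache slice so a rejected proposal can restore it
public:
  Cache &C;
  int slice, N;
  std::vector<double> saved;
  SliceGuard(Cache &C_, int slice_, int N_) : C(C_), slice(slice_), N(N_) {
    if (slice < 3) {
      saved.resize(2 * N);
      for (int i = 0; i < N; ++i) {
        saved[2 * i] = C.obs[6 * i + slice];
        saved[2 * i + 1] = C.obs[6 * i + 3 + slice];
      }
    } else if (slice == 3) {
      saved.assign(C.lphi1.begin(), C.lphi1.end());
    } else {
      const int m = slice - 4;
      saved.resize(3 * N);
      for (int i = 0; i < N; ++i)
        for (int n = 0; n < 3; ++n)
          saved[3 * i + n] = C.lphi2[9 * i + 3 * m + n];
    }
  }
  void restore() {
    if (slice < 3) {
      for (int i = 0; i < N; ++i) {
        C.obs[6 * i + slice] = saved[2 * i];
        C.obs[6 * i + 3 + slice] = saved[2 * i + 1];
      }
    } else if (slice == 3) {
      std::copy(saved.begin(), saved.end(), C.lphi1.begin());
    } else {
      const int m = slice - 4;
      for (int i = 0; i < N; ++i)
        for (int n = 0; n < 3; ++n)
          C.lphi2[9 * i + 3 * m + n] = saved[3 * i + n];
    }
  }
};

static void refresh_slice(const ModelData &dat, const double *mu,
                          const double *gb, int slice, Cache &C) {
  if (slice < 3) cache_obs_col(dat, mu, gb, slice, C);
  else if (slice == 3) cache_lphi1(dat, mu, gb, C);
  else cache_lphi2_row(dat, mu, gb, slice - 4, C);
}

// [[Rcpp::export(name = ".run_chain_cpp")]]
List run_chain_cpp(IntegerMatrix y, NumericMatrix date, NumericVector snag,
                   int J, NumericVector mu0, NumericVector beta0,
                   IntegerVector gamma0, double V0, IntegerMatrix z0,
                   int prior_mode,  // 0 = fixed_sigma, 1 = link_barker
                   double sigma_fixed, double ig_shape, double ig_rate,
                   NumericVector pseudo_mean, NumericVector pseudo_var,
                   double incl_prior, int n_iter, int n_burn,
                   IntegerVector keep_iters, NumericVector prop_sd0,
                   bool adapt, bool gvs, bool sample_latent,
                   LogicalVector update_mu, LogicalVector update_beta) {
  ModelData dat{(int)y.nrow(), J, y, date, snag};
  const int N = dat.N;
  double mu[11], beta[5], prop_sd[16];
  int gamma[5];
  for (int j = 0; j < 11; ++j) mu[j] = mu0[j];
  for (int k = 0; k < 5; ++k) { beta[k] = beta0[k]; gamma[k] = gamma0[k]; }
  for (int b = 0; b < 16; ++b) prop_sd[b] = prop_sd0[b];
  double V = V0;
  IntegerMatrix z = clone(z0);

  const int n_keep = keep_iters.size();
  const int n_par = 11 + 5 + 5 + 2;  // mu, beta, gamma, V, sigma_k
  NumericMatrix pars(n_keep, n_par);
  NumericVector ll_keep(n_keep);
  IntegerVector model_keep(n_keep);
  IntegerMatrix z_keep(n_keep, 2 * N);
  NumericVector acc_count(16), prop_count(16);

  RNGScope scope;
  double gb[5];
  eff_coef(beta, gamma, gb);
  Cache C(N);
  cache_all(dat, mu, gb, C);
  double cur_ll = cache_total_ll(C, z, N);
  if (!R_finite(cur_ll))
    stop("non-finite complete-data log-likelihood at initialization");

  const double ltau = std::log(incl_prior) - std::log1p(-incl_prior);
  int kidx = 0;

  for (int iter = 1; iter <= n_iter; ++iter) {
    if (iter % 512 == 0) Rcpp::checkUserInterrupt();
    const bool adapting = adapt && iter <= n_burn;
    const double step = adapting ? std::pow((double)iter, -0.6) : 0.0;

    // -- latent states ----------------------------------------------------
    if (sample_latent) cur_ll = cache_draw_z(C, z, N);

    // -- intercepts (random walk on the logit scale, logistic prior) ------
    for (int j = 0; j < 11; ++j) {
      if (!update_mu[j]) continue;
      const double old = mu[j];
      SliceGuard g(C, MU_SLICE[j], N);
      mu[j] = old + norm_rand() * prop_sd[j];
      refresh_slice(dat, mu, gb, MU_SLICE[j], C);
      const double new_ll = cache_total_ll(C, z, N);
      const double lacc =
          (new_ll + lprior_mu(mu[j])) - (cur_ll + lprior_mu(old));
      const double a = (lacc >= 0) ? 1.0 : std::exp(lacc);
      prop_count[j] += 1.0;
      if (unif_rand() < a) { cur_ll = new_ll; acc_count[j] += 1.0; }
      else { mu[j] = old; g.restore(); }
      if (adapting)
        prop_sd[j] = std::exp(std::log(prop_sd[j]) + step * (a - 0.44));
    }

    // -- (gamma_k, beta_k) pairs ------------------------------------------
    for (int k = 0; k < 5; ++k) {
      if (gvs) {
        // exact full conditional of gamma_k given beta and z; under the
        // Link-Barker prior the slab variance V/(#active + 11) changes for
        // every included coefficient when gamma_k flips, so their normal
        // terms enter the odds as well
        int ninc_o = 0;
        for (int j = 0; j < 5; ++j) if (j != k && gamma[j]) ++ninc_o;
        const int gsave = gamma[k];
        SliceGuard g(C, BETA_SLICE[k], N);
        gamma[k] = 1 - gsave;
        eff_coef(beta, gamma, gb);
        refresh_slice(dat, mu, gb, BETA_SLICE[k], C);
        const double ll_flip = cache_total_ll(C, z, N);
        const double ll1 = gsave ? cur_ll : ll_flip;
        const double ll0 = gsave ? ll_flip : cur_ll;
        const double sig1 = (prior_mode == 1)
            ? V / (double)(ninc_o + 1 + 11) : sigma_fixed;
        const double sig0 = (prior_mode == 1)
            ? V / (double)(ninc_o + 11) : sigma_fixed;
        double lpr1 = R::dnorm(beta[k], 0.0, std::sqrt(sig1), 1);
        double lpr0 = R::dnorm(beta[k], pseudo_mean[k],
                               std::sqrt(pseudo_var[k]), 1);
        for (int j = 0; j < 5; ++j) {
          if (j == k || !gamma[j]) continue;
          lpr1 += R::dnorm(beta[j], 0.0, std::sqrt(sig1), 1);
          lpr0 += R::dnorm(beta[j], 0.0, std::sqrt(sig0), 1);
        }
        const double logit_q = (ll1 + lpr1) - (ll0 + lpr0) + ltau;
        const double q = 1.0 / (1.0 + std::exp(-logit_q));
        gamma[k] = (unif_rand() < q) ? 1 : 0;
        if (gamma[k] == gsave) { g.restore(); eff_coef(beta, gamma, gb); }
        cur_ll = gamma[k] ? ll1 : ll0;
      }
      if (gamma[k]) {
        if (!update_beta[k]) continue;
        int ninc = 0;
        for (int j = 0; j < 5; ++j) ninc += gamma[j];
        const double sig = (prior_mode == 1)
            ? V / (double)(ninc + 11) : sigma_fixed;
        const double sd = std::sqrt(sig);
        const double old = beta[k];
        SliceGuard g(C, BETA_SLICE[k], N);
        beta[k] = old + norm_rand() * prop_sd[11 + k];
        eff_coef(beta, gamma, gb);
        refresh_slice(dat, mu, gb, BETA_SLICE[k], C);
        const double new_ll = cache_total_ll(C, z, N);
        const double lacc = (new_ll + R::dnorm(beta[k], 0.0, sd, 1)) -
                            (cur_ll + R::dnorm(old, 0.0, sd, 1));
        const double a = (lacc >= 0) ? 1.0 : std::exp(lacc);
        prop_count[11 + k] += 1.0;
        if (unif_rand() < a) { cur_ll = new_ll; acc_count[11 + k] += 1.0; }
        else { beta[k] = old; eff_coef(beta, gamma, gb); g.restore(); }
        if (adapting)
          prop_sd[11 + k] =
              std::exp(std::log(prop_sd[11 + k]) + step * (a - 0.44));
      } else {
        // excluded: refresh from the pseudo-prior; gamma_k * beta_k = 0
        // so the likelihood and cache are untouched
        beta[k] = pseudo_mean[k] + std::sqrt(pseudo_var[k]) * norm_rand();
      }
    }

    // -- total variance V (conjugate inverse-gamma step) -------------------
    if (prior_mode == 1) {
      int ninc = 0; double ssq = 0.0;
      for (int k = 0; k < 5; ++k)
        if (gamma[k]) { ++ninc; ssq += beta[k] * beta[k]; }
      const double c = (double)(ninc + 11);
      const double shape = ig_shape + 0.5 * ninc;
      const double rate = ig_rate + 0.5 * c * ssq;
      const double W = R::rgamma(shape, 1.0 / rate);
      V = 1.0 / W;
    }

    // -- storage ------------------------------------------------------------
    if (kidx < n_keep && iter == keep_iters[kidx]) {
      // audit the incremental cache against a from-scratch evaluation
      const double audit = complete_ll(dat, mu, beta, gamma, z);
      if (!(std::fabs(audit - cur_ll) <= 1e-6 * (1.0 + std::fabs(audit))))
        stop("internal error: cached log-likelihood diverged from direct "
             "evaluation");
      cur_ll = audit;
      int col = 0;
      for (int j = 0; j < 11; ++j) pars(kidx, col++) = mu[j];
      for (int k = 0; k < 5; ++k) pars(kidx, col++) = beta[k];
      int M = 1;
      for (int k = 0; k < 5; ++k) {
        pars(kidx, col++) = gamma[k];
        if (gamma[k]) M += (1 << k);
      }
      pars(kidx, col++) = V;
      int ninc = 0;
      for (int k = 0; k < 5; ++k) ninc += gamma[k];
      pars(kidx, col++) = (prior_mode == 1)
          ? V / (double)(ninc + 11) : sigma_fixed;
      ll_keep[kidx] = cur_ll;
      model_keep[kidx] = M;
      for (int i = 0; i < N; ++i) {
        z_keep(kidx, i) = z(i, 0);
        z_keep(kidx, N + i) = z(i, 1);
      }
      ++kidx;
    }
  }

  NumericVector acc(16);
  for (int b = 0; b < 16; ++b)
    acc[b] = prop_count[b] > 0 ? acc_count[b] / prop_count[b] : NA_REAL;
  return List::create(_["pars"] = pars, _["loglik"] = ll_keep,
                      _["model"] = model_keep, _["z"] = z_keep,
                      _["accept"] = acc,
                      _["prop_sd"] = NumericVector(prop_sd, prop_sd + 16));
}
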