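#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Exact solution of the affine linear ODE dx/dt = A x + b via the augmented
// matrix exponential expm([[A, b], [0, 0]] * t) = [[Phi, psi], [0, 1]], so
// x(t) = Phi x0 + psi.  No inversion of A: safe for singular systems.
// ---------------------------------------------------------------------------
// Fixed-size matrix exponential: [6/6] Pade approximant with scaling and
// squaring (allocation-free fast paths for the 6x6 augmented system and the
// paired Frechet recurrences below).
typedef arma::mat::fixed<6, 6> mat66;

template <arma::uword N>
static void expm_fixed(const typename arma::mat::fixed<N, N>& M,
                       typename arma::mat::fixed<N, N>& E) {
  static const double c[7] = {1.0, 0.5, 5.0 / 44.0, 1.0 / 66.0,
                              1.0 / 792.0, 1.0 / 15840.0, 1.0 / 665280.0};
  double nrm = 0.0;
  for (arma::uword j = 0; j < N; ++j) {
    double cs = 0.0;
    for (arma::uword i = 0; i < N; ++i) cs += std::abs(M(i, j));
    nrm = std::max(nrm, cs);
  }
  int s = 0;
  if (nrm > 0.25) s = (int)std::ceil(std::log2(nrm / 0.25));
  const double sc = std::ldexp(1.0, -s);
  typename arma::mat::fixed<N, N> A = M * sc;
  typename arma::mat::fixed<N, N> A2 = A * A;
  typename arma::mat::fixed<N, N> A4 = A2 * A2;
  typename arma::mat::fixed<N, N> A6 = A4 * A2;
  typename arma::mat::fixed<N, N> Veven;
  Veven.eye();
  Veven = c[0] * Veven + c[2] * A2 + c[4] * A4 + c[6] * A6;
  typename arma::mat::fixed<N, N> Modd;
  Modd.eye();
  Modd = c[1] * Modd + c[3] * A2 + c[5] * A4;
  typename arma::mat::fixed<N, N> U = A * Modd;
  typename arma::mat::fixed<N, N> Nm = Veven + U;
  typename arma::mat::fixed<N, N> D = Veven - U;
  E = arma::solve(D, Nm);
  for (int k = 0; k < s; ++k) E = E * E;
}

// Frechet derivative of the matrix exponential: F = expm(X) and
// L = d expm(X)[G], computed with the same Pade scaling-squaring on the
// block-triangular pair (diag X, upper G) — products of such pairs need
// three 6x6 multiplications instead of one 12x12.
static void expm_frechet66(const mat66& X, const mat66& G, mat66& F,
                           mat66& L) {
  static const double c[7] = {1.0, 0.5, 5.0 / 44.0, 1.0 / 66.0,
                              1.0 / 792.0, 1.0 / 15840.0, 1.0 / 665280.0};
  double nrm = 0.0;
  for (int j = 0; j < 6; ++j) {
    double cs = 0.0;
    for (int i = 0; i < 6; ++i) cs += std::abs(X(i, j));
    nrm = std::max(nrm, cs);
  }
  int s = 0;
  if (nrm > 0.25) s = (int)std::ceil(std::log2(nrm / 0.25));
  const double sc = std::ldexp(1.0, -s);
  mat66 Xs = X * sc, Gs = G * sc;
  mat66 A2d = Xs * Xs, A2u = Xs * Gs + Gs * Xs;
  mat66 A4d = A2d * A2d, A4u = A2d * A2u + A2u * A2d;
  mat66 A6d = A4d * A2d, A6u = A4d * A2u + A4u * A2d;
  mat66 I;
  I.eye();
  mat66 Ed = c[0] * I + c[2] * A2d + c[4] * A4d + c[6] * A6d;
  mat66 Eu = c[2] * A2u + c[4] * A4u + c[6] * A6u;
  mat66 Md = c[1] * I + c[3] * A2d + c[5] * A4d;
  mat66 Mu = c[3] * A2u + c[5] * A4u;
  mat66 Ud = Xs * Md, Uu = Xs * Mu + Gs * Md;
  mat66 Nd = Ed + Ud, Nu = Eu + Uu;
  mat66 Dd = Ed - Ud, Du = Eu - Uu;
  F = arma::solve(Dd, Nd);
  L = arma::solve(Dd, Nu - Du * F);
  for (int k = 0; k < s; ++k) {
    L = F * L + L * F;
    F = F * F;
  }
}

static void phi_psi(const arma::mat& A, const arma::vec& b, double t,
                    arma::mat& Phi, arma::vec& psi) {
  const arma::uword d = A.n_rows;
  if (d == 5) {
    mat66 M, E;
    M.zeros();
    M.submat(0, 0, 4, 4) = A * t;
    M.submat(0, 5, 4, 5) = b * t;
    expm_fixed<6>(M, E);
    Phi = E.submat(0, 0, 4, 4);
    psi = E.submat(0, 5, 4, 5);
    return;
  }
  arma::mat M(d + 1, d + 1, arma::fill::zeros);
  M.submat(0, 0, d - 1, d - 1) = A * t;
  M.submat(0, d, d - 1, d)     = b * t;
  arma::mat E = arma::expmat(M);
  Phi = E.submat(0, 0, d - 1, d - 1);
  psi = E.submat(0, d, d - 1, d);
}

// cache-filling variant writing into cube/matrix slices
static void phi_psi_slice(const arma::mat& A, const arma::vec& b, double t,
                          arma::cube& Phic, arma::mat& psim, int u) {
  mat66 M, E;
  M.zeros();
  M.submat(0, 0, 4, 4) = A * t;
  M.submat(0, 5, 4, 5) = b * t;
  expm_fixed<6>(M, E);
  Phic.slice(u) = E.submat(0, 0, 4, 4);
  psim.col(u) = E.submat(0, 5, 4, 5);
}

// [[Rcpp::export]]
arma::mat cpp_solve_trajectory(const arma::mat& A, const arma::vec& b,
                               const arma::vec& x0, const arma::vec& times) {
  const arma::uword d = A.n_rows;
  arma::mat out(times.n_elem, d);
  arma::mat Phi;
  arma::vec psi;
  for (arma::uword i = 0; i < times.n_elem; ++i) {
    phi_psi(A, b, times[i], Phi, psi);
    out.row(i) = (Phi * x0 + psi).t();
  }
  return out;
}

// ---------------------------------------------------------------------------
// Likelihood pieces shared by the sampler and the standalone evaluator.
// Channel observations: sigmoid link + Gaussian noise, optionally
// right-censored at an upper detection limit.  Diagnoses: ordered logit.
// ---------------------------------------------------------------------------
static inline double log1pexp_c(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}
static inline double logistic_c(double z) {
  return 1.0 / (1.0 + std::exp(-z));
}
static inline double log_logistic_c(double z) { return -log1pexp_c(-z); }

static inline double sigmoid_link_c(double x, double lo, double up,
                                    double slope, double mid) {
  return lo + (up - lo) * logistic_c(slope * (x - mid));
}

static const double LOG_SQRT_2PI = 0.918938533204672742;

// se: extra per-observation noise sd (two-stage trait scoring), so the
// effective sd is sqrt(sigma^2 + se^2)
static inline double obs_term(double value, int censored, double mean,
                              double sigma, double se, double cens_upper) {
  const double sd = se > 0.0 ? std::sqrt(sigma * sigma + se * se) : sigma;
  if (censored) {
    // P(X > upper limit) under N(mean, sd)
    return R::pnorm(cens_upper, mean, sd, 0, 1);
  }
  const double z = (value - mean) / sd;
  return -LOG_SQRT_2PI - std::log(sd) - 0.5 * z * z;
}

static inline double ologit_term(int lab, double eta, double c1, double c2) {
  // labels 0=CN, 1=MCI, 2=AD
  if (lab == 0) return log_logistic_c(c1 - eta);
  if (lab == 2) return log_logistic_c(eta - c2);
  double p = logistic_c(c2 - eta) - logistic_c(c1 - eta);
  return std::log(std::max(p, 1e-300));
}

// Free-entry mask of the velocity matrices: the CSF rows {tau, abeta} do not
// receive input from the cognitive columns {lang, mem, praxis}.
static arma::umat velocity_mask() {
  arma::umat m(5, 5, arma::fill::ones);
  for (int i = 0; i < 2; ++i)
    for (int j = 2; j < 5; ++j) m(i, j) = 0;
  return m;
}

static arma::mat fill_masked(const arma::vec& theta, const arma::umat& mask) {
  arma::mat M(5, 5, arma::fill::zeros);
  arma::uword k = 0;
  for (arma::uword j = 0; j < 5; ++j)
    for (arma::uword i = 0; i < 5; ++i)
      if (mask(i, j)) M(i, j) = theta[k++];
  return M;
}

static arma::vec extract_masked(const arma::mat& M, const arma::umat& mask) {
  arma::vec th(arma::accu(mask));
  arma::uword k = 0;
  for (arma::uword j = 0; j < 5; ++j)
    for (arma::uword i = 0; i < 5; ++i)
      if (mask(i, j)) th[k++] = M(i, j);
  return th;
}

// ---------------------------------------------------------------------------
// Flattened cohort container (built in R by .adpm_pack_data)
// ---------------------------------------------------------------------------
struct CohortData {
  int nsub;
  arma::vec age, apoe;
  arma::vec ut;            // unique times, concatenated over subjects
  arma::ivec ut_start;     // nsub+1 offsets into ut
  arma::ivec ob_sub, ob_tidx, ob_chan, ob_cens, ob_start;
  arma::vec ob_val, ob_se;
  arma::ivec dg_sub, dg_tidx, dg_lab, dg_start;
  arma::vec link_lower, link_upper, link_slope, link_mid, cens_upper, sigma0;
  double w;                // likelihood weight (0 = prior-predictive mode)

  explicit CohortData(const List& d) {
    nsub     = as<int>(d["nsub"]);
    age      = as<arma::vec>(d["age"]);
    apoe     = as<arma::vec>(d["apoe"]);
    ut       = as<arma::vec>(d["ut"]);
    ut_start = as<arma::ivec>(d["ut_start"]);
    ob_sub   = as<arma::ivec>(d["ob_sub"]);
    ob_tidx  = as<arma::ivec>(d["ob_tidx"]);
    ob_chan  = as<arma::ivec>(d["ob_chan"]);
    ob_cens  = as<arma::ivec>(d["ob_cens"]);
    ob_start = as<arma::ivec>(d["ob_start"]);
    ob_val   = as<arma::vec>(d["ob_val"]);
    ob_se    = as<arma::vec>(d["ob_se"]);
    dg_sub   = as<arma::ivec>(d["dg_sub"]);
    dg_tidx  = as<arma::ivec>(d["dg_tidx"]);
    dg_lab   = as<arma::ivec>(d["dg_lab"]);
    dg_start = as<arma::ivec>(d["dg_start"]);
    link_lower = as<arma::vec>(d["link_lower"]);
    link_upper = as<arma::vec>(d["link_upper"]);
    link_slope = as<arma::vec>(d["link_slope"]);
    link_mid   = as<arma::vec>(d["link_mid"]);
    cens_upper = as<arma::vec>(d["cens_upper"]);
    w        = as<double>(d["w"]);
  }
};

struct Params {
  arma::mat V, Wage, Wapoe;
  arma::vec v0, sigma, mu0, tau0, beta_x, beta_y;
  arma::vec slope, mid;          // link shape (may be fixed)
  double c1, c2;
  arma::mat x0;                  // nsub x 5

  explicit Params(const List& p) {
    V      = as<arma::mat>(p["V"]);
    Wage   = as<arma::mat>(p["W_age"]);
    Wapoe  = as<arma::mat>(p["W_apoe"]);
    v0     = as<arma::vec>(p["v0"]);
    sigma  = as<arma::vec>(p["sigma"]);
    mu0    = as<arma::vec>(p["mu0"]);
    tau0   = as<arma::vec>(p["tau0"]);
    beta_x = as<arma::vec>(p["beta_x"]);
    beta_y = as<arma::vec>(p["beta_y"]);
    slope  = as<arma::vec>(p["link_slope"]);
    mid    = as<arma::vec>(p["link_mid"]);
    c1     = as<double>(p["c1"]);
    c2     = as<double>(p["c2"]);
    x0     = as<arma::mat>(p["x0"]);
  }
};

// ---------------------------------------------------------------------------
// Standalone joint log-likelihood + x0 prior (used by build_joint_loglik's
// cross-check and by tests); priors on population parameters not included.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
double cpp_cohort_loglik(const List& data, const List& params) {
  CohortData dat(data);
  Params th(params);
  double ll = 0.0;
  arma::mat Phi;
  arma::vec psi;
  for (int s = 0; s < dat.nsub; ++s) {
    arma::mat A = th.V + dat.age[s] * th.Wage + dat.apoe[s] * th.Wapoe;
    int u0 = dat.ut_start[s], u1 = dat.ut_start[s + 1];
    arma::mat states(u1 - u0, 5);
    arma::vec x0s = th.x0.row(s).t();
    for (int u = u0; u < u1; ++u) {
      phi_psi(A, th.v0, dat.ut[u], Phi, psi);
      states.row(u - u0) = (Phi * x0s + psi).t();
    }
    for (int o = dat.ob_start[s]; o < dat.ob_start[s + 1]; ++o) {
      int k = dat.ob_chan[o];
      double mean = sigmoid_link_c(states(dat.ob_tidx[o], k),
                                   dat.link_lower[k], dat.link_upper[k],
                                   th.slope[k], th.mid[k]);
      ll += dat.w * obs_term(dat.ob_val[o], dat.ob_cens[o], mean,
                             th.sigma[k], dat.ob_se[o],
                             dat.cens_upper[k]);
    }
    for (int g = dat.dg_start[s]; g < dat.dg_start[s + 1]; ++g) {
      arma::vec x = states.row(dat.dg_tidx[g]).t();
      double eta = arma::dot(th.beta_x, x) +
                   th.beta_y[0] * dat.age[s] + th.beta_y[1] * dat.apoe[s];
      ll += dat.w * ologit_term(dat.dg_lab[g], eta, th.c1, th.c2);
    }
    for (int j = 0; j < 5; ++j)
      ll += R::dnorm(x0s[j], th.mu0[j], th.tau0[j], 1);
  }
  return ll;
}

// ---------------------------------------------------------------------------
// Blocked adaptive Metropolis-within-Gibbs sampler
// ---------------------------------------------------------------------------
struct AdaptiveBlock {
  arma::vec cur;
  double log_step;
  arma::mat chol_cov;      // proposal shape (identity until adapted)
  arma::vec run_mean;
  arma::mat run_cov;
  int n_adapt;
  double target;

  void init(const arma::vec& start, double step, double targ) {
    cur = start;
    log_step = std::log(step);
    chol_cov = arma::eye(start.n_elem, start.n_elem);
    run_mean = start;
    run_cov = arma::zeros(start.n_elem, start.n_elem);
    n_adapt = 0;
    target = targ;
  }
  arma::vec propose() {
    arma::vec z(cur.n_elem);
    for (arma::uword i = 0; i < z.n_elem; ++i) z[i] = R::norm_rand();
    return cur + std::exp(log_step) * (chol_cov * z);
  }
  void adapt(double acc_prob) {
    ++n_adapt;
    double gamma = 1.0 / std::sqrt((double)n_adapt + 10.0);
    log_step += gamma * (acc_prob - target);
    log_step = std::min(std::max(log_step, -12.0), 4.0);
    // running covariance for the proposal shape
    arma::vec dx = cur - run_mean;
    run_mean += gamma * dx;
    run_cov = (1.0 - gamma) * run_cov + gamma * (dx * dx.t());
    if (n_adapt > 100 && n_adapt % 25 == 0 && cur.n_elem > 1) {
      arma::mat S = run_cov + 1e-8 * arma::eye(cur.n_elem, cur.n_elem);
      arma::mat L;
      if (arma::chol(L, S, "lower")) chol_cov = L;
    }
  }
};

// [[Rcpp::export]]
List cpp_adpm_mcmc(const List& data, const List& init, const List& priors,
                   const List& control) {
  CohortData dat(data);
  Params th(init);
  const arma::umat mask = velocity_mask();
  const int nfree = arma::accu(mask);
  const int nsub = dat.nsub;

  const int n_warmup = as<int>(control["warmup"]);
  const int n_iter   = as<int>(control["iter"]);
  const bool est_w   = as<bool>(control["estimate_covariate_effects"]);
  const bool est_lnk = as<bool>(control["estimate_links"]);
  const int  refresh = as<int>(control["refresh"]);
  const int  vel_updates = as<int>(control["vel_updates"]);
  const int  hmc_L = as<int>(control["hmc_steps"]);
  const bool x0_refresh = as<bool>(control["x0_refresh"]);

  const double sd_vel   = as<double>(priors["velocity_sd"]);
  const double sd_mu0   = as<double>(priors["mu0_sd"]);
  const double sc_tau0  = as<double>(priors["tau0_scale"]);
  const arma::vec sc_sig = as<arma::vec>(priors["sigma_scale"]);
  const double sd_clin  = as<double>(priors["clinical_sd"]);
  const double sd_gap   = as<double>(priors["log_gap_sd"]);
  const double sd_lslope = as<double>(priors["log_slope_sd"]);
  const double sd_mid   = as<double>(priors["midpoint_sd"]);
  const arma::vec mid_anchor = as<arma::vec>(priors["midpoint_anchor"]);

  // ---- per-subject caches -------------------------------------------------
  const int n_ut = dat.ut.n_elem;
  arma::cube Phis(5, 5, n_ut);
  arma::mat psis(5, n_ut);
  arma::mat states(n_ut, 5);
  arma::vec ob_mean(dat.ob_val.n_elem);
  arma::vec ll_ob(nsub, arma::fill::zeros), ll_dg(nsub, arma::fill::zeros);

  arma::mat A_s;
  arma::mat Phi;
  arma::vec psi;

  auto rebuild_subject = [&](int s) {
    A_s = th.V + dat.age[s] * th.Wage + dat.apoe[s] * th.Wapoe;
    for (int u = dat.ut_start[s]; u < dat.ut_start[s + 1]; ++u)
      phi_psi_slice(A_s, th.v0, dat.ut[u], Phis, psis, u);
  };
  auto states_subject = [&](int s, const arma::vec& x0s) {
    for (int u = dat.ut_start[s]; u < dat.ut_start[s + 1]; ++u)
      states.row(u) = (Phis.slice(u) * x0s + psis.col(u)).t();
  };
  auto obmeans_subject = [&](int s) {
    for (int o = dat.ob_start[s]; o < dat.ob_start[s + 1]; ++o) {
      int k = dat.ob_chan[o];
      ob_mean[o] = sigmoid_link_c(states(dat.ut_start[s] + dat.ob_tidx[o], k),
                                  dat.link_lower[k], dat.link_upper[k],
                                  th.slope[k], th.mid[k]);
    }
  };
  auto obs_ll_subject = [&](int s) {
    double ll = 0.0;
    for (int o = dat.ob_start[s]; o < dat.ob_start[s + 1]; ++o) {
      int k = dat.ob_chan[o];
      ll += obs_term(dat.ob_val[o], dat.ob_cens[o], ob_mean[o], th.sigma[k],
                     dat.ob_se[o], dat.cens_upper[k]);
    }
    return dat.w * ll;
  };
  auto diag_ll_subject = [&](int s) {
    double ll = 0.0;
    for (int g = dat.dg_start[s]; g < dat.dg_start[s + 1]; ++g) {
      arma::vec x = states.row(dat.ut_start[s] + dat.dg_tidx[g]).t();
      double eta = arma::dot(th.beta_x, x) +
                   th.beta_y[0] * dat.age[s] + th.beta_y[1] * dat.apoe[s];
      ll += ologit_term(dat.dg_lab[g], eta, th.c1, th.c2);
    }
    return dat.w * ll;
  };
  auto x0_prior_subject = [&](int s) {
    double lp = 0.0;
    for (int j = 0; j < 5; ++j)
      lp += R::dnorm(th.x0(s, j), th.mu0[j], th.tau0[j], 1);
    return lp;
  };
  auto refresh_all = [&]() {
    for (int s = 0; s < nsub; ++s) {
      rebuild_subject(s);
      states_subject(s, th.x0.row(s).t());
      obmeans_subject(s);
      ll_ob[s] = obs_ll_subject(s);
      ll_dg[s] = diag_ll_subject(s);
    }
  };
  refresh_all();

  // ---- priors -------------------------------------------------------------
  auto lp_vel = [&](const arma::vec& v) {
    return -arma::dot(v, v) / (2.0 * sd_vel * sd_vel);
  };
  auto lp_clin = [&]() {
    double lp = -th.c1 * th.c1 / (2.0 * sd_clin * sd_clin);
    double lg = std::log(th.c2 - th.c1);
    lp += -lg * lg / (2.0 * sd_gap * sd_gap);
    lp += -arma::dot(th.beta_x, th.beta_x) / (2.0 * sd_clin * sd_clin);
    lp += -arma::dot(th.beta_y, th.beta_y) / (2.0 * sd_clin * sd_clin);
    return lp;
  };
  auto lp_sigma = [&]() {        // half-Normal on sigma, sampled on log scale
    double lp = 0.0;
    for (int k = 0; k < 5; ++k)
      lp += -th.sigma[k] * th.sigma[k] / (2.0 * sc_sig[k] * sc_sig[k]) +
            std::log(th.sigma[k]);
    return lp;
  };
  auto lp_links = [&]() {
    double lp = 0.0;
    for (int k = 0; k < 5; ++k) {
      double ls = std::log(th.slope[k]);
      lp += -ls * ls / (2.0 * sd_lslope * sd_lslope);
      double dm = th.mid[k] - mid_anchor[k];
      lp += -dm * dm / (2.0 * sd_mid * sd_mid);
    }
    return lp;
  };

  // ---- blocks -------------------------------------------------------------
  AdaptiveBlock bl_sig, bl_clin, bl_link;
  std::vector<AdaptiveBlock> bl_x0(nsub);
  bl_sig.init(arma::log(th.sigma), 0.05, 0.234);
  arma::vec clin0(9);
  clin0[0] = th.c1;
  clin0[1] = std::log(th.c2 - th.c1);
  clin0.subvec(2, 6) = th.beta_x;
  clin0.subvec(7, 8) = th.beta_y;
  bl_clin.init(clin0, 0.05, 0.234);
  arma::vec link0 = arma::join_cols(arma::log(th.slope), th.mid);
  bl_link.init(link0, 0.02, 0.234);
  for (int s = 0; s < nsub; ++s) {
    arma::vec x0s = th.x0.row(s).t();
    bl_x0[s].init(x0s, 0.3, 0.234);
  }
  arma::vec log_tau0 = arma::log(th.tau0);
  arma::vec step_tau0(5, arma::fill::value(0.2));
  arma::ivec acc_tau0(5, arma::fill::zeros);

  // stored draws
  const int npop = nfree * 3 + 5 /*v0*/ + 5 /*sigma*/ + 10 /*mu0,tau0*/ +
                   9 /*clinical*/ + 10 /*links*/;
  arma::mat pop_draws(n_iter, npop);
  arma::cube x0_draws(n_iter, nsub, 5);
  int acc_vel = 0, acc_sig = 0, acc_clin = 0, acc_link = 0;
  long acc_x0 = 0;

  arma::cube Phis_bak;
  arma::mat psis_bak;
  arma::mat states_bak;
  arma::vec obmean_bak, ll_ob_bak, ll_dg_bak;

  // ---- velocity-field group + subject states: Hamiltonian Monte Carlo ---
  // Position vector: free entries of V, then v0, then (optionally) free
  // entries of W_age and W_apoe, then all subject initial states.  The
  // trajectory-likelihood gradients are exact: for f = g' expm(M t) z the
  // derivative w.r.t. M is the Frechet derivative in the rank-one direction
  // g z' (paired 6x6 Pade recurrences), and the derivative w.r.t. the
  // initial state reuses the cached Phi operators.
  const int vdim = 24 + (est_w ? 2 * nfree : 0);
  const int qdim = vdim + 5 * nsub;

  auto pack_q = [&]() {
    arma::vec v(qdim);
    v.subvec(0, nfree - 1) = extract_masked(th.V, mask);
    v.subvec(nfree, nfree + 4) = th.v0;
    if (est_w) {
      v.subvec(nfree + 5, 2 * nfree + 4) = extract_masked(th.Wage, mask);
      v.subvec(2 * nfree + 5, 3 * nfree + 4) = extract_masked(th.Wapoe,
                                                              mask);
    }
    for (int s = 0; s < nsub; ++s)
      v.subvec(vdim + 5 * s, vdim + 5 * s + 4) = th.x0.row(s).t();
    return v;
  };
  auto unpack_q = [&](const arma::vec& v) {
    th.V = fill_masked(v.subvec(0, nfree - 1), mask);
    th.v0 = v.subvec(nfree, nfree + 4);
    if (est_w) {
      th.Wage = fill_masked(v.subvec(nfree + 5, 2 * nfree + 4), mask);
      th.Wapoe = fill_masked(v.subvec(2 * nfree + 5, 3 * nfree + 4), mask);
    }
    for (int s = 0; s < nsub; ++s)
      th.x0.row(s) = v.subvec(vdim + 5 * s, vdim + 5 * s + 4).t();
  };
  auto q_logpost = [&](const arma::vec& v) {
    unpack_q(v);
    double lp = lp_vel(v.subvec(0, vdim - 1));
    for (int s = 0; s < nsub; ++s) {
      rebuild_subject(s);
      states_subject(s, th.x0.row(s).t());
      obmeans_subject(s);
      ll_ob[s] = obs_ll_subject(s);
      ll_dg[s] = diag_ll_subject(s);
      lp += x0_prior_subject(s);
    }
    return arma::accu(ll_ob) + arma::accu(ll_dg) + lp;
  };
  // gradient at the current state (caches must match th)
  auto q_grad = [&](const arma::vec& v) {
    arma::vec grad(qdim, arma::fill::zeros);
    grad.subvec(0, vdim - 1) = -v.subvec(0, vdim - 1) / (sd_vel * sd_vel);
    for (int s = 0; s < nsub; ++s) {
      const int u0 = dat.ut_start[s], u1 = dat.ut_start[s + 1];
      const int nu = u1 - u0;
      arma::mat G(5, nu, arma::fill::zeros);
      for (int o = dat.ob_start[s]; o < dat.ob_start[s + 1]; ++o) {
        const int k = dat.ob_chan[o];
        const int u = dat.ob_tidx[o];
        // logistic value recovered from the cached mean: no exp() call
        const double pz = (ob_mean[o] - dat.link_lower[k]) /
                          (dat.link_upper[k] - dat.link_lower[k]);
        const double dmean_dx = (dat.link_upper[k] - dat.link_lower[k]) *
                                th.slope[k] * pz * (1.0 - pz);
        const double se_o = dat.ob_se[o];
        const double sd_eff = se_o > 0.0
            ? std::sqrt(th.sigma[k] * th.sigma[k] + se_o * se_o)
            : th.sigma[k];
        double dll_dmean;
        if (dat.ob_cens[o]) {
          const double lpdf = R::dnorm(dat.cens_upper[k], ob_mean[o],
                                       sd_eff, 1);
          const double lsf = R::pnorm(dat.cens_upper[k], ob_mean[o],
                                      sd_eff, 0, 1);
          dll_dmean = std::exp(lpdf - lsf);
        } else {
          dll_dmean = (dat.ob_val[o] - ob_mean[o]) / (sd_eff * sd_eff);
        }
        G(k, u) += dat.w * dll_dmean * dmean_dx;
      }
      for (int g = dat.dg_start[s]; g < dat.dg_start[s + 1]; ++g) {
        const int u = dat.dg_tidx[g];
        arma::vec x = states.row(u0 + u).t();
        const double eta = arma::dot(th.beta_x, x) +
                           th.beta_y[0] * dat.age[s] +
                           th.beta_y[1] * dat.apoe[s];
        double dll_deta;
        const int lab = dat.dg_lab[g];
        if (lab == 0) {
          dll_deta = -logistic_c(eta - th.c1);
        } else if (lab == 2) {
          dll_deta = logistic_c(th.c2 - eta);
        } else {
          const double s1 = logistic_c(th.c1 - eta);
          const double s2 = logistic_c(th.c2 - eta);
          const double p = std::max(s2 - s1, 1e-300);
          dll_deta = (-s2 * (1.0 - s2) + s1 * (1.0 - s1)) / p;
        }
        G.col(u) += dat.w * dll_deta * th.beta_x;
      }
      arma::mat A6 = th.V + dat.age[s] * th.Wage + dat.apoe[s] * th.Wapoe;
      mat66 M6;
      M6.zeros();
      M6.submat(0, 0, 4, 4) = A6;
      M6.submat(0, 5, 4, 5) = th.v0;
      arma::vec::fixed<6> z;
      z.subvec(0, 4) = th.x0.row(s).t();
      z[5] = 1.0;
      arma::mat dM(6, 6, arma::fill::zeros);
      mat66 Xt, Gd, F, L;
      for (int u = 0; u < nu; ++u) {
        const double t = dat.ut[u0 + u];
        const double gn = arma::accu(arma::abs(G.col(u)));
        if (t == 0.0 || gn == 0.0) continue;
        arma::vec::fixed<6> g6;
        g6.zeros();
        // the Frechet block is linear in the direction: normalise so the
        // scaling-squaring count is set by the system norm alone
        g6.subvec(0, 4) = G.col(u) / gn;
        Xt = M6.t() * t;
        Gd = g6 * z.t();
        expm_frechet66(Xt, Gd, F, L);
        dM += (t * gn) * L;
      }
      arma::vec dAfree = extract_masked(dM.submat(0, 0, 4, 4), mask);
      grad.subvec(0, nfree - 1) += dAfree;
      grad.subvec(nfree, nfree + 4) += dM.submat(0, 5, 4, 5);
      if (est_w) {
        grad.subvec(nfree + 5, 2 * nfree + 4) += dat.age[s] * dAfree;
        grad.subvec(2 * nfree + 5, 3 * nfree + 4) += dat.apoe[s] * dAfree;
      }
      // initial-state gradient: sum of Phi' g over times, plus x0 prior
      arma::vec gx0(5, arma::fill::zeros);
      for (int u = 0; u < nu; ++u)
        gx0 += Phis.slice(u0 + u).t() * G.col(u);
      for (int j = 0; j < 5; ++j)
        gx0[j] -= (th.x0(s, j) - th.mu0[j]) / (th.tau0[j] * th.tau0[j]);
      grad.subvec(vdim + 5 * s, vdim + 5 * s + 4) = gx0;
    }
    return grad;
  };

  double v_logstep = std::log(0.01);
  arma::vec v_massinv(qdim, arma::fill::value(2.5e-3));
  v_massinv.subvec(vdim, qdim - 1).fill(2e-2);
  arma::vec v_runmean = pack_q();
  arma::vec v_runvar = v_massinv;
  int hmc_n = 0;

  auto hmc_update = [&](bool warm) {
    Phis_bak = Phis;
    psis_bak = psis;
    states_bak = states;
    obmean_bak = ob_mean;
    ll_ob_bak = ll_ob;
    ll_dg_bak = ll_dg;
    const arma::mat V_bak = th.V, Wage_bak = th.Wage, Wapoe_bak = th.Wapoe;
    const arma::mat x0_bak = th.x0;
    const arma::vec v0_bak = th.v0;
    const arma::vec q0 = pack_q();
    double lp0 = arma::accu(ll_ob) + arma::accu(ll_dg) +
                 lp_vel(q0.subvec(0, vdim - 1));
    for (int s = 0; s < nsub; ++s) lp0 += x0_prior_subject(s);

    arma::vec p(qdim);
    for (int i = 0; i < qdim; ++i)
      p[i] = R::norm_rand() / std::sqrt(v_massinv[i]);
    const double H0 = -lp0 + 0.5 * arma::dot(p % p, v_massinv);
    const double eps = std::exp(v_logstep) *
                       (0.9 + 0.2 * R::unif_rand());
    arma::vec q = q0;
    arma::vec gr = q_grad(q);
    double lp1 = lp0;
    bool bad = false;
    p += 0.5 * eps * gr;
    for (int l = 0; l < hmc_L; ++l) {
      q += eps * (v_massinv % p);
      lp1 = q_logpost(q);
      if (!std::isfinite(lp1)) { bad = true; break; }
      gr = q_grad(q);
      p += (l == hmc_L - 1 ? 0.5 : 1.0) * eps * gr;
    }
    double a = bad ? -1e300
                   : (H0 - (-lp1 + 0.5 * arma::dot(p % p, v_massinv)));
    if (!bad && std::log(R::unif_rand()) < a) {
      ++acc_vel;   // caches already reflect q
    } else {
      th.V = V_bak; th.Wage = Wage_bak; th.Wapoe = Wapoe_bak;
      th.v0 = v0_bak;
      th.x0 = x0_bak;
      Phis = Phis_bak; psis = psis_bak; states = states_bak;
      ob_mean = obmean_bak; ll_ob = ll_ob_bak; ll_dg = ll_dg_bak;
    }
    if (warm) {
      ++hmc_n;
      const double accp = bad ? 0.0 : std::min(1.0, std::exp(a));
      const double gamma = 1.0 / std::sqrt((double)hmc_n + 10.0);
      v_logstep += gamma * (accp - 0.70);
      v_logstep = std::min(std::max(v_logstep, -12.0), 2.0);
      const arma::vec cur = pack_q();
      const arma::vec dx = cur - v_runmean;
      v_runmean += gamma * dx;
      v_runvar = (1.0 - gamma) * v_runvar + gamma * (dx % dx);
      if (hmc_n > 100 && hmc_n % 25 == 0)
        v_massinv = arma::clamp(v_runvar, 1e-10, 1e10);
    }
  };

  const int total = n_warmup + n_iter;
  for (int it = 0; it < total; ++it) {
    const bool warm = it < n_warmup;

    // 1. optional per-subject initial-state refresh (no matrix
    //    exponentials: states are affine in x0 with cached Phi/psi); the
    //    HMC block below also moves x0, so this is an extra mixing aid
    for (int s = 0; x0_refresh && s < nsub; ++s) {
      arma::vec prop = bl_x0[s].propose();
      double lp_old = x0_prior_subject(s) + ll_ob[s] + ll_dg[s];
      arma::rowvec x0_bak = th.x0.row(s);
      double llo_bak = ll_ob[s], lld_bak = ll_dg[s];
      int u0 = dat.ut_start[s], u1 = dat.ut_start[s + 1];
      arma::mat st_bak = states.rows(u0, u1 - 1);
      arma::vec om_bak = ob_mean.subvec(dat.ob_start[s],
                                        std::max(dat.ob_start[s],
                                                 dat.ob_start[s + 1] - 1));
      th.x0.row(s) = prop.t();
      states_subject(s, prop);
      obmeans_subject(s);
      ll_ob[s] = obs_ll_subject(s);
      ll_dg[s] = diag_ll_subject(s);
      double lp_new = x0_prior_subject(s) + ll_ob[s] + ll_dg[s];
      double a = lp_new - lp_old;
      if (std::isfinite(lp_new) && std::log(R::unif_rand()) < a) {
        bl_x0[s].cur = prop;
        ++acc_x0;
      } else {
        th.x0.row(s) = x0_bak;
        states.rows(u0, u1 - 1) = st_bak;
        if (dat.ob_start[s + 1] > dat.ob_start[s])
          ob_mean.subvec(dat.ob_start[s], dat.ob_start[s + 1] - 1) = om_bak;
        ll_ob[s] = llo_bak;
        ll_dg[s] = lld_bak;
      }
      if (warm) bl_x0[s].adapt(std::min(1.0, std::exp(a)));
    }

    // 2. velocity field + subject states: HMC trajectories
    for (int r = 0; r < vel_updates; ++r) hmc_update(warm);

    // 3. noise sds (cached predicted means; no trajectory work)
    {
      arma::vec prop = bl_sig.propose();
      double lp_old = lp_sigma();
      double ll_old = arma::accu(ll_ob);
      arma::vec sig_bak = th.sigma;
      arma::vec llo_bak = ll_ob;
      th.sigma = arma::exp(prop);
      for (int s = 0; s < nsub; ++s) ll_ob[s] = obs_ll_subject(s);
      double a = arma::accu(ll_ob) + lp_sigma() - ll_old - lp_old;
      if (std::isfinite(a) && std::log(R::unif_rand()) < a) {
        bl_sig.cur = prop;
        ++acc_sig;
      } else {
        th.sigma = sig_bak;
        ll_ob = llo_bak;
      }
      if (warm) bl_sig.adapt(std::min(1.0, std::exp(a)));
    }

    // 4. ordered-logit block (cached states)
    {
      arma::vec prop = bl_clin.propose();
      double lp_old = lp_clin();
      double ll_old = arma::accu(ll_dg);
      double c1_bak = th.c1, c2_bak = th.c2;
      arma::vec bx_bak = th.beta_x, by_bak = th.beta_y, lld_bak = ll_dg;
      th.c1 = prop[0];
      th.c2 = prop[0] + std::exp(prop[1]);
      th.beta_x = prop.subvec(2, 6);
      th.beta_y = prop.subvec(7, 8);
      for (int s = 0; s < nsub; ++s) ll_dg[s] = diag_ll_subject(s);
      double a = arma::accu(ll_dg) + lp_clin() - ll_old - lp_old;
      if (std::isfinite(a) && std::log(R::unif_rand()) < a) {
        bl_clin.cur = prop;
        ++acc_clin;
      } else {
        th.c1 = c1_bak; th.c2 = c2_bak;
        th.beta_x = bx_bak; th.beta_y = by_bak;
        ll_dg = lld_bak;
      }
      if (warm) bl_clin.adapt(std::min(1.0, std::exp(a)));
    }

    // 5. link shape (optional; states unchanged, only means recomputed)
    if (est_lnk) {
      arma::vec prop = bl_link.propose();
      double lp_old = lp_links();
      double ll_old = arma::accu(ll_ob);
      arma::vec sl_bak = th.slope, mid_bak = th.mid;
      arma::vec om_bak = ob_mean, llo_bak = ll_ob;
      th.slope = arma::exp(prop.subvec(0, 4));
      th.mid = prop.subvec(5, 9);
      for (int s = 0; s < nsub; ++s) {
        obmeans_subject(s);
        ll_ob[s] = obs_ll_subject(s);
      }
      double a = arma::accu(ll_ob) + lp_links() - ll_old - lp_old;
      if (std::isfinite(a) && std::log(R::unif_rand()) < a) {
        bl_link.cur = prop;
        ++acc_link;
      } else {
        th.slope = sl_bak; th.mid = mid_bak;
        ob_mean = om_bak; ll_ob = llo_bak;
      }
      if (warm) bl_link.adapt(std::min(1.0, std::exp(a)));
    }

    // 6. population mean of initial states: conjugate Gibbs
    for (int j = 0; j < 5; ++j) {
      double prec = nsub / (th.tau0[j] * th.tau0[j]) + 1.0 / (sd_mu0 * sd_mu0);
      double m = arma::accu(th.x0.col(j)) / (th.tau0[j] * th.tau0[j]) / prec;
      th.mu0[j] = m + R::norm_rand() / std::sqrt(prec);
    }

    // 7. population sds of initial states: scalar random-walk on log scale
    for (int j = 0; j < 5; ++j) {
      double prop = log_tau0[j] + step_tau0[j] * R::norm_rand();
      double t_new = std::exp(prop), t_old = th.tau0[j];
      double lp = 0.0;
      for (int s = 0; s < nsub; ++s)
        lp += R::dnorm(th.x0(s, j), th.mu0[j], t_new, 1) -
              R::dnorm(th.x0(s, j), th.mu0[j], t_old, 1);
      lp += -(t_new * t_new - t_old * t_old) / (2.0 * sc_tau0 * sc_tau0) +
            (prop - log_tau0[j]);   // half-Normal prior + log-scale Jacobian
      if (std::log(R::unif_rand()) < lp) {
        log_tau0[j] = prop;
        th.tau0[j] = t_new;
        acc_tau0[j]++;
      }
      if (warm) {
        double g = 1.0 / std::sqrt((double)(it + 11));
        step_tau0[j] *= std::exp(g * (std::min(1.0, std::exp(lp)) - 0.44));
      }
    }

    // store
    if (!warm) {
      int row = it - n_warmup;
      arma::vec out(npop);
      int off = 0;
      out.subvec(off, off + nfree - 1) = extract_masked(th.V, mask);
      off += nfree;
      out.subvec(off, off + nfree - 1) = extract_masked(th.Wage, mask);
      off += nfree;
      out.subvec(off, off + nfree - 1) = extract_masked(th.Wapoe, mask);
      off += nfree;
      out.subvec(off, off + 4) = th.v0; off += 5;
      out.subvec(off, off + 4) = th.sigma; off += 5;
      out.subvec(off, off + 4) = th.mu0; off += 5;
      out.subvec(off, off + 4) = th.tau0; off += 5;
      out[off++] = th.c1;
      out[off++] = th.c2;
      out.subvec(off, off + 4) = th.beta_x; off += 5;
      out.subvec(off, off + 1) = th.beta_y; off += 2;
      out.subvec(off, off + 4) = th.slope; off += 5;
      out.subvec(off, off + 4) = th.mid; off += 5;
      pop_draws.row(row) = out.t();
      for (int s = 0; s < nsub; ++s)
        for (int j = 0; j < 5; ++j) x0_draws(row, s, j) = th.x0(s, j);
    }
    if (refresh > 0 && (it + 1) % refresh == 0)
      Rcpp::Rcout << "iter " << (it + 1) << "/" << total << "\n";
    if ((it & 63) == 0) Rcpp::checkUserInterrupt();
  }

  const double denom_tot = (double)total;
  const double denom_vel = denom_tot * vel_updates;
  return List::create(
      _["pop"] = pop_draws, _["x0"] = x0_draws,
      _["accept"] = List::create(
          _["x0"] = (double)acc_x0 / (denom_tot * nsub),
          _["velocity"] = acc_vel / denom_vel,
          _["sigma"] = acc_sig / denom_tot, _["clinical"] = acc_clin / denom_tot,
          _["links"] = acc_link / denom_tot));
}

// ---------------------------------------------------------------------------
// Conditional initial-state sampling for a new subject: for each posterior
// draw of the population parameters, a short Metropolis chain on x0 given the
// subject's windowed observations (population parameters held fixed per
// draw; warm-started from the previous draw's state).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
arma::mat cpp_sample_x0(const List& subject, const List& draws,
                        const List& fixed, int n_steps, double w) {
  arma::vec ob_time = as<arma::vec>(subject["ob_time"]);
  arma::ivec ob_chan = as<arma::ivec>(subject["ob_chan"]);
  arma::ivec ob_cens = as<arma::ivec>(subject["ob_cens"]);
  arma::vec ob_val = as<arma::vec>(subject["ob_val"]);
  arma::vec ob_se = as<arma::vec>(subject["ob_se"]);
  arma::vec dg_time = as<arma::vec>(subject["dg_time"]);
  arma::ivec dg_lab = as<arma::ivec>(subject["dg_lab"]);
  double age = as<double>(subject["age"]);
  double apoe = as<double>(subject["apoe"]);

  arma::vec lo = as<arma::vec>(fixed["link_lower"]);
  arma::vec up = as<arma::vec>(fixed["link_upper"]);
  arma::vec cu = as<arma::vec>(fixed["cens_upper"]);

  arma::mat V_d = as<arma::mat>(draws["V"]);         // ndraw x 25
  arma::mat Wage_d = as<arma::mat>(draws["W_age"]);
  arma::mat Wapoe_d = as<arma::mat>(draws["W_apoe"]);
  arma::mat v0_d = as<arma::mat>(draws["v0"]);
  arma::mat sig_d = as<arma::mat>(draws["sigma"]);
  arma::mat mu0_d = as<arma::mat>(draws["mu0"]);
  arma::mat tau0_d = as<arma::mat>(draws["tau0"]);
  arma::mat slope_d = as<arma::mat>(draws["link_slope"]);
  arma::mat mid_d = as<arma::mat>(draws["link_mid"]);
  arma::vec c1_d = as<arma::vec>(draws["c1"]);
  arma::vec c2_d = as<arma::vec>(draws["c2"]);
  arma::mat bx_d = as<arma::mat>(draws["beta_x"]);
  arma::mat by_d = as<arma::mat>(draws["beta_y"]);
  const int ndraw = V_d.n_rows;

  // unique times over windowed observations + diagnoses
  arma::vec all_t = arma::join_cols(ob_time, dg_time);
  arma::vec ut = arma::unique(all_t);
  arma::uvec ob_tidx(ob_time.n_elem), dg_tidx(dg_time.n_elem);
  for (arma::uword i = 0; i < ob_time.n_elem; ++i)
    ob_tidx[i] = arma::index_min(arma::abs(ut - ob_time[i]));
  for (arma::uword i = 0; i < dg_time.n_elem; ++i)
    dg_tidx[i] = arma::index_min(arma::abs(ut - dg_time[i]));

  arma::mat out(ndraw, 5);
  arma::vec x = mu0_d.row(0).t();
  double step = 0.4;
  std::vector<arma::mat> Phis(ut.n_elem);
  std::vector<arma::vec> psis(ut.n_elem);
  arma::mat Phi;
  arma::vec psi;

  for (int d = 0; d < ndraw; ++d) {
    arma::mat V(V_d.row(d).t());
    V.reshape(5, 5);
    arma::mat Wage(Wage_d.row(d).t());
    Wage.reshape(5, 5);
    arma::mat Wapoe(Wapoe_d.row(d).t());
    Wapoe.reshape(5, 5);
    arma::mat A = V + age * Wage + apoe * Wapoe;
    arma::vec v0 = v0_d.row(d).t();
    arma::vec sig = sig_d.row(d).t();
    arma::vec mu0 = mu0_d.row(d).t();
    arma::vec tau0 = tau0_d.row(d).t();
    arma::vec slope = slope_d.row(d).t();
    arma::vec mid = mid_d.row(d).t();
    arma::vec bx = bx_d.row(d).t();
    arma::vec by = by_d.row(d).t();
    double c1 = c1_d[d], c2 = c2_d[d];

    for (arma::uword u = 0; u < ut.n_elem; ++u) {
      phi_psi(A, v0, ut[u], Phi, psi);
      Phis[u] = Phi;
      psis[u] = psi;
    }
    auto logpost = [&](const arma::vec& x0) {
      double lp = 0.0;
      for (int j = 0; j < 5; ++j) lp += R::dnorm(x0[j], mu0[j], tau0[j], 1);
      for (arma::uword o = 0; o < ob_val.n_elem; ++o) {
        int k = ob_chan[o];
        arma::vec xt = Phis[ob_tidx[o]] * x0 + psis[ob_tidx[o]];
        double mean = sigmoid_link_c(xt[k], lo[k], up[k], slope[k], mid[k]);
        lp += w * obs_term(ob_val[o], ob_cens[o], mean, sig[k], ob_se[o],
                           cu[k]);
      }
      for (arma::uword g = 0; g < dg_lab.n_elem; ++g) {
        arma::vec xt = Phis[dg_tidx[g]] * x0 + psis[dg_tidx[g]];
        double eta = arma::dot(bx, xt) + by[0] * age + by[1] * apoe;
        lp += w * ologit_term(dg_lab[g], eta, c1, c2);
      }
      return lp;
    };
    double cur_lp = logpost(x);
    int acc = 0;
    for (int m = 0; m < n_steps; ++m) {
      arma::vec prop = x;
      for (int j = 0; j < 5; ++j) prop[j] += step * R::norm_rand();
      double lp = logpost(prop);
      if (std::isfinite(lp) && std::log(R::unif_rand()) < lp - cur_lp) {
        x = prop;
        cur_lp = lp;
        ++acc;
      }
    }
    double rate = (double)acc / n_steps;
    step *= std::exp(0.5 * (rate - 0.3));
    step = std::min(std::max(step, 1e-3), 5.0);
    out.row(d) = x.t();
  }
  return out;
}

// ---------------------------------------------------------------------------
// Per-draw forecasting on a time grid: latent trajectories and ordered-logit
// label probabilities.  Uniform grids use one matrix exponential per draw.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_forecast(const arma::mat& x0_draws, const List& draws, double age,
                  double apoe, const arma::vec& grid) {
  arma::mat V_d = as<arma::mat>(draws["V"]);
  arma::mat Wage_d = as<arma::mat>(draws["W_age"]);
  arma::mat Wapoe_d = as<arma::mat>(draws["W_apoe"]);
  arma::mat v0_d = as<arma::mat>(draws["v0"]);
  arma::vec c1_d = as<arma::vec>(draws["c1"]);
  arma::vec c2_d = as<arma::vec>(draws["c2"]);
  arma::mat bx_d = as<arma::mat>(draws["beta_x"]);
  arma::mat by_d = as<arma::mat>(draws["beta_y"]);
  const int ndraw = x0_draws.n_rows;
  const int nt = grid.n_elem;

  bool uniform = nt > 2;
  double h = nt > 1 ? grid[1] - grid[0] : 0.0;
  for (int i = 1; i < nt - 1; ++i)
    if (std::abs((grid[i + 1] - grid[i]) - h) > 1e-9) { uniform = false; break; }

  arma::cube lat(ndraw, nt, 5);
  arma::cube prob(ndraw, nt, 3);
  arma::mat Phi, Phi0;
  arma::vec psi, psi0;

  for (int d = 0; d < ndraw; ++d) {
    arma::mat V(V_d.row(d).t());
    V.reshape(5, 5);
    arma::mat Wage(Wage_d.row(d).t());
    Wage.reshape(5, 5);
    arma::mat Wapoe(Wapoe_d.row(d).t());
    Wapoe.reshape(5, 5);
    arma::mat A = V + age * Wage + apoe * Wapoe;
    arma::vec v0 = v0_d.row(d).t();
    arma::vec bx = bx_d.row(d).t();
    double b_cov = by_d(d, 0) * age + by_d(d, 1) * apoe;
    double c1 = c1_d[d], c2 = c2_d[d];
    arma::vec x = x0_draws.row(d).t();

    arma::mat xs(nt, 5);
    if (uniform) {
      phi_psi(A, v0, grid[0], Phi0, psi0);
      phi_psi(A, v0, h, Phi, psi);
      arma::vec xt = Phi0 * x + psi0;
      for (int i = 0; i < nt; ++i) {
        xs.row(i) = xt.t();
        if (i < nt - 1) xt = Phi * xt + psi;
      }
    } else {
      for (int i = 0; i < nt; ++i) {
        phi_psi(A, v0, grid[i], Phi, psi);
        xs.row(i) = (Phi * x + psi).t();
      }
    }
    for (int i = 0; i < nt; ++i) {
      double eta = arma::dot(bx, xs.row(i).t()) + b_cov;
      double pcn = R::plogis(c1 - eta, 0.0, 1.0, 1, 0);
      double pcum = R::plogis(c2 - eta, 0.0, 1.0, 1, 0);
      prob(d, i, 0) = pcn;
      prob(d, i, 1) = pcum - pcn;
      prob(d, i, 2) = 1.0 - pcum;
      for (int j = 0; j < 5; ++j) lat(d, i, j) = xs(i, j);
    }
  }
  return List::create(_["latent"] = lat, _["prob"] = prob);
}
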