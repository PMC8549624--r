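// Unconstrained log-posterior (with analytic gradient) of the robust binomial
// GLMM, and a dynamic multinomial no-U-turn sampler with diagonal-metric and
// step-size adaptation during warmup.
//
// Parameter layout of the unconstrained vector theta (length D):
//   [0, K)                     fixed effects beta (design-matrix columns)
//   [K, K+P)                   z_pop   (non-centered: b_pop   = sigma_pop   * z_pop)
//   [K+P, K+P+C)               z_clone (non-centered: b_clone = sigma_clone * z_clone)
//   K+P+C                      log(sigma_pop)    (present iff P > 0)
//   K+P+C+(P>0)                log(sigma_clone)  (present iff C > 0)
//   K+P+C+(P>0)+(C>0)          log(nu)           (present iff C > 0)
//
// Random effects enter the linear predictor multiplied by the per-unit code
// `cre` (the signed pesticide code, or an alternative coding supplied by R).

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double LOG_2PI = 1.8378770664093454836;

static inline double log1pexp_(double x) {
  if (x > 35.0) return x + std::exp(-x);
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

static inline double invlogit_(double x) {
  if (x >= 0) return 1.0 / (1.0 + std::exp(-x));
  double e = std::exp(x);
  return e / (1.0 + e);
}

// log density of the standardized Student-t with df degrees of freedom
static inline double lt_std(double x, double df) {
  return R::lgammafn(0.5 * (df + 1.0)) - R::lgammafn(0.5 * df) -
         0.5 * std::log(df * M_PI) -
         0.5 * (df + 1.0) * std::log1p(x * x / df);
}

// d/dx of lt_std
static inline double dlt_std(double x, double df) {
  return -(df + 1.0) * x / (df + x * x);
}

struct ModelData {
  NumericVector y, N, cre;
  NumericMatrix X;
  IntegerVector pop, clone_;   // 0-based unit -> group maps (ignored if P/C == 0)
  int n, K, P, C;
  // prior hyperparameters
  double beta_df, beta_loc, beta_scale;
  double sd_df, sd_scale;
  double nu_shape, nu_rate;
  double lchoose_const;        // sum_i log C(N_i, y_i), constant in theta
  int D, i_lsp, i_lsc, i_lnu;  // indices of log sigma_pop/sigma_clone/log nu (-1 if absent)
};

static ModelData unpack_model(NumericVector y, NumericVector N, NumericMatrix X,
                              IntegerVector pop, int npop,
                              IntegerVector clone, int nclone,
                              NumericVector cre, List prior) {
  ModelData m;
  m.y = y; m.N = N; m.X = X; m.pop = pop; m.clone_ = clone; m.cre = cre;
  m.n = y.size(); m.K = X.ncol(); m.P = npop; m.C = nclone;
  m.beta_df = as<double>(prior["beta_df"]);
  m.beta_loc = as<double>(prior["beta_loc"]);
  m.beta_scale = as<double>(prior["beta_scale"]);
  m.sd_df = as<double>(prior["sd_df"]);
  m.sd_scale = as<double>(prior["sd_scale"]);
  m.nu_shape = as<double>(prior["nu_shape"]);
  m.nu_rate = as<double>(prior["nu_rate"]);
  m.lchoose_const = 0.0;
  for (int i = 0; i < m.n; ++i) m.lchoose_const += R::lchoose(N[i], y[i]);
  int at = m.K + m.P + m.C;
  m.i_lsp = (m.P > 0) ? at++ : -1;
  m.i_lsc = (m.C > 0) ? at++ : -1;
  m.i_lnu = (m.C > 0) ? at++ : -1;
  m.D = at;
  return m;
}

// log-posterior (up to no constant: the binomial normalizing constant is
// included) on the unconstrained scale, with gradient written into grad.
static double lp_grad(const ModelData& m, const double* theta, double* grad) {
  const int K = m.K, P = m.P, C = m.C, n = m.n;
  for (int j = 0; j < m.D; ++j) grad[j] = 0.0;

  const double* beta = theta;
  const double* zp = theta + K;
  const double* zc = theta + K + P;
  double sp = 0.0, sc = 0.0, nu = 0.0;
  if (P > 0) sp = std::exp(theta[m.i_lsp]);
  if (C > 0) { sc = std::exp(theta[m.i_lsc]); nu = std::exp(theta[m.i_lnu]); }
  if (!std::isfinite(sp) || !std::isfinite(sc) || !std::isfinite(nu))
    return -std::numeric_limits<double>::infinity();

  double lp = 0.0;
  double acc_lsp = 0.0, acc_lsc = 0.0;  // d(loglik)/d sigma before chain rule

  // likelihood
  for (int i = 0; i < n; ++i) {
    double eta = 0.0;
    for (int k = 0; k < K; ++k) eta += m.X(i, k) * beta[k];
    double ci = m.cre[i];
    if (P > 0) eta += ci * sp * zp[m.pop[i]];
    if (C > 0) eta += ci * sc * zc[m.clone_[i]];
    lp += m.y[i] * eta - m.N[i] * log1pexp_(eta);
    double r = m.y[i] - m.N[i] * invlogit_(eta);
    for (int k = 0; k < K; ++k) grad[k] += r * m.X(i, k);
    if (P > 0) {
      grad[K + m.pop[i]] += r * ci * sp;
      acc_lsp += r * ci * zp[m.pop[i]];
    }
    if (C > 0) {
      grad[K + P + m.clone_[i]] += r * ci * sc;
      acc_lsc += r * ci * zc[m.clone_[i]];
    }
  }

  lp += m.lchoose_const;

  // fixed-effect priors: StudentT(beta_df, beta_loc, beta_scale)
  for (int k = 0; k < K; ++k) {
    double x = (beta[k] - m.beta_loc) / m.beta_scale;
    lp += lt_std(x, m.beta_df) - std::log(m.beta_scale);
    grad[k] += dlt_std(x, m.beta_df) / m.beta_scale;
  }

  // z_pop ~ Normal(0, 1)
  for (int g = 0; g < P; ++g) {
    lp += -0.5 * zp[g] * zp[g] - 0.5 * LOG_2PI;
    grad[K + g] -= zp[g];
  }

  // z_clone ~ StudentT(nu, 0, 1); nu-sensitivity accumulated for grad of log nu
  double acc_dnu = 0.0;
  if (C > 0) {
    double lg_const = R::lgammafn(0.5 * (nu + 1.0)) - R::lgammafn(0.5 * nu) -
                      0.5 * std::log(nu * M_PI);
    double dg_const = 0.5 * R::digamma(0.5 * (nu + 1.0)) -
                      0.5 * R::digamma(0.5 * nu) - 0.5 / nu;
    for (int h = 0; h < C; ++h) {
      double z = zc[h], z2 = z * z;
      lp += lg_const - 0.5 * (nu + 1.0) * std::log1p(z2 / nu);
      grad[K + P + h] += -(nu + 1.0) * z / (nu + z2);
      acc_dnu += dg_const - 0.5 * std::log1p(z2 / nu) +
                 (nu + 1.0) * z2 / (2.0 * nu * (nu + z2));
    }
  }

  // half-StudentT(sd_df, 0, sd_scale) priors on the scales, log-Jacobians
  if (P > 0) {
    double x = sp / m.sd_scale;
    lp += M_LN2 + lt_std(x, m.sd_df) - std::log(m.sd_scale) + theta[m.i_lsp];
    grad[m.i_lsp] += sp * (acc_lsp + dlt_std(x, m.sd_df) / m.sd_scale) + 1.0;
  }
  if (C > 0) {
    double x = sc / m.sd_scale;
    lp += M_LN2 + lt_std(x, m.sd_df) - std::log(m.sd_scale) + theta[m.i_lsc];
    grad[m.i_lsc] += sc * (acc_lsc + dlt_std(x, m.sd_df) / m.sd_scale) + 1.0;
    // nu ~ Gamma(shape, rate), log-Jacobian
    lp += m.nu_shape * std::log(m.nu_rate) - R::lgammafn(m.nu_shape) +
          (m.nu_shape - 1.0) * std::log(nu) - m.nu_rate * nu + theta[m.i_lnu];
    grad[m.i_lnu] += m.nu_shape - m.nu_rate * nu + nu * acc_dnu;
  }
  return lp;
}

// [[Rcpp::export]]
List cpp_lp_grad(NumericVector theta, NumericVector y, NumericVector N,
                 NumericMatrix X, IntegerVector pop, int npop,
                 IntegerVector clone, int nclone, NumericVector cre,
                 List prior) {
  ModelData m = unpack_model(y, N, X, pop, npop, clone, nclone, cre, prior);
  if (theta.size() != m.D) stop("theta has length %d, expected %d", theta.size(), m.D);
  NumericVector grad(m.D);
  double lp = lp_grad(m, theta.begin(), grad.begin());
  return List::create(_["lp"] = lp, _["grad"] = grad);
}

// ---------------------------------------------------------------------------
// NUTS

struct State {
  std::vector<double> q, p, g;
  double lp;
};

struct Sampler {
  const ModelData* m;
  std::vector<double> minv;  // diagonal inverse metric (approx posterior variances)
  double eps;
  int max_depth;
  double H0;
  bool divergent;
  double sum_alpha;
  int n_alpha, n_leapfrog;
};

static double energy(const Sampler& s, const State& st) {
  double kin = 0.0;
  for (size_t j = 0; j < st.p.size(); ++j)
    kin += 0.5 * s.minv[j] * st.p[j] * st.p[j];
  return -st.lp + kin;
}

static void leapfrog(Sampler& s, State& st, double eps) {
  int D = (int)st.q.size();
  for (int j = 0; j < D; ++j) st.p[j] += 0.5 * eps * st.g[j];
  for (int j = 0; j < D; ++j) st.q[j] += eps * s.minv[j] * st.p[j];
  st.lp = lp_grad(*s.m, st.q.data(), st.g.data());
  if (!std::isfinite(st.lp)) {
    st.lp = -std::numeric_limits<double>::infinity();
  } else {
    for (int j = 0; j < D; ++j) st.p[j] += 0.5 * eps * st.g[j];
  }
  s.n_leapfrog++;
}

static bool uturn(const Sampler& s, const State& minus, const State& plus) {
  double dot_m = 0.0, dot_p = 0.0;
  for (size_t j = 0; j < minus.q.size(); ++j) {
    double dq = plus.q[j] - minus.q[j];
    dot_m += dq * s.minv[j] * minus.p[j];
    dot_p += dq * s.minv[j] * plus.p[j];
  }
  return (dot_m < 0.0) || (dot_p < 0.0);
}

struct Tree {
  State minus, plus, prop;
  double log_w;
  bool stop;  // divergence or U-turn inside the subtree
};

static double log_sum_exp(double a, double b) {
  if (a == -std::numeric_limits<double>::infinity()) return b;
  if (b == -std::numeric_limits<double>::infinity()) return a;
  double mx = (a > b) ? a : b;
  return mx + std::log(std::exp(a - mx) + std::exp(b - mx));
}

static Tree build_tree(Sampler& s, const State& from, int depth, double eps) {
  if (depth == 0) {
    Tree t;
    State st = from;
    leapfrog(s, st, eps);
    double H = std::isfinite(st.lp) ? energy(s, st)
                                    : std::numeric_limits<double>::infinity();
    double dH = H - s.H0;
    if (!std::isfinite(dH)) dH = std::numeric_limits<double>::infinity();
    t.log_w = -dH;
    if (dH > 1000.0) {
      s.divergent = true;
      t.stop = true;
    } else {
      t.stop = false;
    }
    s.sum_alpha += (dH < 0.0) ? 1.0 : std::exp(-dH);
    s.n_alpha++;
    t.minus = st; t.plus = st; t.prop = st;
    return t;
  }
  Tree t1 = build_tree(s, from, depth - 1, eps);
  if (t1.stop) return t1;
  const State& cont = (eps > 0) ? t1.plus : t1.minus;
  Tree t2 = build_tree(s, cont, depth - 1, eps);
  Tree t;
  t.log_w = log_sum_exp(t1.log_w, t2.log_w);
  // multinomial sampling within the subtree
  double u = unif_rand();
  t.prop = (std::log(u) < t2.log_w - t.log_w) ? t2.prop : t1.prop;
  if (eps > 0) { t.minus = t1.minus; t.plus = t2.plus; }
  else         { t.minus = t2.minus; t.plus = t1.plus; }
  t.stop = t2.stop || uturn(s, t.minus, t.plus);
  return t;
}

// one NUTS transition; updates cur in place, returns divergence flag
static bool nuts_transition(Sampler& s, State& cur) {
  int D = (int)cur.q.size();
  for (int j = 0; j < D; ++j) cur.p[j] = norm_rand() / std::sqrt(s.minv[j]);
  s.H0 = energy(s, cur);
  s.divergent = false;
  s.sum_alpha = 0.0; s.n_alpha = 0;

  State minus = cur, plus = cur, prop = cur;
  double log_w = 0.0;  // weight of the initial point: exp(H0 - H0)
  for (int depth = 0; depth < s.max_depth; ++depth) {
    double dir = (unif_rand() < 0.5) ? -1.0 : 1.0;
    const State& from = (dir > 0) ? plus : minus;
    Tree t = build_tree(s, from, depth, dir * s.eps);
    if (s.divergent) break;
    if (!t.stop) {
      // biased progressive sampling toward the new subtree
      double a = std::exp(t.log_w - log_w);
      if (unif_rand() < a) prop = t.prop;
      log_w = log_sum_exp(log_w, t.log_w);
      if (dir > 0) plus = t.plus; else minus = t.minus;
    }
    if (t.stop || uturn(s, minus, plus)) break;
  }
  cur = prop;
  return s.divergent;
}

// heuristic initial step size (double/halve until acceptance crosses 0.5)
static double find_epsilon(Sampler& s, const State& init) {
  double eps = 1.0;
  State st = init;
  int D = (int)st.q.size();
  for (int j = 0; j < D; ++j) st.p[j] = norm_rand() / std::sqrt(s.minv[j]);
  double H0 = energy(s, st);
  State st1 = st;
  leapfrog(s, st1, eps);
  double dH = std::isfinite(st1.lp) ? H0 - energy(s, st1)
                                    : -std::numeric_limits<double>::infinity();
  double dir = (dH > std::log(0.5)) ? 1.0 : -1.0;
  for (int it = 0; it < 100; ++it) {
    eps *= (dir > 0) ? 2.0 : 0.5;
    if (eps > 1e7 || eps < 1e-10) break;
    st1 = st;
    leapfrog(s, st1, eps);
    dH = std::isfinite(st1.lp) ? H0 - energy(s, st1)
                               : -std::numeric_limits<double>::infinity();
    if (dir > 0 && dH <= std::log(0.5)) break;
    if (dir < 0 && dH >= std::log(0.5)) break;
  }
  return eps;
}

// [[Rcpp::export]]
List cpp_sample_chain(NumericVector y, NumericVector N, NumericMatrix X,
                      IntegerVector pop, int npop, IntegerVector clone,
                      int nclone, NumericVector cre, List prior,
                      NumericVector init, int n_iter, int n_warmup,
                      double target_accept, int max_treedepth) {
  ModelData m = unpack_model(y, N, X, pop, npop, clone, nclone, cre, prior);
  if (init.size() != m.D) stop("init has length %d, expected %d", init.size(), m.D);
  if (n_warmup >= n_iter) stop("n_warmup must be < n_iter");

  Sampler s;
  s.m = &m;
  s.minv.assign(m.D, 1.0);
  s.max_depth = max_treedepth;
  s.n_leapfrog = 0;

  State cur;
  cur.q.assign(init.begin(), init.end());
  cur.p.assign(m.D, 0.0);
  cur.g.assign(m.D, 0.0);
  cur.lp = lp_grad(m, cur.q.data(), cur.g.data());
  if (!std::isfinite(cur.lp)) stop("non-finite log-posterior at the initial point");

  // dual-averaging state
  s.eps = find_epsilon(s, cur);
  double mu = std::log(10.0 * s.eps), log_eps_bar = 0.0, h_bar = 0.0;
  const double da_gamma = 0.05, da_t0 = 10.0, da_kappa = 0.75;
  int da_m = 0;

  // metric adaptation windows (scaled-down Stan schedule)
  int init_buf = 75, term_buf = 50, base_win = 25;
  bool adapt_metric = (m.D > 0) && (n_warmup >= 40);
  if (adapt_metric && init_buf + term_buf + base_win > n_warmup) {
    double f = (double)n_warmup / 150.0;
    init_buf = std::max(1, (int)(75 * f));
    term_buf = std::max(1, (int)(50 * f));
    base_win = n_warmup - init_buf - term_buf;
  }
  int win_start = init_buf, win_size = base_win;
  int win_end = adapt_metric ? (win_start + win_size) : (n_warmup + 1);
  if (adapt_metric && win_end + win_size * 2 + term_buf > n_warmup)
    win_end = n_warmup - term_buf;
  std::vector<double> wf_mean(m.D, 0.0), wf_m2(m.D, 0.0);
  long wf_n = 0;

  int n_kept = n_iter - n_warmup;
  NumericMatrix draws(n_kept, m.D);
  LogicalVector divergent(n_kept);
  int div_warmup = 0;
  double post_alpha = 0.0;
  long post_alpha_n = 0;

  for (int it = 0; it < n_iter; ++it) {
    bool div = nuts_transition(s, cur);
    double alpha = (s.n_alpha > 0) ? s.sum_alpha / s.n_alpha : 0.0;

    if (it < n_warmup) {
      if (div) div_warmup++;
      // dual averaging
      da_m++;
      double w = 1.0 / (da_m + da_t0);
      h_bar = (1.0 - w) * h_bar + w * (target_accept - alpha);
      double log_eps = mu - std::sqrt((double)da_m) / da_gamma * h_bar;
      double w2 = std::pow((double)da_m, -da_kappa);
      log_eps_bar = w2 * log_eps + (1.0 - w2) * log_eps_bar;
      s.eps = std::exp(log_eps);

      if (adapt_metric && it >= win_start && it < win_end) {
        // Welford accumulation over the current window
        wf_n++;
        for (int j = 0; j < m.D; ++j) {
          double d = cur.q[j] - wf_mean[j];
          wf_mean[j] += d / wf_n;
          wf_m2[j] += d * (cur.q[j] - wf_mean[j]);
        }
        if (it == win_end - 1) {
          if (wf_n >= 10) {
            for (int j = 0; j < m.D; ++j) {
              double v = wf_m2[j] / (wf_n - 1);
              s.minv[j] = (wf_n / (wf_n + 5.0)) * v + 1e-3 * (5.0 / (wf_n + 5.0));
            }
          }
          std::fill(wf_mean.begin(), wf_mean.end(), 0.0);
          std::fill(wf_m2.begin(), wf_m2.end(), 0.0);
          wf_n = 0;
          // next (doubled) window; the last one absorbs the remainder
          win_start = win_end;
          win_size *= 2;
          win_end = win_start + win_size;
          if (win_end + win_size * 2 + term_buf > n_warmup || win_end > n_warmup - term_buf)
            win_end = n_warmup - term_buf;
          // restart step-size adaptation around the current value
          s.eps = find_epsilon(s, cur);
          mu = std::log(10.0 * s.eps);
          h_bar = 0.0; log_eps_bar = 0.0; da_m = 0;
        }
      }
      if (it == n_warmup - 1) s.eps = std::exp(log_eps_bar);
    } else {
      int r = it - n_warmup;
      for (int j = 0; j < m.D; ++j) draws(r, j) = cur.q[j];
      divergent[r] = div;
      post_alpha += alpha;
      post_alpha_n++;
    }
    if (it % 256 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
      _["draws"] = draws, _["divergent"] = divergent,
      _["step_size"] = s.eps,
      _["inv_metric"] = NumericVector(s.minv.begin(), s.minv.end()),
      _["accept_stat"] = (post_alpha_n > 0) ? post_alpha / post_alpha_n : NA_REAL,
      _["n_leapfrog"] = s.n_leapfrog,
      _["divergent_warmup"] = div_warmup);
}
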