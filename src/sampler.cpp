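// Metropolis-within-Gibbs sampler for open-population spatial
// capture-recapture models with data augmentation.
//
// Latent structure per individual: a full life history (entry period e,
// death period d) updated jointly by enumerating all valid trajectories
// (O(T^2) states), plus an activity-center path s[.,t] under one of three
// movement priors. Detection parameters move by random-walk MH on the log
// scale with adaptation during burn-in; survival and entrance
// probabilities are conjugate Beta draws under uniform priors when primary
// periods are equally spaced (logit-scale MH otherwise).
//
// Movement priors for the center path are defined for all M augmented
// individuals and all T periods, anchored at t = 1, independent of the
// alive state; paths of never-recruited individuals are sampled from the
// prior so the chain remains proper.

#include <Rcpp.h>
using namespace Rcpp;

static const double NEG_BIG = -1e10; // stands in for -Inf in prefix sums

enum Movement { CONSTANT = 0, INDEPENDENT = 1, MARKOVIAN = 2 };

struct Model {
  int M, J, T;
  IntegerVector y;      // M x J x T
  IntegerMatrix K;      // J x T
  NumericVector trapx, trapy;
  double xmin, xmax, ymin, ymax;
  int movement;
  bool cjs;
  NumericVector delta;  // length T-1, interval lengths
  bool equal_spacing;
  double lambda0_max, sigma_p_max, sigma_s_max;

  inline int yy(int i, int j, int t) const { return y[i + M * (j + J * t)]; }
};

// log binomial likelihood of period t for individual i alive with center (sx, sy)
static double period_loglik(const Model& m, int i, int t, double sx, double sy,
                            double lambda0, double sigma_p) {
  double inv2s2 = 1.0 / (2.0 * sigma_p * sigma_p);
  double ll = 0.0;
  for (int j = 0; j < m.J; ++j) {
    int K = m.K(j, t);
    if (K == 0) continue;
    double dx = sx - m.trapx[j], dy = sy - m.trapy[j];
    double h = lambda0 * std::exp(-(dx * dx + dy * dy) * inv2s2); // hazard
    int yv = m.yy(i, j, t);
    if (yv == 0) {
      ll += -double(K) * h; // K * log(1 - p), with log(1-p) = -h exactly
    } else {
      double p = -std::expm1(-h); // 1 - exp(-h)
      ll += R::dbinom(double(yv), double(K), p, 1);
    }
  }
  return ll;
}

// log of the normal mass on [lo, hi] (truncation constant)
static inline double log_trunc_mass(double mean, double sd, double lo, double hi) {
  double mass = R::pnorm(hi, mean, sd, 1, 0) - R::pnorm(lo, mean, sd, 1, 0);
  if (mass <= 0) return NEG_BIG;
  return std::log(mass);
}

// truncated-normal random-walk step log-density s_prev -> s_t on rectangle S
static double walk_logdens(const Model& m, double px, double py, double cx, double cy,
                           double sigma_s) {
  return R::dnorm(cx, px, sigma_s, 1) + R::dnorm(cy, py, sigma_s, 1) -
         log_trunc_mass(px, sigma_s, m.xmin, m.xmax) -
         log_trunc_mass(py, sigma_s, m.ymin, m.ymax);
}

struct State {
  std::vector<int> entry;  // 1..T, 0 = never (always >0 in CJS mode)
  std::vector<int> death;  // first dead period, entry+1 .. T+1
  NumericMatrix sx, sy;    // M x T centers (constant model: column 0 replicated)
  double phi, lambda0, sigma_p, sigma_s;
  std::vector<double> gamma; // length T
  NumericMatrix L1;          // M x T cached alive log-lik
  std::vector<double> phi_int; // phi^delta[t], length T-1
};

static inline bool alive_at(const State& st, int i, int t) {
  // t is 0-based period; entry/death are 1-based
  return st.entry[i] > 0 && st.entry[i] <= t + 1 && t + 1 < st.death[i];
}

static void refresh_phi_int(const Model& m, State& st) {
  for (int t = 0; t < m.T - 1; ++t) st.phi_int[t] = std::pow(st.phi, m.delta[t]);
}

// recompute the cached alive log-likelihood for (i, t)
static inline void refresh_L1(const Model& m, State& st, int i, int t) {
  double sxv = (m.movement == CONSTANT) ? st.sx(i, 0) : st.sx(i, t);
  double syv = (m.movement == CONSTANT) ? st.sy(i, 0) : st.sy(i, t);
  st.L1(i, t) = period_loglik(m, i, t, sxv, syv, st.lambda0, st.sigma_p);
}

static void refresh_L1_all(const Model& m, State& st) {
  for (int i = 0; i < m.M; ++i)
    for (int t = 0; t < m.T; ++t) refresh_L1(m, st, i, t);
}

// ---- latent life-history update (joint per-individual) -------------------

static void update_z(const Model& m, State& st,
                     const IntegerMatrix& has_det, const IntegerVector& first_det,
                     std::vector<double>& work, std::vector<int>& es, std::vector<int>& ds) {
  int T = m.T;
  std::vector<double> SL1(T + 1), S0(T + 1), log1mg(T), cum1mg(T + 1);
  if (!m.cjs) {
    cum1mg[0] = 0.0;
    for (int t = 0; t < T; ++t) {
      double g = st.gamma[t];
      log1mg[t] = (g >= 1.0) ? NEG_BIG : std::log1p(-g);
      cum1mg[t + 1] = cum1mg[t] + log1mg[t];
    }
  }
  std::vector<double> logphi(T - 1), log1mphi(T - 1);
  for (int t = 0; t < T - 1; ++t) {
    double pi = st.phi_int[t];
    logphi[t] = std::log(pi);
    log1mphi[t] = (pi >= 1.0) ? NEG_BIG : std::log1p(-pi);
  }
  // cumulative survival log-probs: surv[a][b] = sum_{t=a..b-1} logphi[t]
  std::vector<double> cumphi(T);
  cumphi[0] = 0.0;
  for (int t = 1; t < T; ++t) cumphi[t] = cumphi[t - 1] + logphi[t - 1];

  for (int i = 0; i < m.M; ++i) {
    SL1[0] = 0.0; S0[0] = 0.0;
    for (int t = 0; t < T; ++t) {
      SL1[t + 1] = SL1[t] + st.L1(i, t);
      S0[t + 1] = S0[t] + (has_det(i, t) ? NEG_BIG : 0.0);
    }
    int nstate = 0;
    // states: (e, d) with 1 <= e <= T, e < d <= T+1; plus "never" (JS only)
    es.clear(); ds.clear();
    work.clear();
    int e_lo = 1, e_hi = T;
    if (m.cjs) { e_lo = e_hi = first_det[i]; }
    for (int e = e_lo; e <= e_hi; ++e) {
      for (int d = e + 1; d <= T + 1; ++d) {
        double lp = 0.0;
        if (!m.cjs) {
          lp += cum1mg[e - 1];                       // not recruited before e
          lp += (st.gamma[e - 1] <= 0.0) ? NEG_BIG : std::log(st.gamma[e - 1]);
        }
        lp += cumphi[d - 1 - 1] - cumphi[e - 1];     // survive e..d-1
        if (d <= T) lp += log1mphi[d - 1 - 1];       // die at transition d-1 -> d
        // observation: alive on [e, d-1], structural zeros elsewhere
        lp += SL1[d - 1] - SL1[e - 1];
        lp += S0[e - 1] + (S0[T] - S0[d - 1]);
        es.push_back(e); ds.push_back(d);
        work.push_back(lp);
        ++nstate;
      }
    }
    if (!m.cjs) { // never recruited
      es.push_back(0); ds.push_back(T + 2);
      work.push_back(cum1mg[T] + S0[T]);
      ++nstate;
    }
    double mx = work[0];
    for (int k = 1; k < nstate; ++k) mx = std::max(mx, work[k]);
    double tot = 0.0;
    for (int k = 0; k < nstate; ++k) { work[k] = std::exp(work[k] - mx); tot += work[k]; }
    double u = R::runif(0.0, tot), acc = 0.0;
    int pick = nstate - 1;
    for (int k = 0; k < nstate; ++k) { acc += work[k]; if (u <= acc) { pick = k; break; } }
    st.entry[i] = es[pick];
    st.death[i] = ds[pick];
  }
}

// ---- demographic parameter updates ---------------------------------------

static void update_phi(const Model& m, State& st, double& phi_lscale,
                       int& phi_acc, int& phi_try) {
  // sufficient statistics per interval: survivals and deaths
  std::vector<int> nsurv(m.T - 1, 0), ndie(m.T - 1, 0);
  for (int i = 0; i < m.M; ++i) {
    if (st.entry[i] == 0) continue;
    int e = st.entry[i], d = st.death[i];
    for (int t = e; t <= std::min(d - 2, m.T - 1); ++t) nsurv[t - 1]++;
    if (d <= m.T) ndie[d - 2]++;
  }
  if (m.equal_spacing) {
    int s = 0, f = 0;
    for (int t = 0; t < m.T - 1; ++t) { s += nsurv[t]; f += ndie[t]; }
    st.phi = R::rbeta(1.0 + s, 1.0 + f);
  } else {
    // logit-scale random-walk MH on per-unit phi
    auto loglik = [&](double phi) {
      double ll = 0.0;
      for (int t = 0; t < m.T - 1; ++t) {
        double pi = std::pow(phi, m.delta[t]);
        ll += nsurv[t] * std::log(pi);
        if (ndie[t] > 0) ll += ndie[t] * std::log1p(-pi);
      }
      return ll;
    };
    double lo = std::log(st.phi / (1.0 - st.phi));
    double lp = lo + R::rnorm(0.0, std::exp(phi_lscale));
    double phip = 1.0 / (1.0 + std::exp(-lp));
    // Jacobian of logit transform on a Uniform(0,1) prior
    double lr = loglik(phip) - loglik(st.phi) +
                std::log(phip * (1.0 - phip)) - std::log(st.phi * (1.0 - st.phi));
    phi_try++;
    if (std::log(R::runif(0.0, 1.0)) < lr) { st.phi = phip; phi_acc++; }
  }
  refresh_phi_int(m, st);
}

static void update_gamma(const Model& m, State& st) {
  for (int t = 1; t <= m.T; ++t) {
    int avail = 0, rec = 0;
    for (int i = 0; i < m.M; ++i) {
      int e = st.entry[i];
      if (e == 0 || e >= t) {
        ++avail;
        if (e == t) ++rec;
      }
    }
    st.gamma[t - 1] = R::rbeta(1.0 + rec, 1.0 + (avail - rec));
  }
}

// ---- activity-center updates ---------------------------------------------

static inline bool in_S(const Model& m, double x, double y) {
  return x >= m.xmin && x <= m.xmax && y >= m.ymin && y <= m.ymax;
}

static void update_centers(const Model& m, State& st, double s_lscale,
                           long& s_acc, long& s_try) {
  double step = std::exp(s_lscale);
  if (m.movement == CONSTANT) {
    for (int i = 0; i < m.M; ++i) {
      double cx = st.sx(i, 0), cy = st.sy(i, 0);
      bool any_alive = st.entry[i] > 0;
      if (!any_alive) { // prior draw: uniform over S
        st.sx(i, 0) = R::runif(m.xmin, m.xmax);
        st.sy(i, 0) = R::runif(m.ymin, m.ymax);
        for (int t = 0; t < m.T; ++t) refresh_L1(m, st, i, t);
        continue;
      }
      double px = cx + R::rnorm(0.0, step), py = cy + R::rnorm(0.0, step);
      s_try++;
      if (!in_S(m, px, py)) continue;
      double lr = 0.0;
      std::vector<double> newL(m.T);
      for (int t = 0; t < m.T; ++t) {
        if (alive_at(st, i, t)) {
          newL[t] = period_loglik(m, i, t, px, py, st.lambda0, st.sigma_p);
          lr += newL[t] - st.L1(i, t);
        }
      }
      if (std::log(R::runif(0.0, 1.0)) < lr) {
        s_acc++;
        st.sx(i, 0) = px; st.sy(i, 0) = py;
        for (int t = 0; t < m.T; ++t) {
          if (alive_at(st, i, t)) st.L1(i, t) = newL[t];
          else refresh_L1(m, st, i, t);
        }
      }
    }
    return;
  }
  for (int i = 0; i < m.M; ++i) {
    for (int t = 0; t < m.T; ++t) {
      bool has_lik = alive_at(st, i, t);
      if (m.movement == INDEPENDENT) {
        if (!has_lik) { // exact prior (uniform) draw
          st.sx(i, t) = R::runif(m.xmin, m.xmax);
          st.sy(i, t) = R::runif(m.ymin, m.ymax);
          refresh_L1(m, st, i, t);
          continue;
        }
        double px = st.sx(i, t) + R::rnorm(0.0, step);
        double py = st.sy(i, t) + R::rnorm(0.0, step);
        s_try++;
        if (!in_S(m, px, py)) continue;
        double newL = period_loglik(m, i, t, px, py, st.lambda0, st.sigma_p);
        if (std::log(R::runif(0.0, 1.0)) < newL - st.L1(i, t)) {
          s_acc++;
          st.sx(i, t) = px; st.sy(i, t) = py; st.L1(i, t) = newL;
        }
      } else { // MARKOVIAN: walk anchored at t=1, neighbors on both sides
        double cx = st.sx(i, t), cy = st.sy(i, t);
        double px = cx + R::rnorm(0.0, step);
        double py = cy + R::rnorm(0.0, step);
        s_try++;
        if (!in_S(m, px, py)) continue;
        double lr = 0.0;
        if (t > 0) {
          lr += walk_logdens(m, st.sx(i, t - 1), st.sy(i, t - 1), px, py, st.sigma_s) -
                walk_logdens(m, st.sx(i, t - 1), st.sy(i, t - 1), cx, cy, st.sigma_s);
        } // t = 0: uniform prior, cancels
        if (t < m.T - 1) {
          lr += walk_logdens(m, px, py, st.sx(i, t + 1), st.sy(i, t + 1), st.sigma_s) -
                walk_logdens(m, cx, cy, st.sx(i, t + 1), st.sy(i, t + 1), st.sigma_s);
        }
        double newL = 0.0;
        if (has_lik) {
          newL = period_loglik(m, i, t, px, py, st.lambda0, st.sigma_p);
          lr += newL - st.L1(i, t);
        }
        if (std::log(R::runif(0.0, 1.0)) < lr) {
          s_acc++;
          st.sx(i, t) = px; st.sy(i, t) = py;
          if (has_lik) st.L1(i, t) = newL; else refresh_L1(m, st, i, t);
        }
      }
    }
  }
}

// ---- detection / movement-scale parameter updates ------------------------

static double alive_loglik_total(const Model& m, State& st, double lambda0, double sigma_p) {
  double tot = 0.0;
  for (int i = 0; i < m.M; ++i) {
    if (st.entry[i] == 0) continue;
    for (int t = st.entry[i] - 1; t < std::min(st.death[i] - 1, m.T); ++t) {
      double sxv = (m.movement == CONSTANT) ? st.sx(i, 0) : st.sx(i, t);
      double syv = (m.movement == CONSTANT) ? st.sy(i, 0) : st.sy(i, t);
      tot += period_loglik(m, i, t, sxv, syv, lambda0, sigma_p);
    }
  }
  return tot;
}

static void update_detection(const Model& m, State& st,
                             double& l0_lscale, double& sp_lscale,
                             int& l0_acc, int& l0_try, int& sp_acc, int& sp_try) {
  // lambda0: log-scale RW-MH, Uniform(0, lambda0_max) prior
  {
    double cur = st.lambda0;
    double prop = cur * std::exp(R::rnorm(0.0, std::exp(l0_lscale)));
    l0_try++;
    if (prop > 0 && prop < m.lambda0_max) {
      double lr = alive_loglik_total(m, st, prop, st.sigma_p) -
                  alive_loglik_total(m, st, cur, st.sigma_p) +
                  std::log(prop) - std::log(cur); // log-scale proposal Jacobian
      if (std::log(R::runif(0.0, 1.0)) < lr) { st.lambda0 = prop; l0_acc++; }
    }
  }
  {
    double cur = st.sigma_p;
    double prop = cur * std::exp(R::rnorm(0.0, std::exp(sp_lscale)));
    sp_try++;
    if (prop > 0 && prop < m.sigma_p_max) {
      double lr = alive_loglik_total(m, st, st.lambda0, prop) -
                  alive_loglik_total(m, st, st.lambda0, cur) +
                  std::log(prop) - std::log(cur);
      if (std::log(R::runif(0.0, 1.0)) < lr) { st.sigma_p = prop; sp_acc++; }
    }
  }
}

static double walk_prior_total(const Model& m, State& st, double sigma_s) {
  double tot = 0.0;
  for (int i = 0; i < m.M; ++i)
    for (int t = 1; t < m.T; ++t)
      tot += walk_logdens(m, st.sx(i, t - 1), st.sy(i, t - 1),
                          st.sx(i, t), st.sy(i, t), sigma_s);
  return tot;
}

static void update_sigma_s(const Model& m, State& st, double& ss_lscale,
                           int& ss_acc, int& ss_try) {
  double cur = st.sigma_s;
  double prop = cur * std::exp(R::rnorm(0.0, std::exp(ss_lscale)));
  ss_try++;
  if (prop <= 0 || prop >= m.sigma_s_max) return;
  double lr = walk_prior_total(m, st, prop) - walk_prior_total(m, st, cur) +
              std::log(prop) - std::log(cur);
  if (std::log(R::runif(0.0, 1.0)) < lr) { st.sigma_s = prop; ss_acc++; }
}

// ---- driver --------------------------------------------------------------

static void adapt_scale(double& lscale, int acc, int tries, double target = 0.35) {
  if (tries == 0) return;
  double rate = double(acc) / double(tries);
  lscale += (rate - target);
  lscale = std::min(std::max(lscale, -8.0), 4.0);
}

// [[Rcpp::export]]
List run_mcmc_cpp(IntegerVector y_flat, IntegerVector dims, IntegerMatrix Kmat,
                  NumericVector trapx, NumericVector trapy,
                  NumericVector Sbounds, int movement, bool cjs,
                  NumericVector delta_t,
                  NumericVector prior_max, // lambda0_max, sigma_p_max, sigma_s_max
                  int n_iter, int n_burnin, int thin,
                  List inits, bool fix_detection, bool fix_centers,
                  bool save_z, IntegerVector first_det_in) {
  Model m;
  m.M = dims[0]; m.J = dims[1]; m.T = dims[2];
  m.y = y_flat; m.K = Kmat; m.trapx = trapx; m.trapy = trapy;
  m.xmin = Sbounds[0]; m.xmax = Sbounds[1]; m.ymin = Sbounds[2]; m.ymax = Sbounds[3];
  m.movement = movement; m.cjs = cjs;
  m.delta = delta_t;
  m.equal_spacing = true;
  for (int t = 0; t < m.T - 1; ++t) if (delta_t[t] != 1.0) m.equal_spacing = false;
  m.lambda0_max = prior_max[0]; m.sigma_p_max = prior_max[1]; m.sigma_s_max = prior_max[2];

  State st;
  st.entry = as<std::vector<int>>(inits["entry"]);
  st.death = as<std::vector<int>>(inits["death"]);
  st.sx = clone(as<NumericMatrix>(inits["sx"]));
  st.sy = clone(as<NumericMatrix>(inits["sy"]));
  st.phi = as<double>(inits["phi"]);
  st.lambda0 = as<double>(inits["lambda0"]);
  st.sigma_p = as<double>(inits["sigma_p"]);
  st.sigma_s = as<double>(inits["sigma_s"]);
  st.gamma = as<std::vector<double>>(inits["gamma"]);
  st.L1 = NumericMatrix(m.M, m.T);
  st.phi_int.resize(std::max(m.T - 1, 1));
  refresh_phi_int(m, st);

  IntegerMatrix has_det(m.M, m.T);
  IntegerVector first_det = clone(first_det_in);
  for (int i = 0; i < m.M; ++i)
    for (int t = 0; t < m.T; ++t) {
      int any = 0;
      for (int j = 0; j < m.J; ++j) if (m.yy(i, j, t) > 0) { any = 1; break; }
      has_det(i, t) = any;
    }

  refresh_L1_all(m, st);

  int n_keep = (n_iter - n_burnin) / thin;
  int npar = 1 + (cjs ? 0 : m.T) + 2 + 1 + (cjs ? 0 : m.T); // phi, gamma, l0, sp, ss, N
  NumericMatrix draws(n_keep, npar);
  IntegerMatrix zdraws(save_z ? n_keep : 0, save_z ? m.M * m.T : 0);

  double s_lscale = std::log(0.5), l0_lscale = std::log(0.3),
         sp_lscale = std::log(0.2), ss_lscale = std::log(0.3),
         phi_lscale = std::log(0.3);
  long s_acc = 0, s_try = 0;
  int l0_acc = 0, l0_try = 0, sp_acc = 0, sp_try = 0, ss_acc = 0, ss_try = 0,
      phi_acc = 0, phi_try = 0;
  std::vector<double> work;
  std::vector<int> es, ds;
  work.reserve(m.T * (m.T + 1) / 2 + 1);
  int kept = 0;
  bool hit_M = false;

  RNGScope scope;
  for (int it = 0; it < n_iter; ++it) {
    if (!fix_detection) {
      update_detection(m, st, l0_lscale, sp_lscale, l0_acc, l0_try, sp_acc, sp_try);
      refresh_L1_all(m, st);
    }
    if (!fix_centers) {
      update_centers(m, st, s_lscale, s_acc, s_try);
      if (m.movement == MARKOVIAN) update_sigma_s(m, st, ss_lscale, ss_acc, ss_try);
    }
    update_z(m, st, has_det, first_det, work, es, ds);
    update_phi(m, st, phi_lscale, phi_acc, phi_try);
    if (!cjs) update_gamma(m, st);

    if (it < n_burnin && (it + 1) % 50 == 0) {
      adapt_scale(s_lscale, int(s_acc), int(s_try));
      adapt_scale(l0_lscale, l0_acc, l0_try);
      adapt_scale(sp_lscale, sp_acc, sp_try);
      adapt_scale(ss_lscale, ss_acc, ss_try);
      adapt_scale(phi_lscale, phi_acc, phi_try);
      s_acc = s_try = 0; l0_acc = l0_try = 0; sp_acc = sp_try = 0;
      ss_acc = ss_try = 0; phi_acc = phi_try = 0;
    }

    if (it >= n_burnin && (it - n_burnin) % thin == 0 && kept < n_keep) {
      int c = 0;
      draws(kept, c++) = st.phi;
      if (!cjs) for (int t = 0; t < m.T; ++t) draws(kept, c++) = st.gamma[t];
      draws(kept, c++) = st.lambda0;
      draws(kept, c++) = st.sigma_p;
      draws(kept, c++) = st.sigma_s;
      if (!cjs) {
        for (int t = 0; t < m.T; ++t) {
          int N = 0;
          for (int i = 0; i < m.M; ++i) if (alive_at(st, i, t)) ++N;
          draws(kept, c++) = N;
          if (N >= m.M) hit_M = true;
        }
      }
      if (save_z) {
        for (int i = 0; i < m.M; ++i)
          for (int t = 0; t < m.T; ++t)
            zdraws(kept, i + m.M * t) = alive_at(st, i, t) ? 1 : 0;
      }
      ++kept;
    }
  }

  return List::create(
    _["draws"] = draws,
    _["z_draws"] = zdraws,
    _["hit_M"] = hit_M,
    _["accept"] = NumericVector::create(
      _["centers"] = s_try > 0 ? double(s_acc) / double(s_try) : NA_REAL,
      _["lambda0"] = l0_try > 0 ? double(l0_acc) / double(l0_try) : NA_REAL,
      _["sigma_p"] = sp_try > 0 ? double(sp_acc) / double(sp_try) : NA_REAL,
      _["sigma_s"] = ss_try > 0 ? double(ss_acc) / double(ss_try) : NA_REAL)
  );
}
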