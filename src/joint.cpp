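#include "core.h"
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Joint hierarchical model over both tasks.
//
// Unconstrained parameter vector layout (subject-major):
//   [0, N*pts)                two-step subject parameters
//   [ts_grp, ts_grp+n_tg)     two-step group parameters
//   [g_sub, g_sub+N*pg)       gambling subject parameters
//   [g_grp, g_grp+n_gg)       gambling group parameters
//
// hybrid subject (pts=6):   logit-alpha, beta_mb, beta_mf, beta_2, p, beta_bias
// hybrid group (16):        mu x5 (a, mb, mf, b2, p), log-sd x5,
//                           coupling mb x3 (loss, risk, theta), coupling mf x3
// regression subject (4):   b_stay, b_reward, b_common, b_reward_common
// regression group (20):    mu x4, log-sd x4, g x12 (feature-major:
//                           {1, reward, common, reward*common} x {loss, risk, theta})
// PT subject (4):           log-kappa, log-gamma_m, log-gamma_g, log-theta
// PT group (8):             mu_log_kappa, mu_gamma_m, mu_gamma_g, mu_theta,
//                           log-sd x4
// MV subject (3):           log-kappa, log-w, log-theta
// MV group (6):             mu x3, log-sd x3
//
// Subject-level priors: Gaussian hierarchies on logit-alpha, the betas and the
// regression coefficients (beta_mb/beta_mf means shifted by the coupling terms
// applied to per-draw z-scored covariates), N(0, 10^2) on beta_bias,
// log-normal kappa, and zero-truncated Gaussians for gamma/w/theta.
// ---------------------------------------------------------------------------

struct JointModel {
  int N;
  int ts_model;   // 0 regression, 1 hybrid
  int g_model;    // 0 prospect theory, 1 mean-variance
  double psm;     // prior scale multiplier on all mean-effect priors
  double lambda, baseline, p_common;
  bool has_fixed_z;
  std::vector<double> zfix;   // N x 3 column-major, when has_fixed_z

  std::vector<TwoStepTrials> ts;                 // hybrid data
  // regression data as sufficient statistics: the features take at most four
  // distinct patterns (reward x common), so per subject we keep the pattern
  // rows (regX, row-major, 4 per pattern), the trial counts (regN) and the
  // stay counts (regY1)
  std::vector<std::vector<double>> regX;
  std::vector<std::vector<double>> regN, regY1;
  std::vector<GambleTrials> gam;

  int pts, n_tg, pg, n_gg;
  int ts_grp, g_sub, g_grp, n_theta;

  void init_layout() {
    pts = ts_model == 1 ? 6 : 4;
    n_tg = ts_model == 1 ? 16 : 20;
    pg = g_model == 0 ? 4 : 3;
    n_gg = g_model == 0 ? 8 : 6;
    ts_grp = N * pts;
    g_sub = ts_grp + n_tg;
    g_grp = g_sub + N * pg;
    n_theta = g_grp + n_gg;
  }

  // Covariates (log loss aversion, risk measure, inverse temperature),
  // z-scored across subjects within the current draw (population SD).
  // Returns false when a covariate is constant across subjects.
  bool compute_z(const double* th, std::vector<double>& z) const {
    z.resize(3 * N);
    if (has_fixed_z) { z = zfix; return true; }
    for (int c = 0; c < 3; ++c) {
      double m = 0.0;
      for (int i = 0; i < N; ++i) {
        const double* p = th + g_sub + i * pg;
        double v;
        if (g_model == 0)
          v = (c == 0) ? p[0] : (c == 1 ? 1.0 - std::exp(p[2]) : std::exp(p[3]));
        else
          v = (c == 0) ? p[0] : (c == 1 ? std::exp(p[1]) : std::exp(p[2]));
        z[c * N + i] = v;
        m += v;
      }
      m /= N;
      double s2 = 0.0;
      for (int i = 0; i < N; ++i) {
        z[c * N + i] -= m;
        s2 += z[c * N + i] * z[c * N + i];
      }
      double s = std::sqrt(s2 / N);
      if (!(s > 0.0) || !R_finite(s)) return false;
      for (int i = 0; i < N; ++i) z[c * N + i] /= s;
    }
    return true;
  }

  double ll_ts(int i, const double* th, const std::vector<double>& z) const {
    if (ts_model == 1) {
      const double* p = th + i * pts;
      HybridParams par{1.0 / (1.0 + std::exp(-p[0])), p[1], p[2], p[3], p[4],
                       p[5], lambda, baseline, p_common};
      // hybrid_run only writes into the trial arrays in simulate mode
      return hybrid_run(const_cast<TwoStepTrials&>(ts[i]), par, false,
                        nullptr, 0, nullptr, nullptr, nullptr);
    }
    const double* b = th + i * pts;
    const double* g = th + ts_grp + 8;
    double eff[4];
    for (int k = 0; k < 4; ++k)
      eff[k] = b[k] + g[3 * k] * z[i] + g[3 * k + 1] * z[N + i] +
               g[3 * k + 2] * z[2 * N + i];
    const std::vector<double>& X = regX[i];
    const std::vector<double>& n = regN[i];
    const std::vector<double>& y1 = regY1[i];
    int np = static_cast<int>(n.size());
    double ll = 0.0;
    for (int r = 0; r < np; ++r) {
      const double* f = X.data() + 4 * r;
      double eta = f[0] * eff[0] + f[1] * eff[1] + f[2] * eff[2] + f[3] * eff[3];
      ll += y1[r] * eta - n[r] * log1pexp(eta);
    }
    return ll;
  }

  double ll_g(int i, const double* th) const {
    const double* p = th + g_sub + i * pg;
    double pars[4];
    if (g_model == 0) {
      pars[0] = std::exp(p[0]); pars[1] = std::exp(p[1]);
      pars[2] = std::exp(p[2]); pars[3] = std::exp(p[3]);
    } else {
      pars[0] = std::exp(p[0]); pars[1] = std::exp(p[1]);
      pars[2] = std::exp(p[2]);
    }
    return gamble_loglik_core(gam[i], g_model, pars);
  }

  // Coupled prior terms for one hybrid subject's beta_mb and beta_mf.
  double coupling_terms(int i, const double* th,
                        const std::vector<double>& z) const {
    const double* p = th + i * pts;
    const double* gr = th + ts_grp;
    double sd_mb = std::exp(gr[6]), sd_mf = std::exp(gr[7]);
    double zi0 = z[i], zi1 = z[N + i], zi2 = z[2 * N + i];
    double m_mb = gr[1] + gr[10] * zi0 + gr[11] * zi1 + gr[12] * zi2;
    double m_mf = gr[2] + gr[13] * zi0 + gr[14] * zi1 + gr[15] * zi2;
    return ldnorm(p[1], m_mb, sd_mb) + ldnorm(p[2], m_mf, sd_mf);
  }

  double coupling_sum(const double* th, const std::vector<double>& z) const {
    if (ts_model != 1) return 0.0;
    double s = 0.0;
    for (int i = 0; i < N; ++i) s += coupling_terms(i, th, z);
    return s;
  }

  double prior_ts_sub(int i, const double* th,
                      const std::vector<double>& z) const {
    const double* p = th + i * pts;
    const double* gr = th + ts_grp;
    if (ts_model == 1) {
      double s = ldnorm(p[0], gr[0], std::exp(gr[5]))        // logit-alpha
               + ldnorm(p[3], gr[3], std::exp(gr[8]))        // beta_2
               + ldnorm(p[4], gr[4], std::exp(gr[9]))        // perseveration
               + ldnorm(p[5], 0.0, 10.0);                    // beta_bias
      return s + coupling_terms(i, th, z);
    }
    double s = 0.0;
    for (int k = 0; k < 4; ++k)
      s += ldnorm(p[k], gr[k], std::exp(gr[4 + k]));
    return s;
  }

  double prior_g_sub(int i, const double* th) const {
    const double* p = th + g_sub + i * pg;
    const double* gr = th + g_grp;
    if (g_model == 0) {
      return ldnorm(p[0], gr[0], std::exp(gr[4]))                 // log kappa
           + ltruncnorm_logscale(p[1], gr[1], std::exp(gr[5]))    // gamma_m
           + ltruncnorm_logscale(p[2], gr[2], std::exp(gr[6]))    // gamma_g
           + ltruncnorm_logscale(p[3], gr[3], std::exp(gr[7]));   // theta
    }
    return ldnorm(p[0], gr[0], std::exp(gr[3]))
         + ltruncnorm_logscale(p[1], gr[1], std::exp(gr[4]))      // w
         + ltruncnorm_logscale(p[2], gr[2], std::exp(gr[5]));     // theta
  }

  double prior_group(const double* th) const {
    const double* gr = th + ts_grp;
    double s = 0.0;
    if (ts_model == 1) {
      s += ldnorm(gr[0], 0.0, 5.0 * psm);                 // mu logit-alpha
      for (int k = 1; k < 5; ++k) s += ldnorm(gr[k], 0.0, 10.0 * psm);
      for (int k = 5; k < 10; ++k) s += lhalfcauchy_logscale(gr[k], 2.5);
      for (int k = 10; k < 16; ++k) s += ldnorm(gr[k], 0.0, 10.0 * psm);
    } else {
      for (int k = 0; k < 4; ++k) s += ldnorm(gr[k], 0.0, 2.0 * psm);
      for (int k = 4; k < 8; ++k) s += lhalfcauchy_logscale(gr[k], 2.5);
      for (int k = 8; k < 20; ++k) s += ldnorm(gr[k], 0.0, 2.0 * psm);
    }
    const double* gg = th + g_grp;
    if (g_model == 0) {
      s += ldnorm(gg[0], 0.0, 2.0 * psm) + ldnorm(gg[1], 0.0, 2.0 * psm) +
           ldnorm(gg[2], 0.0, 2.0 * psm) + ldnorm(gg[3], 0.0, 10.0 * psm);
      for (int k = 4; k < 8; ++k) s += lhalfcauchy_logscale(gg[k], 2.5);
    } else {
      s += ldnorm(gg[0], 0.0, 2.0 * psm) + ldnorm(gg[1], 0.0, 2.0 * psm) +
           ldnorm(gg[2], 0.0, 10.0 * psm);
      for (int k = 3; k < 6; ++k) s += lhalfcauchy_logscale(gg[k], 2.5);
    }
    return s;
  }
};

static JointModel build_model(List data, List opts) {
  JointModel m;
  m.ts_model = as<int>(opts["ts_model"]);
  m.g_model = as<int>(opts["g_model"]);
  m.psm = as<double>(opts["psm"]);
  m.lambda = as<double>(opts["lambda"]);
  m.baseline = as<double>(opts["baseline"]);
  m.p_common = as<double>(opts["p_common"]);

  List tsd = data["ts"], gd = data["gamble"];
  m.N = tsd.size();
  if (m.ts_model == 1) {
    m.ts.resize(m.N);
    for (int i = 0; i < m.N; ++i) {
      List s = tsd[i];
      IntegerVector c1 = s["c1"], s2 = s["s2"], c2 = s["c2"];
      NumericVector r = s["r"];
      TwoStepTrials& d = m.ts[i];
      int n = c1.size();
      d.c1.assign(c1.begin(), c1.end());
      d.s2.assign(s2.begin(), s2.end());
      d.c2.assign(c2.begin(), c2.end());
      d.r.assign(r.begin(), r.end());
      (void)n;
    }
  } else {
    m.regX.resize(m.N); m.regN.resize(m.N); m.regY1.resize(m.N);
    for (int i = 0; i < m.N; ++i) {
      List s = tsd[i];
      NumericMatrix X = s["X"];
      NumericVector n = s["n"], y1 = s["y1"];
      int np = X.nrow();
      m.regX[i].resize(4 * np);
      for (int r = 0; r < np; ++r)
        for (int k = 0; k < 4; ++k) m.regX[i][4 * r + k] = X(r, k);
      m.regN[i].assign(n.begin(), n.end());
      m.regY1[i].assign(y1.begin(), y1.end());
    }
  }
  m.gam.resize(m.N);
  for (int i = 0; i < m.N; ++i) {
    List s = gd[i];
    NumericVector g1 = s["g1"], g2 = s["g2"], su = s["sure"];
    IntegerVector mx = s["mixed"], ch = s["choice"];
    GambleTrials& d = m.gam[i];
    d.g1.assign(g1.begin(), g1.end());
    d.g2.assign(g2.begin(), g2.end());
    d.sure.assign(su.begin(), su.end());
    d.mixed.assign(mx.begin(), mx.end());
    d.choice.assign(ch.begin(), ch.end());
  }

  m.has_fixed_z = false;
  if (opts.containsElementNamed("fixed_z") && !Rf_isNull(opts["fixed_z"])) {
    NumericMatrix zf = opts["fixed_z"];
    m.has_fixed_z = true;
    m.zfix.resize(3 * m.N);
    for (int c = 0; c < 3; ++c)
      for (int i = 0; i < m.N; ++i) m.zfix[c * m.N + i] = zf(i, c);
  }
  m.init_layout();
  return m;
}

// [[Rcpp::export]]
List cpp_joint_logpost(List data, List opts, NumericVector theta) {
  JointModel m = build_model(data, opts);
  if (theta.size() != m.n_theta)
    stop("theta has length %d, expected %d", theta.size(), m.n_theta);
  const double* th = theta.begin();
  for (int j = 0; j < m.n_theta; ++j)
    if (!R_finite(th[j]))
      return List::create(_["logpost"] = R_NegInf, _["loglik"] = R_NegInf,
                          _["logprior"] = R_NegInf);
  std::vector<double> z;
  if (!m.compute_z(th, z))
    return List::create(_["logpost"] = R_NegInf, _["loglik"] = R_NegInf,
                        _["logprior"] = R_NegInf);
  double ll = 0.0, lp = m.prior_group(th);
  for (int i = 0; i < m.N; ++i) {
    ll += m.ll_ts(i, th, z) + m.ll_g(i, th);
    lp += m.prior_ts_sub(i, th, z) + m.prior_g_sub(i, th);
  }
  double post = ll + lp;
  if (!R_finite(post)) post = R_NegInf;
  return List::create(_["logpost"] = post, _["loglik"] = ll,
                      _["logprior"] = lp);
}

// ---------------------------------------------------------------------------
// Adaptive Metropolis-within-Gibbs.
//
// Update blocks per scan:
//   - every two-step subject parameter, one at a time (subject-local
//     likelihood plus its own prior term);
//   - each subject's gambling parameters as one joint proposal (gambling
//     likelihood, own priors, and, because the z-scored covariates shift,
//     either every coupled beta_mb/beta_mf prior term (hybrid) or every
//     regression likelihood);
//   - each group-level parameter, one at a time;
//   - translation moves shifting a group mean together with all of its
//     subject-level values (and log kappa jointly with its mean), which
//     decorrelates the group means from the subject block.
// Proposal scales adapt toward fixed acceptance targets during warmup only.
// ---------------------------------------------------------------------------

struct MwgState {
  std::vector<double> theta;
  std::vector<double> ts_ll, g_ll;
  std::vector<double> z;
};

// 2-D adaptive-covariance proposal state for a (mu, log-sd) hierarchy pair.
struct AmState {
  int idx0, idx1;
  double ls = 0.0;                         // log global scale
  long n = 0;
  double m0 = 0, m1 = 0, c00 = 0, c01 = 0, c11 = 0;
  double l11 = 0.2, l21 = 0, l22 = 0.2;    // proposal Cholesky (lower)
  void update(double x0, double x1) {
    ++n;
    double d0 = x0 - m0, d1 = x1 - m1;
    m0 += d0 / n; m1 += d1 / n;
    c00 += d0 * (x0 - m0); c01 += d0 * (x1 - m1); c11 += d1 * (x1 - m1);
    if (n > 100) {
      double f = 2.88 / (n - 1);           // 2.4^2 / d with d = 2
      double a = f * c00 + 1e-6, b = f * c01, cc = f * c11 + 1e-6;
      l11 = std::sqrt(a); l21 = b / l11;
      double rem = cc - l21 * l21;
      l22 = std::sqrt(rem > 1e-12 ? rem : 1e-12);
    }
  }
};

// d-dimensional adaptive-covariance proposal for a subject's gambling block.
struct AmBlock {
  int d; long n = 0;
  std::vector<double> mean, scat, L;
  double ls;
  AmBlock(int d_, double ls0) : d(d_), mean(d_, 0), scat(d_ * d_, 0),
                                L(d_ * d_, 0), ls(ls0) {
    for (int i = 0; i < d; ++i) L[i * d + i] = 1.0;
  }
  void update(const double* x) {
    ++n;
    std::vector<double> dlt(d);
    for (int i = 0; i < d; ++i) dlt[i] = x[i] - mean[i];
    for (int i = 0; i < d; ++i) mean[i] += dlt[i] / n;
    for (int i = 0; i < d; ++i)
      for (int j = 0; j <= i; ++j) scat[i * d + j] += dlt[i] * (x[j] - mean[j]);
    if (n > 150 && n % 25 == 0) {
      double f = 5.76 / d / (n - 1);       // 2.4^2 / d scaling
      std::vector<double> A(d * d, 0), C(d * d, 0);
      for (int i = 0; i < d; ++i)
        for (int j = 0; j <= i; ++j) A[i * d + j] = f * scat[i * d + j];
      for (int i = 0; i < d; ++i) A[i * d + i] += 1e-6;
      for (int i = 0; i < d; ++i) {
        for (int j = 0; j <= i; ++j) {
          double sum = A[i * d + j];
          for (int k = 0; k < j; ++k) sum -= C[i * d + k] * C[j * d + k];
          if (i == j) {
            C[i * d + i] = std::sqrt(sum > 1e-12 ? sum : 1e-12);
          } else C[i * d + j] = sum / C[j * d + j];
        }
      }
      L = C;
    }
  }
  void step(double* out) const {
    double sc = std::exp(ls);
    std::vector<double> z(d);
    for (int i = 0; i < d; ++i) z[i] = R::norm_rand();
    for (int i = 0; i < d; ++i) {
      double s = 0;
      for (int j = 0; j <= i; ++j) s += L[i * d + j] * z[j];
      out[i] = sc * s;
    }
  }
};

// [[Rcpp::export]]
List cpp_run_chain(List data, List opts, NumericVector theta0, int warm_scans,
                   int n_keep, int thin) {
  JointModel m = build_model(data, opts);
  if (theta0.size() != m.n_theta) stop("bad theta0 length");
  RNGScope scope;

  MwgState st;
  st.theta.assign(theta0.begin(), theta0.end());
  if (!m.compute_z(st.theta.data(), st.z)) stop("degenerate covariates at init");
  st.ts_ll.resize(m.N); st.g_ll.resize(m.N);
  for (int i = 0; i < m.N; ++i) {
    st.ts_ll[i] = m.ll_ts(i, st.theta.data(), st.z);
    st.g_ll[i] = m.ll_g(i, st.theta.data());
  }

  // translation moves: (group-mean index, subject parameter offset)
  std::vector<std::pair<int, int>> trans;
  int n_mu_ts = (m.ts_model == 1) ? 5 : 4;
  for (int k = 0; k < n_mu_ts; ++k) trans.push_back({m.ts_grp + k, k});
  trans.push_back({m.g_grp + 0, -1});  // log kappa, flagged by -1

  // scale moves: (log-sd index, subject parameter offset; -1 = log kappa)
  std::vector<std::pair<int, int>> scales;
  for (int k = 0; k < n_mu_ts; ++k)
    scales.push_back({m.ts_grp + n_mu_ts + k, k});
  scales.push_back({m.g_grp + m.pg, -1});  // sigma_log_kappa

  // adapted 2-D moves for the gambling (mu, log-sd) hierarchy pairs
  std::vector<AmState> hier_am(m.pg);
  for (int k = 0; k < m.pg; ++k) {
    hier_am[k].idx0 = m.g_grp + k;
    hier_am[k].idx1 = m.g_grp + m.pg + k;
  }
  // adapted covariance blocks for each subject's gambling parameters
  std::vector<AmBlock> gb_am(m.N, AmBlock(m.pg, std::log(0.10)));

  std::vector<double> ls(m.n_theta, std::log(0.2));
  std::vector<double> ls_tr(trans.size(), std::log(0.15));
  std::vector<double> ls_sc(scales.size(), std::log(0.15));
  std::vector<double> ls_tn(2 * (m.pg - 1), std::log(0.10));
  const double targ_sc = 0.44, targ_bl = 0.25, targ_tr = 0.35;

  NumericMatrix draws(n_keep, m.n_theta);
  std::vector<double> zs(3 * m.N), prop(m.pg);
  std::vector<double> new_ts_ll(m.N);
  long n_acc = 0, n_prop = 0;

  int total_scans = warm_scans + n_keep * thin;
  for (int scan = 0; scan < total_scans; ++scan) {
    bool adapting = scan < warm_scans;
    double eta = 1.0 / std::pow(scan + 2.0, 0.6);
    double* th = st.theta.data();

    // -- two-step subject scalars ------------------------------------------
    for (int i = 0; i < m.N; ++i) {
      for (int k = 0; k < m.pts; ++k) {
        int idx = i * m.pts + k;
        double old = th[idx];
        double old_p = m.prior_ts_sub(i, th, st.z);
        th[idx] = old + std::exp(ls[idx]) * R::norm_rand();
        double new_ll = m.ll_ts(i, th, st.z);
        double d = new_ll + m.prior_ts_sub(i, th, st.z) - st.ts_ll[i] - old_p;
        double ap = R_finite(d) ? std::min(1.0, std::exp(d)) : 0.0;
        ++n_prop;
        if (R::unif_rand() < ap) { st.ts_ll[i] = new_ll; ++n_acc; }
        else th[idx] = old;
        if (adapting) ls[idx] += eta * (ap - targ_sc);
      }
    }

    // -- gambling subject blocks (adapted covariance proposals) -------------
    for (int i = 0; i < m.N; ++i) {
      int off = m.g_sub + i * m.pg;
      if (adapting) gb_am[i].update(th + off);
      for (int k = 0; k < m.pg; ++k) prop[k] = th[off + k];
      double old_part = st.g_ll[i] + m.prior_g_sub(i, th);
      double old_z_part = 0.0;
      if (!m.has_fixed_z) {
        if (m.ts_model == 1) old_z_part = m.coupling_sum(th, st.z);
        else { for (int j = 0; j < m.N; ++j) old_z_part += st.ts_ll[j]; }
      }
      std::vector<double> old_vals(prop), stp(m.pg);
      gb_am[i].step(stp.data());
      for (int k = 0; k < m.pg; ++k) th[off + k] += stp[k];

      double ap = 0.0;
      bool ok = m.has_fixed_z ? (zs = st.z, true) : m.compute_z(th, zs);
      if (ok) {
        double new_part = m.ll_g(i, th) + m.prior_g_sub(i, th);
        double new_z_part = 0.0;
        if (!m.has_fixed_z) {
          if (m.ts_model == 1) new_z_part = m.coupling_sum(th, zs);
          else {
            for (int j = 0; j < m.N; ++j) {
              new_ts_ll[j] = m.ll_ts(j, th, zs);
              new_z_part += new_ts_ll[j];
            }
          }
        }
        double d = new_part + new_z_part - old_part - old_z_part;
        ap = R_finite(d) ? std::min(1.0, std::exp(d)) : 0.0;
      }
      ++n_prop;
      if (ok && R::unif_rand() < ap) {
        st.g_ll[i] = m.ll_g(i, th);
        if (!m.has_fixed_z) {
          st.z = zs;
          if (m.ts_model == 0) st.ts_ll = new_ts_ll;
        }
        ++n_acc;
      } else {
        for (int k = 0; k < m.pg; ++k) th[off + k] = old_vals[k];
      }
      if (adapting) gb_am[i].ls += eta * (ap - targ_bl);
    }

    // -- gambling subject scalars (marginal moves along each coordinate,
    //    which mix the correlated utility parameters faster than the joint
    //    block alone) ---------------------------------------------------------
    for (int i = 0; i < m.N; ++i) {
      for (int k = 0; k < m.pg; ++k) {
        int idx = m.g_sub + i * m.pg + k;
        double old = th[idx];
        double old_part = st.g_ll[i] + m.prior_g_sub(i, th);
        double old_z_part = 0.0;
        if (!m.has_fixed_z) {
          if (m.ts_model == 1) old_z_part = m.coupling_sum(th, st.z);
          else { for (int j = 0; j < m.N; ++j) old_z_part += st.ts_ll[j]; }
        }
        th[idx] = old + std::exp(ls[idx]) * R::norm_rand();
        double ap = 0.0;
        bool ok = m.has_fixed_z ? (zs = st.z, true) : m.compute_z(th, zs);
        double new_gll = 0.0;
        if (ok) {
          new_gll = m.ll_g(i, th);
          double new_part = new_gll + m.prior_g_sub(i, th);
          double new_z_part = 0.0;
          if (!m.has_fixed_z) {
            if (m.ts_model == 1) new_z_part = m.coupling_sum(th, zs);
            else {
              for (int j = 0; j < m.N; ++j) {
                new_ts_ll[j] = m.ll_ts(j, th, zs);
                new_z_part += new_ts_ll[j];
              }
            }
          }
          double d = new_part + new_z_part - old_part - old_z_part;
          ap = R_finite(d) ? std::min(1.0, std::exp(d)) : 0.0;
        }
        ++n_prop;
        if (ok && R::unif_rand() < ap) {
          st.g_ll[i] = new_gll;
          if (!m.has_fixed_z) {
            st.z = zs;
            if (m.ts_model == 0) st.ts_ll = new_ts_ll;
          }
          ++n_acc;
        } else th[idx] = old;
        if (adapting) ls[idx] += eta * (ap - targ_sc);
      }
    }

    // -- group-level scalars ------------------------------------------------
    for (int idx = m.ts_grp; idx < m.n_theta; ++idx) {
      if (idx >= m.g_sub && idx < m.g_grp) { idx = m.g_grp - 1; continue; }
      bool is_reg_g = (m.ts_model == 0) &&
                      (idx >= m.ts_grp + 8 && idx < m.ts_grp + 20);
      bool is_ts_grp = idx < m.g_sub;
      double old = th[idx];
      double old_part = m.prior_group(th);
      if (is_reg_g) { for (int j = 0; j < m.N; ++j) old_part += st.ts_ll[j]; }
      else if (is_ts_grp)
        for (int j = 0; j < m.N; ++j) old_part += m.prior_ts_sub(j, th, st.z);
      else
        for (int j = 0; j < m.N; ++j) old_part += m.prior_g_sub(j, th);

      th[idx] = old + std::exp(ls[idx]) * R::norm_rand();
      double new_part = m.prior_group(th);
      if (is_reg_g) {
        for (int j = 0; j < m.N; ++j) {
          new_ts_ll[j] = m.ll_ts(j, th, st.z);
          new_part += new_ts_ll[j];
        }
      } else if (is_ts_grp)
        for (int j = 0; j < m.N; ++j) new_part += m.prior_ts_sub(j, th, st.z);
      else
        for (int j = 0; j < m.N; ++j) new_part += m.prior_g_sub(j, th);

      double d = new_part - old_part;
      double ap = R_finite(d) ? std::min(1.0, std::exp(d)) : 0.0;
      ++n_prop;
      if (R::unif_rand() < ap) {
        if (is_reg_g) st.ts_ll = new_ts_ll;
        ++n_acc;
      } else th[idx] = old;
      if (adapting) ls[idx] += eta * (ap - targ_sc);
    }

    // -- translation moves ---------------------------------------------------
    for (size_t mIdx = 0; mIdx < trans.size(); ++mIdx) {
      int mu_idx = trans[mIdx].first, sub_k = trans[mIdx].second;
      double delta = std::exp(ls_tr[mIdx]) * R::norm_rand();
      bool gamble_side = sub_k < 0;
      double old_part = m.prior_group(th);
      if (gamble_side) for (int j = 0; j < m.N; ++j) old_part += st.g_ll[j];
      else for (int j = 0; j < m.N; ++j) old_part += st.ts_ll[j];

      th[mu_idx] += delta;
      if (gamble_side)
        for (int j = 0; j < m.N; ++j) th[m.g_sub + j * m.pg] += delta;
      else
        for (int j = 0; j < m.N; ++j) th[j * m.pts + sub_k] += delta;

      double new_part = m.prior_group(th);
      for (int j = 0; j < m.N; ++j)
        new_ts_ll[j] = gamble_side ? m.ll_g(j, th) : m.ll_ts(j, th, st.z);
      for (int j = 0; j < m.N; ++j) new_part += new_ts_ll[j];

      double d = new_part - old_part;
      double ap = R_finite(d) ? std::min(1.0, std::exp(d)) : 0.0;
      ++n_prop;
      if (R::unif_rand() < ap) {
        if (gamble_side) st.g_ll = new_ts_ll; else st.ts_ll = new_ts_ll;
        ++n_acc;
      } else {
        th[mu_idx] -= delta;
        if (gamble_side)
          for (int j = 0; j < m.N; ++j) th[m.g_sub + j * m.pg] -= delta;
        else
          for (int j = 0; j < m.N; ++j) th[j * m.pts + sub_k] -= delta;
      }
      if (adapting) ls_tr[mIdx] += eta * (ap - targ_tr);
    }

    // -- scale moves: rescale a group SD together with its subjects'
    //    residuals (b_i <- m_i + c (b_i - m_i), log-sd <- log-sd + log c),
    //    which decorrelates the group scales from the subject block. The
    //    subject-value transformation contributes a Jacobian of N log c.
    for (size_t sIdx = 0; sIdx < scales.size(); ++sIdx) {
      int lsd_idx = scales[sIdx].first, sub_k = scales[sIdx].second;
      double delta = std::exp(ls_sc[sIdx]) * R::norm_rand();
      double c = std::exp(delta);
      bool gamble_side = sub_k < 0;

      double old_part = m.prior_group(th);
      if (gamble_side) {
        for (int j = 0; j < m.N; ++j)
          old_part += st.g_ll[j] + m.prior_g_sub(j, th);
      } else {
        for (int j = 0; j < m.N; ++j)
          old_part += st.ts_ll[j] + m.prior_ts_sub(j, th, st.z);
      }

      // per-subject prior means (coupled for beta_mb / beta_mf)
      std::vector<double> mvec(m.N);
      const double* gr = th + m.ts_grp;
      for (int j = 0; j < m.N; ++j) {
        if (gamble_side) mvec[j] = th[m.g_grp];  // mu_log_kappa
        else if (m.ts_model == 1 && sub_k == 1)
          mvec[j] = gr[1] + gr[10] * st.z[j] + gr[11] * st.z[m.N + j] +
                    gr[12] * st.z[2 * m.N + j];
        else if (m.ts_model == 1 && sub_k == 2)
          mvec[j] = gr[2] + gr[13] * st.z[j] + gr[14] * st.z[m.N + j] +
                    gr[15] * st.z[2 * m.N + j];
        else mvec[j] = gr[sub_k];
      }
      std::vector<double> old_vals(m.N);
      for (int j = 0; j < m.N; ++j) {
        int idx = gamble_side ? (m.g_sub + j * m.pg) : (j * m.pts + sub_k);
        old_vals[j] = th[idx];
        th[idx] = mvec[j] + c * (th[idx] - mvec[j]);
      }
      th[lsd_idx] += delta;

      double new_part = m.prior_group(th);
      for (int j = 0; j < m.N; ++j) {
        new_ts_ll[j] = gamble_side ? m.ll_g(j, th) : m.ll_ts(j, th, st.z);
        new_part += new_ts_ll[j] + (gamble_side ? m.prior_g_sub(j, th)
                                                : m.prior_ts_sub(j, th, st.z));
      }
      double d = new_part - old_part + m.N * delta;
      double ap = R_finite(d) ? std::min(1.0, std::exp(d)) : 0.0;
      ++n_prop;
      if (R::unif_rand() < ap) {
        if (gamble_side) st.g_ll = new_ts_ll; else st.ts_ll = new_ts_ll;
        ++n_acc;
      } else {
        th[lsd_idx] -= delta;
        for (int j = 0; j < m.N; ++j) {
          int idx = gamble_side ? (m.g_sub + j * m.pg) : (j * m.pts + sub_k);
          th[idx] = old_vals[j];
        }
      }
      if (adapting) ls_sc[sIdx] += eta * (ap - targ_tr);
    }

    // -- gambling truncated-normal hierarchy moves: translate or rescale a
    //    group location together with its subject values on the natural
    //    scale (v_i <- v_i + delta, or v_i <- mu + c (v_i - mu) with
    //    log-sd <- log-sd + log c). Subject values are stored as logs, so the
    //    map contributes a Jacobian of sum(u_i - u_i') (plus N log c for the
    //    scale move); proposals pushing any value to <= 0 are rejected.
    for (int k = 1; k < m.pg; ++k) {
      for (int mv = 0; mv < 2; ++mv) {
        size_t aIdx = 2 * (k - 1) + mv;
        int mu_idx = m.g_grp + k, lsd_idx = m.g_grp + m.pg + k;
        double delta = std::exp(ls_tn[aIdx]) * R::norm_rand();
        double old_part = m.prior_group(th);
        for (int j = 0; j < m.N; ++j)
          old_part += st.g_ll[j] + m.prior_g_sub(j, th);
        std::vector<double> old_u(m.N);
        for (int j = 0; j < m.N; ++j) old_u[j] = th[m.g_sub + j * m.pg + k];
        double mu = th[mu_idx], logdet = 0.0;
        bool ok = true;
        for (int j = 0; j < m.N; ++j) {
          int idx = m.g_sub + j * m.pg + k;
          double v = std::exp(old_u[j]);
          double v2 = (mv == 0) ? v + delta : mu + std::exp(delta) * (v - mu);
          if (!(v2 > 0.0)) { ok = false; break; }
          th[idx] = std::log(v2);
          logdet += old_u[j] - th[idx];
        }
        double ap = 0.0;
        if (ok) {
          if (mv == 0) th[mu_idx] += delta;
          else { th[lsd_idx] += delta; logdet += m.N * delta; }
          double new_part = m.prior_group(th);
          for (int j = 0; j < m.N; ++j)
            new_part += m.ll_g(j, th) + m.prior_g_sub(j, th);
          double d = new_part - old_part + logdet;
          ap = R_finite(d) ? std::min(1.0, std::exp(d)) : 0.0;
        }
        ++n_prop;
        if (ok && R::unif_rand() < ap) {
          for (int j = 0; j < m.N; ++j) st.g_ll[j] = m.ll_g(j, th);
          ++n_acc;
        } else {
          for (int j = 0; j < m.N; ++j) {
            int idx = m.g_sub + j * m.pg + k;
            th[idx] = old_u[j];
          }
          if (ok) {
            if (mv == 0) th[mu_idx] -= delta; else th[lsd_idx] -= delta;
          }
        }
        if (adapting) ls_tn[aIdx] += eta * (ap - targ_tr);
      }
    }

    // -- hierarchy (mu, log-sd) pair moves with adapted 2-D covariance:
    //    the gambling hierarchies have a funnel-shaped ridge (small mu with
    //    large sd trades off against large mu with small sd) that axis-
    //    aligned walks traverse slowly. Prior-only cost.
    for (size_t hIdx = 0; hIdx < hier_am.size(); ++hIdx) {
      AmState& am = hier_am[hIdx];
      int mu_idx = am.idx0, lsd_idx = am.idx1;
      double old_mu = th[mu_idx], old_lsd = th[lsd_idx];
      if (adapting) am.update(old_mu, old_lsd);
      double old_part = m.prior_group(th);
      for (int j = 0; j < m.N; ++j) old_part += m.prior_g_sub(j, th);
      double z1 = R::norm_rand(), z2 = R::norm_rand();
      double s = std::exp(am.ls);
      th[mu_idx] += s * (am.l11 * z1);
      th[lsd_idx] += s * (am.l21 * z1 + am.l22 * z2);
      double new_part = m.prior_group(th);
      for (int j = 0; j < m.N; ++j) new_part += m.prior_g_sub(j, th);
      double d = new_part - old_part;
      double ap = R_finite(d) ? std::min(1.0, std::exp(d)) : 0.0;
      ++n_prop;
      if (R::unif_rand() < ap) ++n_acc;
      else { th[mu_idx] = old_mu; th[lsd_idx] = old_lsd; }
      if (adapting) am.ls += eta * (ap - 0.30);
    }

    if (!adapting) {
      int post = scan - warm_scans;
      if ((post + 1) % thin == 0) {
        int row = post / thin;
        for (int j = 0; j < m.n_theta; ++j) draws(row, j) = st.theta[j];
      }
    }
    if (scan % 200 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["draws"] = draws,
                      _["accept_rate"] = double(n_acc) / double(n_prop));
}
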