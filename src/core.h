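#ifndef MBLOSS_CORE_H
#define MBLOSS_CORE_H

#include <Rcpp.h>
#include <vector>
#include <cmath>

// ---------------------------------------------------------------------------
// Two-step task: hybrid model-based / model-free learner.
//
// States: row 0 = first stage, rows 1 and 2 = the two second-stage states.
// Actions: 0/1 in every state. Missing entries are coded -1 (aborted stage).
// The same routine serves as likelihood (choices given) and as generative
// simulation (choices sampled), so agent and likelihood share one
// value-update implementation by construction.
// ---------------------------------------------------------------------------

struct TwoStepTrials {
  std::vector<int> c1, s2, c2;   // stage-1 choice, stage-2 state, stage-2 choice
  std::vector<double> r;         // reward after stage 2
  int n() const { return static_cast<int>(c1.size()); }
};

struct HybridParams {
  double alpha, beta_mb, beta_mf, beta_2, p_stick, beta_bias;
  double lambda;    // eligibility decay, fixed to 1 in the headline model
  double baseline;  // reference value: Q initialization and decay target
  double p_common;  // veridical common-transition probability
};

// Stable two-option softmax: probability of action `a` given logits x0, x1.
inline double softmax2(double x0, double x1, int a) {
  double m = x0 > x1 ? x0 : x1;
  double e0 = std::exp(x0 - m), e1 = std::exp(x1 - m);
  return (a == 0 ? e0 : e1) / (e0 + e1);
}

// One pass over a session. In simulate mode the TwoStepTrials fields c1/s2/c2/r
// must be pre-sized and are filled in (no aborted trials are generated); the
// payoff matrix (n x 4, columns state0-action0, state0-action1, state1-action0,
// state1-action1) and true mapping drive transitions and rewards.
// Probability logs (chosen-action probabilities) are written when the pointers
// are non-null; -1 marks stages with no choice. Returns the log-likelihood of
// the (given or emitted) choices over complete stages of complete trials.
inline double hybrid_run(TwoStepTrials& d, const HybridParams& par,
                         bool simulate,
                         const double* payoff, int payoff_nrow,
                         const int* true_map,
                         double* p1_out, double* p2_out) {
  double Q[3][2] = {{par.baseline, par.baseline},
                    {par.baseline, par.baseline},
                    {par.baseline, par.baseline}};
  int map_diff = 0;   // (a0->s0 plus a1->s1) minus (a0->s1 plus a1->s0)
  int rep_prev = -1;  // last observed stage-1 action
  double ll = 0.0;
  const int n = d.n();

  for (int t = 0; t < n; ++t) {
    // Inferred mapping: predominant second-stage state of action 0.
    // Ties (including trial 1) keep the first-listed mapping.
    int m0 = (map_diff >= 0) ? 0 : 1;

    // Model-based stage-1 values: Bellman backup with veridical 0.7/0.3.
    double max0 = Q[1][0] > Q[1][1] ? Q[1][0] : Q[1][1];
    double max1 = Q[2][0] > Q[2][1] ? Q[2][0] : Q[2][1];
    double qmb0, qmb1;
    if (m0 == 0) {
      qmb0 = par.p_common * max0 + (1.0 - par.p_common) * max1;
      qmb1 = par.p_common * max1 + (1.0 - par.p_common) * max0;
    } else {
      qmb0 = par.p_common * max1 + (1.0 - par.p_common) * max0;
      qmb1 = par.p_common * max0 + (1.0 - par.p_common) * max1;
    }

    double x0 = par.beta_mb * qmb0 + par.beta_mf * Q[0][0] +
                par.p_stick * (rep_prev == 0 ? 1.0 : 0.0);
    double x1 = par.beta_mb * qmb1 + par.beta_mf * Q[0][1] +
                par.p_stick * (rep_prev == 1 ? 1.0 : 0.0) + par.beta_bias;

    if (simulate) {
      double pr1 = softmax2(x0, x1, 1);
      d.c1[t] = (R::unif_rand() < pr1) ? 1 : 0;
      int maj = (d.c1[t] == 0) ? true_map[0] : true_map[1];
      d.s2[t] = (R::unif_rand() < par.p_common) ? maj : (1 - maj);
    }

    int c1 = d.c1[t], s2 = d.s2[t];

    if (simulate) {
      int srow = 1 + s2;
      double xs0 = par.beta_2 * Q[srow][0], xs1 = par.beta_2 * Q[srow][1];
      d.c2[t] = (R::unif_rand() < softmax2(xs0, xs1, 1)) ? 1 : 0;
      double p_rew = payoff[t + payoff_nrow * (2 * s2 + d.c2[t])];
      d.r[t] = (R::unif_rand() < p_rew) ? 1.0 : 0.0;
    }

    int c2 = d.c2[t];
    bool complete = (c1 >= 0) && (s2 >= 0) && (c2 >= 0);

    if (p1_out) p1_out[t] = -1.0;
    if (p2_out) p2_out[t] = -1.0;

    if (complete) {
      double p1 = softmax2(x0, x1, c1);
      int srow = 1 + s2;
      double p2 = softmax2(par.beta_2 * Q[srow][0], par.beta_2 * Q[srow][1], c2);
      ll += std::log(p1) + std::log(p2);
      if (p1_out) p1_out[t] = p1;
      if (p2_out) p2_out[t] = p2;

      // SARSA(lambda) updates with prediction errors taken before any
      // within-trial value change; traces reset every trial.
      double pe1 = Q[srow][c2] - Q[0][c1];             // r at stage 1 is 0
      double pe2 = d.r[t] - Q[srow][c2];               // terminal value is 0
      Q[0][c1] += par.alpha * pe1 + par.alpha * par.lambda * pe2;
      Q[srow][c2] += par.alpha * pe2;

      // Non-chosen values decay toward the reference point, once per trial,
      // after the learning updates.
      for (int s = 0; s < 3; ++s)
        for (int a = 0; a < 2; ++a)
          if (!((s == 0 && a == c1) || (s == srow && a == c2)))
            Q[s][a] += par.alpha * (par.baseline - Q[s][a]);
    }

    // Transition tally updates whenever the transition was observed,
    // regardless of whether the trial completed.
    if (c1 >= 0 && s2 >= 0)
      map_diff += ((c1 == 0 && s2 == 0) || (c1 == 1 && s2 == 1)) ? 1 : -1;
    if (c1 >= 0) rep_prev = c1;
  }
  return ll;
}

// ---------------------------------------------------------------------------
// Gambling task utilities (prospect theory and mean-variance).
// ---------------------------------------------------------------------------

struct GambleTrials {
  std::vector<double> g1, g2, sure;
  std::vector<int> mixed;   // 1 = mixed valence, 0 = gain only
  std::vector<int> choice;  // 1 = gamble, 0 = sure; -1 = missing
  int n() const { return static_cast<int>(g1.size()); }
};

inline double pt_value(double v, double kappa, double gamma) {
  return v >= 0 ? std::pow(v, gamma) : -kappa * std::pow(-v, gamma);
}

inline double mv_value(double v, double kappa) {
  return v >= 0 ? v : kappa * v;
}

inline double log1pexp(double x) {
  return x > 35.0 ? x : std::log1p(std::exp(x));
}

// Bernoulli-logit log density of y with logit eta.
inline double bern_logit(int y, double eta) {
  return (y == 1 ? eta : 0.0) - log1pexp(eta);
}

// Per-trial gamble logit under either model. g_model: 0 = PT, 1 = MV.
// PT pars: kappa, gamma_m, gamma_g, theta. MV pars: kappa, w, theta.
inline double gamble_logit(const GambleTrials& d, int t, int g_model,
                           const double* pars) {
  if (g_model == 0) {
    double kappa = pars[0], theta = pars[3];
    double gamma = d.mixed[t] ? pars[1] : pars[2];
    double ug = 0.5 * pt_value(d.g1[t], kappa, gamma) +
                0.5 * pt_value(d.g2[t], kappa, gamma);
    double us = pt_value(d.sure[t], kappa, gamma);
    return theta * (ug - us);
  } else {
    double kappa = pars[0], w = pars[1], theta = pars[2];
    double u1 = mv_value(d.g1[t], kappa), u2 = mv_value(d.g2[t], kappa);
    double ug = 0.5 * u1 + 0.5 * u2 - w * std::fabs(u1 - u2) / 2.0;
    double us = mv_value(d.sure[t], kappa);
    return theta * (ug - us);
  }
}

inline double gamble_loglik_core(const GambleTrials& d, int g_model,
                                 const double* pars) {
  double ll = 0.0;
  for (int t = 0; t < d.n(); ++t) {
    if (d.choice[t] < 0) continue;
    ll += bern_logit(d.choice[t], gamble_logit(d, t, g_model, pars));
  }
  return ll;
}

// ---------------------------------------------------------------------------
// Small density helpers (log scale).
// ---------------------------------------------------------------------------

inline double ldnorm(double x, double mu, double sd) {
  double z = (x - mu) / sd;
  return -0.9189385332046727 - std::log(sd) - 0.5 * z * z;
}

// Half-Cauchy(0, scale) density of sd = exp(lsd), including the Jacobian of
// the log transform.
inline double lhalfcauchy_logscale(double lsd, double scale) {
  double sd = std::exp(lsd);
  return std::log(2.0 / M_PI) - std::log(scale * (1.0 + (sd / scale) * (sd / scale))) + lsd;
}

// Gaussian truncated to [0, inf) with free location, evaluated at v = exp(u),
// including the Jacobian of the log transform.
inline double ltruncnorm_logscale(double u, double mu, double sd) {
  double v = std::exp(u);
  // log Phi(mu / sd) via the upper tail of N(0, mu, sd) at 0
  double lnorm = R::pnorm(0.0, mu, sd, 0, 1);
  return ldnorm(v, mu, sd) - lnorm + u;
}

#endif
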