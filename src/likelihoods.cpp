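#include "core.h"
using namespace Rcpp;

static TwoStepTrials as_trials(IntegerVector c1, IntegerVector s2,
                               IntegerVector c2, NumericVector r) {
  int n = c1.size();
  TwoStepTrials d;
  d.c1.resize(n); d.s2.resize(n); d.c2.resize(n); d.r.resize(n);
  for (int t = 0; t < n; ++t) {
    d.c1[t] = c1[t] == NA_INTEGER ? -1 : c1[t];
    d.s2[t] = s2[t] == NA_INTEGER ? -1 : s2[t];
    d.c2[t] = c2[t] == NA_INTEGER ? -1 : c2[t];
    d.r[t] = NumericVector::is_na(r[t]) ? 0.0 : r[t];
  }
  return d;
}

// [[Rcpp::export]]
List cpp_hybrid_loglik(IntegerVector c1, IntegerVector s2, IntegerVector c2,
                       NumericVector r, NumericVector pars, double lambda,
                       double baseline, double p_common, bool per_trial) {
  TwoStepTrials d = as_trials(c1, s2, c2, r);
  HybridParams par{pars[0], pars[1], pars[2], pars[3], pars[4], pars[5],
                   lambda, baseline, p_common};
  int n = d.n();
  NumericVector p1(per_trial ? n : 0), p2(per_trial ? n : 0);
  double ll = hybrid_run(d, par, false, nullptr, 0, nullptr,
                         per_trial ? p1.begin() : nullptr,
                         per_trial ? p2.begin() : nullptr);
  if (!per_trial) return List::create(_["loglik"] = ll);
  return List::create(_["loglik"] = ll, _["p_stage1"] = p1, _["p_stage2"] = p2);
}

// [[Rcpp::export]]
List cpp_simulate_twostep(NumericMatrix payoff, IntegerVector mapping,
                          double p_common, NumericVector pars, double lambda,
                          double baseline) {
  int n = payoff.nrow();
  TwoStepTrials d;
  d.c1.assign(n, -1); d.s2.assign(n, -1); d.c2.assign(n, -1); d.r.assign(n, 0.0);
  HybridParams par{pars[0], pars[1], pars[2], pars[3], pars[4], pars[5],
                   lambda, baseline, p_common};
  int tm[2] = {mapping[0] - 1, mapping[1] - 1};  // R side is 1-based
  NumericVector p1(n), p2(n);
  RNGScope scope;
  double ll = hybrid_run(d, par, true, payoff.begin(), n, tm,
                         p1.begin(), p2.begin());
  return List::create(
    _["choice1"] = IntegerVector(d.c1.begin(), d.c1.end()),
    _["state2"] = IntegerVector(d.s2.begin(), d.s2.end()),
    _["choice2"] = IntegerVector(d.c2.begin(), d.c2.end()),
    _["reward"] = NumericVector(d.r.begin(), d.r.end()),
    _["p_stage1"] = p1, _["p_stage2"] = p2, _["loglik"] = ll);
}
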