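---
title: "Joint hierarchical modelling of model-based control and loss aversion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint hierarchical modelling of model-based control and loss aversion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The scientific problem

Two well-studied laboratory tasks each measure one trait of human decision
making. A **two-step sequential decision task** separates *model-based*
control (prospective planning over a learned transition model) from
*model-free* control (retrospective stimulus–response value learning): on
every trial a first-stage choice leads probabilistically (70% "common" /
30% "rare") to one of two second-stage states, where a second choice yields
a binary reward whose probability drifts across trials. A **gambling task**
measures *loss aversion* (the relative decision weight on losses, κ) and
risk preferences from repeated choices between a 50/50 gamble and a sure
amount.

`mbloss` implements a joint hierarchical Bayesian analysis of both tasks:
each subject's model-based and model-free weights are given group-level
means shifted by coupling coefficients applied to the cohort-standardized
gambling covariates — z-scored log κ, a risk measure, and the gambling
softmax inverse temperature θ. The coupling coefficients (e.g.
`beta_mb_loss`, the effect of loss aversion on model-based control) are the
quantities of scientific interest. Because the original human dataset is
not publicly deposited, the package pairs the analysis with a synthetic
cohort generator that plants a known coupling, so the whole pipeline is
validated by parameter recovery.

# Task generators

`make_twostep_env()` draws the four second-stage payoff probabilities as
independent Gaussian random walks (per-step SD 0.025, in probability units)
with reflecting boundaries at 0.2 and 0.8, over 201 trials. The design
constants are fixed by the task; two choices were genuinely open:

* **Starting values.** The task description fixes the drift but not the
  initial payoff probabilities; we draw them independently and uniformly on
  \[0.2, 0.8\], which is unbiased and matches the walk's stationary range.
* **Reflection rule.** A step beyond a boundary is reflected about it
  (x → 2b − x), re-applied until inside the range.

`make_gambling_offers()` builds 60 mixed-valence offers (gain from
{2, 4, 5, 6, 8, 9, 10, 12} dollars; loss = −multiple × gain with multiples
0.25–2 in steps of 0.125; sure amount 0) and 20 gain-only offers (gamble
gain $2–$30, zero low outcome, sure amount $1–$13), shuffled. Open choices:

* **Mixed composition.** 8 gains × 15 multiples give 120 design cells but
  only 60 trials; we sample 60 distinct (gain, multiple) pairs without
  replacement, giving balanced, reproducible coverage.
* **Gain-only amounts.** Uniform gains on \[2, 30\] and sure amounts on
  \[1, min(13, gain − 0.5)\], rounded to $0.50, so the sure amount is
  always attainable and strictly below the gamble's high outcome.

# Likelihoods

## Two-step task

Two likelihoods are provided. The **trial-pair stay regression**
(`regression_loglik()`, features from `build_stay_features()`) models the
probability of repeating the previous first-stage choice as a 16-term
logistic: per-subject coefficients for the intercept, previous reward
(±1), previous transition type (±1) and their product, plus shared
group-level coefficients for each gambling covariate and its interactions
with those three predictors. The reward main effect indexes model-free
control, the reward × transition interaction indexes model-based control.

The **hybrid learner** (`hybrid_loglik()`) steps a six-parameter model
through the full session: SARSA(λ) value updates with λ fixed at 1
(eligibility traces reset each trial), Q-values initialized at 0.5 with
non-chosen values decaying toward 0.5, a Bellman backup over the veridical
transition probabilities (0.7/0.3) for model-based stage-1 values, and
softmax choice with separate inverse temperatures for the model-based
(`beta_mb`), model-free (`beta_mf`) and second-stage (`beta_2`) value
terms, plus perseveration and a side bias. The action→state mapping is
inferred online from the sign of the transition-count difference
(`transition_mapping()`); ties, including trial 1, deterministically keep
the first-listed mapping.

Numerical and edge-case conventions (the task description leaves these
open; we fixed them once):

* **Decay timing.** The decay of non-chosen values toward 0.5 is applied
  once per trial, after the learning updates, to every state–action pair
  not chosen on that trial. This keeps within-trial updates
  order-independent.
* **Prediction errors** use pre-update values: the stage-1 TD error uses
  the stage-2 value as it stood at the stage-2 decision, and the
  eligibility update uses the same stage-2 prediction error as the stage-2
  value update.
* **Aborted trials** contribute no likelihood and trigger no value
  updates or decay; the transition tally advances if the transition was
  observed, and the perseveration reference tracks the last *observed*
  stage-1 action even when that trial later aborted. (The generator never
  aborts trials; these rules exist for reading real-format data.)
* **Softmax** probabilities are computed with max-subtraction, so large
  temperatures stay finite.

A useful identity doubles as a correctness oracle: recoding rewards 0/1 as
−1/+1, moving the reference point (initialization and decay target) from
0.5 to 0, and halving the three inverse temperatures leaves the session
likelihood unchanged. The test suite asserts this to 1e-10, and also checks
that the probabilities of all possible 2-trial choice sequences sum to 1
and that a hand-stepped two-trial fixture is reproduced exactly.

`simulate_twostep_agent()` runs the *same* compiled update/choice code
generatively, so the agent and the likelihood cannot drift apart; the
likelihood of an emitted session equals the product of the probabilities
logged during simulation, exactly.

## Gambling task

`pt_utility()` implements the prospect-theory value function
(v^γ for gains, −κ(−v)^γ for losses) with no probability weighting
(outcome probabilities are fixed at 0.5). Mixed trials use curvature
`gamma_m`; gain-only trials use a separate `gamma_g`, and 1 − γ_g is the
risk-aversion measure. `mv_utility()` implements the mean–variance
alternative: piecewise-linear value with loss weight κ and a penalty
w × σ, where σ is the probability-weighted SD of the two outcome values —
for a 50/50 gamble, |U(g1) − U(g2)|/2. The σ penalty applies on gain-only
trials too (σ > 0 whenever the outcomes differ), which follows directly
from the definition. Choices follow a softmax with inverse temperature θ
(`gamble_choice_prob()`).

# The joint hierarchical model

`build_joint_model()` + `run_mcmc()` fit one two-step model and one
gambling model simultaneously to all subjects (never both two-step models
at once). Subject-level priors:

* regression coefficients and the learner's logit-α, `beta_2`,
  perseveration: Gaussian with free group mean and SD;
* `beta_mb` and `beta_mf`: Gaussian whose mean is the group baseline plus
  the coupling coefficients times the z-scored covariates;
* `beta_bias`: independent N(0, 10²) per subject (individual nuance, no
  hierarchy);
* κ: log-normal; γ, w, θ: Gaussian truncated to \[0, ∞) with free
  location and scale.

Hyperpriors: N(0, 2²) on regression-model means and covariate
coefficients; N(0, 10²) on learner means (N(0, 5²) for the logit learning
rate) and coupling coefficients; N(0, 2²) on the κ/γ/w means and
N(0, 10²) on the θ mean; half-Cauchy(0, 2.5) on every group SD.
`prior_sensitivity_rerun()` widens all mean-effect priors tenfold (the
half-Cauchy SD hyperpriors are untouched) for the sensitivity reanalysis.

**Covariate standardization.** The published analysis fits both tasks
simultaneously but does not state how z-score(log κ) is computed during
sampling. The default here standardizes *within every draw* across the
current subject-level values (population SD), which is self-contained and
scale-invariant; a two-stage mode (`zscore_mode = "two_stage"`) instead
fixes the covariates at point estimates supplied by the user (e.g. medians
from a gambling-only fit via `two_stage_covariates()`). Neither is asserted
to be the original scheme; the per-draw form is the default because it
propagates the gambling-side uncertainty.

## Sampler

The sampling contract is gradient-based adaptive MCMC with the split-chain
R-hat < 1.1 criterion as the arbiter. `mbloss` ships its own adaptive
Metropolis-within-Gibbs sampler (compiled, seeded, sequential chains):

* single-coordinate random-walk updates for all two-step subject
  parameters and group-level parameters (target acceptance 0.44);
* per-subject joint proposals with adapted covariance (classic adaptive
  Metropolis: the empirical covariance of the subject's gambling
  parameters accumulated during warmup, scaled by 2.4²/d) plus
  single-coordinate moves — loss aversion, curvature and temperature are
  strongly correlated within subject, and isotropic blocks mix them
  slowly. Gambling updates re-standardize the covariates and propagate
  into the coupled priors (hybrid) or every regression likelihood
  (sufficient-statistic form: the stay features collapse to at most four
  reward × transition patterns per subject);
* translation moves shifting a group mean together with all its
  subject-level values, scale moves rescaling a group SD together with the
  subject residuals, and natural-scale translation/scale moves for the
  truncated-Gaussian gambling hierarchies (with the exact Jacobian for the
  log-stored coordinates) — these decorrelate the group level from the
  subject block, which is what limits plain within-Gibbs mixing in
  centered hierarchies;
* adapted 2-D proposals on each gambling hierarchy's (location, log-scale)
  pair, which follow the funnel-shaped ridge between a concentrated and a
  diffuse hierarchy.

The sampler's marginal correctness was pinned during development by a
prior-recovery check — fitting a dataset with no observed choices
reproduces the closed-form prior quantiles of every hyperparameter family
— and every reported fit is gated on the split-chain R-hat. Because the
covariates are re-standardized within every draw, a weakly identified
subject can trade off against the covariate coefficients and create
long-lived posterior configurations; retained draws therefore need to be
spaced widely (the `thin` setting) for short windows to traverse them.

Constrained parameters are sampled on log/logit scales. The hierarchy is
kept *centered* (subject values, not standardized offsets): with
informative per-subject data (201 trials, 80 gambles) the centered form
mixes well under conditional updates and allows subject-local likelihood
caching; the non-centered form mainly helps gradient samplers in
weak-data funnels. Proposal scales adapt by Robbins–Monro during warmup
only and are frozen afterwards. `samples` counts iterations per chain
including `warmup`; each retained draw is separated by `thin` full scans.
Initial points are drawn overdispersed on the unconstrained scale and
re-drawn while the density is non-finite (up to 50 attempts).

Convergence is assessed with `rhat()`, the split-chain potential scale
reduction factor (each chain halved, so within-chain drift inflates the
statistic); all-constant chains are defined to give 1.

# Synthetic cohorts and what recovery shows

`simulate_cohort()` inverts the fitted model generatively: gambling
parameters are drawn from the group families (log-normal κ; truncated
Gaussians for γ/w/θ), covariates are z-scored across the cohort, each
subject's `beta_mb`/`beta_mf` mean is shifted by the coupling
coefficients, and both sessions are simulated per subject. The published
study fits models but describes no generative simulation; the cohort
generator is an inversion of its fitted model and is flagged as such.

Generative defaults: 201 two-step trials and 60 + 20 gambles per subject;
group means `beta_mb` 5.5, `beta_mf` 4.2 (the range reported for human
cohorts on this task), `beta_2` 2.5, perseveration 0.3, logit-α 0
(α ≈ 0.5), bias 0; log κ mean 0.5 (κ ≈ 1.6), γ_m 0.7, γ_g 0.8, θ 1.0
under prospect theory (w 0.3, θ 0.5 under mean–variance); group SDs of
0.8–2.0 on the learner weights and 0.15–0.5 on the gambling side. The
default coupling plants `beta_mb_loss = 3.6` (the magnitude reported for
the loss-aversion effect on model-based control) with all other couplings
zero, model-free couplings zero in particular, since no model-free effect
was found.

Parameter recovery on such cohorts — the planted coupling's posterior mass
above zero, its interval covering the truth, null couplings covering
zero, and per-parameter coverage near 95% — validates the *pipeline*:
likelihood code, prior wiring, covariate standardization and sampler. It
does not validate the model against real behavior: real subjects abort
trials, drift within sessions, and need not follow either utility family.
Those features are deliberately outside the generator.

# Reporting

`summarize_posterior()` reports the median, the central 95% interval
(2.5%/97.5% quantiles over all retained draws pooled across chains) and
1 − p(x > 0), computed as the fraction of draws ≤ 0 — ties at exactly zero
count against positivity, a convention that matters only for determinism.
`differential_effect()` summarizes per-draw differences (model-based minus
model-free coupling). `group_effects_table()` lays these out in the
standard table format with three decimals, so tables are byte-stable under
fixed seeds. `correlation_posterior()` computes, within every retained
draw, the across-subject partial Pearson correlation between a decision
system's weight and a gambling measure, residualized on the other two
covariates; per-draw computation (rather than correlating point estimates)
propagates subject-level uncertainty, and a `point_estimate` mode is
available for comparison. `performance_exclusion()` drops subjects whose
95% intervals for `beta_mb` AND `beta_mf` AND `beta_2` all include zero.

# Problem sizes used in the test suite

The shipped tests exercise the full pipeline at reduced sizes chosen to
keep a complete run comfortable on one CPU: 30-subject cohorts with 4
chains × 1,000 retained draws for hybrid-model recovery (planted and null
couplings), a 20-subject regression + prospect-theory fit with 4 chains ×
500 retained draws for the convergence and prior-sensitivity checks, and
8-subject cohorts for end-to-end byte-stability. Full-scale settings
(8 chains, 4,000/10,000 samples) are the package defaults but are not run
in the tests.

# Known limitations

* No reaction-time modelling, no within-session parameter drift, no
  learning of transition probabilities, and no alternative mixture
  weighting of the two controllers — all fixed by the study design.
* No model comparison (WAIC/LOO) and no posterior-predictive machinery
  beyond what the reports need.
* The Metropolis-within-Gibbs sampler is slower per effective draw than a
  tuned Hamiltonian sampler would be; the shipped settings compensate with
  thinning and targeted group-level moves, and every fit is gated on the
  split-chain R-hat < 1.1 criterion.
* Reproducing the published point estimates requires the original human
  dataset, which is available only on request; the pipeline reproduces the
  analysis surface (models, priors, tables, figures) and is validated by
  recovery on synthetic cohorts instead.
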