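# Shared fixtures, built once per test run.

fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = fixture_cache))
    assign(key, force(expr), envir = fixture_cache)
  get(key, envir = fixture_cache)
}

# A small but informative cohort with the default planted coupling.
small_cohort <- function() {
  memo("small_cohort",
       simulate_cohort(cohort_spec(n_subjects = 8, seed = 301,
                                   n_trials = 120)))
}

# Scaled-down joint fit of the regression + prospect-theory model on a
# 20-subject cohort: shared by the convergence, reporting-determinism and
# prior-sensitivity checks.
regpt_cohort <- function() {
  memo("regpt_cohort", simulate_cohort(cohort_spec(n_subjects = 20, seed = 11)))
}

regpt_spec <- function(seed = 1, psm = 1) {
  # retained draws are spaced widely: short windows on this model can sit
  # inside a single excursion of the theta hierarchy (see methods vignette)
  joint_model_spec("regression", "prospect", chains = 4, samples = 1100,
                   warmup = 600, thin = 80, warmup_thin = 25, seed = seed,
                   prior_scale_multiplier = psm)
}

regpt_fit <- function() {
  memo("regpt_fit", fit_joint_model(regpt_cohort(), regpt_spec()))
}

# Two-trial hybrid session used by the hand-stepped likelihood fixtures.
two_trial_session <- function() {
  data.frame(trial = 1:2,
             choice1 = c(1L, 1L), state2 = c(1L, 2L),
             choice2 = c(1L, 2L), reward = c(1, 0),
             common = c(1L, 0L), aborted = 0L)
}
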