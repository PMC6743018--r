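test_that("a value-blind agent chooses stage-1 actions uniformly", {
  env <- make_twostep_env(seed = 1, n_trials = 4000)
  p <- rl_params(alpha = 0.5)  # all temperatures, stickiness, bias at 0
  s <- simulate_twostep_agent(p, env, seed = 2)
  expect_equal(mean(s$choice1 == 1), 0.5, tolerance = 0.05)
  expect_equal(mean(s$common), 0.7, tolerance = 0.03)
})

test_that("agent simulation is reproducible and matches the session format", {
  env <- make_twostep_env(seed = 3)
  p <- rl_params(0.4, 3, 2, 2, 0.3, 0.1)
  a <- simulate_twostep_agent(p, env, seed = 4)
  b <- simulate_twostep_agent(p, env, seed = 4)
  expect_identical(a, b)
  expect_equal(nrow(a), 201L)
  expect_true(all(a$choice1 %in% 1:2 & a$state2 %in% 1:2 & a$choice2 %in% 1:2))
  expect_true(all(a$reward %in% c(0, 1)))
  expect_true(all(a$aborted == 0L))
})

test_that("agent and likelihood share one implementation: the session
           likelihood equals the product of simulation-time probabilities", {
  env <- make_twostep_env(seed = 5)
  p <- rl_params(0.35, 4, 3, 2.5, 0.4, -0.2)
  s <- simulate_twostep_agent(p, env, seed = 6)
  expect_identical(hybrid_loglik(p, s), attr(s, "loglik"))
  expect_equal(hybrid_loglik(p, s),
               sum(log(attr(s, "p_stage1"))) + sum(log(attr(s, "p_stage2"))))
})

test_that("a strongly model-free agent shows the reward main effect
           regardless of transition type", {
  env <- make_twostep_env(seed = 7, n_trials = 10000)
  p <- rl_params(alpha = 0.5, beta_mf = 8)
  s <- simulate_twostep_agent(p, env, seed = 8)
  f <- build_stay_features(s)
  stay_rew <- mean(f$stay[f$reward_prev == 1])
  stay_unrew <- mean(f$stay[f$reward_prev == -1])
  expect_gt(stay_rew, stay_unrew + 0.05)
  # and within each transition type separately
  for (ct in c(-1, 1)) {
    sel <- f$common_prev == ct
    expect_gt(mean(f$stay[sel & f$reward_prev == 1]),
              mean(f$stay[sel & f$reward_prev == -1]))
  }
})

test_that("gamblers behave sensibly in limiting cases", {
  off <- make_gambling_offers(seed = 9)
  # theta = 0: indifference
  g0 <- simulate_gambler(pt_params(2, 0.7, 0.8, 0), off, seed = 10)
  expect_equal(attr(g0, "prob_gamble"), rep(0.5, 80))
  # extreme loss aversion: mixed gambles almost never chosen
  gk <- simulate_gambler(pt_params(50, 1, 1, 2), off, seed = 11)
  mixed <- gk$trial_type == "mixed"
  expect_lt(mean(attr(gk, "prob_gamble")[mixed]), 0.01)
  # expected-value dominance on gain-only trials at large theta
  sess <- data.frame(trial_type = "gain_only", g1 = 20, g2 = 0, sure = 4)
  gd <- simulate_gambler(pt_params(1, 1, 1, 50), sess, seed = 12)
  expect_equal(attr(gd, "prob_gamble"), 1)
  # reproducibility
  expect_identical(simulate_gambler(pt_params(2, .7, .8, 1), off, seed = 13),
                   simulate_gambler(pt_params(2, .7, .8, 1), off, seed = 13))
})

test_that("cohort generation plants the requested coupling", {
  # zero coupling: beta_mb independent of log kappa
  cs0 <- cohort_spec(n_subjects = 200, seed = 21,
                     coupling_mb = c(loss = 0, risk = 0, theta = 0),
                     n_trials = 2)
  co0 <- simulate_cohort(cs0)
  expect_lt(abs(cor(co0$truth$beta_mb, co0$truth$log_kappa)), 0.2)

  # planted loss coupling: strong positive rank correlation
  cs1 <- cohort_spec(n_subjects = 200, seed = 22,
                     coupling_mb = c(loss = 3.6, risk = 0, theta = 0),
                     n_trials = 2)
  co1 <- simulate_cohort(cs1)
  expect_gt(cor(co1$truth$beta_mb, co1$truth$log_kappa, method = "spearman"),
            0.5)
})

test_that("cohort bookkeeping and z-scoring are exact", {
  co <- small_cohort()
  n <- co$spec$n_subjects
  expect_equal(sort(unique(co$twostep$subject)), 1:n)
  expect_equal(sort(unique(co$gambling$subject)), 1:n)
  expect_equal(nrow(co$truth), n)
  expect_equal(nrow(co$twostep), n * co$spec$n_trials)
  expect_equal(nrow(co$gambling), n * 80L)
  for (zc in c("z_loss", "z_risk", "z_theta")) {
    expect_equal(mean(co$truth[[zc]]), 0, tolerance = 1e-12)
    expect_equal(sqrt(mean(co$truth[[zc]]^2)), 1, tolerance = 1e-12)
  }
  expect_error(cohort_spec(n_subjects = 1), "at least 2")
})

test_that("cohorts are reproducible and written files round-trip", {
  cs <- cohort_spec(n_subjects = 3, seed = 33, n_trials = 10)
  a <- simulate_cohort(cs)
  b <- simulate_cohort(cs)
  expect_identical(a$truth, b$truth)
  expect_identical(a$twostep, b$twostep)
  dir <- tempfile()
  write_cohort(a, dir)
  back <- read_cohort(dir)
  expect_equal(back$twostep$choice1, a$twostep$choice1)
  expect_equal(back$truth$beta_mb, a$truth$beta_mb)
  expect_equal(attr(back$truth, "meta")$seed, 33)
  unlink(dir, recursive = TRUE)
})
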