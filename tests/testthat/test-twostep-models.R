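test_that("stay features are built from qualifying trial pairs", {
  # 2 trials, same stage-1 choice, trial 1 rewarded via common transition
  s <- data.frame(trial = 1:2, choice1 = c(1L, 1L), state2 = c(1L, 1L),
                  choice2 = c(2L, 1L), reward = c(1, 0), common = c(1L, 1L))
  f <- build_stay_features(s)
  expect_equal(nrow(f), 1L)
  expect_equal(f$stay, 1L)
  expect_equal(f$reward_prev, 1)
  expect_equal(f$common_prev, 1)

  # predecessor unrewarded after a rare transition, choice switched
  s2 <- data.frame(trial = 1:2, choice1 = c(1L, 2L), state2 = c(2L, 1L),
                   choice2 = c(1L, 1L), reward = c(0, 1), common = c(0L, 1L))
  f2 <- build_stay_features(s2)
  expect_equal(f2$stay, 0L)
  expect_equal(f2$reward_prev, -1)
  expect_equal(f2$common_prev, -1)

  # single trial: no predecessor
  expect_equal(nrow(build_stay_features(s[1, ])), 0L)

  # aborted predecessor drops the pair; later pairs survive
  s3 <- data.frame(trial = 1:3, choice1 = c(1L, NA, 2L),
                   state2 = c(1L, NA, 2L), choice2 = c(1L, NA, 2L),
                   reward = c(1, NA, 0), common = c(1L, NA, 1L))
  expect_equal(nrow(build_stay_features(s3)), 0L)
  s4 <- data.frame(trial = 1:3, choice1 = c(NA, 1L, 1L),
                   state2 = c(NA, 1L, 2L), choice2 = c(NA, 1L, 2L),
                   reward = c(NA, 1, 0), common = c(NA, 1L, 0L))
  expect_equal(nrow(build_stay_features(s4)), 1L)
})

make_reg_params <- function(b, subjects = "1") {
  bm <- matrix(rep(b, each = length(subjects)), nrow = length(subjects),
               dimnames = list(subjects, NULL))
  g <- stats::setNames(rep(0, 12), mbloss:::reg_g_names)
  list(b = bm, g = g)
}

test_that("stay regression log-likelihood matches hand arithmetic", {
  f <- data.frame(subject = 1, stay = 1L, reward_prev = 1, common_prev = 1)
  cov <- data.frame(subject = 1, loss = 0, risk = 0, theta = 0)

  # null model
  p0 <- make_reg_params(c(0, 0, 0, 0))
  expect_equal(regression_loglik(p0, f, cov), log(0.5))

  # reward and reward x common effects at published group medians, as inputs:
  # x = 0.350 + 0.139 = 0.489
  p1 <- make_reg_params(c(0, 0.350, 0, 0.139))
  expect_equal(regression_loglik(p1, f, cov), log(stats::plogis(0.489)))

  # additivity: doubling the dataset doubles the log-likelihood
  f10 <- do.call(rbind, replicate(10, f, simplify = FALSE))
  p2 <- make_reg_params(c(0.2, 0.3, -0.1, 0.15))
  expect_equal(regression_loglik(p2, rbind(f10, f10), cov),
               2 * regression_loglik(p2, f10, cov))

  # covariate terms enter all 16 slots
  p3 <- make_reg_params(c(0, 0, 0, 0))
  p3$g[] <- c(0.1, 0, 0, 0.2, 0, 0, 0, 0, 0, 0.3, 0, 0)
  cov2 <- data.frame(subject = 1, loss = 2, risk = 0, theta = 0)
  expect_equal(regression_loglik(p3, f, cov2),
               log(stats::plogis(2 * (0.1 + 0.2 + 0.3))))

  expect_error(regression_loglik(p0, f, cov[0, ]), "covariates")
})

test_that("transition mapping follows the count-difference sign rule", {
  expect_equal(transition_mapping(matrix(c(7, 0, 0, 3), 2, byrow = TRUE)),
               c(1L, 2L))
  expect_equal(transition_mapping(matrix(c(1, 5, 6, 2), 2, byrow = TRUE)),
               c(2L, 1L))
  # ties, including the all-zero start, keep the first-listed mapping
  expect_equal(transition_mapping(matrix(c(2, 2, 2, 2), 2)), c(1L, 2L))
  expect_equal(transition_mapping(matrix(0, 2, 2)), c(1L, 2L))
})

test_that("hybrid likelihood gives symmetric probabilities on trial 1 and a
           uniform policy at zero temperatures", {
  s <- two_trial_session()
  p0 <- rl_params(alpha = 0.5)
  out <- hybrid_loglik(p0, s, per_trial = TRUE)
  expect_equal(out$p_stage1, c(0.5, 0.5))
  expect_equal(out$p_stage2, c(0.5, 0.5))
  expect_equal(out$loglik, 4 * log(0.5))

  # value terms are symmetric on trial 1 whenever stickiness and bias are 0
  p1 <- rl_params(alpha = 0.3, beta_mb = 2, beta_mf = 1, beta_2 = 1.5)
  first <- hybrid_loglik(p1, s, per_trial = TRUE)
  expect_equal(first$p_stage1[1], 0.5)
  expect_equal(first$p_stage2[1], 0.5)
})

test_that("hybrid likelihood matches the hand-stepped two-trial fixtures", {
  s <- two_trial_session()
  # model-free only: alpha 0.5, beta_mf 1. Trial 1 probabilities are 0.5;
  # after a rewarded trial Q(s1, a1) = 0.75 (TD step of 0 plus eligibility
  # 0.5 * 1 * (1 - 0.5)), so trial 2 stage 1 gives plogis(0.75 - 0.5).
  p_mf <- rl_params(alpha = 0.5, beta_mf = 1)
  expect_equal(hybrid_loglik(p_mf, s),
               3 * log(0.5) + log(stats::plogis(0.25)), tolerance = 1e-12)

  # model-based only: after trial 1 the inferred mapping is action 1 ->
  # state 1 and Q(state 1, action 1) = 0.75, so the Bellman backup gives
  # stage-1 values 0.7*0.75 + 0.3*0.5 = 0.675 vs 0.7*0.5 + 0.3*0.75 = 0.575.
  p_mb <- rl_params(alpha = 0.5, beta_mb = 1)
  expect_equal(hybrid_loglik(p_mb, s),
               3 * log(0.5) + log(stats::plogis(0.1)), tolerance = 1e-12)

  # third trial exercises the decay and a non-zero stage-1 TD error:
  # after trial 2, Q(s1, a1) = 0.375, Q(s1, a2) = 0.5
  s3 <- rbind(s, data.frame(trial = 3, choice1 = 2L, state2 = 1L,
                            choice2 = 1L, reward = 1, common = 0L,
                            aborted = 0L))
  expect_equal(hybrid_loglik(p_mf, s3),
               4 * log(0.5) + log(stats::plogis(0.25)) +
                 log(stats::plogis(0.125)), tolerance = 1e-12)
})

test_that("perseveration and bias act on stage 1 as specified", {
  s <- two_trial_session()
  p <- rl_params(alpha = 0.5, p_stick = 0.7)
  out <- hybrid_loglik(p, s, per_trial = TRUE)
  # trial 2 repeats the previous action: rep adds 0.7 to the chosen logit
  expect_equal(out$p_stage1[2], stats::plogis(0.7))
  pb <- rl_params(alpha = 0.5, beta_bias = -0.4)
  outb <- hybrid_loglik(pb, s, per_trial = TRUE)
  # bias attaches to action 2; action 1 chosen on both trials
  expect_equal(outb$p_stage1, rep(stats::plogis(0.4), 2))
})

test_that("aborted trials contribute no likelihood and no updates", {
  s <- two_trial_session()
  s_ab <- rbind(data.frame(trial = 0, choice1 = NA_integer_,
                           state2 = NA_integer_, choice2 = NA_integer_,
                           reward = NA_real_, common = NA_integer_,
                           aborted = 1L),
                s)
  s_ab$trial <- 1:3
  p <- rl_params(alpha = 0.5, beta_mf = 1)
  expect_equal(hybrid_loglik(p, s_ab), hybrid_loglik(p, s))
  # a stage-1-only abort still moves the perseveration reference
  s_p <- rbind(s[1, ],
               data.frame(trial = 2, choice1 = 2L, state2 = NA_integer_,
                          choice2 = NA_integer_, reward = NA_real_,
                          common = NA_integer_, aborted = 1L),
               transform(s[2, ], trial = 3))
  pp <- rl_params(alpha = 0.5, p_stick = 0.7)
  out <- hybrid_loglik(pp, s_p, per_trial = TRUE)
  expect_equal(out$p_stage1[3], 1 - stats::plogis(0.7))  # rep now action 2
})

test_that("total probability over all two-trial choice sequences is 1", {
  p <- rl_params(alpha = 0.4, beta_mb = 2, beta_mf = 1.5, beta_2 = 2,
                 p_stick = 0.5, beta_bias = 0.2)
  rewards <- c(1, 0)
  total <- 0
  for (c11 in 1:2) for (c21 in 1:2) for (c12 in 1:2) for (c22 in 1:2) {
    s <- data.frame(trial = 1:2, choice1 = c(c11, c12),
                    state2 = c(c11, c12),   # common transitions throughout
                    choice2 = c(c21, c22), reward = rewards,
                    common = 1L)
    total <- total + exp(hybrid_loglik(p, s))
  }
  expect_equal(total, 1, tolerance = 1e-12)
})

test_that("recoding rewards to -1/+1 with baseline 0 and halved temperatures
           leaves the likelihood unchanged", {
  env <- make_twostep_env(seed = 31)
  p <- rl_params(alpha = 0.35, beta_mb = 4, beta_mf = 3, beta_2 = 2.5,
                 p_stick = 0.4, beta_bias = -0.2)
  s <- simulate_twostep_agent(p, env, seed = 32)
  ll01 <- hybrid_loglik(p, s, baseline = 0.5)
  s2 <- s
  s2$reward <- 2 * s$reward - 1
  p2 <- rl_params(alpha = 0.35, beta_mb = 2, beta_mf = 1.5, beta_2 = 1.25,
                  p_stick = 0.4, beta_bias = -0.2)
  ll11 <- hybrid_loglik(p2, s2, baseline = 0)
  expect_equal(ll01, ll11, tolerance = 1e-10)
})

test_that("Q-values stay in [0, 1] (probabilities sum to 1 by construction)", {
  env <- make_twostep_env(seed = 41)
  for (alpha in c(0.1, 0.5, 0.9)) {
    p <- rl_params(alpha = alpha, beta_mb = 30, beta_mf = 30, beta_2 = 30)
    s <- simulate_twostep_agent(p, env, seed = 42)
    out <- hybrid_loglik(p, s, per_trial = TRUE)
    expect_true(all(out$p_stage1 > 0 & out$p_stage1 < 1))
    expect_true(all(out$p_stage2 > 0 & out$p_stage2 < 1))
    expect_true(all(is.finite(out$loglik)))
  }
})

test_that("generating parameters beat strongly perturbed ones in average
           likelihood on a long session", {
  env <- make_twostep_env(seed = 51, n_trials = 2000)
  p <- rl_params(alpha = 0.4, beta_mb = 4, beta_mf = 3, beta_2 = 2.5,
                 p_stick = 0.3)
  s <- simulate_twostep_agent(p, env, seed = 52)
  ll_true <- hybrid_loglik(p, s)
  for (q in list(rl_params(0.9, 0, 8, 0.5, -1),
                 rl_params(0.05, 8, 0, 6, 2),
                 rl_params(0.4, 0, 0, 0, 0))) {
    expect_gt(ll_true, hybrid_loglik(q, s))
  }
})

test_that("out-of-range learning rates are rejected", {
  expect_error(rl_params(alpha = 0), "alpha")
  expect_error(rl_params(alpha = 1), "alpha")
})
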