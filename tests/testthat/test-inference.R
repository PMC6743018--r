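test_that("z-scoring uses the population SD and rejects degenerate input", {
  expect_equal(zscore_within_draw(c(1, 2, 3)),
               c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  x <- rnorm(17)
  z <- zscore_within_draw(x)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(z^2)), 1, tolerance = 1e-12)
  expect_error(zscore_within_draw(rep(2, 5)), "constant")
  expect_error(zscore_within_draw(1), "at least 2")
})

test_that("split-chain R-hat separates mixed from unmixed chains", {
  set.seed(1)
  same <- matrix(rnorm(4000), ncol = 4)
  expect_lt(rhat(same), 1.05)
  apart <- cbind(rnorm(500), rnorm(500, 10))
  expect_gt(rhat(apart), 2)
  # within-chain drift is caught by splitting
  drift <- cbind(c(rnorm(250), rnorm(250, 5)), c(rnorm(250), rnorm(250, 5)))
  expect_gt(rhat(drift), 1.5)
  expect_equal(rhat(matrix(1, 100, 3)), 1)  # constant-chain convention
  expect_error(rhat(matrix(rnorm(100), ncol = 1)), "2 chains")
})

test_that("the joint log density decomposes and respects its support", {
  co <- small_cohort()
  spec <- joint_model_spec("hybrid", "prospect", chains = 2, samples = 20,
                           warmup = 10, thin = 1, seed = 1)
  m <- build_joint_model(co, spec)
  # a finite, varied point
  vals <- list()
  for (i in seq_along(m$subjects)) {
    vals[[sprintf("kappa[%d]", i)]] <- 1 + 0.2 * i
    vals[[sprintf("theta[%d]", i)]] <- 0.5 + 0.05 * i
    vals[[sprintf("gamma_g[%d]", i)]] <- 0.6 + 0.03 * i
  }
  th <- pack_params(m, vals)
  parts <- m$log_density_parts(th)
  expect_true(is.finite(parts$logpost))
  expect_equal(parts$logpost, parts$loglik + parts$logprior)

  # negative group SD is outside the support
  th_bad <- pack_params(m, c(vals, list(sigma_beta_mb = -1)))
  expect_identical(m$log_density(th_bad), -Inf)
  # learning rate outside (0, 1) likewise
  th_bad2 <- pack_params(m, c(vals, list(`alpha[1]` = 1.5)))
  expect_identical(m$log_density(th_bad2), -Inf)
})

test_that("duplicating the dataset doubles the data term at matched
           subject-level values", {
  co <- small_cohort()
  n <- length(unique(co$twostep$subject))
  ts2 <- co$twostep; gm2 <- co$gambling
  ts2$subject <- ts2$subject + n; gm2$subject <- gm2$subject + n
  dbl <- list(twostep = rbind(co$twostep, ts2),
              gambling = rbind(co$gambling, gm2))
  spec <- joint_model_spec("hybrid", "prospect", chains = 2, samples = 20,
                           warmup = 10, thin = 1, seed = 1)
  m1 <- build_joint_model(co, spec)
  m2 <- build_joint_model(dbl, spec)
  vals1 <- list(); vals2 <- list()
  for (i in seq_len(n)) {
    for (v in list(c("kappa", 1 + 0.2 * i), c("theta", 0.4 + 0.05 * i),
                   c("gamma_m", 0.7), c("gamma_g", 0.6 + 0.03 * i),
                   c("beta_mb", 2 + 0.3 * i), c("beta_mf", 1 + 0.1 * i))) {
      vals1[[sprintf("%s[%d]", v[1], i)]] <- as.numeric(v[2])
      vals2[[sprintf("%s[%d]", v[1], i)]] <- as.numeric(v[2])
      vals2[[sprintf("%s[%d]", v[1], i + n)]] <- as.numeric(v[2])
    }
  }
  ll1 <- m1$log_density_parts(pack_params(m1, vals1))$loglik
  ll2 <- m2$log_density_parts(pack_params(m2, vals2))$loglik
  expect_equal(ll2, 2 * ll1, tolerance = 1e-10)
})

test_that("the prior scale multiplier widens mean priors by the closed-form
           Gaussian difference", {
  co <- small_cohort()
  base <- joint_model_spec("hybrid", "prospect", chains = 2, samples = 20,
                           warmup = 10, thin = 1, seed = 1)
  wide <- prior_sensitivity_rerun(base)
  m1 <- build_joint_model(co, base)
  m10 <- build_joint_model(co, wide)
  vals <- list(mu_beta_mb = 3)
  for (i in seq_along(m1$subjects)) {
    vals[[sprintf("kappa[%d]", i)]] <- 1 + 0.2 * i
    vals[[sprintf("gamma_g[%d]", i)]] <- 0.6 + 0.03 * i
    vals[[sprintf("theta[%d]", i)]] <- 0.5 + 0.05 * i
  }
  th <- pack_params(m1, vals)
  d <- m10$log_density_parts(th)$logprior - m1$log_density_parts(th)$logprior
  # every mean-effect prior changes dnorm(x, 0, 10 s) - dnorm(x, 0, s);
  # compute the expected difference directly from the evaluated point
  nat <- stats::setNames(
    mbloss:::apply_transform(th, m1$transform), m1$param_names)
  mean_sc <- c(mu_logit_alpha = 5, mu_beta_mb = 10, mu_beta_mf = 10,
               mu_beta_2 = 10, mu_persev = 10,
               beta_mb_loss = 10, beta_mb_risk = 10, beta_mb_theta = 10,
               beta_mf_loss = 10, beta_mf_risk = 10, beta_mf_theta = 10,
               mu_log_kappa = 2, mu_gamma_m = 2, mu_gamma_g = 2,
               mu_theta = 10)
  expected <- sum(dnorm(nat[names(mean_sc)], 0, 10 * mean_sc, log = TRUE) -
                    dnorm(nat[names(mean_sc)], 0, mean_sc, log = TRUE))
  expect_equal(d, expected, tolerance = 1e-8)
})

test_that("subjects missing one task are rejected", {
  co <- small_cohort()
  gm <- co$gambling[co$gambling$subject != 3, ]
  spec <- joint_model_spec("hybrid", "prospect")
  expect_error(build_joint_model(list(twostep = co$twostep, gambling = gm),
                                 spec), "both tasks")
})

test_that("run_mcmc returns the contracted draw counts, names, and is
           seed-reproducible", {
  co <- small_cohort()
  spec <- joint_model_spec("hybrid", "prospect", chains = 3, samples = 40,
                           warmup = 20, thin = 2, seed = 5)
  m <- build_joint_model(co, spec)
  fit <- run_mcmc(m)
  expect_s3_class(fit, "posterior_draws")
  expect_equal(dim(fit$draws), c(20L, 3L, m$n_theta))
  expect_equal(dimnames(fit$draws)[[3]], m$param_names)
  expect_true(all(is.finite(fit$draws)))
  # natural-scale constraints hold
  expect_true(all(fit$draws[, , "kappa[1]"] > 0))
  expect_true(all(fit$draws[, , "alpha[2]"] > 0 &
                    fit$draws[, , "alpha[2]"] < 1))
  fit2 <- run_mcmc(m)
  expect_identical(fit$draws, fit2$draws)
  spec2 <- spec; spec2$seed <- 6L
  fit3 <- run_mcmc(m, spec2)
  expect_false(identical(fit$draws, fit3$draws))
})

test_that("posterior draws persist to text and round-trip with chain
           structure intact", {
  co <- small_cohort()
  spec <- joint_model_spec("hybrid", "prospect", chains = 2, samples = 24,
                           warmup = 12, thin = 1, seed = 13)
  fit <- fit_joint_model(co, spec)
  path <- tempfile(fileext = ".tsv")
  write_draws(fit, path)
  back <- read_draws(path)
  expect_identical(unname(back$draws), unname(fit$draws))
  expect_identical(back$param_names, fit$param_names)
  expect_equal(back$spec$twostep_model, "hybrid")
  expect_equal(rhat(back), rhat(fit))
  unlink(path)
})

test_that("per-draw z-scored covariates are standardized within every draw", {
  co <- small_cohort()
  spec <- joint_model_spec("hybrid", "prospect", chains = 2, samples = 30,
                           warmup = 15, thin = 1, seed = 7)
  fit <- fit_joint_model(co, spec)
  cov <- mbloss:::subject_covariate_draws(fit)
  for (v in list(cov$log_kappa, cov$risk, cov$theta)) {
    z <- t(apply(v, 1, zscore_within_draw))
    expect_equal(rowMeans(z), rep(0, nrow(z)), tolerance = 1e-10)
    expect_equal(sqrt(rowMeans(z^2)), rep(1, nrow(z)), tolerance = 1e-10)
  }
})

test_that("the two-stage covariate mode accepts fixed covariates", {
  co <- small_cohort()
  spec <- joint_model_spec("hybrid", "prospect", chains = 2, samples = 30,
                           warmup = 15, thin = 1, seed = 8,
                           zscore_mode = "two_stage")
  expect_error(build_joint_model(co, spec), "fixed_covariates")
  fixed <- data.frame(subject = co$truth$subject,
                      loss = co$truth$log_kappa,
                      risk = co$truth$risk,
                      theta = co$truth$theta)
  fit <- fit_joint_model(co, spec, fixed_covariates = fixed)
  expect_equal(dim(fit$draws)[1], 15L)
  expect_true(all(is.finite(fit$draws)))
})

test_that("doubling trials per subject sharpens subject-level beta_mb", {
  cs_short <- cohort_spec(n_subjects = 6, seed = 91, n_trials = 100)
  cs_long <- cohort_spec(n_subjects = 6, seed = 91, n_trials = 400)
  spec <- joint_model_spec("hybrid", "prospect", chains = 2, samples = 350,
                           warmup = 150, thin = 3, seed = 9)
  sd_of <- function(co) {
    fit <- fit_joint_model(co, spec)
    mean(vapply(seq_len(6), function(i)
      stats::sd(extract_draws(fit, sprintf("beta_mb[%d]", i))), numeric(1)))
  }
  expect_lt(sd_of(simulate_cohort(cs_long)),
            sd_of(simulate_cohort(cs_short)))
})
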