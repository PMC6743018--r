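# A hand-built posterior_draws object for reporting unit tests.
fake_fit <- function(draws_list, n_subjects = 0, chains = 2,
                     twostep_model = "hybrid", gambling_model = "prospect") {
  nit <- length(draws_list[[1]]) / chains
  arr <- array(NA_real_, dim = c(nit, chains, length(draws_list)),
               dimnames = list(NULL, paste0("chain", seq_len(chains)),
                               names(draws_list)))
  for (v in names(draws_list)) arr[, , v] <- draws_list[[v]]
  spec <- joint_model_spec(twostep_model, gambling_model, chains = chains,
                           samples = nit + 1, warmup = 1, thin = 1)
  structure(list(draws = arr, param_names = names(draws_list),
                 subjects = seq_len(n_subjects), spec = spec,
                 accept_rate = 0.4, runtime_s = 0),
            class = "posterior_draws")
}

test_that("posterior summaries match their definitions", {
  fit <- fake_fit(list(a = rep(c(-1, 1), 500), b = abs(rnorm(1000)) + 0.1))
  s <- summarize_posterior(fit, "a")
  expect_equal(s$median, 0)
  expect_equal(s$p_leq_zero, 0.5)
  expect_equal(summarize_posterior(fit, "b")$p_leq_zero, 0)
  expect_error(summarize_posterior(fit, "zzz"), "unknown variable")

  set.seed(2)
  fitn <- fake_fit(list(x = rnorm(20000)))
  sn <- summarize_posterior(fitn, "x")
  expect_equal(sn$ci_lower, -1.96, tolerance = 0.08)
  expect_equal(sn$ci_upper, 1.96, tolerance = 0.08)
})

test_that("differential effects summarize the per-draw difference", {
  set.seed(3)
  a <- rnorm(2000, 3); b <- rnorm(2000, 0)
  fit <- fake_fit(list(a = a, b = b))
  d <- differential_effect(fit, "a", "b")
  expect_equal(d$median, 3, tolerance = 0.15)
  expect_equal(unname(unlist(d[c("median", "ci_lower", "ci_upper")])),
               unname(quantile(a - b, c(0.5, 0.025, 0.975))))
  same <- differential_effect(fit, "a", "a")
  expect_equal(same$median, 0)
  expect_equal(same$ci_lower, 0)
})

test_that("formatted tables are deterministic given the draws", {
  fit <- fake_fit(list(a = rep(c(-1, 1), 500), b = rnorm(1000)))
  rows <- rbind(summarize_posterior(fit, "a", "first"),
                summarize_posterior(fit, "b", "second"))
  t1 <- format_summary_table(rows)
  t2 <- format_summary_table(rows)
  expect_identical(t1, t2)
  expect_named(t1, c("Parameter", "Description",
                     "Median & 95% credible interval", "1-p(x>0)"))
  expect_match(t1[["Median & 95% credible interval"]][1],
               "^-?\\d+\\.\\d{3} \\(-?\\d+\\.\\d{3}, -?\\d+\\.\\d{3}\\)$")
})

make_subject_fit <- function(n = 6, nit = 400, couple = 0) {
  set.seed(11)
  vars <- list()
  logk <- rnorm(n, 0.5, 0.5)
  for (i in seq_len(n)) {
    vars[[sprintf("beta_mb[%d]", i)]] <-
      rnorm(nit, 4 + couple * logk[i], 0.3)
    vars[[sprintf("beta_mf[%d]", i)]] <- rnorm(nit, 3, 0.3)
    vars[[sprintf("beta_2[%d]", i)]] <- rnorm(nit, 2, 0.3)
    vars[[sprintf("kappa[%d]", i)]] <- exp(rnorm(nit, logk[i], 0.05))
    vars[[sprintf("gamma_g[%d]", i)]] <- rnorm(nit, 0.8, 0.02)
    vars[[sprintf("theta[%d]", i)]] <- abs(rnorm(nit, 1, 0.05))
  }
  fake_fit(vars, n_subjects = n)
}

test_that("correlation posteriors behave on constructed draws", {
  fit <- make_subject_fit(couple = 4)
  rho <- correlation_posterior(fit, "mb", "log_kappa")
  expect_length(rho, 400)
  expect_gt(median(rho), 0.5)
  # residualizing on nothing and correlating a variable with itself gives 1
  n <- length(fit$subjects)
  self <- vapply(seq_len(n), function(i)
    extract_draws(fit, sprintf("beta_mb[%d]", i)),
    numeric(400))
  expect_equal(mbloss:::partial_cor(self[1, ], self[1, ], NULL), 1)
  # affine rescaling of the measure leaves the correlation unchanged
  set.seed(21)
  x <- rnorm(12); y <- rnorm(12); C <- cbind(rnorm(12), rnorm(12))
  expect_equal(mbloss:::partial_cor(x, 2.5 * y + 3, C),
               mbloss:::partial_cor(x, y, C), tolerance = 1e-12)
  rho_pt <- correlation_posterior(fit, "mb", "log_kappa",
                                  point_estimate = TRUE)
  expect_true(abs(rho_pt) <= 1)
  fit0 <- make_subject_fit(couple = 0)
  rho0 <- correlation_posterior(fit0, "mf", "risk")
  expect_lt(abs(median(rho0)), 0.6)
  expect_error(correlation_posterior(make_subject_fit(n = 3), "mb",
                                     "log_kappa"), "4 subjects")
})

test_that("performance exclusion applies the three-interval rule", {
  nit <- 500
  set.seed(12)
  vars <- list()
  # subject 1: all three intervals straddle 0 -> excluded
  vars[["beta_mb[1]"]] <- rnorm(nit, 0, 1)
  vars[["beta_mf[1]"]] <- rnorm(nit, 0, 1)
  vars[["beta_2[1]"]] <- rnorm(nit, 0, 1)
  # subject 2: beta_2 strictly positive -> retained
  vars[["beta_mb[2]"]] <- rnorm(nit, 0, 1)
  vars[["beta_mf[2]"]] <- rnorm(nit, 0, 1)
  vars[["beta_2[2]"]] <- rnorm(nit, 5, 0.1)
  # subject 3: everything strong -> retained
  vars[["beta_mb[3]"]] <- rnorm(nit, 5, 0.1)
  vars[["beta_mf[3]"]] <- rnorm(nit, 5, 0.1)
  vars[["beta_2[3]"]] <- rnorm(nit, 5, 0.1)
  fit <- fake_fit(vars, n_subjects = 3)
  kept <- performance_exclusion(fit)
  expect_equal(as.integer(kept), c(2L, 3L))
  expect_equal(as.integer(attr(kept, "excluded")), 1L)
  expect_identical(performance_exclusion(fit), performance_exclusion(fit))
})

test_that("prior sensitivity rerun multiplies only the mean-prior scales", {
  spec <- joint_model_spec("hybrid", "prospect")
  s10 <- prior_sensitivity_rerun(spec)
  expect_equal(s10$prior_scale_multiplier, 10)
  expect_warning(s100 <- prior_sensitivity_rerun(s10), "already")
  expect_equal(s100$prior_scale_multiplier, 100)
  # everything else untouched (the half-Cauchy SD scale is a model constant)
  s10$prior_scale_multiplier <- spec$prior_scale_multiplier
  expect_identical(s10, spec)
})

test_that("recovery reports compare medians and intervals against truth", {
  fit <- make_subject_fit()
  n <- length(fit$subjects)
  med <- vapply(seq_len(n), function(i)
    median(extract_draws(fit, sprintf("beta_mb[%d]", i))), numeric(1))
  truth <- data.frame(subject = seq_len(n), beta_mb = med,
                      kappa = vapply(seq_len(n), function(i)
                        median(extract_draws(fit, sprintf("kappa[%d]", i))),
                        numeric(1)))
  rep1 <- recovery_report(truth, fit)
  expect_setequal(rep1$parameter, c("beta_mb", "kappa"))
  bm <- rep1[rep1$parameter == "beta_mb", ]
  expect_equal(bm$bias, 0, tolerance = 1e-12)
  expect_equal(bm$rmse, 0, tolerance = 1e-12)
  expect_equal(bm$coverage, 1)
  expect_error(recovery_report(truth[-1, ], fit), "missing")
  expect_error(recovery_report(truth, fit, parameters = "nope"), "must exist")
})
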