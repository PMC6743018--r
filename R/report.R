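#' Posterior summary of one variable
#'
#' Median, central 95% credible interval (2.5% and 97.5% quantiles over all
#' retained draws pooled across chains), and the one-sided mass
#' `1 - p(x > 0)`, computed as the fraction of draws <= 0 (ties at exactly 0
#' count against positivity, which makes the summary deterministic).
#'
#' @param fit A `posterior_draws` object.
#' @param variable Variable name.
#' @param description Optional human-readable description.
#' @return One-row data frame of class `summary_row`: `parameter`,
#'   `description`, `median`, `ci_lower`, `ci_upper`, `p_leq_zero`.
#' @export
summarize_posterior <- function(fit, variable, description = "") {
  x <- extract_draws(fit, variable)
  summary_row(x, variable, description)
}

summary_row <- function(x, parameter, description = "") {
  q <- unname(stats::quantile(x, c(0.025, 0.5, 0.975)))
  out <- data.frame(parameter = parameter, description = description,
                    median = q[2], ci_lower = q[1], ci_upper = q[3],
                    p_leq_zero = mean(x <= 0))
  class(out) <- c("summary_row", "data.frame")
  out
}

#' Posterior summary of the difference of two variables
#'
#' Summarizes the per-draw difference `var_a - var_b` (e.g. the differential
#' effect of loss aversion on model-based vs. model-free control).
#'
#' @inheritParams summarize_posterior
#' @param var_a,var_b Variable names; draws are aligned by iteration/chain.
#' @return A `summary_row` for the difference.
#' @export
differential_effect <- function(fit, var_a, var_b, description = "") {
  a <- extract_draws(fit, var_a)
  b <- extract_draws(fit, var_b)
  if (length(a) != length(b))
    stop("mismatched draw counts", call. = FALSE)  # cannot happen within one fit
  summary_row(a - b, sprintf("%s - %s", var_a, var_b), description)
}

#' Layout a set of posterior summaries as a report table
#'
#' Formats rows in the style `parameter | description |
#' median (2.5%, 97.5%) | 1-p(x>0)` with three decimals, so tables are
#' byte-stable under fixed seeds.
#'
#' @param rows A data frame of stacked `summary_row`s.
#' @return Character-column data frame ready to print or write.
#' @export
format_summary_table <- function(rows) {
  data.frame(
    Parameter = rows$parameter,
    Description = rows$description,
    `Median & 95% credible interval` = sprintf(
      "%.3f (%.3f, %.3f)", rows$median, rows$ci_lower, rows$ci_upper),
    `1-p(x>0)` = sprintf("%.3f", rows$p_leq_zero),
    check.names = FALSE)
}

#' Group-level effects table for a fitted joint model
#'
#' Builds the standard reporting table for a fit: the model-free and
#' model-based main effects, the three covariate effects on each, and the
#' differential (model-based minus model-free) covariate effects.
#'
#' @param fit A `posterior_draws` object.
#' @return Formatted character table (see [format_summary_table()]).
#' @export
group_effects_table <- function(fit) {
  hyb <- fit$spec$twostep_model == "hybrid"
  mf <- if (hyb) "mu_beta_mf" else "mu_reward"
  mb <- if (hyb) "mu_beta_mb" else "mu_reward_common"
  eff <- function(sys, cov) {
    if (hyb) sprintf("beta_%s_%s", sys, cov)
    else sprintf("g_reward%s_%s", if (sys == "mb") "_common" else "", cov)
  }
  covs <- c("loss", "risk", "theta")
  cov_desc <- c(loss = "loss aversion", risk = "risk aversion",
                theta = "gamble inverse temperature")
  rows <- rbind(
    summarize_posterior(fit, mf, "Model-free control"),
    do.call(rbind, lapply(covs, function(cv) summarize_posterior(
      fit, eff("mf", cv),
      sprintf("Effect of %s on model-free control", cov_desc[cv])))),
    summarize_posterior(fit, mb, "Model-based control"),
    do.call(rbind, lapply(covs, function(cv) summarize_posterior(
      fit, eff("mb", cv),
      sprintf("Effect of %s on model-based control", cov_desc[cv])))),
    do.call(rbind, lapply(covs, function(cv) differential_effect(
      fit, eff("mb", cv), eff("mf", cv),
      sprintf("Differential effect of %s on model-based control",
              cov_desc[cv])))))
  format_summary_table(rows)
}

#' Draw-wise correlation posterior between a decision system and a gambling
#' measure
#'
#' For every retained draw, computes across subjects the Pearson correlation
#' between the subject-level system weight (`beta_mb` or `beta_mf`) and the
#' gambling measure (log loss aversion or the risk measure), after
#' residualizing both on the control covariates (by default the other two
#' gambling covariates, e.g. risk aversion and the gambling inverse
#' temperature when the measure is log loss aversion).
#'
#' @param fit A `posterior_draws` object from a hybrid-model fit.
#' @param system `"mb"` or `"mf"`.
#' @param measure `"log_kappa"` or `"risk"`.
#' @param controls Character vector among `"log_kappa"`, `"risk"`,
#'   `"theta"`; defaults to the two covariates other than `measure`.
#' @param point_estimate If `TRUE`, return instead the single correlation
#'   between per-subject posterior medians.
#' @return Numeric vector of per-draw partial correlations (or a scalar).
#' @export
correlation_posterior <- function(fit, system = c("mb", "mf"),
                                  measure = c("log_kappa", "risk"),
                                  controls = NULL, point_estimate = FALSE) {
  system <- match.arg(system)
  measure <- match.arg(measure)
  if (fit$spec$twostep_model != "hybrid")
    stop("subject-level system weights require a hybrid-model fit",
         call. = FALSE)
  n <- length(fit$subjects)
  if (n < 4L) stop("need at least 4 subjects", call. = FALSE)
  if (is.null(controls))
    controls <- setdiff(c("log_kappa", "risk", "theta"), measure)
  cov <- subject_covariate_draws(fit)
  sys_d <- vapply(seq_len(n), function(i)
    extract_draws(fit, sprintf("beta_%s[%d]", system, i)),
    numeric(prod(dim(fit$draws)[1:2])))
  if (point_estimate) {
    x <- apply(sys_d, 2, stats::median)
    y <- apply(cov[[measure]], 2, stats::median)
    C <- vapply(controls, function(cn) apply(cov[[cn]], 2, stats::median),
                numeric(n))
    return(partial_cor(x, y, C))
  }
  vapply(seq_len(nrow(sys_d)), function(d) {
    C <- vapply(controls, function(cn) cov[[cn]][d, ], numeric(n))
    partial_cor(sys_d[d, ], cov[[measure]][d, ], C)
  }, numeric(1))
}

partial_cor <- function(x, y, controls) {
  if (length(controls) == 0L || NCOL(controls) == 0L) return(stats::cor(x, y))
  Z <- cbind(1, controls)
  rx <- stats::lm.fit(Z, x)$residuals
  ry <- stats::lm.fit(Z, y)$residuals
  stats::cor(rx, ry)
}

#' Performance-based subject exclusion
#'
#' Flags subjects whose 95% credible intervals for performance at both task
#' steps all include 0: both stage-1 control weights (`beta_mb` AND
#' `beta_mf`) and the stage-2 weight (`beta_2`). A subject is retained if
#' any of the three intervals excludes 0.
#'
#' @param fit A `posterior_draws` object from a hybrid-model fit.
#' @param level Credible level of the intervals.
#' @return The retained subject ids, with the excluded ids as attribute
#'   `excluded`.
#' @export
performance_exclusion <- function(fit, level = 0.95) {
  if (fit$spec$twostep_model != "hybrid")
    stop("exclusion uses hybrid-model subject weights", call. = FALSE)
  a <- (1 - level) / 2
  straddles <- function(base, i) {
    q <- stats::quantile(extract_draws(fit, sprintf("%s[%d]", base, i)),
                         c(a, 1 - a))
    q[1] <= 0 && q[2] >= 0
  }
  n <- length(fit$subjects)
  excl <- vapply(seq_len(n), function(i)
    straddles("beta_mb", i) && straddles("beta_mf", i) &&
      straddles("beta_2", i), logical(1))
  out <- fit$subjects[!excl]
  attr(out, "excluded") <- fit$subjects[excl]
  out
}

#' Prior sensitivity rerun specification
#'
#' Returns the spec with the prior scale multiplier increased tenfold, so
#' all mean-effect priors widen by 10 while the half-Cauchy SD hyperpriors
#' stay untouched. Applying it to an already-widened spec compounds the
#' multiplier (with a warning).
#'
#' @param spec A [joint_model_spec()].
#' @return The modified spec.
#' @export
prior_sensitivity_rerun <- function(spec) {
  stopifnot(inherits(spec, "joint_model_spec"))
  if (spec$prior_scale_multiplier != 1)
    warning("prior scale multiplier already ", spec$prior_scale_multiplier,
            "; multiplying again", call. = FALSE)
  spec$prior_scale_multiplier <- spec$prior_scale_multiplier * 10
  spec
}

#' Parameter-recovery report
#'
#' Compares subject-level posteriors against the generative ground truth:
#' for each parameter, the mean bias of the posterior median, the RMSE, and
#' the empirical coverage of the 95% credible intervals.
#'
#' @param truth Data frame with a `subject` column and one column per
#'   parameter (names matching the fit's subject-level variable bases, e.g.
#'   `beta_mb`).
#' @param fit A `posterior_draws` object.
#' @param parameters Parameter bases to report; defaults to all subject-level
#'   bases present in both the fit and `truth`.
#' @return Data frame with columns `parameter`, `bias`, `rmse`, `coverage`.
#' @export
recovery_report <- function(truth, fit, parameters = NULL) {
  n <- length(fit$subjects)
  bases <- unique(sub("\\[\\d+\\]$", "",
                      grep("\\[", fit$param_names, value = TRUE)))
  if (is.null(parameters)) parameters <- intersect(bases, names(truth))
  if (!all(parameters %in% names(truth)) || !all(parameters %in% bases))
    stop("parameters must exist in both `truth` and the fit", call. = FALSE)
  idx <- match(fit$subjects, truth$subject)
  if (anyNA(idx)) stop("`truth` is missing fitted subjects", call. = FALSE)
  rows <- lapply(parameters, function(p) {
    tv <- truth[[p]][idx]
    d <- vapply(seq_len(n), function(i)
      extract_draws(fit, sprintf("%s[%d]", p, i)),
      numeric(prod(dim(fit$draws)[1:2])))
    med <- apply(d, 2, stats::median)
    q <- apply(d, 2, stats::quantile, c(0.025, 0.975))
    data.frame(parameter = p, bias = mean(med - tv),
               rmse = sqrt(mean((med - tv)^2)),
               coverage = mean(q[1, ] <= tv & tv <= q[2, ]))
  })
  do.call(rbind, rows)
}

#' End-to-end parameter-recovery run
#'
#' Simulates a cohort, fits the requested joint model, and reports recovery
#' of the subject-level parameters together with the posterior summaries of
#' the coupling coefficients.
#'
#' @param cspec A [cohort_spec()].
#' @param mspec A [joint_model_spec()].
#' @return List with the cohort, the fit, the [recovery_report()], and the
#'   coupling-coefficient summary table.
#' @export
recover_cohort <- function(cspec, mspec) {
  cohort <- simulate_cohort(cspec)
  fit <- fit_joint_model(cohort, mspec)
  couplings <- if (mspec$twostep_model == "hybrid")
    c("beta_mb_loss", "beta_mb_risk", "beta_mb_theta",
      "beta_mf_loss", "beta_mf_risk", "beta_mf_theta")
  else paste0("g_", reg_g_names)
  rows <- do.call(rbind, lapply(couplings, function(v)
    summarize_posterior(fit, v)))
  list(cohort = cohort, fit = fit,
       recovery = recovery_report(cohort$truth, fit),
       couplings = rows)
}

#' Scatter of decision-system weight against a gambling measure
#'
#' Plots per-subject posterior medians of the system weight against the
#' measure (both residualized on the controls), with the draw-wise
#' correlation posterior summarized in the subtitle. Requires ggplot2.
#'
#' @inheritParams correlation_posterior
#' @return A ggplot object.
#' @export
plot_correlation <- function(fit, system = c("mb", "mf"),
                             measure = c("log_kappa", "risk"),
                             controls = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_correlation requires ggplot2", call. = FALSE)
  system <- match.arg(system)
  measure <- match.arg(measure)
  if (is.null(controls))
    controls <- setdiff(c("log_kappa", "risk", "theta"), measure)
  n <- length(fit$subjects)
  cov <- subject_covariate_draws(fit)
  sys_d <- vapply(seq_len(n), function(i)
    extract_draws(fit, sprintf("beta_%s[%d]", system, i)),
    numeric(prod(dim(fit$draws)[1:2])))
  Cm <- vapply(controls, function(cn) apply(cov[[cn]], 2, stats::median),
               numeric(n))
  Z <- cbind(1, Cm)
  df <- data.frame(
    x = stats::lm.fit(Z, apply(cov[[measure]], 2, stats::median))$residuals,
    y = stats::lm.fit(Z, apply(sys_d, 2, stats::median))$residuals)
  rho <- correlation_posterior(fit, system, measure, controls)
  q <- stats::quantile(rho, c(0.025, 0.5, 0.975))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         color = "black") +
    ggplot2::labs(
      x = sprintf("%s (residualized)",
                  if (measure == "log_kappa") "log loss aversion"
                  else "risk aversion"),
      y = sprintf("beta_%s (residualized medians)", system),
      subtitle = sprintf("correlation posterior: %.2f (%.2f, %.2f)",
                         q[2], q[1], q[3]))
}
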