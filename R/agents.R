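#' Simulate a hybrid learner on the two-step task
#'
#' Runs the same value-update and choice code path as [hybrid_loglik()]
#' generatively: on each trial the agent's stage-1 and stage-2 choices are
#' drawn from the model's softmax probabilities, the second-stage state is
#' drawn from the environment's transition structure, and the binary reward
#' from the current payoff probability. No trials are aborted.
#'
#' @param params An [rl_params()] object.
#' @param env A [make_twostep_env()] environment.
#' @param seed Integer seed; the session is deterministic given the seed.
#' @param baseline Reference value (Q initialization and decay target).
#' @return A data frame of class `twostep_session` with columns `trial`,
#'   `choice1`, `state2`, `choice2`, `reward`, `common`, `aborted`, and
#'   attributes `p_stage1` / `p_stage2` (the probabilities of the emitted
#'   choices) and `loglik` (their summed logs).
#' @export
simulate_twostep_agent <- function(params, env, seed, baseline = 0.5) {
  stopifnot(inherits(params, "rl_params"), inherits(env, "twostep_env"))
  res <- withr_seed(seed, {
    cpp_simulate_twostep(env$payoff_probs, env$mapping, env$p_common,
                         unlist(params[c("alpha", "beta_mb", "beta_mf",
                                         "beta_2", "p_stick", "beta_bias")]),
                         params$lambda, baseline)
  })
  choice1 <- res$choice1 + 1L
  state2 <- res$state2 + 1L
  out <- data.frame(trial = seq_along(choice1),
                    choice1 = choice1,
                    state2 = state2,
                    choice2 = res$choice2 + 1L,
                    reward = res$reward,
                    common = as.integer(env$mapping[choice1] == state2),
                    aborted = 0L)
  attr(out, "p_stage1") <- res$p_stage1
  attr(out, "p_stage2") <- res$p_stage2
  attr(out, "loglik") <- res$loglik
  class(out) <- c("twostep_session", "data.frame")
  out
}

#' Simulate a gambler on an offer list
#'
#' Draws each gamble/sure choice from a Bernoulli with the softmax gamble
#' probability implied by the utility model, using the same utility code
#' path as [gambling_loglik()].
#'
#' @param params A [pt_params()] or [mv_params()] object.
#' @param offers A [make_gambling_offers()] offer table.
#' @param seed Integer seed.
#' @return A data frame of class `gambling_session` with the offer columns
#'   plus `choice` (1 = gamble), and attribute `prob_gamble`.
#' @export
simulate_gambler <- function(params, offers, seed) {
  p <- gamble_probs(params, offers)
  choice <- withr_seed(seed, stats::rbinom(length(p), 1L, p))
  out <- cbind(as.data.frame(offers), choice = choice)
  attr(out, "prob_gamble") <- p
  class(out) <- c("gambling_session", "data.frame")
  out
}

#' Cohort specification for synthetic joint data
#'
#' Describes the group-level generative distributions for a cohort of
#' subjects who each complete one two-step session and one gambling session,
#' together with the cross-task coupling: each subject's model-based (and
#' optionally model-free) weight is drawn around a mean shifted by the
#' coupling coefficients applied to the cohort-z-scored gambling covariates
#' (log loss aversion, risk preference, inverse temperature).
#'
#' Defaults mirror the study design (201 two-step trials with 70/30
#' transitions and drifting payoffs; 60 mixed + 20 gain-only gambles) with
#' group means in the range reported for human cohorts on these tasks and a
#' single planted coupling of log loss aversion into the model-based weight.
#'
#' @param n_subjects Number of subjects (>= 2, required for z-scoring).
#' @param seed Integer seed.
#' @param gambling_model `"prospect"` or `"meanvariance"`.
#' @param coupling_mb,coupling_mf Length-3 coupling coefficients
#'   (loss, risk, theta) shifting `beta_mb` / `beta_mf`.
#' @param means,sds Named numeric vectors overriding individual group means
#'   / SDs; see `cohort_defaults()` in the source for the full set.
#' @param n_trials,n_mixed,n_gain_only Per-subject trial counts.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 117L, seed = 1L,
                        gambling_model = c("prospect", "meanvariance"),
                        coupling_mb = c(loss = 3.6, risk = 0, theta = 0),
                        coupling_mf = c(loss = 0, risk = 0, theta = 0),
                        means = NULL, sds = NULL,
                        n_trials = 201L, n_mixed = 60L, n_gain_only = 20L) {
  gambling_model <- match.arg(gambling_model)
  n_subjects <- as.integer(n_subjects)
  if (is.na(n_subjects) || n_subjects < 2L)
    stop("`n_subjects` must be at least 2 (covariates are z-scored across ",
         "the cohort)", call. = FALSE)
  def <- cohort_defaults(gambling_model)
  if (!is.null(means)) {
    stopifnot(all(names(means) %in% names(def$means)))
    def$means[names(means)] <- means
  }
  if (!is.null(sds)) {
    stopifnot(all(names(sds) %in% names(def$sds)))
    if (any(sds < 0)) stop("group SDs must be >= 0", call. = FALSE)
    def$sds[names(sds)] <- sds
  }
  structure(list(n_subjects = n_subjects, seed = as.integer(seed),
                 gambling_model = gambling_model,
                 coupling_mb = coupling_mb, coupling_mf = coupling_mf,
                 means = def$means, sds = def$sds,
                 n_trials = as.integer(n_trials), n_mixed = as.integer(n_mixed),
                 n_gain_only = as.integer(n_gain_only)),
            class = "cohort_spec")
}

# Group-level generative defaults. Learner means sit in the range reported
# for human cohorts on this task; gambling means give kappa ~ 1.6, mild
# curvature, and choice stochasticity that leaves both tasks informative.
cohort_defaults <- function(gambling_model) {
  means <- c(logit_alpha = 0, beta_mb = 5.5, beta_mf = 4.2, beta_2 = 2.5,
             persev = 0.3, beta_bias = 0,
             log_kappa = 0.5, theta = 1.0)
  sds <- c(logit_alpha = 0.8, beta_mb = 2.0, beta_mf = 1.5, beta_2 = 0.8,
           persev = 0.3, beta_bias = 0.3,
           log_kappa = 0.5, theta = 0.5)
  if (gambling_model == "prospect") {
    means <- c(means, gamma_m = 0.7, gamma_g = 0.8)
    sds <- c(sds, gamma_m = 0.15, gamma_g = 0.15)
  } else {
    means <- c(means, w = 0.3)
    means[["theta"]] <- 0.5
    sds <- c(sds, w = 0.2)
    sds[["theta"]] <- 0.25
  }
  list(means = means, sds = sds)
}

# Truncated-at-zero Gaussian draws via the inverse CDF.
rtnorm0 <- function(n, mean, sd) {
  lo <- stats::pnorm(0, mean, sd)
  stats::qnorm(stats::runif(n, lo, 1), mean, sd)
}

#' Simulate a joint cohort with planted cross-task coupling
#'
#' Draws each subject's gambling parameters from the group distributions
#' (log-normal loss aversion; zero-truncated Gaussians for curvature / SD
#' penalty and inverse temperature), z-scores the three covariates across
#' the cohort (log kappa; risk measured as `1 - gamma_g` under prospect
#' theory or `w` under mean-variance; theta), shifts each subject's mean
#' `beta_mb` and `beta_mf` by the coupling coefficients, draws the remaining
#' learner parameters, and simulates both sessions per subject.
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `cohort`: `twostep` and `gambling` (stacked
#'   per-trial data frames with a `subject` column), `truth` (per-subject
#'   generative parameters and z-scored covariates), and `spec`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_subjects
  mu <- spec$means; sd <- spec$sds
  pt <- spec$gambling_model == "prospect"

  truth <- withr_seed(spec$seed, {
    log_kappa <- stats::rnorm(n, mu[["log_kappa"]], sd[["log_kappa"]])
    theta <- rtnorm0(n, mu[["theta"]], sd[["theta"]])
    if (pt) {
      gamma_m <- rtnorm0(n, mu[["gamma_m"]], sd[["gamma_m"]])
      gamma_g <- rtnorm0(n, mu[["gamma_g"]], sd[["gamma_g"]])
      risk <- 1 - gamma_g
    } else {
      w <- rtnorm0(n, mu[["w"]], sd[["w"]])
      risk <- w
    }
    z <- cbind(loss = zscore_within_draw(log_kappa),
               risk = zscore_within_draw(risk),
               theta = zscore_within_draw(theta))
    beta_mb <- stats::rnorm(n, mu[["beta_mb"]] + z %*% spec$coupling_mb,
                            sd[["beta_mb"]])
    beta_mf <- stats::rnorm(n, mu[["beta_mf"]] + z %*% spec$coupling_mf,
                            sd[["beta_mf"]])
    out <- data.frame(
      subject = seq_len(n),
      alpha = stats::plogis(stats::rnorm(n, mu[["logit_alpha"]],
                                         sd[["logit_alpha"]])),
      beta_mb = beta_mb, beta_mf = beta_mf,
      beta_2 = stats::rnorm(n, mu[["beta_2"]], sd[["beta_2"]]),
      persev = stats::rnorm(n, mu[["persev"]], sd[["persev"]]),
      beta_bias = stats::rnorm(n, mu[["beta_bias"]], sd[["beta_bias"]]),
      kappa = exp(log_kappa), log_kappa = log_kappa, theta = theta,
      risk = risk, z_loss = z[, 1], z_risk = z[, 2], z_theta = z[, 3])
    if (pt) {
      out$gamma_m <- gamma_m; out$gamma_g <- gamma_g
    } else out$w <- w
    out$seed_ts <- sample.int(2^31 - 2, n)
    out$seed_gm <- sample.int(2^31 - 2, n)
    out
  })

  ts_list <- vector("list", n)
  gm_list <- vector("list", n)
  for (i in seq_len(n)) {
    rp <- rl_params(alpha = truth$alpha[i], beta_mb = truth$beta_mb[i],
                    beta_mf = truth$beta_mf[i], beta_2 = truth$beta_2[i],
                    p_stick = truth$persev[i], beta_bias = truth$beta_bias[i])
    env <- make_twostep_env(seed = truth$seed_ts[i], n_trials = spec$n_trials)
    s <- simulate_twostep_agent(rp, env, seed = truth$seed_ts[i] %% 2^20 + i)
    s <- cbind(subject = i, as.data.frame(s))
    ts_list[[i]] <- s

    gp <- if (pt)
      pt_params(truth$kappa[i], truth$gamma_m[i], truth$gamma_g[i],
                truth$theta[i])
    else mv_params(truth$kappa[i], truth$w[i], truth$theta[i])
    offers <- make_gambling_offers(seed = truth$seed_gm[i],
                                   n_mixed = spec$n_mixed,
                                   n_gain_only = spec$n_gain_only)
    g <- simulate_gambler(gp, offers, seed = truth$seed_gm[i] %% 2^20 + i)
    gm_list[[i]] <- cbind(subject = i, as.data.frame(g))
  }

  structure(list(twostep = do.call(rbind, ts_list),
                 gambling = do.call(rbind, gm_list),
                 truth = truth, spec = spec),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Synthetic joint cohort: %d subjects (%s gambling model)\n",
              x$spec$n_subjects, x$spec$gambling_model))
  cat(sprintf("  two-step trials/subject: %d; gambles/subject: %d\n",
              x$spec$n_trials, x$spec$n_mixed + x$spec$n_gain_only))
  cat(sprintf("  coupling into beta_mb (loss, risk, theta): %s\n",
              paste(format(x$spec$coupling_mb), collapse = ", ")))
  invisible(x)
}
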