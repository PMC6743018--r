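#' Specify a joint two-task hierarchical model
#'
#' Chooses one two-step likelihood (trial-pair stay regression or hybrid
#' learner) and one gambling likelihood (prospect theory or mean-variance),
#' the MCMC settings, and the prior-scale multiplier used for sensitivity
#' reruns. Exactly one model per task is fitted per run; the two tasks are
#' coupled through the per-draw z-scored gambling covariates.
#'
#' `samples` counts iterations per chain including warmup, so each chain
#' retains `samples - warmup` draws; the defaults (8 chains of 4,000 with
#' 1,000 warmup, 10,000 for the regression model) retain 24,000 / 72,000
#' draws. `thin` is a sampler-level setting: each retained draw is separated
#' by `thin` full update scans, and warmup runs `warmup * thin` scans.
#'
#' @param twostep_model `"hybrid"` or `"regression"`.
#' @param gambling_model `"prospect"` or `"meanvariance"`.
#' @param chains Number of chains (>= 2, required for convergence checks).
#' @param samples Iterations per chain including warmup.
#' @param warmup Warmup iterations per chain (adaptation only, discarded).
#' @param thin Update scans between retained draws.
#' @param warmup_thin Update scans per warmup iteration; defaults to `thin`.
#'   Setting it lower than `thin` buys widely spaced retained draws without
#'   paying the same multiplier during warmup.
#' @param seed Integer seed.
#' @param prior_scale_multiplier Multiplies the scale of every mean-effect
#'   prior (group means, coupling coefficients, regression covariate
#'   coefficients); SD hyperpriors are untouched. Default 1.
#' @param zscore_mode `"per_draw"` (covariates re-standardized within every
#'   draw from the current subject-level values) or `"two_stage"` (fixed
#'   covariates supplied to [build_joint_model()]).
#' @param lambda,baseline,p_common Hybrid-model constants.
#' @return A list of class `joint_model_spec`.
#' @export
joint_model_spec <- function(twostep_model = c("hybrid", "regression"),
                             gambling_model = c("prospect", "meanvariance"),
                             chains = 8L, samples = NULL, warmup = 1000L,
                             thin = 10L, warmup_thin = NULL, seed = 1L,
                             prior_scale_multiplier = 1,
                             zscore_mode = c("per_draw", "two_stage"),
                             lambda = 1, baseline = 0.5, p_common = 0.7) {
  twostep_model <- match.arg(twostep_model)
  gambling_model <- match.arg(gambling_model)
  zscore_mode <- match.arg(zscore_mode)
  if (is.null(samples))
    samples <- if (twostep_model == "regression") 10000L else 4000L
  chains <- as.integer(chains); samples <- as.integer(samples)
  warmup <- as.integer(warmup); thin <- as.integer(thin)
  if (chains < 2L) stop("`chains` must be >= 2", call. = FALSE)
  if (samples <= warmup) stop("`samples` must exceed `warmup`", call. = FALSE)
  if (thin < 1L) stop("`thin` must be >= 1", call. = FALSE)
  warmup_thin <- as.integer(if (is.null(warmup_thin)) thin else warmup_thin)
  if (warmup_thin < 1L) stop("`warmup_thin` must be >= 1", call. = FALSE)
  if (prior_scale_multiplier <= 0)
    stop("`prior_scale_multiplier` must be positive", call. = FALSE)
  structure(list(twostep_model = twostep_model,
                 gambling_model = gambling_model, chains = chains,
                 samples = samples, warmup = warmup, thin = thin,
                 warmup_thin = warmup_thin, seed = as.integer(seed),
                 prior_scale_multiplier = prior_scale_multiplier,
                 zscore_mode = zscore_mode, lambda = lambda,
                 baseline = baseline, p_common = p_common),
            class = "joint_model_spec")
}

#' @export
print.joint_model_spec <- function(x, ...) {
  cat("Joint model specification\n")
  cat(sprintf("  two-step: %s; gambling: %s\n", x$twostep_model,
              x$gambling_model))
  cat(sprintf("  chains: %d, samples: %d (warmup %d, thin %d), seed %d\n",
              x$chains, x$samples, x$warmup, x$thin, x$seed))
  if (x$prior_scale_multiplier != 1)
    cat(sprintf("  prior scale multiplier: %g\n", x$prior_scale_multiplier))
  if (x$zscore_mode != "per_draw")
    cat("  covariates: fixed (two-stage)\n")
  invisible(x)
}

#' Z-score a vector with the population standard deviation
#'
#' Standardizes to mean 0, SD 1, using the population (divide-by-n) SD, as
#' applied to the cross-task covariates within every posterior draw.
#'
#' @param values Numeric vector, length >= 2, non-constant.
#' @return The standardized vector.
#' @examples
#' zscore_within_draw(c(1, 2, 3))
#' @export
zscore_within_draw <- function(values) {
  if (length(values) < 2L)
    stop("need at least 2 values to z-score", call. = FALSE)
  s <- sqrt(mean((values - mean(values))^2))
  if (!is.finite(s) || s == 0)
    stop("cannot z-score a constant vector", call. = FALSE)
  (values - mean(values)) / s
}

# --- parameter layout -------------------------------------------------------

# Per-coordinate variable names (natural scale) and transforms from the
# sampled (unconstrained) scale: "id", "plogis", "exp".
model_layout <- function(twostep_model, gambling_model, subjects) {
  n <- length(subjects)
  sub_nm <- function(base) {
    as.vector(t(outer(seq_len(n), base,
                      function(i, b) sprintf("%s[%d]", b, i))))
  }
  if (twostep_model == "hybrid") {
    ts_sub <- c("alpha", "beta_mb", "beta_mf", "beta_2", "persev", "beta_bias")
    ts_sub_tr <- c("plogis", "id", "id", "id", "id", "id")
    ts_grp <- c("mu_logit_alpha", "mu_beta_mb", "mu_beta_mf", "mu_beta_2",
                "mu_persev", "sigma_logit_alpha", "sigma_beta_mb",
                "sigma_beta_mf", "sigma_beta_2", "sigma_persev",
                "beta_mb_loss", "beta_mb_risk", "beta_mb_theta",
                "beta_mf_loss", "beta_mf_risk", "beta_mf_theta")
    ts_grp_tr <- c(rep("id", 5), rep("exp", 5), rep("id", 6))
  } else {
    ts_sub <- c("b_stay", "b_reward", "b_common", "b_reward_common")
    ts_sub_tr <- rep("id", 4)
    ts_grp <- c("mu_stay", "mu_reward", "mu_common", "mu_reward_common",
                "sigma_stay", "sigma_reward", "sigma_common",
                "sigma_reward_common", paste0("g_", reg_g_names))
    ts_grp_tr <- c(rep("id", 4), rep("exp", 4), rep("id", 12))
  }
  if (gambling_model == "prospect") {
    g_sub <- c("kappa", "gamma_m", "gamma_g", "theta")
    g_grp <- c("mu_log_kappa", "mu_gamma_m", "mu_gamma_g", "mu_theta",
               "sigma_log_kappa", "sigma_gamma_m", "sigma_gamma_g",
               "sigma_theta")
  } else {
    g_sub <- c("kappa", "w", "theta")
    g_grp <- c("mu_log_kappa", "mu_w", "mu_theta", "sigma_log_kappa",
               "sigma_w", "sigma_theta")
  }
  g_sub_tr <- rep("exp", length(g_sub))
  g_grp_tr <- c(rep("id", length(g_sub)), rep("exp", length(g_sub)))
  list(names = c(sub_nm(ts_sub), ts_grp, sub_nm(g_sub), g_grp),
       transform = c(rep(ts_sub_tr, n), ts_grp_tr, rep(g_sub_tr, n),
                     g_grp_tr),
       ts_sub = ts_sub, g_sub = g_sub,
       n_theta = n * length(ts_sub) + length(ts_grp) +
         n * length(g_sub) + length(g_grp))
}

apply_transform <- function(x, transform) {
  out <- x
  pl <- transform == "plogis"; ex <- transform == "exp"
  if (is.matrix(x)) {
    out[, pl] <- stats::plogis(x[, pl, drop = FALSE])
    out[, ex] <- exp(x[, ex, drop = FALSE])
  } else {
    out[pl] <- stats::plogis(x[pl])
    out[ex] <- exp(x[ex])
  }
  out
}

invert_transform <- function(x, transform) {
  out <- x
  out[transform == "plogis"] <- stats::qlogis(x[transform == "plogis"])
  out[transform == "exp"] <- log(x[transform == "exp"])
  out
}

# --- data packing -----------------------------------------------------------

#' Build the joint log-density over all parameters
#'
#' Packs both tasks' sessions into the internal format and returns the joint
#' model object whose log density is the sum of every subject's two-step and
#' gambling log-likelihoods and the hierarchical log-prior, with the
#' cross-task covariates z-scored within the evaluation (or fixed, in
#' two-stage mode).
#'
#' @param data A [simulate_cohort()] object, or any list with `twostep` and
#'   `gambling` per-trial data frames carrying a shared `subject` column.
#' @param spec A [joint_model_spec()].
#' @param fixed_covariates For `zscore_mode = "two_stage"`: data frame with
#'   columns `subject`, `loss`, `risk`, `theta` (point estimates; z-scored
#'   internally).
#' @return A list of class `joint_model` with the packed data, the parameter
#'   names/transforms, and functions `log_density(theta)` (unconstrained
#'   parameter vector; `-Inf` outside the support) and
#'   `log_density_parts(theta)` (list with `logpost`, `loglik`, `logprior`).
#' @seealso [pack_params()] to build `theta` from natural-scale values.
#' @export
build_joint_model <- function(data, spec, fixed_covariates = NULL) {
  stopifnot(inherits(spec, "joint_model_spec"))
  ts <- data$twostep; gm <- data$gambling
  if (is.null(ts) || is.null(gm))
    stop("`data` must contain `twostep` and `gambling` tables", call. = FALSE)
  subjects <- sort(unique(c(ts$subject, gm$subject)))
  if (!all(subjects %in% ts$subject) || !all(subjects %in% gm$subject))
    stop("every subject must have sessions for both tasks", call. = FALSE)

  ts_list <- lapply(subjects, function(id) {
    s <- ts[ts$subject == id, , drop = FALSE]
    if (spec$twostep_model == "hybrid") {
      v <- validate_twostep(s)
      list(c1 = v$c1, s2 = v$s2, c2 = v$c2, r = v$r)
    } else {
      # collapse to sufficient statistics: features take at most four
      # patterns (reward x common), each with a trial count and a stay count
      f <- build_stay_features(s)
      if (nrow(f) == 0L)
        return(list(X = matrix(0, 0L, 4L), n = numeric(0), y1 = numeric(0)))
      key <- paste(f$reward_prev, f$common_prev)
      n <- tapply(f$stay, key, length)
      y1 <- tapply(f$stay, key, sum)
      parts <- strsplit(names(n), " ", fixed = TRUE)
      rew <- vapply(parts, function(p) as.numeric(p[1]), numeric(1))
      com <- vapply(parts, function(p) as.numeric(p[2]), numeric(1))
      list(X = cbind(1, rew, com, rew * com),
           n = as.numeric(n), y1 = as.numeric(y1))
    }
  })
  gm_list <- lapply(subjects, function(id) {
    s <- gm[gm$subject == id, , drop = FALSE]
    if (any(!s$trial_type %in% c("mixed", "gain_only")))
      stop("gambling trials must be tagged mixed/gain_only", call. = FALSE)
    list(g1 = as.numeric(s$g1), g2 = as.numeric(s$g2),
         sure = as.numeric(s$sure),
         mixed = as.integer(s$trial_type == "mixed"),
         choice = as.integer(s$choice))
  })

  fixed_z <- NULL
  if (spec$zscore_mode == "two_stage") {
    if (is.null(fixed_covariates))
      stop("two-stage mode requires `fixed_covariates`", call. = FALSE)
    idx <- match(subjects, fixed_covariates$subject)
    if (anyNA(idx)) stop("fixed covariates missing a subject", call. = FALSE)
    fixed_z <- cbind(zscore_within_draw(fixed_covariates$loss[idx]),
                     zscore_within_draw(fixed_covariates$risk[idx]),
                     zscore_within_draw(fixed_covariates$theta[idx]))
  }

  opts <- list(ts_model = if (spec$twostep_model == "hybrid") 1L else 0L,
               g_model = if (spec$gambling_model == "prospect") 0L else 1L,
               psm = spec$prior_scale_multiplier, lambda = spec$lambda,
               baseline = spec$baseline, p_common = spec$p_common,
               fixed_z = fixed_z)
  layout <- model_layout(spec$twostep_model, spec$gambling_model, subjects)
  packed <- list(ts = ts_list, gamble = gm_list)

  model <- list(data = packed, opts = opts, spec = spec, subjects = subjects,
                param_names = layout$names, transform = layout$transform,
                layout = layout, n_theta = layout$n_theta)
  model$log_density <- function(theta) {
    theta[!is.finite(theta)] <- NaN
    cpp_joint_logpost(packed, opts, as.numeric(theta))$logpost
  }
  model$log_density_parts <- function(theta) {
    theta[!is.finite(theta)] <- NaN
    cpp_joint_logpost(packed, opts, as.numeric(theta))
  }
  class(model) <- "joint_model"
  model
}

#' @export
print.joint_model <- function(x, ...) {
  cat(sprintf("Joint hierarchical model: %s two-step + %s gambling\n",
              x$spec$twostep_model, x$spec$gambling_model))
  cat(sprintf("  %d subjects, %d parameters\n", length(x$subjects), x$n_theta))
  invisible(x)
}

#' Pack natural-scale parameter values into the sampled vector
#'
#' Builds the unconstrained parameter vector of a [build_joint_model()]
#' object from natural-scale values, applying the model's transforms (logit
#' for the learning rate, log for positives and group SDs). Values outside
#' the support (e.g. a negative group SD) map to coordinates on which the
#' log density is `-Inf`.
#'
#' Note that in per-draw z-scoring mode a point with identical gambling
#' parameters for every subject lies outside the support (the covariates
#' cannot be standardized), so at least one subject-level gambling value
#' should differ across subjects for the density to be finite.
#'
#' @param model A `joint_model`.
#' @param values Named list or vector: names as in `model$param_names`
#'   (subject-level entries like `"beta_mb[3]"`). Unnamed coordinates
#'   default to `default`.
#' @param default Fill value (natural scale) for unspecified coordinates.
#' @return Numeric vector of length `model$n_theta`.
#' @export
pack_params <- function(model, values = list(), default = NULL) {
  nat <- numeric(model$n_theta)
  names(nat) <- model$param_names
  nat[model$transform == "id"] <- 0
  nat[model$transform == "plogis"] <- 0.5
  nat[model$transform == "exp"] <- if (is.null(default)) 1 else default
  if (!is.null(default)) nat[] <- default
  v <- unlist(values)
  if (length(v)) {
    if (is.null(names(v)) || !all(names(v) %in% model$param_names))
      stop("all `values` must be named by model parameters", call. = FALSE)
    nat[names(v)] <- v
  }
  suppressWarnings(invert_transform(nat, model$transform))
}

# Overdispersed starting point on the unconstrained scale: identity
# coordinates near 0, positives near exp(-0.2), moderate jitter everywhere.
init_theta <- function(model) {
  tr <- model$transform
  th <- stats::rnorm(model$n_theta, 0, 0.4)
  th[tr == "exp"] <- th[tr == "exp"] - 0.2
  th
}

#' Run MCMC on a joint model
#'
#' Samples the joint posterior with an adaptive Metropolis-within-Gibbs
#' scheme: single-coordinate random-walk updates for two-step subject
#' parameters and group-level parameters, joint proposals for each subject's
#' gambling parameters (whose z-scored covariates feed back into the
#' two-step side), and translation moves that shift a group mean together
#' with its subject-level values. Proposal scales adapt during warmup only;
#' chains run sequentially, each seeded from `spec$seed`, so results are
#' reproducible.
#'
#' Initial points are drawn from an overdispersed distribution on the
#' unconstrained scale and re-drawn (up to 50 times) while the log density
#' is not finite.
#'
#' @param model A [build_joint_model()] object.
#' @param spec MCMC settings; defaults to the spec the model was built with.
#' @param verbose If `TRUE`, log per-chain seed, acceptance rate and wall
#'   time as chains finish.
#' @return A `posterior_draws` object: `draws` is an iterations x chains x
#'   variables array on the natural scale, with `param_names`, the spec, and
#'   sampling metadata. Use [rhat()] to check convergence.
#' @export
run_mcmc <- function(model, spec = model$spec, verbose = FALSE) {
  stopifnot(inherits(model, "joint_model"))
  n_keep <- spec$samples - spec$warmup
  warm_scans <- spec$warmup * (spec$warmup_thin %||% spec$thin)
  t0 <- Sys.time()
  draws <- array(NA_real_,
                 dim = c(n_keep, spec$chains, model$n_theta),
                 dimnames = list(NULL, paste0("chain", seq_len(spec$chains)),
                                 model$param_names))
  acc <- numeric(spec$chains)
  for (ch in seq_len(spec$chains)) {
    res <- withr_seed(spec$seed + 7193 * ch, {
      th0 <- init_theta(model)
      tries <- 1L
      while (!is.finite(model$log_density(th0))) {
        tries <- tries + 1L
        if (tries > 50L)
          stop("could not find a finite starting point", call. = FALSE)
        th0 <- init_theta(model)
      }
      cpp_run_chain(model$data, model$opts, th0, warm_scans, n_keep,
                    spec$thin)
    })
    draws[, ch, ] <- apply_transform(res$draws, model$transform)
    acc[ch] <- res$accept_rate
    if (verbose)
      message(sprintf("chain %d/%d: seed %d, acceptance %.2f, %.1f s elapsed",
                      ch, spec$chains, spec$seed + 7193L * ch,
                      res$accept_rate,
                      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  structure(list(draws = draws, param_names = model$param_names,
                 subjects = model$subjects, spec = spec,
                 accept_rate = acc,
                 runtime_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
            class = "posterior_draws")
}

#' Simulate-or-load, build, and fit in one call
#'
#' @param data Cohort or list with `twostep` / `gambling` tables.
#' @inheritParams build_joint_model
#' @return A `posterior_draws` object.
#' @export
fit_joint_model <- function(data, spec, fixed_covariates = NULL) {
  run_mcmc(build_joint_model(data, spec, fixed_covariates), spec)
}

#' @export
print.posterior_draws <- function(x, ...) {
  d <- dim(x$draws)
  cat(sprintf("Posterior draws: %d iterations x %d chains x %d variables\n",
              d[1], d[2], d[3]))
  cat(sprintf("  model: %s + %s; seed %d; mean acceptance %.2f; %.1f s\n",
              x$spec$twostep_model, x$spec$gambling_model, x$spec$seed,
              mean(x$accept_rate), x$runtime_s))
  r <- suppressWarnings(max(rhat(x), na.rm = TRUE))
  cat(sprintf("  max split-chain R-hat: %.3f\n", r))
  invisible(x)
}

#' Extract draws for one variable
#'
#' @param fit A `posterior_draws` object.
#' @param variable Variable name (see `fit$param_names`).
#' @param pool If `TRUE` (default) return a single vector pooled across
#'   chains; otherwise an iterations x chains matrix.
#' @return Numeric vector or matrix.
#' @export
extract_draws <- function(fit, variable, pool = TRUE) {
  stopifnot(inherits(fit, "posterior_draws"))
  if (!variable %in% fit$param_names)
    stop(sprintf("unknown variable '%s'", variable), call. = FALSE)
  m <- fit$draws[, , variable, drop = TRUE]
  if (is.null(dim(m))) m <- matrix(m, ncol = dim(fit$draws)[2])
  if (pool) as.vector(m) else m
}

#' Split-chain potential scale reduction factor
#'
#' Computes the split-chain R-hat for every variable (each chain is split in
#' half, doubling the chain count, so within-chain drift inflates the
#' statistic). Values near 1 indicate convergence; the working criterion is
#' R-hat < 1.1 for all variables. Chains that are all identical and constant
#' have no variance on either side of the ratio; that degenerate case is
#' defined here as 1.
#'
#' @param draws A `posterior_draws` object, or an iterations x chains matrix
#'   for a single variable.
#' @return Named vector of R-hat values (or a scalar for a matrix input).
#' @export
rhat <- function(draws) {
  if (inherits(draws, "posterior_draws")) {
    out <- vapply(seq_len(dim(draws$draws)[3]), function(v)
      rhat_matrix(draws$draws[, , v, drop = TRUE]), numeric(1))
    names(out) <- draws$param_names
    return(out)
  }
  rhat_matrix(as.matrix(draws))
}

rhat_matrix <- function(m) {
  if (ncol(m) < 2L)
    stop("R-hat requires at least 2 chains", call. = FALSE)
  if (nrow(m) < 4L)
    stop("R-hat requires at least 4 draws per chain", call. = FALSE)
  half <- floor(nrow(m) / 2)
  sp <- cbind(m[seq_len(half), , drop = FALSE],
              m[half + seq_len(half), , drop = FALSE])
  n <- nrow(sp)
  means <- colMeans(sp)
  W <- mean(apply(sp, 2, stats::var))
  B <- n * stats::var(means)
  if (!is.finite(W) || W == 0) {
    if (is.finite(B) && B > 0) return(Inf)
    return(1)
  }
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Point-estimate gambling covariates for two-stage fitting
#'
#' Fits the gambling model alone (the two-step data enter as empty feature
#' sets, so only the gambling likelihood is informative) and returns each
#' subject's posterior-median log loss aversion, risk measure and inverse
#' temperature, for use as `fixed_covariates` in a two-stage joint fit.
#'
#' @param data Cohort or list with `twostep` / `gambling` tables.
#' @param spec A [joint_model_spec()]; its `gambling_model`, seed and MCMC
#'   sizes are used.
#' @return Data frame with columns `subject`, `loss`, `risk`, `theta`.
#' @export
two_stage_covariates <- function(data, spec) {
  subjects <- sort(unique(data$gambling$subject))
  empty_ts <- data.frame(subject = rep(subjects, each = 2L),
                         trial = rep(1:2, length(subjects)),
                         choice1 = NA_integer_, state2 = NA_integer_,
                         choice2 = NA_integer_, reward = NA_real_,
                         common = NA_integer_, aborted = 1L)
  sp <- spec
  sp$twostep_model <- "regression"
  sp$zscore_mode <- "per_draw"
  class(sp) <- "joint_model_spec"
  fit <- fit_joint_model(list(twostep = empty_ts, gambling = data$gambling),
                         sp)
  cov <- subject_covariate_draws(fit)
  data.frame(subject = subjects,
             loss = apply(cov$log_kappa, 2, stats::median),
             risk = apply(cov$risk, 2, stats::median),
             theta = apply(cov$theta, 2, stats::median))
}

# Pooled draw x subject matrices of the three gambling covariates.
subject_covariate_draws <- function(fit) {
  n <- length(fit$subjects)
  get <- function(base) {
    vapply(seq_len(n),
           function(i) extract_draws(fit, sprintf("%s[%d]", base, i)),
           numeric(prod(dim(fit$draws)[1:2])))
  }
  kap <- get("kappa")
  risk <- if (fit$spec$gambling_model == "prospect") 1 - get("gamma_g")
          else get("w")
  list(log_kappa = log(kap), risk = risk, theta = get("theta"))
}
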