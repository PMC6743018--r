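#' Hybrid learner parameters
#'
#' The six free parameters of the hybrid model-based / model-free learner:
#' learning rate `alpha`, inverse temperatures `beta_mb` (model-based stage-1
#' weight), `beta_mf` (model-free stage-1 weight) and `beta_2` (second
#' stage), perseveration weight `p_stick`, and stage-1 side bias
#' `beta_bias`. The eligibility decay `lambda` is fixed to 1 in the headline
#' model and excluded from inference; it can be overridden for
#' experimentation.
#'
#' @param alpha Learning rate in (0, 1).
#' @param beta_mb,beta_mf,beta_2 Inverse softmax temperatures.
#' @param p_stick Perseveration weight (> 0 repeats, < 0 switches).
#' @param beta_bias Stage-1 bias toward the second action.
#' @param lambda Eligibility decay, fixed at 1 by default.
#' @return A named list of class `rl_params`.
#' @export
rl_params <- function(alpha, beta_mb = 0, beta_mf = 0, beta_2 = 0,
                      p_stick = 0, beta_bias = 0, lambda = 1) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("`alpha` must lie strictly in (0, 1)", call. = FALSE)
  structure(list(alpha = alpha, beta_mb = beta_mb, beta_mf = beta_mf,
                 beta_2 = beta_2, p_stick = p_stick, beta_bias = beta_bias,
                 lambda = lambda),
            class = "rl_params")
}

#' Log-likelihood of a two-step session under the hybrid learner
#'
#' Steps the hybrid SARSA(lambda) + Bellman-backup model through a session in
#' trial order and accumulates the log-probabilities of the observed stage-1
#' and stage-2 choices. Model-based stage-1 values combine the veridical
#' transition probabilities (`p_common` / `1 - p_common`) with the
#' action-to-state mapping inferred from the running transition tally (see
#' [transition_mapping()]). Aborted trials contribute no likelihood and
#' trigger no value updates; the transition tally and the perseveration
#' reference are still advanced by whatever stages were observed.
#'
#' @param params An [rl_params()] object.
#' @param session Two-step session data frame with columns `choice1`,
#'   `state2`, `choice2` (1/2, `NA` when the stage was not reached) and
#'   `reward`.
#' @param per_trial If `TRUE`, also return per-trial chosen-action
#'   probabilities (`-1` where a stage is missing).
#' @param baseline Reference value: Q initialization and the target of the
#'   non-chosen decay. The default 0.5 is the midpoint of the 0/1 rewards;
#'   recoding rewards to -1/+1 with `baseline = 0` and halved temperatures
#'   leaves the likelihood unchanged.
#' @param p_common Veridical common-transition probability.
#' @return The log-likelihood, or a list with `loglik`, `p_stage1`,
#'   `p_stage2` when `per_trial = TRUE`.
#' @export
hybrid_loglik <- function(params, session, per_trial = FALSE, baseline = 0.5,
                          p_common = 0.7) {
  stopifnot(inherits(params, "rl_params"))
  s <- validate_twostep(session)
  res <- cpp_hybrid_loglik(s$c1, s$s2, s$c2, s$r,
                           unlist(params[c("alpha", "beta_mb", "beta_mf",
                                           "beta_2", "p_stick", "beta_bias")]),
                           params$lambda, baseline, p_common, per_trial)
  if (per_trial) res else res$loglik
}

# 0-based integer columns with -1 for missing stages.
validate_twostep <- function(session) {
  need <- c("choice1", "state2", "choice2", "reward")
  if (!all(need %in% names(session)))
    stop("session must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  to0 <- function(x) {
    x <- as.integer(x)
    bad <- !is.na(x) & !x %in% c(1L, 2L)
    if (any(bad)) stop("choices/states must be 1, 2 or NA", call. = FALSE)
    ifelse(is.na(x), -1L, x - 1L)
  }
  list(c1 = to0(session$choice1), s2 = to0(session$state2),
       c2 = to0(session$choice2),
       r = ifelse(is.na(session$reward), 0, as.numeric(session$reward)))
}

#' Infer the action-to-state mapping from a transition tally
#'
#' The predominant second-stage state of each first-stage action is chosen
#' by the sign of the difference between consistent tallies
#' (action 1 to state 1 plus action 2 to state 2) and inconsistent ones.
#' Ties, including the all-zero tally before any transition has been seen,
#' deterministically keep the first-listed mapping (action 1 to state 1).
#'
#' @param counts 2 x 2 matrix of observed (action, state) transition counts.
#' @return Integer vector of length 2: the predominant state of each action.
#' @export
transition_mapping <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == 2L), all(counts >= 0))
  diff <- (counts[1, 1] + counts[2, 2]) - (counts[1, 2] + counts[2, 1])
  if (diff >= 0) c(1L, 2L) else c(2L, 1L)
}

#' Trial-pair stay/switch features
#'
#' Builds one regression row per trial with a usable predecessor: the
#' outcome `stay` (1 when the same stage-1 action was chosen as on the
#' previous trial) and the signed predictors `reward_prev` and `common_prev`
#' (+1/-1 for rewarded/unrewarded and common/rare previous transitions).
#' The first trial of each session is excluded, as are trials without a
#' stage-1 choice and trials whose predecessor was aborted.
#'
#' @param session Two-step session data frame with columns `choice1`,
#'   `state2`, `choice2`, `reward`, `common` (1 = common transition) and
#'   optionally `subject`.
#' @return Data frame with columns `subject`, `stay`, `reward_prev`,
#'   `common_prev`; zero rows when no trial qualifies.
#' @export
build_stay_features <- function(session) {
  if (is.null(session$common))
    stop("session must have a `common` transition-type column", call. = FALSE)
  if (is.null(session$subject)) session$subject <- 1L
  out <- lapply(split(session, session$subject), function(s) {
    s <- s[order(s$trial %||% seq_len(nrow(s))), , drop = FALSE]
    n <- nrow(s)
    if (n < 2L) return(NULL)
    t <- 2:n
    prev_complete <- !is.na(s$choice1[t - 1]) & !is.na(s$state2[t - 1]) &
      !is.na(s$choice2[t - 1]) & !is.na(s$reward[t - 1])
    ok <- !is.na(s$choice1[t]) & prev_complete
    if (!any(ok)) return(NULL)
    t <- t[ok]
    data.frame(subject = s$subject[t],
               stay = as.integer(s$choice1[t] == s$choice1[t - 1]),
               reward_prev = ifelse(s$reward[t - 1] > 0, 1, -1),
               common_prev = ifelse(s$common[t - 1] > 0, 1, -1))
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(subject = integer(), stay = integer(),
                      reward_prev = numeric(), common_prev = numeric())
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# The 12 group-level covariate-interaction coefficients of the stay
# regression, in feature-major order.
reg_g_names <- c("loss", "risk", "theta",
                 "reward_loss", "reward_risk", "reward_theta",
                 "common_loss", "common_risk", "common_theta",
                 "reward_common_loss", "reward_common_risk",
                 "reward_common_theta")

#' Log-likelihood of the trial-pair stay regression
#'
#' Bernoulli log-likelihood of the stay outcomes under the 16-term logistic
#' model: per-subject coefficients for the intercept, previous reward,
#' previous transition type and their interaction, plus shared group-level
#' coefficients for each gambling covariate (z-scored log loss aversion,
#' risk preference, inverse temperature) and its interactions with the three
#' within-task predictors.
#'
#' @param params List with `b`, an n_subjects x 4 matrix of per-subject
#'   coefficients (columns stay, reward, common, reward_common; rownames =
#'   subject ids), and `g`, a named vector of the 12 group-level covariate
#'   coefficients (names as in `mbloss:::reg_g_names`).
#' @param features Output of [build_stay_features()].
#' @param covariates Data frame with columns `subject`, `loss`, `risk`,
#'   `theta` (z-scored per-subject gambling measures).
#' @return Summed Bernoulli log-likelihood.
#' @export
regression_loglik <- function(params, features, covariates) {
  if (nrow(features) == 0L) return(0)
  b <- params$b
  g <- params$g[reg_g_names]
  if (anyNA(g)) stop("`params$g` must contain the 12 coefficients named ",
                     paste(reg_g_names, collapse = ", "), call. = FALSE)
  subj <- as.character(features$subject)
  if (!all(subj %in% as.character(covariates$subject)))
    stop("every subject in `features` needs a row in `covariates`",
         call. = FALSE)
  cov_idx <- match(subj, as.character(covariates$subject))
  zl <- covariates$loss[cov_idx]
  zr <- covariates$risk[cov_idx]
  zt <- covariates$theta[cov_idx]
  if (anyNA(zl) || anyNA(zr) || anyNA(zt))
    stop("missing covariate values", call. = FALSE)
  bi <- b[match(subj, rownames(b)), , drop = FALSE]
  f <- cbind(1, features$reward_prev, features$common_prev,
             features$reward_prev * features$common_prev)
  gm <- matrix(g, nrow = 4L, byrow = TRUE)  # feature x covariate
  eff <- bi + cbind(zl, zr, zt) %*% t(gm)
  eta <- rowSums(f * eff)
  log1pexp <- pmax(eta, 0) + log1p(exp(-abs(eta)))
  sum(ifelse(features$stay == 1, eta, 0) - log1pexp)
}
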