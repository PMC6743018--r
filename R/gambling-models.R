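#' Prospect-theory utility
#'
#' Power-function value with a multiplicative loss weight:
#' `U(v) = v^gamma` for `v >= 0` and `U(v) = -kappa * (-v)^gamma` otherwise.
#' No probability weighting is applied (outcome probabilities are fixed at
#' their veridical 0.5 values in this task).
#'
#' @param v Outcome in dollars (vectorized).
#' @param kappa Loss-aversion weight, > 0.
#' @param gamma Curvature exponent, > 0; `1 - gamma` indexes risk aversion.
#' @return Utility in utils, same length as `v`.
#' @examples
#' pt_utility(c(4, -4), kappa = 1.5, gamma = 0.5)
#' @export
pt_utility <- function(v, kappa, gamma) {
  if (!is.numeric(kappa) || length(kappa) != 1L || kappa <= 0)
    stop("`kappa` must be a positive scalar", call. = FALSE)
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0)
    stop("`gamma` must be a positive scalar", call. = FALSE)
  ifelse(v >= 0, v^gamma, -kappa * (-v)^gamma)
}

#' Mean-variance utility of a 50/50 gamble
#'
#' Linear piecewise value with loss weight `kappa` and a penalty linear in
#' the standard deviation of the two (weighted) outcomes:
#' `U = 0.5 U2(g1) + 0.5 U2(g2) - w * sigma`, where `U2(v) = v` for gains,
#' `kappa * v` for losses, and `sigma` is the probability-weighted
#' (population) standard deviation of the two-point outcome distribution,
#' `|U2(g1) - U2(g2)| / 2` for a 50/50 gamble.
#'
#' @param g1,g2 The two gamble outcomes in dollars (vectorized).
#' @param kappa Loss weight, > 0.
#' @param w Risk penalty per standard-deviation dollar, >= 0.
#' @return Utility in utils.
#' @examples
#' mv_utility(10, -10, kappa = 2, w = 1)
#' @export
mv_utility <- function(g1, g2, kappa, w) {
  if (!is.numeric(kappa) || length(kappa) != 1L || kappa <= 0)
    stop("`kappa` must be a positive scalar", call. = FALSE)
  if (!is.numeric(w) || length(w) != 1L || w < 0)
    stop("`w` must be non-negative", call. = FALSE)
  u1 <- mv_value(g1, kappa)
  u2 <- mv_value(g2, kappa)
  0.5 * u1 + 0.5 * u2 - w * abs(u1 - u2) / 2
}

mv_value <- function(v, kappa) ifelse(v >= 0, v, kappa * v)

#' Softmax probability of choosing the gamble
#'
#' `P(gamble) = logistic(theta * (u_gamble - u_sure))`, computed stably.
#'
#' @param u_gamble,u_sure Utilities of the gamble and the sure option.
#' @param theta Inverse softmax temperature, >= 0.
#' @return Probability of choosing the gamble.
#' @examples
#' gamble_choice_prob(1, 0, theta = 1)  # 1 / (1 + exp(-1))
#' @export
gamble_choice_prob <- function(u_gamble, u_sure, theta) {
  if (!is.numeric(theta) || length(theta) != 1L || theta < 0)
    stop("`theta` must be non-negative", call. = FALSE)
  stats::plogis(theta * (u_gamble - u_sure))
}

#' Parameter containers for the gambling models
#'
#' `pt_params()` holds the four prospect-theory parameters (loss aversion
#' `kappa`, curvatures `gamma_m` for mixed-valence and `gamma_g` for
#' gain-only trials, inverse temperature `theta`); `mv_params()` holds the
#' three mean-variance parameters (`kappa`, SD penalty `w`, `theta`).
#'
#' @param kappa Loss weight, > 0.
#' @param gamma_m,gamma_g Curvature exponents, > 0.
#' @param w SD penalty, >= 0.
#' @param theta Inverse softmax temperature, >= 0.
#' @return A named list of class `pt_params` or `mv_params`.
#' @export
pt_params <- function(kappa, gamma_m, gamma_g, theta) {
  stopifnot(kappa > 0, gamma_m > 0, gamma_g > 0, theta >= 0)
  structure(list(kappa = kappa, gamma_m = gamma_m, gamma_g = gamma_g,
                 theta = theta), class = "pt_params")
}

#' @rdname pt_params
#' @export
mv_params <- function(kappa, w, theta) {
  stopifnot(kappa > 0, w >= 0, theta >= 0)
  structure(list(kappa = kappa, w = w, theta = theta), class = "mv_params")
}

# Per-trial probability of choosing the gamble for a full offer table under
# either utility model. `offers` needs columns trial_type, g1, g2, sure.
gamble_probs <- function(params, offers) {
  type <- offers$trial_type
  if (any(!type %in% c("mixed", "gain_only")))
    stop("every trial must be tagged 'mixed' or 'gain_only'", call. = FALSE)
  if (inherits(params, "pt_params")) {
    gamma <- ifelse(type == "mixed", params$gamma_m, params$gamma_g)
    u_g <- 0.5 * pt_pow(offers$g1, params$kappa, gamma) +
           0.5 * pt_pow(offers$g2, params$kappa, gamma)
    u_s <- pt_pow(offers$sure, params$kappa, gamma)
  } else if (inherits(params, "mv_params")) {
    u_g <- mv_utility(offers$g1, offers$g2, params$kappa, params$w)
    u_s <- mv_value(offers$sure, params$kappa)
  } else {
    stop("`params` must be pt_params or mv_params", call. = FALSE)
  }
  stats::plogis(params$theta * (u_g - u_s))
}

# Vectorized prospect-theory value allowing a per-trial gamma.
pt_pow <- function(v, kappa, gamma) {
  ifelse(v >= 0, v^gamma, -kappa * (-v)^gamma)
}

#' Log-likelihood of a gambling session
#'
#' Sums the Bernoulli log-probabilities of the observed gamble/sure choices
#' under a prospect-theory or mean-variance utility model. Under prospect
#' theory, mixed-valence trials use `gamma_m` and gain-only trials use
#' `gamma_g`; the zero sure amount on mixed trials has utility 0.
#'
#' @param params A `pt_params` or `mv_params` object.
#' @param session Data frame with columns `trial_type`, `g1`, `g2`, `sure`,
#'   and `choice` (1 = gamble, 0 = sure).
#' @param per_trial If `TRUE`, also return the per-trial gamble
#'   probabilities.
#' @return The log-likelihood (scalar), or if `per_trial` a list with
#'   `loglik` and `prob_gamble`.
#' @export
gambling_loglik <- function(params, session, per_trial = FALSE) {
  if (is.null(session$choice))
    stop("`session` must have a `choice` column", call. = FALSE)
  p <- gamble_probs(params, session)
  y <- session$choice
  ll <- sum(ifelse(y == 1, log(p), log1p(-p)))
  if (per_trial) list(loglik = ll, prob_gamble = p) else ll
}
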