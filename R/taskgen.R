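#' Build a two-step task environment
#'
#' Constructs the transition/payoff structure of the sequential two-step
#' decision task: two first-stage actions, each leading predominantly (with
#' probability `p_common`) to one of two second-stage states, and four
#' second-stage actions whose binary payoff probabilities follow independent
#' Gaussian random walks with reflecting boundaries.
#'
#' Each of the four payoff probabilities starts at an independent uniform
#' draw within `bounds` and takes `n_trials - 1` Gaussian steps of standard
#' deviation `drift_sd`; steps past a boundary are reflected about it
#' (`x -> 2 b - x`, re-applied until in range).
#'
#' @param seed Integer seed; the environment is deterministic given the seed.
#' @param n_trials Number of trials (rows of the payoff matrix).
#' @param drift_sd Standard deviation of the per-trial Gaussian drift, in
#'   probability units.
#' @param bounds Length-2 numeric, the lower and upper reflecting boundaries.
#' @param p_common Probability of the predominant ("common") transition.
#' @return An object of class `twostep_env`: a list with `payoff_probs`
#'   (`n_trials` x 4 matrix, columns = second-stage state x action),
#'   `p_common`, `mapping` (predominant second-stage state, 1 or 2, for each
#'   first-stage action), `drift_sd`, `bounds`, `seed`.
#' @examples
#' env <- make_twostep_env(seed = 1)
#' range(env$payoff_probs)
#' @export
make_twostep_env <- function(seed, n_trials = 201L, drift_sd = 0.025,
                             bounds = c(0.2, 0.8), p_common = 0.7) {
  stopifnot(length(n_trials) == 1L, length(drift_sd) == 1L,
            length(p_common) == 1L)
  n_trials <- as.integer(n_trials)
  if (is.na(n_trials) || n_trials < 1L)
    stop("`n_trials` must be a positive integer", call. = FALSE)
  if (!is.numeric(drift_sd) || drift_sd < 0)
    stop("`drift_sd` must be non-negative", call. = FALSE)
  if (length(bounds) != 2L || !is.numeric(bounds) ||
      bounds[1] < 0 || bounds[2] > 1 || bounds[1] >= bounds[2])
    stop("`bounds` must satisfy 0 <= lower < upper <= 1", call. = FALSE)
  if (p_common < 0 || p_common > 1)
    stop("`p_common` must be a probability", call. = FALSE)

  payoff <- withr_seed(seed, {
    start <- stats::runif(4L, bounds[1], bounds[2])
    steps <- matrix(stats::rnorm(4L * (n_trials - 1L), 0, drift_sd),
                    nrow = max(n_trials - 1L, 0L), ncol = 4L)
    walks <- vapply(seq_len(4L), function(j) {
      reflected_walk(start[j], if (n_trials > 1L) steps[, j] else numeric(0),
                     bounds)
    }, numeric(n_trials))
    matrix(walks, nrow = n_trials, ncol = 4L,
           dimnames = list(NULL, c("s1a1", "s1a2", "s2a1", "s2a2")))
  })

  structure(
    list(payoff_probs = payoff, p_common = p_common,
         mapping = c(1L, 2L),   # action 1 -> state 1 predominant, mirrored
         drift_sd = drift_sd, bounds = bounds, n_trials = n_trials,
         seed = as.integer(seed)),
    class = "twostep_env"
  )
}

# Random walk with reflecting boundaries: x -> 2 b - x, re-applied until
# inside [lower, upper]. `steps` has length n - 1.
reflected_walk <- function(start, steps, bounds) {
  n <- length(steps) + 1L
  x <- numeric(n)
  x[1] <- start
  for (t in seq_along(steps)) {
    v <- x[t] + steps[t]
    v <- reflect_into(v, bounds[1], bounds[2])
    x[t + 1L] <- v
  }
  x
}

reflect_into <- function(v, lower, upper) {
  while (v < lower || v > upper) {
    if (v < lower) v <- 2 * lower - v
    if (v > upper) v <- 2 * upper - v
  }
  v
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards.
withr_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' @export
print.twostep_env <- function(x, ...) {
  cat("Two-step task environment\n")
  cat(sprintf("  trials: %d, common transition p = %.2f\n",
              x$n_trials, x$p_common))
  cat(sprintf("  payoff drift sd = %.3f, reflecting bounds [%.2f, %.2f]\n",
              x$drift_sd, x$bounds[1], x$bounds[2]))
  cat(sprintf("  payoff probability range: [%.3f, %.3f]\n",
              min(x$payoff_probs), max(x$payoff_probs)))
  invisible(x)
}

#' Sample a second-stage state given a first-stage action
#'
#' Returns the action's predominant second-stage state with probability
#' `p_common`, and the other state otherwise. Uses the current RNG stream.
#'
#' @param env A `twostep_env`.
#' @param stage1_action First-stage action, 1 or 2.
#' @return Second-stage state id, 1 or 2.
#' @export
sample_transition <- function(env, stage1_action) {
  stopifnot(inherits(env, "twostep_env"))
  if (!stage1_action %in% c(1L, 2L))
    stop("`stage1_action` must be 1 or 2", call. = FALSE)
  maj <- env$mapping[stage1_action]
  if (stats::runif(1) < env$p_common) maj else (3L - maj)
}

# Mixed-valence design grid: gains in dollars, loss = -multiple * gain with
# multiples 0.25..2 in steps of 0.125.
mixed_gains <- c(2, 4, 5, 6, 8, 9, 10, 12)
mixed_multiples <- seq(0.25, 2, by = 0.125)

#' Generate a gambling-task offer list
#'
#' Builds the trial list for the 50/50 gambling task: `n_mixed` mixed-valence
#' offers (one gain outcome, one loss outcome, sure amount 0) and
#' `n_gain_only` gain-only offers (one gain outcome, one zero outcome, and a
#' smaller sure gain), shuffled into random order.
#'
#' Mixed offers are a seeded sample without replacement from the design grid
#' of gains \{2, 4, 5, 6, 8, 9, 10, 12\} dollars crossed with loss multiples
#' 0.25 to 2 in steps of 0.125 (loss = -multiple x gain). Gain-only gambles
#' draw the gain uniformly from $2-$30 and the sure amount uniformly from $1
#' up to min($13, gain - $0.50), both rounded to $0.50.
#'
#' @param seed Integer seed.
#' @param n_mixed Number of mixed-valence trials.
#' @param n_gain_only Number of gain-only trials.
#' @return A data.frame of class `gamble_offers` with columns `trial`,
#'   `trial_type` ("mixed"/"gain_only"), `g1` (gain outcome), `g2` (loss or
#'   zero outcome), `sure`.
#' @examples
#' offers <- make_gambling_offers(seed = 1)
#' table(offers$trial_type)
#' @export
make_gambling_offers <- function(seed, n_mixed = 60L, n_gain_only = 20L) {
  n_mixed <- as.integer(n_mixed)
  n_gain_only <- as.integer(n_gain_only)
  if (is.na(n_mixed) || n_mixed < 0L || is.na(n_gain_only) || n_gain_only < 0L)
    stop("offer counts must be non-negative", call. = FALSE)
  grid <- expand.grid(gain = mixed_gains, multiple = mixed_multiples)
  if (n_mixed > nrow(grid))
    stop(sprintf("`n_mixed` exceeds the %d available (gain, multiple) pairs",
                 nrow(grid)), call. = FALSE)

  offers <- withr_seed(seed, {
    mixed <- NULL
    if (n_mixed > 0L) {
      pick <- grid[sample.int(nrow(grid), n_mixed), , drop = FALSE]
      mixed <- data.frame(trial_type = "mixed",
                          g1 = pick$gain,
                          g2 = -pick$multiple * pick$gain,
                          sure = 0)
    }
    gain_only <- NULL
    if (n_gain_only > 0L) {
      g1 <- round_half(stats::runif(n_gain_only, 2, 30))
      sure <- round_half(stats::runif(n_gain_only, 1, pmin(13, g1 - 0.5)))
      gain_only <- data.frame(trial_type = "gain_only", g1 = g1, g2 = 0,
                              sure = sure)
    }
    all <- rbind(mixed, gain_only)
    all <- all[sample.int(nrow(all)), , drop = FALSE]
    all
  })
  offers <- cbind(trial = seq_len(nrow(offers)), offers)
  rownames(offers) <- NULL
  class(offers) <- c("gamble_offers", "data.frame")
  attr(offers, "seed") <- as.integer(seed)
  offers
}

round_half <- function(x) round(x * 2) / 2
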