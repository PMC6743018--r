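#' Write a data table with a JSON metadata header
#'
#' Writes tab-separated values preceded by `#`-prefixed lines carrying a
#' JSON metadata block. Numeric columns are formatted with 17 significant
#' digits so that [read_mbloss_table()] round-trips doubles bit-exactly.
#'
#' @param df Data frame.
#' @param path Output path.
#' @param meta Named list of metadata (seeds, parameters, ...).
#' @return `path`, invisibly.
#' @export
write_mbloss_table <- function(df, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(meta))
    writeLines(paste0("# ", jsonlite::toJSON(meta, auto_unbox = TRUE,
                                             digits = NA)), con)
  cols <- lapply(df, function(x) {
    if (is.double(x)) sprintf("%.17g", x) else as.character(x)
  })
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df))
    writeLines(do.call(paste, c(cols, sep = "\t")), con)
  invisible(path)
}

#' Read a table written by [write_mbloss_table()]
#'
#' @param path File path.
#' @return Data frame with the parsed JSON metadata as attribute `meta`.
#' @export
read_mbloss_table <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^# ", lines)
  meta <- NULL
  if (length(meta_lines))
    meta <- jsonlite::fromJSON(paste(sub("^# ", "", lines[meta_lines]),
                                     collapse = ""))
  body <- if (length(meta_lines)) lines[-meta_lines] else lines
  df <- utils::read.delim(text = paste(body, collapse = "\n"),
                          stringsAsFactors = FALSE, check.names = FALSE)
  attr(df, "meta") <- meta
  df
}

#' Write / read a two-step environment
#'
#' The payoff-probability walks are stored one trial per row with a JSON
#' metadata header (seed, drift, bounds, transition structure); reading
#' reconstructs the environment bit-exactly.
#'
#' @param env A [make_twostep_env()] object.
#' @param path File path.
#' @return `write_twostep_env()` returns `path` invisibly;
#'   `read_twostep_env()` returns the `twostep_env`.
#' @export
write_twostep_env <- function(env, path) {
  stopifnot(inherits(env, "twostep_env"))
  df <- as.data.frame(env$payoff_probs)
  write_mbloss_table(df, path, meta = list(
    type = "twostep_env", seed = env$seed, n_trials = env$n_trials,
    drift_sd = env$drift_sd, bounds = env$bounds, p_common = env$p_common,
    mapping = env$mapping))
}

#' @rdname write_twostep_env
#' @export
read_twostep_env <- function(path) {
  df <- read_mbloss_table(path)
  meta <- attr(df, "meta")
  if (is.null(meta) || !identical(meta$type, "twostep_env"))
    stop("not a two-step environment file", call. = FALSE)
  structure(
    list(payoff_probs = as.matrix(df), p_common = meta$p_common,
         mapping = as.integer(meta$mapping), drift_sd = meta$drift_sd,
         bounds = as.numeric(meta$bounds), n_trials = meta$n_trials,
         seed = as.integer(meta$seed)),
    class = "twostep_env")
}

#' Write a simulated cohort to delimited text
#'
#' Writes `twostep.tsv`, `gambling.tsv` and `truth.tsv` (one trial / subject
#' per row) into `dir`, each with a JSON metadata header recording the
#' cohort seed and generative settings.
#'
#' @param cohort A [simulate_cohort()] object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  meta <- list(seed = cohort$spec$seed,
               n_subjects = cohort$spec$n_subjects,
               gambling_model = cohort$spec$gambling_model,
               coupling_mb = cohort$spec$coupling_mb,
               coupling_mf = cohort$spec$coupling_mf)
  write_mbloss_table(cohort$twostep, file.path(dir, "twostep.tsv"),
                     c(meta, task = "twostep"))
  write_mbloss_table(cohort$gambling, file.path(dir, "gambling.tsv"),
                     c(meta, task = "gambling"))
  write_mbloss_table(cohort$truth, file.path(dir, "truth.tsv"),
                     c(meta, task = "truth"))
  invisible(dir)
}

#' Persist posterior draws as self-describing delimited text
#'
#' Flattens the iterations x chains x variables array to one row per
#' (iteration, chain) with variable columns, preceded by a JSON metadata
#' header carrying the model spec, subjects and sampler diagnostics; the
#' chain structure needed for convergence checks survives the round trip.
#'
#' @param fit A `posterior_draws` object.
#' @param path Output path.
#' @return `write_draws()` returns `path` invisibly; `read_draws()` returns
#'   a `posterior_draws` object.
#' @export
write_draws <- function(fit, path) {
  stopifnot(inherits(fit, "posterior_draws"))
  d <- dim(fit$draws)
  flat <- matrix(aperm(fit$draws, c(1, 2, 3)), d[1] * d[2], d[3])
  df <- data.frame(iteration = rep(seq_len(d[1]), d[2]),
                   chain = rep(seq_len(d[2]), each = d[1]))
  df[fit$param_names] <- as.data.frame(flat)
  write_mbloss_table(df, path, meta = list(
    type = "posterior_draws", spec = unclass(fit$spec),
    subjects = fit$subjects, accept_rate = fit$accept_rate,
    runtime_s = fit$runtime_s))
}

#' @rdname write_draws
#' @export
read_draws <- function(path) {
  df <- read_mbloss_table(path)
  meta <- attr(df, "meta")
  if (is.null(meta) || !identical(meta$type, "posterior_draws"))
    stop("not a posterior draws file", call. = FALSE)
  vars <- setdiff(names(df), c("iteration", "chain"))
  n_it <- max(df$iteration); n_ch <- max(df$chain)
  arr <- array(NA_real_, c(n_it, n_ch, length(vars)),
               dimnames = list(NULL, paste0("chain", seq_len(n_ch)), vars))
  for (ch in seq_len(n_ch))
    arr[, ch, ] <- as.matrix(df[df$chain == ch, vars])
  spec <- meta$spec
  class(spec) <- "joint_model_spec"
  structure(list(draws = arr, param_names = vars,
                 subjects = meta$subjects, spec = spec,
                 accept_rate = meta$accept_rate,
                 runtime_s = meta$runtime_s),
            class = "posterior_draws")
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `twostep.tsv`, `gambling.tsv`,
#'   `truth.tsv`.
#' @return A list with `twostep`, `gambling`, `truth` tables (class
#'   `cohort`; the generative spec is not reconstructed).
#' @export
read_cohort <- function(dir) {
  out <- list(twostep = read_mbloss_table(file.path(dir, "twostep.tsv")),
              gambling = read_mbloss_table(file.path(dir, "gambling.tsv")),
              truth = read_mbloss_table(file.path(dir, "truth.tsv")),
              spec = NULL)
  class(out) <- "cohort"
  out
}
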