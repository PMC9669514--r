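#' Configuration of a synthetic sequential trial dataset
#'
#' Describes the generative model for a sequence of two-arm trials reported
#' as summary statistics. The true effect of trial j is
#' `theta_j = theta0 + drift_per_trial * (j - 1) + tau * u_j` with
#' `u_j` standard normal: `theta0` is the baseline mean difference,
#' `drift_per_trial` encodes a learning curve (a systematic change of the
#' intervention effect across successive trials, the violation that breaks
#' conditional planning; 0 means the constant-effect assumption holds), and
#' `tau` is the between-trial SD of true effects. The observed mean
#' difference is `md_j ~ Normal(theta_j, se_j^2)` with
#' `se_j^2 = sd_active^2/n_active + sd_sham^2/n_sham`, and `se_j` is
#' recorded as the (true) standard error, mirroring how trial reports are
#' consumed downstream.
#'
#' @param n_trials number of trials in the sequence.
#' @param theta0 baseline true mean difference.
#' @param drift_per_trial change in the true effect per publication step,
#'   default 0.
#' @param tau between-trial SD of true effects, default 0 (nonnegative).
#' @param sd_active,sd_sham per-arm outcome SDs, default 15 mmHg each (a
#'   typical ambulatory blood-pressure change SD).
#' @param n_active,n_sham per-arm sizes, recycled to `n_trials`; default 40
#'   per arm, the scale of the shipped renal-denervation trials.
#' @param seed integer seed, default 1.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_trials, theta0, drift_per_trial = 0,
                             tau = 0, sd_active = 15, sd_sham = 15,
                             n_active = 40, n_sham = 40, seed = 1L) {
  if (n_trials < 1) stop("`n_trials` must be >= 1", call. = FALSE)
  if (tau < 0) stop("`tau` must be >= 0", call. = FALSE)
  if (sd_active <= 0 || sd_sham <= 0)
    stop("per-arm SDs must be > 0", call. = FALSE)
  n_active <- rep_len(as.integer(n_active), n_trials)
  n_sham <- rep_len(as.integer(n_sham), n_trials)
  if (any(n_active < 2) || any(n_sham < 2))
    stop("per-arm sizes must be >= 2", call. = FALSE)
  structure(list(n_trials = as.integer(n_trials), theta0 = theta0,
                 drift_per_trial = drift_per_trial, tau = tau,
                 sd_active = sd_active, sd_sham = sd_sham,
                 n_active = n_active, n_sham = n_sham,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# deterministic per-trial quantities shared by the scalar and vectorized
# generators
synthetic_moments <- function(config) {
  j <- seq_len(config$n_trials)
  list(
    theta_mean = config$theta0 + config$drift_per_trial * (j - 1),
    se = sqrt(config$sd_active^2 / config$n_active +
                config$sd_sham^2 / config$n_sham)
  )
}

#' Generate a synthetic trial sequence
#'
#' Draws one trial sequence from the model in [synthetic_config()] and
#' returns it as a [trial_set] in the same summary format as real data, so
#' every downstream stage (meta-analysis, sequential monitoring,
#' conditional planning) runs unchanged on simulated input. Fully
#' reproducible from the config's seed. The true per-trial effects are
#' attached as attribute `"theta_true"`.
#'
#' @param config a [synthetic_config].
#' @return a [trial_set] of `n_trials` simulated trials.
#' @examples
#' generate_trials(synthetic_config(6, theta0 = -3, seed = 42))
#' @export
generate_trials <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  mo <- synthetic_moments(config)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(config$seed)
  theta <- mo$theta_mean + config$tau * stats::rnorm(config$n_trials)
  md <- stats::rnorm(config$n_trials, theta, mo$se)
  k <- config$n_trials
  out <- trial_set(data.frame(
    trial_id = sprintf("sim_%03d", seq_len(k)),
    label = sprintf("Simulated trial %d", seq_len(k)),
    order = seq_len(k),
    year = 2000L + seq_len(k),
    n_active = config$n_active,
    n_sham = config$n_sham,
    md = md,
    se_md = mo$se,
    planned_n_active = NA_integer_,
    planned_n_sham = NA_integer_,
    planned_power = NA_real_,
    anticipated_delta = NA_real_,
    anticipated_sd = NA_real_,
    allocation_ratio = 1,
    prospectively_powered = FALSE,
    stringsAsFactors = FALSE
  ))
  attr(out, "theta_true") <- theta
  out
}

# Vectorized draw of R replicate md-sequences (R x K matrix); one seed for
# the whole batch. Used by coverage_study, where per-replicate trial_set
# construction would dominate the runtime.
generate_md_matrix <- function(config, replicates) {
  mo <- synthetic_moments(config)
  k <- config$n_trials
  set.seed(config$seed)
  u <- matrix(stats::rnorm(replicates * k), replicates, k)
  eps <- matrix(stats::rnorm(replicates * k), replicates, k)
  theta <- matrix(mo$theta_mean, replicates, k, byrow = TRUE) +
    config$tau * u
  md <- theta + sweep(eps, 2L, mo$se, `*`)
  list(md = md, theta = theta, se = mo$se)
}

#' Operating characteristics of the pipeline on synthetic data
#'
#' Monte-Carlo study of two frequentist guarantees: the coverage of the
#' final 95% confidence interval for the fixed-effect estimand (the
#' inverse-variance weighted average of the true per-trial effects, which
#' equals `theta0` when drift and tau are zero), and the probability that
#' sequential monitoring crosses a boundary anywhere in the sequence
#' (the empirical type-I error when `theta0 = 0`, `drift = 0`).
#' Boundaries are computed once per design (trial sizes are common across
#' replicates) and the replicate z-paths are evaluated against them in
#' vectorized form.
#'
#' @param config a [synthetic_config].
#' @param replicates number of replicate sequences, at least 100.
#' @param design a [sequential_design] for the monitoring arm of the study.
#' @param level confidence level for the coverage arm, default 0.95.
#' @return a list with `coverage`, `crossing_rate`, `replicates`, and the
#'   per-replicate final pooled estimates `pooled_md` (for moment checks).
#' @examples
#' cfg <- synthetic_config(6, theta0 = 0, seed = 7)
#' coverage_study(cfg, 200, sequential_design(delta_plan = -2, sd_plan = 10))
#' @export
coverage_study <- function(config, replicates,
                           design = sequential_design(delta_plan = -2,
                                                      sd_plan = 10),
                           level = 0.95) {
  stopifnot(inherits(config, "synthetic_config"),
            inherits(design, "sequential_design"))
  if (replicates < 100) stop("`replicates` must be >= 100", call. = FALSE)
  sim <- generate_md_matrix(config, replicates)
  w <- 1 / sim$se^2
  wcum <- cumsum(w)
  # cumulative pooled estimates: rows = replicates, cols = looks
  num <- t(apply(sweep(sim$md, 2L, w, `*`), 1L, cumsum))
  pooled <- sweep(num, 2L, wcum, `/`)
  se_pooled <- 1 / sqrt(wcum)
  z <- sweep(pooled, 2L, se_pooled, `/`)
  k <- config$n_trials

  # coverage of the fixed-effect estimand at the final look
  estimand <- as.numeric(sim$theta %*% w) / sum(w)
  zc <- stats::qnorm(1 - (1 - level) / 2)
  covered <- abs(pooled[, k] - estimand) <= zc * se_pooled[k]

  # monitoring: common boundary schedule across replicates
  cum_n <- cumsum(config$n_active + config$n_sham)
  ris <- required_information_size(design)
  info <- if (design$information_metric == "participants") cum_n else wcum
  t_obs <- pmin(info / ris, 1)
  keep <- !duplicated(t_obs)
  sched <- compute_boundaries(design, t_obs[keep])
  boundaries <- sched$boundaries[cumsum(keep)]
  crossed <- abs(z) >= matrix(boundaries, replicates, k, byrow = TRUE)

  list(coverage = mean(covered),
       crossing_rate = mean(apply(crossed, 1L, any)),
       replicates = replicates,
       pooled_md = pooled[, k],
       estimand = estimand)
}
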