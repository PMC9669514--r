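#' Inverse-variance fixed-effect meta-analysis of mean differences
#'
#' Pools per-trial mean differences with weights `w_i = 1/SE_i^2`. The
#' pooled estimate is `sum(w * md) / sum(w)` with standard error
#' `1/sqrt(sum(w))`; the 95% confidence interval and the two-sided p-value
#' use the standard normal reference, the convention of inverse-variance
#' meta-analysis software. Heterogeneity is summarized by Cochran's Q, the
#' DerSimonian-Laird between-study variance tau^2 (zero for a single
#' trial), and I^2.
#'
#' @param trials a [trial_set] or any data frame with columns `md` and
#'   `se_md` (a subset of trials is fine).
#' @param level confidence level, default 0.95.
#' @return an object of class `meta_result`: `k_trials`, `pooled_md`,
#'   `se_pooled`, `ci_low`, `ci_high`, `z`, `p_two_sided`, `q`, `df`,
#'   `tau2`, `i2`, `weights`.
#' @examples
#' rdn <- rdn_trials()
#' pool_fixed(rdn[1:4, ])
#' @export
pool_fixed <- function(trials, level = 0.95) {
  md <- check_md_se(trials)
  w <- 1 / md$se^2
  k <- length(w)
  pooled <- sum(w * md$md) / sum(w)
  se <- 1 / sqrt(sum(w))
  zc <- stats::qnorm(1 - (1 - level) / 2)
  z <- pooled / se
  q <- sum(w * (md$md - pooled)^2)
  df <- k - 1L
  tau2 <- if (k >= 2L) dl_tau2(md$md, md$se)$tau2 else 0
  i2 <- if (k >= 2L && q > 0) max(0, (q - df) / q) else 0
  structure(list(
    k_trials = k, pooled_md = pooled, se_pooled = se,
    ci_low = pooled - zc * se, ci_high = pooled + zc * se,
    z = z, p_two_sided = 2 * stats::pnorm(-abs(z)),
    q = q, df = df, tau2 = tau2, i2 = i2, weights = w
  ), class = "meta_result")
}

check_md_se <- function(trials) {
  if (!is.data.frame(trials) || nrow(trials) == 0L)
    stop("need a non-empty set of trials", call. = FALSE)
  if (!all(c("md", "se_md") %in% names(trials)))
    stop("need columns md and se_md", call. = FALSE)
  if (any(is.na(trials$md)) || any(is.na(trials$se_md)) ||
      any(trials$se_md <= 0))
    stop("md must be non-missing and se_md positive", call. = FALSE)
  list(md = as.numeric(trials$md), se = as.numeric(trials$se_md))
}

dl_tau2 <- function(md, se) {
  w <- 1 / se^2
  pooled <- sum(w * md) / sum(w)
  q <- sum(w * (md - pooled)^2)
  df <- length(md) - 1L
  denom <- sum(w) - sum(w^2) / sum(w)
  tau2 <- if (denom > 0) max(0, (q - df) / denom) else 0
  list(tau2 = tau2, q = q, df = df)
}

#' DerSimonian-Laird between-study variance
#'
#' Moment estimator of the between-study variance of true effects:
#' `tau^2 = max(0, (Q - df) / (sum(w) - sum(w^2)/sum(w)))` with
#' fixed-effect weights `w_i = 1/SE_i^2` and Cochran's
#' `Q = sum(w * (md_i - pooled)^2)`. Truncated at zero whenever Q falls
#' below its degrees of freedom.
#'
#' @param trials a [trial_set] or data frame with `md` and `se_md`;
#'   at least two trials.
#' @return a list with `tau2`, `q` and `df`.
#' @examples
#' estimate_tau2_dl(rdn_trials())  # tau2 = 0 for the shipped data
#' @export
estimate_tau2_dl <- function(trials) {
  md <- check_md_se(trials)
  if (length(md$md) < 2L)
    stop("need at least two trials to estimate tau^2", call. = FALSE)
  dl_tau2(md$md, md$se)
}

#' Random-effects pooling with a given between-study variance
#'
#' Inverse-variance pooling with weights `1/(SE_i^2 + tau2)`. With
#' `tau2 = 0` this reduces exactly to [pool_fixed()]. The heterogeneity
#' summaries (Q, tau^2 as estimated by DerSimonian-Laird, I^2) are reported
#' from the fixed-effect weights as usual.
#'
#' @param trials a [trial_set] or data frame with `md` and `se_md`.
#' @param tau2 between-study variance; default: DerSimonian-Laird estimate.
#' @param level confidence level, default 0.95.
#' @return a `meta_result` (weights are the random-effects weights).
#' @export
pool_random <- function(trials, tau2 = NULL, level = 0.95) {
  md <- check_md_se(trials)
  if (is.null(tau2))
    tau2 <- if (length(md$md) >= 2L) dl_tau2(md$md, md$se)$tau2 else 0
  if (tau2 < 0) stop("tau2 must be >= 0", call. = FALSE)
  fe <- pool_fixed(trials, level = level)
  w <- 1 / (md$se^2 + tau2)
  pooled <- sum(w * md$md) / sum(w)
  se <- 1 / sqrt(sum(w))
  zc <- stats::qnorm(1 - (1 - level) / 2)
  z <- pooled / se
  structure(list(
    k_trials = fe$k_trials, pooled_md = pooled, se_pooled = se,
    ci_low = pooled - zc * se, ci_high = pooled + zc * se,
    z = z, p_two_sided = 2 * stats::pnorm(-abs(z)),
    q = fe$q, df = fe$df, tau2 = tau2, i2 = fe$i2, weights = w
  ), class = "meta_result")
}

#' Cumulative meta-analysis in publication order
#'
#' Re-runs the fixed-effect meta-analysis on the first j trials for
#' j = 1..K, following the chronological order of publication, and tracks
#' the running total of randomized participants. This is the evidence
#' trajectory that sequential monitoring and conditional planning operate
#' on.
#'
#' @param trials a [trial_set], sorted by `order`.
#' @param level confidence level, default 0.95.
#' @return a data frame of class `cumulative_meta` with one row per step:
#'   `upto_order`, `trial_id`, `cumulative_n`, `pooled_md`, `se_pooled`,
#'   `ci_low`, `ci_high`, `z`, `p_two_sided`. The full `meta_result` of
#'   each step is attached as attribute `"metas"`.
#' @examples
#' cumulative_meta(rdn_trials())
#' @export
cumulative_meta <- function(trials, level = 0.95) {
  trials <- trial_set(trials)
  k <- nrow(trials)
  metas <- lapply(seq_len(k), function(j) pool_fixed(trials[seq_len(j), ],
                                                     level = level))
  out <- data.frame(
    upto_order = trials$order,
    trial_id = trials$trial_id,
    cumulative_n = cumsum(trials$n_active + trials$n_sham),
    pooled_md = vapply(metas, `[[`, numeric(1), "pooled_md"),
    se_pooled = vapply(metas, `[[`, numeric(1), "se_pooled"),
    ci_low = vapply(metas, `[[`, numeric(1), "ci_low"),
    ci_high = vapply(metas, `[[`, numeric(1), "ci_high"),
    z = vapply(metas, `[[`, numeric(1), "z"),
    p_two_sided = vapply(metas, `[[`, numeric(1), "p_two_sided"),
    stringsAsFactors = FALSE
  )
  attr(out, "metas") <- metas
  class(out) <- c("cumulative_meta", "data.frame")
  out
}

#' @export
print.meta_result <- function(x, digits = 2, ...) {
  cat(sprintf(
    "Meta-analysis of %d trial%s\n  pooled MD %.*f mmHg (95%% CI %.*f to %.*f), z = %.2f, p = %.4g\n  Q = %.2f (df = %d), tau^2 = %.4g, I^2 = %.1f%%\n",
    x$k_trials, if (x$k_trials == 1L) "" else "s",
    digits, x$pooled_md, digits, x$ci_low, digits, x$ci_high,
    x$z, x$p_two_sided, x$q, x$df, x$tau2, 100 * x$i2))
  invisible(x)
}
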