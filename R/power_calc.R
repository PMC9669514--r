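#' Specification of a two-sample difference-in-means power calculation
#'
#' Bundles the assumptions behind a conventional two-arm sample-size
#' calculation for a continuous endpoint: the anticipated mean difference
#' `delta` (mmHg in the shipped example), the common per-arm standard
#' deviation `sd`, the type-I error `alpha`, the target `power`, the
#' active:control `allocation_ratio` k, the number of `sides` of the test,
#' and an optional superiority `margin` subtracted from `delta` (used by
#' designs that must beat the sham arm by a clinically meaningful amount
#' rather than by zero).
#'
#' Two computational methods are supported. `"noncentral_t"` (the default)
#' evaluates the exact power of the two-sample t-test via the noncentral t
#' distribution; `"normal"` uses the classical closed-form normal
#' approximation. The exact method is the default because published
#' calculations from standard software (nQuery, Stata's power command) are
#' t-based, and the two methods differ by about one participant per arm at
#' typical sizes.
#'
#' @param delta anticipated mean difference (same units as the outcome).
#' @param sd common per-arm standard deviation; must be positive.
#' @param alpha type-I error, default 0.05.
#' @param power target power, default 0.80.
#' @param allocation_ratio active:control ratio k > 0, default 1.
#' @param sides 1 or 2 (default 2).
#' @param margin superiority margin subtracted from `delta`, default 0.
#' @param method `"noncentral_t"` or `"normal"`.
#' @return an object of class `power_spec`.
#' @examples
#' power_spec(delta = 6, sd = 8)
#' @export
power_spec <- function(delta, sd, alpha = 0.05, power = 0.80,
                       allocation_ratio = 1, sides = 2, margin = 0,
                       method = c("noncentral_t", "normal")) {
  method <- match.arg(method)
  if (!is.numeric(delta) || is.na(delta))
    stop("`delta` must be a number", call. = FALSE)
  if (!is.numeric(sd) || is.na(sd) || sd <= 0)
    stop("`sd` must be > 0", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must lie in (0, 1)",
                                     call. = FALSE)
  if (power <= 0 || power >= 1) stop("`power` must lie in (0, 1)",
                                     call. = FALSE)
  if (allocation_ratio <= 0) stop("`allocation_ratio` must be > 0",
                                  call. = FALSE)
  if (!sides %in% c(1, 2)) stop("`sides` must be 1 or 2", call. = FALSE)
  if (delta == margin)
    stop("`delta` must differ from `margin` (no effect to detect)",
         call. = FALSE)
  structure(list(delta = delta, sd = sd, alpha = alpha, power = power,
                 allocation_ratio = allocation_ratio, sides = sides,
                 margin = margin, method = method),
            class = "power_spec")
}

# Effect beyond the margin, on the absolute scale used by two-sided tests.
effect_size <- function(spec) abs(spec$delta - spec$margin)

#' Power of the two-sample difference-in-means test
#'
#' Computes the probability of rejecting the null hypothesis of equal means
#' for given per-arm sizes under the assumptions in `spec`. The
#' `"noncentral_t"` method evaluates the exact t-test power with
#' `df = n_active + n_control - 2` and noncentrality
#' `(delta - margin) / (sd * sqrt(1/n_active + 1/n_control))`; the
#' `"normal"` method replaces the t reference by the standard normal.
#'
#' @param n_active,n_control per-arm sample sizes (each at least 2).
#' @param spec a [power_spec].
#' @return the power, a probability in (0, 1).
#' @examples
#' power_two_means(29, 29, power_spec(delta = 6, sd = 8))
#' @export
power_two_means <- function(n_active, n_control, spec) {
  stopifnot(inherits(spec, "power_spec"))
  if (any(n_active < 2) || any(n_control < 2))
    stop("per-arm sizes must be >= 2", call. = FALSE)
  e <- effect_size(spec)
  ncp <- e / (spec$sd * sqrt(1 / n_active + 1 / n_control))
  if (spec$method == "normal") {
    crit <- stats::qnorm(1 - spec$alpha / spec$sides)
    pow <- stats::pnorm(ncp - crit)
    if (spec$sides == 2) pow <- pow + stats::pnorm(-ncp - crit)
  } else {
    df <- n_active + n_control - 2
    crit <- stats::qt(1 - spec$alpha / spec$sides, df)
    pow <- 1 - stats::pt(crit, df, ncp = ncp)
    if (spec$sides == 2) pow <- pow + stats::pt(-crit, df, ncp = ncp)
  }
  pow
}

#' Smallest per-arm sample sizes reaching the target power
#'
#' For the normal method the control-arm size has the closed form
#' `(1 + 1/k) * sd^2 * (z_{1-alpha/sides} + z_{power})^2 / (delta - margin)^2`;
#' the real-valued solution is rounded up per arm (control size is its
#' ceiling, active size is the ceiling of k times the rounded control size).
#' For the exact noncentral-t method the smallest integer control size whose
#' t-test power reaches the target is found by search, with
#' `n_active = ceiling(k * n_control)`.
#'
#' @param spec a [power_spec].
#' @param n_cap largest admissible control-arm size, default `1e6`.
#' @return a list with `n_active`, `n_control`, `n_total` and the
#'   `achieved_power` at the returned sizes.
#' @examples
#' sample_size_two_means(power_spec(delta = 6, sd = 8))  # 29 per arm
#' @export
sample_size_two_means <- function(spec, n_cap = 1e6) {
  stopifnot(inherits(spec, "power_spec"))
  e <- effect_size(spec)
  k <- spec$allocation_ratio
  zq <- stats::qnorm(1 - spec$alpha / spec$sides) + stats::qnorm(spec$power)
  nc_real <- (1 + 1 / k) * spec$sd^2 * zq^2 / e^2
  if (spec$method == "normal") {
    n_control <- max(2L, as.integer(ceiling(nc_real)))
    n_active <- max(2L, as.integer(ceiling(k * n_control)))
  } else {
    # start just below the normal solution, then walk to the minimal size
    m <- max(2, min(floor(nc_real) - 2, n_cap))
    pow_at <- function(m) power_two_means(max(2, ceiling(k * m)), m, spec)
    while (m < n_cap && pow_at(m) < spec$power) m <- m + 1
    if (pow_at(m) < spec$power)
      stop(sprintf("target power not reached within n_cap = %d per arm",
                   as.integer(n_cap)), call. = FALSE)
    while (m > 2 && pow_at(m - 1) >= spec$power) m <- m - 1
    n_control <- as.integer(m)
    n_active <- max(2L, as.integer(ceiling(k * m)))
  }
  if (n_control > n_cap)
    stop(sprintf("target power not reached within n_cap = %d per arm",
                 as.integer(n_cap)), call. = FALSE)
  list(n_active = n_active, n_control = n_control,
       n_total = n_active + n_control,
       achieved_power = power_two_means(n_active, n_control, spec))
}

#' Replicate each trial's reported sample-size calculation
#'
#' Re-runs the conventional calculation from every prospectively powered
#' trial's own printed assumptions (anticipated difference, per-arm SD,
#' planned power; a two-sided 5% test is assumed where the trial states
#' nothing else) and flags whether the recomputed per-arm sizes equal the
#' sizes the trialists printed. Trials without planning fields
#' (proof-of-concept designs) are skipped with a notice.
#'
#' @param trials a [trial_set].
#' @param alpha type-I error assumed for the replication, default 0.05
#'   two-sided.
#' @param method calculation method, default exact `"noncentral_t"`.
#' @return a data frame with one row per powered trial: the printed and the
#'   recalculated per-arm sizes and a `matches_reported` flag.
#' @examples
#' replicate_reported(rdn_trials())
#' @export
replicate_reported <- function(trials, alpha = 0.05,
                               method = "noncentral_t") {
  trials <- trial_set(trials)
  powered <- !is.na(trials$planned_power)
  skipped <- trials$trial_id[!powered]
  if (length(skipped) > 0L)
    message("skipping trials without planning fields: ",
            paste(skipped, collapse = ", "))
  rows <- lapply(which(powered), function(i) {
    spec <- power_spec(delta = trials$anticipated_delta[i],
                       sd = trials$anticipated_sd[i],
                       alpha = alpha,
                       power = trials$planned_power[i],
                       allocation_ratio = trials$allocation_ratio[i],
                       method = method)
    ss <- sample_size_two_means(spec)
    data.frame(
      trial_id = trials$trial_id[i],
      label = trials$label[i],
      planned_n_active = trials$planned_n_active[i],
      planned_n_sham = trials$planned_n_sham[i],
      recalc_n_active = ss$n_active,
      recalc_n_sham = ss$n_control,
      matches_reported = ss$n_active == trials$planned_n_active[i] &&
        ss$n_control == trials$planned_n_sham[i],
      stringsAsFactors = FALSE
    )
  })
  if (length(rows) == 0L) {
    return(data.frame(trial_id = character(), label = character(),
                      planned_n_active = integer(),
                      planned_n_sham = integer(),
                      recalc_n_active = integer(), recalc_n_sham = integer(),
                      matches_reported = logical(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Relative difference between achieved and calculated sample size
#'
#' `100 * (achieved - calculated) / achieved`, rounded to the nearest
#' integer percent for reporting. A positive value means the trial enrolled
#' more participants than its own calculation required (for example to
#' absorb anticipated dropout).
#'
#' @param achieved_total achieved total sample size; must be positive.
#' @param calculated_total calculated total sample size.
#' @return integer percentage.
#' @examples
#' relative_difference(535, 474)  # 11
#' @export
relative_difference <- function(achieved_total, calculated_total) {
  if (any(achieved_total <= 0))
    stop("achieved sample size must be positive", call. = FALSE)
  as.integer(round(100 * (achieved_total - calculated_total) /
                     achieved_total))
}
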