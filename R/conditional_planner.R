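#' Assumptions for conditional planning of a next trial
#'
#' Collects everything the conditional-power calculation needs besides the
#' current meta-analysis: the effect `theta_assumed` the new trial is
#' expected to show (by default the current pooled mean difference, the
#' evidence-based choice), the per-arm SD `sd_new` of the new trial, the
#' test level, the target power, and two switches. `conditioning`
#' distinguishes the conditional calculation (the observed pooled estimate
#' enters the updated statistic as a fixed quantity; only the new trial is
#' random) from the unconditional one (the updated pooled estimate is drawn
#' around `theta_assumed` with the full updated precision).
#' `rejection_rule` is either the fixed-sample two-sided z-test or a
#' sequential boundary (supply a [compute_boundaries()] schedule via
#' `boundary`; the boundary at the first look not yet reached is used as
#' the critical value).
#'
#' @param sd_new per-arm SD of the planned trial, positive.
#' @param theta_assumed assumed effect of the new trial; `NULL` (default)
#'   means "use the current pooled estimate".
#' @param alpha two-sided level, default 0.05.
#' @param target_power target conditional power, default 0.80.
#' @param conditioning `"conditional_on_estimate"` or `"unconditional"`.
#' @param rejection_rule `"fixed_sample"` or `"sequential_boundary"`.
#' @param boundary a `boundary_schedule`, required for the sequential rule.
#' @param n_cap largest admissible per-arm size, default `1e6`.
#' @param mc_reps Monte-Carlo replicates for `method = "simulation"`,
#'   default 1000.
#' @param seed integer seed for the Monte-Carlo draws, default 1.
#' @return an object of class `plan_assumptions`.
#' @export
plan_assumptions <- function(sd_new, theta_assumed = NULL, alpha = 0.05,
                             target_power = 0.80,
                             conditioning = c("conditional_on_estimate",
                                              "unconditional"),
                             rejection_rule = c("fixed_sample",
                                                "sequential_boundary"),
                             boundary = NULL, n_cap = 1e6, mc_reps = 1000,
                             seed = 1L) {
  conditioning <- match.arg(conditioning)
  rejection_rule <- match.arg(rejection_rule)
  if (!is.numeric(sd_new) || is.na(sd_new) || sd_new <= 0)
    stop("`sd_new` must be > 0", call. = FALSE)
  if (target_power <= 0 || target_power >= 1)
    stop("`target_power` must lie in (0, 1)", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must lie in (0, 1)",
                                     call. = FALSE)
  if (n_cap < 1) stop("`n_cap` must be >= 1", call. = FALSE)
  if (mc_reps < 1) stop("`mc_reps` must be >= 1", call. = FALSE)
  if (rejection_rule == "sequential_boundary" &&
      !inherits(boundary, "boundary_schedule"))
    stop("the sequential rejection rule needs a boundary_schedule",
         call. = FALSE)
  structure(list(theta_assumed = theta_assumed, sd_new = sd_new,
                 alpha = alpha, target_power = target_power,
                 conditioning = conditioning,
                 rejection_rule = rejection_rule, boundary = boundary,
                 n_cap = as.integer(n_cap), mc_reps = as.integer(mc_reps),
                 seed = as.integer(seed)),
            class = "plan_assumptions")
}

# critical value implied by the rejection rule
critical_value <- function(assume, info_fraction = 1) {
  if (assume$rejection_rule == "fixed_sample") {
    stats::qnorm(1 - assume$alpha / 2)
  } else {
    b <- assume$boundary
    j <- which(b$looks >= min(info_fraction, 1))
    if (length(j) == 0L) j <- length(b$looks)
    b$boundaries[j[1L]]
  }
}

# mean and sd of the updated z-statistic given old evidence and a new trial
updated_z_law <- function(meta_old, n_per_arm, assume) {
  W <- if (is.null(meta_old)) 0 else 1 / meta_old$se_pooled^2
  theta_old <- if (is.null(meta_old)) 0 else meta_old$pooled_md
  theta <- if (is.null(assume$theta_assumed)) theta_old else
    assume$theta_assumed
  w_new <- n_per_arm / (2 * assume$sd_new^2)
  if (!is.finite(w_new) || w_new <= 0)
    stop("degenerate new-trial weight", call. = FALSE)
  if (assume$conditioning == "conditional_on_estimate") {
    mu <- (W * theta_old + w_new * theta) / sqrt(W + w_new)
    sdv <- sqrt(w_new / (W + w_new))
  } else {
    mu <- theta * sqrt(W + w_new)
    sdv <- 1
  }
  list(mu = mu, sd = sdv, w_new = w_new, W = W, theta = theta,
       theta_old = theta_old)
}

#' Conditional power of the updated meta-analysis
#'
#' Probability that the meta-analysis, after adding a planned two-arm trial
#' of `n_per_arm` participants per arm, rejects the null hypothesis of no
#' effect. The new trial contributes inverse-variance weight
#' `w_new = n / (2 * sd_new^2)` and its estimate is drawn from
#' `Normal(theta_assumed, 1/w_new)`; the updated statistic is
#' `Z = (W_old * md_old + w_new * md_new) / sqrt(W_old + w_new)`. With no
#' prior evidence (`meta_old = NULL`) this reduces to the ordinary
#' normal-approximation power of a stand-alone trial of that size.
#'
#' @param meta_old a `meta_result` for the accumulated evidence, or `NULL`
#'   for no prior evidence.
#' @param n_per_arm per-arm size of the planned trial, at least 1.
#' @param assume a [plan_assumptions].
#' @param method `"analytic"` (closed-form normal calculation) or
#'   `"simulation"` (seeded Monte-Carlo over the new trial's estimate).
#' @return rejection probability in (0, 1).
#' @examples
#' m1 <- pool_fixed(rdn_trials()[1, ])
#' conditional_power(m1, 325, plan_assumptions(sd_new = 10,
#'   conditioning = "unconditional"))
#' @export
conditional_power <- function(meta_old, n_per_arm, assume,
                              method = c("analytic", "simulation")) {
  method <- match.arg(method)
  stopifnot(inherits(assume, "plan_assumptions"))
  if (n_per_arm < 1) stop("`n_per_arm` must be >= 1", call. = FALSE)
  law <- updated_z_law(meta_old, n_per_arm, assume)
  cv <- critical_value(assume)
  if (method == "analytic") {
    stats::pnorm((-cv - law$mu) / law$sd) +
      1 - stats::pnorm((cv - law$mu) / law$sd)
  } else {
    # substream per candidate n so that a search over n is reproducible
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
    set.seed(assume$seed + as.integer(n_per_arm) %% 1000003L)
    md_new <- stats::rnorm(assume$mc_reps, law$theta, 1 / sqrt(law$w_new))
    if (assume$conditioning == "conditional_on_estimate") {
      z <- (law$W * law$theta_old + law$w_new * md_new) /
        sqrt(law$W + law$w_new)
    } else {
      pooled <- stats::rnorm(assume$mc_reps, law$theta,
                             1 / sqrt(law$W + law$w_new))
      z <- pooled * sqrt(law$W + law$w_new)
    }
    mean(abs(z) >= cv)
  }
}

#' Plan the size of the next trial from the accumulated evidence
#'
#' Finds the smallest per-arm sample size whose conditional power reaches
#' the target. When the accumulated meta-analysis already rejects the null
#' under the chosen rejection rule, no further trial is needed and the
#' planned size is zero (flagged `already_rejected`).
#'
#' @inheritParams conditional_power
#' @return an object of class `plan_result`: `n_per_arm`,
#'   `achieved_power`, `already_rejected`, `method`, and the `assumptions`
#'   snapshot.
#' @examples
#' m1 <- pool_fixed(rdn_trials()[1, ])
#' plan_next_trial(m1, plan_assumptions(sd_new = 10,
#'   conditioning = "unconditional"))
#' @export
plan_next_trial <- function(meta_old, assume,
                            method = c("analytic", "simulation")) {
  method <- match.arg(method)
  stopifnot(inherits(assume, "plan_assumptions"))
  cv <- critical_value(assume)
  if (!is.null(meta_old) && abs(meta_old$z) >= cv) {
    return(structure(list(n_per_arm = 0L, achieved_power = NA_real_,
                          already_rejected = TRUE, method = method,
                          assumptions = assume),
                     class = "plan_result"))
  }
  pow <- function(n) conditional_power(meta_old, n, assume, method = method)
  lo <- 1L; hi <- 2L
  while (hi < assume$n_cap && pow(hi) < assume$target_power) {
    lo <- hi
    hi <- min(assume$n_cap, hi * 2L)
  }
  if (pow(hi) < assume$target_power) {
    stop(sprintf(
      "target power %.3f not reachable below n_cap = %d (power at cap: %.4f)",
      assume$target_power, assume$n_cap, pow(assume$n_cap)), call. = FALSE)
  }
  while (hi - lo > 1L) {  # invariant: pow(lo) < target <= pow(hi)
    mid <- lo + (hi - lo) %/% 2L
    if (pow(mid) < assume$target_power) lo <- mid else hi <- mid
  }
  n <- if (pow(lo) >= assume$target_power) lo else hi
  structure(list(n_per_arm = n, achieved_power = pow(n),
                 already_rejected = FALSE, method = method,
                 assumptions = assume),
            class = "plan_result")
}

#' Prospective conditional-planning walk over a trial sequence
#'
#' Replays the planning process a collaborative group would have run: after
#' each published trial j, pool trials 1..j, assume the next trial will show
#' the pooled effect, and compute the per-arm size a (j+1)-th trial would
#' need for the updated meta-analysis to reject the null with the target
#' conditional power. Once the accumulated evidence already rejects, the
#' planned size is zero. The output compares the planned sizes with the
#' sizes the trialists actually enrolled.
#'
#' @param trials a [trial_set].
#' @param assume a [plan_assumptions]; its `theta_assumed` is overridden at
#'   each step by the current pooled estimate.
#' @param method `"analytic"` or `"simulation"`.
#' @return a data frame of class `prospective_walk`: one row per planning
#'   step with `upto_order` (evidence used), `plans_order` (the trial being
#'   planned), `theta_assumed`, `planned_n_per_arm`, `already_rejected`,
#'   `achieved_power`, and the actually enrolled `actual_n_active` /
#'   `actual_n_sham` where that trial exists.
#' @examples
#' prospective_walk(rdn_trials(), plan_assumptions(sd_new = 10))
#' @export
prospective_walk <- function(trials, assume,
                             method = c("analytic", "simulation")) {
  method <- match.arg(method)
  trials <- trial_set(trials)
  k <- nrow(trials)
  rows <- lapply(seq_len(k), function(j) {
    meta_j <- pool_fixed(trials[seq_len(j), ])
    a <- assume
    a$theta_assumed <- meta_j$pooled_md
    pr <- plan_next_trial(meta_j, a, method = method)
    has_next <- j < k
    data.frame(
      upto_order = j,
      plans_order = j + 1L,
      theta_assumed = meta_j$pooled_md,
      planned_n_per_arm = pr$n_per_arm,
      already_rejected = pr$already_rejected,
      achieved_power = pr$achieved_power,
      actual_n_active = if (has_next) trials$n_active[j + 1L] else NA_integer_,
      actual_n_sham = if (has_next) trials$n_sham[j + 1L] else NA_integer_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("prospective_walk", "data.frame")
  out
}

#' Recalculate trial sizes using the meta-analytic effect
#'
#' The simpler evidence-based comparator to conditional planning: for each
#' prospectively powered trial after the first, redo its conventional
#' sample-size calculation replacing the trialists' anticipated difference
#' by the pooled mean difference of all earlier trials, keeping the trial's
#' own SD assumption and 80% power (exact noncentral-t method).
#'
#' @param trials a [trial_set].
#' @param power target power, default 0.80.
#' @param alpha two-sided level, default 0.05.
#' @return data frame with one row per eligible trial: `trial_id`,
#'   `delta_meta` (the pooled MD of earlier trials), `sd_own`, and the
#'   recalculated per-arm sizes.
#' @examples
#' recalc_with_meta_effect(rdn_trials())
#' @export
recalc_with_meta_effect <- function(trials, power = 0.80, alpha = 0.05) {
  trials <- trial_set(trials)
  k <- nrow(trials)
  rows <- lapply(seq_len(k), function(j) {
    if (j == 1L || is.na(trials$anticipated_sd[j])) return(NULL)
    meta_prev <- pool_fixed(trials[seq_len(j - 1L), ])
    spec <- power_spec(delta = meta_prev$pooled_md,
                       sd = trials$anticipated_sd[j],
                       alpha = alpha, power = power,
                       allocation_ratio = trials$allocation_ratio[j],
                       method = "noncentral_t")
    ss <- sample_size_two_means(spec)
    data.frame(trial_id = trials$trial_id[j],
               delta_meta = meta_prev$pooled_md,
               sd_own = trials$anticipated_sd[j],
               recalc_n_active = ss$n_active,
               recalc_n_sham = ss$n_control,
               stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0L)
    return(data.frame(trial_id = character(), delta_meta = numeric(),
                      sd_own = numeric(), recalc_n_active = integer(),
                      recalc_n_sham = integer(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' @export
print.plan_result <- function(x, ...) {
  if (x$already_rejected) {
    cat("No further trial needed: the accumulated evidence already rejects the null.\n")
  } else {
    cat(sprintf(
      "Next trial: %d participants per arm (conditional power %.3f, %s, %s)\n",
      x$n_per_arm, x$achieved_power, x$method,
      x$assumptions$conditioning))
  }
  invisible(x)
}
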