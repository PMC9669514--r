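#' Design of a sequentially monitored meta-analysis
#'
#' Collects the anchors of an error-spending sequential analysis: the
#' overall two-sided type-I error `alpha`, the target `power`, and a
#' planning effect `delta_plan` with per-arm SD `sd_plan` that fix the
#' required information size (the denominator of the information fraction).
#' `spending` selects the spending family: `"obrien_fleming_type"` (the
#' continuous O'Brien-Fleming-type function, conservative early), or
#' `"pocock_type"` (approximately constant boundaries), or `"none"` for the
#' naive rule that tests every look at the fixed-sample critical value
#' (which does not control the overall error and is included as the
#' conventional comparator). `information_metric` chooses whether looks are
#' placed on the randomized-participants scale (cumulative N over the
#' required N) or on the statistical-information scale (cumulative
#' inverse-variance weight over the required information).
#'
#' @param delta_plan planning mean difference (nonzero; sign is ignored).
#' @param sd_plan planning per-arm SD, positive.
#' @param alpha overall two-sided type-I error, default 0.05.
#' @param power target power, default 0.90.
#' @param spending spending family, see above.
#' @param information_metric `"participants"` or `"statistical_information"`.
#' @return an object of class `sequential_design`.
#' @examples
#' sequential_design(delta_plan = -2, sd_plan = 10)
#' @export
sequential_design <- function(delta_plan, sd_plan, alpha = 0.05,
                              power = 0.90,
                              spending = c("obrien_fleming_type",
                                           "pocock_type", "none"),
                              information_metric = c("participants",
                                                     "statistical_information")) {
  spending <- match.arg(spending)
  information_metric <- match.arg(information_metric)
  if (!is.numeric(delta_plan) || is.na(delta_plan) || delta_plan == 0)
    stop("`delta_plan` must be a nonzero number", call. = FALSE)
  if (!is.numeric(sd_plan) || is.na(sd_plan) || sd_plan <= 0)
    stop("`sd_plan` must be > 0", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must lie in (0, 1)",
                                     call. = FALSE)
  if (power <= 0 || power >= 1) stop("`power` must lie in (0, 1)",
                                     call. = FALSE)
  structure(list(alpha = alpha, power = power, delta_plan = delta_plan,
                 sd_plan = sd_plan, spending = spending,
                 information_metric = information_metric),
            class = "sequential_design")
}

#' Required information size of a meta-analysis
#'
#' The fixed-sample total sample size (both arms, 1:1 allocation) that a
#' meta-analysis needs to detect the planning effect:
#' `N = ceiling(4 * sd^2 * (z_{1-alpha/2} + z_{power})^2 / delta^2)`.
#' Under the `"statistical_information"` metric the analogous maximum
#' information `I_max = (z_{1-alpha/2} + z_{power})^2 / delta^2` is
#' returned instead (the target for the cumulative inverse-variance weight
#' `sum(1/SE^2)`).
#'
#' @param design a [sequential_design].
#' @return required total participants (integer) or required statistical
#'   information (numeric), depending on the design's metric.
#' @examples
#' required_information_size(sequential_design(delta_plan = 10, sd_plan = 10))
#' @export
required_information_size <- function(design) {
  stopifnot(inherits(design, "sequential_design"))
  zq <- stats::qnorm(1 - design$alpha / 2) + stats::qnorm(design$power)
  if (design$information_metric == "participants") {
    as.integer(ceiling(4 * design$sd_plan^2 * zq^2 / design$delta_plan^2))
  } else {
    zq^2 / design$delta_plan^2
  }
}

#' Cumulative type-I error spent at an information fraction
#'
#' The continuous spending functions:
#' O'Brien-Fleming-type `f(t) = 2 - 2 * pnorm(qnorm(1 - alpha/2)/sqrt(t))`,
#' Pocock-type `f(t) = alpha * log(1 + (exp(1) - 1) * t)`. Both are
#' nondecreasing with `f(1) = alpha`.
#'
#' @param spending `"obrien_fleming_type"` or `"pocock_type"`.
#' @param t information fraction(s) in (0, 1].
#' @param alpha overall two-sided type-I error.
#' @return cumulative alpha spent, same length as `t`.
#' @examples
#' spending_value("obrien_fleming_type", 0.5, 0.05)
#' @export
spending_value <- function(spending, t, alpha) {
  spending <- match.arg(spending, c("obrien_fleming_type", "pocock_type"))
  if (any(t <= 0) || any(t > 1))
    stop("information fractions must lie in (0, 1]", call. = FALSE)
  if (spending == "obrien_fleming_type") {
    2 - 2 * stats::pnorm(stats::qnorm(1 - alpha / 2) / sqrt(t))
  } else {
    alpha * log(1 + (exp(1) - 1) * t)
  }
}

#' Two-sided error-spending boundaries at observed looks
#'
#' Computes symmetric rejection boundaries `b_j` such that the probability
#' of a first crossing at look j equals the spending increment
#' `f(t_j) - f(t_{j-1})` under the null, using the canonical joint law of
#' sequential z-statistics (`Cov(Z_i, Z_j) = sqrt(t_i/t_j)`). The
#' computation is the classical recursion over the sub-density of the
#' non-crossed sample path, evaluated by trapezoidal quadrature on a grid
#' of at least `ngrid` nodes per look, with boundary root-finding to 1e-6.
#' The first boundary has the closed form `qnorm(1 - f(t_1)/2)`. A spending
#' increment of (numerically) zero yields an infinite boundary at that look.
#'
#' With `spending = "none"` every boundary equals the fixed-sample critical
#' value `qnorm(1 - alpha/2)` and no error-spending accounting is done.
#'
#' @param design a [sequential_design].
#' @param looks strictly increasing information fractions in (0, 1].
#' @param ngrid quadrature nodes per look (minimum 256 enforced).
#' @return an object of class `boundary_schedule`: `looks`, `alpha_spent`,
#'   `boundaries`, and `crossed_at` (`NA` until filled by [monitor()]).
#' @examples
#' d <- sequential_design(delta_plan = -2, sd_plan = 10)
#' compute_boundaries(d, looks = c(0.5, 1))
#' @export
compute_boundaries <- function(design, looks, ngrid = 512) {
  stopifnot(inherits(design, "sequential_design"))
  if (length(looks) == 0L) stop("need at least one look", call. = FALSE)
  if (any(looks <= 0) || any(looks > 1))
    stop("information fractions must lie in (0, 1]", call. = FALSE)
  if (any(diff(looks) <= 0))
    stop("information fractions must be strictly increasing", call. = FALSE)
  ngrid <- max(256L, as.integer(ngrid))
  K <- length(looks)
  alpha <- design$alpha

  if (design$spending == "none") {
    b <- rep(stats::qnorm(1 - alpha / 2), K)
    return(structure(list(looks = looks, alpha_spent = rep(NA_real_, K),
                          boundaries = b, crossed_at = NA_integer_,
                          spending = "none", alpha = alpha),
                     class = "boundary_schedule"))
  }

  f <- spending_value(design$spending, looks, alpha)
  b <- numeric(K)
  # recursion state: sub-density of S_j = Z_j * sqrt(t_j) on the surviving
  # region, as (grid, values, step)
  grid <- NULL; dens <- NULL; h <- NULL
  zmax <- 12  # effective support cap for infinite boundaries

  for (j in seq_len(K)) {
    if (j == 1L) {
      b[1] <- if (f[1] <= 0) Inf else stats::qnorm(1 - f[1] / 2)
    } else {
      dt <- looks[j] - looks[j - 1L]
      inc <- f[j] - f[j - 1L]
      if (inc <= 1e-12) {
        b[j] <- Inf
      } else {
        sdt <- sqrt(dt)
        cross_minus_inc <- function(bb) {
          thr <- bb * sqrt(looks[j])
          tails <- stats::pnorm((-thr - grid) / sdt) +
            stats::pnorm((grid - thr) / sdt)
          trap_sum(dens * tails, h) - inc
        }
        b[j] <- stats::uniroot(cross_minus_inc, interval = c(1e-3, zmax),
                               extendInt = "downX", tol = 1e-6)$root
      }
    }
    # propagate the sub-density to the surviving region at look j
    thr <- min(b[j], zmax) * sqrt(looks[j])
    newgrid <- seq(-thr, thr, length.out = ngrid)
    hh <- newgrid[2L] - newgrid[1L]
    if (j == 1L) {
      newdens <- stats::dnorm(newgrid, 0, sqrt(looks[1L]))
    } else {
      dt <- looks[j] - looks[j - 1L]
      sdt <- sqrt(dt)
      kern <- outer(newgrid, grid, function(a, b2) stats::dnorm(a - b2, 0, sdt))
      newdens <- as.numeric(kern %*% (dens * trap_weights(length(grid), h)))
    }
    grid <- newgrid; dens <- newdens; h <- hh
  }

  structure(list(looks = looks, alpha_spent = f, boundaries = b,
                 crossed_at = NA_integer_, spending = design$spending,
                 alpha = alpha),
            class = "boundary_schedule")
}

trap_weights <- function(n, h) {
  w <- rep(h, n)
  w[c(1L, n)] <- h / 2
  w
}

trap_sum <- function(v, h) {
  n <- length(v)
  h * (sum(v) - (v[1L] + v[n]) / 2)
}

#' Sequentially monitor a trial sequence
#'
#' Runs the cumulative fixed-effect meta-analysis over the trials in
#' publication order, places a look at each trial's publication (at the
#' observed cumulative information fraction, capped at 1), computes the
#' error-spending boundaries at those looks, and finds the first look at
#' which the cumulative z-statistic crosses the boundary in absolute value
#' (the "final timepoint"). Participants randomized in trials published
#' after the final timepoint are counted as unnecessary.
#'
#' Looks that fall at or beyond the required information size are capped at
#' fraction 1, where all remaining alpha is spent; any further looks reuse
#' the boundary of the first full-information look.
#'
#' @param trials a [trial_set].
#' @param design a [sequential_design].
#' @param ngrid quadrature nodes per look, see [compute_boundaries()].
#' @return an object of class `sequential_monitor`: a per-look table
#'   (`upto_order`, `trial_id`, `cumulative_n`, `information_fraction`,
#'   `boundary`, `z`, `crossed`), the `boundary_schedule`, the required
#'   information size `ris`, `final_timepoint` (first crossing look, `NA`
#'   if never crossed), and `unnecessary_total` / `unnecessary_sham`.
#' @examples
#' monitor(rdn_trials(), sequential_design(delta_plan = -2, sd_plan = 10))
#' @export
monitor <- function(trials, design, ngrid = 512) {
  trials <- trial_set(trials)
  stopifnot(inherits(design, "sequential_design"))
  cm <- cumulative_meta(trials)
  ris <- required_information_size(design)
  info <- if (design$information_metric == "participants") {
    cm$cumulative_n
  } else {
    1 / cm$se_pooled^2
  }
  t_obs <- pmin(info / ris, 1)

  # strictly increasing looks for the boundary recursion: keep the first
  # look that reaches full information, later looks reuse its boundary
  keep <- !duplicated(t_obs)
  sched <- compute_boundaries(design, t_obs[keep], ngrid = ngrid)
  boundaries <- sched$boundaries[cumsum(keep)]

  crossed <- abs(cm$z) >= boundaries
  final <- if (any(crossed)) which(crossed)[1L] else NA_integer_
  sched$crossed_at <- final

  after <- if (is.na(final)) logical(nrow(trials)) else trials$order > final
  table <- data.frame(
    upto_order = cm$upto_order,
    trial_id = cm$trial_id,
    cumulative_n = cm$cumulative_n,
    information_fraction = t_obs,
    boundary = boundaries,
    z = cm$z,
    crossed = crossed,
    stringsAsFactors = FALSE
  )
  structure(list(
    table = table, schedule = sched, ris = ris,
    final_timepoint = final,
    unnecessary_total = sum(trials$n_active[after] + trials$n_sham[after]),
    unnecessary_sham = sum(trials$n_sham[after]),
    design = design
  ), class = "sequential_monitor")
}

#' @export
print.boundary_schedule <- function(x, ...) {
  cat(sprintf("Error-spending boundary schedule (%s, alpha = %g)\n",
              x$spending, x$alpha))
  print(data.frame(t = x$looks, alpha_spent = x$alpha_spent,
                   boundary = x$boundaries), ...)
  invisible(x)
}

#' @export
print.sequential_monitor <- function(x, ...) {
  cat(sprintf("Sequential monitoring (%s spending, RIS = %s)\n",
              x$design$spending, format(x$ris)))
  print(x$table, ...)
  if (is.na(x$final_timepoint)) {
    cat("No boundary crossing; all trials contribute to the evidence.\n")
  } else {
    cat(sprintf(
      "Final timepoint: look %d; %d participants randomized afterwards (%d sham) were unnecessary.\n",
      x$final_timepoint, x$unnecessary_total, x$unnecessary_sham))
  }
  invisible(x)
}
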