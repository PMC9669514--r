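# shared test fixtures and independent oracles

# a minimal valid trial-set data frame, convenient to perturb in tests
make_trial_df <- function(md, se, n_active = 40, n_sham = 40) {
  k <- length(md)
  data.frame(
    trial_id = sprintf("t%02d", seq_len(k)),
    label = sprintf("Trial %d", seq_len(k)),
    order = seq_len(k),
    year = 2000L + seq_len(k),
    n_active = rep_len(n_active, k),
    n_sham = rep_len(n_sham, k),
    md = md,
    se_md = se,
    planned_n_active = NA_integer_,
    planned_n_sham = NA_integer_,
    planned_power = NA_real_,
    anticipated_delta = NA_real_,
    anticipated_sd = NA_real_,
    allocation_ratio = 1,
    prospectively_powered = FALSE,
    stringsAsFactors = FALSE
  )
}

random_trial_df <- function(k, seed) {
  set.seed(seed)
  make_trial_df(md = rnorm(k, -2, 3), se = runif(k, 0.5, 4))
}

# independent inverse-variance pooling oracle: weighted mean via a
# different code path (base weighted.mean on long doubles of w)
oracle_pool <- function(md, se) {
  w <- 1 / se^2
  list(pooled = stats::weighted.mean(md, w), se = sqrt(1 / sum(w)))
}

# brute-force grid search for the smallest per-arm n whose exact t power
# reaches the target (independent of the package's search code)
oracle_min_n_t <- function(delta, sd, power = 0.8, alpha = 0.05,
                           n_max = 2000) {
  for (n in 2:n_max) {
    ncp <- abs(delta) / (sd * sqrt(2 / n))
    q <- qt(1 - alpha / 2, 2 * n - 2)
    pw <- 1 - pt(q, 2 * n - 2, ncp = ncp) + pt(-q, 2 * n - 2, ncp = ncp)
    if (pw >= power) return(n)
  }
  NA_integer_
}
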