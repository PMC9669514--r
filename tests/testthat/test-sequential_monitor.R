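test_that("required information size follows the fixed-sample closed form", {
  d <- sequential_design(delta_plan = 10, sd_plan = 10)
  expect_equal(required_information_size(d), 43L)  # 4*100*10.507/100 -> 42.03
  # doubling the SD quadruples the requirement (up to integer ceiling)
  d2 <- sequential_design(delta_plan = 10, sd_plan = 20)
  expect_equal(required_information_size(d2),
               as.integer(ceiling(4 * 400 * (qnorm(.975) + qnorm(.9))^2 / 100)))
  expect_gte(required_information_size(d2), 4L * required_information_size(d) - 4L)
  # higher power costs more information
  d80 <- sequential_design(delta_plan = 10, sd_plan = 10, power = 0.80)
  expect_lt(required_information_size(d80), required_information_size(d))
  # statistical-information variant
  ds <- sequential_design(delta_plan = 10, sd_plan = 10,
                          information_metric = "statistical_information")
  expect_equal(required_information_size(ds),
               (qnorm(.975) + qnorm(.9))^2 / 100, tolerance = 1e-12)
  expect_error(sequential_design(delta_plan = 0, sd_plan = 10), "nonzero")
})

test_that("spending functions satisfy their boundary conditions", {
  expect_equal(spending_value("obrien_fleming_type", 1, 0.05), 0.05,
               tolerance = 1e-12)
  expect_equal(spending_value("pocock_type", 1, 0.05), 0.05,
               tolerance = 1e-12)
  # high-precision check of the O'Brien-Fleming-type value at half information
  expect_equal(spending_value("obrien_fleming_type", 0.5, 0.05),
               2 - 2 * pnorm(qnorm(0.975) / sqrt(0.5)), tolerance = 1e-14)
  expect_equal(spending_value("obrien_fleming_type", 0.5, 0.05),
               0.00558, tolerance = 2e-3)
  ts <- seq(0.2, 1, by = 0.05)
  for (fam in c("obrien_fleming_type", "pocock_type")) {
    f <- spending_value(fam, ts, 0.05)
    expect_true(all(diff(f) > 0))
    expect_true(all(f > 0 & f <= 0.05 + 1e-12))
  }
  expect_lt(spending_value("obrien_fleming_type", 1e-4, 0.05), 1e-8)
  expect_error(spending_value("obrien_fleming_type", 0, 0.05), "fraction")
})

test_that("a single look at full information reduces to the fixed-sample test", {
  d <- sequential_design(delta_plan = -2, sd_plan = 10)
  sched <- compute_boundaries(d, looks = 1)
  expect_equal(sched$boundaries, qnorm(0.975), tolerance = 1e-9)
})

test_that("two-look boundaries match the closed form and a Monte-Carlo oracle", {
  d <- sequential_design(delta_plan = -2, sd_plan = 10)
  sched <- compute_boundaries(d, looks = c(0.5, 1))
  f1 <- spending_value("obrien_fleming_type", 0.5, 0.05)
  expect_equal(sched$boundaries[1], qnorm(1 - f1 / 2), tolerance = 1e-6)
  expect_equal(round(sched$boundaries[1], 4), 2.7718)
  # Monte-Carlo oracle over the correlated sequential z-statistics
  nrep <- 1e6
  set.seed(2024)
  s1 <- rnorm(nrep, 0, sqrt(0.5))
  s2 <- s1 + rnorm(nrep, 0, sqrt(0.5))
  cross1 <- abs(s1 / sqrt(0.5)) >= sched$boundaries[1]
  cross2 <- !cross1 & abs(s2) >= sched$boundaries[2]
  p1 <- mean(cross1); p2 <- mean(cross2); ptot <- mean(cross1 | cross2)
  se1 <- sqrt(p1 * (1 - p1) / nrep)
  se2 <- sqrt(p2 * (1 - p2) / nrep)
  setot <- sqrt(ptot * (1 - ptot) / nrep)
  expect_lt(abs(p1 - f1), 3 * se1)
  expect_lt(abs(p2 - (0.05 - f1)), 3 * se2)
  expect_lt(abs(ptot - 0.05), 3 * setot)
  expect_error(compute_boundaries(d, looks = c(0.7, 0.3)), "increasing")
})

test_that("multi-look boundaries reproduce the spending increments by Monte Carlo", {
  looks <- c(0.3, 0.55, 0.8, 1)
  nrep <- 5e5
  for (fam in c("obrien_fleming_type", "pocock_type")) {
    d <- sequential_design(delta_plan = -2, sd_plan = 10, spending = fam)
    sched <- compute_boundaries(d, looks)
    expect_true(all(is.finite(sched$boundaries)))
    if (fam == "obrien_fleming_type")
      expect_true(all(diff(sched$boundaries) < 0))
    set.seed(7)
    inc <- sapply(diff(c(0, looks)), function(dt) rnorm(nrep, 0, sqrt(dt)))
    s <- t(apply(inc, 1, cumsum))
    z <- sweep(s, 2, sqrt(looks), `/`)
    alive <- rep(TRUE, nrep)
    finc <- diff(c(0, sched$alpha_spent))
    for (j in seq_along(looks)) {
      hit <- alive & abs(z[, j]) >= sched$boundaries[j]
      p <- mean(hit)
      se <- sqrt(max(p * (1 - p), 1e-12) / nrep)
      expect_lt(abs(p - finc[j]), 3 * se + 1e-5)
      alive <- alive & !hit
    }
    expect_lt(abs(mean(!alive) - 0.05), 3 * sqrt(0.05 * 0.95 / nrep))
  }
})

test_that("monitoring the shipped trials finds the fourth study decisive", {
  rdn <- rdn_trials()
  # conventional fixed-sample rule at every look
  conv <- monitor(rdn, sequential_design(delta_plan = -2, sd_plan = 10,
                                         spending = "none"))
  expect_equal(round(conv$table$z, 2),
               c(-1.27, -1.80, -1.79, -2.49, -3.39, -3.38))
  expect_equal(conv$final_timepoint, 4L)
  expect_equal(conv$table$cumulative_n[conv$final_timepoint], 755L)
  # error-spending monitoring under the package's documented design anchor
  mon <- monitor(rdn, sequential_design(delta_plan = -2, sd_plan = 10))
  expect_equal(mon$final_timepoint, 4L)
  expect_equal(mon$unnecessary_total, 226L)
  expect_equal(mon$unnecessary_sham, 114L)
  expect_true(all(diff(mon$table$boundary) < 0))
  expect_false(any(mon$table$crossed[1:3]))
})

test_that("an uncrossable design yields no final timepoint", {
  rdn <- rdn_trials()
  # tiny planning effect: information fraction stays minute, boundaries huge
  d <- sequential_design(delta_plan = -0.05, sd_plan = 10)
  mon <- monitor(rdn, d)
  expect_true(is.na(mon$final_timepoint))
  expect_equal(mon$unnecessary_total, 0L)
  expect_equal(mon$unnecessary_sham, 0L)
})

test_that("looks beyond the required information are capped at one", {
  df <- make_trial_df(md = c(-8, -8, -8), se = c(1, 1, 1),
                      n_active = 200, n_sham = 200)
  d <- sequential_design(delta_plan = -10, sd_plan = 10)  # RIS = 43
  mon <- monitor(trial_set(df), d)
  expect_true(all(mon$table$information_fraction == 1))
  expect_equal(mon$final_timepoint, 1L)
})
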