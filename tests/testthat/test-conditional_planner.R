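test_that("with no prior evidence conditional power is stand-alone power", {
  assume <- plan_assumptions(sd_new = 10, theta_assumed = -6)
  for (n in c(20, 50, 100)) {
    cp <- conditional_power(NULL, n, assume)
    sp <- power_spec(delta = -6, sd = 10, method = "normal")
    expect_equal(cp, power_two_means(n, n, sp), tolerance = 1e-12)
  }
  # and planning reduces to the stand-alone normal sample size
  assume <- plan_assumptions(sd_new = 10, theta_assumed = -10)
  pr <- plan_next_trial(NULL, assume)
  ss <- sample_size_two_means(power_spec(delta = -10, sd = 10,
                                         method = "normal"))
  expect_equal(pr$n_per_arm, ss$n_control)
})

test_that("planning from the first trial alone crosses 80% power at 325/arm", {
  m1 <- pool_fixed(rdn_trials()[1, ])
  assume <- plan_assumptions(sd_new = 10, theta_assumed = -1.96,
                             conditioning = "unconditional")
  expect_lt(conditional_power(m1, 324, assume), 0.80)
  expect_gte(conditional_power(m1, 325, assume), 0.80)
  pr <- plan_next_trial(m1, assume)
  expect_equal(pr$n_per_arm, 325L)
  expect_false(pr$already_rejected)
  # conditioning on the observed estimate adds deterministic evidence,
  # so power at equal n is strictly larger
  cond <- plan_assumptions(sd_new = 10, theta_assumed = -1.96)
  expect_gt(conditional_power(m1, 325, cond),
            conditional_power(m1, 325, assume))
})

test_that("analytic and simulated conditional power agree within MC error", {
  m1 <- pool_fixed(rdn_trials()[1, ])
  grid <- expand.grid(n = c(50, 200, 325), theta = c(-1, -1.96, -3),
                      conditioning = c("conditional_on_estimate",
                                       "unconditional"),
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    assume <- plan_assumptions(sd_new = 10, theta_assumed = grid$theta[i],
                               conditioning = grid$conditioning[i],
                               mc_reps = 1e5, seed = 1L)
    pa <- conditional_power(m1, grid$n[i], assume)
    ps <- conditional_power(m1, grid$n[i], assume, method = "simulation")
    se <- sqrt(pa * (1 - pa) / assume$mc_reps)
    expect_lt(abs(ps - pa), 3 * se + 1e-12)
  }
  # simulation is reproducible under a fixed seed
  assume <- plan_assumptions(sd_new = 10, theta_assumed = -2, mc_reps = 1e4,
                             seed = 7L)
  expect_identical(conditional_power(m1, 100, assume, method = "simulation"),
                   conditional_power(m1, 100, assume, method = "simulation"))
})

test_that("conditional power grows with n and with the assumed effect", {
  m1 <- pool_fixed(rdn_trials()[1, ])
  for (conditioning in c("conditional_on_estimate", "unconditional")) {
    assume <- plan_assumptions(sd_new = 10, theta_assumed = -2,
                               conditioning = conditioning)
    ns <- c(10, 30, 100, 300, 1000)
    pows <- vapply(ns, function(n) conditional_power(m1, n, assume),
                   numeric(1))
    expect_true(all(diff(pows) > 0))
    pows_theta <- vapply(c(-0.5, -1, -2, -4), function(th) {
      a <- plan_assumptions(sd_new = 10, theta_assumed = th,
                            conditioning = conditioning)
      conditional_power(m1, 200, a)
    }, numeric(1))
    expect_true(all(diff(pows_theta) > 0))
  }
})

test_that("the planner is minimal and flags an already-decisive synthesis", {
  rdn <- rdn_trials()
  m1 <- pool_fixed(rdn[1, ])
  for (theta in c(-1.5, -2.5, -4)) {
    assume <- plan_assumptions(sd_new = 10, theta_assumed = theta)
    pr <- plan_next_trial(m1, assume)
    expect_gte(pr$achieved_power, 0.80)
    expect_lt(conditional_power(m1, pr$n_per_arm - 1L, assume), 0.80)
  }
  # after five trials the cumulative z is about -3.39: nothing more needed
  m5 <- pool_fixed(rdn[1:5, ])
  pr5 <- plan_next_trial(m5, plan_assumptions(sd_new = 10))
  expect_true(pr5$already_rejected)
  expect_equal(pr5$n_per_arm, 0L)
  # unreachable target errors and reports the power at the cap
  weak <- plan_assumptions(sd_new = 10, theta_assumed = -0.01, n_cap = 500)
  expect_error(plan_next_trial(m1, weak), "n_cap")
})

test_that("the prospective walk replays planning over the trial sequence", {
  rdn <- rdn_trials()
  walk <- prospective_walk(rdn, plan_assumptions(sd_new = 10))
  expect_equal(nrow(walk), 6L)
  expect_equal(walk$theta_assumed,
               cumulative_meta(rdn)$pooled_md, tolerance = 1e-12)
  # once the synthesis rejects (after trial 4), planned sizes drop to zero
  expect_false(any(walk$already_rejected[1:3]))
  expect_true(all(walk$already_rejected[4:6]))
  expect_true(all(walk$planned_n_per_arm[4:6] == 0L))
  expect_true(all(walk$planned_n_per_arm[1:3] > 0L))
  # a single-trial set gives one row identical to plan_next_trial
  one <- trial_set(make_trial_df(md = -2, se = 1.5))
  w1 <- prospective_walk(one, plan_assumptions(sd_new = 10))
  a1 <- plan_assumptions(sd_new = 10, theta_assumed = -2)
  expect_equal(nrow(w1), 1L)
  expect_equal(w1$planned_n_per_arm, plan_next_trial(pool_fixed(one),
                                                     a1)$n_per_arm)
})

test_that("recalculating with the meta-analytic effect matches hand results", {
  rdn <- rdn_trials()
  tab <- recalc_with_meta_effect(rdn)
  expect_equal(tab$trial_id, c("desch_2015", "reset", "radiance_solo"))
  # independent oracle on the pooled effects of the preceding trials
  cm <- cumulative_meta(rdn)$pooled_md
  expect_equal(tab$recalc_n_sham[1], oracle_min_n_t(abs(cm[1]), 8))   # 263
  expect_equal(tab$recalc_n_sham[2], oracle_min_n_t(abs(cm[2]), 13))
  expect_equal(tab$recalc_n_sham[3], oracle_min_n_t(abs(cm[5]), 12))  # 190
  expect_equal(tab$recalc_n_sham[1], 263L)
  expect_equal(tab$recalc_n_sham[3], 190L)
})

test_that("a sequential rejection rule uses the boundary as critical value", {
  d <- sequential_design(delta_plan = -2, sd_plan = 10)
  sched <- compute_boundaries(d, looks = c(0.5, 1))
  m1 <- pool_fixed(rdn_trials()[1, ])
  fixed <- plan_assumptions(sd_new = 10, theta_assumed = -2)
  seqr <- plan_assumptions(sd_new = 10, theta_assumed = -2,
                           rejection_rule = "sequential_boundary",
                           boundary = sched)
  # the early boundary is stricter than 1.96, so more patients are needed
  expect_gt(plan_next_trial(m1, seqr)$n_per_arm,
            plan_next_trial(m1, fixed)$n_per_arm)
  expect_error(plan_assumptions(sd_new = 10,
                                rejection_rule = "sequential_boundary"),
               "boundary_schedule")
})
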