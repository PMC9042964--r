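test_that("fracture rates follow the doubling-time definition and are monotone", {
  spec <- synthetic_epi_spec(
    base_rate_at_50 = c(hip = 5, vertebral = 5, other = 5),
    age_doubling_time = c(hip = 10, vertebral = 10, other = 10)
  )
  epi <- make_epi_tables(spec)
  fi <- epi$fracture_incidence
  expect_equal(fi$hip[fi$age == 60], 10 / 1000)        # one doubling
  expect_equal(fi$hip[fi$age == 70], 20 / 1000)        # two doublings
  expect_true(all(diff(fi$hip) > 0))
  expect_equal(range(fi$age), c(50, 100))
})

test_that("generation is deterministic: same spec gives identical tables", {
  a <- make_epi_tables(synthetic_epi_spec(seed = 3))
  b <- make_epi_tables(synthetic_epi_spec(seed = 3))
  expect_identical(a, b)
})

test_that("Gompertz mortality is monotone in age and matches the formula", {
  spec <- synthetic_epi_spec(gompertz = list(level = 0.002, slope = 0.09))
  epi <- make_epi_tables(spec)
  qx <- epi$mortality$qx
  expect_true(all(diff(qx) > 0))
  # independent evaluation of the Gompertz annual death probability
  ages <- epi$mortality$age
  expect_equal(qx, 1 - exp(-0.002 * exp(0.09 * (ages - 50))), tolerance = 1e-12)
  expect_true(all(qx >= 0 & qx <= 1))
})

test_that("simulated exponential event times match the closed-form event fraction", {
  spec <- synthetic_trial_spec(
    n_per_arm = 10000, follow_up = 4,
    hazard_model = list(a = list(hip = list(shape = 1, scale = 10)),
                        b = list(hip = list(shape = 1, scale = 10))),
    censoring_rate = 0, seed = 11
  )
  rec <- simulate_trial(spec)
  one_arm <- rec[rec$arm == "a", ]
  p_true <- 1 - exp(-0.1)           # P(event within 1 year), rate = 1/scale
  p_hat <- mean(one_arm$time_years <= 1 & one_arm$event == 1)
  se <- sqrt(p_true * (1 - p_true) / nrow(one_arm))
  expect_lt(abs(p_hat - p_true), 3 * se)
})

test_that("zero censoring leaves only events and administrative censoring", {
  spec <- synthetic_trial_spec(n_per_arm = 500, censoring_rate = 0, seed = 2)
  rec <- simulate_trial(spec)
  censored <- rec[rec$event == 0, ]
  expect_true(all(censored$time_years == spec$follow_up))
  expect_true(all(rec$time_years <= spec$follow_up))
})

test_that("identical hazards in both arms give per-cycle RR near 1", {
  spec <- synthetic_trial_spec(
    n_per_arm = 20000, follow_up = 4,
    hazard_model = list(active = list(hip = list(shape = 1, scale = 12)),
                        comparator = list(hip = list(shape = 1, scale = 12))),
    censoring_rate = 0, seed = 5
  )
  rec <- simulate_trial(spec)
  fa <- fit_survival(rec, "hip", "active", "exponential")
  fc <- fit_survival(rec, "hip", "comparator", "exponential")
  expect_equal(cycle_rr(fa, fc, 1), 1, tolerance = 0.05)
})

test_that("Kaplan-Meier estimate converges to the generating survival", {
  spec <- synthetic_trial_spec(
    n_per_arm = 50000, follow_up = 4,
    hazard_model = list(a = list(hip = list(shape = 1.3, scale = 8))),
    censoring_rate = 0.05, seed = 21
  )
  rec <- simulate_trial(spec)
  km <- survival::survfit(survival::Surv(time_years, event) ~ 1, data = rec)
  grid <- seq(0.1, 3.9, by = 0.1)
  km_s <- summary(km, times = grid)$surv
  true_s <- pweibull(grid, 1.3, 8, lower.tail = FALSE)
  expect_lt(max(abs(km_s - true_s)), 0.02)
})

test_that("trial records carry their generating parameters", {
  spec <- synthetic_trial_spec(n_per_arm = 10, seed = 1)
  rec <- simulate_trial(spec)
  expect_identical(attr(rec, "generating_params"), spec$hazard_model)
  expect_named(rec, c("subject_id", "arm", "endpoint", "time_years", "event"))
})

test_that("reference fixture embeds the published parameter values", {
  cfg <- ref_config()
  # per-cycle RR of the sequence vs the oral comparator, cycle 3
  vs_active <- cfg$regimens$romo_aln$rr_vs_active
  expect_equal(vs_active$hip[vs_active$cycle == 3], 0.56)
  expect_equal(vs_active$vertebral[vs_active$cycle == 3], 0.38)
  # utility age 70-74
  ut <- cfg$epi$utilities
  expect_equal(ut$utility[ut$age_min == 70], 0.831)
  # first-year hip fracture cost, 70-79
  fy <- cfg$costs$first_year
  expect_equal(fy$cost[fy$fracture_type == "hip" & fy$age_min == 70], 27512)
  # annual drug costs and monitoring sums
  comp <- cfg$regimens$romo_aln$components
  expect_equal(comp$annual_drug_cost, c(7881, 109))
  expect_equal(comp$annual_monitoring_cost, c(310, 119))
  expect_equal(cfg$costs$ltc_entry_prob_after_hip, 0.37)
  expect_equal(cfg$costs$ltc_daily_cost, 184.96)
  expect_true(cfg$epi$stand_in)
})
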