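# Oracles: the exponential MLE has the closed form events/exposure; Weibull
# recovery is checked against the generating parameters of synthetic data.

test_that("exponential fit matches the closed-form MLE (events/exposure)", {
  spec <- synthetic_trial_spec(
    n_per_arm = 20000, follow_up = 4,
    hazard_model = list(a = list(hip = list(shape = 1, scale = 10))),
    censoring_rate = 0.02, seed = 13
  )
  rec <- simulate_trial(spec)
  fit <- fit_survival(rec, "hip", "a", "exponential")
  d <- sum(rec$event)
  rate_mle <- d / sum(rec$time_years)     # independent closed form
  expect_equal(unname(fit$pars[["rate"]]), rate_mle, tolerance = 1e-4)
  # and the MLE is within 3 SE of the generating rate 0.1
  expect_lt(abs(rate_mle - 0.1), 3 * 0.1 / sqrt(d))
})

test_that("Weibull fit recovers generating shape and scale within 2%", {
  spec <- synthetic_trial_spec(
    n_per_arm = 50000, follow_up = 6,
    hazard_model = list(a = list(hip = list(shape = 1.4, scale = 7))),
    censoring_rate = 0, seed = 17
  )
  rec <- simulate_trial(spec)
  fit <- fit_survival(rec, "hip", "a", "weibull")
  expect_equal(unname(fit$pars[["shape"]]), 1.4, tolerance = 0.02)
  expect_equal(unname(fit$pars[["scale"]]), 7, tolerance = 0.02)
})

test_that("information criteria are consistent with the log-likelihood", {
  spec <- synthetic_trial_spec(n_per_arm = 500, seed = 3)
  rec <- simulate_trial(spec)
  fit <- fit_survival(rec, "hip", "active", "weibull")
  expect_equal(fit$aic, 2 * fit$n_params - 2 * fit$log_likelihood)
  expect_equal(fit$bic, fit$n_params * log(fit$n) - 2 * fit$log_likelihood)
  # worked arithmetic: k = 2, lnL = -100 gives AIC 204
  expect_equal(2 * 2 - 2 * (-100), 204)
})

test_that("fitting requires events and distinct event times", {
  rec <- tibble::tibble(arm = "a", endpoint = "hip",
                        time_years = c(1, 2, 3), event = c(0, 0, 0))
  expect_error(fit_survival(rec, "hip", "a", "exponential"), "event times")
})

test_that("family selection minimizes the criterion with deterministic ties", {
  stub <- function(fam, aic, bic, k) {
    structure(list(family = fam, aic = aic, bic = bic, n_params = k),
              class = "osteo_survfit")
  }
  fits <- list(stub("weibull", 204, 210, 2), stub("gompertz", 210, 214, 2),
               stub("gengamma", 230, 240, 3))
  expect_equal(select_family(fits, "AIC")$family, "weibull")
  expect_equal(select_family(fits, "second-AIC")$family, "gompertz")
  # tie: prefer fewer parameters, then name
  tied <- list(stub("weibull", 204, 208, 2), stub("exponential", 204, 206, 1))
  expect_equal(select_family(tied, "AIC")$family, "exponential")
  tied2 <- list(stub("lognormal", 204, 208, 2), stub("loglogistic", 204, 208, 2))
  expect_equal(select_family(tied2, "AIC")$family, "loglogistic")
  expect_equal(select_family(fits, "BIC")$family, "weibull")
  expect_error(select_family(list()), "empty")
})

test_that("cycle incidence matches the exponential closed form and memorylessness", {
  fit <- list(family = "exponential", pars = c(rate = 0.1))
  expect_equal(cycle_incidence(fit, 1), 1 - exp(-0.05), tolerance = 1e-12)
  # identical across cycles iff exponential
  expect_equal(cycle_incidence(fit, 7), cycle_incidence(fit, 1), tolerance = 1e-12)
  wb <- list(family = "weibull", pars = c(shape = 1.5, scale = 10))
  expect_gt(cycle_incidence(wb, 7), cycle_incidence(wb, 1))
  zero <- list(family = "exponential", pars = c(rate = 0))
  expect_equal(cycle_incidence(zero, 1), 0)
})

test_that("cycle RR is the incidence ratio, 1 for identical fits, monotone for
           monotone-hazard vs constant-hazard arms", {
  f1 <- list(family = "exponential", pars = c(rate = 0.1))
  expect_equal(cycle_rr(f1, f1, 1:10), rep(1, 10))
  wb <- list(family = "weibull", pars = c(shape = 1.5, scale = 10))
  rr <- cycle_rr(wb, f1, 1:10)
  expect_true(all(diff(rr) > 0))
  expect_equal(rr[1], cycle_incidence(wb, 1) / cycle_incidence(f1, 1))
})

test_that("composition with the comparator's RR vs placebo is a per-cycle product", {
  sched <- reference_rr_vs_active()
  out <- compose_vs_placebo(sched, c(hip = 0.61, vertebral = 0.57, other = 0.84))
  expect_equal(out$hip[1], 0.89 * 0.61)         # 0.5429
  expect_equal(out$vertebral[3], 0.38 * 0.57)   # 0.2166
  # identity schedule returns the comparator's constant schedule
  ident <- sched
  for (ty in c("hip", "vertebral", "other")) ident[[ty]] <- rep(1, 10)
  out2 <- compose_vs_placebo(ident, c(hip = 0.61, vertebral = 0.57, other = 0.84))
  expect_equal(out2$hip, rep(0.61, 10))
  # order independence (scalar products commute)
  a <- compose_vs_placebo(compose_vs_placebo(sched, c(hip = 0.5, vertebral = 0.5, other = 0.5)),
                          c(hip = 0.8, vertebral = 0.8, other = 0.8))
  b <- compose_vs_placebo(compose_vs_placebo(sched, c(hip = 0.8, vertebral = 0.8, other = 0.8)),
                          c(hip = 0.5, vertebral = 0.5, other = 0.5))
  expect_equal(a, b)
  expect_error(compose_vs_placebo(sched, c(hip = -1, vertebral = 0.5, other = 0.5)),
               "> 0")
})

test_that("offset RR hits its boundary identities and is continuous monotone", {
  expect_equal(offset_rr(0.6, 0, 5), 0.6)
  expect_equal(offset_rr(0.6, 5, 5), 1.0)
  expect_equal(offset_rr(0.6, 2.5, 5), 0.8)      # linear midpoint
  expect_equal(offset_rr(0.6, 7, 5), 1.0)        # clamped after the offset
  t <- seq(0, 6, by = 0.01)
  rr <- offset_rr(0.6, t, 5)
  expect_true(all(diff(rr) >= 0))
  expect_lt(max(abs(diff(rr))), 0.01)            # no jumps
  expect_error(offset_rr(0.6, 1, 0), "offset_duration")
  expect_error(offset_rr(0.6, -1, 5), "t_since_stop")
})

test_that("derived schedules select per arm separately and cover all cycles", {
  rec <- simulate_trial(synthetic_trial_spec(n_per_arm = 3000, seed = 9))
  d <- suppressWarnings(derive_rr_schedule(rec))
  expect_named(d$schedule, c("cycle", "hip", "other"))
  expect_equal(nrow(d$schedule), 10)
  expect_true(all(d$schedule$hip > 0))
  expect_named(d$fits$hip, c("active", "comparator"))
})
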