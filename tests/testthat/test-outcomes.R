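# a minimal hand-built trace: everyone in one state for one or two cycles
mini_trace <- function(state, ages, occupancy = 1000) {
  ss <- state_space(8)
  t_n <- length(ages)
  occ <- matrix(0, t_n, ss$n, dimnames = list(NULL, ss$states$name))
  occ[, which(ss$states$name == state)] <- occupancy
  structure(
    list(occupancy = occ, ages = ages,
         events = matrix(0, t_n, 3, dimnames = list(NULL, c("hip", "vertebral", "other"))),
         events_corrected = matrix(0, t_n, 2,
                                   dimnames = list(NULL, c("vertebral", "other"))),
         state_space = ss, regimen = "test", cohort = 1000,
         final = occ[t_n, ]),
    class = "osteo_trace"
  )
}

test_that("discount factor follows (1+r)^-t", {
  expect_equal(discount_factor(0.015, 0), 1)
  expect_equal(discount_factor(0, c(1, 5, 50)), rep(1, 3))
  expect_equal(discount_factor(0.015, 10), 1.015^-10)
  expect_equal(discount_factor(0.015, 10), 0.86167, tolerance = 1e-5)
  expect_error(discount_factor(-0.01, 1), "rate")
  expect_error(discount_factor(0.01, -1), "t must")
})

test_that("a cycle of first-year hip state at age 72 accrues the published product", {
  cfg <- ref_config()
  tr <- mini_trace("hip_a1", ages = 72)
  q <- accrue_qalys(tr, cfg)
  # 1000 persons x utility 0.831 (70-74) x multiplier 0.55 x half-year
  expect_equal(q$qalys[1], 1000 * 0.831 * 0.55 * 0.5)
  expect_equal(q$life_years[1], 500)
})

test_that("QALYs equal life-years when utilities and multipliers are 1", {
  cfg <- ref_config()
  cfg$epi$utilities$utility <- 1
  cfg$utility_mult <- utility_multipliers(
    first_year = c(hip = 1, vertebral = 1, other = 1),
    subsequent_years = c(hip = 1, vertebral = 1))
  acc <- accrue_outcomes(cfg, "alendronate")
  expect_equal(acc$totals$qalys, acc$totals$life_years, tolerance = 1e-12)
  expect_equal(acc$qaly_stream$qalys, acc$qaly_stream$life_years, tolerance = 1e-12)
})

test_that("QALYs never exceed life-years under multiplicative disutilities", {
  for (acc in ref_accruals()) {
    expect_lte(acc$totals$qalys, acc$totals$life_years)
    expect_true(all(acc$qaly_stream$qalys <= acc$qaly_stream$life_years + 1e-12))
  }
})

test_that("an empty cohort accrues nothing", {
  cfg <- ref_config()
  tr <- mini_trace("dead", ages = c(80, 80.5))
  q <- accrue_qalys(tr, cfg)
  expect_equal(q$qalys, c(0, 0))
  cc <- accrue_costs(tr, cfg, "alendronate")
  expect_equal(cc$total_cost, c(0, 0))
})

test_that("a person-year in the post-hip state costs the published subsequent-year
           amount plus expected long-term-care use", {
  cfg <- ref_config()
  tr <- mini_trace("hip_p3", ages = c(80, 80.5))
  cc <- accrue_costs(tr, cfg, "alendronate")
  # subsequent-year medical cost: $5171 per person-year
  expect_equal(sum(cc$subsequent_fracture_cost), 1000 * 5171)
  # LTC side-stream: 37% of hip-branch occupancy at $184.96/day
  expect_equal(sum(cc$ltc_cost), 0.37 * 1000 * 184.96 * 365.25, tolerance = 1e-9)
  # no drug/monitoring after the treatment window in this synthetic trace:
  # cycles here are 1-2, so treatment costs do accrue to alive persons
  expect_equal(cc$drug_cost[1], 1000 * 109 * 0.5)
})

test_that("drug costs follow the component schedule for the sequence regimen", {
  cfg <- ref_config()
  acc <- accrue_outcomes(cfg, "romo_aln")
  cc <- acc$cost_stream
  alive <- rowSums(acc$trace$occupancy[, acc$trace$state_space$alive, drop = FALSE])
  # romosozumab year: $7881/yr; alendronate years 2-5: $109/yr
  expect_equal(cc$drug_cost[1:2], alive[1:2] * 7881 * 0.5)
  expect_equal(cc$drug_cost[3:10], alive[3:10] * 109 * 0.5)
  expect_equal(cc$drug_cost[11:15], rep(0, 5))
  expect_equal(cc$monitoring_cost[1:2], alive[1:2] * 310 * 0.5)
  expect_equal(cc$monitoring_cost[3:10], alive[3:10] * 119 * 0.5)
})

test_that("zero discount makes discounted equal undiscounted; zero costs zero out", {
  cfg <- ref_config()
  cfg$econ$discount_rate_costs <- 0
  cfg$econ$discount_rate_qalys <- 0
  acc <- accrue_outcomes(cfg, "alendronate")
  expect_equal(acc$totals$cost, acc$totals$cost_undisc, tolerance = 1e-12)
  expect_equal(acc$totals$qalys, acc$totals$qalys_undisc, tolerance = 1e-12)

  cfg0 <- ref_config()
  cfg0$costs$first_year$cost <- 0
  cfg0$costs$subsequent_year[] <- 0
  cfg0$costs$ltc_daily_cost <- 0
  for (nm in names(cfg0$regimens)) {
    cfg0$regimens[[nm]]$components$annual_drug_cost[] <- 0
    cfg0$regimens[[nm]]$components$annual_monitoring_cost[] <- 0
  }
  acc0 <- accrue_outcomes(cfg0, "alendronate")
  expect_equal(acc0$totals$cost, 0)
})

test_that("discounting never increases any component", {
  for (acc in ref_accruals()) {
    cc <- acc$cost_stream
    for (col in c("drug_cost", "monitoring_cost", "first_year_fracture_cost",
                  "subsequent_fracture_cost", "ltc_cost", "total_cost")) {
      expect_true(all(cc[[paste0(col, "_disc")]] <= cc[[col]] + 1e-12))
    }
  }
})

test_that("societal perspective adds productivity and out-of-pocket costs", {
  cfg <- ref_config()
  acc_p <- accrue_outcomes(cfg, "romo_aln")
  cfg$econ$perspective <- "societal"
  acc_s <- accrue_outcomes(cfg, "romo_aln")
  expect_equal(sum(acc_p$cost_stream$societal_cost), 0)
  expect_gt(sum(acc_s$cost_stream$societal_cost), 0)
  expect_gt(acc_s$totals$cost, acc_p$totals$cost)
})

test_that("comparison labels dominance and computes ICUR and NMB", {
  mk <- function(regimen, cost, qalys) {
    tibble::tibble(regimen = regimen, cost = cost, qalys = qalys)
  }
  totals <- dplyr::bind_rows(mk("a", 10000, 8.0), mk("b", 10343, 7.897),
                             mk("c", 11000, 8.1))
  cea <- compare_regimens(totals, wtp = 50000)
  cmp <- tidy(cea)
  # a vs b: cost -343, qalys +0.103 -> dominant, NMB = 50000*.103 + 343
  ab <- cmp[cmp$regimen == "a", ]
  expect_equal(ab$d_cost, -343)
  expect_equal(ab$d_qalys, 0.103)
  expect_equal(ab$status, "dominant")
  expect_true(is.na(ab$icur))
  expect_equal(ab$nmb, 50000 * 0.103 + 343)
  # c vs a: +1000 cost, +0.1 qalys -> ICUR 10000
  ca <- cmp[cmp$regimen == "c", ]
  expect_equal(ca$icur, 10000)
  expect_equal(ca$status, "trade-off")
  # input order invariance
  cea2 <- compare_regimens(totals[c(3, 1, 2), ], wtp = 50000)
  expect_equal(tidy(cea2), cmp)
  expect_error(compare_regimens(totals[1, ]), "at least 2")
})

test_that("incremental() reports a named pair directly", {
  res <- ref_accruals()
  inc <- incremental(res, "romo_aln", "alendronate")
  expect_equal(inc$d_cost,
               res[[1]]$totals$cost - res[[2]]$totals$cost)
  expect_error(incremental(res, "nope", "alendronate"), "unknown regimen")
})
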