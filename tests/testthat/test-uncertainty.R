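test_that("lognormal spread from a 95% CI matches the standard formula", {
  sdlog <- osteocea:::sdlog_from_ci(0.42, 0.90)
  expect_equal(sdlog, (log(0.90) - log(0.42)) / (2 * qnorm(0.975)))
  expect_equal(sdlog, 0.1944, tolerance = 1e-3)
  # median of the sampled distribution is the point estimate
  set.seed(1)
  draws <- osteocea:::rlnorm_point(20000, 0.61, sdlog)
  expect_equal(median(draws), 0.61, tolerance = 0.01)
})

test_that("beta and gamma draws are moment-matched to the point estimate", {
  set.seed(2)
  b <- osteocea:::rbeta_point(50000, 0.831, 0.02)
  expect_equal(mean(b), 0.831, tolerance = 0.005)
  expect_equal(sd(b), 0.02, tolerance = 0.05)
  g <- osteocea:::rgamma_point(50000, 5171, 500)
  expect_equal(mean(g), 5171, tolerance = 0.01)
  expect_equal(sd(g), 500, tolerance = 0.05)
})

test_that("zero-variance specification returns the point estimates unchanged", {
  cfg <- degenerate_config()
  set.seed(3)
  draw <- sample_params(cfg)
  expect_equal(draw, cfg, tolerance = 1e-12)
})

test_that("parameter draws are seed-deterministic", {
  cfg <- ref_config()
  set.seed(7); d1 <- sample_params(cfg)
  set.seed(7); d2 <- sample_params(cfg)
  expect_equal(d1, d2, tolerance = 1e-15)
  set.seed(8); d3 <- sample_params(cfg)
  expect_false(isTRUE(all.equal(d1$risk_adj$rr_prior_fracture,
                                d3$risk_adj$rr_prior_fracture)))
})

test_that("sequence schedule draws stay linked to the comparator draw", {
  cfg <- ref_config()
  set.seed(9)
  draw <- sample_params(cfg)
  aln <- unlist(draw$regimens$alendronate$rr_schedule[1, c("hip", "vertebral", "other")])
  romo <- draw$regimens$romo_aln
  expect_equal(romo$rr_schedule$hip, romo$rr_vs_active$hip * aln[["hip"]])
  expect_equal(romo$rr_schedule$vertebral,
               romo$rr_vs_active$vertebral * aln[["vertebral"]])
})

test_that("PSA is reproducible and its CEAC is a partition of unity", {
  cfg <- ref_config()
  p1 <- run_psa(cfg, n = 8, seed = 5)
  p2 <- run_psa(cfg, n = 8, seed = 5)
  expect_identical(p1$iterations, p2$iterations)
  expect_identical(p1$ceac, p2$ceac)
  sums <- p1$ceac |>
    dplyr::group_by(wtp) |>
    dplyr::summarise(p = sum(probability), .groups = "drop")
  expect_equal(sums$p, rep(1, nrow(sums)), tolerance = 1e-12)
  expect_true(all(p1$ceac$probability >= 0 & p1$ceac$probability <= 1))
})

test_that("degenerate distributions give identical iterations and a CEAC of 1
           for the dominant regimen", {
  cfg <- degenerate_config()
  psa <- run_psa(cfg, n = 4, seed = 1)
  per_reg <- split(psa$iterations, psa$iterations$regimen)
  for (d in per_reg) {
    expect_equal(diff(range(d$cost)), 0)
    expect_equal(diff(range(d$qalys)), 0)
  }
  # the sequence dominates at the point estimates: most QALYs, least cost
  best <- psa$means$regimen[which.max(psa$means$qalys)]
  expect_equal(best, "romo_aln")
  romo_ceac <- psa$ceac[psa$ceac$regimen == "romo_aln", ]
  expect_true(all(romo_ceac$probability == 1))
})

test_that("survival-parameter sampling perturbs fit-derived schedules", {
  cfg <- make_reference_fixture(include_trial_data = TRUE,
                                trial_spec = synthetic_trial_spec(n_per_arm = 1500,
                                                                  seed = 2))
  fits <- suppressWarnings(osteocea:::prepare_efficacy_fits(cfg))
  set.seed(11)
  d1 <- suppressWarnings(sample_params(cfg, fits = fits))
  set.seed(12)
  d2 <- suppressWarnings(sample_params(cfg, fits = fits))
  s1 <- d1$regimens$romo_aln$rr_vs_active$hip
  s2 <- d2$regimens$romo_aln$rr_vs_active$hip
  expect_false(isTRUE(all.equal(s1, s2)))
  expect_true(all(s1 > 0) && all(s2 > 0))
})

test_that("DSA base INMB equals the deterministic reference INMB and ranking is
           order-invariant; null parameters give zero-width bars", {
  cfg <- ref_config()
  params <- default_dsa_params(cfg)
  dsa <- run_dsa(cfg, params = params)
  res <- ref_accruals()
  base <- incremental(res, "romo_aln", "alendronate", wtp = 50000)$nmb
  expect_equal(dsa$base_inmb, base, tolerance = 1e-9)
  expect_true(all(dsa$results$base_inmb == dsa$base_inmb))
  # risedronate efficacy cannot move the romo-vs-alendronate INMB
  ris_rows <- dsa$results[grepl("risedronate", dsa$results$parameter), ]
  expect_true(all(ris_rows$extent == 0))
  # extent-sorted output is invariant to input parameter order
  dsa_rev <- run_dsa(cfg, params = rev(params))
  expect_equal(dplyr::arrange(dsa$results, parameter),
               dplyr::arrange(dsa_rev$results, parameter))
})

test_that("scenario runner covers the published scenario set with unique names", {
  scen <- reference_scenarios()
  expect_gte(length(scen), 14)
  expect_false(anyDuplicated(names(scen)) > 0)
  expect_error(run_scenarios(ref_config(), scenarios = "not_a_scenario"),
               "unknown scenario")
})

test_that("no-override scenario equals the reference case and discount-0 makes
           discounting a no-op", {
  cfg <- ref_config()
  out <- run_scenarios(cfg, scenarios = "discount_0", mode = "deterministic")
  res <- tidy(out)
  ref <- res[res$scenario == "reference_case" & res$comparator == "alendronate", ]
  base <- incremental(ref_accruals(), "romo_aln", "alendronate")
  expect_equal(ref$d_cost, base$d_cost, tolerance = 1e-9)
  expect_equal(ref$d_qalys, base$d_qalys, tolerance = 1e-9)
  # discount 0: discounted totals equal undiscounted totals exactly
  cfg0 <- cfg
  cfg0$econ$discount_rate_costs <- 0
  cfg0$econ$discount_rate_qalys <- 0
  acc <- accrue_outcomes(cfg0, "romo_aln")
  expect_equal(acc$totals$cost, acc$totals$cost_undisc)
  expect_equal(acc$totals$qalys, acc$totals$qalys_undisc)
})

test_that("the romosozumab/risedronate sequence scenario composes efficacy as
           specified", {
  cfg <- ref_config()
  mod <- reference_scenarios()$romo_risedronate$modify(cfg)
  expect_true("romo_ris" %in% names(mod$regimens))
  expect_false("romo_aln" %in% names(mod$regimens))
  sched <- mod$regimens$romo_ris$rr_schedule
  vs_active <- cfg$regimens$romo_aln$rr_vs_active
  # cycles 1-2 equivalent to the alendronate sequence
  expect_equal(sched$hip[1:2], vs_active$hip[1:2] * 0.61)
  # cycles 3-10 apply the sequence RRs to risedronate vs placebo
  expect_equal(sched$hip[3:10], vs_active$hip[3:10] * 0.73)
  expect_equal(sched$vertebral[3:10], vs_active$vertebral[3:10] * 0.61)
  # oral component priced as risedronate
  comps <- mod$regimens$romo_ris$components
  expect_equal(comps$annual_drug_cost[comps$drug == "risedronate"], 103)
})
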