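# Model parameters: typed constructors, validation, and config I/O.
#
# Every number the model consumes lives in one `osteo_config` object, so a
# run is fully determined by (config, seed).  Tables are tibbles; scalar
# blocks are named lists.  All monetary values are CAD (2020).

#' Population definition
#'
#' Describes the modelled cohort: postmenopausal women at very high fracture
#' risk (femoral-neck BMD T-score at or below -2.5 with a prior fragility
#' fracture).
#'
#' @param mean_age Cohort age at baseline, years (50--100).
#' @param sex Only `"female"` is supported.
#' @param t_score Femoral-neck BMD T-score (standard deviations); must be
#'   at or below -2.5 for the target population.
#' @param prior_fracture_mix Named numeric, proportions with a
#'   `single` vs `multiple` prior fracture; must sum to 1.
#' @return A list of class `osteo_population`.
#' @export
population_spec <- function(mean_age = 74,
                            sex = "female",
                            t_score = -2.5,
                            prior_fracture_mix = c(single = 0.5, multiple = 0.5)) {
  out <- structure(
    list(mean_age = mean_age, sex = sex, t_score = t_score,
         prior_fracture_mix = prior_fracture_mix),
    class = "osteo_population"
  )
  validate_population(out)
}

validate_population <- function(x) {
  check_range(x$mean_age, 50, 100, "population$mean_age")
  if (!identical(x$sex, "female")) {
    abort("population$sex must be 'female'")
  }
  if (x$t_score > -2.5) {
    abort("population$t_score must be <= -2.5 (very-high-risk definition)")
  }
  mix <- x$prior_fracture_mix
  if (!all(sort(names(mix)) == c("multiple", "single"))) {
    abort("population$prior_fracture_mix needs names 'single' and 'multiple'")
  }
  if (any(mix < 0 | mix > 1) || abs(sum(mix) - 1) > 1e-8) {
    abort("population$prior_fracture_mix proportions must lie in [0,1] and sum to 1")
  }
  x
}

#' Treatment regimen definition
#'
#' A named sequence of drug components with its per-cycle fracture relative
#' risks versus placebo, cost schedule and offset behaviour.
#'
#' @param name Regimen label.
#' @param components Tibble with columns `drug`, `duration_cycles`,
#'   `annual_drug_cost`, `annual_monitoring_cost`.  Components are taken in
#'   order; their durations must sum to `treatment_duration`.
#' @param rr_schedule Tibble with columns `cycle` (1..treatment_duration),
#'   `hip`, `vertebral`, `other`: per-cycle fracture relative risks of the
#'   regimen versus placebo (untreated very-high-risk population).
#' @param treatment_duration Treatment length in cycles (default 10 = 5 years).
#' @param offset_duration Years over which the fracture-reduction benefit
#'   declines linearly to zero after treatment stops (default 5, equal to the
#'   treatment length).
#' @param rr_provenance `"direct-table"` if the schedule was supplied, or
#'   `"derived-from-fits"` if it came from parametric survival fits.
#' @param rr_vs_active Optional tibble in the same layout as `rr_schedule`:
#'   per-cycle RRs of this regimen versus an active comparator (used to
#'   re-compose sequence scenarios); `rr_schedule` remains the versus-placebo
#'   schedule the engine consumes.
#' @return A list of class `osteo_regimen`.
#' @export
regimen_spec <- function(name, components, rr_schedule,
                         treatment_duration = 10L,
                         offset_duration = 5,
                         rr_provenance = c("direct-table", "derived-from-fits"),
                         rr_vs_active = NULL) {
  rr_provenance <- match.arg(rr_provenance)
  components <- tibble::as_tibble(components)
  out <- structure(
    list(name = name,
         components = components,
         rr_schedule = tibble::as_tibble(rr_schedule),
         treatment_duration = as.integer(treatment_duration),
         offset_duration = offset_duration,
         rr_provenance = rr_provenance,
         rr_vs_active = if (!is.null(rr_vs_active)) tibble::as_tibble(rr_vs_active)),
    class = "osteo_regimen"
  )
  validate_regimen(out)
}

validate_regimen <- function(x) {
  need <- c("drug", "duration_cycles", "annual_drug_cost", "annual_monitoring_cost")
  missing_cols <- setdiff(need, names(x$components))
  if (length(missing_cols)) {
    abort(paste0("regimen '", x$name, "': components lack column(s) ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (x$treatment_duration <= 0) {
    abort(paste0("regimen '", x$name, "': treatment_duration must be > 0"))
  }
  if (x$offset_duration <= 0) {
    abort(paste0("regimen '", x$name, "': offset_duration must be > 0"))
  }
  if (sum(x$components$duration_cycles) != x$treatment_duration) {
    abort(paste0("regimen '", x$name,
                 "': component durations must sum to treatment_duration"))
  }
  if (any(x$components$annual_drug_cost < 0) ||
      any(x$components$annual_monitoring_cost < 0)) {
    abort(paste0("regimen '", x$name, "': component costs must be >= 0"))
  }
  validate_rr_schedule(x$rr_schedule, n_cycles = x$treatment_duration)
  x
}

#' Validate a per-cycle relative-risk schedule
#'
#' Checks a 10-cycle-by-3-fracture-type schedule of treatment relative risks
#' versus placebo.  RRs above 1 are legal late in a waning sequence (the
#' non-vertebral risks of a bone-forming sequence can cross 1 once the
#' comparator's effect accumulates) and trigger a warning, not an error.
#'
#' @param schedule Tibble with columns `cycle`, `hip`, `vertebral`, `other`.
#' @param n_cycles Expected number of cycles (default 10).
#' @return The schedule, invisibly checked, as a tibble.
#' @export
validate_rr_schedule <- function(schedule, n_cycles = 10L) {
  schedule <- tibble::as_tibble(schedule)
  need <- c("cycle", FRACTURE_TYPES)
  missing_cols <- setdiff(need, names(schedule))
  if (length(missing_cols)) {
    abort(paste0("rr_schedule lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(schedule) < n_cycles ||
      !all(seq_len(n_cycles) %in% schedule$cycle)) {
    abort(paste0("rr_schedule must cover cycles 1..", n_cycles))
  }
  vals <- as.matrix(schedule[FRACTURE_TYPES])
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("rr_schedule: all relative risks must be finite and > 0")
  }
  if (any(vals > 1)) {
    over <- which(vals > 1, arr.ind = TRUE)
    warn(paste0("rr_schedule: ", nrow(over),
                " relative risk(s) exceed 1 (treatment increases risk there)"))
  }
  schedule
}

#' Age-indexed epidemiological tables
#'
#' @param fracture_incidence Tibble `age`, `hip`, `vertebral`, `other`:
#'   annual fracture rate per person in the female general population.
#' @param mortality Tibble `age`, `qx`: annual probability of death.
#' @param mortality_rr Tibble `fracture_type`, `year_band`
#'   (`"first"`/`"subsequent"`), `age_min`, `age_max`, `rr`: relative risk of
#'   death versus the general population by time since fracture.
#' @param utilities Tibble `age_min`, `age_max`, `utility`: female general
#'   population utility by age band.
#' @param stand_in Logical: are these synthetic stand-ins for unpublished
#'   source tables?  Propagated into run reports.
#' @return A list of class `osteo_epi`.
#' @export
epi_tables <- function(fracture_incidence, mortality, mortality_rr, utilities,
                       stand_in = FALSE) {
  out <- structure(
    list(fracture_incidence = tibble::as_tibble(fracture_incidence),
         mortality = tibble::as_tibble(mortality),
         mortality_rr = tibble::as_tibble(mortality_rr),
         utilities = tibble::as_tibble(utilities),
         stand_in = isTRUE(stand_in)),
    class = "osteo_epi"
  )
  validate_epi(out)
}

validate_epi <- function(x) {
  fi <- x$fracture_incidence
  if (!all(c("age", FRACTURE_TYPES) %in% names(fi))) {
    abort("epi$fracture_incidence needs columns age, hip, vertebral, other")
  }
  if (is.unsorted(fi$age, strictly = TRUE)) {
    abort("epi$fracture_incidence: ages must be strictly increasing")
  }
  if (any(as.matrix(fi[FRACTURE_TYPES]) < 0)) {
    abort("epi$fracture_incidence: rates must be >= 0")
  }
  mt <- x$mortality
  if (!all(c("age", "qx") %in% names(mt))) abort("epi$mortality needs columns age, qx")
  if (is.unsorted(mt$age, strictly = TRUE)) {
    abort("epi$mortality: ages must be strictly increasing")
  }
  check_range(mt$qx, 0, 1, "epi$mortality$qx")
  mr <- x$mortality_rr
  need <- c("fracture_type", "year_band", "age_min", "age_max", "rr")
  if (!all(need %in% names(mr))) {
    abort(paste0("epi$mortality_rr needs columns ", paste(need, collapse = ", ")))
  }
  if (any(mr$rr <= 0)) abort("epi$mortality_rr$rr must be > 0")
  ut <- x$utilities
  if (!all(c("age_min", "age_max", "utility") %in% names(ut))) {
    abort("epi$utilities needs columns age_min, age_max, utility")
  }
  check_range(ut$utility, 0, 1, "epi$utilities$utility")
  x
}

#' Baseline fracture-risk adjustment for the very-high-risk population
#'
#' General-population fracture rates are scaled up for prior fracture and for
#' the BMD deficit of the target cohort:
#' `rate * rr_prior_fracture * rr_per_sd_bmd ^ t_score_gap`.
#'
#' @param rr_prior_fracture Relative risk of subsequent fracture given prior
#'   fracture (applied to all fracture types).
#' @param rr_per_sd_bmd Named numeric (`hip`, `vertebral`, `other`): relative
#'   risk per standard deviation decline in BMD.
#' @param t_score_gap SD between target-population and general-population BMD.
#' @return A list of class `osteo_risk_adjustment`.
#' @export
risk_adjustment <- function(rr_prior_fracture = 2.0,
                            rr_per_sd_bmd = c(hip = 2.6, vertebral = 1.8, other = 1.5),
                            t_score_gap = 0.7) {
  out <- structure(
    list(rr_prior_fracture = rr_prior_fracture,
         rr_per_sd_bmd = rr_per_sd_bmd,
         t_score_gap = t_score_gap),
    class = "osteo_risk_adjustment"
  )
  if (out$rr_prior_fracture <= 0) abort("risk_adjustment$rr_prior_fracture must be > 0")
  if (!all(FRACTURE_TYPES %in% names(out$rr_per_sd_bmd))) {
    abort("risk_adjustment$rr_per_sd_bmd needs names hip, vertebral, other")
  }
  if (any(out$rr_per_sd_bmd <= 0)) abort("risk_adjustment$rr_per_sd_bmd must be > 0")
  out
}

#' Fracture cost tables
#'
#' @param first_year Tibble `fracture_type`, `age_min`, `age_max`, `cost`:
#'   direct medical cost (CAD) in the first year after fracture.
#' @param subsequent_year Named numeric (`hip`, `vertebral`): annual cost in
#'   the second and following years after fracture.
#' @param ltc_entry_prob_after_hip Proportion of hip-fracture patients
#'   entering long-term care.
#' @param ltc_daily_cost CAD per day of long-term care.
#' @param societal List with `hourly_wage` (CAD), `time_off_hours` (named by
#'   fracture type, hours of lost work per fracture), `visit_out_of_pocket`
#'   (CAD per scheduled monitoring visit).
#' @return A list of class `osteo_costs`.
#' @export
cost_tables <- function(first_year, subsequent_year,
                        ltc_entry_prob_after_hip, ltc_daily_cost,
                        societal = NULL) {
  out <- structure(
    list(first_year = tibble::as_tibble(first_year),
         subsequent_year = subsequent_year,
         ltc_entry_prob_after_hip = ltc_entry_prob_after_hip,
         ltc_daily_cost = ltc_daily_cost,
         societal = societal),
    class = "osteo_costs"
  )
  validate_costs(out)
}

validate_costs <- function(x) {
  need <- c("fracture_type", "age_min", "age_max", "cost")
  if (!all(need %in% names(x$first_year))) {
    abort(paste0("costs$first_year needs columns ", paste(need, collapse = ", ")))
  }
  if (any(x$first_year$cost < 0)) abort("costs$first_year$cost must be >= 0")
  if (!all(c("hip", "vertebral") %in% names(x$subsequent_year))) {
    abort("costs$subsequent_year needs names hip and vertebral")
  }
  if (any(x$subsequent_year < 0)) abort("costs$subsequent_year must be >= 0")
  check_range(x$ltc_entry_prob_after_hip, 0, 1, "costs$ltc_entry_prob_after_hip")
  if (x$ltc_daily_cost < 0) abort("costs$ltc_daily_cost must be >= 0")
  if (!is.null(x$societal)) {
    s <- x$societal
    if (!all(c("hourly_wage", "time_off_hours", "visit_out_of_pocket") %in% names(s))) {
      abort("costs$societal needs hourly_wage, time_off_hours, visit_out_of_pocket")
    }
    if (s$hourly_wage < 0 || s$visit_out_of_pocket < 0 || any(s$time_off_hours < 0)) {
      abort("costs$societal values must be >= 0")
    }
  }
  x
}

#' Utility multipliers by fracture state
#'
#' @param first_year Named numeric (`hip`, `vertebral`, `other`): multiplier
#'   applied to general-population utility in the first year after fracture.
#' @param subsequent_years Named numeric (`hip`, `vertebral`): multiplier in
#'   the second and following years.
#' @return A list of class `osteo_utility_multipliers`.
#' @export
utility_multipliers <- function(first_year = c(hip = 0.55, vertebral = 0.68, other = 0.83),
                                subsequent_years = c(hip = 0.86, vertebral = 0.85)) {
  out <- structure(
    list(first_year = first_year, subsequent_years = subsequent_years),
    class = "osteo_utility_multipliers"
  )
  if (!all(FRACTURE_TYPES %in% names(out$first_year))) {
    abort("utility_multipliers$first_year needs names hip, vertebral, other")
  }
  if (!all(c("hip", "vertebral") %in% names(out$subsequent_years))) {
    abort("utility_multipliers$subsequent_years needs names hip, vertebral")
  }
  vals <- c(out$first_year, out$subsequent_years)
  if (any(vals <= 0 | vals > 1)) {
    abort("utility_multipliers must lie in (0, 1]")
  }
  out
}

#' Economic settings
#'
#' @param discount_rate_costs,discount_rate_qalys Annual discount rates.
#' @param cycle_length Cycle length in years; the reference case uses 0.5.
#' @param max_age Age at which the horizon closes out (mortality-only run-off
#'   continues to `runoff_age` or cohort extinction).
#' @param runoff_age Hard stop for the mortality-only run-off.
#' @param wtp_grid Willingness-to-pay grid (CAD/QALY) for CEAC and NMB.
#' @param perspective `"payer"` or `"societal"`.
#' @param half_cycle_correction Logical; reference case is `FALSE`.
#' @return A list of class `osteo_econ`.
#' @export
econ_settings <- function(discount_rate_costs = 0.015,
                          discount_rate_qalys = 0.015,
                          cycle_length = 0.5,
                          max_age = 100,
                          runoff_age = 110,
                          wtp_grid = NULL,
                          perspective = c("payer", "societal"),
                          half_cycle_correction = FALSE) {
  perspective <- match.arg(perspective)
  if (is.null(wtp_grid)) wtp_grid <- seq(0, 200000, by = 1000)
  out <- structure(
    list(discount_rate_costs = discount_rate_costs,
         discount_rate_qalys = discount_rate_qalys,
         cycle_length = cycle_length,
         max_age = max_age,
         runoff_age = runoff_age,
         wtp_grid = wtp_grid,
         perspective = perspective,
         half_cycle_correction = isTRUE(half_cycle_correction)),
    class = "osteo_econ"
  )
  if (out$discount_rate_costs < 0 || out$discount_rate_qalys < 0) {
    abort("econ: discount rates must be >= 0")
  }
  if (out$cycle_length != 0.5) {
    abort("econ$cycle_length must be 0.5 years (the model's cycle grid)")
  }
  out
}

#' Excess-mortality modifier after fracture
#'
#' Only a fraction of the observed post-fracture excess mortality is treated
#' as caused by the fracture; the effective relative risk applied to the
#' hazard is `1 + attributable_fraction * (rr - 1)`, for a limited number of
#' years after the event.
#'
#' @param attributable_fraction Fraction of excess mortality attributable to
#'   the fracture itself (reference case 0.30).
#' @param excess_duration Named numeric, years of excess mortality by fracture
#'   type (reference case hip 8, vertebral 8, other 1).
#' @param hip_only_first_year If `TRUE`, only the first year after a hip
#'   fracture carries excess mortality (scenario).
#' @return A list of class `osteo_mortality_modifier`.
#' @export
mortality_modifier <- function(attributable_fraction = 0.30,
                               excess_duration = c(hip = 8, vertebral = 8, other = 1),
                               hip_only_first_year = FALSE) {
  out <- structure(
    list(attributable_fraction = attributable_fraction,
         excess_duration = excess_duration,
         hip_only_first_year = isTRUE(hip_only_first_year)),
    class = "osteo_mortality_modifier"
  )
  check_range(out$attributable_fraction, 0, 1, "mortality_modifier$attributable_fraction")
  if (!all(FRACTURE_TYPES %in% names(out$excess_duration))) {
    abort("mortality_modifier$excess_duration needs names hip, vertebral, other")
  }
  if (any(out$excess_duration <= 0)) abort("mortality_modifier$excess_duration must be > 0")
  out
}

#' Uncertainty specification for probabilistic analysis
#'
#' Distribution families follow standard practice: lognormal for relative
#' risks (median at the point estimate, log-sd from the CI), beta for
#' utilities/proportions, gamma for costs, normal for survival-model
#' location/scale parameters.  Where no CI is available, a spread of
#' `default_spread` above and below the point estimate is treated as a 95%
#' interval.
#'
#' @param rr_ci Tibble `regimen`, `fracture_type`, `low`, `high`: 95% CIs for
#'   constant treatment RRs versus placebo.
#' @param default_spread Relative half-width used when no CI exists (0.25).
#' @param sample_survival_params Sample survival-fit parameters jointly from
#'   their asymptotic normal distribution when a regimen's schedule is
#'   derived from fits.
#' @return A list of class `osteo_uncertainty`.
#' @export
uncertainty_spec <- function(rr_ci = NULL,
                             default_spread = 0.25,
                             sample_survival_params = TRUE) {
  out <- structure(
    list(rr_ci = if (!is.null(rr_ci)) tibble::as_tibble(rr_ci),
         default_spread = default_spread,
         sample_survival_params = isTRUE(sample_survival_params)),
    class = "osteo_uncertainty"
  )
  if (out$default_spread < 0) abort("uncertainty$default_spread must be >= 0")
  out
}

#' Assemble a full model configuration
#'
#' @param population [population_spec()]
#' @param regimens Named list of [regimen_spec()] objects.
#' @param epi [epi_tables()]
#' @param risk_adj [risk_adjustment()]
#' @param costs [cost_tables()]
#' @param utility_mult [utility_multipliers()]
#' @param econ [econ_settings()]
#' @param mortality_mod [mortality_modifier()]
#' @param uncertainty [uncertainty_spec()]
#' @param trial_data Optional tibble of time-to-event records
#'   (`subject_id`, `arm`, `endpoint`, `time_years`, `event`) from which
#'   cycle RR schedules can be re-derived via survival fits.
#' @return A list of class `osteo_config`.
#' @export
model_config <- function(population, regimens, epi, risk_adj, costs,
                         utility_mult, econ, mortality_mod,
                         uncertainty = uncertainty_spec(),
                         trial_data = NULL) {
  out <- structure(
    list(population = population,
         regimens = regimens,
         epi = epi,
         risk_adj = risk_adj,
         costs = costs,
         utility_mult = utility_mult,
         econ = econ,
         mortality_mod = mortality_mod,
         uncertainty = uncertainty,
         trial_data = if (!is.null(trial_data)) tibble::as_tibble(trial_data)),
    class = "osteo_config"
  )
  validate_config(out)
}

#' Validate a model configuration
#'
#' Re-runs every component validator; errors name the offending field.
#' @param config An `osteo_config`.
#' @return The config, invisibly validated.
#' @export
validate_config <- function(config) {
  required <- c("population", "regimens", "epi", "risk_adj", "costs",
                "utility_mult", "econ", "mortality_mod", "uncertainty")
  missing_parts <- required[!vapply(required, function(f) !is.null(config[[f]]), logical(1))]
  if (length(missing_parts)) {
    abort(paste0("config is missing required block(s): ",
                 paste(missing_parts, collapse = ", ")))
  }
  validate_population(config$population)
  if (!length(config$regimens)) abort("config$regimens must contain at least one regimen")
  if (is.null(names(config$regimens)) || any(names(config$regimens) == "")) {
    abort("config$regimens must be a named list")
  }
  purrr::walk(config$regimens, validate_regimen)
  validate_epi(config$epi)
  validate_costs(config$costs)
  config
}

#' @export
print.osteo_config <- function(x, ...) {
  cat("<osteo_config>\n")
  cat("  population : mean age", x$population$mean_age, "| T-score", x$population$t_score, "\n")
  cat("  regimens   :", paste(names(x$regimens), collapse = ", "), "\n")
  cat("  perspective:", x$econ$perspective,
      "| discount", x$econ$discount_rate_costs, "(costs)",
      x$econ$discount_rate_qalys, "(QALYs)\n")
  if (isTRUE(x$epi$stand_in)) {
    cat("  note       : epidemiological tables are synthetic stand-ins\n")
  }
  invisible(x)
}

# ---- config file I/O -------------------------------------------------------

tbl_to_list <- function(x) lapply(as.list(x), function(col) unname(col))

list_to_tbl <- function(x) tibble::as_tibble(lapply(x, unlist))

#' Read a model configuration from a YAML file
#'
#' Tables may be given inline (column lists) or as `{file: path.csv}`
#' references relative to the config file, with a header row.
#'
#' @param path Path to a YAML configuration.
#' @return A validated `osteo_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  raw <- yaml::read_yaml(path)
  base_dir <- dirname(path)

  get_tbl <- function(x, what) {
    if (is.null(x)) abort(paste0("config is missing required table: ", what))
    if (!is.null(x$file)) {
      f <- file.path(base_dir, x$file)
      if (!file.exists(f)) abort(paste0("table file for ", what, " not found: ", f))
      return(tibble::as_tibble(utils::read.csv(f, check.names = FALSE)))
    }
    list_to_tbl(x)
  }

  pop <- do.call(population_spec, c(
    raw$population[c("mean_age", "sex", "t_score")],
    list(prior_fracture_mix = unlist(raw$population$prior_fracture_mix))
  ))

  regimens <- purrr::map(raw$regimens, function(r) {
    regimen_spec(
      name = r$name,
      components = list_to_tbl(r$components),
      rr_schedule = get_tbl(r$rr_schedule, paste0("rr_schedule (", r$name, ")")),
      treatment_duration = r$treatment_duration %||% 10L,
      offset_duration = r$offset_duration %||% 5,
      rr_provenance = r$rr_provenance %||% "direct-table",
      rr_vs_active = if (!is.null(r$rr_vs_active)) list_to_tbl(r$rr_vs_active)
    )
  })
  names(regimens) <- vapply(regimens, `[[`, character(1), "name")

  epi <- epi_tables(
    fracture_incidence = get_tbl(raw$epi$fracture_incidence, "epi$fracture_incidence"),
    mortality = get_tbl(raw$epi$mortality, "epi$mortality"),
    mortality_rr = get_tbl(raw$epi$mortality_rr, "epi$mortality_rr"),
    utilities = get_tbl(raw$epi$utilities, "epi$utilities"),
    stand_in = isTRUE(raw$epi$stand_in)
  )

  risk_adj <- risk_adjustment(
    rr_prior_fracture = raw$risk_adj$rr_prior_fracture,
    rr_per_sd_bmd = unlist(raw$risk_adj$rr_per_sd_bmd),
    t_score_gap = raw$risk_adj$t_score_gap
  )

  societal <- raw$costs$societal
  if (!is.null(societal)) {
    for (nm in setdiff(names(societal), c("hourly_wage", "visit_out_of_pocket"))) {
      societal[[nm]] <- unlist(societal[[nm]])
    }
  }
  costs <- cost_tables(
    first_year = get_tbl(raw$costs$first_year, "costs$first_year"),
    subsequent_year = unlist(raw$costs$subsequent_year),
    ltc_entry_prob_after_hip = raw$costs$ltc_entry_prob_after_hip,
    ltc_daily_cost = raw$costs$ltc_daily_cost,
    societal = societal
  )

  utility_mult <- utility_multipliers(
    first_year = unlist(raw$utility_mult$first_year),
    subsequent_years = unlist(raw$utility_mult$subsequent_years)
  )

  econ_raw <- raw$econ %||% list()
  econ <- econ_settings(
    discount_rate_costs = econ_raw$discount_rate_costs %||% 0.015,
    discount_rate_qalys = econ_raw$discount_rate_qalys %||% 0.015,
    cycle_length = econ_raw$cycle_length %||% 0.5,
    max_age = econ_raw$max_age %||% 100,
    runoff_age = econ_raw$runoff_age %||% 110,
    wtp_grid = if (!is.null(econ_raw$wtp_grid)) unlist(econ_raw$wtp_grid),
    perspective = econ_raw$perspective %||% "payer",
    half_cycle_correction = isTRUE(econ_raw$half_cycle_correction)
  )

  mm_raw <- raw$mortality_mod %||% list()
  mortality_mod <- mortality_modifier(
    attributable_fraction = mm_raw$attributable_fraction %||% 0.30,
    excess_duration = if (!is.null(mm_raw$excess_duration)) {
      unlist(mm_raw$excess_duration)
    } else c(hip = 8, vertebral = 8, other = 1),
    hip_only_first_year = isTRUE(mm_raw$hip_only_first_year)
  )

  unc_raw <- raw$uncertainty %||% list()
  uncertainty <- uncertainty_spec(
    rr_ci = if (!is.null(unc_raw$rr_ci)) list_to_tbl(unc_raw$rr_ci),
    default_spread = unc_raw$default_spread %||% 0.25,
    sample_survival_params = !isFALSE(unc_raw$sample_survival_params)
  )

  trial_data <- if (!is.null(raw$trial_data)) get_tbl(raw$trial_data, "trial_data")

  model_config(pop, regimens, epi, risk_adj, costs, utility_mult, econ,
               mortality_mod, uncertainty, trial_data)
}

#' Write a model configuration to a YAML file
#'
#' Inverse of [load_config()]: `load_config(write_config(cfg, f))` reproduces
#' the configuration field-for-field.  All tables are written inline.
#'
#' @param config An `osteo_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  as_plain <- function(x) {
    if (tibble::is_tibble(x)) tbl_to_list(x)
    else if (is.list(x)) lapply(x, as_plain)
    else if (!is.null(names(x)) && length(x) > 1) as.list(x)
    else x
  }
  raw <- list(
    population = list(
      mean_age = config$population$mean_age,
      sex = config$population$sex,
      t_score = config$population$t_score,
      prior_fracture_mix = as.list(config$population$prior_fracture_mix)
    ),
    regimens = purrr::map(config$regimens, function(r) {
      list(name = r$name,
           components = tbl_to_list(r$components),
           rr_schedule = tbl_to_list(r$rr_schedule),
           treatment_duration = r$treatment_duration,
           offset_duration = r$offset_duration,
           rr_provenance = r$rr_provenance,
           rr_vs_active = if (!is.null(r$rr_vs_active)) tbl_to_list(r$rr_vs_active))
    }),
    epi = list(
      fracture_incidence = tbl_to_list(config$epi$fracture_incidence),
      mortality = tbl_to_list(config$epi$mortality),
      mortality_rr = tbl_to_list(config$epi$mortality_rr),
      utilities = tbl_to_list(config$epi$utilities),
      stand_in = config$epi$stand_in
    ),
    risk_adj = list(
      rr_prior_fracture = config$risk_adj$rr_prior_fracture,
      rr_per_sd_bmd = as.list(config$risk_adj$rr_per_sd_bmd),
      t_score_gap = config$risk_adj$t_score_gap
    ),
    costs = list(
      first_year = tbl_to_list(config$costs$first_year),
      subsequent_year = as.list(config$costs$subsequent_year),
      ltc_entry_prob_after_hip = config$costs$ltc_entry_prob_after_hip,
      ltc_daily_cost = config$costs$ltc_daily_cost,
      societal = if (!is.null(config$costs$societal)) {
        lapply(config$costs$societal,
               function(v) if (length(v) > 1 || !is.null(names(v))) as.list(v) else v)
      }
    ),
    utility_mult = list(
      first_year = as.list(config$utility_mult$first_year),
      subsequent_years = as.list(config$utility_mult$subsequent_years)
    ),
    econ = list(
      discount_rate_costs = config$econ$discount_rate_costs,
      discount_rate_qalys = config$econ$discount_rate_qalys,
      cycle_length = config$econ$cycle_length,
      max_age = config$econ$max_age,
      runoff_age = config$econ$runoff_age,
      wtp_grid = config$econ$wtp_grid,
      perspective = config$econ$perspective,
      half_cycle_correction = config$econ$half_cycle_correction
    ),
    mortality_mod = list(
      attributable_fraction = config$mortality_mod$attributable_fraction,
      excess_duration = as.list(config$mortality_mod$excess_duration),
      hip_only_first_year = config$mortality_mod$hip_only_first_year
    ),
    uncertainty = list(
      rr_ci = if (!is.null(config$uncertainty$rr_ci)) tbl_to_list(config$uncertainty$rr_ci),
      default_spread = config$uncertainty$default_spread,
      sample_survival_params = config$uncertainty$sample_survival_params
    ),
    trial_data = if (!is.null(config$trial_data)) tbl_to_list(config$trial_data)
  )
  raw <- raw[!vapply(raw, is.null, logical(1))]
  yaml::write_yaml(raw, path, precision = 15)
  invisible(path)
}

# ---- small shared helpers --------------------------------------------------

check_range <- function(x, lo, hi, what) {
  if (any(!is.finite(x)) || any(x < lo) || any(x > hi)) {
    abort(paste0(what, " must lie in [", lo, ", ", hi, "]"))
  }
  invisible(x)
}
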