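# Baseline epidemiology: age interpolation, very-high-risk adjustment, and
# rate/probability conversions on the half-year cycle grid.

CYCLE_YEARS <- 0.5

#' Linearly interpolate (or extrapolate) an age-indexed rate table
#'
#' Values between knots are linearly interpolated; beyond the knot range the
#' terminal segment is extended linearly and the result floored at 0.
#'
#' @param table Tibble with an `age` column and one value column (or a named
#'   value column given by `col`).
#' @param age Ages (vector ok) at which to evaluate.
#' @param col Name of the value column (default: the first non-age column).
#' @return Numeric vector of rates, never negative.
#' @export
interpolate_age_rate <- function(table, age, col = NULL) {
  if (is.null(col)) col <- setdiff(names(table), "age")[1]
  knots_x <- table$age
  knots_y <- table[[col]]
  if (length(knots_x) < 2) abort("interpolate_age_rate: need at least 2 knots")
  n <- length(knots_x)
  # linear extrapolation using terminal slopes
  slope_lo <- (knots_y[2] - knots_y[1]) / (knots_x[2] - knots_x[1])
  slope_hi <- (knots_y[n] - knots_y[n - 1]) / (knots_x[n] - knots_x[n - 1])
  y <- stats::approx(knots_x, knots_y, xout = age, rule = 2)$y
  below <- age < knots_x[1]
  above <- age > knots_x[n]
  y[below] <- knots_y[1] + slope_lo * (age[below] - knots_x[1])
  y[above] <- knots_y[n] + slope_hi * (age[above] - knots_x[n])
  pmax(y, 0)
}

#' Look up a value in an age-band table
#'
#' Bands are `[age_min, age_max)`; ages above the last band use it.
#'
#' @param table Tibble with `age_min`, `age_max` and a value column.
#' @param age Ages to look up.
#' @param col Value column name.
#' @return Vector of values.
#' @export
lookup_age_band <- function(table, age, col) {
  idx <- vapply(age, function(a) {
    i <- which(a >= table$age_min & a < table$age_max)
    if (!length(i)) {
      if (a >= max(table$age_max)) i <- which.max(table$age_max) else i <- which.min(table$age_min)
    }
    i[1]
  }, integer(1))
  table[[col]][idx]
}

#' Adjust a general-population fracture rate to the very-high-risk cohort
#'
#' `rate * rr_prior_fracture * rr_per_sd_bmd[type] ^ t_score_gap`.
#'
#' @param gen_rate Annual general-population rate(s).
#' @param adj A [risk_adjustment()].
#' @param fracture_type One of `"hip"`, `"vertebral"`, `"other"`.
#' @return Adjusted annual rate.
#' @export
adjust_baseline_risk <- function(gen_rate, adj, fracture_type) {
  stopifnot(fracture_type %in% FRACTURE_TYPES)
  gen_rate * adj$rr_prior_fracture *
    adj$rr_per_sd_bmd[[fracture_type]]^adj$t_score_gap
}

#' Convert an annual rate to a per-cycle probability
#'
#' Constant-hazard conversion on the half-year cycle: `1 - exp(-rate/2)`.
#'
#' @param annual_rate Annual event rate (>= 0).
#' @return Per-cycle probability in `[0, 1)`.
#' @export
rate_to_cycle_prob <- function(annual_rate) {
  if (any(annual_rate < 0)) abort("rate_to_cycle_prob: rate must be >= 0")
  1 - exp(-annual_rate * CYCLE_YEARS)
}

#' Convert a per-cycle probability back to an annual rate
#' @param prob Per-cycle probability in `[0, 1)`.
#' @return Annual rate.
#' @export
cycle_prob_to_rate <- function(prob) {
  check_range(prob, 0, 1, "cycle_prob_to_rate: prob")
  -log(1 - prob) / CYCLE_YEARS
}

prob_annual_to_rate <- function(q) -log(1 - pmin(q, 1 - 1e-12))

#' Effective mortality relative risk after attribution
#'
#' Only `attributable_fraction` of the observed excess mortality is treated
#' as caused by the fracture: `1 + f * (rr - 1)`.
#'
#' @param rr Observed all-cause mortality RR in the fracture state.
#' @param attributable_fraction Fraction attributable (reference case 0.30).
#' @return Effective RR applied on the hazard scale.
#' @export
attributable_rr <- function(rr, attributable_fraction = 0.30) {
  1 + attributable_fraction * (rr - 1)
}

#' Look up the post-fracture mortality RR band
#'
#' Year 1 after the event uses the first-year RR; years 2 through the
#' excess-mortality duration use the subsequent-years RR; afterwards 1.
#' "Other" fractures carry excess mortality in the first year only.
#'
#' @param epi An [epi_tables()] object.
#' @param modifier A [mortality_modifier()].
#' @param fracture_type Fracture type, or `NA` for the at-risk state.
#' @param years_since Completed-years since the event plus one (1 = first
#'   year).
#' @param age Current age.
#' @return Observed RR (before attribution); 1 outside the excess window.
#' @export
mortality_rr_band <- function(epi, modifier, fracture_type, years_since, age) {
  if (is.na(fracture_type)) return(1)
  dur <- modifier$excess_duration[[fracture_type]]
  if (modifier$hip_only_first_year) {
    if (fracture_type != "hip" || years_since > 1) return(1)
  }
  if (years_since > dur) return(1)
  band <- if (years_since <= 1) "first" else "subsequent"
  tbl <- epi$mortality_rr[epi$mortality_rr$fracture_type == fracture_type &
                            epi$mortality_rr$year_band == band, ]
  if (!nrow(tbl)) return(1)
  lookup_age_band(tbl, age, "rr")
}

#' Per-cycle death probability in a health state
#'
#' The base annual death probability (interpolated from the life table) is
#' converted to a hazard, multiplied by the attributable excess-mortality RR
#' for the state, and converted back to a half-year cycle probability.
#'
#' @param age Current age.
#' @param epi An [epi_tables()] object.
#' @param modifier A [mortality_modifier()].
#' @param fracture_type Fracture type of the current state (`NA` if at risk).
#' @param years_since Years since the fracture event (1 = first year).
#' @return Per-cycle probability of death, capped at 1.
#' @export
mortality_prob <- function(age, epi, modifier, fracture_type = NA, years_since = 1) {
  q_annual <- pmin(pmax(interpolate_age_rate(epi$mortality, age, col = "qx"), 0), 1)
  lambda <- prob_annual_to_rate(q_annual)
  rr_obs <- mortality_rr_band(epi, modifier, fracture_type, years_since, age)
  rr_eff <- attributable_rr(rr_obs, modifier$attributable_fraction)
  pmin(1 - exp(-lambda * rr_eff * CYCLE_YEARS), 1)
}
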