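# Treatment efficacy: parametric survival fits to trial time-to-event data,
# per-cycle incidence and relative risks, indirect composition versus
# placebo, and the linear offset of benefit after treatment stops.

SURV_FAMILIES <- c(exponential = "exp",
                   weibull = "weibull",
                   gompertz = "gompertz",
                   loglogistic = "llogis",
                   lognormal = "lnorm",
                   gengamma = "gengamma")

#' Fit a parametric survival model to trial records
#'
#' Maximum-likelihood fit with right censoring, per arm and endpoint
#' (arms are fitted separately so fracture incidence can change over time
#' differently in each regimen).
#'
#' @param records Tibble with columns `arm`, `endpoint`, `time_years`,
#'   `event` (1 = fracture observed).
#' @param endpoint Endpoint to fit (e.g. `"hip"`).
#' @param arm Arm to fit.
#' @param family One of `r paste(names(SURV_FAMILIES), collapse = ", ")`.
#' @return An object of class `osteo_survfit` with elements `family`,
#'   `pars` (natural parameters), `coef` and `vcov` (estimation scale, for
#'   probabilistic sampling), `intercept`, `scale`, `log_likelihood`,
#'   `n_params`, `aic`, `bic`, `n`.
#' @export
fit_survival <- function(records, endpoint, arm,
                         family = names(SURV_FAMILIES)) {
  family <- match.arg(family)
  dat <- records[records$endpoint == endpoint & records$arm == arm, ]
  if (!nrow(dat)) abort("fit_survival: no records for this arm/endpoint")
  ev_times <- unique(dat$time_years[dat$event == 1])
  if (length(ev_times) < 2) {
    abort("fit_survival: need at least 2 distinct event times")
  }
  fit <- tryCatch(
    flexsurv::flexsurvreg(
      survival::Surv(time_years, event) ~ 1,
      data = dat, dist = SURV_FAMILIES[[family]]
    ),
    error = function(e) {
      abort(paste0("fit_survival: ", family, " fit failed to converge: ",
                   conditionMessage(e)))
    }
  )
  k <- fit$npars
  ll <- fit$loglik
  co <- setNames(fit$res.t[, "est"], rownames(fit$res.t))
  structure(
    list(family = family,
         pars = setNames(fit$res[, "est"], rownames(fit$res)),
         coef = co,
         vcov = fit$cov,
         intercept = unname(co[1]),
         scale = if (k >= 2) unname(co[2]) else NA_real_,
         log_likelihood = ll,
         n_params = k,
         aic = 2 * k - 2 * ll,
         bic = k * log(nrow(dat)) - 2 * ll,
         n = nrow(dat),
         endpoint = endpoint,
         arm = arm),
    class = "osteo_survfit"
  )
}

#' Survival function of a fitted (or parameter-specified) model
#'
#' @param fit An `osteo_survfit`, or a list with `family` and `pars`.
#' @param t Times (years).
#' @return S(t).
#' @export
survfit_surv <- function(fit, t) {
  p <- fit$pars
  switch(fit$family,
    exponential = exp(-p[["rate"]] * t),
    weibull = stats::pweibull(t, p[["shape"]], p[["scale"]], lower.tail = FALSE),
    gompertz = flexsurv::pgompertz(t, p[["shape"]], p[["rate"]], lower.tail = FALSE),
    loglogistic = flexsurv::pllogis(t, p[["shape"]], p[["scale"]], lower.tail = FALSE),
    lognormal = stats::plnorm(t, p[["meanlog"]], p[["sdlog"]], lower.tail = FALSE),
    gengamma = flexsurv::pgengamma(t, p[["mu"]], p[["sigma"]], p[["Q"]],
                                   lower.tail = FALSE),
    abort(paste0("unknown survival family: ", fit$family))
  )
}

#' @export
print.osteo_survfit <- function(x, ...) {
  cat("<osteo_survfit>", x$family, "|", x$arm, "/", x$endpoint,
      "| logLik", format(x$log_likelihood, digits = 6),
      "| AIC", format(x$aic, digits = 6), "\n")
  invisible(x)
}

#' @export
tidy.osteo_survfit <- function(x, ...) {
  tibble::tibble(
    term = names(x$pars),
    estimate = unname(x$pars),
    transformed = unname(x$coef)
  )
}

#' @export
glance.osteo_survfit <- function(x, ...) {
  tibble::tibble(
    family = x$family, arm = x$arm, endpoint = x$endpoint,
    logLik = x$log_likelihood, AIC = x$aic, BIC = x$bic,
    nobs = x$n, n_params = x$n_params
  )
}

#' Select a survival family by information criterion
#'
#' `"AIC"` and `"BIC"` return the minimal-criterion fit; `"second-AIC"`
#' returns the fit with the second-smallest AIC (a scenario used to probe
#' structural uncertainty in the efficacy extrapolation).  Ties are broken
#' by parsimony (fewer parameters), then lexicographic family name.
#'
#' @param fits List of `osteo_survfit` objects.
#' @param criterion `"AIC"`, `"BIC"`, or `"second-AIC"`.
#' @return The selected fit.
#' @export
select_family <- function(fits, criterion = c("AIC", "BIC", "second-AIC")) {
  criterion <- match.arg(criterion)
  if (!length(fits)) abort("select_family: empty fit list")
  crit <- switch(criterion,
    "AIC" = vapply(fits, `[[`, numeric(1), "aic"),
    "BIC" = vapply(fits, `[[`, numeric(1), "bic"),
    "second-AIC" = vapply(fits, `[[`, numeric(1), "aic")
  )
  k <- vapply(fits, `[[`, numeric(1), "n_params")
  fam <- vapply(fits, `[[`, character(1), "family")
  ord <- order(crit, k, fam)
  pick <- if (criterion == "second-AIC") min(2L, length(fits)) else 1L
  fits[[ord[pick]]]
}

#' Conditional fracture incidence in a model cycle
#'
#' `(S(t_{j-1}) - S(t_j)) / S(t_{j-1})` with cycle boundaries on the
#' half-year grid.
#'
#' @param fit An `osteo_survfit`.
#' @param cycle_index Cycle number, 1..10.
#' @return Conditional per-cycle incidence.
#' @export
cycle_incidence <- function(fit, cycle_index) {
  stopifnot(all(cycle_index >= 1))
  t0 <- (cycle_index - 1) * CYCLE_YEARS
  t1 <- cycle_index * CYCLE_YEARS
  s0 <- survfit_surv(fit, t0)
  s1 <- survfit_surv(fit, t1)
  if (any(s0 <= 0)) abort("cycle_incidence: survival is 0 at cycle start")
  (s0 - s1) / s0
}

#' Per-cycle relative risk between two fitted arms
#'
#' @param active_fit,comparator_fit `osteo_survfit` objects for the same
#'   endpoint.
#' @param cycle_index Cycle number(s).
#' @return Ratio of conditional cycle incidences (active / comparator).
#' @export
cycle_rr <- function(active_fit, comparator_fit, cycle_index) {
  num <- cycle_incidence(active_fit, cycle_index)
  den <- cycle_incidence(comparator_fit, cycle_index)
  if (any(den == 0)) abort("cycle_rr: comparator incidence is 0")
  num / den
}

#' Derive a per-cycle RR schedule from trial records
#'
#' Fits all six parametric families per arm for the fitted endpoints,
#' selects by the requested criterion, and forms per-cycle incidence ratios
#' for cycles 1..`n_cycles`.  Only hip and non-vertebral ("other") schedules
#' are derived from fits; vertebral efficacy is consumed directly from
#' published per-cycle values.
#'
#' @param records Trial records (see [simulate_trial()]).
#' @param active,comparator Arm labels.
#' @param endpoints Endpoints to derive (default `c("hip", "other")`).
#' @param criterion Selection criterion, see [select_family()].
#' @param n_cycles Number of treatment cycles (default 10).
#' @return List with `schedule` (tibble `cycle` x endpoint columns) and
#'   `fits` (selected `osteo_survfit` per arm/endpoint).
#' @export
derive_rr_schedule <- function(records, active = "active", comparator = "comparator",
                               endpoints = c("hip", "other"),
                               criterion = "AIC", n_cycles = 10L) {
  fits <- list()
  cols <- list(cycle = seq_len(n_cycles))
  for (ep in endpoints) {
    sel <- purrr::map(c(active, comparator), function(arm) {
      all_fits <- purrr::map(names(SURV_FAMILIES), function(fam) {
        tryCatch(fit_survival(records, ep, arm, fam), error = function(e) NULL)
      })
      all_fits <- purrr::compact(all_fits)
      # drop degenerate fits (survival collapsing to 0 inside the horizon)
      all_fits <- purrr::keep(all_fits, function(f) {
        s <- survfit_surv(f, seq(CYCLE_YEARS, n_cycles * CYCLE_YEARS, by = CYCLE_YEARS))
        all(is.finite(s)) && all(s > 1e-8) && is.finite(f$aic)
      })
      if (!length(all_fits)) abort(paste0("no survival family converged for ",
                                          arm, "/", ep))
      select_family(all_fits, criterion)
    })
    names(sel) <- c("active", "comparator")
    fits[[ep]] <- sel
    cols[[ep]] <- cycle_rr(sel$active, sel$comparator, seq_len(n_cycles))
  }
  list(schedule = tibble::as_tibble(cols), fits = fits)
}

#' Compose per-cycle RRs versus an active comparator with the comparator's
#' constant RR versus placebo
#'
#' @param rr_vs_active Tibble `cycle` plus fracture-type columns: per-cycle
#'   RRs of the sequence versus the active comparator.
#' @param rr_active_vs_placebo Named numeric: the comparator's constant RR
#'   versus placebo per fracture type.
#' @return Tibble of per-cycle RRs versus placebo (per-cycle product).
#' @export
compose_vs_placebo <- function(rr_vs_active, rr_active_vs_placebo) {
  out <- tibble::as_tibble(rr_vs_active)
  types <- intersect(names(out), names(rr_active_vs_placebo))
  if (!length(types)) abort("compose_vs_placebo: no shared fracture-type columns")
  if (any(unlist(out[types]) <= 0) || any(rr_active_vs_placebo[types] <= 0)) {
    abort("compose_vs_placebo: relative risks must be > 0")
  }
  for (ty in types) out[[ty]] <- out[[ty]] * rr_active_vs_placebo[[ty]]
  out
}

#' Effective relative risk during the treatment-offset period
#'
#' After treatment stops, the fracture-reduction benefit `1 - base_rr`
#' declines linearly to 0 over `offset_duration` years:
#' `1 - (1 - base_rr) * max(0, 1 - t_since_stop / offset_duration)`.
#'
#' @param base_rr RR at the end of treatment.
#' @param t_since_stop Years since treatment stopped (>= 0).
#' @param offset_duration Offset period, years (> 0).
#' @return Effective RR: `base_rr` at `t = 0`, 1 from `t >= offset_duration`.
#' @export
offset_rr <- function(base_rr, t_since_stop, offset_duration) {
  if (offset_duration <= 0) abort("offset_rr: offset_duration must be > 0")
  if (any(t_since_stop < 0)) abort("offset_rr: t_since_stop must be >= 0")
  1 - (1 - base_rr) * pmax(0, 1 - t_since_stop / offset_duration)
}
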