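# Outcome accrual: life-years, QALYs and costs from a cohort trace and its
# fracture ledger, discounted on the half-year cycle grid, and incremental
# cost-utility comparison across regimens.
#
# Accrual conventions (reference case): no half-cycle correction; cycle
# accruals use start-of-cycle occupancy; first-year fracture costs and
# event disutilities for hierarchy-corrected events are spread over the two
# cycles following the event.

#' Discount factor
#'
#' @param rate Annual discount rate (fraction, >= 0).
#' @param t Time in years (>= 0).
#' @return `(1 + rate)^(-t)`.
#' @export
discount_factor <- function(rate, t) {
  if (any(rate < 0)) abort("discount_factor: rate must be >= 0")
  if (any(t < 0)) abort("discount_factor: t must be >= 0")
  (1 + rate)^(-t)
}

# spread per-cycle event quantities over the event cycle and the next one
spread_two_cycles <- function(x) {
  out <- x / 2
  if (length(x) > 1) out[-1] <- out[-1] + x[-length(x)] / 2
  out
}

#' Accrue QALY streams from a trace
#'
#' Per cycle: occupancy x age-band utility x fracture-state multiplier x 1/2
#' year.  First-year multipliers apply in acute states, subsequent-year
#' multipliers in post states, the "other" multiplier during its 1-year
#' state.  Hierarchy-corrected events (which never occupy states) contribute
#' a one-year first-year disutility stream spread over two cycles.
#'
#' @param trace An `osteo_trace`.
#' @param config The `osteo_config` the trace was run from.
#' @return Tibble per cycle: `life_years`, `qalys`, undiscounted, plus
#'   discounted versions (`*_disc`), per 1000 persons.
#' @export
accrue_qalys <- function(trace, config) {
  ss <- trace$state_space
  epi <- config$epi
  um <- config$utility_mult
  t_n <- nrow(trace$occupancy)
  util <- lookup_age_band(epi$utilities, trace$ages, "utility")
  mult <- c(atrisk = 1, dead = 0,
            hip_first = um$first_year[["hip"]],
            vert_first = um$first_year[["vertebral"]],
            other_first = um$first_year[["other"]],
            hip_subseq = um$subsequent_years[["hip"]],
            vert_subseq = um$subsequent_years[["vertebral"]])
  m_state <- mult[ss$mult_cat]

  alive <- rowSums(trace$occupancy[, ss$alive, drop = FALSE])
  ly <- alive * CYCLE_YEARS
  q_state <- as.vector(trace$occupancy %*% m_state) * util * CYCLE_YEARS

  # one-year disutility stream for corrected (ledger-only) events
  dis_v <- spread_two_cycles(trace$events_corrected[, "vertebral"] *
                               (1 - um$first_year[["vertebral"]]))
  dis_o <- spread_two_cycles(trace$events_corrected[, "other"] *
                               (1 - um$first_year[["other"]]))
  q <- unname(q_state - (dis_v + dis_o) * util * CYCLE_YEARS)

  t_years <- (seq_len(t_n) - 1) * CYCLE_YEARS
  df <- discount_factor(config$econ$discount_rate_qalys, t_years)
  tibble::tibble(
    cycle = seq_len(t_n),
    life_years = ly,
    qalys = q,
    life_years_disc = ly * df,
    qalys_disc = q * df
  )
}

#' Accrue cost streams from a trace
#'
#' Drug and monitoring costs accrue to alive persons during the treatment
#' cycles (full persistence).  First-year fracture costs attach to events
#' (direct and hierarchy-corrected) at the age-banded rate, spread over two
#' cycles.  Subsequent-year costs accrue to post-hip/post-vertebral
#' occupancy.  A fixed fraction of hip-fracture patients enter long-term
#' care: LTC cost accrues to that fraction of the surviving hip-branch
#' occupancy for their remaining lifetime, additive to the subsequent-year
#' medical cost.  The societal perspective adds productivity loss per event
#' and out-of-pocket travel per scheduled monitoring visit.
#'
#' @param trace An `osteo_trace`.
#' @param config The `osteo_config`.
#' @param regimen The regimen run (object or name from the config).
#' @param perspective Override the config perspective (optional).
#' @return Tibble per cycle with component cost streams (per 1000 persons),
#'   undiscounted and discounted (`*_disc`).
#' @export
accrue_costs <- function(trace, config, regimen, perspective = NULL) {
  if (is.character(regimen)) regimen <- config$regimens[[regimen]]
  perspective <- perspective %||% config$econ$perspective
  ss <- trace$state_space
  costs <- config$costs
  t_n <- nrow(trace$occupancy)
  st <- ss$states

  alive <- rowSums(trace$occupancy[, ss$alive, drop = FALSE])

  # per-cycle drug + monitoring schedule from the component sequence
  comp_cycle <- rep(seq_len(nrow(regimen$components)),
                    times = regimen$components$duration_cycles)
  drug <- monitor <- visits <- numeric(t_n)
  td <- min(regimen$treatment_duration, t_n)
  ann_visits <- costs$societal$annual_visits
  for (t in seq_len(td)) {
    comp <- regimen$components[comp_cycle[t], ]
    drug[t] <- alive[t] * comp$annual_drug_cost * CYCLE_YEARS
    monitor[t] <- alive[t] * comp$annual_monitoring_cost * CYCLE_YEARS
    if (!is.null(ann_visits) && comp$drug %in% names(ann_visits)) {
      visits[t] <- alive[t] * ann_visits[[comp$drug]] * CYCLE_YEARS
    }
  }

  # first-year fracture costs attach to events, age-banded, over 2 cycles
  fy <- sapply(FRACTURE_TYPES, function(ty) {
    tbl <- costs$first_year[costs$first_year$fracture_type == ty, ]
    lookup_age_band(tbl, trace$ages, "cost")
  })
  ev <- trace$events
  ev[, "vertebral"] <- ev[, "vertebral"] + trace$events_corrected[, "vertebral"]
  ev[, "other"] <- ev[, "other"] + trace$events_corrected[, "other"]
  fy_by_type <- sapply(FRACTURE_TYPES, function(ty)
    spread_two_cycles(ev[, ty] * fy[, ty]))
  first_year_cost <- rowSums(fy_by_type)

  post_hip <- rowSums(trace$occupancy[, st$branch == "hip" & st$phase != "acute",
                                      drop = FALSE])
  post_vert <- rowSums(trace$occupancy[, st$branch == "vertebral" & st$phase != "acute",
                                       drop = FALSE])
  subsequent_cost <- (post_hip * costs$subsequent_year[["hip"]] +
                        post_vert * costs$subsequent_year[["vertebral"]]) * CYCLE_YEARS

  hip_branch_occ <- rowSums(trace$occupancy[, ss$hip_branch, drop = FALSE])
  ltc_cost <- costs$ltc_entry_prob_after_hip * hip_branch_occ *
    costs$ltc_daily_cost * 365.25 * CYCLE_YEARS

  societal_cost <- numeric(t_n)
  if (perspective == "societal" && !is.null(costs$societal)) {
    s <- costs$societal
    productivity <- rowSums(sapply(FRACTURE_TYPES, function(ty)
      ev[, ty] * s$time_off_hours[[ty]] * s$hourly_wage))
    societal_cost <- productivity + visits * s$visit_out_of_pocket
  }

  t_years <- (seq_len(t_n) - 1) * CYCLE_YEARS
  df <- discount_factor(config$econ$discount_rate_costs, t_years)
  out <- tibble::tibble(
    cycle = seq_len(t_n),
    drug_cost = drug,
    monitoring_cost = monitor,
    first_year_fracture_cost = first_year_cost,
    subsequent_fracture_cost = subsequent_cost,
    ltc_cost = ltc_cost,
    societal_cost = societal_cost
  )
  out$total_cost <- rowSums(out[, -1])
  # per-fracture-type attribution (LTC and subsequent-hip costs are hip costs)
  out$fracture_cost_hip <- fy_by_type[, "hip"] +
    post_hip * costs$subsequent_year[["hip"]] * CYCLE_YEARS + ltc_cost
  out$fracture_cost_vertebral <- fy_by_type[, "vertebral"] +
    post_vert * costs$subsequent_year[["vertebral"]] * CYCLE_YEARS
  out$fracture_cost_other <- fy_by_type[, "other"]
  for (col in setdiff(names(out), "cycle")) {
    out[[paste0(col, "_disc")]] <- out[[col]] * df
  }
  out
}

#' Run one regimen and accrue all outcomes
#'
#' @param config An `osteo_config`.
#' @param regimen Regimen object or name.
#' @param prepared Internal: precomputed inputs for repeated runs.
#' @return A list of class `osteo_accrual`: scalar totals per person
#'   (costs CAD, QALYs, life-years; discounted and undiscounted), component
#'   breakdown, fracture totals per 1000, and the trace.
#' @export
accrue_outcomes <- function(config, regimen, prepared = NULL) {
  if (is.character(regimen)) regimen <- config$regimens[[regimen]]
  trace <- run_trace(config, regimen, prepared = prepared)
  q <- accrue_qalys(trace, config)
  cc <- accrue_costs(trace, config, regimen)
  led <- fracture_ledger(trace)

  per_person <- function(x) sum(x) / trace$cohort
  totals <- tibble::tibble(
    regimen = regimen$name,
    cost = per_person(cc$total_cost_disc),
    qalys = per_person(q$qalys_disc),
    life_years = per_person(q$life_years_disc),
    cost_undisc = per_person(cc$total_cost),
    qalys_undisc = per_person(q$qalys),
    life_years_undisc = per_person(q$life_years),
    drug_cost = per_person(cc$drug_cost_disc),
    monitoring_cost = per_person(cc$monitoring_cost_disc),
    fracture_cost = per_person(cc$first_year_fracture_cost_disc +
                                 cc$subsequent_fracture_cost_disc +
                                 cc$ltc_cost_disc),
    fracture_cost_hip = per_person(cc$fracture_cost_hip_disc),
    fracture_cost_vertebral = per_person(cc$fracture_cost_vertebral_disc),
    fracture_cost_other = per_person(cc$fracture_cost_other_disc),
    societal_cost = per_person(cc$societal_cost_disc),
    fractures_per_1000 = led$total[["total"]],
    hip_fractures_per_1000 = led$total[["hip"]],
    vertebral_fractures_per_1000 = led$total[["vertebral"]],
    other_fractures_per_1000 = led$total[["other"]]
  )
  structure(
    list(totals = totals, qaly_stream = q, cost_stream = cc,
         ledger = led, trace = trace, regimen = regimen$name),
    class = "osteo_accrual"
  )
}

#' @export
print.osteo_accrual <- function(x, ...) {
  t <- x$totals
  cat("<osteo_accrual>", t$regimen,
      "| cost", format(round(t$cost), big.mark = ","),
      "| QALYs", round(t$qalys, 3),
      "| LYs", round(t$life_years, 3),
      "| fx/1000", round(t$fractures_per_1000), "\n")
  invisible(x)
}

#' @export
tidy.osteo_accrual <- function(x, ...) x$totals

#' Fully incremental cost-utility comparison
#'
#' Regimens are ordered by QALYs; each is compared with the previous
#' non-dominated regimen.  A strategy is `dominant` over the comparison when
#' it costs less and yields more QALYs, `dominated` conversely; otherwise
#' the ICUR (incremental cost per QALY gained) is reported.  Net monetary
#' benefit is computed at `wtp`.
#'
#' @param results List of `osteo_accrual` objects (or a tibble of their
#'   totals).
#' @param wtp Willingness-to-pay (CAD/QALY) for NMB (default 50000).
#' @return An object of class `osteo_cea` with `totals` and pairwise
#'   `comparisons` tibbles.
#' @export
compare_regimens <- function(results, wtp = 50000) {
  totals <- if (tibble::is_tibble(results)) results else
    dplyr::bind_rows(purrr::map(results, "totals"))
  if (nrow(totals) < 2) abort("compare_regimens: need at least 2 regimens")
  ord <- totals[order(totals$qalys, totals$cost), ]

  comparisons <- purrr::map_dfr(seq_len(nrow(ord))[-1], function(i) {
    ref <- ord[i - 1, ]
    cur <- ord[i, ]
    d_cost <- cur$cost - ref$cost
    d_qalys <- cur$qalys - ref$qalys
    tibble::tibble(
      regimen = cur$regimen,
      comparator = ref$regimen,
      d_cost = d_cost,
      d_qalys = d_qalys,
      icur = dplyr::case_when(
        d_cost < 0 & d_qalys > 0 ~ NA_real_,
        d_cost > 0 & d_qalys < 0 ~ NA_real_,
        d_qalys == 0 ~ NA_real_,
        TRUE ~ d_cost / d_qalys
      ),
      status = dplyr::case_when(
        d_cost < 0 & d_qalys >= 0 ~ "dominant",
        d_cost >= 0 & d_qalys < 0 ~ "dominated",
        TRUE ~ "trade-off"
      ),
      nmb = wtp * d_qalys - d_cost
    )
  })
  structure(list(totals = ord, comparisons = comparisons, wtp = wtp),
            class = "osteo_cea")
}

#' Incremental comparison of two named regimens
#'
#' @param results List of `osteo_accrual` objects or tibble of totals.
#' @param regimen,comparator Regimen names.
#' @param wtp Willingness-to-pay for NMB.
#' @return One-row tibble with `d_cost`, `d_qalys`, `icur`, `status`, `nmb`.
#' @export
incremental <- function(results, regimen, comparator, wtp = 50000) {
  totals <- if (tibble::is_tibble(results)) results else
    dplyr::bind_rows(purrr::map(results, "totals"))
  a <- totals[totals$regimen == regimen, ]
  b <- totals[totals$regimen == comparator, ]
  if (!nrow(a) || !nrow(b)) abort("incremental: unknown regimen name")
  d_cost <- a$cost - b$cost
  d_qalys <- a$qalys - b$qalys
  tibble::tibble(
    regimen = regimen, comparator = comparator,
    d_cost = d_cost, d_qalys = d_qalys,
    icur = if (d_cost < 0 && d_qalys > 0) NA_real_
           else if (d_qalys == 0) NA_real_ else d_cost / d_qalys,
    status = if (d_cost < 0 && d_qalys >= 0) "dominant"
             else if (d_cost >= 0 && d_qalys < 0) "dominated" else "trade-off",
    nmb = wtp * d_qalys - d_cost
  )
}

#' @export
print.osteo_cea <- function(x, ...) {
  cat("<osteo_cea> fully incremental comparison (wtp =",
      format(x$wtp, big.mark = ","), "CAD/QALY)\n")
  print(as.data.frame(dplyr::mutate(
    x$comparisons,
    d_cost = round(.data$d_cost), d_qalys = round(.data$d_qalys, 3),
    icur = round(.data$icur), nmb = round(.data$nmb)
  )), row.names = FALSE)
  invisible(x)
}

#' @export
tidy.osteo_cea <- function(x, ...) x$comparisons

#' @export
glance.osteo_cea <- function(x, ...) {
  best <- x$totals[which.max(x$wtp * x$totals$qalys - x$totals$cost), ]
  tibble::tibble(
    n_regimens = nrow(x$totals),
    wtp = x$wtp,
    optimal = best$regimen,
    max_qalys = max(x$totals$qalys),
    min_cost = min(x$totals$cost)
  )
}
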