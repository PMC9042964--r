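# Markov cohort engine: 7-state hierarchical fracture model expanded into
# cycle-resolution tunnel states (year-since-event bookkeeping for mortality,
# utilities and costs), run over a lifetime horizon.
#
# Hierarchy (most severe first): hip > vertebral > other.  Occupancy never
# flows from a hip state to a vertebral/other fracture state; undercounted
# lower-hierarchy events are added to the fracture ledger by a correction
# term that does not move occupancy.

#' Expanded state space of the cohort model
#'
#' The seven health states (at-risk, hip, post-hip, vertebral,
#' post-vertebral, other, dead) are expanded into cycle-resolution tunnel
#' layers: the acute hip/vertebral states last 2 cycles (1 year), the post
#' states carry a year-since-event clock up to `depth_years` (mortality RR
#' bands are yearly), the "other" state lasts 2 cycles and returns to
#' at-risk.
#'
#' @param depth_years Tunnel depth in years for post-fracture states
#'   (default 8, the excess-mortality window).
#' @return A list describing the expanded state space (indices, branches,
#'   allowed fracture exits, tunnel-advance map, multiplier categories).
#' @export
state_space <- function(depth_years = 8) {
  depth_years <- max(2, ceiling(depth_years))
  key <- as.character(depth_years)
  cached <- .state_space_cache[[key]]
  if (!is.null(cached)) return(cached)
  post_cycles <- 3:(2 * depth_years)            # years 2..depth
  blocks <- list(
    tibble::tibble(name = "atrisk", branch = "atrisk", phase = "atrisk",
                   cycle_since = NA_integer_),
    tibble::tibble(name = c("hip_a1", "hip_a2"), branch = "hip",
                   phase = "acute", cycle_since = 1:2),
    tibble::tibble(name = paste0("hip_p", post_cycles), branch = "hip",
                   phase = "post", cycle_since = post_cycles),
    tibble::tibble(name = "hip_late", branch = "hip", phase = "late",
                   cycle_since = 2L * depth_years + 1L),
    tibble::tibble(name = c("vert_a1", "vert_a2"), branch = "vertebral",
                   phase = "acute", cycle_since = 1:2),
    tibble::tibble(name = paste0("vert_p", post_cycles), branch = "vertebral",
                   phase = "post", cycle_since = post_cycles),
    tibble::tibble(name = "vert_late", branch = "vertebral", phase = "late",
                   cycle_since = 2L * depth_years + 1L),
    tibble::tibble(name = c("other_1", "other_2"), branch = "other",
                   phase = "other", cycle_since = 1:2),
    tibble::tibble(name = "dead", branch = "dead", phase = "dead",
                   cycle_since = NA_integer_)
  )
  states <- dplyr::bind_rows(blocks)
  n <- nrow(states)
  states$id <- seq_len(n)
  states$years_since <- ceiling(states$cycle_since / 2)

  idx <- function(nm) states$id[states$name == nm]
  entry <- c(hip = idx("hip_a1"), vertebral = idx("vert_a1"), other = idx("other_1"))
  i_dead <- idx("dead")
  i_atrisk <- idx("atrisk")

  # allowed fracture exits enforce the severity hierarchy
  allowed <- matrix(FALSE, n, 3, dimnames = list(states$name, FRACTURE_TYPES))
  allowed[states$branch == "atrisk", ] <- TRUE
  allowed[states$branch == "other", ] <- TRUE
  allowed[states$branch == "hip", "hip"] <- TRUE
  allowed[states$branch == "vertebral", c("hip", "vertebral")] <- TRUE
  allowed[states$branch == "dead", ] <- FALSE

  # tunnel advance (target when no fracture and no death)
  adv <- integer(n)
  for (i in seq_len(n)) {
    b <- states$branch[i]
    cs <- states$cycle_since[i]
    adv[i] <-
      if (b == "atrisk") i_atrisk
      else if (b == "dead") i_dead
      else if (b == "other") { if (cs == 1) idx("other_2") else i_atrisk }
      else if (states$phase[i] == "late") i
      else {  # acute/post hip or vertebral: age one cycle, cap at late
        nxt <- states$id[states$branch == b &
                           !is.na(states$cycle_since) &
                           states$cycle_since == cs + 1]
        if (length(nxt)) nxt else states$id[states$branch == b & states$phase == "late"]
      }
  }
  adv_mat <- matrix(0, n, n)
  adv_mat[cbind(seq_len(n), adv)] <- 1

  mult_cat <- dplyr::case_when(
    states$branch == "atrisk" ~ "atrisk",
    states$branch == "dead" ~ "dead",
    states$branch == "other" ~ "other_first",
    states$phase == "acute" & states$branch == "hip" ~ "hip_first",
    states$phase == "acute" & states$branch == "vertebral" ~ "vert_first",
    states$branch == "hip" ~ "hip_subseq",
    TRUE ~ "vert_subseq"
  )

  out <- list(n = n, states = states, depth_years = depth_years,
              entry = entry, i_dead = i_dead, i_atrisk = i_atrisk,
              allowed = allowed, advance = adv, adv_mat = adv_mat,
              mult_cat = mult_cat,
              alive = states$branch != "dead",
              hip_branch = states$branch == "hip",
              vert_branch = states$branch == "vertebral")
  .state_space_cache[[key]] <- out
  out
}

.state_space_cache <- new.env(parent = emptyenv())

#' Build a single-cycle transition matrix
#'
#' Places the supplied per-cycle exit probabilities directly: each state's
#' allowed fracture exits and its death probability leave the state; the
#' remainder follows the tunnel-advance map (at-risk stays, acute states age
#' into post states, "other" returns to at-risk after 2 cycles).  Rows sum
#' to 1 exactly; forbidden transitions are structurally zero.
#'
#' @param ss A [state_space()].
#' @param fracture_probs Named length-3 vector (`hip`, `vertebral`, `other`)
#'   of per-cycle fracture probabilities, or an `n x 3` matrix of per-state
#'   probabilities (already competing-risk allocated).
#' @param death_probs Scalar or length-`n` vector of per-cycle death
#'   probabilities.
#' @return An `n x n` transition matrix.
#' @export
build_matrix <- function(ss, fracture_probs, death_probs) {
  n <- ss$n
  if (is.null(dim(fracture_probs))) {
    fracture_probs <- matrix(rep(fracture_probs[FRACTURE_TYPES], each = n), n, 3,
                             dimnames = list(NULL, FRACTURE_TYPES))
  }
  fp <- fracture_probs * ss$allowed
  dp <- rep_len(death_probs, n)
  dp[!ss$alive] <- 0
  exit <- rowSums(fp) + dp
  if (any(exit > 1 + 1e-12)) {
    abort("build_matrix: competing exit probabilities exceed 1 (mis-scaled rates?)")
  }
  M <- ss$adv_mat * (1 - exit)
  for (ty in FRACTURE_TYPES) {
    M[, ss$entry[[ty]]] <- M[, ss$entry[[ty]]] + fp[, ty]
  }
  M[, ss$i_dead] <- M[, ss$i_dead] + dp
  M[ss$i_dead, ] <- 0
  M[ss$i_dead, ss$i_dead] <- 1
  M
}

# Precompute per-cycle, age-dependent inputs shared by every regimen run.
prepare_run_inputs <- function(config) {
  a0 <- config$population$mean_age
  econ <- config$econ
  t_max <- ceiling((econ$runoff_age - a0) / CYCLE_YEARS) + 1L
  ages <- a0 + (seq_len(t_max) - 1) * CYCLE_YEARS

  epi <- config$epi
  gen <- sapply(FRACTURE_TYPES, function(ty)
    interpolate_age_rate(epi$fracture_incidence, ages, col = ty))
  adj <- config$risk_adj
  base_rates <- sapply(FRACTURE_TYPES, function(ty)
    adjust_baseline_risk(gen[, ty], adj, ty))

  qx <- pmin(pmax(interpolate_age_rate(epi$mortality, ages, col = "qx"), 0), 1)
  lambda <- prob_annual_to_rate(qx)

  band_rr <- function(ty, band) {
    tbl <- epi$mortality_rr[epi$mortality_rr$fracture_type == ty &
                              epi$mortality_rr$year_band == band, ]
    if (!nrow(tbl)) rep(1, t_max) else lookup_age_band(tbl, ages, "rr")
  }
  rr_bands <- cbind(none = rep(1, t_max),
                    hip_first = band_rr("hip", "first"),
                    hip_subseq = band_rr("hip", "subsequent"),
                    vert_first = band_rr("vertebral", "first"),
                    vert_subseq = band_rr("vertebral", "subsequent"),
                    other_first = band_rr("other", "first"))

  util <- lookup_age_band(epi$utilities, ages, "utility")
  fy_cost <- sapply(FRACTURE_TYPES, function(ty) {
    tbl <- config$costs$first_year[config$costs$first_year$fracture_type == ty, ]
    lookup_age_band(tbl, ages, "cost")
  })

  list(a0 = a0, t_max = t_max, ages = ages, base_rates = base_rates,
       lambda = lambda, rr_bands = rr_bands, util = util, fy_cost = fy_cost)
}

# Map each expanded state to its mortality RR band column for this config.
state_band_index <- function(ss, modifier) {
  st <- ss$states
  cols <- c("none", "hip_first", "hip_subseq", "vert_first", "vert_subseq",
            "other_first")
  band <- vapply(seq_len(ss$n), function(i) {
    b <- st$branch[i]
    if (b %in% c("atrisk", "dead")) return("none")
    ty <- if (b == "other") "other" else b
    y <- st$years_since[i]
    if (modifier$hip_only_first_year && (ty != "hip" || y > 1)) return("none")
    if (y > modifier$excess_duration[[ty]]) return("none")
    if (y <= 1) paste0(switch(ty, hip = "hip", vertebral = "vert", other = "other"),
                       "_first")
    else if (ty == "other") "none"
    else paste0(switch(ty, hip = "hip", vertebral = "vert"), "_subseq")
  }, character(1))
  match(band, cols)
}

# Per-cycle treatment RR by fracture type: schedule during treatment, then
# linear offset of the end-of-treatment benefit.
treatment_rr_cycle <- function(regimen, t) {
  sched <- regimen$rr_schedule
  td <- regimen$treatment_duration
  if (t <= td) {
    unlist(sched[sched$cycle == t, FRACTURE_TYPES])
  } else {
    base <- unlist(sched[sched$cycle == td, FRACTURE_TYPES])
    offset_rr(base, (t - td - 1) * CYCLE_YEARS, regimen$offset_duration)
  }
}

# full t_max x 3 treatment RR matrix (treatment cycles, then linear offset)
treatment_rr_matrix <- function(regimen, t_max) {
  sched <- regimen$rr_schedule[order(regimen$rr_schedule$cycle), ]
  td <- regimen$treatment_duration
  m <- matrix(1, t_max, 3, dimnames = list(NULL, FRACTURE_TYPES))
  on_tx <- seq_len(min(td, t_max))
  m[on_tx, ] <- as.matrix(sched[on_tx, FRACTURE_TYPES])
  if (t_max > td) {
    base <- unlist(sched[td, FRACTURE_TYPES])
    post <- (td + 1):t_max
    t_since <- (post - td - 1) * CYCLE_YEARS
    for (ty in FRACTURE_TYPES) {
      m[post, ty] <- offset_rr(base[[ty]], t_since, regimen$offset_duration)
    }
  }
  m
}

#' Run the cohort trace for one regimen
#'
#' Propagates 1000 persons from baseline age over a lifetime horizon
#' (fracture and death transitions to `max_age`, then a mortality-only
#' run-off until cohort extinction or `runoff_age`).  Per cycle, competing
#' events are allocated proportionally from summed hazard rates; treatment
#' relative risks follow the regimen schedule during treatment and the
#' linear offset afterwards.
#'
#' @param config An `osteo_config`.
#' @param regimen An `osteo_regimen` or the name of one in `config$regimens`.
#' @param prepared Optional precomputed inputs (internal, for repeated runs).
#' @return An object of class `osteo_trace`: occupancy matrix (cycles x
#'   expanded states, start-of-cycle, per 1000 persons), ages, the fracture
#'   ledger (direct and hierarchy-corrected events), and the state space.
#' @export
run_trace <- function(config, regimen, prepared = NULL) {
  if (is.character(regimen)) regimen <- config$regimens[[regimen]]
  if (is.null(regimen)) abort("run_trace: unknown regimen")
  if (is.null(prepared)) prepared <- prepare_run_inputs(config)
  mm <- config$mortality_mod
  ss <- state_space(max(8, max(mm$excess_duration[c("hip", "vertebral")])))
  band_idx <- state_band_index(ss, mm)
  frac <- mm$attributable_fraction
  n <- ss$n
  t_max <- prepared$t_max
  max_age <- config$econ$max_age

  occ <- matrix(0, t_max, n, dimnames = list(NULL, ss$states$name))
  ev_direct <- matrix(0, t_max, 3, dimnames = list(NULL, FRACTURE_TYPES))
  ev_corr <- matrix(0, t_max, 2, dimnames = list(NULL, c("vertebral", "other")))

  v <- numeric(n)
  v[ss$i_atrisk] <- 1000
  allowed <- ss$allowed
  rr_treat_m <- treatment_rr_matrix(regimen, t_max)
  t_used <- t_max

  for (t in seq_len(t_max)) {
    occ[t, ] <- v
    alive_mass <- 1000 - v[ss$i_dead]
    if (alive_mass < 1e-6) { t_used <- t; break }

    age <- prepared$ages[t]
    r_f <- prepared$base_rates[t, ] * rr_treat_m[t, ]
    if (age > max_age) r_f[] <- 0           # mortality-only run-off

    rr_obs <- prepared$rr_bands[t, band_idx]
    r_d <- prepared$lambda[t] * attributable_rr(rr_obs, frac)
    r_d[!ss$alive] <- 0

    R <- as.vector(allowed %*% r_f) + r_d
    p_exit <- 1 - exp(-R * CYCLE_YEARS)
    share <- ifelse(R > 0, p_exit / R, 0)
    alloc_f <- (allowed * rep(r_f, each = n)) * share
    alloc_d <- r_d * share

    ev <- as.vector(v %*% alloc_f)
    dead_in <- sum(v * alloc_d)

    v_stay <- v * (1 - p_exit)
    v_next <- as.vector(v_stay %*% ss$adv_mat)
    v_next[ss$entry] <- v_next[ss$entry] + ev
    v_next[ss$i_dead] <- v_next[ss$i_dead] + dead_in

    p_marg <- 1 - exp(-r_f * CYCLE_YEARS)
    hip_occ <- sum(v[ss$hip_branch])
    vert_occ <- sum(v[ss$vert_branch])
    ev_direct[t, ] <- ev
    ev_corr[t, "vertebral"] <- hip_occ * p_marg[["vertebral"]]
    ev_corr[t, "other"] <- (hip_occ + vert_occ) * p_marg[["other"]]

    v <- v_next
    t_used <- t
  }

  keep <- seq_len(t_used)
  structure(
    list(occupancy = occ[keep, , drop = FALSE],
         ages = prepared$ages[keep],
         events = ev_direct[keep, , drop = FALSE],
         events_corrected = ev_corr[keep, , drop = FALSE],
         state_space = ss,
         regimen = regimen$name,
         cohort = 1000,
         final = v),
    class = "osteo_trace"
  )
}

#' Aggregate a trace to the seven model health states
#'
#' @param x An `osteo_trace`.
#' @param ... Unused.
#' @return Tibble: `cycle`, `age`, occupancy of the seven states per 1000,
#'   and per-cycle fracture events (direct and hierarchy-corrected).
#' @export
tidy.osteo_trace <- function(x, ...) {
  st <- x$state_space$states
  agg <- function(sel) rowSums(x$occupancy[, sel, drop = FALSE])
  tibble::tibble(
    cycle = seq_along(x$ages),
    age = x$ages,
    at_risk = x$occupancy[, x$state_space$i_atrisk],
    hip = agg(st$branch == "hip" & st$phase == "acute"),
    post_hip = agg(st$branch == "hip" & st$phase != "acute"),
    vertebral = agg(st$branch == "vertebral" & st$phase == "acute"),
    post_vertebral = agg(st$branch == "vertebral" & st$phase != "acute"),
    other = agg(st$branch == "other"),
    dead = x$occupancy[, x$state_space$i_dead],
    events_hip = x$events[, "hip"],
    events_vertebral = x$events[, "vertebral"],
    events_other = x$events[, "other"],
    corrected_vertebral = x$events_corrected[, "vertebral"],
    corrected_other = x$events_corrected[, "other"]
  )
}

#' @export
print.osteo_trace <- function(x, ...) {
  led <- fracture_ledger(x)
  cat("<osteo_trace>", x$regimen, "|", length(x$ages), "cycles | ages",
      min(x$ages), "-", round(max(x$ages), 1), "\n")
  cat("  lifetime fractures per 1000:",
      paste(names(led$total), round(led$total, 1), collapse = ", "), "\n")
  invisible(x)
}

#' Lifetime fracture counts from a trace
#'
#' Direct transitions plus hierarchy-corrected additions, per 1000 persons.
#'
#' @param trace An `osteo_trace`.
#' @return List with `per_cycle` tibble and `total` named vector
#'   (hip, vertebral, other, total).
#' @export
fracture_ledger <- function(trace) {
  per_cycle <- tibble::tibble(
    cycle = seq_along(trace$ages),
    age = trace$ages,
    hip = trace$events[, "hip"],
    vertebral = trace$events[, "vertebral"] + trace$events_corrected[, "vertebral"],
    other = trace$events[, "other"] + trace$events_corrected[, "other"]
  )
  total <- c(hip = sum(per_cycle$hip),
             vertebral = sum(per_cycle$vertebral),
             other = sum(per_cycle$other))
  total <- c(total, total = sum(total))
  list(per_cycle = per_cycle, total = total)
}

#' Individual-level microsimulation oracle
#'
#' Simulates `n_individuals` through the same per-cycle transition
#' probabilities as the cohort trace; used to validate the cohort engine
#' (occupancies agree within Monte-Carlo error).
#'
#' @param config An `osteo_config`.
#' @param regimen Regimen (object or name).
#' @param n_individuals Number of simulated individuals.
#' @param seed Integer seed.
#' @return An `osteo_trace` (occupancy scaled to per 1000).
#' @export
microsim_oracle <- function(config, regimen, n_individuals = 10000, seed = 1L) {
  if (is.character(regimen)) regimen <- config$regimens[[regimen]]
  if (n_individuals < 1) abort("microsim_oracle: n_individuals must be >= 1")
  set.seed(seed)
  prepared <- prepare_run_inputs(config)
  mm <- config$mortality_mod
  ss <- state_space(max(8, max(mm$excess_duration[c("hip", "vertebral")])))
  band_idx <- state_band_index(ss, mm)
  frac <- mm$attributable_fraction
  n <- ss$n
  t_max <- prepared$t_max
  max_age <- config$econ$max_age
  scale <- 1000 / n_individuals

  occ <- matrix(0, t_max, n, dimnames = list(NULL, ss$states$name))
  ev_direct <- matrix(0, t_max, 3, dimnames = list(NULL, FRACTURE_TYPES))
  ev_corr <- matrix(0, t_max, 2, dimnames = list(NULL, c("vertebral", "other")))

  counts <- integer(n)
  counts[ss$i_atrisk] <- n_individuals
  rr_treat_m <- treatment_rr_matrix(regimen, t_max)
  t_used <- t_max

  for (t in seq_len(t_max)) {
    occ[t, ] <- counts * scale
    if (sum(counts[ss$alive]) == 0) { t_used <- t; break }

    age <- prepared$ages[t]
    r_f <- prepared$base_rates[t, ] * rr_treat_m[t, ]
    if (age > max_age) r_f[] <- 0
    rr_obs <- prepared$rr_bands[t, band_idx]
    r_d <- prepared$lambda[t] * attributable_rr(rr_obs, frac)
    r_d[!ss$alive] <- 0

    R <- as.vector(ss$allowed %*% r_f) + r_d
    p_exit <- 1 - exp(-R * CYCLE_YEARS)
    share <- ifelse(R > 0, p_exit / R, 0)
    alloc_f <- (ss$allowed * rep(r_f, each = n)) * share
    alloc_d <- r_d * share
    p_marg <- 1 - exp(-r_f * CYCLE_YEARS)

    new_counts <- integer(n)
    for (s in which(counts > 0)) {
      probs <- c(alloc_f[s, ], alloc_d[s], 1 - sum(alloc_f[s, ]) - alloc_d[s])
      draw <- as.vector(stats::rmultinom(1, counts[s], probs))
      ev_direct[t, ] <- ev_direct[t, ] + draw[1:3] * scale
      new_counts[ss$entry] <- new_counts[ss$entry] + draw[1:3]
      new_counts[ss$i_dead] <- new_counts[ss$i_dead] + draw[4]
      new_counts[ss$advance[s]] <- new_counts[ss$advance[s]] + draw[5]
    }
    hip_n <- sum(counts[ss$hip_branch])
    vert_n <- sum(counts[ss$vert_branch])
    if (hip_n > 0) {
      ev_corr[t, "vertebral"] <- stats::rbinom(1, hip_n, p_marg[["vertebral"]]) * scale
    }
    if (hip_n + vert_n > 0) {
      ev_corr[t, "other"] <- stats::rbinom(1, hip_n + vert_n, p_marg[["other"]]) * scale
    }
    counts <- new_counts
    t_used <- t
  }

  keep <- seq_len(t_used)
  structure(
    list(occupancy = occ[keep, , drop = FALSE],
         ages = prepared$ages[keep],
         events = ev_direct[keep, , drop = FALSE],
         events_corrected = ev_corr[keep, , drop = FALSE],
         state_space = ss,
         regimen = regimen$name,
         cohort = 1000,
         n_individuals = n_individuals,
         final = counts * scale),
    class = "osteo_trace"
  )
}
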