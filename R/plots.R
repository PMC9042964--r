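# ggplot2 displays for model results.

#' Plot cost-effectiveness acceptability curves
#'
#' @param psa An `osteo_psa`.
#' @return A ggplot.
#' @export
plot_ceac <- function(psa) {
  ggplot2::ggplot(psa$ceac,
                  ggplot2::aes(x = .data$wtp, y = .data$probability,
                               colour = .data$regimen)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::scale_x_continuous(labels = function(x) format(x, big.mark = ",")) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay (CAD per QALY)",
                  y = "Probability cost-effective",
                  colour = "Regimen",
                  title = "Cost-effectiveness acceptability curves") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.osteo_psa <- function(object, ...) plot_ceac(object)

#' Plot the PSA scatter (incremental cost vs incremental QALYs)
#'
#' @param psa An `osteo_psa`.
#' @param regimen,comparator Regimen names; defaults to the first two.
#' @return A ggplot.
#' @export
plot_psa_scatter <- function(psa, regimen = NULL, comparator = NULL) {
  regs <- psa$regimens
  regimen <- regimen %||% regs[1]
  comparator <- comparator %||% regs[2]
  it <- psa$iterations
  a <- it[it$regimen == regimen, ]
  b <- it[it$regimen == comparator, ]
  d <- tibble::tibble(d_cost = a$cost - b$cost, d_qalys = a$qalys - b$qalys)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$d_qalys, y = .data$d_cost)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost (CAD)",
                  title = paste(regimen, "vs", comparator)) +
    ggplot2::theme_minimal()
}

#' Tornado diagram of one-way sensitivity results
#'
#' @param dsa An `osteo_dsa`.
#' @param top Number of parameters shown (default all).
#' @return A ggplot.
#' @export
plot_tornado <- function(dsa, top = Inf) {
  d <- utils::head(dsa$results, top)
  d$label <- factor(d$label, levels = rev(d$label))
  ggplot2::ggplot(d) +
    ggplot2::geom_segment(ggplot2::aes(y = .data$label, yend = .data$label,
                                       x = .data$inmb_low, xend = .data$inmb_high),
                          linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = dsa$base_inmb, linetype = 2) +
    ggplot2::labs(x = paste0("INMB (", dsa$regimen, " vs ", dsa$comparator,
                             ") at WTP ", format(dsa$wtp, big.mark = ",")),
                  y = NULL, title = "One-way sensitivity (tornado)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.osteo_dsa <- function(object, ...) plot_tornado(object, ...)

#' Plot cohort-state occupancy over time
#'
#' @param trace An `osteo_trace`.
#' @return A ggplot of the seven aggregated health states.
#' @export
plot_trace <- function(trace) {
  d <- tidy(trace) |>
    tidyr::pivot_longer(cols = c("at_risk", "hip", "post_hip", "vertebral",
                                 "post_vertebral", "other", "dead"),
                        names_to = "state", values_to = "occupancy")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$age, y = .data$occupancy,
                                  fill = .data$state)) +
    ggplot2::geom_area() +
    ggplot2::labs(x = "Age (years)", y = "Persons (per 1000)",
                  title = paste("Cohort trace:", trace$regimen)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.osteo_trace <- function(object, ...) plot_trace(object)
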