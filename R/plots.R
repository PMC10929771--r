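# ggplot2 displays for the result types.

#' Cost-effectiveness plane for a strategy comparison
#'
#' @param object An `ecea_comparison` from [compare_strategies()].
#' @param ... Unused.
#' @return A ggplot: incremental DALYs averted per person against incremental
#'   cost per person, with the threshold line whose slope is the
#'   cost-effectiveness threshold.
#' @export
autoplot.ecea_comparison <- function(object, ...) {
  run <- attr(object, "base_run")
  thr <- if (!is.null(run)) run$ce_threshold else 3015
  ggplot2::ggplot(
    as_tibble(object),
    ggplot2::aes(
      x = .data$d_daly_pp, y = .data$d_cost_pp,
      colour = .data$arm, shape = .data$eligibility
    )
  ) +
    ggplot2::geom_abline(slope = thr, intercept = 0, linetype = 2) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey70") +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(
      x = "Incremental DALYs averted per person",
      y = "Incremental cost per person (USD)",
      title = "Cost-effectiveness plane",
      subtitle = sprintf("Dashed line: $%g per DALY averted", thr)
    ) +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness acceptability curves
#'
#' @param object An `ecea_psa` (curves are computed with [ceac()]) or an
#'   `ecea_ceac` tibble.
#' @param wtp_grid Grid used when `object` is an `ecea_psa`.
#' @param ... Unused.
#' @return A ggplot of the probability each arm is optimal against
#'   willingness to pay.
#' @export
autoplot.ecea_psa <- function(object, wtp_grid = seq(0, 6000, by = 250), ...) {
  autoplot.ecea_ceac(ceac(object, wtp_grid))
}

#' @rdname autoplot.ecea_psa
#' @export
autoplot.ecea_ceac <- function(object, ...) {
  ggplot2::ggplot(
    as_tibble(object),
    ggplot2::aes(x = .data$wtp, y = .data$probability, colour = .data$arm)
  ) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = "Willingness to pay (USD per DALY averted)",
      y = "Probability most cost-effective",
      title = "Cost-effectiveness acceptability curves"
    ) +
    ggplot2::theme_minimal()
}

#' Tornado diagram for one-way sensitivity analyses
#'
#' @param object An `ecea_tornado` from [one_way()] or [tornado_scenarios()].
#' @param ... Unused.
#' @return A ggplot with one bar per (parameter, arm) spanning the INMB at the
#'   low and high parameter values.
#' @export
autoplot.ecea_tornado <- function(object, ...) {
  df <- as_tibble(object) %>%
    mutate(label = paste(.data$parameter, .data$arm, sep = " | ")) %>%
    arrange(.data$swing) %>%
    mutate(label = factor(.data$label, levels = unique(.data$label)))
  ggplot2::ggplot(df, ggplot2::aes(y = .data$label)) +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60", linetype = 2) +
    ggplot2::geom_segment(
      ggplot2::aes(
        x = .data$inmb_low, xend = .data$inmb_high,
        yend = .data$label, colour = .data$arm
      ),
      linewidth = 4
    ) +
    ggplot2::labs(
      x = "Incremental net monetary benefit per person (USD)", y = NULL,
      title = "One-way sensitivity analyses"
    ) +
    ggplot2::theme_minimal()
}
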