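#' Plot the vulnerability-reliance classification
#'
#' Scatter of mean SSF contribution against mean prevalence of inadequate
#' intake, with the percentile cutoffs drawn as dashed lines and the
#' absolute thresholds as dotted lines; countries lacking intake data are
#' shown along the x axis as "vulnerability unknown".
#'
#' @param object An `ssf_classification`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ssf_classification <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    mutate(status = dplyr::case_when(
      is.na(.data$vulnerable_percentile) & .data$reliant_percentile ~
        "reliant, vulnerability unknown",
      is.na(.data$vulnerable_percentile) ~ "vulnerability unknown",
      .data$reliant_percentile & .data$vulnerable_percentile ~
        "reliant & vulnerable",
      .data$reliant_percentile ~ "reliant",
      .data$vulnerable_percentile ~ "vulnerable",
      TRUE ~ "neither"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_ssf_contribution,
                                   y = .data$mean_inadequate_intake,
                                   colour = .data$status)) +
    ggplot2::geom_point(size = 2, na.rm = TRUE) +
    ggplot2::geom_vline(xintercept = attr(object, "supply_cutoff"),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_hline(yintercept = attr(object, "intake_cutoff"),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_vline(xintercept = attr(object, "supply_threshold"),
                        linetype = "dotted", colour = "grey60") +
    ggplot2::geom_hline(yintercept = attr(object, "intake_threshold"),
                        linetype = "dotted", colour = "grey60") +
    ggplot2::scale_x_continuous(labels = function(v) sprintf("%.0f%%",
                                                             100 * v)) +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%",
                                                             100 * v)) +
    ggplot2::labs(x = "Mean SSF contribution to nutrient supply",
                  y = "Mean prevalence of inadequate intake",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.ssf_classification
#' @export
autoplot.ssf_run <- function(object, ...) {
  autoplot(object$classification, ...)
}

#' Plot SSF contribution fractions by nutrient and scope
#'
#' Distribution of per-country SSF contribution fractions for each nutrient,
#' faceted by denominator scope.
#'
#' @param records Output of [ssf_contribution()].
#' @return A ggplot.
#' @export
plot_contributions <- function(records) {
  ggplot2::ggplot(records |> filter(!is.na(.data$ssf_fraction)),
                  ggplot2::aes(x = .data$nutrient, y = .data$ssf_fraction)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(~denominator_scope, ncol = 1) +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%",
                                                             100 * v)) +
    ggplot2::labs(x = NULL, y = "SSF share of nutrient supply") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Plot a sensitivity sweep
#'
#' Percentile sweeps show reliant/vulnerable counts against the percentile;
#' pipeline sweeps (buffer distance, artisanal trade) show the per-country
#' all-foods mean contribution across levels.
#'
#' @param object An `ssf_sensitivity`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ssf_sensitivity <- function(object, ...) {
  if (object$axis == "percentile") {
    df <- object$summary |>
      select("percentile", reliant = "n_reliant_percentile",
             vulnerable = "n_vulnerable_percentile") |>
      tidyr::pivot_longer(c("reliant", "vulnerable"), names_to = "flag",
                          values_to = "n")
    ggplot2::ggplot(df, ggplot2::aes(x = .data$percentile, y = .data$n,
                                     colour = .data$flag)) +
      ggplot2::geom_step(direction = "hv") +
      ggplot2::geom_point() +
      ggplot2::labs(x = "Classification percentile", y = "Countries flagged",
                    colour = NULL) +
      ggplot2::theme_minimal()
  } else {
    df <- object$summary$by_country |>
      mutate(level = factor(.data$level, levels = unique(.data$level)))
    ggplot2::ggplot(df, ggplot2::aes(x = .data$level,
                                     y = .data$mean_fraction,
                                     group = .data$country)) +
      ggplot2::geom_line(alpha = 0.4) +
      ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%",
                                                               100 * v)) +
      ggplot2::labs(x = object$axis,
                    y = "Mean SSF share of all-food nutrient supply") +
      ggplot2::theme_minimal()
  }
}
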