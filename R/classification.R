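#' Classify countries by SSF reliance and nutritional vulnerability
#'
#' Applies two rule families and emits both. Percentile rules: a country is
#' reliant (vulnerable) when its mean SSF contribution (mean prevalence of
#' inadequate intake) lies strictly above the interpolated percentile cutoff
#' of the cross-country distribution — i.e. within the 70th-100th percentile
#' band under the default. Absolute rules: reliant when the mean SSF
#' contribution is at least `supply_threshold` (default 15%), vulnerable
#' when the mean prevalence of inadequate intake is at least
#' `intake_threshold` (default 50%); both boundaries inclusive. Countries
#' without inadequate-intake data keep `NA` vulnerability flags — "reliant,
#' vulnerability unknown" rather than not vulnerable — and are excluded
#' from the intake percentile distribution.
#'
#' @param contributions Per-country mean SSF contribution: `country` plus
#'   `mean_fraction` (as from [mean_contribution()]) or
#'   `mean_ssf_contribution`.
#' @param inadequate Either per-country means (`country`,
#'   `mean_inadequate_intake` or `prevalence`) or per-nutrient prevalences
#'   (`country`, `nutrient`, `prevalence`), averaged over `nutrients`.
#' @param percentile Percentile for the distribution-based rules.
#' @param supply_threshold,intake_threshold Absolute-rule thresholds.
#' @param nutrients Nutrient set for averaging per-nutrient prevalences.
#' @return A tibble of class `ssf_classification`: `country`,
#'   `mean_ssf_contribution`, `mean_inadequate_intake`,
#'   `reliant_percentile`, `vulnerable_percentile`, `reliant_absolute`,
#'   `vulnerable_absolute`; cutoffs and parameters in attributes
#'   (see [glance.ssf_classification()]).
#' @examples
#' contrib <- tibble::tibble(country = sprintf("C%02d", 1:10),
#'                           mean_fraction = seq(0.01, 0.10, by = 0.01))
#' intake <- tibble::tibble(country = sprintf("C%02d", 1:10),
#'                          mean_inadequate_intake = seq(0.1, 1, by = 0.1))
#' classify(contrib, intake)
#' @export
classify <- function(contributions, inadequate, percentile = 0.70,
                     supply_threshold = 0.15, intake_threshold = 0.50,
                     nutrients = ASSESSED_NUTRIENTS) {
  assert_fraction(percentile, "percentile")
  assert_fraction(supply_threshold, "supply_threshold")
  assert_fraction(intake_threshold, "intake_threshold")
  contrib <- standardise_country_value(
    contributions, c("mean_ssf_contribution", "mean_fraction"),
    "mean_ssf_contribution")
  if (!is.null(inadequate) && "nutrient" %in% names(inadequate)) {
    inadequate <- inadequate |>
      filter(.data$nutrient %in% nutrients) |>
      group_by(.data$country) |>
      summarise(mean_inadequate_intake = mean(.data$prevalence,
                                              na.rm = TRUE),
                .groups = "drop")
  }
  intake <- if (is.null(inadequate)) {
    tibble::tibble(country = contrib$country,
                   mean_inadequate_intake = NA_real_)
  } else {
    standardise_country_value(
      inadequate, c("mean_inadequate_intake", "prevalence"),
      "mean_inadequate_intake")
  }
  df <- contrib |> left_join(intake, by = "country")
  if (sum(!is.na(df$mean_ssf_contribution)) < 2) {
    stop_data("classification needs at least two countries with data")
  }
  cut_sup <- percentile_cutoff(df$mean_ssf_contribution, percentile)
  cut_int <- percentile_cutoff(df$mean_inadequate_intake, percentile)
  # strictly above the cutoff, except that the 0th percentile band covers
  # every country with data (the minimum equals its own cutoff)
  above <- function(x, cutoff) {
    if (percentile == 0) {
      flag <- rep(TRUE, length(x))
      flag[is.na(x) | is.na(cutoff)] <- NA
      flag
    } else {
      x > cutoff
    }
  }
  out <- df |>
    mutate(reliant_percentile = above(.data$mean_ssf_contribution, cut_sup),
           vulnerable_percentile = above(.data$mean_inadequate_intake,
                                         cut_int),
           reliant_absolute = .data$mean_ssf_contribution >= supply_threshold,
           vulnerable_absolute = .data$mean_inadequate_intake >=
             intake_threshold)
  structure(out,
            class = c("ssf_classification", class(out)),
            supply_cutoff = cut_sup, intake_cutoff = cut_int,
            percentile = percentile, supply_threshold = supply_threshold,
            intake_threshold = intake_threshold)
}

standardise_country_value <- function(df, candidates, to) {
  assert_columns(df, "country", "classification input")
  col <- intersect(candidates, names(df))[1]
  if (is.na(col)) {
    stop_data(sprintf("classification input needs one of: %s",
                      paste(candidates, collapse = ", ")))
  }
  df2 <- df[, c("country", col)]
  names(df2) <- c("country", to)
  tibble::as_tibble(df2)
}

#' @describeIn classify One-row summary: cutoffs, thresholds and flag
#'   counts.
#' @param x An `ssf_classification`.
#' @param ... Unused.
#' @export
glance.ssf_classification <- function(x, ...) {
  tibble::tibble(n_countries = nrow(x),
                 percentile = attr(x, "percentile"),
                 supply_cutoff = attr(x, "supply_cutoff"),
                 intake_cutoff = attr(x, "intake_cutoff"),
                 supply_threshold = attr(x, "supply_threshold"),
                 intake_threshold = attr(x, "intake_threshold"),
                 n_reliant_percentile = sum(x$reliant_percentile,
                                            na.rm = TRUE),
                 n_vulnerable_percentile = sum(x$vulnerable_percentile,
                                               na.rm = TRUE),
                 n_reliant_absolute = sum(x$reliant_absolute, na.rm = TRUE),
                 n_vulnerable_absolute = sum(x$vulnerable_absolute,
                                             na.rm = TRUE),
                 n_intake_missing = sum(is.na(x$mean_inadequate_intake)))
}

#' @describeIn classify Tidy form: one row per country and rule family.
#' @export
tidy.ssf_classification <- function(x, ...) {
  tibble::as_tibble(x) |>
    tidyr::pivot_longer(c("reliant_percentile", "vulnerable_percentile",
                          "reliant_absolute", "vulnerable_absolute"),
                        names_to = c("flag", "rule"), names_sep = "_",
                        values_to = "value")
}
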