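#' Convert apparent consumption to nutrient supply
#'
#' For every consumption cell, multiplies tonnes live weight by 1e4 (hundred
#' -gram units per tonne), the edible fraction and the per-100 g nutrient
#' concentration, then sums within country x sector x nutrient. Domestic
#' taxa are matched through the hierarchical fallback ([match_taxa()]);
#' import rows, which are resolved only to commodity category, use the
#' commodity mean profile. Units follow the profile units per nutrient
#' (mg/yr for iron, zinc and calcium; ug/yr for vitamins A and B12; g/yr for
#' DHA+EPA and protein).
#'
#' @param consumption Output of [apparent_consumption()].
#' @param lookup A [build_lookup()] index.
#' @param taxa Taxonomy table: `scientific_name`, `genus`, `family`,
#'   `order`, `class`, `commodity`.
#' @return A tibble `country`, `sector`, `nutrient`, `mass_per_year`.
#' @export
nutrient_supply <- function(consumption, lookup, taxa) {
  assert_columns(consumption, c("country", "taxon", "sector", "commodity",
                                "tonnes"), "consumption")
  dom <- consumption |> filter(.data$sector != "imports")
  imp <- consumption |> filter(.data$sector == "imports")

  matched <- NULL
  if (nrow(dom)) {
    keys <- taxa |>
      filter(.data$scientific_name %in% unique(dom$taxon))
    missing <- setdiff(unique(dom$taxon), keys$scientific_name)
    if (length(missing)) {
      stop_data(paste0("consumed taxa absent from the taxonomy table: ",
                       paste(utils::head(missing, 5), collapse = ", ")))
    }
    matched <- match_taxa(keys, lookup) |>
      select("scientific_name", all_of(NUTRIENTS), "edible_fraction")
    dom <- dom |> left_join(matched, by = c(taxon = "scientific_name"))
  }
  if (nrow(imp)) {
    com_profiles <- purrr::map(set_names(unique(imp$commodity)),
                               ~ commodity_profile(.x, lookup)) |>
      purrr::list_rbind(names_to = "commodity")
    imp <- imp |> left_join(com_profiles, by = "commodity")
  }
  bind_rows(dom, imp) |>
    tidyr::pivot_longer(all_of(NUTRIENTS), names_to = "nutrient",
                        values_to = "concentration") |>
    mutate(mass = .data$tonnes * 1e4 * .data$edible_fraction *
             .data$concentration) |>
    group_by(.data$country, .data$sector, .data$nutrient) |>
    summarise(mass_per_year = sum(.data$mass), .groups = "drop")
}

#' Per-capita daily nutrient supply by sector
#'
#' Divides annual sector supply by the consuming population and by 365.
#' Small-scale sectors (artisanal, subsistence) are assumed to be consumed
#' by the coastal population; industrial, recreational, mariculture and
#' import supply by the national population.
#'
#' @param supply Output of [nutrient_supply()].
#' @param coastal_pop Coastal population: `country`, `persons` (a single
#'   buffer distance; see [coastal_population()]).
#' @param national_pop National population: `country`, `persons`.
#' @return `supply` with `population` and `per_capita_per_day` columns.
#' @export
per_capita_supply <- function(supply, coastal_pop, national_pop) {
  if ("buffer_km" %in% names(coastal_pop) &&
      length(unique(coastal_pop$buffer_km)) > 1) {
    stop_config("`coastal_pop` must be at a single buffer distance",
                "coastal_pop")
  }
  out <- supply |>
    left_join(coastal_pop |> select("country", coastal = "persons"),
              by = "country") |>
    left_join(national_pop |> select("country", national = "persons"),
              by = "country") |>
    mutate(population = ifelse(.data$sector %in% SSF_SECTORS, .data$coastal,
                               .data$national))
  undefined <- out |>
    filter(.data$mass_per_year > 0,
           is.na(.data$population) | .data$population == 0)
  if (nrow(undefined)) {
    stop_data(paste0(
      "positive nutrient supply but zero (or unknown) consuming population ",
      "for: ",
      paste(unique(paste0(undefined$country, "/", undefined$sector)),
            collapse = ", ")))
  }
  out |>
    mutate(per_capita_per_day = ifelse(
      .data$mass_per_year == 0, 0,
      .data$mass_per_year / (.data$population * 365))) |>
    select("country", "sector", "nutrient", "mass_per_year", "population",
           "per_capita_per_day")
}

#' Small-scale fisheries' share of nutrient supply
#'
#' Computes, per country and nutrient, the fraction of per-capita daily
#' nutrient supply that comes from small-scale fisheries (artisanal plus
#' subsistence), under three denominator scopes: all seafood source-sectors
#' (`seafood`); seafood plus non-seafood animal-sourced food groups
#' (`animal_sourced`); and seafood plus all non-seafood food groups
#' (`all_foods`). Because seafood is by far the predominant dietary source
#' of DHA+EPA, all non-seafood contributions to the DHA+EPA denominator are
#' set to zero in every scope, so its three fractions coincide. Undefined
#' fractions (zero denominator) are returned as `NA`, never as zero.
#'
#' @param per_capita Output of [per_capita_supply()].
#' @param gnd Non-seafood per-capita supply: `country`, `food_group`,
#'   `nutrient`, `per_capita_per_day`.
#' @param scopes Subset of `c("seafood", "animal_sourced", "all_foods")`.
#' @param animal_groups Food-group labels counted as animal-sourced.
#' @return A tibble `country`, `nutrient`, `denominator_scope`,
#'   `ssf_fraction`.
#' @export
ssf_contribution <- function(per_capita, gnd,
                             scopes = CONTRIBUTION_SCOPES,
                             animal_groups = ANIMAL_GROUPS) {
  scopes <- match.arg(scopes, CONTRIBUTION_SCOPES, several.ok = TRUE)
  assert_columns(gnd, c("country", "food_group", "nutrient",
                        "per_capita_per_day"), "gnd")
  countries <- union(unique(per_capita$country), unique(gnd$country))
  sea <- per_capita |>
    group_by(.data$country, .data$nutrient) |>
    summarise(
      ssf = sum(.data$per_capita_per_day[.data$sector %in% SSF_SECTORS]),
      seafood = sum(.data$per_capita_per_day),
      .groups = "drop") |>
    tidyr::complete(country = countries, nutrient = NUTRIENTS,
                    fill = list(ssf = 0, seafood = 0))
  nonsea <- gnd |>
    group_by(.data$country, .data$nutrient) |>
    summarise(
      animal = sum(.data$per_capita_per_day[.data$food_group %in%
                                              animal_groups]),
      allfood = sum(.data$per_capita_per_day), .groups = "drop")
  combined <- sea |>
    left_join(nonsea, by = c("country", "nutrient")) |>
    mutate(animal = tidyr::replace_na(.data$animal, 0),
           allfood = tidyr::replace_na(.data$allfood, 0)) |>
    # seafood-only assumption for DHA+EPA
    mutate(animal = ifelse(.data$nutrient == "dha_epa", 0, .data$animal),
           allfood = ifelse(.data$nutrient == "dha_epa", 0, .data$allfood))
  denom <- list(seafood = combined$seafood,
                animal_sourced = combined$seafood + combined$animal,
                all_foods = combined$seafood + combined$allfood)
  purrr::map(scopes, function(sc) {
    D <- denom[[sc]]
    combined |>
      transmute(.data$country, .data$nutrient, denominator_scope = sc,
                ssf_fraction = ifelse(D > 0, .data$ssf / D, NA_real_))
  }) |>
    purrr::list_rbind() |>
    arrange(.data$denominator_scope, .data$country,
            match(.data$nutrient, NUTRIENTS))
}

#' Mean contribution across assessed nutrients
#'
#' Unweighted arithmetic mean of the SSF contribution over the assessed
#' nutrient set — by default the six micronutrients and fatty acids (iron,
#' zinc, calcium, vitamin A, vitamin B12, DHA+EPA), with protein computed
#' elsewhere but excluded from means. Countries with one or more missing
#' nutrient fractions are averaged over the available ones and flagged via
#' `n_missing`.
#'
#' @param records Output of [ssf_contribution()] (any subset of scopes).
#' @param nutrients Nutrient set to average over.
#' @return A tibble per country (and `denominator_scope`, if present):
#'   `mean_fraction`, `n_nutrients`, `n_missing`.
#' @export
mean_contribution <- function(records, nutrients = ASSESSED_NUTRIENTS) {
  assert_columns(records, c("country", "nutrient", "ssf_fraction"),
                 "contribution records")
  grp <- intersect(c("country", "denominator_scope"), names(records))
  records |>
    filter(.data$nutrient %in% nutrients) |>
    group_by(across(all_of(grp))) |>
    summarise(mean_fraction = {
      v <- .data$ssf_fraction[!is.na(.data$ssf_fraction)]
      if (length(v)) mean(v) else NA_real_
    },
    n_nutrients = length(nutrients),
    n_missing = sum(is.na(.data$ssf_fraction)),
    .groups = "drop")
}
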