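#' Keep only catch destined for direct human consumption
#'
#' Removes commercial (artisanal and industrial) catch that is discarded or
#' reduced to fishmeal and fish oil. Non-commercial sectors (subsistence,
#' recreational) and mariculture pass through untouched: their catch is
#' assumed to be entirely for human consumption.
#'
#' @param catch A data frame of catch records: `country`, `scientific_name`,
#'   `sector`, `end_use`, `tonnes` (live weight/yr).
#' @return The filtered tibble.
#' @export
filter_human_consumption <- function(catch) {
  assert_columns(catch, c("country", "scientific_name", "sector", "end_use",
                          "tonnes"), "catch")
  bad <- setdiff(unique(catch$end_use), END_USES)
  if (length(bad)) {
    stop_data(paste0("unknown end_use value(s): ", paste(bad, collapse = ", ")))
  }
  bad <- setdiff(unique(catch$sector), CATCH_SECTORS)
  if (length(bad)) {
    stop_data(paste0("unknown sector value(s): ", paste(bad, collapse = ", ")))
  }
  catch |>
    filter(!.data$sector %in% COMMERCIAL_SECTORS |
             .data$end_use == "direct_human_consumption") |>
    tibble::as_tibble()
}

#' Estimate re-exports per country and commodity
#'
#' Combines two routes: re-exports recorded as such in the trade table, and
#' processed re-exports inferred as the excess of exports over domestic
#' production in the food balance sheet (imported seafood that was processed
#' before leaving again cannot have been produced domestically). The total
#' is capped at recorded exports.
#'
#' @param trade A data frame of trade flows: `country`, `commodity`, `flow`
#'   (`import`, `export` or `reexport_recorded`), `tonnes` (product
#'   weight/yr).
#' @param fbs_production Food-balance-sheet production: `country`,
#'   `commodity`, `tonnes`.
#' @return A tibble per country x commodity: `recorded_reexports`,
#'   `processed_reexports`, `total_reexports`.
#' @examples
#' trade <- tibble::tibble(country = "AAA", commodity = "pelagic_fish",
#'                         flow = c("export", "reexport_recorded"),
#'                         tonnes = c(30, 2))
#' fbs <- tibble::tibble(country = "AAA", commodity = "pelagic_fish",
#'                       tonnes = 25)
#' estimate_reexports(trade, fbs)  # processed 5, total 7
#' @export
estimate_reexports <- function(trade, fbs_production) {
  assert_columns(trade, c("country", "commodity", "flow", "tonnes"), "trade")
  bad <- setdiff(unique(trade$flow), c("import", "export",
                                       "reexport_recorded"))
  if (length(bad)) {
    stop_data(paste0("unknown trade flow(s): ", paste(bad, collapse = ", ")))
  }
  wide <- trade_flows_wide(trade)
  prod <- fbs_production |>
    group_by(.data$country, .data$commodity) |>
    summarise(production = sum(.data$tonnes), .groups = "drop")
  wide |>
    full_join(prod, by = c("country", "commodity")) |>
    mutate(across(c("imports", "exports", "recorded_reexports", "production"),
                  ~ tidyr::replace_na(.x, 0))) |>
    mutate(processed_reexports = pmax(0, .data$exports - .data$production),
           total_reexports = pmin(.data$recorded_reexports +
                                    .data$processed_reexports,
                                  .data$exports)) |>
    select("country", "commodity", "recorded_reexports",
           "processed_reexports", "total_reexports")
}

trade_flows_wide <- function(trade) {
  trade |>
    group_by(.data$country, .data$commodity, .data$flow) |>
    summarise(tonnes = sum(.data$tonnes), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "flow", values_from = "tonnes",
                       values_fill = 0) |>
    (\(d) {
      for (col in c("import", "export", "reexport_recorded")) {
        if (!col %in% names(d)) d[[col]] <- 0
      }
      d
    })() |>
    select("country", "commodity", imports = "import", exports = "export",
           recorded_reexports = "reexport_recorded")
}

#' Correct trade flows for re-exports
#'
#' Subtracts estimated total re-exports from both recorded imports and
#' recorded exports, clamping at zero, so that re-exported seafood is not
#' counted as consumed in the transit country nor as lost production in the
#' origin country.
#'
#' @inheritParams estimate_reexports
#' @param reexports Output of [estimate_reexports()].
#' @return A tibble per country x commodity with adjusted `imports` and
#'   `exports`.
#' @export
adjust_trade <- function(trade, reexports) {
  trade_flows_wide(trade) |>
    full_join(reexports |> select("country", "commodity", "total_reexports"),
              by = c("country", "commodity")) |>
    mutate(across(c("imports", "exports", "total_reexports"),
                  ~ tidyr::replace_na(.x, 0))) |>
    mutate(imports = pmax(0, .data$imports - .data$total_reexports),
           exports = pmax(0, .data$exports - .data$total_reexports)) |>
    select("country", "commodity", "imports", "exports")
}

#' Remove the freshwater share of crustacean exports
#'
#' The analysis is marine-only, but crustacean trade statistics mix in
#' freshwater species; the estimated freshwater share is removed from
#' crustacean-commodity exports before export subtraction.
#'
#' @param exports A data frame with `country`, `commodity`, `exports`.
#' @param fraction Either a single fraction in `[0, 1]` or a data frame
#'   `country`, `fraction` of per-country freshwater shares.
#' @param commodity The crustacean commodity label.
#' @return `exports` with crustacean rows scaled by `1 - fraction`.
#' @export
remove_freshwater_crustaceans <- function(exports, fraction,
                                          commodity = CRUSTACEAN_COMMODITY) {
  assert_columns(exports, c("country", "commodity", "exports"), "exports")
  if (is.data.frame(fraction)) {
    assert_columns(fraction, c("country", "fraction"), "fraction")
    assert_fraction(fraction$fraction, "fraction")
    exports |>
      left_join(fraction, by = "country") |>
      mutate(fraction = tidyr::replace_na(.data$fraction, 0),
             exports = ifelse(.data$commodity == .env$commodity,
                              .data$exports * (1 - .data$fraction),
                              .data$exports)) |>
      select(-"fraction")
  } else {
    assert_fraction(fraction, "fraction")
    exports |>
      mutate(exports = ifelse(.data$commodity == .env$commodity,
                              .data$exports * (1 - .env$fraction),
                              .data$exports))
  }
}

#' Subtract exports from production by proportional allocation
#'
#' Allocates each country's adjusted commodity exports across the
#' (species, sector) production cells of that commodity, proportionally to
#' their production tonnage, and subtracts the allocation. Cells driven
#' negative — more exported than locally produced — are clamped at zero and
#' the unallocatable surplus is reported rather than silently dropped.
#' Artisanal production is part of the exportable pool in the conservative
#' base case; set `artisanal_exportable = FALSE` to retain it domestically.
#'
#' @param production Post-filter production: `country`, `scientific_name`,
#'   `sector` (commercial sectors and mariculture), `tonnes` live weight.
#' @param exports Adjusted exports per `country` x `commodity` (column
#'   `exports`, product weight).
#' @param commodity_map A data frame mapping `scientific_name` to
#'   `commodity`.
#' @param artisanal_exportable Is artisanal production exportable?
#' @param conversion_factors Optional data frame `commodity`, `factor`
#'   converting trade product weight to live-weight equivalents before
#'   subtraction (default factor 1 for every commodity).
#' @return A list with `retained` (production net of allocated exports) and
#'   `surplus` (per country x commodity export tonnage that had no
#'   production to be allocated against).
#' @examples
#' prod <- tibble::tibble(country = "AAA",
#'                        scientific_name = c("Sp a", "Sp b"),
#'                        sector = "industrial", tonnes = c(60, 40))
#' cmap <- tibble::tibble(scientific_name = c("Sp a", "Sp b"),
#'                        commodity = "pelagic_fish")
#' exp <- tibble::tibble(country = "AAA", commodity = "pelagic_fish",
#'                       exports = 50)
#' subtract_exports(prod, exp, cmap)$retained$tonnes  # 30, 20
#' @export
subtract_exports <- function(production, exports, commodity_map,
                             artisanal_exportable = TRUE,
                             conversion_factors = NULL) {
  assert_columns(production, c("country", "scientific_name", "sector",
                               "tonnes"), "production")
  assert_columns(commodity_map, c("scientific_name", "commodity"),
                 "commodity_map")
  prod <- production |>
    left_join(commodity_map |> select("scientific_name", "commodity") |>
                distinct(), by = "scientific_name")
  if (anyNA(prod$commodity)) {
    missing <- unique(prod$scientific_name[is.na(prod$commodity)])
    stop_data(paste0("taxa without a commodity mapping: ",
                     paste(utils::head(missing, 5), collapse = ", ")))
  }
  exp_live <- exports
  if (!is.null(conversion_factors)) {
    assert_columns(conversion_factors, c("commodity", "factor"),
                   "conversion_factors")
    exp_live <- exp_live |>
      left_join(conversion_factors, by = "commodity") |>
      mutate(exports = .data$exports * tidyr::replace_na(.data$factor, 1)) |>
      select(-"factor")
  }
  exportable_sectors <- c(if (artisanal_exportable) "artisanal",
                          "industrial", "mariculture")
  prod <- prod |>
    mutate(exportable = .data$sector %in% exportable_sectors) |>
    group_by(.data$country, .data$commodity) |>
    mutate(pool = sum(.data$tonnes[.data$exportable])) |>
    ungroup() |>
    left_join(exp_live |> select("country", "commodity", "exports"),
              by = c("country", "commodity")) |>
    mutate(exports = tidyr::replace_na(.data$exports, 0),
           allocation = ifelse(.data$exportable & .data$pool > 0,
                               .data$exports * .data$tonnes / .data$pool, 0),
           retained = pmax(0, .data$tonnes - .data$allocation))
  pool_by_cell <- prod |>
    group_by(.data$country, .data$commodity) |>
    summarise(pool = sum(.data$tonnes[.data$exportable]), .groups = "drop")
  surplus <- exp_live |>
    left_join(pool_by_cell, by = c("country", "commodity")) |>
    mutate(pool = tidyr::replace_na(.data$pool, 0),
           surplus = pmax(0, .data$exports - .data$pool)) |>
    filter(.data$surplus > 0) |>
    select("country", "commodity", "surplus")
  list(retained = prod |>
         select("country", "scientific_name", "sector", "commodity",
                tonnes = "retained"),
       surplus = surplus,
       allocation = prod |>
         select("country", "scientific_name", "sector", "commodity",
                production = "tonnes", "allocation", retained = "retained"),
       exports = exp_live |> select("country", "commodity", "exports"))
}

#' Assemble national apparent seafood consumption
#'
#' Joins retained commercial/mariculture production, re-export-adjusted
#' imports (resolved only to commodity category, under source-sector
#' `imports`) and the full non-commercial catch (subsistence and
#' recreational, assumed entirely consumed domestically and untouched by
#' trade) into one consumption table.
#'
#' @param retained `retained` element of [subtract_exports()].
#' @param imports Adjusted imports per `country` x `commodity` (column
#'   `imports`).
#' @param noncommercial Non-commercial catch: `country`, `scientific_name`,
#'   `sector`, `tonnes`.
#' @param commodity_map Mapping `scientific_name` -> `commodity`.
#' @return A tibble `country`, `taxon`, `sector`, `commodity`, `tonnes`; for
#'   import rows `taxon` is the commodity label.
#' @export
apparent_consumption <- function(retained, imports, noncommercial,
                                 commodity_map) {
  noncom <- noncommercial |>
    group_by(.data$country, .data$scientific_name, .data$sector) |>
    summarise(tonnes = sum(.data$tonnes), .groups = "drop") |>
    left_join(commodity_map |> select("scientific_name", "commodity") |>
                distinct(), by = "scientific_name")
  out <- bind_rows(
    retained |>
      select("country", taxon = "scientific_name", "sector", "commodity",
             "tonnes"),
    imports |>
      filter(.data$imports > 0) |>
      transmute(.data$country, taxon = .data$commodity, sector = "imports",
                .data$commodity, tonnes = .data$imports),
    noncom |>
      select("country", taxon = "scientific_name", "sector", "commodity",
             "tonnes"))
  if (any(out$tonnes < 0)) {
    stop_data("negative tonnage in apparent consumption")
  }
  out |> arrange(.data$country, .data$taxon, .data$sector)
}
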