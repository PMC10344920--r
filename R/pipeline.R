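#' Configure a pipeline run
#'
#' Collects every knob of a full analysis run into one validated object that
#' can be serialized to YAML for provenance. In `synthetic` mode the input
#' tables are generated ([generate_world()]) from `world` (arguments to
#' [world_config()]) and `seed`; in `tabular` mode they are read from
#' `input_dir`, a directory previously written by [write_world()] or
#' assembled externally with the same schemas.
#'
#' @param mode `"synthetic"` or `"tabular"`.
#' @param input_dir Input directory for tabular mode.
#' @param world Named list of [world_config()] arguments (synthetic mode).
#' @param seed Integer seed (synthetic mode; overrides `world$seed`).
#' @param buffer_km Coastal buffer for the headline run; `NULL` means the
#'   world's configured default.
#' @param artisanal_exportable Is artisanal catch in the exportable pool?
#' @param percentile,supply_threshold,intake_threshold See [classify()].
#' @param nutrients Nutrient set for means and classification.
#' @param conversion_factors Optional `commodity`/`factor` table converting
#'   trade product weight to live weight (default 1).
#' @param output_dir If set, stage CSVs and `report.json` are written here.
#' @return A list of class `ssf_run_config`.
#' @export
run_config <- function(mode = c("synthetic", "tabular"), input_dir = NULL,
                       world = list(), seed = NULL, buffer_km = NULL,
                       artisanal_exportable = TRUE, percentile = 0.70,
                       supply_threshold = 0.15, intake_threshold = 0.50,
                       nutrients = ASSESSED_NUTRIENTS,
                       conversion_factors = NULL, output_dir = NULL) {
  mode <- match.arg(mode)
  if (mode == "tabular" && is.null(input_dir)) {
    stop_config("tabular mode needs `input_dir`", "input_dir")
  }
  assert_fraction(percentile, "percentile")
  structure(list(mode = mode, input_dir = input_dir, world = world,
                 seed = seed, buffer_km = buffer_km,
                 artisanal_exportable = isTRUE(artisanal_exportable),
                 percentile = percentile,
                 supply_threshold = supply_threshold,
                 intake_threshold = intake_threshold,
                 nutrients = nutrients,
                 conversion_factors = conversion_factors,
                 output_dir = output_dir),
            class = "ssf_run_config")
}

#' Run the full supply-accounting pipeline
#'
#' Wires every stage together: end-use filtering, re-export estimation and
#' trade adjustment, freshwater-crustacean correction, proportional export
#' subtraction, apparent consumption, hierarchical nutrient matching,
#' nutrient-supply conversion, coastal/national per-capita division,
#' contribution fractions under the three scopes, six-nutrient country
#' means, and classification. The run is a pure function of the world and
#' parameters; identical inputs give identical reports.
#'
#' @param world An `ssf_world`, or a directory written by [write_world()],
#'   or `NULL` to build one from `config`.
#' @param config Optional [run_config()]; explicit arguments override it.
#' @param buffer_km,artisanal_exportable,percentile,supply_threshold,intake_threshold,nutrients,conversion_factors,output_dir
#'   See [run_config()].
#' @return A list of class `ssf_run` with elements `consumption`, `supply`,
#'   `per_capita`, `contributions`, `mean_contributions`, `classification`,
#'   `match_stats`, `coastal_population`, `national_population`,
#'   `export_surplus`, `residuals`, `params`.
#' @examples
#' w <- generate_world(world_config(n_countries = 3, n_species = 12,
#'                                  grid_cells_per_country = 20, seed = 2))
#' run <- run_pipeline(w)
#' glance(run)
#' @export
run_pipeline <- function(world = NULL, config = NULL, buffer_km = NULL,
                         artisanal_exportable = NULL, percentile = NULL,
                         supply_threshold = NULL, intake_threshold = NULL,
                         nutrients = NULL, conversion_factors = NULL,
                         output_dir = NULL) {
  pick <- function(arg, field, default) {
    arg %||% (if (!is.null(config)) config[[field]] else NULL) %||% default
  }
  if (is.null(world)) {
    if (is.null(config)) stop_config("either `world` or `config` is required")
    world <- if (config$mode == "tabular") {
      read_world(config$input_dir)
    } else {
      wargs <- config$world %||% list()
      if (!is.null(config$seed)) wargs$seed <- config$seed
      generate_world(do.call(world_config, wargs))
    }
  } else if (is.character(world)) {
    world <- read_world(world)
  }
  stopifnot(inherits(world, "ssf_world"))
  params <- list(
    buffer_km = pick(buffer_km, "buffer_km",
                     world$config$buffer_km_default),
    artisanal_exportable = pick(artisanal_exportable,
                                "artisanal_exportable", TRUE),
    percentile = pick(percentile, "percentile", 0.70),
    supply_threshold = pick(supply_threshold, "supply_threshold", 0.15),
    intake_threshold = pick(intake_threshold, "intake_threshold", 0.50),
    nutrients = pick(nutrients, "nutrients", ASSESSED_NUTRIENTS),
    freshwater_crustacean_fraction =
      world$config$freshwater_crustacean_export_fraction %||% 0,
    seed = world$config$seed)
  conversion_factors <- pick(conversion_factors, "conversion_factors", NULL)
  output_dir <- pick(output_dir, "output_dir", NULL)

  lookup <- build_lookup(world$profiles)
  filtered <- filter_human_consumption(bind_rows(world$catch,
                                                 world$mariculture))
  production <- filtered |>
    filter(.data$sector %in% c(COMMERCIAL_SECTORS, "mariculture")) |>
    group_by(.data$country, .data$scientific_name, .data$sector) |>
    summarise(tonnes = sum(.data$tonnes), .groups = "drop")
  noncommercial <- filtered |>
    filter(.data$sector %in% NONCOMMERCIAL_SECTORS)

  reexports <- estimate_reexports(world$trade, world$fbs_production)
  adjusted <- adjust_trade(world$trade, reexports)
  exports_adj <- adjusted |>
    select("country", "commodity", "exports") |>
    remove_freshwater_crustaceans(params$freshwater_crustacean_fraction)
  sub <- subtract_exports(production, exports_adj, world$taxa,
                          artisanal_exportable = params$artisanal_exportable,
                          conversion_factors = conversion_factors)
  consumption <- apparent_consumption(
    sub$retained, adjusted |> select("country", "commodity", "imports"),
    noncommercial, world$taxa)

  supply <- nutrient_supply(consumption, lookup, world$taxa)
  coastal <- coastal_population(world$population_cells, world$coastline,
                                params$buffer_km)
  national <- national_population(world$population_cells)
  per_capita <- per_capita_supply(supply, coastal, national)
  contributions <- ssf_contribution(per_capita, world$gnd_nonseafood)
  mean_contributions <- mean_contribution(contributions,
                                          nutrients = params$nutrients)
  classification <- classify(
    mean_contributions |> filter(.data$denominator_scope == "all_foods"),
    world$inadequate_intake, percentile = params$percentile,
    supply_threshold = params$supply_threshold,
    intake_threshold = params$intake_threshold,
    nutrients = params$nutrients)

  match_stats <- match_statistics(match_taxa(world$taxa, lookup))

  residuals <- mass_balance_residuals(sub)
  run <- structure(list(
    consumption = consumption, supply = supply, per_capita = per_capita,
    contributions = contributions, mean_contributions = mean_contributions,
    classification = classification, match_stats = match_stats,
    coastal_population = coastal, national_population = national,
    export_surplus = sub$surplus, residuals = residuals,
    params = params,
    passed = max(c(0, residuals$relative_residual), na.rm = TRUE) < 1e-9),
    class = "ssf_run")
  if (!is.null(output_dir)) write_run(run, output_dir)
  run
}

# retained + allocated exports must reproduce post-filter production
# (pre-clamp, surplus accounted separately); effectively allocated exports
# plus the reported surplus must reproduce the adjusted live-weight exports
mass_balance_residuals <- function(sub) {
  alloc <- sub$allocation |>
    group_by(.data$country, .data$commodity) |>
    summarise(retained_preclamp = sum(.data$production - .data$allocation),
              allocated_effective = sum(pmin(.data$allocation,
                                             .data$production)),
              production = sum(.data$production),
              allocated = sum(.data$allocation),
              .groups = "drop") |>
    full_join(sub$exports, by = c("country", "commodity")) |>
    left_join(sub$surplus, by = c("country", "commodity")) |>
    mutate(across(c("production", "allocated", "retained_preclamp",
                    "allocated_effective", "exports", "surplus"),
                  ~ tidyr::replace_na(.x, 0)))
  alloc |>
    mutate(
      production_residual = abs(.data$retained_preclamp + .data$allocated -
                                  .data$production) /
        pmax(.data$production, 1),
      export_residual = abs(.data$allocated_effective + .data$surplus -
                              .data$exports) / pmax(.data$exports, 1),
      relative_residual = pmax(.data$production_residual,
                               .data$export_residual))
}

#' @export
print.ssf_run <- function(x, ...) {
  cat("<ssf_run>\n")
  cat(sprintf("  buffer %.0f km, artisanal exportable: %s\n",
              x$params$buffer_km, x$params$artisanal_exportable))
  cat(sprintf("  %d consumption cells, %d supply cells\n",
              nrow(x$consumption), nrow(x$supply)))
  g <- glance(x)
  cat(sprintf("  mean SSF share: seafood %.1f%%, animal-sourced %.1f%%, all foods %.1f%%\n",
              100 * g$mean_share_seafood, 100 * g$mean_share_animal,
              100 * g$mean_share_all_foods))
  cat(sprintf("  reliant (percentile rule): %d; vulnerable: %d; mass balance ok: %s\n",
              g$n_reliant_percentile, g$n_vulnerable_percentile, x$passed))
  invisible(x)
}

#' @describeIn run_pipeline Per-country classification table.
#' @param x An `ssf_run`.
#' @param ... Unused.
#' @export
tidy.ssf_run <- function(x, ...) tibble::as_tibble(x$classification)

#' @describeIn run_pipeline One-row run summary: cross-country mean SSF
#'   share per scope, flag counts, match quality, worst residual.
#' @export
glance.ssf_run <- function(x, ...) {
  scope_mean <- function(sc) {
    m <- x$mean_contributions |>
      filter(.data$denominator_scope == sc)
    mean(m$mean_fraction, na.rm = TRUE)
  }
  cg <- glance(x$classification)
  tibble::tibble(
    n_countries = nrow(x$classification),
    mean_share_seafood = scope_mean("seafood"),
    mean_share_animal = scope_mean("animal_sourced"),
    mean_share_all_foods = scope_mean("all_foods"),
    n_reliant_percentile = cg$n_reliant_percentile,
    n_vulnerable_percentile = cg$n_vulnerable_percentile,
    n_reliant_absolute = cg$n_reliant_absolute,
    n_vulnerable_absolute = cg$n_vulnerable_absolute,
    match_family_or_better = attr(x$match_stats, "family_or_better"),
    max_relative_residual = max(c(0, x$residuals$relative_residual)))
}

#' Write run outputs
#'
#' Writes the stage CSVs (`apparent_consumption.csv`, `supply.csv`,
#' `per_capita.csv`, `contributions.csv`, `mean_contributions.csv`,
#' `classification.csv`, `coastal_population.csv`, `match_levels.csv`) plus
#' a machine-readable `report.json` with parameters, row counts, residuals
#' and summaries.
#'
#' @param run An `ssf_run`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) readr::write_csv(df, file.path(dir, name))
  w(run$consumption, "apparent_consumption.csv")
  w(run$supply, "supply.csv")
  w(run$per_capita, "per_capita.csv")
  w(run$contributions, "contributions.csv")
  w(run$mean_contributions, "mean_contributions.csv")
  w(tibble::as_tibble(run$classification), "classification.csv")
  w(run$coastal_population, "coastal_population.csv")
  w(run$match_stats, "match_levels.csv")
  report <- list(params = run$params,
                 rows = purrr::map_int(
                   run[c("consumption", "supply", "per_capita",
                         "contributions", "classification")], nrow),
                 max_relative_residual =
                   max(c(0, run$residuals$relative_residual)),
                 passed = run$passed,
                 summary = glance(run),
                 classification = tibble::as_tibble(run$classification))
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(dir)
}
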