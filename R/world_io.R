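WORLD_TABLES <- c(catch = "catch.csv", mariculture = "mariculture.csv",
                  trade = "trade.csv", fbs_production = "fbs_production.csv",
                  profiles = "profiles.csv", taxa = "commodity_map.csv",
                  population_cells = "population_cells.csv",
                  coastline = "coastline.csv", gnd_nonseafood = "gnd.csv",
                  inadequate_intake = "inadequate_intake.csv")

#' Write a synthetic world to a directory of CSV tables
#'
#' One CSV per input table (`catch.csv`, `mariculture.csv`, `trade.csv`,
#' `fbs_production.csv`, `profiles.csv`, `commodity_map.csv`,
#' `population_cells.csv`, `coastline.csv`, `gnd.csv`,
#' `inadequate_intake.csv`), plus `truth.json` with the bookkept expected
#' outputs and `config.yaml` with the generating configuration. Doubles are
#' written with shortest round-trip precision, so a [read_world()] /
#' [run_pipeline()] round trip reproduces the in-memory results.
#'
#' @param world An `ssf_world`.
#' @param dir Target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  stopifnot(inherits(world, "ssf_world"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (el in names(WORLD_TABLES)) {
    readr::write_csv(world[[el]], file.path(dir, WORLD_TABLES[[el]]),
                     na = "")
  }
  cfg <- unclass(world$config)
  cfg$taxonomy_shape <- as.list(cfg$taxonomy_shape)
  cfg$profile_missingness_by_rank <- as.list(cfg$profile_missingness_by_rank)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  if (!is.null(world$truth)) {
    jsonlite::write_json(unclass(world$truth),
                         file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(dir)
}

#' Read a world directory
#'
#' Reads the tables written by [write_world()] (or assembled externally with
#' the same column schemas) and rebuilds an `ssf_world`. The ground truth is
#' recomputed from the tables with [world_truth()] rather than parsed back
#' from `truth.json`, so externally edited tables stay consistent with their
#' truth.
#'
#' @param dir Directory containing the world CSVs and `config.yaml`.
#' @return An `ssf_world`.
#' @export
read_world <- function(dir) {
  if (!dir.exists(dir)) stop_config(sprintf("no such directory: %s", dir),
                                    "input_dir")
  cfgf <- file.path(dir, "config.yaml")
  if (!file.exists(cfgf)) stop_config("world directory lacks config.yaml",
                                      "input_dir")
  config <- do.call(world_config, yaml::read_yaml(cfgf))
  world <- list(config = config)
  specs <- list(
    catch = readr::cols(country = "c", scientific_name = "c", sector = "c",
                        end_use = "c", tonnes = "d"),
    mariculture = readr::cols(country = "c", scientific_name = "c",
                              sector = "c", end_use = "c", tonnes = "d"),
    trade = readr::cols(country = "c", commodity = "c", flow = "c",
                        tonnes = "d"),
    fbs_production = readr::cols(country = "c", commodity = "c",
                                 tonnes = "d"),
    profiles = readr::cols(scientific_name = "c", genus = "c", family = "c",
                           order = "c", class = "c", commodity = "c",
                           .default = "d"),
    taxa = readr::cols(.default = "c"),
    population_cells = readr::cols(country = "c", x = "d", y = "d",
                                   persons = "d"),
    coastline = readr::cols(country = "c", vertex = "i", x = "d", y = "d"),
    gnd_nonseafood = readr::cols(country = "c", food_group = "c",
                                 nutrient = "c", per_capita_per_day = "d"),
    inadequate_intake = readr::cols(country = "c", nutrient = "c",
                                    prevalence = "d"))
  for (el in names(WORLD_TABLES)) {
    f <- file.path(dir, WORLD_TABLES[[el]])
    if (!file.exists(f)) stop_config(sprintf("missing table: %s",
                                             WORLD_TABLES[[el]]),
                                     "input_dir")
    world[[el]] <- readr::read_csv(f, col_types = specs[[el]],
                                   na = c("", "NA"), progress = FALSE)
  }
  world$countries <- sort(unique(c(world$population_cells$country,
                                   world$catch$country,
                                   world$gnd_nonseafood$country)))
  world <- structure(world, class = "ssf_world")
  world$truth <- world_truth(world)
  world
}
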