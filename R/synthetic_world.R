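# Biologically plausible per-100 g edible-portion concentration ranges used
# for log-uniform draws (mg, mg, mg, ug RAE, ug, g, g). Log-uniform gives the
# heavy-tailed spread seen in aquatic food-composition data and stresses the
# hierarchical matcher.
NUTRIENT_RANGES <- list(iron = c(0.2, 10), zinc = c(0.2, 8),
                        calcium = c(5, 300), vitamin_a = c(1, 150),
                        vitamin_b12 = c(0.5, 20), dha_epa = c(0.05, 3),
                        protein = c(10, 25))

# per-capita-per-day supply ranges for one non-seafood food group
GND_RANGES <- list(iron = c(0.05, 3), zinc = c(0.05, 3), calcium = c(5, 300),
                   vitamin_a = c(1, 200), vitamin_b12 = c(0.05, 2),
                   dha_epa = c(0.001, 0.05), protein = c(1, 20))

# probability an individual nutrient value is missing in a species-keyed
# profile record (commodity-keyed records are always complete)
PROFILE_NUTRIENT_NA_PROB <- 0.15
PROFILE_EDIBLE_NA_PROB <- 0.05

runif_log <- function(n, range) exp(runif(n, log(range[1]), log(range[2])))

#' Generate a synthetic world with known ground truth
#'
#' Draws a self-consistent miniature study system: countries with rectangular
#' planar geometry (western edge = coastline), a nested taxonomy, catch by
#' country x species x sector x end-use, mariculture production, a seafood
#' trade table with genuine re-export flows, taxonomically keyed nutrient
#' profiles with injected missingness, a gridded population, non-seafood
#' nutrient supply by food group, and prevalence of inadequate intake. The
#' returned object carries a `truth` element with the expected output of
#' every downstream pipeline stage, bookkept directly from the generated
#' tables without calling any pipeline function (see
#' [ground_truth_contributions()] for an even more literal recomputation).
#'
#' Sector shares of each country-species catch are drawn from a symmetric
#' Dirichlet allocation (normalised unit-rate gamma draws); commercial catch
#' is split across end uses with discard and fishmeal/fish-oil shares drawn
#' from the configured ranges. Exports are `export_intensity` of exportable
#' post-filter production plus re-exported imports; half of each re-export
#' flow is recorded as such, the other half is only discoverable as processed
#' re-exports from the production-export gap in the food balance sheet.
#'
#' @param config A [world_config()] object.
#' @return A list of class `ssf_world` with elements `config`, `countries`,
#'   `taxa`, `catch`, `mariculture`, `trade`, `fbs_production`, `profiles`,
#'   `population_cells`, `coastline`, `gnd_nonseafood`, `inadequate_intake`
#'   and `truth`.
#' @examples
#' w <- generate_world(world_config(n_countries = 3, n_species = 12,
#'                                  grid_cells_per_country = 20, seed = 1))
#' nrow(w$catch)
#' @export
generate_world <- function(config) {
  if (!inherits(config, "ssf_world_config")) {
    config <- do.call(world_config, as.list(config))
  }
  validate_world_config(config)
  world <- withr::with_seed(config$seed, generate_world_impl(config))
  world$truth <- compute_world_truth(world)
  world
}

generate_world_impl <- function(config) {
  countries <- sprintf("C%02d", seq_len(config$n_countries))
  taxa <- generate_taxonomy(config)
  catch <- generate_catch(config, countries, taxa)
  mariculture <- generate_mariculture(config, countries, taxa)
  profiles <- generate_profiles(config, taxa)
  geo <- generate_geography(config, countries)
  trade <- generate_trade(config, countries, taxa, catch, mariculture)
  gnd <- tidyr::crossing(country = countries,
                         food_group = c(ANIMAL_GROUPS, OTHER_FOOD_GROUPS),
                         nutrient = NUTRIENTS) |>
    mutate(per_capita_per_day = map_dbl(.data$nutrient,
                                        ~ runif_log(1, GND_RANGES[[.x]])))
  inadequate <- tidyr::crossing(country = countries,
                                nutrient = ASSESSED_NUTRIENTS) |>
    mutate(prevalence = runif(dplyr::n(), 0.05, 0.95))

  structure(list(config = config,
                 countries = countries,
                 taxa = taxa,
                 catch = catch,
                 mariculture = mariculture,
                 trade = trade$trade,
                 fbs_production = trade$fbs_production,
                 profiles = profiles,
                 population_cells = geo$cells,
                 coastline = geo$coastline,
                 gnd_nonseafood = gnd,
                 inadequate_intake = inadequate,
                 truth = NULL),
            class = "ssf_world")
}

generate_taxonomy <- function(config) {
  shp <- config$taxonomy_shape
  classes <- sprintf("Class%02d", seq_len(shp[["class"]]))
  orders <- sprintf("Order%02d", seq_len(shp[["order"]]))
  families <- sprintf("Family%02d", seq_len(shp[["family"]]))
  genera <- sprintf("Genus%02d", seq_len(shp[["genus"]]))

  order_class <- sample(classes, length(orders), replace = TRUE)
  family_order <- sample(orders, length(families), replace = TRUE)
  genus_family <- sample(families, length(genera), replace = TRUE)
  # every commodity category must be represented so the terminal fallback
  # and the crustacean export correction always have substrate
  family_commodity <- c(COMMODITIES,
                        sample(COMMODITIES, max(0, length(families) -
                                                  length(COMMODITIES)),
                               replace = TRUE))[seq_along(families)]

  species_genus <- sample(genera, config$n_species, replace = TRUE)
  fam <- genus_family[match(species_genus, genera)]
  tibble(scientific_name = sprintf("%s sp%03d", species_genus,
                                   seq_len(config$n_species)),
         genus = species_genus,
         family = fam,
         order = family_order[match(fam, families)],
         class = order_class[match(family_order[match(fam, families)],
                                   orders)],
         commodity = family_commodity[match(fam, families)])
}

generate_catch <- function(config, countries, taxa) {
  wild <- setdiff(config$sectors_active, "mariculture")
  if (length(wild) == 0) {
    return(tibble(country = character(), scientific_name = character(),
                  sector = character(), end_use = character(),
                  tonnes = numeric()))
  }
  base <- tidyr::crossing(country = countries,
                          scientific_name = taxa$scientific_name) |>
    filter(runif(dplyr::n()) < 0.4) |>
    mutate(total = runif_log(dplyr::n(), c(20, 5000)))
  # symmetric Dirichlet sector shares via normalised unit-rate gammas
  shares <- matrix(rgamma(nrow(base) * length(wild), shape = 1),
                   ncol = length(wild))
  shares <- shares / rowSums(shares)
  colnames(shares) <- wild
  long <- base |>
    bind_cols(as_tibble(shares)) |>
    tidyr::pivot_longer(all_of(wild), names_to = "sector",
                        values_to = "share") |>
    mutate(tonnes = .data$total * .data$share) |>
    select("country", "scientific_name", "sector", "tonnes")

  com <- long |> filter(.data$sector %in% COMMERCIAL_SECTORS)
  non <- long |> filter(!.data$sector %in% COMMERCIAL_SECTORS) |>
    mutate(end_use = "direct_human_consumption")
  if (nrow(com)) {
    com <- com |>
      mutate(discard = runif(dplyr::n(), config$discard_fraction_range[1],
                             config$discard_fraction_range[2]),
             fmfo = runif(dplyr::n(), config$fmfo_fraction_range[1],
                          config$fmfo_fraction_range[2]))
    com <- bind_rows(
      com |> mutate(end_use = "direct_human_consumption",
                    tonnes = .data$tonnes * (1 - .data$discard - .data$fmfo)),
      com |> mutate(end_use = "discard", tonnes = .data$tonnes * .data$discard),
      com |> mutate(end_use = "fishmeal_fish_oil",
                    tonnes = .data$tonnes * .data$fmfo)) |>
      select(-"discard", -"fmfo")
  }
  bind_rows(com, non) |>
    filter(.data$tonnes > 0) |>
    select("country", "scientific_name", "sector", "end_use", "tonnes") |>
    arrange(.data$country, .data$scientific_name, .data$sector, .data$end_use)
}

generate_mariculture <- function(config, countries, taxa) {
  if (!"mariculture" %in% config$sectors_active) {
    return(tibble(country = character(), scientific_name = character(),
                  sector = character(), end_use = character(),
                  tonnes = numeric()))
  }
  n_farmed <- min(5L, nrow(taxa))
  purrr::map(countries, function(cty) {
    tibble(country = cty,
           scientific_name = sample(taxa$scientific_name, n_farmed),
           sector = "mariculture",
           end_use = "direct_human_consumption",
           tonnes = runif_log(n_farmed, c(10, 2000)))
  }) |>
    purrr::list_rbind() |>
    arrange(.data$country, .data$scientific_name)
}

generate_profiles <- function(config, taxa) {
  miss <- config$profile_missingness_by_rank
  keep <- runif(nrow(taxa)) >= miss[["species"]]
  # whole-group removals force deeper fallback levels
  for (rk in c("genus", "family", "order", "class")) {
    groups <- unique(taxa[[rk]])
    dropped <- groups[runif(length(groups)) < miss[[rk]]]
    keep <- keep & !(taxa[[rk]] %in% dropped)
  }
  sp <- taxa[keep, , drop = FALSE]
  n <- nrow(sp)
  conc <- purrr::map(NUTRIENTS, function(nu) {
    v <- runif_log(n, NUTRIENT_RANGES[[nu]])
    v[runif(n) < PROFILE_NUTRIENT_NA_PROB] <- NA_real_
    v
  }) |> set_names(NUTRIENTS)
  ef <- runif(n, 0.3, 0.9)
  ef[runif(n) < PROFILE_EDIBLE_NA_PROB] <- NA_real_
  species_profiles <- bind_cols(as_tibble(sp), as_tibble(conc),
                                tibble(edible_fraction = ef))
  # one complete commodity-keyed record per category: the terminal fallback
  # (mirroring commodity-group average profiles) can never be empty
  m <- length(COMMODITIES)
  commodity_profiles <- tibble(scientific_name = NA_character_,
                               genus = NA_character_, family = NA_character_,
                               order = NA_character_, class = NA_character_,
                               commodity = COMMODITIES) |>
    bind_cols(purrr::map(NUTRIENTS,
                         ~ runif_log(m, NUTRIENT_RANGES[[.x]])) |>
                set_names(NUTRIENTS) |> as_tibble(),
              tibble(edible_fraction = runif(m, 0.4, 0.8)))
  bind_rows(species_profiles, commodity_profiles)
}

generate_geography <- function(config, countries) {
  n <- length(countries)
  frac <- runif(n, config$coastal_fraction_range[1],
                config$coastal_fraction_range[2])
  width <- config$buffer_km_default / frac
  height <- 100
  y0 <- (seq_len(n) - 1) * 1000
  g <- config$grid_cells_per_country
  cells <- purrr::map(seq_len(n), function(i) {
    tibble(country = countries[i],
           x = (seq_len(g) - 0.5) * width[i] / g,
           y = y0[i] + runif(g, 0, height),
           persons = round(runif(g, 500, 5000)))
  }) |> purrr::list_rbind()
  coastline <- tibble(country = rep(countries, each = 2),
                      vertex = rep(1:2, n),
                      x = 0,
                      y = as.vector(rbind(y0, y0 + height)))
  list(cells = cells, coastline = coastline)
}

# exportable post-filter production by country x commodity: commercial
# direct-human-consumption catch plus mariculture
exportable_production_by_commodity <- function(config, taxa, catch,
                                               mariculture) {
  dom <- bind_rows(
    catch |> filter(.data$sector %in% COMMERCIAL_SECTORS,
                    .data$end_use == "direct_human_consumption"),
    mariculture)
  dom |>
    left_join(taxa |> select("scientific_name", "commodity"),
              by = "scientific_name") |>
    group_by(.data$country, .data$commodity) |>
    summarise(tonnes = sum(.data$tonnes), .groups = "drop")
}

generate_trade <- function(config, countries, taxa, catch, mariculture) {
  fbs <- exportable_production_by_commodity(config, taxa, catch, mariculture)
  full <- tidyr::crossing(country = countries, commodity = COMMODITIES) |>
    left_join(fbs, by = c("country", "commodity")) |>
    mutate(production = tidyr::replace_na(.data$tonnes, 0)) |>
    select(-"tonnes")
  full <- full |>
    mutate(dom_exports = .data$production * config$export_intensity *
             runif(dplyr::n(), 0.5, 1))
  # distribute each commodity's world export pool as imports
  full <- full |>
    group_by(.data$commodity) |>
    mutate(w = rgamma(dplyr::n(), shape = 1),
           imports = sum(.data$dom_exports) * .data$w / sum(.data$w)) |>
    ungroup() |>
    mutate(reexports = .data$imports * config$reexport_share,
           recorded_reexports = 0.5 * .data$reexports,
           exports = .data$dom_exports + .data$reexports)
  trade <- bind_rows(
    full |> transmute(.data$country, .data$commodity, flow = "import",
                      tonnes = .data$imports),
    full |> transmute(.data$country, .data$commodity, flow = "export",
                      tonnes = .data$exports),
    full |> transmute(.data$country, .data$commodity,
                      flow = "reexport_recorded",
                      tonnes = .data$recorded_reexports)) |>
    filter(.data$tonnes > 0) |>
    arrange(.data$country, .data$commodity, .data$flow)
  list(trade = trade,
       fbs_production = full |>
         select("country", "commodity", tonnes = "production") |>
         filter(.data$tonnes > 0))
}

#' @export
print.ssf_world <- function(x, ...) {
  cat("<ssf_world>\n")
  cat(sprintf("  %d countries, %d taxa, seed %d\n", length(x$countries),
              nrow(x$taxa), x$config$seed))
  cat(sprintf("  catch: %d records; mariculture: %d; trade flows: %d; profiles: %d\n",
              nrow(x$catch), nrow(x$mariculture), nrow(x$trade),
              nrow(x$profiles)))
  invisible(x)
}
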