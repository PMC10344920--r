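#' Configure a synthetic world
#'
#' Builds and validates the configuration for [generate_world()]. The
#' defaults describe the standard validation world used throughout the test
#' suite: 20 coastal countries, 100 marine taxa nested in a
#' class/order/family/genus taxonomy, all five catch sectors active, moderate
#' trade openness and re-export activity, and nutrient-profile missingness
#' spread across taxonomic ranks so that the hierarchical matcher's fallback
#' levels are exercised by construction.
#'
#' Geometry is deliberately planar: each country is a rectangle whose western
#' edge is its coastline, so coastal-strip populations have exact closed
#' forms. Widths are set from `coastal_fraction_range` so that the fraction
#' of the population living within `buffer_km_default` of the coast falls in
#' that range.
#'
#' @param n_countries Number of countries (>= 2).
#' @param n_species Number of species-level taxa.
#' @param taxonomy_shape Named counts of higher taxa: `class`, `order`,
#'   `family`, `genus` (all >= 1).
#' @param sectors_active Subset of
#'   `c("artisanal","subsistence","industrial","recreational","mariculture")`.
#' @param discard_fraction_range Interval in `[0,1]`: share of commercial
#'   catch discarded at sea.
#' @param fmfo_fraction_range Interval in `[0,1]`: share of commercial catch
#'   reduced to fishmeal and fish oil.
#' @param export_intensity Fraction in `[0,1]` scaling how much of exportable
#'   production leaves each country.
#' @param reexport_share Fraction in `[0,1]` of imports that are re-exported
#'   (half recorded as such, half re-exported after processing).
#' @param freshwater_crustacean_export_fraction Fraction of crustacean-
#'   commodity exports attributed to freshwater species (removed before
#'   export subtraction, since the analysis is marine-only).
#' @param profile_missingness_by_rank Named fractions: `species` is the
#'   probability a species lacks its own profile record; `genus`, `family`,
#'   `order`, `class` are probabilities that a whole group's profiles are
#'   removed, pushing its species to coarser fallback levels.
#' @param coastal_fraction_range Interval in `(0,1]`: target share of each
#'   country's population within `buffer_km_default` of the coast.
#' @param grid_cells_per_country Number of population grid cells per country.
#' @param buffer_km_default Headline coastal buffer distance (km).
#' @param seed Integer seed; fixed seed gives a field-for-field identical
#'   world.
#' @return A validated list of class `ssf_world_config`.
#' @examples
#' cfg <- world_config(n_countries = 4, n_species = 20, seed = 7)
#' cfg$n_countries
#' @export
world_config <- function(n_countries = 20,
                         n_species = 100,
                         taxonomy_shape = c(class = 3, order = 8,
                                            family = 20, genus = 45),
                         sectors_active = CATCH_SECTORS,
                         discard_fraction_range = c(0.05, 0.20),
                         fmfo_fraction_range = c(0.05, 0.25),
                         export_intensity = 0.35,
                         reexport_share = 0.15,
                         freshwater_crustacean_export_fraction = 0.10,
                         profile_missingness_by_rank = c(species = 0.35,
                                                         genus = 0.15,
                                                         family = 0.08,
                                                         order = 0.04,
                                                         class = 0),
                         coastal_fraction_range = c(0.2, 0.8),
                         grid_cells_per_country = 60,
                         buffer_km_default = 50,
                         seed = 1L) {
  cfg <- list(n_countries = as.integer(n_countries),
              n_species = as.integer(n_species),
              taxonomy_shape = unlist(taxonomy_shape),
              sectors_active = as.character(unlist(sectors_active)),
              discard_fraction_range = unlist(discard_fraction_range),
              fmfo_fraction_range = unlist(fmfo_fraction_range),
              export_intensity = export_intensity,
              reexport_share = reexport_share,
              freshwater_crustacean_export_fraction =
                freshwater_crustacean_export_fraction,
              profile_missingness_by_rank =
                unlist(profile_missingness_by_rank),
              coastal_fraction_range = unlist(coastal_fraction_range),
              grid_cells_per_country = as.integer(grid_cells_per_country),
              buffer_km_default = buffer_km_default,
              seed = as.integer(seed))
  validate_world_config(cfg)
  structure(cfg, class = "ssf_world_config")
}

validate_world_config <- function(cfg) {
  if (is.na(cfg$n_countries) || cfg$n_countries < 2)
    stop_config("`n_countries` must be >= 2", "n_countries")
  if (is.na(cfg$n_species) || cfg$n_species < 1)
    stop_config("`n_species` must be >= 1", "n_species")
  shp <- cfg$taxonomy_shape
  if (!all(c("class", "order", "family", "genus") %in% names(shp)))
    stop_config("`taxonomy_shape` must name class, order, family and genus",
                "taxonomy_shape")
  if (any(shp < 1))
    stop_config("`taxonomy_shape` counts must be strictly positive",
                "taxonomy_shape")
  if (!all(cfg$sectors_active %in% CATCH_SECTORS) ||
      length(cfg$sectors_active) < 1)
    stop_config("`sectors_active` must be a non-empty subset of the sector vocabulary",
                "sectors_active")
  for (f in c("discard_fraction_range", "fmfo_fraction_range",
              "coastal_fraction_range")) {
    r <- cfg[[f]]
    if (length(r) != 2 || anyNA(r) || any(r < 0) || any(r > 1) || r[1] > r[2])
      stop_config(sprintf("`%s` must be an ordered interval within [0, 1]", f), f)
  }
  if (cfg$coastal_fraction_range[1] <= 0)
    stop_config("`coastal_fraction_range` must be strictly positive",
                "coastal_fraction_range")
  for (f in c("export_intensity", "reexport_share",
              "freshwater_crustacean_export_fraction"))
    assert_fraction(cfg[[f]], f)
  miss <- cfg$profile_missingness_by_rank
  if (!all(c("species", "genus", "family", "order", "class") %in% names(miss)))
    stop_config("`profile_missingness_by_rank` must name species, genus, family, order and class",
                "profile_missingness_by_rank")
  assert_fraction(miss, "profile_missingness_by_rank")
  if (cfg$grid_cells_per_country < 1)
    stop_config("`grid_cells_per_country` must be >= 1", "grid_cells_per_country")
  if (is.na(cfg$buffer_km_default) || cfg$buffer_km_default <= 0)
    stop_config("`buffer_km_default` must be positive", "buffer_km_default")
  if (is.na(cfg$seed))
    stop_config("`seed` must be an integer", "seed")
  invisible(cfg)
}

#' @export
print.ssf_world_config <- function(x, ...) {
  cat("<ssf_world_config>\n")
  cat(sprintf("  %d countries, %d species (%s)\n", x$n_countries, x$n_species,
              paste(sprintf("%s=%d", names(x$taxonomy_shape),
                            x$taxonomy_shape), collapse = ", ")))
  cat(sprintf("  sectors: %s\n", paste(x$sectors_active, collapse = ", ")))
  cat(sprintf("  export intensity %.2f, re-export share %.2f, seed %d\n",
              x$export_intensity, x$reexport_share, x$seed))
  invisible(x)
}
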