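# Ground-truth bookkeeping for synthetic worlds.
#
# Everything in this file is deliberately written in plain base R
# (data.frame, tapply, match, arrays) so that the expected values carried by
# a synthetic world never depend on the dplyr pipeline stages they are used
# to validate. `world_truth()` is the vectorised bookkeeper invoked by
# `generate_world()`; `ground_truth_contributions()` re-derives the same
# quantities a second time with explicit record-by-record loops.

kkey <- function(a, b) paste(a, b, sep = "\r")

#' Expected pipeline outputs for a synthetic world
#'
#' Recomputes, by direct mass-balance bookkeeping over the generated tables,
#' what every pipeline stage should produce: apparent consumption by
#' country/taxon/sector, nutrient supply and per-capita supply by
#' country/sector/nutrient, SSF contribution fractions under the three
#' denominator scopes, per-country six-nutrient means, and the
#' vulnerable/reliant classification flags. None of the pipeline-stage
#' functions are called.
#'
#' @param world An `ssf_world`.
#' @param buffer_km Coastal buffer distance; defaults to the world's
#'   configured default.
#' @param artisanal_exportable Is artisanal production part of the exportable
#'   pool (the conservative base case)?
#' @param percentile,supply_threshold,intake_threshold Classification
#'   parameters (see [classify()]).
#' @return A list of class `ssf_truth` of expected stage outputs.
#' @export
world_truth <- function(world, buffer_km = NULL, artisanal_exportable = TRUE,
                        percentile = 0.70, supply_threshold = 0.15,
                        intake_threshold = 0.50) {
  cfg <- world$config
  if (is.null(buffer_km)) buffer_km <- cfg$buffer_km_default
  fwc <- cfg$freshwater_crustacean_export_fraction
  countries <- world$countries
  taxa <- as.data.frame(world$taxa)
  catch <- as.data.frame(world$catch)
  mar <- as.data.frame(world$mariculture)
  trade <- as.data.frame(world$trade)
  fbs <- as.data.frame(world$fbs_production)

  # --- end-use filter; commercial + mariculture production; non-commercial
  com <- catch[catch$sector %in% COMMERCIAL_SECTORS &
                 catch$end_use == "direct_human_consumption",
               c("country", "scientific_name", "sector", "tonnes")]
  prod <- rbind(com, mar[, c("country", "scientific_name", "sector", "tonnes")])
  prod <- agg_sum(prod, c("country", "scientific_name", "sector"))
  noncom <- catch[catch$sector %in% NONCOMMERCIAL_SECTORS,
                  c("country", "scientific_name", "sector", "tonnes")]
  noncom <- agg_sum(noncom, c("country", "scientific_name", "sector"))
  prod$commodity <- taxa$commodity[match(prod$scientific_name,
                                         taxa$scientific_name)]

  # --- trade: re-export estimation and adjustment per country x commodity
  fv <- function(fl) {
    d <- trade[trade$flow == fl, ]
    if (!nrow(d)) return(numeric(0))
    tapply(d$tonnes, kkey(d$country, d$commodity), sum)
  }
  impv <- fv("import"); expv <- fv("export"); recv <- fv("reexport_recorded")
  fbsv <- if (nrow(fbs)) tapply(fbs$tonnes, kkey(fbs$country, fbs$commodity),
                                sum) else numeric(0)
  keys <- unique(c(names(impv), names(expv), names(recv), names(fbsv),
                   kkey(prod$country, prod$commodity)))
  pick <- function(v, k) { out <- v[k]; out[is.na(out)] <- 0
    as.numeric(out) }
  I <- pick(impv, keys); E <- pick(expv, keys)
  R <- pick(recv, keys); P <- pick(fbsv, keys)
  processed <- pmax(0, E - P)
  total <- pmin(R + processed, E)
  adjE <- pmax(0, E - total)
  adjI <- pmax(0, I - total)
  key_com <- sub("^.*\r", "", keys)
  key_cty <- sub("\r.*$", "", keys)
  adjE[key_com == CRUSTACEAN_COMMODITY] <-
    adjE[key_com == CRUSTACEAN_COMMODITY] * (1 - fwc)

  # --- proportional export allocation with clamp at zero
  exportable <- c(if (artisanal_exportable) "artisanal", "industrial",
                  "mariculture")
  pk <- kkey(prod$country, prod$commodity)
  is_exp <- prod$sector %in% exportable
  poolv <- stats::setNames(rep(0, length(keys)), keys)
  if (nrow(prod)) {
    pool <- tapply(prod$tonnes * is_exp, pk, sum)
    poolv[names(pool)] <- pool
  }
  adjEv <- stats::setNames(adjE, keys)
  alloc <- ifelse(is_exp & poolv[pk] > 0,
                  adjEv[pk] * prod$tonnes / poolv[pk], 0)
  retained <- pmax(0, prod$tonnes - alloc)
  surplus <- pmax(0, adjE - unname(poolv[keys]))

  # --- apparent consumption
  cons <- rbind(
    data.frame(country = prod$country, taxon = prod$scientific_name,
               sector = prod$sector, commodity = prod$commodity,
               tonnes = retained),
    data.frame(country = key_cty[adjI > 0], taxon = key_com[adjI > 0],
               sector = rep("imports", sum(adjI > 0)),
               commodity = key_com[adjI > 0], tonnes = adjI[adjI > 0]),
    if (nrow(noncom)) data.frame(
      country = noncom$country, taxon = noncom$scientific_name,
      sector = noncom$sector,
      commodity = taxa$commodity[match(noncom$scientific_name,
                                       taxa$scientific_name)],
      tonnes = noncom$tonnes))

  # --- nutrient matching (hierarchical fallback, per-nutrient)
  profiles <- as.data.frame(world$profiles)
  pnorm <- lapply(LEVEL_COLUMNS, function(cl) normalize_key(profiles[[cl]]))
  fields <- c(NUTRIENTS, "edible_fraction")
  match_one <- function(tx) {
    res <- stats::setNames(rep(NA_real_, length(fields)), fields)
    for (lv in MATCH_LEVELS) {
      key <- normalize_key(tx[[LEVEL_COLUMNS[[lv]]]])
      if (is.na(key)) next
      hit <- which(!is.na(pnorm[[lv]]) & pnorm[[lv]] == key)
      if (!length(hit)) next
      for (f in fields) {
        if (is.na(res[[f]])) {
          v <- profiles[[f]][hit]
          v <- v[!is.na(v)]
          if (length(v)) res[[f]] <- mean(v)
        }
      }
      if (!anyNA(res)) break
    }
    res
  }
  dom_taxa <- unique(cons$taxon[cons$sector != "imports"])
  taxa_rows <- taxa[match(dom_taxa, taxa$scientific_name), , drop = FALSE]
  prof_dom <- do.call(rbind, lapply(seq_along(dom_taxa), function(i)
    match_one(taxa_rows[i, , drop = FALSE])))
  imp_coms <- unique(cons$commodity[cons$sector == "imports"])
  prof_imp <- do.call(rbind, lapply(imp_coms, function(cm)
    match_one(data.frame(scientific_name = NA, genus = NA, family = NA,
                         order = NA, class = NA, commodity = cm))))
  prof_key <- c(dom_taxa, imp_coms)
  prof_all <- rbind(prof_dom, prof_imp)
  ridx <- ifelse(cons$sector == "imports",
                 match(cons$commodity, prof_key),
                 match(cons$taxon, prof_key))

  # --- nutrient supply: tonnes x 1e4 (100 g units/tonne) x edible x conc
  nC <- length(countries)
  supply <- array(0, dim = c(nC, length(SOURCE_SECTORS), length(NUTRIENTS)),
                  dimnames = list(countries, SOURCE_SECTORS, NUTRIENTS))
  ci <- match(cons$country, countries)
  si <- match(cons$sector, SOURCE_SECTORS)
  ef <- prof_all[ridx, "edible_fraction"]
  for (ni in seq_along(NUTRIENTS)) {
    mass <- cons$tonnes * 1e4 * ef * prof_all[ridx, NUTRIENTS[ni]]
    for (r in seq_along(mass)) {
      supply[ci[r], si[r], ni] <- supply[ci[r], si[r], ni] + mass[r]
    }
  }

  # --- populations: coastline is the x = 0 western edge, so planar distance
  # for every cell is simply its x coordinate
  cells <- as.data.frame(world$population_cells)
  coastal <- tapply(cells$persons * (cells$x <= buffer_km), cells$country, sum)
  national <- tapply(cells$persons, cells$country, sum)
  coastal <- pick(coastal, countries); national <- pick(national, countries)

  percap <- supply
  for (s in seq_along(SOURCE_SECTORS)) {
    popn <- if (SOURCE_SECTORS[s] %in% SSF_SECTORS) coastal else national
    percap[, s, ] <- supply[, s, ] / (popn * 365)
    percap[, s, ][popn == 0 & supply[, s, ] == 0] <- 0
  }

  # --- contributions under the three denominator scopes
  gnd <- as.data.frame(world$gnd_nonseafood)
  animal_sum <- all_sum <- matrix(0, nC, length(NUTRIENTS),
                                  dimnames = list(countries, NUTRIENTS))
  gi <- match(gnd$country, countries); gn <- match(gnd$nutrient, NUTRIENTS)
  for (r in seq_len(nrow(gnd))) {
    all_sum[gi[r], gn[r]] <- all_sum[gi[r], gn[r]] + gnd$per_capita_per_day[r]
    if (gnd$food_group[r] %in% ANIMAL_GROUPS) {
      animal_sum[gi[r], gn[r]] <- animal_sum[gi[r], gn[r]] +
        gnd$per_capita_per_day[r]
    }
  }
  # DHA+EPA is assumed to come exclusively from seafood
  animal_sum[, "dha_epa"] <- 0
  all_sum[, "dha_epa"] <- 0

  ssf_pc <- apply(percap[, SSF_SECTORS, , drop = FALSE], c(1, 3), sum)
  sea_pc <- apply(percap, c(1, 3), sum)
  frac <- function(D) ifelse(D > 0, ssf_pc / D, NA_real_)
  f_sea <- frac(sea_pc)
  f_asf <- frac(sea_pc + animal_sum)
  f_all <- frac(sea_pc + all_sum)

  # --- means over the six assessed nutrients, and classification flags
  mean_over <- function(m) {
    v <- rowMeans(m[, ASSESSED_NUTRIENTS, drop = FALSE], na.rm = TRUE)
    v[is.nan(v)] <- NA_real_
    unname(v)
  }
  mean_all <- mean_over(f_all)
  ii <- as.data.frame(world$inadequate_intake)
  ii <- ii[ii$nutrient %in% ASSESSED_NUTRIENTS, ]
  mean_int <- rep(NA_real_, nC)
  if (nrow(ii)) {
    mi <- tapply(ii$prevalence, ii$country, mean)
    mean_int <- as.numeric(mi[countries])
  }
  cut_sup <- percentile_cutoff(mean_all, percentile)
  cut_int <- percentile_cutoff(mean_int, percentile)
  above <- function(x, cutoff) {
    if (percentile == 0) {
      flag <- rep(TRUE, length(x)); flag[is.na(x) | is.na(cutoff)] <- NA
      flag
    } else x > cutoff
  }
  flags <- tibble::tibble(
    country = countries,
    mean_ssf_contribution = mean_all,
    mean_inadequate_intake = mean_int,
    reliant_percentile = above(mean_all, cut_sup),
    vulnerable_percentile = above(mean_int, cut_int),
    reliant_absolute = mean_all >= supply_threshold,
    vulnerable_absolute = mean_int >= intake_threshold)

  contrib_tbl <- function(m) {
    tibble::tibble(country = rep(countries, times = length(NUTRIENTS)),
                   nutrient = rep(NUTRIENTS, each = nC),
                   ssf_fraction = as.vector(m))
  }
  grid <- expand.grid(country = countries, sector = SOURCE_SECTORS,
                      nutrient = NUTRIENTS, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  structure(list(
    expected_apparent_consumption = tibble::as_tibble(
      agg_sum(cons[, c("country", "taxon", "sector", "tonnes")],
              c("country", "taxon", "sector"))),
    expected_supply = tibble::as_tibble(
      data.frame(grid, mass_per_year = as.vector(supply))),
    expected_per_capita = tibble::as_tibble(
      data.frame(grid, per_capita_per_day = as.vector(percap))),
    expected_contribution_seafood = contrib_tbl(f_sea),
    expected_contribution_asf = contrib_tbl(f_asf),
    expected_contribution_allfoods = contrib_tbl(f_all),
    expected_flags = flags,
    coastal_population = tibble::tibble(country = countries,
                                        coastal_persons = coastal,
                                        national_persons = national),
    export_surplus = tibble::tibble(country = key_cty, commodity = key_com,
                                    surplus = surplus)[surplus > 0, ],
    params = list(buffer_km = buffer_km,
                  artisanal_exportable = artisanal_exportable,
                  percentile = percentile,
                  supply_threshold = supply_threshold,
                  intake_threshold = intake_threshold)),
    class = "ssf_truth")
}

compute_world_truth <- world_truth

agg_sum <- function(df, by) {
  if (!nrow(df)) {
    df$tonnes <- numeric(0)
    return(df[, c(by, "tonnes")])
  }
  out <- aggregate(df[["tonnes"]], df[by], sum)
  names(out) <- c(by, "tonnes")
  out[do.call(order, out[by]), , drop = FALSE]
}
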