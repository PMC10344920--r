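one_taxon_world <- function() {
  taxa <- tibble::tibble(scientific_name = "Sp a", genus = "G", family = "F",
                         order = "O", class = "K",
                         commodity = "pelagic_fish")
  lookup <- build_lookup(make_profile("Sp a", genus = "G", family = "F",
                                      order = "O", class = "K",
                                      commodity = "pelagic_fish",
                                      calcium = 20, edible_fraction = 0.5))
  list(taxa = taxa, lookup = lookup)
}

test_that("supply conversion follows the edible-portion unit arithmetic", {
  fx <- one_taxon_world()
  cons <- tibble::tibble(country = "C01", taxon = "Sp a",
                         sector = "artisanal", commodity = "pelagic_fish",
                         tonnes = 1)
  sup <- nutrient_supply(cons, fx$lookup, fx$taxa)
  # 1 t x 10^4 hundred-gram units x 0.5 edible x 20 mg/100 g = 100,000 mg
  expect_equal(sup$mass_per_year[sup$nutrient == "calcium"], 1e5)
  zero <- nutrient_supply(dplyr::mutate(cons, tonnes = 0), fx$lookup,
                          fx$taxa)
  expect_true(all(zero$mass_per_year == 0))
})

test_that("imports are valued at the commodity mean profile", {
  p <- dplyr::bind_rows(
    make_profile("Sp a", commodity = "molluscs", zinc = 2,
                 edible_fraction = 1),
    make_profile("Sp b", genus = "H", commodity = "molluscs", zinc = 6,
                 edible_fraction = 1))
  lk <- build_lookup(p)
  cons <- tibble::tibble(country = "C01", taxon = "molluscs",
                         sector = "imports", commodity = "molluscs",
                         tonnes = 1)
  sup <- nutrient_supply(cons, lk, tibble::tibble(scientific_name = character(),
                                                  commodity = character()))
  expect_equal(sup$mass_per_year[sup$nutrient == "zinc"], 1 * 1e4 * 1 * 4)
})

test_that("per-capita division uses coastal population for SSF sectors", {
  supply <- tibble::tibble(country = "C01",
                           sector = c("artisanal", "industrial"),
                           nutrient = "protein",
                           mass_per_year = c(365, 730))
  coastal <- tibble::tibble(country = "C01", persons = 1)
  national <- tibble::tibble(country = "C01", persons = 2)
  pc <- per_capita_supply(supply, coastal, national)
  expect_equal(pc$per_capita_per_day[pc$sector == "artisanal"], 1)
  expect_equal(pc$per_capita_per_day[pc$sector == "industrial"], 1)
  # doubling the coastal population halves SSF per-capita supply
  pc2 <- per_capita_supply(supply, dplyr::mutate(coastal, persons = 2),
                           national)
  expect_equal(pc2$per_capita_per_day[pc2$sector == "artisanal"], 0.5)
  expect_error(per_capita_supply(supply,
                                 dplyr::mutate(coastal, persons = 0),
                                 national),
               class = "nutrisupply_data_error")
})

test_that("an SSF-only producer has seafood-scope fraction one", {
  pc <- tibble::tibble(country = "C01", sector = "subsistence",
                       nutrient = NUTR, mass_per_year = 1, population = 10,
                       per_capita_per_day = 0.3)
  gnd <- tibble::tibble(country = "C01", food_group = "beef",
                        nutrient = NUTR, per_capita_per_day = 0.6)
  out <- ssf_contribution(pc, gnd)
  sea <- out[out$denominator_scope == "seafood", ]
  expect_true(all(sea$ssf_fraction == 1))
  asf <- out[out$denominator_scope == "animal_sourced", ]
  expect_equal(asf$ssf_fraction[asf$nutrient == "iron"], 1 / 3)
  # DHA+EPA: non-seafood denominators forced to zero in every scope
  expect_true(all(out$ssf_fraction[out$nutrient == "dha_epa"] == 1))
})

test_that("undefined denominators give missing fractions, not zeros", {
  pc <- tibble::tibble(country = "C01", sector = "industrial",
                       nutrient = "dha_epa", mass_per_year = 0,
                       population = 10, per_capita_per_day = 0)
  gnd <- tibble::tibble(country = "C01", food_group = "grains",
                        nutrient = "dha_epa", per_capita_per_day = 0.2)
  out <- ssf_contribution(pc, gnd)
  expect_true(all(is.na(out$ssf_fraction[out$nutrient == "dha_epa"])))
})

test_that("scopes are nested and DHA+EPA scopes coincide on random worlds", {
  for (s in c(17, 18)) {
    run <- run_pipeline(small_world(s))
    wide <- run$contributions |>
      tidyr::pivot_wider(names_from = denominator_scope,
                         values_from = ssf_fraction)
    ok <- with(wide, is.na(seafood) |
                 (all_foods <= animal_sourced + 1e-12 &
                    animal_sourced <= seafood + 1e-12))
    expect_true(all(ok))
    dha <- wide[wide$nutrient == "dha_epa" & !is.na(wide$seafood), ]
    expect_equal(dha$all_foods, dha$seafood, tolerance = 1e-12)
    expect_equal(dha$animal_sourced, dha$seafood, tolerance = 1e-12)
  }
})

test_that("sector contributions to seafood supply sum to one", {
  run <- run_pipeline(small_world(19))
  shares <- run$per_capita |>
    dplyr::group_by(country, nutrient) |>
    dplyr::summarise(total = sum(per_capita_per_day), .groups = "drop") |>
    dplyr::filter(total > 0)
  per_sector <- run$per_capita |>
    dplyr::inner_join(shares, by = c("country", "nutrient")) |>
    dplyr::group_by(country, nutrient) |>
    dplyr::summarise(s = sum(per_capita_per_day / total), .groups = "drop")
  expect_equal(per_sector$s, rep(1, nrow(per_sector)), tolerance = 1e-9)
})

test_that("mean contribution averages the assessed six and flags gaps", {
  rec <- tibble::tibble(country = "C01", nutrient = NUTR[1:6],
                        denominator_scope = "all_foods",
                        ssf_fraction = 0.1)
  expect_equal(mean_contribution(rec)$mean_fraction, 0.1)
  rec2 <- dplyr::mutate(rec, ssf_fraction = c(0, 0, 0, 0, 0, 0.6))
  expect_equal(mean_contribution(rec2)$mean_fraction, 0.1)
  rec3 <- dplyr::mutate(rec, ssf_fraction = c(NA, 0.2, 0.2, 0.2, 0.2, 0.2))
  m <- mean_contribution(rec3)
  expect_equal(m$mean_fraction, 0.2)
  expect_equal(m$n_missing, 1L)
  # protein never enters the assessed mean
  rec4 <- dplyr::bind_rows(rec, tibble::tibble(
    country = "C01", nutrient = "protein", denominator_scope = "all_foods",
    ssf_fraction = 0.9))
  expect_equal(mean_contribution(rec4)$mean_fraction, 0.1)
})
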