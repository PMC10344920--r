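catch_row <- function(country = "C01", sci = "Gadus morhua",
                      sector = "industrial",
                      end_use = "direct_human_consumption", tonnes = 10) {
  tibble::tibble(country = country, scientific_name = sci, sector = sector,
                 end_use = end_use, tonnes = tonnes)
}

test_that("discard and fishmeal catch is removed from commercial sectors only", {
  catch <- dplyr::bind_rows(
    catch_row(sector = "industrial", end_use = "discard"),
    catch_row(sector = "industrial", end_use = "fishmeal_fish_oil"),
    catch_row(sector = "industrial", tonnes = 5),
    catch_row(sector = "artisanal", end_use = "discard"),
    catch_row(sector = "subsistence", end_use = "discard", tonnes = 2),
    catch_row(sector = "recreational", tonnes = 3))
  out <- filter_human_consumption(catch)
  expect_equal(nrow(out), 3)
  expect_true(all(out$end_use == "direct_human_consumption" |
                    !out$sector %in% c("artisanal", "industrial")))
  # non-commercial rows pass through untouched, whatever the end use
  expect_true(any(out$sector == "subsistence" & out$end_use == "discard"))
  expect_identical(filter_human_consumption(out), out)
  expect_error(filter_human_consumption(
    catch_row(end_use = "ornamental")), class = "nutrisupply_data_error")
})

test_that("re-exports combine recorded flows and the production-export gap", {
  # production covers exports: nothing inferred
  t1 <- tibble::tibble(country = "C01", commodity = "pelagic_fish",
                       flow = "export", tonnes = 10)
  f1 <- tibble::tibble(country = "C01", commodity = "pelagic_fish",
                       tonnes = 25)
  r1 <- estimate_reexports(t1, f1)
  expect_equal(r1$processed_reexports, 0)
  expect_equal(r1$total_reexports, 0)

  # exports 30 against production 25 with 2 recorded: 5 processed, 7 total
  t2 <- tibble::tibble(country = "C01", commodity = "pelagic_fish",
                       flow = c("export", "reexport_recorded"),
                       tonnes = c(30, 2))
  r2 <- estimate_reexports(t2, f1)
  expect_equal(r2$recorded_reexports, 2)
  expect_equal(r2$processed_reexports, 5)
  expect_equal(r2$total_reexports, 7)
})

test_that("re-export estimation matches a cellwise oracle on random tables", {
  withr::local_seed(404)
  for (rep in 1:10) {
    n <- 30
    tr <- tibble::tibble(
      country = sample(sprintf("C%02d", 1:5), n, replace = TRUE),
      commodity = sample(c("pelagic_fish", "crustaceans", "molluscs"), n,
                         replace = TRUE),
      flow = sample(c("import", "export", "reexport_recorded"), n,
                    replace = TRUE),
      tonnes = runif(n, 0, 100))
    fbs <- tibble::tibble(
      country = sample(sprintf("C%02d", 1:5), 8, replace = TRUE),
      commodity = sample(c("pelagic_fish", "crustaceans"), 8, replace = TRUE),
      tonnes = runif(8, 0, 120))
    est <- estimate_reexports(tr, fbs)
    adj <- adjust_trade(tr, est)
    for (i in seq_len(nrow(est))) {
      sub <- tr[tr$country == est$country[i] &
                  tr$commodity == est$commodity[i], ]
      E <- sum(sub$tonnes[sub$flow == "export"])
      I <- sum(sub$tonnes[sub$flow == "import"])
      R <- sum(sub$tonnes[sub$flow == "reexport_recorded"])
      P <- sum(fbs$tonnes[fbs$country == est$country[i] &
                            fbs$commodity == est$commodity[i]])
      expect_equal(est$recorded_reexports[i], R)
      expect_equal(est$processed_reexports[i], max(0, E - P))
      tot <- min(R + max(0, E - P), E)
      expect_equal(est$total_reexports[i], tot)
      a <- adj[adj$country == est$country[i] &
                 adj$commodity == est$commodity[i], ]
      expect_equal(a$exports, max(0, E - tot))
      expect_equal(a$imports, max(0, I - tot))
    }
  }
})

test_that("trade adjustment clamps at zero and is identity without re-exports", {
  tr <- tibble::tibble(country = "C01", commodity = "molluscs",
                       flow = c("import", "export"), tonnes = c(8, 12))
  zero <- tibble::tibble(country = "C01", commodity = "molluscs",
                         recorded_reexports = 0, processed_reexports = 0,
                         total_reexports = 0)
  adj <- adjust_trade(tr, zero)
  expect_equal(adj$imports, 8)
  expect_equal(adj$exports, 12)
  full <- dplyr::mutate(zero, total_reexports = 12)
  adj2 <- adjust_trade(tr, full)
  expect_equal(adj2$exports, 0)
  expect_equal(adj2$imports, 0)
})

test_that("the freshwater share is removed from crustacean exports only", {
  ex <- tibble::tibble(country = c("C01", "C01"),
                       commodity = c("crustaceans", "molluscs"),
                       exports = c(40, 40))
  expect_equal(remove_freshwater_crustaceans(ex, 0)$exports, c(40, 40))
  expect_equal(remove_freshwater_crustaceans(ex, 1)$exports, c(0, 40))
  expect_equal(remove_freshwater_crustaceans(ex, 0.25)$exports, c(30, 40))
  percountry <- tibble::tibble(country = "C01", fraction = 0.5)
  expect_equal(remove_freshwater_crustaceans(ex, percountry)$exports,
               c(20, 40))
  expect_error(remove_freshwater_crustaceans(ex, 1.2),
               class = "nutrisupply_config_error")
})

test_that("exports are allocated proportionally and clamped at zero", {
  cmap <- tibble::tibble(scientific_name = c("Sp a", "Sp b"),
                         commodity = "pelagic_fish")
  prod <- tibble::tibble(country = "C01",
                         scientific_name = c("Sp a", "Sp b"),
                         sector = "industrial", tonnes = c(60, 40))
  ex <- tibble::tibble(country = "C01", commodity = "pelagic_fish",
                       exports = 50)
  out <- subtract_exports(prod, ex, cmap)
  expect_equal(out$retained$tonnes, c(30, 20))
  expect_equal(nrow(out$surplus), 0)

  # exports exceed production: everything clamps to zero, surplus reported
  ex2 <- dplyr::mutate(ex, exports = 150)
  out2 <- subtract_exports(prod, ex2, cmap)
  expect_equal(out2$retained$tonnes, c(0, 0))
  expect_equal(out2$surplus$surplus, 50)

  # non-exportable artisanal production is untouched when retained
  prod3 <- dplyr::bind_rows(prod,
                            tibble::tibble(country = "C01",
                                           scientific_name = "Sp a",
                                           sector = "artisanal",
                                           tonnes = 100))
  out3 <- subtract_exports(prod3, ex, cmap, artisanal_exportable = FALSE)
  expect_equal(out3$retained$tonnes[out3$retained$sector == "artisanal"], 100)
  expect_equal(out3$retained$tonnes[out3$retained$sector == "industrial"],
               c(30, 20))
  out4 <- subtract_exports(prod3, ex, cmap, artisanal_exportable = TRUE)
  # pool widens to 200; allocation shifts to shares of 50 across cells
  expect_equal(sum(out4$allocation$allocation), 50)
  expect_equal(out4$retained$tonnes[out4$retained$sector == "artisanal"],
               100 - 50 * 100 / 200)

  expect_error(subtract_exports(prod, ex, cmap[0, ]),
               class = "nutrisupply_data_error")
})

test_that("random allocations equal a brute-force per-cell oracle", {
  withr::local_seed(505)
  for (rep in 1:10) {
    n <- 25
    cmap <- tibble::tibble(scientific_name = paste0("Sp ", 1:8),
                           commodity = sample(c("pelagic_fish", "molluscs"),
                                              8, replace = TRUE))
    prod <- tibble::tibble(
      country = sample(c("C01", "C02"), n, replace = TRUE),
      scientific_name = sample(cmap$scientific_name, n, replace = TRUE),
      sector = sample(c("artisanal", "industrial", "mariculture"), n,
                      replace = TRUE),
      tonnes = runif(n, 0, 50)) |>
      dplyr::distinct(country, scientific_name, sector, .keep_all = TRUE)
    ex <- tidyr::crossing(country = c("C01", "C02"),
                          commodity = c("pelagic_fish", "molluscs")) |>
      dplyr::mutate(exports = runif(4, 0, 120))
    out <- subtract_exports(prod, ex, cmap)
    prod_c <- dplyr::left_join(prod, cmap, by = "scientific_name")
    for (i in seq_len(nrow(prod_c))) {
      pool <- sum(prod_c$tonnes[prod_c$country == prod_c$country[i] &
                                  prod_c$commodity == prod_c$commodity[i]])
      E <- ex$exports[ex$country == prod_c$country[i] &
                        ex$commodity == prod_c$commodity[i]]
      expected <- max(0, prod_c$tonnes[i] - E * prod_c$tonnes[i] / pool)
      got <- out$retained$tonnes[
        out$retained$country == prod_c$country[i] &
          out$retained$scientific_name == prod_c$scientific_name[i] &
          out$retained$sector == prod_c$sector[i]]
      expect_equal(got, expected, tolerance = 1e-12)
    }
  }
})

test_that("apparent consumption assembles the three sources", {
  cmap <- tibble::tibble(scientific_name = c("Sp a", "Sp b"),
                         commodity = c("pelagic_fish", "molluscs"))
  retained <- tibble::tibble(country = "C01", scientific_name = "Sp a",
                             sector = "industrial",
                             commodity = "pelagic_fish", tonnes = 12)
  imports <- tibble::tibble(country = "C01",
                            commodity = c("molluscs", "crustaceans"),
                            imports = c(5, 0))
  noncom <- tibble::tibble(country = "C01", scientific_name = "Sp b",
                           sector = "subsistence", tonnes = 7)
  out <- apparent_consumption(retained, imports, noncom, cmap)
  expect_equal(nrow(out), 3)  # zero-import commodity dropped
  imp <- out[out$sector == "imports", ]
  expect_identical(imp$taxon, "molluscs")
  expect_equal(imp$tonnes, 5)
  expect_equal(out$tonnes[out$sector == "subsistence"], 7)
})

test_that("mass balance holds across random worlds", {
  for (s in c(21, 22, 23)) {
    run <- run_pipeline(small_world(s))
    expect_true(all(run$consumption$tonnes >= 0))
    expect_lt(max(run$residuals$relative_residual), 1e-9)
    expect_true(run$passed)
  }
})
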