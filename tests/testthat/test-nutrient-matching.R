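test_that("rank means are arithmetic means over shared rank values", {
  p <- dplyr::bind_rows(
    make_profile("Gadus morhua", calcium = 10),
    make_profile("Gadus ogac", calcium = 30))
  lk <- build_lookup(p)
  expect_equal(lk$tables$genus$calcium, 20)
  expect_equal(nrow(lk$tables$species), 2)
  single <- build_lookup(make_profile("Solo fish", calcium = 7, zinc = 3))
  for (lv in c("species", "genus", "family", "order", "class", "commodity")) {
    expect_equal(single$tables[[lv]]$calcium, 7, label = lv)
    expect_equal(single$tables[[lv]]$zinc, 3, label = lv)
  }
  expect_error(build_lookup(p[0, ]), class = "nutrisupply_data_error")
})

test_that("randomized rank means equal exhaustive group means", {
  withr::local_seed(101)
  p <- random_profiles(200, na_prob = 0.3)
  lk <- build_lookup(p)
  rank_cols <- c(species = "scientific_name", genus = "genus",
                 family = "family", order = "order", class = "class",
                 commodity = "commodity")
  for (lv in names(rank_cols)) {
    tbl <- lk$tables[[lv]]
    keyvals <- tolower(trimws(p[[rank_cols[[lv]]]]))
    for (i in seq_len(nrow(tbl))) {
      rows <- which(!is.na(keyvals) & keyvals == tbl$.key[i])
      for (nu in c(NUTR, "edible_fraction")) {
        v <- p[[nu]][rows]
        v <- v[!is.na(v)]
        expected <- if (length(v)) mean(v) else NA_real_
        expect_equal(tbl[[nu]][i], expected,
                     label = sprintf("%s/%s/%s", lv, tbl$.key[i], nu))
      }
    }
  }
})

test_that("fallback walks species, genus, family, order, class, commodity", {
  p <- dplyr::bind_rows(
    make_profile("Gadus morhua", iron = 2),
    make_profile("Gadus ogac", iron = 4),
    make_profile("Merluccius merluccius", genus = "Merluccius",
                 family = "Merlucciidae", iron = 8),
    make_profile("Clupea harengus", genus = "Clupea", family = "Clupeidae",
                 order = "Clupeiformes", commodity = "pelagic_fish",
                 iron = 16),
    tibble::tibble(scientific_name = NA, genus = NA, family = NA, order = NA,
                   class = NA, commodity = "crustaceans", iron = 32, zinc = 1,
                   calcium = 1, vitamin_a = 1, vitamin_b12 = 1, dha_epa = 1,
                   protein = 1, edible_fraction = 0.4))
  lk <- build_lookup(p)
  tx <- function(...) tibble::tibble(...)

  r <- match_nutrients(tx(scientific_name = "Gadus morhua", genus = "Gadus",
                          family = "Gadidae", order = "Gadiformes",
                          class = "Actinopterygii",
                          commodity = "demersal_fish"), lk)
  expect_identical(r$level, "species")
  expect_equal(r$profile$iron, 2)

  r <- match_nutrients(tx(scientific_name = "Gadus nov", genus = "Gadus",
                          family = "Gadidae", order = "Gadiformes",
                          class = "Actinopterygii",
                          commodity = "demersal_fish"), lk)
  expect_identical(r$level, "genus")
  expect_equal(r$profile$iron, 3)  # mean of the two congeners

  r <- match_nutrients(tx(scientific_name = "Novel sp", genus = "Novelus",
                          family = "Merlucciidae", order = "Gadiformes",
                          class = "Actinopterygii",
                          commodity = "demersal_fish"), lk)
  expect_identical(r$level, "family")
  expect_equal(r$profile$iron, 8)

  r <- match_nutrients(tx(scientific_name = "Weird sp", genus = "X",
                          family = "Y", order = "Clupeiformes",
                          class = "Actinopterygii",
                          commodity = "pelagic_fish"), lk)
  expect_identical(r$level, "order")
  expect_equal(r$profile$iron, 16)

  # unknown everywhere except commodity: terminal fallback
  r <- match_nutrients(tx(scientific_name = "Alien sp", genus = "A",
                          family = "B", order = "C", class = "D",
                          commodity = "crustaceans"), lk)
  expect_identical(r$level, "commodity")
  expect_equal(r$profile$iron, 32)

  expect_error(match_nutrients(tx(scientific_name = "Alien sp", genus = "A",
                                  family = "B", order = "C", class = "D",
                                  commodity = "unheard_of"), lk),
               class = "nutrisupply_data_error")
})

test_that("names are matched after case-folding and whitespace collapse", {
  lk <- build_lookup(make_profile("Gadus  morhua", calcium = 9))
  r <- match_nutrients(tibble::tibble(scientific_name = " gadus MORHUA ",
                                      genus = "Gadus", family = "Gadidae",
                                      order = "Gadiformes",
                                      class = "Actinopterygii",
                                      commodity = "demersal_fish"), lk)
  expect_identical(r$level, "species")
  expect_equal(r$profile$calcium, 9)
})

test_that("a nutrient missing at the match level falls back alone", {
  p <- dplyr::bind_rows(
    make_profile("Gadus morhua", iron = NA_real_, zinc = 5,
                 edible_fraction = NA_real_),
    make_profile("Gadus ogac", iron = 7, zinc = 9, edible_fraction = 0.6))
  lk <- build_lookup(p)
  r <- match_nutrients(tibble::tibble(scientific_name = "Gadus morhua",
                                      genus = "Gadus", family = "Gadidae",
                                      order = "Gadiformes",
                                      class = "Actinopterygii",
                                      commodity = "demersal_fish"), lk)
  expect_identical(r$level, "species")
  expect_equal(r$profile$zinc, 5)             # species value
  expect_equal(r$profile$iron, 7)             # genus fallback for iron only
  expect_identical(unname(r$field_levels[["iron"]]), "genus")
  expect_equal(r$profile$edible_fraction, 0.6)  # edible fraction same chain
})

test_that("matching equals the brute-force scan on randomized pairs", {
  withr::local_seed(202)
  n_pairs <- 0
  for (rep in 1:40) {
    p <- random_profiles(sample(5:25, 1), na_prob = 0.35)
    lk <- build_lookup(p)
    pool <- random_taxon_pool()
    taxa <- tibble::as_tibble(pool[sample(nrow(pool), 6, replace = TRUE), ])
    # sometimes degrade the taxon to a coarser key
    res <- match_taxa(taxa, lk)
    for (i in seq_len(nrow(taxa))) {
      oracle <- nutrisupply:::oracle_match_taxon(as.list(taxa[i, ]), p)
      expect_identical(res$match_level[i], oracle$level)
      for (nu in c(NUTR, "edible_fraction")) {
        expect_equal(res[[nu]][i], unname(oracle$values[[nu]]),
                     label = sprintf("rep %d row %d %s", rep, i, nu))
        expect_identical(res[[paste0(nu, "_level")]][i],
                         unname(oracle$field_levels[[nu]]))
      }
      n_pairs <- n_pairs + 1
    }
  }
  expect_gte(n_pairs, 200)
})

test_that("adding a species profile never coarsens its match level", {
  withr::local_seed(303)
  for (rep in 1:20) {
    p <- random_profiles(10, na_prob = 0.3)
    lk <- build_lookup(p)
    pool <- random_taxon_pool()
    tx <- tibble::as_tibble(pool[sample(nrow(pool), 1), ])
    before <- match_taxa(tx, lk)$match_level
    p2 <- dplyr::bind_rows(p, tibble::as_tibble(tx) |>
                             dplyr::mutate(iron = 1, zinc = 1, calcium = 1,
                                           vitamin_a = 1, vitamin_b12 = 1,
                                           dha_epa = 1, protein = 1,
                                           edible_fraction = 0.5))
    after <- match_taxa(tx, build_lookup(p2))$match_level
    expect_identical(after, "species")
    lv <- c("species", "genus", "family", "order", "class", "commodity")
    expect_lte(match(after, lv), match(before, lv))
  }
})

test_that("match statistics count levels and the family-or-better share", {
  s <- match_statistics(rep("species", 4))
  expect_equal(s$fraction[s$level == "species"], 1)
  expect_equal(sum(s$fraction), 1)

  levels <- c(rep("species", 3), rep("genus", 2), rep("family", 2),
              rep("order", 1), rep("commodity", 2))
  s <- match_statistics(levels)
  expect_equal(sum(s$fraction), 1)
  expect_equal(attr(s, "family_or_better"), 0.7)
  expect_equal(s$n[s$level == "commodity"], 2L)
})

test_that("commodity profiles are category means", {
  p <- dplyr::bind_rows(
    make_profile("A one", commodity = "molluscs", zinc = 1),
    make_profile("B two", genus = "B", commodity = "molluscs", zinc = 3),
    make_profile("C three", genus = "C", commodity = "cephalopods", zinc = 10))
  lk <- build_lookup(p)
  expect_equal(commodity_profile("molluscs", lk)$zinc, 2)
  expect_equal(commodity_profile("cephalopods", lk)$zinc, 10)
  expect_error(commodity_profile("nope", lk),
               class = "nutrisupply_data_error")
})
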