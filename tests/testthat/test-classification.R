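ten_countries <- function() {
  tibble::tibble(country = sprintf("C%02d", 1:10),
                 mean_fraction = seq(0.01, 0.10, by = 0.01))
}

test_that("the percentile cutoff interpolates order statistics", {
  x <- seq(0.01, 0.10, by = 0.01)
  expect_equal(percentile_cutoff(x, 0.70), 0.073)
  withr::local_seed(707)
  for (rep in 1:20) {
    v <- runif(sample(2:40, 1))
    p <- runif(1)
    expect_equal(percentile_cutoff(v, p),
                 unname(stats::quantile(v, p, type = 7)))
  }
  expect_equal(percentile_cutoff(c(NA, 5, NA), 0.5), 5)
  expect_true(is.na(percentile_cutoff(numeric(0), 0.5)))
})

test_that("the 70th-percentile rule flags exactly the top three of ten", {
  intake <- tibble::tibble(country = sprintf("C%02d", 1:10),
                           mean_inadequate_intake = seq(0.05, 0.95,
                                                        length.out = 10))
  cl <- classify(ten_countries(), intake)
  # rank-based oracle: strictly above the interpolated cutoff
  cutoff <- 0.073
  oracle <- ten_countries()$mean_fraction > cutoff
  expect_identical(cl$reliant_percentile, oracle)
  expect_equal(sum(cl$reliant_percentile), 3)
  expect_identical(cl$country[cl$reliant_percentile],
                   sprintf("C%02d", 8:10))
})

test_that("absolute rules are inclusive at the thresholds", {
  contrib <- tibble::tibble(country = c("A", "B", "C"),
                            mean_fraction = c(0.1499999, 0.15, 0.1500001))
  intake <- tibble::tibble(country = c("A", "B", "C"),
                           mean_inadequate_intake = c(0.4999, 0.50, 0.51))
  cl <- classify(contrib, intake)
  expect_identical(cl$reliant_absolute, c(FALSE, TRUE, TRUE))
  expect_identical(cl$vulnerable_absolute, c(FALSE, TRUE, TRUE))
})

test_that("a Somalia-like profile is both vulnerable and reliant", {
  contrib <- tibble::tibble(country = c("SOM", "X1", "X2"),
                            mean_fraction = c(0.20, 0.02, 0.05))
  intake <- tibble::tibble(country = c("SOM", "X1", "X2"),
                           mean_inadequate_intake = c(0.90, 0.30, 0.20))
  cl <- classify(contrib, intake)
  som <- cl[cl$country == "SOM", ]
  expect_true(som$reliant_absolute && som$vulnerable_absolute)
})

test_that("missing intake data yields missing vulnerability, never FALSE", {
  contrib <- ten_countries()
  intake <- tibble::tibble(country = sprintf("C%02d", 1:10),
                           mean_inadequate_intake = c(rep(NA_real_, 4),
                                                      seq(0.2, 1,
                                                          length.out = 6)))
  cl <- classify(contrib, intake)
  expect_true(all(is.na(cl$vulnerable_percentile[1:4])))
  expect_true(all(is.na(cl$vulnerable_absolute[1:4])))
  expect_false(anyNA(cl$reliant_percentile))
  # the cutoff is computed over countries with data only
  expect_equal(attr(cl, "intake_cutoff"),
               percentile_cutoff(seq(0.2, 1, length.out = 6), 0.7))
  cl_none <- classify(contrib, NULL)
  expect_true(all(is.na(cl_none$vulnerable_percentile)))
})

test_that("per-nutrient prevalences are averaged before classification", {
  contrib <- ten_countries()[1:2, ]
  intake <- tidyr::crossing(country = c("C01", "C02"),
                            nutrient = NUTR[1:6]) |>
    dplyr::mutate(prevalence = rep(c(0.2, 0.8), each = 6))
  cl <- classify(contrib, intake)
  expect_equal(cl$mean_inadequate_intake, c(0.2, 0.8))
})

test_that("classification is invariant to country order", {
  contrib <- ten_countries()
  intake <- tibble::tibble(country = contrib$country,
                           mean_inadequate_intake = runif(10))
  cl1 <- classify(contrib, intake)
  perm <- sample(10)
  cl2 <- classify(contrib[perm, ], intake[sample(10), ])
  cl2 <- cl2[match(cl1$country, cl2$country), ]
  expect_equal(cl1$reliant_percentile, cl2$reliant_percentile)
  expect_equal(cl1$vulnerable_percentile, cl2$vulnerable_percentile)
  expect_error(classify(contrib[1, ], intake),
               class = "nutrisupply_data_error")
})

test_that("percentile sweeps flag everyone at 0, no one at 1, monotonely", {
  contrib <- ten_countries()
  intake <- tibble::tibble(country = contrib$country,
                           mean_inadequate_intake = seq(0.1, 1,
                                                        length.out = 10))
  sw <- sweep_percentile(contrib, intake, percentiles = c(0, 0.25, 0.5,
                                                          0.7, 0.9, 1))
  s <- sw$summary
  expect_equal(s$n_reliant_percentile[s$percentile == 0], 10)
  expect_equal(s$n_reliant_percentile[s$percentile == 1], 0)
  expect_true(all(diff(s$n_reliant_percentile) <= 0))
  expect_true(all(diff(s$n_vulnerable_percentile) <= 0))
  # rank oracle at each percentile (the 0th-percentile band covers everyone)
  for (p in s$percentile) {
    cutoff <- percentile_cutoff(contrib$mean_fraction, p)
    expected <- if (p == 0) sum(!is.na(contrib$mean_fraction)) else
      sum(contrib$mean_fraction > cutoff)
    expect_equal(s$n_reliant_percentile[s$percentile == p], expected)
  }
})
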