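# shared fixture builders: everything is generated in code, no data files

NUTR <- c("iron", "zinc", "calcium", "vitamin_a", "vitamin_b12", "dha_epa",
          "protein")

small_world <- function(seed, ...) {
  generate_world(world_config(n_countries = 5, n_species = 25,
                              grid_cells_per_country = 24, seed = seed, ...))
}

# one profile record with full taxonomy; nutrient values settable/NA-able
make_profile <- function(scientific_name = "Gadus morhua", genus = "Gadus",
                         family = "Gadidae", order = "Gadiformes",
                         class = "Actinopterygii",
                         commodity = "demersal_fish", edible_fraction = 0.5,
                         ...) {
  vals <- list(iron = 1, zinc = 1, calcium = 1, vitamin_a = 1,
               vitamin_b12 = 1, dha_epa = 1, protein = 1)
  vals <- utils::modifyList(vals, list(...))
  tibble::tibble(scientific_name = scientific_name, genus = genus,
                 family = family, order = order, class = class,
                 commodity = commodity, !!!vals,
                 edible_fraction = edible_fraction)
}

# random profile set over a small nested taxonomy pool, with per-value
# missingness, plus one complete commodity-keyed record per category
random_profiles <- function(n = 20, na_prob = 0.25) {
  pool <- random_taxon_pool()
  rows <- pool[sample(nrow(pool), n, replace = TRUE), ]
  for (nu in c(NUTR, "edible_fraction")) {
    v <- runif(n, 0.1, 10)
    v[runif(n) < na_prob] <- NA_real_
    rows[[nu]] <- v
  }
  terminal <- tibble::tibble(scientific_name = NA_character_,
                             genus = NA_character_, family = NA_character_,
                             order = NA_character_, class = NA_character_,
                             commodity = c("pelagic_fish", "demersal_fish",
                                           "crustaceans"))
  for (nu in c(NUTR, "edible_fraction")) {
    terminal[[nu]] <- runif(nrow(terminal), 0.1, 10)
  }
  dplyr::bind_rows(tibble::as_tibble(rows), terminal)
}

random_taxon_pool <- function(n_species = 30) {
  genera <- paste0("G", 1:8)
  families <- paste0("F", 1:4)
  orders <- paste0("O", 1:3)
  classes <- paste0("K", 1:2)
  gf <- sample(families, length(genera), replace = TRUE)
  fo <- sample(orders, length(families), replace = TRUE)
  oc <- sample(classes, length(orders), replace = TRUE)
  fc <- sample(c("pelagic_fish", "demersal_fish", "crustaceans"),
               length(families), replace = TRUE)
  g <- sample(genera, n_species, replace = TRUE)
  f <- gf[match(g, genera)]
  data.frame(scientific_name = paste0(g, " sp", seq_len(n_species)),
             genus = g, family = f, order = fo[match(f, families)],
             class = oc[match(fo[match(f, families)], orders)],
             commodity = fc[match(f, families)],
             stringsAsFactors = FALSE)
}

# join two tables on keys and return the largest relative difference in
# `col`, treating absent cells as zero
max_rel_diff <- function(a, b, keys, col_a, col_b = col_a, floor = 1) {
  j <- dplyr::full_join(a, b, by = keys, suffix = c("_a", "_b"))
  ca <- if (col_a %in% names(j)) j[[col_a]] else j[[paste0(col_a, "_a")]]
  cb <- if (col_b %in% names(j) && col_b != col_a) j[[col_b]] else
    j[[paste0(col_b, "_b")]]
  ca[is.na(ca)] <- 0
  cb[is.na(cb)] <- 0
  if (!length(ca)) return(0)
  max(abs(ca - cb) / pmax(abs(cb), floor))
}
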