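# Record-by-record oracle for synthetic-world ground truth. Written as
# explicit loops with environment accumulators — no vectorised grouping, no
# shared code with either the generator bookkeeper or the pipeline — so it
# can serve as a genuinely independent check on both.

bump <- function(acc, key, val) {
  cur <- get0(key, envir = acc, inherits = FALSE, ifnotfound = 0)
  assign(key, cur + val, envir = acc)
}

acc_new <- function() new.env(parent = emptyenv())

acc_get <- function(acc, key) get0(key, envir = acc, inherits = FALSE,
                                   ifnotfound = 0)

# brute-force hierarchical match: scan every profile row at every level in
# priority order; per-field values fall through to deeper levels when a
# level has no non-missing record for that field
oracle_match_taxon <- function(tx, profiles) {
  fields <- c(NUTRIENTS, "edible_fraction")
  values <- stats::setNames(rep(NA_real_, length(fields)), fields)
  field_levels <- stats::setNames(rep(NA_character_, length(fields)), fields)
  overall <- NA_character_
  for (lv in MATCH_LEVELS) {
    col <- LEVEL_COLUMNS[[lv]]
    key <- normalize_key(tx[[col]])
    if (is.na(key)) next
    rows <- integer(0)
    for (j in seq_len(nrow(profiles))) {
      pv <- normalize_key(profiles[[col]][j])
      if (!is.na(pv) && pv == key) rows <- c(rows, j)
    }
    if (!length(rows)) next
    if (is.na(overall)) overall <- lv
    for (f in fields) {
      if (is.na(values[[f]])) {
        tot <- 0; cnt <- 0
        for (j in rows) {
          v <- profiles[[f]][j]
          if (!is.na(v)) { tot <- tot + v; cnt <- cnt + 1 }
        }
        if (cnt > 0) { values[[f]] <- tot / cnt; field_levels[[f]] <- lv }
      }
    }
  }
  list(values = values, level = overall, field_levels = field_levels)
}

#' Recompute a synthetic world's ground truth by brute force
#'
#' Independently re-derives every expected quantity carried in
#' `world$truth` using explicit record-by-record loops: end-use filtering,
#' re-export estimation, trade adjustment, proportional export allocation,
#' apparent consumption, brute-force hierarchical nutrient matching, supply
#' conversion, coastal/national per-capita division, contribution fractions,
#' six-nutrient means and classification flags. Shares no aggregation code
#' with [world_truth()] or with the pipeline stages, and must agree with
#' `world$truth` to floating-point accuracy.
#'
#' @inheritParams world_truth
#' @return A list of class `ssf_truth`, shaped exactly like `world$truth`.
#' @export
ground_truth_contributions <- function(world, buffer_km = NULL,
                                       artisanal_exportable = TRUE,
                                       percentile = 0.70,
                                       supply_threshold = 0.15,
                                       intake_threshold = 0.50) {
  cfg <- world$config
  if (is.null(buffer_km)) buffer_km <- cfg$buffer_km_default
  fwc <- cfg$freshwater_crustacean_export_fraction
  countries <- world$countries
  taxa <- as.data.frame(world$taxa)
  sep <- "\r"
  k2 <- function(a, b) paste(a, b, sep = sep)
  k3 <- function(a, b, c) paste(a, b, c, sep = sep)

  commodity_of <- stats::setNames(taxa$commodity, taxa$scientific_name)

  # --- production (commercial DHC + mariculture) and non-commercial catch
  prod_acc <- acc_new(); noncom_acc <- acc_new()
  catch <- as.data.frame(world$catch)
  for (r in seq_len(nrow(catch))) {
    sec <- catch$sector[r]
    if (sec %in% COMMERCIAL_SECTORS) {
      if (catch$end_use[r] == "direct_human_consumption") {
        bump(prod_acc, k3(catch$country[r], catch$scientific_name[r], sec),
             catch$tonnes[r])
      }
    } else if (sec %in% NONCOMMERCIAL_SECTORS) {
      bump(noncom_acc, k3(catch$country[r], catch$scientific_name[r], sec),
           catch$tonnes[r])
    }
  }
  mar <- as.data.frame(world$mariculture)
  for (r in seq_len(nrow(mar))) {
    bump(prod_acc, k3(mar$country[r], mar$scientific_name[r], mar$sector[r]),
         mar$tonnes[r])
  }

  # --- trade flows and food-balance production per country x commodity
  imp <- acc_new(); ex <- acc_new(); rec <- acc_new(); fbsp <- acc_new()
  trade <- as.data.frame(world$trade)
  for (r in seq_len(nrow(trade))) {
    key <- k2(trade$country[r], trade$commodity[r])
    fl <- trade$flow[r]
    if (fl == "import") bump(imp, key, trade$tonnes[r])
    else if (fl == "export") bump(ex, key, trade$tonnes[r])
    else if (fl == "reexport_recorded") bump(rec, key, trade$tonnes[r])
  }
  fbs <- as.data.frame(world$fbs_production)
  for (r in seq_len(nrow(fbs))) {
    bump(fbsp, k2(fbs$country[r], fbs$commodity[r]), fbs$tonnes[r])
  }

  prod_keys <- ls(prod_acc)
  prod_cty <- prod_sci <- prod_sec <- character(length(prod_keys))
  prod_t <- numeric(length(prod_keys))
  for (i in seq_along(prod_keys)) {
    parts <- strsplit(prod_keys[i], sep, fixed = TRUE)[[1]]
    prod_cty[i] <- parts[1]; prod_sci[i] <- parts[2]; prod_sec[i] <- parts[3]
    prod_t[i] <- acc_get(prod_acc, prod_keys[i])
  }
  prod_com <- unname(commodity_of[prod_sci])

  trade_keys <- unique(c(ls(imp), ls(ex), ls(rec), ls(fbsp),
                         k2(prod_cty, prod_com)))
  adjE <- adjI <- stats::setNames(numeric(length(trade_keys)), trade_keys)
  surplus_list <- list()
  exportable <- c(if (artisanal_exportable) "artisanal", "industrial",
                  "mariculture")
  pool <- acc_new()
  for (i in seq_along(prod_keys)) {
    if (prod_sec[i] %in% exportable) {
      bump(pool, k2(prod_cty[i], prod_com[i]), prod_t[i])
    }
  }
  for (key in trade_keys) {
    E <- acc_get(ex, key); I <- acc_get(imp, key)
    R <- acc_get(rec, key); P <- acc_get(fbsp, key)
    processed <- max(0, E - P)
    total <- min(R + processed, E)
    e_adj <- max(0, E - total)
    i_adj <- max(0, I - total)
    com <- strsplit(key, sep, fixed = TRUE)[[1]][2]
    if (com == CRUSTACEAN_COMMODITY) e_adj <- e_adj * (1 - fwc)
    adjE[[key]] <- e_adj
    adjI[[key]] <- i_adj
    pl <- acc_get(pool, key)
    if (e_adj > pl) {
      surplus_list[[key]] <- e_adj - pl
    }
  }

  # --- retained production and apparent consumption entries
  cons_cty <- cons_tax <- cons_sec <- cons_com <- character(0)
  cons_t <- numeric(0)
  push <- function(cty, tax, sec, com, t) {
    cons_cty[[length(cons_cty) + 1]] <<- cty
    cons_tax[[length(cons_tax) + 1]] <<- tax
    cons_sec[[length(cons_sec) + 1]] <<- sec
    cons_com[[length(cons_com) + 1]] <<- com
    cons_t[[length(cons_t) + 1]] <<- t
  }
  for (i in seq_along(prod_keys)) {
    key <- k2(prod_cty[i], prod_com[i])
    alloc <- 0
    if (prod_sec[i] %in% exportable && acc_get(pool, key) > 0) {
      alloc <- adjE[[key]] * prod_t[i] / acc_get(pool, key)
    }
    push(prod_cty[i], prod_sci[i], prod_sec[i], prod_com[i],
         max(0, prod_t[i] - alloc))
  }
  for (key in trade_keys) {
    if (adjI[[key]] > 0) {
      parts <- strsplit(key, sep, fixed = TRUE)[[1]]
      push(parts[1], parts[2], "imports", parts[2], adjI[[key]])
    }
  }
  for (key in ls(noncom_acc)) {
    parts <- strsplit(key, sep, fixed = TRUE)[[1]]
    push(parts[1], parts[2], parts[3], unname(commodity_of[parts[2]]),
         acc_get(noncom_acc, key))
  }

  # --- matching and supply
  profiles <- as.data.frame(world$profiles)
  match_cache <- list()
  supply_acc <- acc_new()
  for (i in seq_along(cons_t)) {
    ck <- if (cons_sec[i] == "imports") paste0("com:", cons_com[i])
          else cons_tax[i]
    if (is.null(match_cache[[ck]])) {
      tx <- if (cons_sec[i] == "imports") {
        list(scientific_name = NA, genus = NA, family = NA, order = NA,
             class = NA, commodity = cons_com[i])
      } else {
        as.list(taxa[match(cons_tax[i], taxa$scientific_name), ])
      }
      match_cache[[ck]] <- oracle_match_taxon(tx, profiles)$values
    }
    vals <- match_cache[[ck]]
    for (nu in NUTRIENTS) {
      bump(supply_acc, k3(cons_cty[i], cons_sec[i], nu),
           cons_t[i] * 1e4 * vals[["edible_fraction"]] * vals[[nu]])
    }
  }

  # --- populations: planar distance of a cell to its country's coastline
  cells <- as.data.frame(world$population_cells)
  coast <- as.data.frame(world$coastline)
  coastal <- national <- stats::setNames(numeric(length(countries)),
                                         countries)
  for (r in seq_len(nrow(cells))) {
    cty <- cells$country[r]
    national[[cty]] <- national[[cty]] + cells$persons[r]
    seg <- coast[coast$country == cty, ]
    seg <- seg[order(seg$vertex), ]
    dmin <- Inf
    for (s in seq_len(nrow(seg) - 1)) {
      dmin <- min(dmin, point_segment_distance(
        cells$x[r], cells$y[r], seg$x[s], seg$y[s], seg$x[s + 1],
        seg$y[s + 1]))
    }
    if (dmin <= buffer_km) coastal[[cty]] <- coastal[[cty]] + cells$persons[r]
  }

  # --- per-capita supply, contributions, means, flags
  gnd <- as.data.frame(world$gnd_nonseafood)
  n_c <- length(countries); n_n <- length(NUTRIENTS)
  supply_out <- percap_out <- numeric(0)
  percap_arr <- array(0, dim = c(n_c, length(SOURCE_SECTORS), n_n),
                      dimnames = list(countries, SOURCE_SECTORS, NUTRIENTS))
  supply_arr <- percap_arr
  for (nu_i in seq_len(n_n)) {
    for (se_i in seq_along(SOURCE_SECTORS)) {
      for (co_i in seq_len(n_c)) {
        m <- acc_get(supply_acc, k3(countries[co_i], SOURCE_SECTORS[se_i],
                                    NUTRIENTS[nu_i]))
        supply_arr[co_i, se_i, nu_i] <- m
        popn <- if (SOURCE_SECTORS[se_i] %in% SSF_SECTORS)
          coastal[[countries[co_i]]] else national[[countries[co_i]]]
        percap_arr[co_i, se_i, nu_i] <-
          if (popn == 0 && m == 0) 0 else m / (popn * 365)
      }
    }
  }

  f_sea <- f_asf <- f_all <- matrix(NA_real_, n_c, n_n,
                                    dimnames = list(countries, NUTRIENTS))
  for (co_i in seq_len(n_c)) {
    for (nu_i in seq_len(n_n)) {
      nu <- NUTRIENTS[nu_i]
      ssf <- 0; sea <- 0
      for (se in SOURCE_SECTORS) {
        v <- percap_arr[co_i, se, nu_i]
        sea <- sea + v
        if (se %in% SSF_SECTORS) ssf <- ssf + v
      }
      animal <- 0; allfood <- 0
      if (nu != "dha_epa") {
        for (r in seq_len(nrow(gnd))) {
          if (gnd$country[r] == countries[co_i] && gnd$nutrient[r] == nu) {
            allfood <- allfood + gnd$per_capita_per_day[r]
            if (gnd$food_group[r] %in% ANIMAL_GROUPS) {
              animal <- animal + gnd$per_capita_per_day[r]
            }
          }
        }
      }
      if (sea > 0) f_sea[co_i, nu_i] <- ssf / sea
      if (sea + animal > 0) f_asf[co_i, nu_i] <- ssf / (sea + animal)
      if (sea + allfood > 0) f_all[co_i, nu_i] <- ssf / (sea + allfood)
    }
  }

  mean_all <- mean_int <- rep(NA_real_, n_c)
  ii <- as.data.frame(world$inadequate_intake)
  for (co_i in seq_len(n_c)) {
    vals <- f_all[co_i, ASSESSED_NUTRIENTS]
    vals <- vals[!is.na(vals)]
    if (length(vals)) mean_all[co_i] <- mean(vals)
    iv <- ii$prevalence[ii$country == countries[co_i] &
                          ii$nutrient %in% ASSESSED_NUTRIENTS]
    iv <- iv[!is.na(iv)]
    if (length(iv)) mean_int[co_i] <- mean(iv)
  }
  # interpolated order-statistic cutoff, written out longhand
  cut_of <- function(x, p) {
    x <- sort(x[!is.na(x)])
    n <- length(x)
    if (n == 0) return(NA_real_)
    if (n == 1) return(x)
    h <- (n - 1) * p + 1
    lo <- floor(h)
    x[lo] + (h - lo) * (x[min(lo + 1, n)] - x[lo])
  }
  cut_sup <- cut_of(mean_all, percentile)
  cut_int <- cut_of(mean_int, percentile)
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

  cons_df <- acc_new()
  for (i in seq_along(cons_t)) {
    bump(cons_df, k3(cons_cty[i], cons_tax[i], cons_sec[i]), cons_t[i])
  }
  ckeys <- ls(cons_df)
  cparts <- do.call(rbind, strsplit(ckeys, sep, fixed = TRUE))
  cons_tbl <- data.frame(country = cparts[, 1], taxon = cparts[, 2],
                         sector = cparts[, 3],
                         tonnes = vapply(ckeys, function(k)
                           acc_get(cons_df, k), numeric(1)))
  cons_tbl <- cons_tbl[order(cons_tbl$country, cons_tbl$taxon,
                             cons_tbl$sector), ]
  rownames(cons_tbl) <- NULL

  grid <- expand.grid(country = countries, sector = SOURCE_SECTORS,
                      nutrient = NUTRIENTS, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  contrib_tbl <- function(m) {
    tibble::tibble(country = rep(countries, times = n_n),
                   nutrient = rep(NUTRIENTS, each = n_c),
                   ssf_fraction = as.vector(m))
  }
  sk <- names(surplus_list)
  structure(list(
    expected_apparent_consumption = tibble::as_tibble(cons_tbl),
    expected_supply = tibble::as_tibble(
      data.frame(grid, mass_per_year = as.vector(supply_arr))),
    expected_per_capita = tibble::as_tibble(
      data.frame(grid, per_capita_per_day = as.vector(percap_arr))),
    expected_contribution_seafood = contrib_tbl(f_sea),
    expected_contribution_asf = contrib_tbl(f_asf),
    expected_contribution_allfoods = contrib_tbl(f_all),
    expected_flags = flags,
    coastal_population = tibble::tibble(
      country = countries,
      coastal_persons = unname(coastal),
      national_persons = unname(national)),
    export_surplus = tibble::tibble(
      country = vapply(sk, function(k)
        strsplit(k, sep, fixed = TRUE)[[1]][1], character(1),
        USE.NAMES = FALSE),
      commodity = vapply(sk, function(k)
        strsplit(k, sep, fixed = TRUE)[[1]][2], character(1),
        USE.NAMES = FALSE),
      surplus = unlist(surplus_list, use.names = FALSE) %||% numeric(0)),
    params = list(buffer_km = buffer_km,
                  artisanal_exportable = artisanal_exportable,
                  percentile = percentile,
                  supply_threshold = supply_threshold,
                  intake_threshold = intake_threshold)),
    class = "ssf_truth")
}
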