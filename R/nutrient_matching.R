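#' Build a hierarchical nutrient-profile lookup
#'
#' Indexes food-composition profile records for mean-aggregation queries at
#' each taxonomic rank. A profile record is keyed by whatever ranks it
#' carries (scientific name, genus, family, order, class) plus a commodity
#' category, which is always present and acts as the terminal fallback. Rank
#' means are unweighted arithmetic means over the non-missing values of all
#' records sharing that rank value; names are matched exactly after
#' case-folding and whitespace normalization.
#'
#' @param profiles A data frame with columns `scientific_name`, `genus`,
#'   `family`, `order`, `class`, `commodity`, the seven nutrient columns
#'   (`iron`, `zinc`, `calcium`, `vitamin_a`, `vitamin_b12`, `dha_epa`,
#'   `protein`; per 100 g edible raw muscle tissue) and `edible_fraction`.
#'   Higher ranks may be blank (`NA`) for records keyed at a coarser rank.
#' @return A `nutrient_lookup` object: per-level mean tables.
#' @examples
#' p <- tibble::tibble(scientific_name = c("Gadus morhua", "Gadus ogac"),
#'                     genus = "Gadus", family = "Gadidae", order = "Gadiformes",
#'                     class = "Actinopterygii", commodity = "demersal_fish",
#'                     iron = c(0.4, 0.6), zinc = c(0.5, 0.7), calcium = c(10, 30),
#'                     vitamin_a = c(2, 4), vitamin_b12 = c(1, 3),
#'                     dha_epa = c(0.2, 0.4), protein = c(18, 20),
#'                     edible_fraction = c(0.5, 0.6))
#' lk <- build_lookup(p)
#' lk$tables$genus$calcium  # 20
#' @export
build_lookup <- function(profiles) {
  if (is.null(profiles) || nrow(profiles) == 0) {
    stop_data("profile list is empty: cannot build a nutrient lookup")
  }
  assert_columns(profiles, c(TAXON_RANKS, "commodity", NUTRIENTS,
                             "edible_fraction"), "profiles")
  if (anyNA(profiles$commodity)) {
    stop_data("every nutrient profile must carry a commodity label")
  }
  fields <- c(NUTRIENTS, "edible_fraction")
  tables <- purrr::map(set_names(MATCH_LEVELS), function(lv) {
    col <- LEVEL_COLUMNS[[lv]]
    profiles |>
      mutate(.key = normalize_key(.data[[col]])) |>
      filter(!is.na(.data$.key)) |>
      group_by(.data$.key) |>
      summarise(across(all_of(fields), ~ {
        v <- .x[!is.na(.x)]
        if (length(v)) mean(v) else NA_real_
      }), n_records = dplyr::n(), .groups = "drop")
  })
  structure(list(tables = tables, profiles = tibble::as_tibble(profiles)),
            class = "nutrient_lookup")
}

#' @export
print.nutrient_lookup <- function(x, ...) {
  cat("<nutrient_lookup>\n")
  for (lv in MATCH_LEVELS) {
    cat(sprintf("  %-10s %4d keys\n", lv, nrow(x$tables[[lv]])))
  }
  invisible(x)
}

#' Match taxa to nutrient profiles by hierarchical fallback
#'
#' Assigns each taxon the mean profile at the first matching level in the
#' priority order species, genus, family, order, class, commodity. The
#' recorded `match_level` is the most specific level with at least one
#' profile record; individual nutrients (and the edible fraction) whose mean
#' is undefined at that level — every record missing the value — fall
#' through to the next level for that field only, so the most specific
#' available data is always used.
#'
#' @param taxa A data frame with columns `scientific_name`, `genus`,
#'   `family`, `order`, `class` (any of which may be `NA`) and `commodity`
#'   (required).
#' @param lookup A [build_lookup()] index.
#' @return `taxa` with, per field, the matched value, a `<field>_level`
#'   column naming the level that supplied it, and `match_level`.
#' @export
match_taxa <- function(taxa, lookup) {
  stopifnot(inherits(lookup, "nutrient_lookup"))
  assert_columns(taxa, "commodity", "taxa")
  for (r in setdiff(TAXON_RANKS, names(taxa))) taxa[[r]] <- NA_character_
  fields <- c(NUTRIENTS, "edible_fraction")
  n <- nrow(taxa)
  if (n == 0L) {
    out <- tibble::as_tibble(taxa)
    for (f in fields) {
      out[[f]] <- numeric(0)
      out[[paste0(f, "_level")]] <- character(0)
    }
    out$match_level <- character(0)
    return(out)
  }
  vals <- array(NA_real_, dim = c(n, length(fields), length(MATCH_LEVELS)),
                dimnames = list(NULL, fields, MATCH_LEVELS))
  hit <- matrix(FALSE, n, length(MATCH_LEVELS),
                dimnames = list(NULL, MATCH_LEVELS))
  for (lv in MATCH_LEVELS) {
    tbl <- lookup$tables[[lv]]
    idx <- match(normalize_key(taxa[[LEVEL_COLUMNS[[lv]]]]), tbl$.key)
    hit[, lv] <- !is.na(idx)
    for (f in fields) vals[, f, lv] <- tbl[[f]][idx]
  }
  unmatched <- rowSums(hit) == 0
  if (any(unmatched)) {
    stop_data(paste0("no nutrient profile found at any level for taxa: ",
                     paste(utils::head(taxa$scientific_name[unmatched], 5),
                           collapse = ", ")),
              taxa = taxa[unmatched, , drop = FALSE])
  }
  first_level <- MATCH_LEVELS[apply(hit, 1, which.max)]
  out <- tibble::as_tibble(taxa)
  for (f in fields) {
    m <- vals[, f, , drop = FALSE]
    dim(m) <- c(n, length(MATCH_LEVELS))
    pos <- apply(!is.na(m), 1, function(z) if (any(z)) which(z)[1] else NA_integer_)
    out[[f]] <- m[cbind(seq_len(n), pos)]
    out[[paste0(f, "_level")]] <- MATCH_LEVELS[pos]
  }
  out$match_level <- first_level
  out
}

#' Match a single taxon
#'
#' Single-taxon form of [match_taxa()], returning the matched mean profile
#' and the fallback level used.
#'
#' @param taxon A one-row data frame or named list with the taxon's rank
#'   names and commodity label.
#' @inheritParams match_taxa
#' @return A list of class `match_result` with elements `profile` (one-row
#'   tibble of nutrient values and edible fraction), `level`, and
#'   `field_levels` (per-field fallback level).
#' @export
match_nutrients <- function(taxon, lookup) {
  res <- match_taxa(tibble::as_tibble(as.list(taxon)), lookup)
  fields <- c(NUTRIENTS, "edible_fraction")
  structure(list(profile = res[, fields],
                 level = res$match_level,
                 field_levels = set_names(
                   purrr::map_chr(fields, ~ res[[paste0(.x, "_level")]]),
                   fields)),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> level = %s\n", x$level))
  print(x$profile)
  invisible(x)
}

#' Match-level statistics
#'
#' Tabulates the share of taxa resolved at each fallback level, and the
#' combined share resolved at family level or better (species, genus or
#' family) — the headline match-quality figure for a profile database.
#'
#' @param results Output of [match_taxa()], or a character vector of levels.
#' @return A tibble with `level`, `n` and `fraction` (fractions sum to 1),
#'   with the combined species+genus+family share in attribute
#'   `family_or_better`.
#' @export
match_statistics <- function(results) {
  levels <- if (is.character(results)) results else results$match_level
  if (length(levels) == 0) stop_data("no match results to summarise")
  counts <- table(factor(levels, levels = MATCH_LEVELS))
  out <- tibble::tibble(level = MATCH_LEVELS,
                        n = as.integer(counts),
                        fraction = as.integer(counts) / length(levels))
  attr(out, "family_or_better") <-
    sum(out$fraction[out$level %in% c("species", "genus", "family")])
  out
}

#' Commodity-category mean profile
#'
#' The arithmetic mean profile over all records carrying a commodity label,
#' used for import flows, which are resolved only to commodity category.
#'
#' @param category A commodity label.
#' @inheritParams match_taxa
#' @return A one-row tibble of mean nutrient values and edible fraction.
#' @export
commodity_profile <- function(category, lookup) {
  stopifnot(inherits(lookup, "nutrient_lookup"))
  tbl <- lookup$tables$commodity
  idx <- match(normalize_key(category), tbl$.key)
  if (is.na(idx)) {
    stop_data(sprintf("unknown commodity category: '%s'", category))
  }
  tbl[idx, c(NUTRIENTS, "edible_fraction")]
}
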