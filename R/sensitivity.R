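new_sensitivity <- function(axis, levels, runs, summary, flag_flips,
                            base_level) {
  structure(list(axis = axis, levels = levels, runs = runs,
                 summary = summary, flag_flips = flag_flips,
                 base_level = base_level),
            class = "ssf_sensitivity")
}

flag_changes <- function(base, other) {
  b <- tibble::as_tibble(base)[, c("country", "reliant_percentile",
                                   "vulnerable_percentile")]
  o <- tibble::as_tibble(other)[, c("country", "reliant_percentile",
                                    "vulnerable_percentile")]
  j <- b |> inner_join(o, by = "country", suffix = c("_base", ""))
  sum(xor(j$reliant_percentile_base, j$reliant_percentile) |
        xor(j$vulnerable_percentile_base, j$vulnerable_percentile),
      na.rm = TRUE)
}

#' Sensitivity to the coastal buffer distance
#'
#' Reruns the full pipeline at each buffer distance and reports per-country
#' mean SSF contributions by distance, flag counts, and how many countries'
#' percentile-rule flags flip relative to the first (base) distance. With a
#' fixed population grid a wider buffer can only enlarge the coastal
#' population, so per-capita SSF supply — and with it the contribution
#' fractions — weakly decreases in the distance.
#'
#' @param world An `ssf_world`.
#' @param distances Buffer distances in km (>= 2 of them; the first is the
#'   base case).
#' @param ... Further arguments passed to [run_pipeline()].
#' @return An `ssf_sensitivity` object.
#' @export
sweep_buffer <- function(world, distances = BUFFER_DISTANCES_KM, ...) {
  if (length(distances) < 1) stop_config("no distances supplied", "distances")
  runs <- purrr::map(set_names(distances, paste0(distances, "km")),
                     function(d) run_pipeline(world, buffer_km = d, ...))
  sensitivity_from_runs("buffer_km", distances, runs)
}

#' Sensitivity to treating artisanal catch as exportable
#'
#' Two pipeline runs differing only in whether artisanal production is part
#' of the exportable pool: exported (the conservative base case) versus
#' entirely retained domestically. Retention can only keep more artisanal
#' tonnage at home, so every country's SSF supply and contribution under
#' retention is at least its exportable-case value.
#'
#' @param world An `ssf_world`.
#' @param ... Further arguments passed to [run_pipeline()].
#' @return An `ssf_sensitivity` object with levels `exportable` (base) and
#'   `retained`.
#' @export
sweep_artisanal_trade <- function(world, ...) {
  runs <- list(
    exportable = run_pipeline(world, artisanal_exportable = TRUE, ...),
    retained = run_pipeline(world, artisanal_exportable = FALSE, ...))
  sensitivity_from_runs("artisanal_exportable", c("exportable", "retained"),
                        runs)
}

sensitivity_from_runs <- function(axis, levels, runs) {
  summary <- purrr::imap(runs, function(run, lv) {
    glance(run) |> mutate(level = lv, .before = 1)
  }) |> purrr::list_rbind()
  by_country <- purrr::imap(runs, function(run, lv) {
    run$mean_contributions |>
      filter(.data$denominator_scope == "all_foods") |>
      transmute(level = lv, .data$country, .data$mean_fraction)
  }) |> purrr::list_rbind()
  flips <- purrr::imap(runs, function(run, lv) {
    tibble::tibble(level = lv,
                   n_flag_flips = flag_changes(runs[[1]]$classification,
                                               run$classification))
  }) |> purrr::list_rbind()
  new_sensitivity(axis, levels, runs,
                  summary = list(runs = summary, by_country = by_country),
                  flag_flips = flips, base_level = names(runs)[1])
}

#' Sensitivity to the classification percentile
#'
#' Re-applies the percentile classification rules over a grid of
#' percentiles, holding the contribution and intake distributions fixed.
#' Because the cutoff is non-decreasing in the percentile and flags require
#' being strictly above it, flag counts weakly decrease along the sweep.
#'
#' @param contributions,inadequate As in [classify()].
#' @param percentiles Percentiles to sweep (>= 2).
#' @param ... Further arguments passed to [classify()].
#' @return An `ssf_sensitivity` whose `summary` has one row per percentile
#'   with reliant/vulnerable counts.
#' @export
sweep_percentile <- function(contributions, inadequate,
                             percentiles = c(0.5, 0.6, 0.7, 0.8, 0.9),
                             ...) {
  if (length(percentiles) < 1) stop_config("no percentiles supplied",
                                           "percentiles")
  runs <- purrr::map(set_names(percentiles, paste0("p", percentiles)),
                     function(p) classify(contributions, inadequate,
                                          percentile = p, ...))
  summary <- purrr::map2(runs, percentiles, function(cl, p) {
    glance(cl) |> mutate(percentile = p)
  }) |> purrr::list_rbind()
  flips <- purrr::imap(runs, function(cl, lv) {
    tibble::tibble(level = lv,
                   n_flag_flips = flag_changes(runs[[1]], cl))
  }) |> purrr::list_rbind()
  new_sensitivity("percentile", percentiles, runs, summary, flips,
                  names(runs)[1])
}

#' @export
print.ssf_sensitivity <- function(x, ...) {
  cat(sprintf("<ssf_sensitivity> axis: %s, %d levels (base: %s)\n",
              x$axis, length(x$levels), x$base_level))
  s <- if (is.data.frame(x$summary)) x$summary else x$summary$runs
  print(s)
  invisible(x)
}

#' @export
tidy.ssf_sensitivity <- function(x, ...) {
  if (is.data.frame(x$summary)) x$summary else x$summary$by_country
}
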