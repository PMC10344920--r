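# planar point-to-segment Euclidean distance, vectorised over points
point_segment_distance <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax; dy <- by - ay
  len2 <- dx * dx + dy * dy
  t <- if (len2 == 0) 0 else pmin(1, pmax(0, ((px - ax) * dx +
                                                (py - ay) * dy) / len2))
  sqrt((px - (ax + t * dx))^2 + (py - (ay + t * dy))^2)
}

cell_coast_distance <- function(cells, coastline,
                                mode = c("planar", "geographic")) {
  mode <- match.arg(mode)
  if (is.null(coastline) || nrow(coastline) == 0) {
    stop_config("coastline is empty", "coastline")
  }
  assert_columns(cells, c("country", "x", "y", "persons"), "population cells")
  assert_columns(coastline, c("country", "vertex", "x", "y"), "coastline")
  dist_one <- function(cl, seg) {
    seg <- seg[order(seg$vertex), , drop = FALSE]
    if (nrow(seg) < 2) stop_config("coastline needs at least two vertices",
                                   "coastline")
    if (mode == "planar") {
      d <- rep(Inf, nrow(cl))
      for (s in seq_len(nrow(seg) - 1)) {
        d <- pmin(d, point_segment_distance(cl$x, cl$y, seg$x[s], seg$y[s],
                                            seg$x[s + 1], seg$y[s + 1]))
      }
      d
    } else {
      # geographic mode: x = lon, y = lat; great-circle point-to-segment
      geosphere::dist2Line(cbind(cl$x, cl$y),
                           cbind(seg$x, seg$y))[, "distance"] / 1000
    }
  }
  cells |>
    group_by(.data$country) |>
    group_modify(function(cl, key) {
      seg <- coastline[coastline$country == key$country, , drop = FALSE]
      if (nrow(seg) == 0) {
        stop_config(sprintf("no coastline for country %s", key$country),
                    "coastline")
      }
      cl$distance_km <- dist_one(cl, seg)
      cl
    }) |>
    ungroup()
}

#' Cells within a coastal buffer
#'
#' Selects the population cells whose centroid lies within `buffer_km` of
#' the country's nearest coastline segment. In planar mode (synthetic
#' worlds) coordinates are km on a plane and the distance is Euclidean
#' point-to-segment; in geographic mode `x`/`y` are lon/lat degrees and the
#' distance is the great-circle distance to the nearest polyline segment.
#' Membership is decided by the cell centroid only, with no areal weighting.
#'
#' @param cells Population cells: `country`, `x`, `y`, `persons`.
#' @param coastline Polyline vertices per country: `country`, `vertex`
#'   (ordering), `x`, `y`.
#' @param buffer_km Buffer distance in km (> 0).
#' @param mode `"planar"` or `"geographic"`.
#' @return The subset of `cells` within the buffer, with a `distance_km`
#'   column.
#' @export
coastal_mask <- function(cells, coastline, buffer_km,
                         mode = c("planar", "geographic")) {
  if (length(buffer_km) != 1 || is.na(buffer_km) || buffer_km <= 0) {
    stop_config("`buffer_km` must be a single positive distance", "buffer_km")
  }
  cell_coast_distance(cells, coastline, mode) |>
    filter(.data$distance_km <= buffer_km)
}

#' Coastal population per country
#'
#' Sums persons over the cells within `buffer_km` of the coastline, per
#' country. Several buffer distances can be requested at once; distances are
#' computed a single time. Countries whose cells all fall outside a buffer
#' get an explicit zero row, and a warning is emitted for them since any
#' small-scale fisheries supply there would have no consuming population.
#'
#' @inheritParams coastal_mask
#' @param buffer_km One or more buffer distances in km.
#' @return A tibble `country`, `buffer_km`, `persons`, one row per country
#'   per buffer; `persons` is non-decreasing in `buffer_km`.
#' @export
coastal_population <- function(cells, coastline, buffer_km,
                               mode = c("planar", "geographic")) {
  if (any(is.na(buffer_km)) || any(buffer_km <= 0)) {
    stop_config("`buffer_km` must be positive", "buffer_km")
  }
  with_dist <- cell_coast_distance(cells, coastline, mode)
  countries <- unique(cells$country)
  out <- purrr::map(sort(unique(buffer_km)), function(b) {
    with_dist |>
      group_by(.data$country) |>
      summarise(persons = sum(.data$persons[.data$distance_km <= b]),
                .groups = "drop") |>
      mutate(buffer_km = b)
  }) |>
    purrr::list_rbind() |>
    tidyr::complete(country = countries, buffer_km = sort(unique(buffer_km)),
                    fill = list(persons = 0)) |>
    select("country", "buffer_km", "persons") |>
    arrange(.data$country, .data$buffer_km)
  empty <- out |> filter(.data$persons == 0)
  if (nrow(empty)) {
    warn(paste0("zero coastal population for: ",
                paste(unique(paste0(empty$country, " @", empty$buffer_km,
                                    " km")), collapse = ", ")))
  }
  out
}

#' National population per country
#'
#' @param cells Population cells: `country`, `persons`.
#' @return A tibble `country`, `persons`.
#' @export
national_population <- function(cells) {
  cells |>
    group_by(.data$country) |>
    summarise(persons = sum(.data$persons), .groups = "drop")
}
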