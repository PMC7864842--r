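#' Great-circle distance (haversine)
#'
#' Haversine distance on a sphere of radius 6371 km. Vectorized over both
#' endpoints.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees.
#' @return Distance(s) in km.
#' @export
#' @examples
#' great_circle_distance(0, 0, 0, 180)  # half circumference, ~20015 km
great_circle_distance <- function(lat1, lon1, lat2, lon2) {
  k <- max(length(lat1), length(lon1), length(lat2), length(lon2))
  p1 <- cbind(rep_len(lon1, k), rep_len(lat1, k))
  p2 <- cbind(rep_len(lon2, k), rep_len(lat2, k))
  geosphere::distHaversine(p1, p2, r = 6371) # r in km -> result in km
}

# dense distance matrix (km) between two sets of (lat, lon) points
distance_matrix_km <- function(lat_a, lon_a, lat_b, lon_b) {
  geosphere::distm(cbind(lon_a, lat_a), cbind(lon_b, lat_b),
                   fun = function(p1, p2) geosphere::distHaversine(p1, p2, r = 6371))
}

#' Merge neighbouring populations toward a target mean sample size
#'
#' While the mean sample size of populations carrying the focal haplogroup
#' is below `target_mean`, the smallest such population is merged with its
#' great-circle nearest neighbour: coordinates become the sample-weighted
#' centroid, sample and haplogroup counts are summed. Populations sharing
#' identical coordinates are merged first. Total samples and counts are
#' conserved.
#'
#' @param pops Population tibble: `population`, `lat`, `lon`, `n`, plus
#'   count columns.
#' @param haplogroup Name of the focal count column (e.g. `"count_C"`).
#' @param target_mean Target mean sample size among carrier populations
#'   (default 50).
#' @return The merged population tibble.
#' @export
merge_populations <- function(pops, haplogroup, target_mean = 50) {
  stopifnot(haplogroup %in% names(pops), nrow(pops) >= 1)
  count_cols <- c("n", grep("^count_", names(pops), value = TRUE))
  merge_two <- function(df, a, b) {
    w <- df$n[c(a, b)]
    df$lat[a] <- sum(df$lat[c(a, b)] * w) / sum(w)
    df$lon[a] <- sum(df$lon[c(a, b)] * w) / sum(w)
    for (cc in count_cols) df[[cc]][a] <- df[[cc]][a] + df[[cc]][b]
    df$population[a] <- paste(df$population[c(a, b)], collapse = "+")
    df[-b, , drop = FALSE]
  }
  # collapse exact coordinate duplicates first
  repeat {
    key <- paste(pops$lat, pops$lon)
    dup <- which(duplicated(key))
    if (length(dup) == 0) break
    pops <- merge_two(pops, match(key[dup[1L]], key), dup[1L])
  }
  repeat {
    carriers <- which(pops[[haplogroup]] > 0)
    if (length(carriers) == 0 || nrow(pops) == 1) break
    if (mean(pops$n[carriers]) >= target_mean) break
    a <- carriers[order(pops$n[carriers], pops$population[carriers])][1L]
    d <- great_circle_distance(pops$lat[a], pops$lon[a], pops$lat, pops$lon)
    d[a] <- Inf
    b <- which.min(d)
    pops <- merge_two(pops, min(a, b), max(a, b))
  }
  pops
}

#' Spatial grid constructor
#'
#' A regular lon/lat grid stored as a tibble (`lon`, `lat`, `value`) with
#' the grid geometry in attributes; `NA` marks no-data nodes.
#'
#' @param df Tibble with `lon`, `lat`, `value`.
#' @param cell_deg Cell size in degrees.
#' @param layer One of `"frequency"`, `"presence"`, `"combination"`.
#' @return A tibble of class `spatial_grid`.
#' @export
spatial_grid <- function(df, cell_deg, layer = "frequency") {
  stopifnot(all(c("lon", "lat", "value") %in% names(df)))
  structure(as_tibble(df),
            cell_deg = cell_deg, layer = layer,
            class = c("spatial_grid", class(as_tibble(df))))
}

same_grid <- function(a, b) {
  isTRUE(all.equal(a$lon, b$lon)) && isTRUE(all.equal(a$lat, b$lat))
}

#' Inverse-distance (generalized Shepard) interpolation
#'
#' Interpolates per-population values onto a regular grid. At each node,
#' populations within `radius_km` contribute with truncated inverse-distance
#' weights; with the default Franke–Little kernel
#' `w = ((R - d) / (R d))^power`. A node coinciding with a population takes
#' that population's value exactly; a node with no population in range is
#' no-data. Interpolated values are convex combinations of contributing
#' values.
#'
#' @param pops Population tibble with `lat`, `lon`.
#' @param values Numeric vector, one value in `[0, 1]` per population.
#' @param grid Optional tibble of `lon`, `lat` nodes; by default a
#'   `cell_deg`-spaced grid over the data's bounding box padded by
#'   `radius_km`.
#' @param power Weight exponent (default 3, "weight function 3").
#' @param radius_km Radius of influence in km (default 2000).
#' @param kernel `"franke_little"` (default) or `"inverse_power"`
#'   (`w = d^-power`, truncated at the radius).
#' @param cell_deg Default grid spacing in degrees.
#' @return A [spatial_grid()] of interpolated frequencies.
#' @export
shepard_interpolate <- function(pops, values, grid = NULL, power = 3,
                                radius_km = 2000,
                                kernel = c("franke_little", "inverse_power"),
                                cell_deg = 1) {
  kernel <- match.arg(kernel)
  if (power <= 0) abort("`power` must be > 0.")
  if (radius_km <= 0) abort("`radius_km` must be > 0.")
  stopifnot(length(values) == nrow(pops))
  if (any(values < 0 | values > 1)) abort("`values` must lie in [0, 1].")
  if (is.null(grid)) {
    pad <- radius_km / 111.195  # km per degree of latitude on r = 6371 km
    lon <- seq(floor(min(pops$lon) - pad), ceiling(max(pops$lon) + pad),
               by = cell_deg)
    lat <- seq(max(-90, floor(min(pops$lat) - pad)),
               min(90, ceiling(max(pops$lat) + pad)), by = cell_deg)
    grid <- tidyr::expand_grid(lon = lon, lat = lat)
  }
  D <- distance_matrix_km(grid$lat, grid$lon, pops$lat, pops$lon)
  val <- rep(NA_real_, nrow(grid))
  for (k in seq_len(nrow(grid))) {
    d <- D[k, ]
    hit <- which(d < 1e-9)
    if (length(hit) > 0) { val[k] <- values[hit[1L]]; next }
    inr <- which(d <= radius_km)
    if (length(inr) == 0) next
    w <- switch(kernel,
      franke_little = ((radius_km - d[inr]) / (radius_km * d[inr]))^power,
      inverse_power = d[inr]^(-power))
    val[k] <- sum(w * values[inr]) / sum(w)
  }
  spatial_grid(tibble(lon = grid$lon, lat = grid$lat, value = val),
               cell_deg = cell_deg, layer = "frequency")
}

#' Presence/absence map from a frequency grid
#'
#' @param freq_grid A frequency [spatial_grid()].
#' @param epsilon Frequency above which a haplogroup counts as present
#'   (default 0: any positive interpolated frequency).
#' @return A presence [spatial_grid()] over {0, 1, NA}.
#' @export
presence_map <- function(freq_grid, epsilon = 0) {
  stopifnot(inherits(freq_grid, "spatial_grid"))
  out <- freq_grid
  out$value <- ifelse(is.na(freq_grid$value), NA_real_,
                      as.numeric(freq_grid$value > epsilon))
  attr(out, "layer") <- "presence"
  out
}

#' Combine presence maps into a haplogroup-count map
#'
#' Nodewise sum of presence layers on identical grids; a no-data layer
#' contributes 0, but nodes where every layer is no-data stay no-data. The
#' value domain is {0, ..., k} for k maps ("none, one, two, or all three"
#' for the classic three-haplogroup map).
#'
#' @param maps List of presence [spatial_grid()]s with identical geometry.
#' @return A combination [spatial_grid()].
#' @export
combine_presence <- function(maps) {
  stopifnot(length(maps) >= 1)
  for (m in maps[-1L]) {
    if (!same_grid(maps[[1L]], m)) abort("Grid specifications differ.")
  }
  vals <- vapply(maps, function(m) m$value, numeric(nrow(maps[[1L]])))
  if (is.null(dim(vals))) vals <- base::matrix(vals, nrow = 1L)
  all_na <- rowSums(!is.na(vals)) == 0
  out <- maps[[1L]]
  out$value <- ifelse(all_na, NA_real_, rowSums(vals, na.rm = TRUE))
  attr(out, "layer") <- "combination"
  out
}

#' @export
print.spatial_grid <- function(x, ...) {
  cat(sprintf("<spatial_grid> %s layer, %d nodes (%d no-data), %g deg cells\n",
              attr(x, "layer"), nrow(x), sum(is.na(x$value)),
              attr(x, "cell_deg")))
  NextMethod()
}

#' Plot a spatial grid
#'
#' @param object A [spatial_grid()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot spatial_grid
#' @export
autoplot.spatial_grid <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$lon, y = .data$lat,
                                       fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "Longitude", y = "Latitude",
                  fill = attr(object, "layer")) +
    ggplot2::theme_minimal()
}
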