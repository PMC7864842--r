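#' Assign simulated samples to geolocated populations
#'
#' Places `n_pops` populations on a map and assigns each tip of the
#' genealogy to one, with the haplogroup composition of a population
#' depending on the tip's clade: each child clade of the root is given a
#' geographic centre, and a tip joins a population with probability
#' decaying in the distance between the population and its clade's centre.
#' Under `"linear_cline"` the populations sit on a west-to-east transect and
#' clade centres are spread along it; under `"patchy"` populations are
#' scattered uniformly in the study box and each clade gets a random centre
#' with a shorter decay scale, producing compact clade territories.
#'
#' @param gen A [simulate_genealogy()] result.
#' @param n_pops Number of populations (>= 1).
#' @param geography `"linear_cline"` or `"patchy"`.
#' @param seed Integer seed (default derived from `gen$config$seed`).
#' @return A tibble with one row per sample: `sample_id`, `population`,
#'   `lat`, `lon`.
#' @export
simulate_populations <- function(gen, n_pops = 10L,
                                 geography = c("linear_cline", "patchy"),
                                 seed = NULL) {
  stopifnot(inherits(gen, "genealogy"))
  geography <- match.arg(geography)
  if (n_pops < 1) abort("`n_pops` must be >= 1.")
  seed <- seed %||% derive_seed(gen$config$seed, "populations")
  set.seed(seed)

  phy <- gen$phy
  n <- length(phy$tip.label)
  root <- n + 1L
  below <- descendant_tips(phy)
  clades <- phylo_children(phy)[[root]]
  k <- length(clades)

  if (geography == "linear_cline") {
    pop_lon <- seq(0, 90, length.out = n_pops)
    pop_lat <- rep(20, n_pops)
    centre_lon <- seq(5, 85, length.out = k)
    scale_km <- 2500
  } else {
    pop_lon <- runif(n_pops, 0, 90)
    pop_lat <- runif(n_pops, 0, 40)
    centre_lon <- runif(k, 0, 90)
    scale_km <- 1000
  }
  centre_lat <- rep(20, k)

  clade_of_tip <- integer(n)
  for (j in seq_len(k)) clade_of_tip[below[[clades[j]]]] <- j

  pop_id <- integer(n)
  for (i in seq_len(n)) {
    j <- clade_of_tip[i]
    d <- great_circle_distance(centre_lat[j], centre_lon[j], pop_lat, pop_lon)
    w <- exp(-d / scale_km)
    pop_id[i] <- sample.int(n_pops, 1L, prob = w / sum(w))
  }
  tibble(
    sample_id = phy$tip.label,
    population = sprintf("P%02d", pop_id),
    lat = pop_lat[pop_id],
    lon = pop_lon[pop_id]
  )
}

#' Aggregate per-sample haplogroup calls into a population table
#'
#' @param pop_table Tibble from [simulate_populations()] (or equivalent):
#'   `sample_id`, `population`, `lat`, `lon`.
#' @param calls Tibble with `sample_id` and `haplogroup` columns (e.g. from
#'   [call_haplogroups()]).
#' @return A tibble with one row per population: `population`, `lat`, `lon`,
#'   `n`, and one `count_<haplogroup>` column per observed haplogroup.
#' @export
population_haplogroup_counts <- function(pop_table, calls) {
  joined <- dplyr::left_join(pop_table, calls[, c("sample_id", "haplogroup")],
                             by = "sample_id")
  joined$haplogroup[is.na(joined$haplogroup)] <- "unresolved"
  counts <- joined |>
    dplyr::count(.data$population, .data$lat, .data$lon, .data$haplogroup) |>
    tidyr::pivot_wider(names_from = "haplogroup", values_from = "n",
                       names_prefix = "count_", values_fill = 0L)
  counts$n <- rowSums(counts[grep("^count_", names(counts))])
  dplyr::relocate(counts, "n", .after = "lon")
}
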