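test_that("haversine distance matches closed-form anchors", {
  expect_equal(great_circle_distance(10, 20, 10, 20), 0)
  expect_equal(great_circle_distance(0, 0, 0, 180), pi * 6371,
               tolerance = 1e-6)
  # symmetry
  expect_equal(great_circle_distance(12, 34, -5, 100),
               great_circle_distance(-5, 100, 12, 34))
})

test_that("population merging hits the target mean and conserves counts", {
  pops <- tibble::tibble(
    population = c("A", "B"),
    lat = c(10, 10), lon = c(20, 20.8993),  # ~100 km apart at lat 10
    n = c(20, 30), count_C = c(5, 10)
  )
  merged <- merge_populations(pops, "count_C", target_mean = 50)
  expect_identical(nrow(merged), 1L)
  expect_equal(merged$n, 50)
  expect_equal(merged$count_C, 15)
  # sample-weighted centroid
  expect_equal(merged$lat, 10)
  expect_equal(merged$lon, (20 * 20 + 20.8993 * 30) / 50)

  # already satisfied -> identity
  big <- tibble::tibble(population = c("A", "B"), lat = c(0, 5),
                        lon = c(0, 5), n = c(60, 70), count_C = c(1, 2))
  expect_identical(merge_populations(big, "count_C"), big)

  # conservation on a random configuration
  set.seed(3)
  many <- tibble::tibble(population = sprintf("P%02d", 1:12),
                         lat = runif(12, 0, 30), lon = runif(12, 0, 60),
                         n = rpois(12, 12) + 1L)
  many$count_C <- rbinom(12, many$n, 0.4)
  m2 <- merge_populations(many, "count_C", target_mean = 40)
  expect_equal(sum(m2$n), sum(many$n))
  expect_equal(sum(m2$count_C), sum(many$count_C))
  carriers <- m2$count_C > 0
  expect_true(nrow(m2) == 1 || mean(m2$n[carriers]) >= 40)
})

test_that("Shepard interpolation is exact at populations, convex, truncated", {
  pops <- tibble::tibble(population = c("A", "B"), lat = c(10, 10),
                         lon = c(0, 20))
  vals <- c(0.2, 0.6)
  grid <- tibble::tibble(lon = c(0, 10, 60, 20), lat = c(10, 10, 10, 10))
  fg <- shepard_interpolate(pops, vals, grid = grid)
  expect_equal(fg$value[1], 0.2)   # node at population A exactly
  expect_equal(fg$value[4], 0.6)   # node at population B exactly
  expect_equal(fg$value[2], 0.4)   # equidistant -> arithmetic mean
  expect_true(is.na(fg$value[3]))  # > 2000 km from everything
  expect_error(shepard_interpolate(pops, vals, power = 0), "power")
  expect_error(shepard_interpolate(pops, vals, radius_km = -1), "radius")
  expect_error(shepard_interpolate(pops, c(2, 0.5)), "0, 1")

  # convex bounds + order invariance on random data
  set.seed(8)
  rp <- tibble::tibble(population = sprintf("P%d", 1:6),
                       lat = runif(6, 0, 30), lon = runif(6, 0, 50))
  rv <- runif(6)
  rg <- tibble::tibble(lon = runif(40, -10, 60), lat = runif(40, -10, 40))
  out <- shepard_interpolate(rp, rv, grid = rg)
  for (k in seq_len(40)) {
    d <- great_circle_distance(rg$lat[k], rg$lon[k], rp$lat, rp$lon)
    inr <- d <= 2000
    if (!any(inr)) {
      expect_true(is.na(out$value[k]))
    } else {
      expect_gte(out$value[k], min(rv[inr]) - 1e-9)
      expect_lte(out$value[k], max(rv[inr]) + 1e-9)
    }
  }
  shuf <- sample(6)
  out2 <- shepard_interpolate(rp[shuf, ], rv[shuf], grid = rg)
  expect_equal(out$value, out2$value)
})

test_that("presence and combination maps follow the no-data rules", {
  grid <- tibble::tibble(lon = 1:4, lat = rep(0, 4),
                         value = c(0, 0.3, NA, 0.0001))
  fg <- spatial_grid(grid, cell_deg = 1)
  pm <- presence_map(fg)
  expect_equal(pm$value, c(0, 1, NA, 1))
  # all-zero frequency -> all-zero presence
  z <- spatial_grid(tibble::tibble(lon = 1:3, lat = rep(0, 3),
                                   value = rep(0, 3)), 1)
  expect_equal(presence_map(z)$value, rep(0, 3))

  a <- spatial_grid(tibble::tibble(lon = 1:3, lat = rep(0, 3),
                                   value = c(1, 1, NA)), 1, "presence")
  b <- spatial_grid(tibble::tibble(lon = 1:3, lat = rep(0, 3),
                                   value = c(0, 1, NA)), 1, "presence")
  d <- spatial_grid(tibble::tibble(lon = 1:3, lat = rep(0, 3),
                                   value = c(NA, 1, NA)), 1, "presence")
  combo <- combine_presence(list(a, b, d))
  # (1,0,NA) -> 1; (1,1,1) -> 3; all-NA stays NA
  expect_equal(combo$value, c(1, 3, NA))
  expect_true(all(combo$value[!is.na(combo$value)] %in% 0:3))
  # identical maps of ones sum to the layer count
  ones <- spatial_grid(tibble::tibble(lon = 1:2, lat = c(0, 0),
                                      value = c(1, 1)), 1, "presence")
  expect_equal(combine_presence(list(ones, ones, ones))$value, c(3, 3))
  # mismatched grids error
  off <- spatial_grid(tibble::tibble(lon = 2:4, lat = rep(0, 3),
                                     value = c(1, 1, 1)), 1, "presence")
  expect_error(combine_presence(list(a, off)), "differ")
})

test_that("two disjoint clade regions overlap only in the 2000 km zone", {
  pops <- tibble::tibble(
    population = c("c1", "c2", "d1", "d2"),
    lat = rep(20, 4), lon = c(0, 4, 40, 44),
    n = rep(25, 4), count_C = c(25, 25, 0, 0), count_D = c(0, 0, 25, 25)
  )
  grid <- tidyr::expand_grid(lon = seq(-20, 64, by = 2), lat = 20)
  fC <- shepard_interpolate(pops, pops$count_C / pops$n, grid = grid)
  fD <- shepard_interpolate(pops, pops$count_D / pops$n, grid = grid)
  combo <- combine_presence(list(presence_map(fC), presence_map(fD)))
  for (k in seq_len(nrow(grid))) {
    dC <- min(great_circle_distance(20, grid$lon[k], 20, c(0, 4)))
    dD <- min(great_circle_distance(20, grid$lon[k], 20, c(40, 44)))
    expected <- if (dC > 2000 && dD > 2000) NA_real_
                else (dC <= 2000) + (dD <= 2000)
    expect_equal(combo$value[k], expected,
                 info = sprintf("lon %s", grid$lon[k]))
  }
})
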