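test_that("great-circle distance matches closed forms and is a metric", {
  expect_equal(great_circle_distance(10, 20, 10, 20), 0)
  expect_equal(great_circle_distance(0, 0, 0, 180), pi * 6371,
               tolerance = 1e-6)
  expect_equal(great_circle_distance(0, 0, 0, 1), 2 * pi * 6371 / 360,
               tolerance = 1e-6)
  expect_error(great_circle_distance(91, 0, 0, 0), "out of range")

  set.seed(1)
  lat <- runif(30, -80, 80); lon <- runif(30, -170, 170)
  i <- sample(30, 50, TRUE); j <- sample(30, 50, TRUE); k <- sample(30, 50, TRUE)
  dij <- great_circle_distance(lat[i], lon[i], lat[j], lon[j])
  dji <- great_circle_distance(lat[j], lon[j], lat[i], lon[i])
  dik <- great_circle_distance(lat[i], lon[i], lat[k], lon[k])
  dkj <- great_circle_distance(lat[k], lon[k], lat[j], lon[j])
  expect_equal(dij, dji)
  expect_true(all(dij <= dik + dkj + 1e-9))
  expect_true(all(dij[i == j] == 0))
})

test_that("haversine agrees with an independent geodesic library", {
  skip_if_not_installed("geosphere")
  set.seed(2)
  a <- cbind(runif(20, -170, 170), runif(20, -80, 80))
  b <- cbind(runif(20, -170, 170), runif(20, -80, 80))
  ours <- great_circle_distance(a[, 2], a[, 1], b[, 2], b[, 1])
  ref <- geosphere::distHaversine(a, b, r = 6371)
  expect_equal(ours, ref, tolerance = 1e-9)
})

test_that("raster reader handles the ESRI ASCII dialect and its errors", {
  path <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols 2", "nrows 2", "xllcorner 5", "yllcorner 45",
               "cellsize 0.5", "NODATA_value -9999",
               "5 5", "5 5"), path)
  g <- read_population_raster(path)
  expect_equal(sum(g$counts), 20)
  expect_equal(g$cellsize, 0.5)

  writeLines(c("ncols 2", "nrows 2", "xllcorner 5", "yllcorner 45",
               "cellsize 0.5", "NODATA_value -9999",
               "5 -9999", "-9999 5"), path)
  g2 <- read_population_raster(path)
  expect_equal(sum(g2$counts), 10)
  expect_equal(g2$counts[1, 2], 0)

  writeLines(c("ncols 2", "nrows 2", "xllcorner 5", "yllcorner 45",
               "cellsize 0.5", "NODATA_value -9999", "5 5 5"), path)
  expect_error(read_population_raster(path), "does not match")

  writeLines(c("ncols 2", "xllcorner 5", "yllcorner 45", "cellsize 0.5",
               "1 2"), path)
  expect_error(read_population_raster(path), "missing")

  writeLines(c("ncols 2", "nrows 1", "xllcorner 5", "yllcorner 45",
               "cellsize 0.5", "NODATA_value -9999", "0 0"), path)
  expect_error(read_population_raster(path), "zero total")
})

test_that("raster write-then-read round-trips counts and georeferencing", {
  g <- synth_population_grid(c(40, 42), c(0, 3), cellsize = 0.25,
                             n_cities = 2, total_population = 5000,
                             seed = 3)
  path <- withr::local_tempfile(fileext = ".asc")
  write_population_raster(g, path)
  g2 <- read_population_raster(path)
  expect_equal(g2$counts, g$counts)
  expect_equal(g2$xllcorner, g$xllcorner)
  expect_equal(g2$yllcorner, g$yllcorner)
  expect_equal(g2$cellsize, g$cellsize)
})

test_that("synthetic grids are deterministic Gaussian-city mixtures", {
  g1 <- synth_population_grid(c(40, 45), c(0, 5), cellsize = 0.1,
                              n_cities = 1, city_sd_km = 5,
                              total_population = 1e4, seed = 9,
                              city_centers = data.frame(lat = 42.5, lon = 2.5))
  peak <- which(g1$counts == max(g1$counts), arr.ind = TRUE)
  centers <- grid_cell_centers(g1)
  peak_cell <- centers[centers$row == peak[1] & centers$col == peak[2], ]
  expect_lt(abs(peak_cell$lat - 42.5), 0.11)
  expect_lt(abs(peak_cell$lon - 2.5), 0.11)
  expect_equal(sum(g1$counts), 1e4)

  # two cities with 3:1 weights hold mass in about that ratio
  g2 <- synth_population_grid(
    c(40, 46), c(0, 8), cellsize = 0.1, n_cities = 2,
    city_weights = c(3, 1), city_sd_km = 20, total_population = 1e5,
    city_centers = data.frame(lat = c(42, 44), lon = c(2, 6)), seed = 1)
  cc <- grid_cell_centers(g2)
  d1 <- great_circle_distance(cc$lat, cc$lon, 42, 2)
  d2 <- great_circle_distance(cc$lat, cc$lon, 44, 6)
  m1 <- sum(cc$count[d1 < 60]); m2 <- sum(cc$count[d2 < 60])
  expect_lt(abs(m1 / m2 - 3), 3 * 0.05 * 3)

  g3 <- synth_population_grid(c(40, 45), c(0, 5), cellsize = 0.1,
                              n_cities = 2, total_population = 1e4, seed = 5)
  g4 <- synth_population_grid(c(40, 45), c(0, 5), cellsize = 0.1,
                              n_cities = 2, total_population = 1e4, seed = 5)
  expect_identical(g3$counts, g4$counts)
  expect_error(synth_population_grid(c(40, 40.01), c(0, 0.01),
                                     cellsize = 0.5),
               "smaller than one cell")
})

test_that("initial positions follow the population weights", {
  counts <- matrix(0, 2, 5)
  counts[1, 1] <- 1
  g <- population_grid(counts, 0, 40, 0.5)
  pos <- sample_initial_positions(g, 50, seed = 1)
  expect_true(all(pos$lat >= 40.5 & pos$lat <= 41))
  expect_true(all(pos$lon >= 0 & pos$lon <= 0.5))

  expect_equal(nrow(sample_initial_positions(g, 0)), 0)
  expect_error(sample_initial_positions(
    structure(list(counts = matrix(0, 1, 1)), class = "population_grid"), 5))

  # two equal cells: binomial bound at n = 1e4
  counts2 <- matrix(c(1, 1), 1, 2)
  g2 <- population_grid(counts2, 0, 40, 0.5)
  pos2 <- sample_initial_positions(g2, 1e4, seed = 2)
  n1 <- sum(pos2$lon < 0.5)
  expect_lt(abs(n1 - 5000), 3 * sqrt(1e4 * 0.25))

  # TV distance to the weights on a 10-cell grid at n = 1e6
  counts3 <- matrix(1:10, 1, 10)
  g3 <- population_grid(counts3, 0, 40, 0.5)
  pos3 <- sample_initial_positions(g3, 1e6, seed = 3)
  cell <- findInterval(pos3$lon, seq(0, 5, 0.5), rightmost.closed = TRUE)
  emp <- tabulate(cell, 10) / 1e6
  expect_lt(0.5 * sum(abs(emp - (1:10) / 55)), 0.01)
})

test_that("jump lengths follow the specified laws", {
  spec <- jump_spec()
  set.seed(4)
  x <- sample_jump_length(spec, 1e5)
  expect_true(all(x >= 1 & x <= 20000))
  # empirical CDF vs analytic truncated CDF
  xs <- sort(x)
  emp <- seq_along(xs) / length(xs)
  expect_lt(max(abs(emp - ptrunc_powerlaw(xs, 1.55, 1, 20000))), 0.006)

  u <- jump_spec("uniform", d_min = 10, d_max = 20)
  set.seed(5)
  xu <- sample_jump_length(u, 2e4)
  expect_true(all(xu >= 10 & xu <= 20))
  expect_gt(suppressWarnings(ks.test(xu, "punif", 10, 20))$p.value, 0.01)

  nrm <- jump_spec("normal", mean = 50, sd = 10, d_min = 30)
  set.seed(6)
  xn <- sample_jump_length(nrm, 1e4)
  expect_true(all(xn >= 30))
  expect_lt(abs(mean(xn) - 51.7), 2)  # truncated-normal mean, not 50
})

test_that("truncated power-law MLE recovers known exponents", {
  set.seed(7)
  for (a in c(1.2, 1.55, 2.5)) {
    x <- qtrunc_powerlaw(runif(2e5), a, 1, 20000)
    fit <- fit_truncated_powerlaw(x, 1, 20000)
    expect_lt(abs(fit$alpha - a), 0.02)
  }
})

test_that("jump targets are annulus-restricted and density-weighted", {
  # 3x3 grid, cellsize 0.5 deg, centres at lat {41.25, 40.75, 40.25};
  # origin at the central cell centre (40.75, 0.75): the north neighbour is
  # ~55.6 km away, inside the annulus of r = 80 (width = cell diagonal)
  counts <- matrix(0, 3, 3)
  counts[1, 2] <- 10   # north cell
  counts[2, 2] <- 5    # origin cell (distance ~0, outside annulus)
  g <- population_grid(counts, 0, 40, 0.5)
  set.seed(8)
  tg <- sample_jump_target(g, 40.75, 0.75, rep(80, 200))
  expect_true(all(tg$in_annulus))
  expect_true(all(tg$lat > 41))

  # east and west neighbours (~42.1 km) weighted 9:1 inside the annulus
  counts2 <- matrix(0, 3, 3)
  counts2[2, 1] <- 9; counts2[2, 3] <- 1
  g2 <- population_grid(counts2, 0, 40, 0.5)
  set.seed(9)
  tg2 <- sample_jump_target(g2, 40.75, 0.75, rep(40, 2000))
  west <- sum(tg2$lon < 0.5)
  expect_lt(abs(west - 1800), 3 * sqrt(2000 * 0.9 * 0.1))

  # uniform equatorial density: bearings uniform over 12 sectors
  gu <- population_grid(matrix(1, 201, 201), 0, -20.1, 0.2)
  set.seed(10)
  r <- runif(1e5, 100, 500)
  tg3 <- sample_jump_target(gu, 0, 20.1, r)
  brg <- atan2(tg3$lon - 20.1, tg3$lat - 0)
  sect <- cut(brg, breaks = seq(-pi, pi, length.out = 13),
              include.lowest = TRUE)
  expect_gt(chisq.test(table(sect))$p.value, 0.01)

  # fallback: empty annulus lands in the populated cell closest to r
  tg4 <- sample_jump_target(g, 40.75, 0.75, 5000)
  expect_false(tg4$in_annulus[1])
  expect_false(is.na(tg4$lat[1]))
  tg5 <- sample_jump_target(g, 40.75, 0.75, 5000, fallback = "none")
  expect_true(is.na(tg5$lat[1]))
  expect_error(sample_jump_target(g, 10, 10, 50), "outside")
})

test_that("jump-target sampling never returns an unpopulated cell", {
  w <- small_world(n = 1)
  set.seed(11)
  tg <- sample_jump_target(w$grid, 45, 6, sample_jump_length(
    jump_spec(d_max = 2000), 500))
  cc <- grid_cell_centers(w$grid)
  row <- w$grid$nrows - floor((tg$lat - w$grid$yllcorner) / w$grid$cellsize)
  col <- floor((tg$lon - w$grid$xllcorner) / w$grid$cellsize) + 1
  counts <- w$grid$counts[cbind(row, col)]
  expect_true(all(counts > 0))
})
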