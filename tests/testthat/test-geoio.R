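test_that("grid equality requires all fields to match", {
  g <- grid_spec(0, 100, 10, 10, 10, "A")
  expect_true(grid_equal(g, grid_spec(0, 100, 10, 10, 10, "A")))
  expect_false(grid_equal(g, grid_spec(0, 100, 10, 10, 10, "B")))
  expect_false(grid_equal(g, grid_spec(0, 100, 5, 10, 10, "A")))
  expect_false(grid_equal(g, grid_spec(1, 100, 10, 10, 10, "A")))
  expect_error(grid_spec(0, 100, -10, 10, 10), "positive")
  expect_error(grid_spec(0, 100, 10, 0, 10), "positive integers")
})

test_that("point lookup follows the half-open pixel convention", {
  g <- tiny_grid(3, 4, 10)
  # centers
  expect_equal(unlist(cell_at(g, 5, 25)), c(row = 1L, col = 1L))
  expect_equal(unlist(cell_at(g, 35, 5)), c(row = 3L, col = 4L))
  # left/top edges belong to the cell, right/bottom edges to the next
  expect_equal(cell_at(g, 10, 25)$col, 2L)
  expect_equal(cell_at(g, 0, 30)$row, 1L)
  # outside the extent
  expect_true(is.na(cell_at(g, 40, 5)$col))
  expect_true(is.na(cell_at(g, 5, 0)$row))
})

test_that("point_sample returns containing-cell values, nodata, and errors", {
  g <- tiny_grid(3, 3, 10)
  v <- matrix(as.numeric(1:9), 3, 3)
  v[2, 2] <- NA
  b <- raster_band(g, "x", v, units = "index")
  expect_equal(point_sample(b, 5, 25), 1)      # center of (1,1)
  expect_true(is.na(point_sample(b, 15, 15)))  # nodata cell
  expect_error(point_sample(b, 35, 5), "outside")
  # a point 1 cm inside the right edge of the last column
  expect_equal(point_sample(b, 30 - 0.01, 5), v[3, 3])
})

test_that("point_sample agrees with the exhaustive containment oracle", {
  g <- grid_spec(-20, 35, 7, 5, 6, "test")
  set.seed(11)
  v <- matrix(rnorm(30), 5, 6)
  b <- raster_band(g, "x", v, units = "index")
  xs <- runif(60, -20, -20 + 6 * 7 - 1e-9)
  ys <- runif(60, 35 - 5 * 7 + 1e-9, 35)
  for (i in seq_along(xs)) {
    rc <- oracle_cell_of(g, xs[i], ys[i])
    expect_equal(point_sample(b, xs[i], ys[i]), v[rc[1], rc[2]])
  }
})

test_that("nearest resampling replicates 20 m cells into 2x2 10 m blocks", {
  src_g <- grid_spec(0, 40, 20, 2, 2, "test")
  src <- raster_band(src_g, "VV", matrix(c(1, 3, 2, 4), 2, 2),
                     units = "linear_power")
  tgt <- grid_spec(0, 40, 10, 4, 4, "test")
  out <- resample_to_grid(src, tgt, "nearest")
  expect_equal(out$values, matrix(c(1, 1, 3, 3,
                                    1, 1, 3, 3,
                                    2, 2, 4, 4,
                                    2, 2, 4, 4), 4, 4))
  expect_true(all(out$values %in% src$values))
})

test_that("resampling is exact on an identical grid and constant-preserving", {
  b <- const_band(0.37, 6, 6)
  same <- resample_to_grid(b, b$grid, "nearest")
  expect_identical(same$values, b$values)
  finer <- grid_spec(0, 60, 5, 12, 12, "test")
  bl <- resample_to_grid(b, finer, "bilinear")
  expect_true(all(abs(bl$values - 0.37) < 1e-12))
  # idempotence on an already aligned band
  again <- resample_to_grid(same, b$grid, "bilinear")
  expect_equal(again$values, b$values)
})

test_that("disjoint extents and CRS mismatches are errors", {
  b <- const_band(1, 4, 4)
  far <- grid_spec(1e5, 1e5, 10, 4, 4, "test")
  expect_error(resample_to_grid(b, far, "nearest"), "disjoint")
  other <- grid_spec(0, 40, 10, 4, 4, "other-crs")
  expect_error(resample_to_grid(b, other), "CRS")
})

test_that("ASCII grid and scene serialization round-trips values, masks, grid", {
  g <- grid_spec(120, 980, 10, 7, 5, "utm-ish")
  set.seed(3)
  v <- matrix(rnorm(35, 0, 5), 7, 5)
  v[c(3, 17)] <- NA
  b <- raster_band(g, "VV", v, units = "dB")
  p <- withr::local_tempfile(fileext = ".asc")
  write_asc(b, p)
  back <- read_asc(p, name = "VV", units = "dB", crs_label = "utm-ish")
  expect_true(grid_equal(back$grid, g))
  expect_identical(back$mask, b$mask)
  expect_equal(back$values, b$values, tolerance = 1e-12)

  sc <- scene_stack("2021-06-10",
                    list(B2 = const_band(0.1, 7, 5, "B2"),
                         B3 = const_band(0.2, 7, 5, "B3"),
                         B4 = raster_band(tiny_grid(7, 5), "B4", v / 10)),
                    sensor = "S2")
  d <- withr::local_tempdir()
  write_scene(sc, file.path(d, "s"))
  back <- read_scene(file.path(d, "s"), c("B2", "B3", "B4"))
  expect_equal(length(back$bands), 3L)
  expect_identical(back$date, as.Date("2021-06-10"))
  expect_equal(back$bands$B4$values, sc$bands$B4$values, tolerance = 1e-12)
  expect_true(all(vapply(back$bands,
                         function(x) grid_equal(x$grid, back$grid),
                         logical(1))))
  # requesting a band the file does not have is a format error
  expect_error(read_scene(file.path(d, "s"), c("B2", "B3", "B4", "B8")),
               "requested")
  expect_error(read_scene(file.path(d, "missing")), "manifest")
})

test_that("wetland GeoJSON round-trips attributes and geometry", {
  spec <- small_spec()
  w <- generate_wetlands(spec, seed = 5)
  p <- withr::local_tempfile(fileext = ".geojson")
  write_wetlands(w, p)
  back <- read_wetlands(p)
  lu <- c("OP", "DA", "BL", "FO", "SS", "HB", "HP", "CC", "WW", "EHW")
  expect_equal(back$wetland_id, w$wetland_id)
  expect_equal(as.matrix(back[lu]), as.matrix(w[lu]), tolerance = 1e-12)
  expect_equal(back$Area, w$Area, tolerance = 1e-9)
  expect_equal(back$polygon[[1]], w$polygon[[1]], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("sample records validate station, nutrient, and window", {
  s <- tibble::tibble(wetland_id = "W01", station = "inlet", x = 1, y = 1,
                      date = as.Date("2021-05-01"), nutrient = "N",
                      concentration_mg_L = 0.5)
  p <- withr::local_tempfile(fileext = ".csv")
  write_samples(s, p)
  expect_equal(as.data.frame(read_samples(p)), as.data.frame(s))
  bad <- s; bad$station <- "edge"
  expect_error(validate_samples(bad), "station")
  bad <- s; bad$concentration_mg_L <- -1
  expect_error(validate_samples(bad), "non-negative")
  expect_error(validate_samples(s, as.Date(c("2022-01-01", "2024-12-31"))),
               "window")
})

test_that("7-day climate means match a direct window computation", {
  set.seed(9)
  dates <- seq(as.Date("2021-01-01"), as.Date("2021-03-01"), by = "day")
  clim <- tibble::tibble(wetland_id = "W01", date = dates,
                         rain_mm = rexp(length(dates)),
                         temp_f = rnorm(length(dates), 40, 5))
  got <- climate_7day(clim, "W01", as.Date("2021-02-10"))
  win <- clim[clim$date > as.Date("2021-02-03") &
                clim$date <= as.Date("2021-02-10"), ]
  expect_equal(got$AveRain, mean(win$rain_mm))
  expect_equal(got$AveTemp, mean(win$temp_f))
  expect_error(climate_7day(clim, "W01", as.Date("2021-01-03")), "cover")
})
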