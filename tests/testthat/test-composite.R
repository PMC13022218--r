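test_that("quarter assignment honours calendar boundaries", {
  q <- assign_quarter(as.Date(c("2021-01-01", "2021-03-31", "2021-04-01",
                                "2024-12-31", "2022-07-01", "2022-09-30")))
  expect_equal(q$key, c("2021-Q1", "2021-Q1", "2021-Q2", "2024-Q4",
                        "2022-Q3", "2022-Q3"))
  expect_equal(q$year, c(2021L, 2021L, 2021L, 2024L, 2022L, 2022L))
})

make_scene <- function(date, vals, nm = "B4", units = "reflectance",
                       sensor = "S2", nr = 3, nc = 3) {
  scene_stack(date, stats::setNames(
    list(raster_band(tiny_grid(nr, nc), nm, vals, units = units)), nm),
    sensor = sensor)
}

test_that("quarterly composite is the masked arithmetic mean", {
  s1 <- make_scene("2021-02-01", matrix(0.2, 3, 3))
  s2 <- make_scene("2021-03-15", matrix(0.4, 3, 3))
  out <- quarterly_composite(list(s1, s2), 2021, "Q1")
  expect_equal(out$bands$B4$values, matrix(0.3, 3, 3))

  # a single scene composites to itself
  one <- quarterly_composite(list(s1), 2021, "Q1")
  expect_equal(one$bands$B4$values, s1$bands$B4$values)

  # nodata in one of two scenes leaves the valid value
  v <- matrix(0.4, 3, 3); v[2, 2] <- NA
  s2b <- make_scene("2021-03-15", v)
  out <- quarterly_composite(list(s1, s2b), 2021, "Q1")
  expect_equal(out$bands$B4$values[2, 2], 0.2)
  expect_equal(out$bands$B4$values[1, 1], 0.3)

  # scenes from other quarters are excluded; empty quarters error
  s3 <- make_scene("2021-04-01", matrix(0.9, 3, 3))
  out <- quarterly_composite(list(s1, s2, s3), 2021, "Q1")
  expect_equal(out$bands$B4$values[1, 1], 0.3)
  expect_error(quarterly_composite(list(s1), 2021, "Q3"), "no scenes")
  expect_equal(unname(out$n_scenes["S2"]), 2L)
})

test_that("composite equals the loop oracle on random masked scenes", {
  set.seed(21)
  scenes <- lapply(1:4, function(i) {
    v <- matrix(runif(9, 0, 1), 3, 3)
    v[sample(9, 2)] <- NA
    make_scene(as.Date("2021-01-05") + i * 7, v)
  })
  out <- quarterly_composite(scenes, 2021, "Q1")
  expect_equal(out$bands$B4$values,
               oracle_masked_mean(lapply(scenes, function(s) s$bands$B4)))
  # mean composite of k identical scenes equals any one scene
  same <- lapply(1:3, function(i) make_scene(as.Date("2021-02-01") + i,
                                             scenes[[1]]$bands$B4$values))
  out <- quarterly_composite(same, 2021, "Q1")
  expect_equal(out$bands$B4$values, scenes[[1]]$bands$B4$values)
})

test_that("compositing commutes with band selection", {
  set.seed(22)
  two_band_scene <- function(date) {
    g <- tiny_grid(3, 3)
    scene_stack(date, list(
      B4 = raster_band(g, "B4", matrix(runif(9), 3, 3)),
      B8 = raster_band(g, "B8", matrix(runif(9), 3, 3))
    ), sensor = "S2")
  }
  scenes <- list(two_band_scene("2021-01-10"), two_band_scene("2021-02-10"))
  full <- quarterly_composite(scenes, 2021, "Q1")
  only_b8 <- lapply(scenes, function(s) { s$bands <- s$bands["B8"]; s })
  sub <- quarterly_composite(only_b8, 2021, "Q1")
  expect_equal(full$bands$B8$values, sub$bands$B8$values)
})

test_that("SAR must be linear power before compositing; indices derive from composited bands", {
  sdb <- make_scene("2021-01-10", matrix(-12, 3, 3), nm = "VV", units = "dB",
                    sensor = "S1")
  expect_error(quarterly_composite(list(sdb), 2021, "Q1"), "db_to_linear")

  g <- tiny_grid(2, 2)
  mk <- function(date, b8, b4) {
    scene_stack(date, list(B8 = raster_band(g, "B8", matrix(b8, 2, 2)),
                           B4 = raster_band(g, "B4", matrix(b4, 2, 2))), "S2")
  }
  # mean-then-index: NDVI of the means, not the mean of NDVIs
  out <- quarterly_composite(list(mk("2021-01-05", 0.6, 0.1),
                                  mk("2021-02-05", 0.2, 0.3)), 2021, "Q1")
  expect_equal(out$bands$NDVI$values[1, 1], (0.4 - 0.2) / (0.4 + 0.2))
})

test_that("feature table links samples to wetlands, climate, and composites", {
  study <- synth_study(small_spec(), seed = 31)
  comps <- study_composites(study)
  ft <- build_feature_table(study$samples, comps, study$wetlands,
                            study$climate)
  expect_equal(nrow(ft), nrow(study$samples))   # no row silently dropped
  expect_equal(nrow(ft), 3 * 3 * 6)
  expect_setequal(attr(ft, "discrete_features"), discrete_features())
  expect_setequal(attr(ft, "continuous_features"), continuous_features())
  expect_false(any(is.na(ft$concentration)))
  expect_true(all(!ft$flagged))

  # discrete block is constant within a wetland
  per_w <- dplyr::summarise(dplyr::group_by(ft, wetland_id),
                            n_hp = dplyr::n_distinct(HP),
                            n_area = dplyr::n_distinct(Area))
  expect_true(all(per_w$n_hp == 1) && all(per_w$n_area == 1))

  # two samples in the same pixel and quarter share continuous features
  s2 <- study$samples[c(1, 1), ]
  s2$station <- c("inlet", "middle")
  ft2 <- build_feature_table(s2, comps, study$wetlands, study$climate)
  expect_equal(as.numeric(ft2[1, continuous_features()]),
               as.numeric(ft2[2, continuous_features()]))

  # linkage errors name the offending keys
  expect_error(build_feature_table(study$samples, comps[-1], study$wetlands,
                                   study$climate),
               names(comps)[1])
  bad <- study$samples
  bad$wetland_id[1] <- "W99"
  expect_error(build_feature_table(bad, comps, study$wetlands, study$climate),
               "W99")
})

test_that("samples on nodata pixels are flagged, not dropped", {
  study <- synth_study(small_spec(), seed = 32)
  comps <- study_composites(study)
  # punch a nodata hole at the first sample's pixel in every continuous band
  k <- assign_quarter(study$samples$date[1])$key
  rc <- cell_at(comps[[k]]$bands[[1]]$grid, study$samples$x[1],
                study$samples$y[1])
  comps[[k]]$bands <- lapply(comps[[k]]$bands, function(b) {
    b$values[rc$row, rc$col] <- NA
    raster_band(b$grid, b$name, b$values, units = b$units)
  })
  ft <- build_feature_table(study$samples, comps, study$wetlands,
                            study$climate)
  expect_equal(nrow(ft), nrow(study$samples))
  expect_true(ft$flagged[1])
  # every sample sharing that pixel and quarter is flagged, no others
  same_px <- ft$wetland_id == ft$wetland_id[1] &
    ft$station == ft$station[1] &
    assign_quarter(ft$date)$key == k
  expect_identical(ft$flagged, unname(same_px))
})
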