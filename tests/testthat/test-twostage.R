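# compact synthetic regression tables for direct stage fits
make_table <- function(n = 120, noise = 0, seed = 1,
                       f = function(d) 2 * d$HP) {
  withr::with_seed(seed, {
    d <- tibble::tibble(
      HP = runif(n, 0, 30), DA = runif(n, 0, 40), Area = runif(n, 0.1, 1),
      NDVI = runif(n, -0.2, 0.9), VV_VH = runif(n, 1, 8),
      quarter = sample(paste0("Q", 1:4), n, replace = TRUE)
    )
    d$concentration <- f(d) + rnorm(n, 0, noise)
    d$flagged <- FALSE
    d
  })
}

test_that("train/test split is exact, seeded, disjoint, and exhaustive", {
  tab <- make_table(100)
  sp <- split_train_test(tab, 0.7, seed = 5)
  expect_equal(nrow(sp$train), 70)
  expect_equal(nrow(sp$test), 30)
  expect_equal(nrow(dplyr::intersect(sp$train, sp$test)), 0)
  expect_equal(dplyr::arrange(dplyr::bind_rows(sp$train, sp$test), HP),
               dplyr::arrange(tab, HP))
  sp2 <- split_train_test(tab, 0.7, seed = 5)
  expect_identical(sp$train, sp2$train)
  sp3 <- split_train_test(tab, 0.7, seed = 6)
  expect_false(identical(sp$train, sp3$train))
  # stratified: the fraction holds within each stratum
  spq <- split_train_test(tab, 0.7, seed = 5, strata = "quarter")
  for (q in paste0("Q", 1:4)) {
    nq <- sum(tab$quarter == q)
    expect_equal(sum(spq$train$quarter == q), round(0.7 * nq))
  }
})

test_that("validation metrics match their formulas and the loop oracle", {
  m <- evaluate_predictions(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unlist(m[c("r2", "rmse", "mae", "mbe")]),
               c(r2 = 1, rmse = 0, mae = 0, mbe = 0))
  m <- evaluate_predictions(c(2, 2), c(1, 3))
  expect_equal(unlist(m[c("r2", "rmse", "mae", "mbe")]),
               c(r2 = 0, rmse = 1, mae = 1, mbe = 0))
  obs <- c(0.3, 0.9, 1.4)
  m <- evaluate_predictions(obs + 0.5, obs)
  expect_equal(m$mbe, 0.5)
  expect_equal(m$mae, 0.5)
  # zero-variance observations make r2 undefined
  expect_true(is.na(evaluate_predictions(c(1, 2), c(2, 2))$r2))

  set.seed(41)
  for (i in 1:25) {
    n <- sample(2:60, 1)
    pred <- rnorm(n); obs <- rnorm(n)
    got <- evaluate_predictions(pred, obs)
    want <- oracle_metrics(pred, obs)
    expect_equal(got$r2, want$r2, tolerance = 1e-12)
    expect_equal(got$rmse, want$rmse, tolerance = 1e-12)
    expect_equal(got$mae, want$mae, tolerance = 1e-12)
    expect_equal(got$mbe, want$mbe, tolerance = 1e-12)
    expect_true(got$rmse >= got$mae)
    expect_true(got$mae >= abs(got$mbe))
  }
})

test_that("stage 1 recovers a noiseless discrete signal and ranks its driver first", {
  tab <- make_table(150, noise = 0)
  s1 <- fit_stage1(tab, c("HP", "DA", "Area"), seed = 3)
  td <- tidy(s1$model)
  expect_equal(td$feature[1], "HP")
  expect_gt(1 - var(s1$residuals) / var(tab$concentration), 0.8)
  # in-sample fit is nearly interpolating
  r2_in <- evaluate_predictions(
    predict(s1$model$model, data = as.data.frame(tab))$predictions,
    tab$concentration)$r2
  expect_gt(r2_in, 0.95)
  # importance normalizes to one
  expect_equal(sum(s1$model$importance), 1, tolerance = 1e-6)
})

test_that("stage 1 finds nothing in pure noise", {
  r2s <- vapply(1:5, function(i) {
    tab <- make_table(120, seed = 100 + i, f = function(d) 0)
    tab$concentration <- withr::with_seed(200 + i, rnorm(120))
    sp <- split_train_test(tab, 0.7, seed = i)
    s1 <- fit_stage1(sp$train, c("HP", "DA", "Area"), seed = i)
    pred <- predict(s1$model$model,
                    data = as.data.frame(sp$test))$predictions
    evaluate_predictions(pred, sp$test$concentration)$r2
  }, numeric(1))
  expect_lt(median(r2s), 0.15)
})

test_that("degenerate stage inputs error or warn", {
  tab <- make_table(60)
  expect_error(fit_stage1(tab[1, ], c("HP")), "at least 2")
  expect_error(fit_stage1(tab, character(0)), "empty feature set")
  const <- tab; const$concentration <- 1
  expect_warning(fit_stage1(const, c("HP", "DA"), seed = 1), "constant")
})

test_that("stage 2 recovers a continuous residual signal and ignores noise", {
  tab <- make_table(150, noise = 0)
  resid <- 3 * tab$NDVI
  sp <- split_train_test(cbind(tab, .r = resid), 0.7, seed = 9)
  s2 <- fit_stage2(sp$train, sp$train$.r, c("NDVI", "VV_VH"), seed = 9)
  expect_equal(tidy(s2)$feature[1], "NDVI")
  pred <- predict(s2$model, data = as.data.frame(sp$test))$predictions
  expect_gt(evaluate_predictions(pred, sp$test$.r)$r2, 0.9)
  # zero residuals predict approximately zero everywhere
  suppressWarnings(s2z <- fit_stage2(sp$train, rep(0, nrow(sp$train)),
                                     c("NDVI", "VV_VH"), seed = 9))
  predz <- predict(s2z$model, data = as.data.frame(sp$test))$predictions
  expect_true(all(abs(predz) < 1e-9))
  # flagged rows are excluded from the fit
  fl <- sp$train
  fl$flagged[1:10] <- TRUE
  s2f <- fit_stage2(fl, fl$.r, c("NDVI", "VV_VH"), seed = 9)
  expect_equal(s2f$n_train, nrow(fl) - 10)
})

test_that("final prediction is additive, falls back, and clips", {
  tab <- make_table(150, noise = 0.1,
                    f = function(d) 1 + 0.05 * d$HP + 1.5 * d$NDVI)
  m <- fit_two_stage(tab, seed = 11)
  pr <- predict(m, tab)
  expect_equal(pr$final_raw, pr$baseline + pr$correction, tolerance = 1e-12)
  expect_true(all(pr$provenance == "two_stage"))
  # incomplete continuous block -> baseline only
  tab2 <- tab[1:5, ]
  tab2$NDVI[2] <- NA
  pr2 <- predict(m, tab2)
  expect_equal(pr2$provenance[2], "baseline_only")
  expect_equal(pr2$final_raw[2], pr2$baseline[2])
  expect_equal(pr2$correction[2], 0)

  # negativity guard
  neg <- make_table(80, noise = 0, f = function(d) d$NDVI - 0.5)
  mneg <- fit_two_stage(neg, seed = 12)
  low <- neg[which.min(neg$NDVI)[1], ]
  expect_warning(predict(mneg, low), "clipped")
  pr3 <- suppressWarnings(predict(mneg, low))
  expect_gte(pr3$final, 0)
  expect_lt(pr3$final_raw, 0)
  # raw layer keeps the unclipped value, additivity pre-clipping intact
  expect_equal(pr3$final_raw, pr3$baseline + pr3$correction,
               tolerance = 1e-12)
})

test_that("two-stage metrics report all three scales and improve on stage 1", {
  tab <- make_table(200, noise = 0.05,
                    f = function(d) 1 + 0.05 * d$HP + 1.5 * d$NDVI)
  m <- fit_two_stage(tab, seed = 13)
  expect_setequal(m$metrics$stage, c("stage1", "stage2", "final"))
  fin <- m$metrics[m$metrics$stage == "final", ]
  s1 <- m$metrics[m$metrics$stage == "stage1", ]
  expect_gt(fin$r2, s1$r2)
  expect_true(all(m$metrics$rmse >= m$metrics$mae))
  g <- glance(m)
  expect_equal(g$r2_final, fin$r2)
  expect_equal(g$n_train + g$n_test, 200)
})

test_that("fixed seeds give bit-identical models and metrics", {
  tab <- make_table(150, noise = 0.1,
                    f = function(d) 1 + 0.05 * d$HP + 1.5 * d$NDVI)
  m1 <- fit_two_stage(tab, seed = 21)
  m2 <- fit_two_stage(tab, seed = 21)
  expect_identical(m1$metrics, m2$metrics)
  expect_identical(m1$stage1$importance, m2$stage1$importance)
})

test_that("importance heatmaps average over years per quarter", {
  fake_model <- function(imp, stage = 1L) {
    structure(list(importance = imp, importance_raw = imp, stage = stage,
                   feature_names = names(imp)), class = "stage_model")
  }
  e <- function(y, q, imp) list(year = y, quarter = q,
                                model = fake_model(imp))
  # one model per quarter: heatmap equals the raw importances
  hm <- importance_heatmap(list(e(2021, "Q1", c(HP = 0.6, DA = 0.4))))
  expect_equal(hm$importance[hm$feature == "HP"], 0.6)
  # two years average cellwise
  hm <- importance_heatmap(list(
    e(2021, "Q1", c(HP = 0.2, DA = 0.8)),
    e(2022, "Q1", c(HP = 0.4, DA = 0.6))))
  expect_equal(hm$importance[hm$feature == "HP" & hm$quarter == "Q1"], 0.3)
  expect_equal(hm$n_models, c(2L, 2L))
  # a feature absent from one model averages over those that contain it
  hm <- importance_heatmap(list(
    e(2021, "Q2", c(HP = 0.5, DA = 0.5)),
    e(2022, "Q2", c(HP = 1.0))))
  expect_equal(hm$importance[hm$feature == "HP" & hm$quarter == "Q2"], 0.75)
  expect_equal(hm$n_models[hm$feature == "DA"], 1L)
  # mixed stages refuse to combine
  expect_error(importance_heatmap(list(
    e(2021, "Q1", c(HP = 1)),
    list(year = 2021, quarter = "Q1",
         model = fake_model(c(NDVI = 1), stage = 2L)))), "same stage")
  m <- importance_matrix(importance_heatmap(list(
    e(2021, "Q1", c(HP = 0.2, DA = 0.8)), e(2021, "Q2", c(HP = 0.7, DA = 0.3)))))
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(m["HP", "Q2"], 0.7)
})

test_that("prediction maps obey map algebra, per-wetland constancy, and masking", {
  study <- synth_study(small_spec(), seed = 51)
  comps <- study_composites(study)
  ft <- build_feature_table(study$samples, comps, study$wetlands,
                            study$climate)
  m <- fit_two_stage(ft, seed = 51)
  pm <- predict_map(m, comps[[1]], study$wetlands, study$climate)

  valid <- !pm$final_raw$mask
  expect_true(any(valid))
  resid <- pm$final_raw$values[valid] -
    (pm$baseline$values[valid] + pm$correction$values[valid])
  expect_lt(max(abs(resid)), 1e-9)

  # baseline constant within each wetland
  for (w in seq_len(nrow(study$wetlands))) {
    ctr <- cell_centers(pm$baseline$grid)
    px <- rep(ctr$x, each = pm$baseline$grid$n_rows)
    py <- rep(ctr$y, times = pm$baseline$grid$n_cols)
    nb <- length(unique(stats::na.omit(
      pm$baseline$values[matrix(wetstage:::points_in_ring(
        study$wetlands$polygon[[w]], px, py),
        pm$baseline$grid$n_rows)])))
    expect_equal(nb, 1L)
  }

  # pixels outside all polygons are nodata in every layer
  outside <- pm$final$mask[1, 1]
  expect_true(outside)
  expect_true(pm$baseline$mask[1, 1] && pm$correction$mask[1, 1])

  # a missing stage-2 band is reported by name
  broken <- comps[[1]]
  broken$bands$NDVI <- NULL
  expect_error(predict_map(m, broken, study$wetlands), "NDVI")
})
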