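#' Random-forest hyperparameters
#'
#' Defaults for both stages: 500 trees, `mtry = floor(p/3)` (the regression
#' convention), unlimited depth, minimum node size 1, impurity-based
#' importance (permutation available).
#'
#' @param num_trees Number of trees.
#' @param mtry Variables tried per split; `NULL` means `floor(p/3)` (at
#'   least 1).
#' @param min_node_size Minimum terminal node size.
#' @param importance `"impurity"` or `"permutation"`.
#' @return A list of class `rf_params`.
#' @export
rf_params <- function(num_trees = 500, mtry = NULL, min_node_size = 1,
                      importance = c("impurity", "permutation")) {
  structure(list(num_trees = num_trees, mtry = mtry,
                 min_node_size = min_node_size,
                 importance = match.arg(importance)),
            class = "rf_params")
}

#' Split a table into 70/30 train/test partitions
#'
#' Disjoint, exhaustive, seeded random partition with
#' `|train| = round(train_fraction * n)`. With `strata`, the split is drawn
#' independently within each stratum (rounded per stratum).
#'
#' @param table A data frame.
#' @param train_fraction Fraction assigned to training (default 0.70).
#' @param seed Integer seed; the same seed always yields the same partition.
#' @param strata Optional column name to stratify by.
#' @return A list with tibbles `train` and `test`.
#' @export
split_train_test <- function(table, train_fraction = 0.7, seed = 1L,
                             strata = NULL) {
  stopifnot(nrow(table) > 0, train_fraction > 0, train_fraction < 1)
  idx <- withr::with_seed(seed, {
    if (is.null(strata)) {
      sample.int(nrow(table), round(train_fraction * nrow(table)))
    } else {
      groups <- split(seq_len(nrow(table)), table[[strata]])
      unlist(lapply(groups, function(g) {
        g[sample.int(length(g), round(train_fraction * length(g)))]
      }), use.names = FALSE)
    }
  })
  list(train = tibble::as_tibble(table[sort(idx), , drop = FALSE]),
       test = tibble::as_tibble(table[setdiff(seq_len(nrow(table)), sort(idx)),
                                      , drop = FALSE]))
}

# shared single-stage fit on a feature block
fit_stage <- function(data, features, target, params, seed, stage) {
  if (length(features) == 0) stop("empty feature set", call. = FALSE)
  missing <- setdiff(features, names(data))
  if (length(missing) > 0) {
    stop(sprintf("stage %d features absent from table: %s", stage,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (nrow(data) < 2) {
    stop(sprintf("stage %d needs at least 2 training rows, got %d", stage,
                 nrow(data)), call. = FALSE)
  }
  y <- data[[target]]
  if (stats::sd(y) == 0) {
    warning(sprintf("stage %d target is constant; the fit is degenerate", stage),
            call. = FALSE)
  }
  df <- as.data.frame(data[, features, drop = FALSE])
  df$.target <- y
  p <- length(features)
  fit <- ranger::ranger(
    dependent.variable.name = ".target", data = df,
    num.trees = params$num_trees,
    mtry = params$mtry %||% max(1L, floor(p / 3)),
    min.node.size = params$min_node_size,
    importance = params$importance,
    seed = seed, num.threads = 1
  )
  imp_raw <- fit$variable.importance[features]
  imp_raw[is.na(imp_raw)] <- 0
  s <- sum(imp_raw)
  structure(list(model = fit, feature_names = features,
                 importance_raw = imp_raw,
                 importance = if (s > 0) imp_raw / s else imp_raw,
                 stage = stage, n_train = nrow(data), seed = seed,
                 params = params),
            class = "stage_model")
}

#' @export
print.stage_model <- function(x, ...) {
  top <- names(sort(x$importance, decreasing = TRUE))[seq_len(min(3, length(x$importance)))]
  cat(sprintf("<stage_model %d> %d features, n_train=%d; top importance: %s\n",
              x$stage, length(x$feature_names), x$n_train,
              paste(top, collapse = ", ")))
  invisible(x)
}

predict_stage <- function(object, newdata) {
  df <- as.data.frame(newdata[, object$feature_names, drop = FALSE])
  stats::predict(object$model, data = df, num.threads = 1)$predictions
}

#' Fit the stage-1 baseline model
#'
#' A random forest regressing observed concentration on the discrete
#' per-wetland predictors. Returns the fitted model together with the
#' per-row training residuals `observed - predicted` that stage 2 will
#' model. By default the stage-1 prediction used to form residuals is the
#' out-of-bag prediction for each training row (`residual_source = "oob"`):
#' in-sample random-forest predictions are nearly interpolating, which
#' would leave stage 2 a near-zero target; OOB predictions give residuals
#' on the same scale the model actually errs at. `"insample"` is available
#' for comparison.
#'
#' @param train Training feature table (see [build_feature_table()]).
#' @param features Discrete feature names (default [discrete_features()]
#'   intersected with the table).
#' @param target Target column (default `"concentration"`).
#' @param params [rf_params()].
#' @param seed Integer seed for the forest.
#' @param residual_source `"oob"` (default) or `"insample"`.
#' @return A list: `model` (a `stage_model`), `residuals` (numeric, one per
#'   training row).
#' @export
fit_stage1 <- function(train, features = NULL, target = "concentration",
                       params = rf_params(), seed = 1L,
                       residual_source = c("oob", "insample")) {
  residual_source <- match.arg(residual_source)
  features <- features %||% intersect(DISCRETE_FEATURES, names(train))
  m <- fit_stage(train, features, target, params, seed, stage = 1L)
  if (residual_source == "oob") {
    pred <- m$model$predictions
    # rows never out of bag (possible at tiny n) fall back to in-sample
    if (anyNA(pred)) {
      ins <- predict_stage(m, train)
      pred[is.na(pred)] <- ins[is.na(pred)]
    }
  } else {
    pred <- predict_stage(m, train)
  }
  list(model = m, residuals = train[[target]] - pred)
}

#' Fit the stage-2 residual model
#'
#' A second, independent random forest regressing the stage-1 training
#' residuals on the continuous satellite-derived predictors. Rows flagged
#' for incomplete continuous features are excluded from the fit.
#'
#' @param train Training feature table (same rows as passed to
#'   [fit_stage1()]).
#' @param residuals Stage-1 training residuals, aligned to `train` rows.
#' @param features Continuous feature names (default
#'   [continuous_features()] intersected with the table).
#' @param params [rf_params()].
#' @param seed Integer seed.
#' @return A `stage_model` (stage 2).
#' @export
fit_stage2 <- function(train, residuals, features = NULL,
                       params = rf_params(), seed = 1L) {
  stopifnot(length(residuals) == nrow(train))
  features <- features %||% intersect(CONTINUOUS_FEATURES, names(train))
  keep <- stats::complete.cases(train[, features, drop = FALSE])
  if ("flagged" %in% names(train)) keep <- keep & !train$flagged
  df <- train[keep, , drop = FALSE]
  df$.residual <- residuals[keep]
  fit_stage(df, features, ".residual", params, seed, stage = 2L)
}

#' Fit the full two-stage model on a feature table
#'
#' Convenience wrapper: 70/30 split, stage-1 baseline fit on discrete
#' features, stage-2 residual fit on continuous features, and a hold-out
#' [metrics_report()]. With `scope = "pooled"` (one model across quarters)
#' the quarter is one-hot encoded into the stage-1 feature block so the
#' baseline can carry seasonal level shifts.
#'
#' @param table Feature table from [build_feature_table()].
#' @param nutrient Optional filter on the table's `nutrient` column.
#' @param train_fraction,seed,strata Passed to [split_train_test()]; the
#'   same seed also seeds both forests.
#' @param params [rf_params()].
#' @param residual_source See [fit_stage1()].
#' @param scope `"pooled"` (default; quarter one-hots in stage 1) or
#'   `"single"` (no quarter encoding; use when fitting one quarter's rows).
#' @param clip_negative Clip negative final predictions to 0 (default
#'   `TRUE`).
#' @return An object of class `two_stage_model` with elements `stage1`,
#'   `stage2`, `metrics` (see [metrics_report()]), `split` (row ids),
#'   `nutrient`, and the configuration used.
#' @export
fit_two_stage <- function(table, nutrient = NULL, train_fraction = 0.7,
                          seed = 1L, strata = NULL, params = rf_params(),
                          residual_source = c("oob", "insample"),
                          scope = c("pooled", "single"),
                          clip_negative = TRUE) {
  residual_source <- match.arg(residual_source)
  scope <- match.arg(scope)
  if (!is.null(nutrient)) {
    table <- dplyr::filter(table, .data$nutrient == !!nutrient)
  }
  if (nrow(table) == 0) stop("no rows to fit", call. = FALSE)
  disc <- intersect(attr(table, "discrete_features") %||% DISCRETE_FEATURES,
                    names(table))
  cont <- intersect(attr(table, "continuous_features") %||% CONTINUOUS_FEATURES,
                    names(table))
  if (scope == "pooled" && "quarter" %in% names(table)) {
    for (q in paste0("Q", 1:4)) table[[q]] <- as.numeric(table$quarter == q)
    disc <- c(disc, paste0("Q", 1:4))
  }
  parts <- split_train_test(table, train_fraction, seed, strata)
  s1 <- fit_stage1(parts$train, disc, params = params, seed = seed,
                   residual_source = residual_source)
  s2 <- fit_stage2(parts$train, s1$residuals, cont, params = params,
                   seed = seed + 1L)
  model <- structure(
    list(stage1 = s1$model, stage2 = s2, nutrient = nutrient,
         discrete_features = disc, continuous_features = cont,
         residual_source = residual_source, scope = scope,
         clip_negative = clip_negative, seed = seed,
         split = list(train_ids = parts$train[["sample_id"]],
                      n_train = nrow(parts$train), n_test = nrow(parts$test),
                      train_fraction = train_fraction, strata = strata)),
    class = "two_stage_model")
  model$metrics <- metrics_report(model, parts$test)
  model
}

#' @export
print.two_stage_model <- function(x, ...) {
  cat(sprintf("<two_stage_model%s> n_train=%d, n_test=%d\n",
              if (!is.null(x$nutrient)) paste0(" ", x$nutrient) else "",
              x$split$n_train, x$split$n_test))
  if (!is.null(x$metrics)) print(x$metrics)
  invisible(x)
}

#' Predict concentrations for feature rows
#'
#' Final prediction = stage-1 baseline + stage-2 residual correction,
#' additive to machine precision. Rows whose continuous block is incomplete
#' fall back to the baseline alone (`provenance = "baseline_only"`).
#' Negative sums are clipped to 0 when the model was fitted with
#' `clip_negative = TRUE` (a warning reports how many); the unclipped value
#' is kept in `final_raw`.
#'
#' @param object A `two_stage_model`.
#' @param newdata Feature table rows.
#' @param ... Unused.
#' @return A tibble with `baseline`, `correction`, `final_raw`, `final`
#'   (mg/L) and `provenance`.
#' @export
predict.two_stage_model <- function(object, newdata, ...) {
  if (object$scope == "pooled" && !all(paste0("Q", 1:4) %in% names(newdata)) &&
      "quarter" %in% names(newdata)) {
    for (q in paste0("Q", 1:4)) newdata[[q]] <- as.numeric(newdata$quarter == q)
  }
  baseline <- predict_stage(object$stage1, newdata)
  complete <- stats::complete.cases(
    newdata[, object$continuous_features, drop = FALSE])
  correction <- rep(0, nrow(newdata))
  if (any(complete)) {
    correction[complete] <- predict_stage(object$stage2,
                                          newdata[complete, , drop = FALSE])
  }
  final_raw <- baseline + correction
  final <- final_raw
  if (isTRUE(object$clip_negative) && any(final < 0)) {
    warning(sprintf("%d negative prediction(s) clipped to 0", sum(final < 0)),
            call. = FALSE)
    final[final < 0] <- 0
  }
  tibble::tibble(baseline = baseline, correction = correction,
                 final_raw = final_raw, final = final,
                 provenance = ifelse(complete, "two_stage", "baseline_only"))
}

#' Hold-out validation metrics
#'
#' Computes, on paired predictions and observations, the coefficient of
#' determination `r2 = 1 - SS_res / SS_tot`, the root mean square error,
#' the mean absolute error, and the mean bias error `mean(pred - obs)`
#' (positive = systematic over-prediction). With zero-variance
#' observations r2 is undefined and reported as `NA`.
#'
#' @param predicted,observed Equal-length numeric vectors.
#' @return A one-row tibble: `r2`, `rmse`, `mae`, `mbe`, `n`.
#' @export
evaluate_predictions <- function(predicted, observed) {
  stopifnot(length(predicted) == length(observed), length(observed) > 0)
  e <- predicted - observed
  ss_tot <- sum((observed - mean(observed))^2)
  tibble::tibble(
    r2 = if (ss_tot == 0) NA_real_ else 1 - sum(e^2) / ss_tot,
    rmse = sqrt(mean(e^2)),
    mae = mean(abs(e)),
    mbe = mean(e),
    n = length(e)
  )
}

#' Stage-wise validation report
#'
#' Evaluates a fitted two-stage model on held-out rows at all three levels:
#' `stage1` compares the baseline prediction with observed concentrations;
#' `stage2` compares the residual model's prediction with the *realised*
#' test residuals `observed - baseline` (the residual scale); `final`
#' compares `baseline + correction` (pre-clipping) with observed
#' concentrations.
#'
#' @param model A `two_stage_model`.
#' @param test Held-out feature table rows.
#' @return A tibble with one row per stage (`stage` in
#'   `c("stage1", "stage2", "final")`) and columns `r2`, `rmse`, `mae`,
#'   `mbe`, `n`.
#' @export
metrics_report <- function(model, test) {
  pr <- suppressWarnings(predict(model, test))
  obs <- test$concentration
  realised_resid <- obs - pr$baseline
  dplyr::bind_rows(
    dplyr::mutate(evaluate_predictions(pr$baseline, obs), stage = "stage1"),
    dplyr::mutate(evaluate_predictions(pr$correction, realised_resid),
                  stage = "stage2"),
    dplyr::mutate(evaluate_predictions(pr$final_raw, obs), stage = "final")
  )[, c("stage", "r2", "rmse", "mae", "mbe", "n")]
}

# ---- spatial prediction ----------------------------------------------------

# vectorised even-odd (ray casting) point-in-polygon; boundary points count
# as inside
points_in_ring <- function(ring, x, y) {
  ring <- close_ring(ring)
  n <- nrow(ring) - 1L
  inside <- rep(FALSE, length(x))
  for (i in seq_len(n)) {
    x1 <- ring[i, 1]; y1 <- ring[i, 2]
    x2 <- ring[i + 1L, 1]; y2 <- ring[i + 1L, 2]
    crosses <- ((y1 > y) != (y2 > y)) &
      (x < (x2 - x1) * (y - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
  }
  inside
}

#' Per-pixel quarterly prediction map
#'
#' Applies a fitted two-stage model over a quarter composite: the stage-1
#' baseline layer is constant within each wetland polygon (its discrete
#' attributes plus the quarter's climate are per-wetland constants), the
#' stage-2 correction layer varies per pixel with the composite's
#' continuous predictors, and the final layer is their per-pixel sum (map
#' algebra). Pixels outside every wetland polygon are nodata in all layers.
#'
#' @param model A `two_stage_model`.
#' @param composite A [quarterly_composite()] result covering the wetlands.
#' @param wetlands Wetland tibble.
#' @param climate Optional daily climate tibble; when given, the per-wetland
#'   `AveRain`/`AveTemp` used for the baseline are the 7-day means averaged
#'   over the quarter (the quarter-mean climate state); otherwise the
#'   wetlands' static values are used.
#' @return An object of class `prediction_map`: the quarter key, and
#'   `raster_band`s `baseline`, `correction`, `final` (clipped according to
#'   the model) plus `final_raw` as a diagnostic layer.
#' @export
predict_map <- function(model, composite, wetlands, climate = NULL) {
  need <- setdiff(model$continuous_features, names(composite$bands))
  if (length(need) > 0) {
    stop(sprintf("composite %s lacks band(s) required by stage 2: %s",
                 composite$key, paste(need, collapse = ", ")), call. = FALSE)
  }
  g <- composite$bands[[1]]$grid
  ctr <- cell_centers(g)
  px <- rep(ctr$x, each = g$n_rows)
  py <- rep(ctr$y, times = g$n_cols)

  wid <- rep(NA_integer_, length(px))
  for (w in seq_len(nrow(wetlands))) {
    inside <- points_in_ring(wetlands$polygon[[w]], px, py)
    wid[inside & is.na(wid)] <- w
  }
  sel <- which(!is.na(wid))
  baseline <- matrix(NA_real_, g$n_rows, g$n_cols)
  correction <- matrix(NA_real_, g$n_rows, g$n_cols)

  if (length(sel) > 0) {
    # one baseline value per wetland: discrete attributes + quarter one-hot
    wdisc <- wetlands[, intersect(model$discrete_features, names(wetlands)),
                      drop = FALSE]
    if (!is.null(climate)) {
      q <- as.integer(sub("Q", "", composite$quarter))
      qdates <- seq(as.Date(sprintf("%d-%02d-01", composite$year,
                                    (q - 1) * 3 + 1)),
                    by = "day",
                    length.out = c(90, 91, 92, 92)[q])
      qdates <- qdates[assign_quarter(qdates)$key == composite$key]
      clim <- purrr::map_dfr(wetlands$wetland_id, function(id) {
        m <- climate_7day(climate, rep(id, length(qdates)), qdates)
        tibble::tibble(AveRain = mean(m$AveRain), AveTemp = mean(m$AveTemp))
      })
      wdisc$AveRain <- clim$AveRain
      wdisc$AveTemp <- clim$AveTemp
    }
    wdisc$quarter <- composite$quarter
    if (model$scope == "pooled") {
      for (qq in paste0("Q", 1:4)) {
        wdisc[[qq]] <- as.numeric(composite$quarter == qq)
      }
    }
    base_by_wetland <- predict_stage(model$stage1, wdisc)
    baseline[sel] <- base_by_wetland[wid[sel]]

    # per-pixel continuous block from the composite
    cont <- tibble::as_tibble(lapply(
      stats::setNames(model$continuous_features, model$continuous_features),
      function(nm) as.vector(composite$bands[[nm]]$values[sel])))
    ok <- stats::complete.cases(cont)
    corr <- rep(0, length(sel))
    if (any(ok)) {
      corr[ok] <- predict_stage(model$stage2, cont[ok, , drop = FALSE])
    }
    correction[sel] <- corr
  }

  final_raw <- baseline + correction
  final <- final_raw
  if (isTRUE(model$clip_negative)) final[final < 0] <- 0
  structure(list(
    year = composite$year, quarter = composite$quarter, key = composite$key,
    baseline = raster_band(g, "baseline", baseline, units = "mg_per_L"),
    correction = raster_band(g, "correction", correction, units = "mg_per_L"),
    final = raster_band(g, "final", final, units = "mg_per_L"),
    final_raw = raster_band(g, "final_raw", final_raw, units = "mg_per_L")
  ), class = "prediction_map")
}

#' @export
print.prediction_map <- function(x, ...) {
  v <- x$final$values[!x$final$mask]
  cat(sprintf("<prediction_map %s> %d wetland pixels, final range %.3f-%.3f mg/L\n",
              x$key, length(v), min(v), max(v)))
  invisible(x)
}

#' Write a prediction map's layers to a directory
#'
#' Serialises `baseline`, `correction`, `final` (and `final_raw`) as a
#' scene directory of ASCII grids named `map_<year>_<quarter>`.
#'
#' @param map A `prediction_map`.
#' @param dir Parent directory.
#' @return The map directory path, invisibly.
#' @export
write_prediction_map <- function(map, dir) {
  q <- as.integer(sub("Q", "", map$quarter))
  date <- as.Date(sprintf("%d-%02d-01", map$year, (q - 1) * 3 + 1))
  path <- file.path(dir, sprintf("map_%d_%s", map$year, map$quarter))
  sc <- scene_stack(date, list(baseline = map$baseline,
                               correction = map$correction,
                               final = map$final,
                               final_raw = map$final_raw),
                    sensor = "prediction")
  write_scene(sc, path)
  invisible(path)
}

# ---- variable importance ---------------------------------------------------

#' Quarter-averaged variable-importance heatmap
#'
#' Summarises the importance scores of several fitted stage models into a
#' features x quarters table: each cell is the mean importance of the
#' feature over the year-models fitted for that quarter (missing
#' year-models are simply absent from the mean; `n_models` records the
#' provenance). Ranks break ties by descending score then feature name.
#'
#' @param models A list of entries `list(year =, quarter =, model =)` where
#'   `model` is a `stage_model` (all of the same stage).
#' @return A tibble of class `importance_heatmap` with columns `feature`,
#'   `quarter`, `importance`, `n_models`; attribute `stage`.
#' @export
importance_heatmap <- function(models) {
  stopifnot(length(models) >= 1)
  stage <- unique(vapply(models, function(m) m$model$stage, integer(1)))
  if (length(stage) != 1) {
    stop("all models must belong to the same stage", call. = FALSE)
  }
  long <- purrr::map_dfr(models, function(m) {
    tibble::tibble(year = m$year, quarter = m$quarter,
                   feature = names(m$model$importance),
                   importance = unname(m$model$importance))
  })
  out <- long |>
    dplyr::group_by(.data$feature, .data$quarter) |>
    dplyr::summarise(importance = mean(.data$importance),
                     n_models = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$importance), .data$feature)
  attr(out, "stage") <- stage
  class(out) <- c("importance_heatmap", class(out))
  out
}

#' Importance heatmap as a features x quarters matrix
#'
#' @param heatmap An [importance_heatmap()] result.
#' @return A numeric matrix, rows = features (by mean importance,
#'   descending), columns = quarters present.
#' @export
importance_matrix <- function(heatmap) {
  wide <- tidyr::pivot_wider(heatmap[, c("feature", "quarter", "importance")],
                             names_from = "quarter",
                             values_from = "importance")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$feature
  ord <- order(-rowMeans(m, na.rm = TRUE), rownames(m))
  m[ord, sort(colnames(m)), drop = FALSE]
}
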