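#' Build a pipeline run configuration
#'
#' Collects every knob of the workflow in one validated list: input paths,
#' study scope, model options and the master seed. A deterministic hash of
#' the configuration is embedded in every output file so artifacts from
#' different configurations are distinguishable.
#'
#' @param wetlands,scenes,samples Paths to the wetlands GeoJSON, the
#'   directory of scene directories, and the samples CSV (required).
#' @param climate Optional daily climate CSV path.
#' @param output Run output directory.
#' @param nutrients Character vector, subset of `c("N", "P")`.
#' @param years,quarters Optional study-scope filters (integer years;
#'   quarters as `"Q1"`..`"Q4"`).
#' @param srvi_numerator,residual_source,clip_negative See [sar_indices()],
#'   [fit_stage1()], [fit_two_stage()].
#' @param scope `"per_quarter"` (one model per year-quarter where counts
#'   permit, with automatic pooled fallback) or `"pooled"`.
#' @param min_quarter_train Minimum training rows for a per-quarter model
#'   before falling back to pooled (default 20).
#' @param params [rf_params()].
#' @param train_fraction,seed,strata Split specification.
#' @return A list of class `run_config` with a `hash` field.
#' @export
run_config <- function(wetlands, scenes, samples, climate = NULL,
                       output = "wetstage_run",
                       nutrients = c("N", "P"), years = NULL, quarters = NULL,
                       srvi_numerator = "vv",
                       residual_source = "oob",
                       clip_negative = TRUE,
                       scope = c("per_quarter", "pooled"),
                       min_quarter_train = 20,
                       params = rf_params(),
                       train_fraction = 0.7, seed = 1L, strata = NULL) {
  cfg <- list(
    paths = list(wetlands = wetlands, scenes = scenes, samples = samples,
                 climate = climate, output = output),
    nutrients = nutrients, years = years, quarters = quarters,
    srvi_numerator = srvi_numerator, residual_source = residual_source,
    clip_negative = clip_negative, scope = match.arg(scope),
    min_quarter_train = min_quarter_train,
    params = unclass(params),
    train_fraction = train_fraction, seed = as.integer(seed), strata = strata
  )
  cfg$hash <- config_hash(cfg)
  structure(cfg, class = "run_config")
}

#' Deterministic configuration hash
#'
#' Order-independent hash over every analytical field of a [run_config()];
#' embedded in all pipeline outputs so artifacts from different
#' configurations are distinguishable. Recompute after mutating a config
#' by hand.
#'
#' @param cfg A `run_config` (the stored `hash` field is ignored).
#' @return A character scalar.
#' @export
config_hash <- function(cfg) {
  cfg$hash <- NULL
  canon <- function(x) {
    if (is.list(x)) {
      x <- x[order(names(x))]
      lapply(x, canon)
    } else x
  }
  rlang::hash(canon(unclass(cfg)))
}

#' Read / write a run configuration as YAML
#'
#' The configuration round-trips through serialization unchanged (the hash
#' is recomputed and verified on read).
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  # YAML 1.1 parses bare Y/N as booleans; in this domain they are nutrient
  # codes, so keep the single letters as strings and resolve real booleans
  keep_yn <- function(x) {
    if (x %in% c("y", "Y", "n", "N")) x else tolower(x) %in% c("true", "yes", "on")
  }
  y <- yaml::read_yaml(path, handlers = list("bool#yes" = keep_yn,
                                             "bool#no" = keep_yn))
  cfg <- do.call(run_config, c(
    y$paths,
    y[setdiff(names(y), c("paths", "hash", "params"))],
    if (!is.null(y$params)) list(params = do.call(rf_params, y$params))
  ))
  cfg
}

#' @rdname read_run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

validate_run_config <- function(cfg) {
  required <- c("wetlands", "scenes", "samples")
  for (p in required) {
    if (is.null(cfg$paths[[p]])) {
      stop(sprintf("config error: missing required path '%s'", p),
           call. = FALSE)
    }
    if (!file.exists(cfg$paths[[p]])) {
      stop(sprintf("config error: path '%s' does not exist: %s", p,
                   cfg$paths[[p]]), call. = FALSE)
    }
  }
  if (!is.null(cfg$paths$climate) && !file.exists(cfg$paths$climate)) {
    stop(sprintf("config error: climate path does not exist: %s",
                 cfg$paths$climate), call. = FALSE)
  }
  if (!all(cfg$nutrients %in% c("N", "P"))) {
    stop("config error: nutrients must be a subset of N, P", call. = FALSE)
  }
  invisible(cfg)
}

log_event <- function(con, stage, ...) {
  rec <- c(list(ts = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), stage = stage),
           list(...))
  writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
  message(sprintf("[wetstage] %s: %s", stage,
                  paste(sprintf("%s=%s", names(list(...)),
                                vapply(list(...), function(v)
                                  paste(format(v), collapse = ","),
                                  character(1))),
                        collapse = " ")))
}

#' Run the full two-stage mapping workflow
#'
#' Orchestrates: read inputs, convert SAR to linear power, quarterly
#' compositing, feature assembly, 70/30 split and two-stage fitting per
#' nutrient, hold-out metrics, per-pixel prediction maps, and
#' quarter-averaged importance heatmaps. Every output carries the config
#' hash; a JSON-lines event log records per-stage row counts and seeds.
#' Any stage failure aborts with the stage name in the message.
#'
#' @param config A [run_config()] (or path to its YAML).
#' @return Invisibly, a list with `metrics`, `models`, `maps`,
#'   `importance`, and the output directory. Side effects: writes
#'   `metrics.json`, `importance_stage1.csv`, `importance_stage2.csv`,
#'   map and composite directories, and `log.jsonl` under the output path.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  validate_run_config(config)
  out_dir <- config$paths$output
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logcon <- file(file.path(out_dir, "log.jsonl"), "w")
  on.exit(close(logcon))
  log_event(logcon, "start", config_hash = config$hash, seed = config$seed)

  step <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  wetlands <- step("read_wetlands", read_wetlands(config$paths$wetlands))
  samples <- step("read_samples", read_samples(config$paths$samples))
  climate <- if (!is.null(config$paths$climate)) {
    step("read_climate", read_climate(config$paths$climate))
  }
  scene_dirs <- list.dirs(config$paths$scenes, recursive = FALSE)
  scenes <- step("read_scenes", purrr::map(scene_dirs, read_scene))
  log_event(logcon, "inputs", n_wetlands = nrow(wetlands),
            n_samples = nrow(samples), n_scenes = length(scenes))

  # scope filters
  aq <- assign_quarter(samples$date)
  keep <- rep(TRUE, nrow(samples))
  if (!is.null(config$years)) keep <- keep & aq$year %in% config$years
  if (!is.null(config$quarters)) keep <- keep & aq$quarter %in% config$quarters
  samples <- samples[keep, , drop = FALSE]
  aq <- aq[keep, , drop = FALSE]
  qkeys <- sort(unique(aq$key))

  scenes <- step("sar_to_linear", purrr::map(scenes, function(s) {
    if (s$sensor != "S1") return(s)
    s$bands <- purrr::map(s$bands, function(b) {
      if (b$units == "dB") db_to_linear(b) else b
    })
    s
  }))

  composites <- step("composite", {
    cs <- purrr::map(qkeys, function(k) {
      y <- as.integer(sub("-Q.*", "", k))
      q <- sub("^.*-", "", k)
      quarterly_composite(scenes, y, q,
                          srvi_numerator = config$srvi_numerator)
    })
    names(cs) <- qkeys
    cs
  })
  for (comp in composites) write_composite(comp, file.path(out_dir, "composites"))
  log_event(logcon, "composite", quarters = qkeys)

  features <- step("features",
                   build_feature_table(samples, composites, wetlands, climate))
  write_feature_table(features, file.path(out_dir, "features.csv"))
  log_event(logcon, "features", n_rows = nrow(features),
            n_flagged = sum(features$flagged))

  results <- list()
  for (nut in config$nutrients) {
    tab <- dplyr::filter(features, .data$nutrient == nut)
    if (nrow(tab) == 0) next
    attr(tab, "discrete_features") <- attr(features, "discrete_features")
    attr(tab, "continuous_features") <- attr(features, "continuous_features")

    scope_used <- config$scope
    if (config$scope == "per_quarter") {
      per_q_n <- tab |>
        dplyr::count(.data$year, .data$quarter) |>
        dplyr::mutate(n_train = round(config$train_fraction * .data$n))
      if (any(per_q_n$n_train < config$min_quarter_train)) {
        scope_used <- "pooled"
        log_event(logcon, "scope_fallback", nutrient = nut,
                  reason = sprintf("min per-quarter training rows %d < %d",
                                   min(per_q_n$n_train),
                                   config$min_quarter_train))
      }
    }

    fit_one <- function(rows, scope) {
      fit_two_stage(rows, train_fraction = config$train_fraction,
                    seed = config$seed, strata = config$strata,
                    params = do.call(rf_params, config$params),
                    residual_source = config$residual_source,
                    scope = scope, clip_negative = config$clip_negative)
    }

    if (scope_used == "pooled") {
      model <- step(paste0("fit_", nut), fit_one(tab, "pooled"))
      models <- list(pooled = model)
      metrics <- dplyr::mutate(model$metrics, nutrient = nut,
                               model_scope = "pooled")
      model_for_key <- function(k) model
    } else {
      groups <- dplyr::group_split(dplyr::group_by(tab, .data$year,
                                                   .data$quarter))
      gkeys <- purrr::map_chr(groups, ~ sprintf("%d-%s", .x$year[1],
                                                .x$quarter[1]))
      models <- purrr::map(groups, function(gr) {
        gr <- tibble::as_tibble(gr)
        attr(gr, "discrete_features") <- attr(features, "discrete_features")
        attr(gr, "continuous_features") <- attr(features, "continuous_features")
        step(paste0("fit_", nut), fit_one(gr, "single"))
      })
      names(models) <- gkeys
      metrics <- purrr::map_dfr(gkeys, function(k) {
        dplyr::mutate(models[[k]]$metrics, nutrient = nut, model_scope = k)
      })
      model_for_key <- function(k) models[[k]]
    }
    log_event(logcon, "fit", nutrient = nut, scope = scope_used,
              n_models = length(models),
              n_train = sum(purrr::map_int(models, ~ .x$split$n_train)),
              n_test = sum(purrr::map_int(models, ~ .x$split$n_test)))

    # per-(year, quarter) importance analysis, averaged into the heatmaps
    imp <- step("importance", {
      groups <- dplyr::group_split(dplyr::group_by(tab, .data$year,
                                                   .data$quarter))
      entries1 <- list(); entries2 <- list()
      for (gr in groups) {
        gr <- tibble::as_tibble(gr)
        if (nrow(gr) < 10) next
        disc <- intersect(attr(features, "discrete_features"), names(gr))
        cont <- intersect(attr(features, "continuous_features"), names(gr))
        s1 <- fit_stage1(gr, disc, params = do.call(rf_params, config$params),
                         seed = config$seed,
                         residual_source = config$residual_source)
        s2 <- fit_stage2(gr, s1$residuals, cont,
                         params = do.call(rf_params, config$params),
                         seed = config$seed + 1L)
        e <- list(year = gr$year[1], quarter = gr$quarter[1])
        entries1 <- c(entries1, list(c(e, list(model = s1$model))))
        entries2 <- c(entries2, list(c(e, list(model = s2))))
      }
      list(stage1 = if (length(entries1)) importance_heatmap(entries1),
           stage2 = if (length(entries2)) importance_heatmap(entries2))
    })
    for (st in c("stage1", "stage2")) {
      if (!is.null(imp[[st]])) {
        hm <- dplyr::mutate(tibble::as_tibble(imp[[st]]),
                            config_hash = config$hash)
        readr::write_csv(hm, file.path(out_dir,
                                       sprintf("importance_%s_%s.csv", nut, st)))
      }
    }

    # prediction maps (pooled scope: one model over all quarters; per-quarter
    # scope: each quarter's model maps its own composite)
    maps <- step(paste0("map_", nut), {
      out <- purrr::map(qkeys, function(k) {
        m <- model_for_key(k)
        if (is.null(m)) return(NULL)
        pm <- predict_map(m, composites[[k]], wetlands, climate)
        write_prediction_map(pm, file.path(out_dir, "maps", nut))
        pm
      })
      stats::setNames(out, qkeys)
    })

    results[[nut]] <- list(models = models, metrics = metrics,
                           importance = imp, maps = maps,
                           scope_used = scope_used)
  }

  all_metrics <- purrr::map_dfr(results, "metrics")
  metrics_out <- list(
    config_hash = config$hash, seed = config$seed,
    residual_source = config$residual_source,
    stage2_scale = "residual model vs realized test residuals (observed - stage-1 baseline)",
    metrics = all_metrics
  )
  jsonlite::write_json(metrics_out, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       pretty = TRUE)
  log_event(logcon, "done", n_metrics_rows = nrow(all_metrics))
  invisible(c(results, list(output = out_dir, metrics = all_metrics,
                            config = config)))
}
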