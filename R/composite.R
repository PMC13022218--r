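#' Feature name sets
#'
#' The canonical ordered names of the stage-1 (discrete, per-wetland) and
#' stage-2 (continuous, per-pixel) predictors.
#'
#' @return A character vector of feature names.
#' @export
discrete_features <- function() DISCRETE_FEATURES

#' @rdname discrete_features
#' @export
continuous_features <- function() CONTINUOUS_FEATURES

#' Assign dates to calendar quarters
#'
#' Calendar-quarter mapping with half-open date ranges: Q1 is January 1
#' through March 31, Q2 April 1 through June 30, and so on.
#'
#' @param dates A `Date` vector (or coercible).
#' @return A tibble with integer `year`, character `quarter` (`"Q1"`..`"Q4"`)
#'   and a `key` label `"<year>-Q<q>"`.
#' @examples
#' assign_quarter(as.Date(c("2021-01-01", "2021-03-31", "2021-04-01")))
#' @export
assign_quarter <- function(dates) {
  dates <- as.Date(dates)
  y <- as.integer(format(dates, "%Y"))
  q <- (as.integer(format(dates, "%m")) - 1L) %/% 3L + 1L
  tibble::tibble(year = y, quarter = paste0("Q", q),
                 key = sprintf("%d-Q%d", y, q))
}

quarter_key <- function(year, quarter) {
  sprintf("%d-%s", as.integer(year), quarter)
}

# mask-aware mean of a list of raster_bands on one grid: sum of valid
# values over count of valid values; zero valid contributions -> nodata
composite_mean <- function(bands) {
  g <- bands[[1]]$grid
  acc <- matrix(0, g$n_rows, g$n_cols)
  cnt <- matrix(0L, g$n_rows, g$n_cols)
  for (b in bands) {
    stopifnot(grid_equal(b$grid, g))
    v <- b$values
    ok <- !b$mask
    v[!ok] <- 0
    acc <- acc + v
    cnt <- cnt + ok
  }
  out <- acc / cnt
  out[cnt == 0L] <- NA_real_
  raster_band(g, bands[[1]]$name, out, units = bands[[1]]$units)
}

#' Quarterly mean composite of scene stacks
#'
#' Averages, per pixel and per band, all scenes whose acquisition date falls
#' in the given calendar quarter, ignoring nodata cells (a pixel with zero
#' valid contributions is nodata). Derived variables are then computed
#' *from the composited bands* (mean-then-index): NDVI/NDWI/EVI from the
#' composited B8/B4/B3/B2, and the SAR ratios and SRVI from the composited
#' linear-power VV/VH. SAR scenes must already be on the linear power
#' scale (see [db_to_linear()]).
#'
#' @param scenes List of [scene_stack()]s (mixed sensors allowed); all on a
#'   common grid.
#' @param year,quarter Quarter selector, e.g. `2021, "Q1"`.
#' @param srvi_numerator Passed to [sar_indices()].
#' @return An object of class `quarter_composite`: fields `year`, `quarter`,
#'   `key`, `bands` (named list of `raster_band`s, spectral bands plus
#'   derived indices), and `n_scenes` (named count per sensor).
#' @export
quarterly_composite <- function(scenes, year, quarter,
                                srvi_numerator = c("vv", "vh")) {
  srvi_numerator <- match.arg(srvi_numerator)
  qk <- quarter_key(year, quarter)
  in_q <- vapply(scenes, function(s) {
    aq <- assign_quarter(s$date)
    aq$key == qk
  }, logical(1))
  sel <- scenes[in_q]
  if (length(sel) == 0) {
    stop(sprintf("no scenes fall in quarter %s", qk), call. = FALSE)
  }
  # group by band name across scenes
  band_names <- unique(unlist(lapply(sel, function(s) names(s$bands))))
  bands <- list()
  for (nm in band_names) {
    contrib <- purrr::compact(purrr::map(sel, ~ .x$bands[[nm]]))
    units <- unique(vapply(contrib, function(b) b$units, character(1)))
    if (length(units) != 1) {
      stop(sprintf("band '%s' appears with mixed units [%s]", nm,
                   paste(units, collapse = ", ")), call. = FALSE)
    }
    if (nm %in% c("VV", "VH") && units == "dB") {
      stop(sprintf("SAR band '%s' is in dB; convert with db_to_linear() before compositing",
                   nm), call. = FALSE)
    }
    bands[[nm]] <- composite_mean(contrib)
  }
  # derived indices from the composited bands
  if (all(c("B8", "B4") %in% names(bands))) {
    bands$NDVI <- ndvi(bands$B8, bands$B4)
  }
  if (all(c("B3", "B8") %in% names(bands))) {
    bands$NDWI <- ndwi(bands$B3, bands$B8)
  }
  if (all(c("B8", "B4", "B2") %in% names(bands))) {
    bands$EVI <- evi(bands$B8, bands$B4, bands$B2)
  }
  if (all(c("VV", "VH") %in% names(bands))) {
    sar <- sar_indices(bands$VV, bands$VH, srvi_numerator = srvi_numerator)
    bands$VV_VH <- sar$vv_vh_ratio
    bands$VH_VV <- sar$cross_ratio
    bands$SRVI <- sar$srvi
  }
  n_scenes <- table(vapply(sel, function(s) s$sensor, character(1)))
  structure(list(year = as.integer(year), quarter = quarter, key = qk,
                 bands = bands,
                 n_scenes = stats::setNames(as.integer(n_scenes),
                                            names(n_scenes))),
            class = "quarter_composite")
}

#' @export
print.quarter_composite <- function(x, ...) {
  cat(sprintf("<quarter_composite %s> %d bands (%s); scenes: %s\n", x$key,
              length(x$bands), paste(names(x$bands), collapse = ", "),
              paste(sprintf("%s=%d", names(x$n_scenes), x$n_scenes),
                    collapse = ", ")))
  invisible(x)
}

#' Write / read a quarter composite as a scene directory
#'
#' Serialises the composite's bands with [write_scene()] under the name
#' `composite_<year>_<quarter>`, dated at the quarter start.
#'
#' @param composite A `quarter_composite`.
#' @param dir Parent directory.
#' @return The composite directory path, invisibly.
#' @export
write_composite <- function(composite, dir) {
  q <- as.integer(sub("Q", "", composite$quarter))
  date <- as.Date(sprintf("%d-%02d-01", composite$year, (q - 1) * 3 + 1))
  path <- file.path(dir, sprintf("composite_%d_%s", composite$year,
                                 composite$quarter))
  sc <- scene_stack(date, composite$bands, sensor = "composite")
  write_scene(sc, path)
  invisible(path)
}

#' Assemble the per-sample model feature table
#'
#' Joins each water sample to (a) the discrete attributes of its wetland,
#' (b) the 7-day trailing climate means ending on its date (from `climate`
#' when given, else the wetland's static `AveRain`/`AveTemp`), and (c) the
#' continuous predictors point-sampled from its quarter's mean composite at
#' the sample coordinates. Rows whose continuous block contains any nodata
#' are flagged (`flagged = TRUE`), never silently dropped: flagged rows are
#' excluded from stage-2 fitting by default but still usable by stage 1.
#'
#' @param samples Sample tibble (see [read_samples()]).
#' @param composites Named list of [quarterly_composite()] results, keyed by
#'   `"<year>-Q<q>"`.
#' @param wetlands Wetland tibble (see [read_wetlands()]).
#' @param climate Optional daily climate tibble (see [read_climate()]).
#' @return A tibble, one row per sample, with id columns (`sample_id`,
#'   `wetland_id`, `station`, `date`, `year`, `quarter`), the discrete and
#'   continuous feature columns in canonical order, `concentration`
#'   (mg/L), and `flagged`. Attributes `discrete_features` and
#'   `continuous_features` record the feature ordering.
#' @export
build_feature_table <- function(samples, composites, wetlands, climate = NULL) {
  validate_samples(samples)
  aq <- assign_quarter(samples$date)
  missing_q <- setdiff(unique(aq$key), names(composites))
  if (length(missing_q) > 0) {
    stop(sprintf("no composite for quarter(s): %s",
                 paste(missing_q, collapse = ", ")), call. = FALSE)
  }
  missing_w <- setdiff(unique(samples$wetland_id), wetlands$wetland_id)
  if (length(missing_w) > 0) {
    stop(sprintf("no wetland unit for id(s): %s",
                 paste(missing_w, collapse = ", ")), call. = FALSE)
  }

  disc <- wetlands[match(samples$wetland_id, wetlands$wetland_id),
                   setdiff(DISCRETE_FEATURES, c("AveRain", "AveTemp"))]
  if (!is.null(climate)) {
    clim <- climate_7day(climate, samples$wetland_id, samples$date)
  } else {
    clim <- wetlands[match(samples$wetland_id, wetlands$wetland_id),
                     c("AveRain", "AveTemp")]
  }

  cont <- matrix(NA_real_, nrow(samples), length(CONTINUOUS_FEATURES),
                 dimnames = list(NULL, CONTINUOUS_FEATURES))
  for (k in unique(aq$key)) {
    idx <- which(aq$key == k)
    comp <- composites[[k]]
    for (nm in CONTINUOUS_FEATURES) {
      b <- comp$bands[[nm]]
      if (is.null(b)) next
      cont[idx, nm] <- point_sample(b, samples$x[idx], samples$y[idx])
    }
  }
  present <- CONTINUOUS_FEATURES[colSums(!is.na(cont)) > 0]
  cont <- cont[, present, drop = FALSE]

  out <- dplyr::bind_cols(
    tibble::tibble(sample_id = seq_len(nrow(samples)),
                   wetland_id = samples$wetland_id,
                   station = samples$station,
                   date = samples$date,
                   year = aq$year, quarter = aq$quarter,
                   nutrient = samples$nutrient),
    disc, clim,
    tibble::as_tibble(cont),
    tibble::tibble(concentration = samples$concentration_mg_L)
  )
  out$flagged <- rowSums(is.na(cont)) > 0
  out <- out[, c("sample_id", "wetland_id", "station", "date", "year",
                 "quarter", "nutrient", DISCRETE_FEATURES, present,
                 "concentration", "flagged")]
  attr(out, "discrete_features") <- DISCRETE_FEATURES
  attr(out, "continuous_features") <- present
  out
}

#' Serialise a feature table with its schema
#'
#' Writes the table to CSV plus a JSON sidecar (`<path>.schema.json`)
#' recording the discrete/continuous feature order and units.
#'
#' @param table Feature table from [build_feature_table()].
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  readr::write_csv(table, path)
  schema <- list(
    discrete_features = attr(table, "discrete_features"),
    continuous_features = attr(table, "continuous_features"),
    target = "concentration", target_units = "mg_per_L",
    climate_units = list(AveRain = "mm", AveTemp = "deg_F"),
    morphometric_units = list(Area = "km2", Perimeter = "km")
  )
  jsonlite::write_json(schema, paste0(path, ".schema.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
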