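# ---- ESRI ASCII grid -------------------------------------------------------
# One band per .asc file; georeferencing (lower-left corner, cell size,
# nodata sentinel) is carried in the 6-line header. Values are written in
# full double precision so write -> read round-trips to 1e-15 relative.

#' Write a raster band as an ESRI ASCII grid
#'
#' @param band A [raster_band()].
#' @param path Output file path (conventionally `.asc`).
#' @return `path`, invisibly.
#' @export
write_asc <- function(band, path) {
  stopifnot(inherits(band, "raster_band"))
  g <- band$grid
  v <- band$values
  v[band$mask] <- ASC_NODATA
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", g$n_cols),
    sprintf("nrows %d", g$n_rows),
    sprintf("xllcorner %.10g", g$origin_x),
    sprintf("yllcorner %.10g", g$origin_y - g$n_rows * g$pixel_size),
    sprintf("cellsize %.10g", g$pixel_size),
    sprintf("NODATA_value %d", ASC_NODATA)
  ), con)
  writeLines(apply(v, 1L, function(r) paste(sprintf("%.17g", r), collapse = " ")),
             con)
  invisible(path)
}

#' Read an ESRI ASCII grid as a raster band
#'
#' @param path File path.
#' @param name Band name to attach (default: file name without extension).
#' @param units Unit tag for the band (see [raster_band()]).
#' @param crs_label CRS label to attach (the `.asc` format does not carry
#'   one).
#' @return A [raster_band()].
#' @export
read_asc <- function(path, name = NULL, units = "index", crs_label = "local") {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  lines <- readLines(path)
  hdr <- list()
  for (i in 1:6) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop(sprintf("%s: malformed ASCII grid header", path), call. = FALSE)
  }
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  vals <- scan(text = lines[-(1:6)], what = double(), quiet = TRUE)
  if (length(vals) != nr * nc) {
    stop(sprintf("%s: expected %d values, found %d", path, nr * nc, length(vals)),
         call. = FALSE)
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else ASC_NODATA
  m[m == nodata] <- NA_real_
  g <- grid_spec(hdr$xllcorner, hdr$yllcorner + nr * hdr$cellsize,
                 hdr$cellsize, nr, nc, crs_label)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  raster_band(g, name, m, units = units)
}

# ---- scene stacks ----------------------------------------------------------
# A scene on disk is a directory holding one .asc per band plus scene.json
# (date, sensor, CRS label, per-band units) since the grid format itself
# carries neither time nor units.

#' Write a scene stack to a directory
#'
#' Writes one ASCII grid per band plus a `scene.json` manifest recording
#' date, sensor, CRS label, and per-band units.
#'
#' @param scene A [scene_stack()].
#' @param path Directory to create/fill.
#' @return `path`, invisibly.
#' @export
write_scene <- function(scene, path) {
  stopifnot(inherits(scene, "scene_stack"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    date = format(scene$date), sensor = scene$sensor,
    crs_label = scene$grid$crs_label,
    bands = purrr::map(scene$bands, function(b) {
      list(name = b$name, file = paste0(b$name, ".asc"), units = b$units)
    }) |> unname()
  )
  for (b in scene$bands) write_asc(b, file.path(path, paste0(b$name, ".asc")))
  jsonlite::write_json(manifest, file.path(path, "scene.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a scene stack from a directory
#'
#' @param path Scene directory written by [write_scene()].
#' @param band_names Optional character vector selecting (and ordering) the
#'   bands to load; requesting a band the scene does not have, or a count
#'   that disagrees with the manifest when all bands are requested, is a
#'   format error.
#' @return A [scene_stack()].
#' @export
read_scene <- function(path, band_names = NULL) {
  mf <- file.path(path, "scene.json")
  if (!file.exists(mf)) stop(sprintf("no scene manifest at %s", mf), call. = FALSE)
  manifest <- jsonlite::read_json(mf)
  have <- vapply(manifest$bands, function(b) b$name, character(1))
  if (is.null(band_names)) {
    band_names <- have
  } else if (!all(band_names %in% have)) {
    stop(sprintf("scene %s has bands [%s]; requested [%s]",
                 path, paste(have, collapse = ", "),
                 paste(band_names, collapse = ", ")), call. = FALSE)
  }
  bands <- purrr::map(band_names, function(nm) {
    info <- manifest$bands[[match(nm, have)]]
    read_asc(file.path(path, info$file), name = nm, units = info$units,
             crs_label = manifest$crs_label)
  })
  names(bands) <- band_names
  g <- bands[[1]]$grid
  if (!all(vapply(bands, function(b) grid_equal(b$grid, g), logical(1)))) {
    stop(sprintf("scene %s: bands are not on a uniform grid", path),
         call. = FALSE)
  }
  scene_stack(manifest$date, bands, sensor = manifest$sensor)
}

# ---- wetland polygons (GeoJSON) -------------------------------------------

#' Read wetland units from GeoJSON
#'
#' Expects a FeatureCollection of Polygon features whose properties carry
#' `wetland_id`, the land-use percentages (`OP`, `DA`, `BL`, `FO`, `SS`,
#' `HB`, `HP`, `CC`, `WW`, `EHW`), and optionally `ave_rain` (mm) /
#' `ave_temp` (deg F). Morphometrics (area, perimeter, SCI, PPS) are
#' recomputed from the ring coordinates via [morphometrics()].
#'
#' @param path GeoJSON file.
#' @return A tibble with one row per wetland: `wetland_id`, a `polygon`
#'   list-column (two-column coordinate matrix of the outer ring),
#'   `Area` (km2), `Perimeter` (km), `SCI`, `PPS`, the land-use percentage
#'   columns, `AveRain`, `AveTemp`.
#' @export
read_wetlands <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  gj <- jsonlite::read_json(path)
  if (!identical(gj$type, "FeatureCollection")) {
    stop(sprintf("%s: expected a GeoJSON FeatureCollection", path), call. = FALSE)
  }
  rows <- purrr::map(gj$features, function(f) {
    if (!identical(f$geometry$type, "Polygon")) {
      stop("only Polygon features are supported", call. = FALSE)
    }
    ring <- do.call(rbind, purrr::map(f$geometry$coordinates[[1]],
                                      ~ as.numeric(unlist(.x))))
    # GeoJSON rings repeat the first vertex; store the open ring
    if (nrow(ring) > 1 && all(ring[1, ] == ring[nrow(ring), ])) {
      ring <- ring[-nrow(ring), , drop = FALSE]
    }
    p <- f$properties
    lu <- purrr::map_dbl(LANDUSE_CLASSES, ~ as.numeric(p[[.x]] %||% 0))
    names(lu) <- LANDUSE_CLASSES
    mm <- morphometrics(ring)
    tibble::tibble(
      wetland_id = as.character(p$wetland_id),
      polygon = list(ring),
      Area = mm$area_km2, Perimeter = mm$perimeter_km,
      SCI = mm$sci, PPS = mm$pps,
      !!!as.list(lu),
      AveRain = as.numeric(p$ave_rain %||% NA_real_),
      AveTemp = as.numeric(p$ave_temp %||% NA_real_)
    )
  })
  out <- dplyr::bind_rows(rows)
  validate_wetlands(out)
  out
}

#' Write wetland units to GeoJSON
#'
#' @param wetlands Wetland tibble as returned by [read_wetlands()] or
#'   [generate_wetlands()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_wetlands <- function(wetlands, path) {
  feats <- purrr::pmap(wetlands, function(wetland_id, polygon, ...) {
    p <- list(...)
    props <- c(list(wetland_id = wetland_id),
               as.list(p[c(LANDUSE_CLASSES)]),
               list(area_km2 = p$Area, perimeter_km = p$Perimeter,
                    ave_rain = p$AveRain, ave_temp = p$AveTemp))
    ring <- rbind(polygon, polygon[1, , drop = FALSE])  # closed ring
    list(type = "Feature",
         properties = props,
         geometry = list(type = "Polygon",
                         coordinates = list(apply(ring, 1L, as.list,
                                                  simplify = FALSE))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

validate_wetlands <- function(w) {
  stopifnot(all(c("wetland_id", "polygon", "Area", "Perimeter",
                  LANDUSE_CLASSES) %in% names(w)))
  if (any(w$Area <= 0) || any(w$Perimeter <= 0)) {
    stop("wetland area and perimeter must be positive", call. = FALSE)
  }
  lu <- as.matrix(w[LANDUSE_CLASSES])
  if (any(lu < 0 | lu > 100)) {
    stop("land-use percentages must lie in [0, 100]", call. = FALSE)
  }
  s <- rowSums(lu)
  if (any(abs(s - 100) > 0.5)) {
    stop(sprintf("land-use percentages must sum to 100 +/- 0.5 (got %s)",
                 paste(sprintf("%.2f", s[abs(s - 100) > 0.5]), collapse = ", ")),
         call. = FALSE)
  }
  invisible(w)
}

# ---- sample and climate tables --------------------------------------------

#' Read water-sample records
#'
#' CSV with header
#' `wetland_id,station,x,y,date,nutrient,concentration_mg_L`; dates
#' ISO-8601; `station` one of inlet/middle/outlet; `nutrient` N or P.
#'
#' @param path CSV file.
#' @param study_window Optional length-2 `Date` vector; records outside it
#'   are an error.
#' @return A tibble of sample records.
#' @export
read_samples <- function(path, study_window = NULL) {
  s <- readr::read_csv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         wetland_id = readr::col_character(),
                         station = readr::col_character(),
                         x = readr::col_double(), y = readr::col_double(),
                         date = readr::col_date(),
                         nutrient = readr::col_character(),
                         concentration_mg_L = readr::col_double()))
  validate_samples(s, study_window)
  s
}

#' @rdname read_samples
#' @param samples Sample tibble.
#' @export
write_samples <- function(samples, path) {
  readr::write_csv(samples, path)
  invisible(path)
}

validate_samples <- function(s, study_window = NULL) {
  if (!all(s$station %in% c("inlet", "middle", "outlet"))) {
    stop("station must be one of inlet, middle, outlet", call. = FALSE)
  }
  if (!all(s$nutrient %in% c("N", "P"))) {
    stop("nutrient must be N or P", call. = FALSE)
  }
  if (any(s$concentration_mg_L < 0)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  if (!is.null(study_window) &&
      (any(s$date < study_window[1]) || any(s$date > study_window[2]))) {
    stop("sample dates fall outside the configured study window", call. = FALSE)
  }
  invisible(s)
}

#' Read a daily climate table
#'
#' CSV with header `wetland_id,date,rain_mm,temp_f`, one row per wetland per
#' day, used to derive the 7-day trailing mean rain/temperature features.
#'
#' @param path CSV file.
#' @return A tibble.
#' @export
read_climate <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    wetland_id = readr::col_character(),
                    date = readr::col_date(),
                    rain_mm = readr::col_double(),
                    temp_f = readr::col_double()))
}

#' 7-day trailing climate means
#'
#' For each requested (wetland, date) pair, the mean of daily rain and
#' temperature over the 7 days ending on (and including) the date,
#' matching the "average 7-day" definition of the AveRain / AveTemp
#' predictors.
#'
#' @param climate Daily climate tibble (see [read_climate()]).
#' @param wetland_id,dates Vectors of equal length.
#' @return A tibble with `AveRain` and `AveTemp` columns, one row per query.
#' @export
climate_7day <- function(climate, wetland_id, dates) {
  dates <- as.Date(dates)
  n <- max(length(wetland_id), length(dates))
  wetland_id <- rep_len(wetland_id, n)
  dates <- rep_len(dates, n)
  rain <- numeric(n)
  temp <- numeric(n)
  for (w in unique(wetland_id)) {
    cw <- climate[climate$wetland_id == w, ]
    cw <- cw[order(cw$date), ]
    idx <- which(wetland_id == w)
    daily <- nrow(cw) > 1 && all(diff(as.integer(cw$date)) == 1L)
    if (daily) {
      # contiguous daily series: trailing 7-day means via cumulative sums
      pos <- match(dates[idx], cw$date)
      if (anyNA(pos) || any(pos < 7L)) {
        stop(sprintf("climate series for wetland '%s' does not cover the 7 days ending %s",
                     w, format(dates[idx][which(is.na(pos) | pos < 7L)[1]])),
             call. = FALSE)
      }
      sr <- c(0, cumsum(cw$rain_mm))
      st <- c(0, cumsum(cw$temp_f))
      rain[idx] <- (sr[pos + 1L] - sr[pos - 6L]) / 7
      temp[idx] <- (st[pos + 1L] - st[pos - 6L]) / 7
    } else {
      for (i in idx) {
        win <- cw[cw$date > dates[i] - 7 & cw$date <= dates[i], ]
        if (nrow(win) == 0) {
          stop(sprintf("no climate records for wetland '%s' in the 7 days ending %s",
                       w, format(dates[i])), call. = FALSE)
        }
        rain[i] <- mean(win$rain_mm)
        temp[i] <- mean(win$temp_f)
      }
    }
  }
  tibble::tibble(AveRain = rain, AveTemp = temp)
}
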