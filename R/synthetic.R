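# ---- Gaussian random fields -----------------------------------------------

# smooth unit-variance random field via FFT convolution of white noise with
# a Gaussian kernel on the torus; range_px is the correlation length in
# pixels
grf <- function(n_rows, n_cols, range_px = 5) {
  grf_k(n_rows, n_cols, grf_kernel_fft(n_rows, n_cols, range_px))
}

# kernel transform, computed once per scene series
grf_kernel_fft <- function(n_rows, n_cols, range_px) {
  dr <- pmin(0:(n_rows - 1), n_rows - (0:(n_rows - 1)))
  dc <- pmin(0:(n_cols - 1), n_cols - (0:(n_cols - 1)))
  stats::fft(exp(-outer(dr^2, dc^2, `+`) / (2 * range_px^2)))
}

grf_k <- function(n_rows, n_cols, K) {
  wn <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  f <- Re(stats::fft(stats::fft(wn) * K, inverse = TRUE)) / (n_rows * n_cols)
  f / stats::sd(f)
}

# ---- generative specification ---------------------------------------------

#' Specification of a synthetic wetland nutrient study
#'
#' Defines the full generative model behind the synthetic inputs: study
#' layout (3 wetlands, 3 stations each, 36 monthly sampling dates over
#' 2021-2023, giving the 324 records of the emulated campaign), a 200 x 200
#' cell 10 m grid, and the known additive concentration model
#'
#' `conc = intercept + beta . discrete + gamma . continuous(pixel, month)
#'        + seasonal(quarter) + trend(year) + noise`, truncated at 0.
#'
#' The seasonal term is a quarter-phase sinusoid
#' `amplitude * cos(pi (q - 2.5) / 2)` peaking in Q2/Q3 (the summer-stress
#' pattern used for nitrogen); the phosphorus preset adds a linear annual
#' decline emulating multi-year recovery. Continuous predictor fields are
#' smooth Gaussian random fields (correlation length `correlation_length`
#' pixels) with per-quarter anomalies; month-to-month variation within a
#' quarter is a scene-wide scalar shift per band plus fine-grained pixel
#' noise, mimicking illumination/moisture differences between acquisitions.
#'
#' @param nutrient `"N"` (default) or `"P"`; selects preset coefficients.
#' @param n_wetlands Number of wetland units (default 3).
#' @param stations_per_wetland Stations per wetland (default 3:
#'   inlet/middle/outlet).
#' @param months Sampling dates, one per month (default the 15th of each
#'   month 2021-01 .. 2023-12).
#' @param grid [grid_spec()] of the scene rasters.
#' @param intercept Baseline concentration, mg/L.
#' @param beta_discrete Named numeric: coefficient per discrete feature
#'   (units: mg/L per feature unit).
#' @param gamma_continuous Named numeric: coefficient per continuous
#'   feature.
#' @param seasonal_amplitude Quarter sinusoid amplitude, mg/L.
#' @param annual_trend Linear trend, mg/L per year since the first study
#'   year.
#' @param noise_sd Observation noise standard deviation, mg/L.
#' @param correlation_length Field correlation length in pixels.
#' @param scene_noise_sd Per-pixel within-month noise added to every band.
#' @param landuse_preset `"bwg-like"` (urban 26.2 / crops 38.2 / forest
#'   14.7 with the hay/pasture share varying across wetlands) or
#'   `"independent"` (each wetland's land-use mix drawn independently; use
#'   when per-feature attribution across many wetlands is the point).
#' @return A list of class `generative_spec`.
#' @export
generative_spec <- function(nutrient = c("N", "P"),
                            n_wetlands = 3,
                            stations_per_wetland = 3,
                            months = seq(as.Date("2021-01-15"),
                                         by = "month", length.out = 36),
                            grid = grid_spec(0, 2000, 10, 200, 200,
                                             "synthetic-local"),
                            intercept = NULL,
                            beta_discrete = NULL,
                            gamma_continuous = NULL,
                            seasonal_amplitude = NULL,
                            annual_trend = NULL,
                            noise_sd = NULL,
                            correlation_length = 5,
                            scene_noise_sd = 0.003,
                            landuse_preset = c("bwg-like", "independent")) {
  nutrient <- match.arg(nutrient)
  landuse_preset <- match.arg(landuse_preset)
  preset <- if (nutrient == "N") {
    list(intercept = 0.3,
         beta_discrete = c(HP = 0.03, AveRain = 0.012, AveTemp = 0.004),
         gamma_continuous = c(NDVI = 1.2, VV_VH = 0.04),
         seasonal_amplitude = 0.4, annual_trend = 0, noise_sd = 0.05)
  } else {
    list(intercept = 0.28,
         beta_discrete = c(HP = 0.004, DA = 0.003, AveRain = 0.0008),
         gamma_continuous = c(NDVI = 0.03),
         seasonal_amplitude = 0.03, annual_trend = -0.05, noise_sd = 0.005)
  }
  spec <- list(
    nutrient = nutrient, n_wetlands = n_wetlands,
    stations_per_wetland = stations_per_wetland,
    months = as.Date(months), grid = grid,
    intercept = intercept %||% preset$intercept,
    beta_discrete = beta_discrete %||% preset$beta_discrete,
    gamma_continuous = gamma_continuous %||% preset$gamma_continuous,
    seasonal_amplitude = seasonal_amplitude %||% preset$seasonal_amplitude,
    annual_trend = annual_trend %||% preset$annual_trend,
    noise_sd = noise_sd %||% preset$noise_sd,
    correlation_length = correlation_length,
    scene_noise_sd = scene_noise_sd,
    landuse_preset = landuse_preset
  )
  stopifnot(spec$noise_sd >= 0,
            all(names(spec$beta_discrete) %in% DISCRETE_FEATURES),
            all(names(spec$gamma_continuous) %in% CONTINUOUS_FEATURES))
  structure(spec, class = "generative_spec")
}

seasonal_component <- function(amplitude, quarter_num) {
  amplitude * cospi((quarter_num - 2.5) / 2)
}

# ---- wetlands --------------------------------------------------------------

#' Generate synthetic wetland units
#'
#' Places `n_wetlands` star-shaped (hence simple, non-self-intersecting)
#' polygons along the grid diagonal, each a radially perturbed circle;
#' radii derive from the center spacing so the units never overlap, about
#' 0.2-0.25 km2 each on the default grid (small wetlands, well under
#' 1 km2 each). Morphometrics
#' are computed from the ring coordinates via [morphometrics()]. Land-use
#' percentages follow the spec's preset and sum to 100 exactly; under
#' `"bwg-like"` the developed / cultivated / forest shares stay within
#' about 2 points of 26.2 / 38.2 / 14.7 while the hay/pasture share spreads
#' across wetlands.
#'
#' @param spec A [generative_spec()].
#' @param seed Integer seed.
#' @return A wetland tibble (see [read_wetlands()] for columns).
#' @export
generate_wetlands <- function(spec, seed = 1L) {
  n <- spec$n_wetlands
  g <- spec$grid
  withr::with_seed(seed, {
    ext_x <- g$n_cols * g$pixel_size
    ext_y <- g$n_rows * g$pixel_size
    # centers along the grid diagonal, margin-safe for the largest radius
    t <- if (n > 1) (seq_len(n) - 1) / (n - 1) else 0.5
    cx <- g$origin_x + (0.21 + 0.58 * t) * ext_x
    cy <- g$origin_y - (0.79 - 0.58 * t) * ext_y
    # radii are derived from the center spacing (and the edge margin) so the
    # diagonal packing is disjoint by construction at any grid size or n;
    # on the default grid with n = 3 this gives ~0.2-0.25 km2 per wetland,
    # small units well under 1 km2
    spacing <- if (n > 1) {
      0.58 * sqrt(ext_x^2 + ext_y^2) / (n - 1)
    } else {
      0.8 * min(ext_x, ext_y)
    }
    r_max <- min(0.45 * spacing, 0.19 * min(ext_x, ext_y))
    r_base <- (r_max / 1.30) * seq(0.85, 1, length.out = n)
    area_targets <- pi * r_base^2
    rows <- vector("list", n)
    for (w in seq_len(n)) {
      R <- sqrt(area_targets[w] / pi)
      th <- seq(0, 2 * pi, length.out = 49)[-49]
      phi <- stats::runif(2, 0, 2 * pi)
      amp <- stats::runif(2, c(0.10, 0.02), c(0.22, 0.07))
      r <- R * (1 + amp[1] * sin(3 * th + phi[1]) + amp[2] * sin(7 * th + phi[2]))
      ring <- cbind(cx[w] + r * cos(th), cy[w] + r * sin(th))
      mm <- morphometrics(ring)
      lu <- generate_landuse(spec$landuse_preset, w, n)
      rows[[w]] <- tibble::tibble(
        wetland_id = sprintf("W%02d", w), polygon = list(ring),
        Area = mm$area_km2, Perimeter = mm$perimeter_km,
        SCI = mm$sci, PPS = mm$pps, !!!as.list(lu),
        AveRain = 3, AveTemp = 55
      )
    }
    out <- dplyr::bind_rows(rows)
    validate_wetlands(out)
    out
  })
}

# land-use mix for one wetland; always sums to exactly 100
generate_landuse <- function(preset, w, n) {
  if (preset == "bwg-like") {
    hp <- seq(5, 20, length.out = max(n, 2))[w]
    base <- c(DA = 26.2, CC = 38.2, FO = 14.7) + stats::runif(3, -2, 2)
    rest <- 100 - sum(base) - hp
    wts <- c(OP = 0.20, BL = 0.05, SS = 0.15, HB = 0.30, WW = 0.20, EHW = 0.10)
    other <- wts * rest
    lu <- c(base, HP = hp, other)
  } else {
    # independent mixes: every class, HP included, is drawn independently
    # of the wetland index (and hence of the size-ordered morphometrics),
    # with HP spanning a deliberately wide range so per-feature effects
    # are identifiable
    hp <- stats::runif(1, 2, 30)
    raw <- stats::rgamma(9, shape = 2)
    raw <- raw / sum(raw) * (100 - hp)
    lu <- c(stats::setNames(raw, c("OP", "DA", "BL", "FO", "SS", "HB",
                                   "CC", "WW", "EHW")), HP = hp)
  }
  lu <- pmax(lu, 0)
  lu <- lu / sum(lu) * 100
  lu[LANDUSE_CLASSES]
}

#' Station coordinates for each wetland
#'
#' Inlet, middle and outlet points placed on a seeded random axis through
#' the wetland centroid at -55%, 0 and +55% of the mean ring radius; the
#' star-polygon construction guarantees all three fall inside the ring.
#'
#' @param wetlands Wetland tibble from [generate_wetlands()].
#' @param seed Integer seed.
#' @return A tibble: `wetland_id`, `station`, `x`, `y`.
#' @export
station_points <- function(wetlands, seed = 1L) {
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(nrow(wetlands)), function(w) {
      ring <- wetlands$polygon[[w]]
      cx <- mean(ring[, 1]); cy <- mean(ring[, 2])
      R <- mean(sqrt((ring[, 1] - cx)^2 + (ring[, 2] - cy)^2))
      ang <- stats::runif(1, 0, 2 * pi)
      off <- c(-0.55, 0, 0.55) * R
      tibble::tibble(
        wetland_id = wetlands$wetland_id[w],
        station = c("inlet", "middle", "outlet"),
        x = cx + off * cos(ang), y = cy + off * sin(ang)
      )
    })
  })
}

# ---- climate ---------------------------------------------------------------

#' Generate a daily climate series per wetland
#'
#' Seasonal temperature sinusoid (deg F) and exponential daily rainfall
#' (mm) with a summer-peaking mean, plus small per-wetland offsets. The
#' series starts 30 days before the first sampling month so that 7-day
#' trailing means are always defined.
#'
#' @param spec A [generative_spec()].
#' @param seed Integer seed.
#' @return A tibble: `wetland_id`, `date`, `rain_mm`, `temp_f`.
#' @export
generate_climate <- function(spec, seed = 1L) {
  dates <- seq(min(spec$months) - 30, max(spec$months) + 16, by = "day")
  doy <- as.integer(format(dates, "%j"))
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(spec$n_wetlands), function(w) {
      toff <- stats::runif(1, -2, 2)
      temp <- 55 + toff + 22 * sin(2 * pi * (doy - 120) / 365) +
        stats::rnorm(length(dates), 0, 3)
      rain_mean <- pmax(0.5, 3 + 1.5 * sin(2 * pi * (doy - 150) / 365))
      rain <- stats::rexp(length(dates), rate = 1 / rain_mean)
      tibble::tibble(wetland_id = sprintf("W%02d", w), date = dates,
                     rain_mm = rain, temp_f = temp)
    })
  })
}

# ---- scenes ----------------------------------------------------------------

# per-band generative parameters: mean level, spatial field scale, coupling
# to the vegetation latent
S2_BAND_PARAMS <- data.frame(
  band = S2_BANDS,
  mean = c(0.05, 0.08, 0.10, 0.16, 0.22, 0.26, 0.30, 0.31, 0.20, 0.14),
  s    = c(0.010, 0.012, 0.015, 0.020, 0.025, 0.030, 0.030, 0.030, 0.030, 0.025),
  veg  = c(-0.004, 0.004, -0.025, 0.010, 0.020, 0.025, 0.060, 0.060, -0.020, -0.020)
)
S1_BAND_PARAMS <- data.frame(
  band = c("VV", "VH"),
  mean = c(-11, -18),
  s    = c(1.2, 1.2),
  veg  = c(-0.3, 0.3)
)

#' Generate monthly Sentinel-like scene stacks
#'
#' For every month in the spec, one optical stack (bands B2-B12, surface
#' reflectance in \[0, 1\]) dated the 10th and one SAR stack (VV, VH in dB,
#' VV above VH on average) dated the 12th, all on the common grid. Each
#' band is a smooth static Gaussian random field plus a per-quarter
#' anomaly field, a scene-wide monthly shift, fine pixel noise, and a
#' coupling to a shared "vegetation" latent whose seasonal cycle peaks in
#' Q2/Q3 — so NDVI and the SAR ratios vary coherently in space and season.
#'
#' @param spec A [generative_spec()].
#' @param seed Integer seed; the same seed reproduces the stacks
#'   bit-identically.
#' @return A list of [scene_stack()]s (alternating S2/S1 by month).
#' @export
generate_scene_series <- function(spec, seed = 1L) {
  g <- spec$grid
  nr <- g$n_rows; nc <- g$n_cols
  L <- spec$correlation_length
  month_start <- as.Date(format(spec$months, "%Y-%m-01"))
  qs <- assign_quarter(month_start)
  qkeys <- unique(qs$key)
  qnum <- as.integer(sub("^.*-Q", "", qs$key))

  K <- grf_kernel_fft(nr, nc, L)
  withr::with_seed(seed, {
    veg_static <- grf_k(nr, nc, K)
    veg_quarter <- lapply(qkeys, function(k) grf_k(nr, nc, K))
    names(veg_quarter) <- qkeys

    all_params <- rbind(S2_BAND_PARAMS, S1_BAND_PARAMS)
    static_f <- lapply(seq_len(nrow(all_params)), function(i) grf_k(nr, nc, K))
    quarter_f <- lapply(seq_len(nrow(all_params)), function(i) {
      f <- lapply(qkeys, function(k) grf_k(nr, nc, K))
      names(f) <- qkeys
      f
    })
    names(static_f) <- names(quarter_f) <- all_params$band

    scenes <- vector("list", 2L * length(spec$months))
    for (m in seq_along(spec$months)) {
      k <- qs$key[m]
      vseason <- 0.8 * c(-1, 0.8, 1, -0.6)[qnum[m]]
      veg <- 0.7 * veg_static + 0.35 * veg_quarter[[k]] + vseason
      make_band <- function(i, units) {
        p <- all_params[i, ]
        shift <- stats::rnorm(1, 0, if (units == "dB") 0.4 else 0.01)
        v <- p$mean + p$s * (0.8 * static_f[[p$band]] +
                               0.45 * quarter_f[[p$band]][[k]]) +
          p$veg * veg + shift +
          stats::rnorm(nr * nc, 0,
                       spec$scene_noise_sd * (if (units == "dB") 40 else 1))
        if (units == "reflectance") v <- pmin(pmax(v, 0.005), 0.995)
        raster_band(g, p$band, matrix(v, nr, nc), units = units)
      }
      s2_bands <- lapply(seq_len(nrow(S2_BAND_PARAMS)), make_band,
                         units = "reflectance")
      names(s2_bands) <- S2_BAND_PARAMS$band
      s1_bands <- lapply(nrow(S2_BAND_PARAMS) + seq_len(2), make_band,
                         units = "dB")
      names(s1_bands) <- S1_BAND_PARAMS$band
      scenes[[2L * m - 1L]] <- scene_stack(month_start[m] + 9, s2_bands, "S2")
      scenes[[2L * m]] <- scene_stack(month_start[m] + 11, s1_bands, "S1")
    }
    scenes
  })
}

# full continuous feature block at map points for one month's pair of
# scenes (SAR converted to linear power); mirrors the quarterly-composite
# derived-variable definitions at scene level
continuous_at_points <- function(s2, s1, x, y) {
  b <- vapply(S2_BANDS, function(nm) point_sample(s2$bands[[nm]], x, y),
              numeric(length(x)))
  b <- matrix(b, nrow = length(x), dimnames = list(NULL, S2_BANDS))
  vv <- 10^(point_sample(s1$bands$VV, x, y) / 10)
  vh <- 10^(point_sample(s1$bands$VH, x, y) / 10)
  cbind(b,
        NDVI = (b[, "B8"] - b[, "B4"]) / (b[, "B8"] + b[, "B4"]),
        NDWI = (b[, "B3"] - b[, "B8"]) / (b[, "B3"] + b[, "B8"]),
        EVI = 2.5 * (b[, "B8"] - b[, "B4"]) /
          (b[, "B8"] + 6 * b[, "B4"] - 7.5 * b[, "B2"] + 1),
        VV = vv, VH = vh, VV_VH = vv / vh, VH_VV = vh / vv,
        SRVI = 4 * vv / (vv + vh))
}

# ---- samples ---------------------------------------------------------------

#' Generate water-sample records with known decomposition
#'
#' One record per station per month (default layout: 3 wetlands x 3
#' stations x 36 months = 324 records). The concentration of each sample
#' is the additive generative model of the spec evaluated at the sample's
#' wetland, pixel and date, truncated at 0; every component is stored in
#' the returned truth table so recovery can be tested exactly.
#'
#' @param spec A [generative_spec()].
#' @param wetlands From [generate_wetlands()].
#' @param scenes From [generate_scene_series()].
#' @param climate From [generate_climate()].
#' @param seed Integer seed (noise and station placement).
#' @return A list: `samples` (the record tibble of [read_samples()] form),
#'   `truth` (per-sample decomposition: `baseline_component`,
#'   `continuous_component`, `seasonal_component`, `trend_component`,
#'   `noise`, `truncated`), and `stations`. The truncation rate is recorded
#'   as attribute `truncation_rate` on `truth`.
#' @export
generate_samples <- function(spec, wetlands, scenes, climate, seed = 1L) {
  stations <- station_points(wetlands, seed = seed)
  dates <- spec$months
  s2_by_month <- list(); s1_by_month <- list()
  for (s in scenes) {
    k <- format(s$date, "%Y-%m")
    if (s$sensor == "S2") s2_by_month[[k]] <- s else s1_by_month[[k]] <- s
  }
  grid_rows <- tidyr::expand_grid(si = seq_len(nrow(stations)),
                                  date = dates)
  n <- nrow(grid_rows)
  wid <- stations$wetland_id[grid_rows$si]
  clim <- climate_7day(climate, wid, grid_rows$date)
  aq <- assign_quarter(grid_rows$date)
  y0 <- min(aq$year)

  noise <- withr::with_seed(seed + 1L, stats::rnorm(n, 0, spec$noise_sd))

  base_disc <- wetlands[match(wid, wetlands$wetland_id),
                        setdiff(DISCRETE_FEATURES, c("AveRain", "AveTemp"))]
  base_disc$AveRain <- clim$AveRain
  base_disc$AveTemp <- clim$AveTemp
  bnames <- names(spec$beta_discrete)
  baseline <- spec$intercept +
    as.matrix(base_disc[, bnames, drop = FALSE]) %*% spec$beta_discrete

  cont <- numeric(n)
  gnames <- names(spec$gamma_continuous)
  mks <- format(grid_rows$date, "%Y-%m")
  for (mk in unique(mks)) {
    idx <- which(mks == mk)
    feats <- continuous_at_points(s2_by_month[[mk]], s1_by_month[[mk]],
                                  stations$x[grid_rows$si[idx]],
                                  stations$y[grid_rows$si[idx]])
    cont[idx] <- as.vector(feats[, gnames, drop = FALSE] %*%
                             spec$gamma_continuous)
  }

  seas <- seasonal_component(spec$seasonal_amplitude,
                             as.integer(sub("Q", "", aq$quarter)))
  trend <- spec$annual_trend * (aq$year - y0)
  raw <- as.vector(baseline) + cont + seas + trend + noise
  conc <- pmax(raw, 0)

  samples <- tibble::tibble(
    wetland_id = wid,
    station = stations$station[grid_rows$si],
    x = stations$x[grid_rows$si], y = stations$y[grid_rows$si],
    date = grid_rows$date,
    nutrient = spec$nutrient,
    concentration_mg_L = conc
  )
  truth <- tibble::tibble(
    wetland_id = wid, station = samples$station, date = samples$date,
    baseline_component = as.vector(baseline),
    continuous_component = cont,
    seasonal_component = seas,
    trend_component = trend,
    noise = noise,
    concentration = conc,
    truncated = raw < 0
  )
  attr(truth, "truncation_rate") <- mean(truth$truncated)
  list(samples = samples, truth = truth, stations = stations)
}

#' Latent per-pixel residual field for a quarter
#'
#' The gamma-weighted continuous component of the generative model,
#' evaluated per pixel from the quarter's mean composite — the spatial
#' signal stage 2 is supposed to recover.
#'
#' @param spec A [generative_spec()].
#' @param composite A [quarterly_composite()] of the spec's scenes for one
#'   quarter.
#' @return A `raster_band` named `"latent_residual"`.
#' @export
synthetic_residual_field <- function(spec, composite) {
  g <- composite$bands[[1]]$grid
  acc <- matrix(0, g$n_rows, g$n_cols)
  for (nm in names(spec$gamma_continuous)) {
    b <- composite$bands[[nm]]
    if (is.null(b)) stop(sprintf("composite lacks band '%s'", nm), call. = FALSE)
    acc <- acc + spec$gamma_continuous[[nm]] * b$values
  }
  raster_band(g, "latent_residual", acc, units = "mg_per_L")
}

#' Generate a complete synthetic study
#'
#' Wetlands, stations, daily climate, monthly scene series, and sample
#' records with their truth decomposition, all from one master seed
#' (sub-seeds are derived deterministically).
#'
#' @param spec A [generative_spec()].
#' @param seed Master integer seed.
#' @return A list: `spec`, `wetlands`, `climate`, `scenes`, `samples`,
#'   `truth`, `stations`.
#' @export
synth_study <- function(spec = generative_spec(), seed = 1L) {
  wetlands <- generate_wetlands(spec, seed = seed)
  climate <- generate_climate(spec, seed = seed + 101L)
  scenes <- generate_scene_series(spec, seed = seed + 202L)
  gs <- generate_samples(spec, wetlands, scenes, climate, seed = seed + 303L)
  list(spec = spec, wetlands = wetlands, climate = climate, scenes = scenes,
       samples = gs$samples, truth = gs$truth, stations = gs$stations)
}

#' Write a synthetic study to disk
#'
#' GeoJSON wetlands, per-month scene directories, samples and climate CSVs,
#' and `truth.json` (the per-sample decomposition plus the truncation
#' rate).
#'
#' @param study From [synth_study()].
#' @param dir Output directory (created).
#' @return `dir`, invisibly.
#' @export
write_synth_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_wetlands(study$wetlands, file.path(dir, "wetlands.geojson"))
  write_samples(study$samples, file.path(dir, "samples.csv"))
  readr::write_csv(study$climate, file.path(dir, "climate.csv"))
  scene_dir <- file.path(dir, "scenes")
  for (s in study$scenes) {
    write_scene(s, file.path(scene_dir,
                             sprintf("%s_%s", tolower(s$sensor),
                                     format(s$date))))
  }
  jsonlite::write_json(
    list(truncation_rate = attr(study$truth, "truncation_rate"),
         samples = study$truth),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  invisible(dir)
}
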