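# shared fixtures and independent oracles, all built in code

tiny_grid <- function(nr = 4, nc = 4, px = 10, crs = "test") {
  grid_spec(0, nr * px, px, nr, nc, crs)
}

const_band <- function(value, nr = 4, nc = 4, name = "B4",
                       units = "reflectance", px = 10) {
  raster_band(tiny_grid(nr, nc, px), name, matrix(value, nr, nc),
              units = units)
}

# a small study sized for unit tests: 48x48 cells at 10 m, 6 monthly dates
small_spec <- function(...) {
  generative_spec(
    months = seq(as.Date("2021-01-15"), by = "month", length.out = 6),
    grid = grid_spec(0, 480, 10, 48, 48, "synthetic-local"),
    ...
  )
}

# prepare composites keyed by quarter from a study's scenes (SAR -> linear)
study_composites <- function(study) {
  scn <- lapply(study$scenes, function(s) {
    if (s$sensor == "S1") s$bands <- lapply(s$bands, db_to_linear)
    s
  })
  keys <- sort(unique(assign_quarter(study$samples$date)$key))
  comps <- lapply(keys, function(k) {
    quarterly_composite(scn, as.integer(sub("-Q.*", "", k)), sub(".*-", "", k))
  })
  names(comps) <- keys
  comps
}

# naive loop implementations of the validation metrics, kept deliberately
# independent of evaluate_predictions()
oracle_metrics <- function(pred, obs) {
  n <- length(pred)
  se <- 0; ae <- 0; be <- 0
  for (i in seq_len(n)) {
    e <- pred[i] - obs[i]
    se <- se + e^2
    ae <- ae + abs(e)
    be <- be + e
  }
  mo <- sum(obs) / n
  sst <- 0
  for (i in seq_len(n)) sst <- sst + (obs[i] - mo)^2
  list(r2 = if (sst == 0) NA_real_ else 1 - se / sst,
       rmse = sqrt(se / n), mae = ae / n, mbe = be / n)
}

# loop oracle for the masked per-pixel mean of a list of raster bands
oracle_masked_mean <- function(bands) {
  g <- bands[[1]]$grid
  out <- matrix(NA_real_, g$n_rows, g$n_cols)
  for (r in seq_len(g$n_rows)) {
    for (c in seq_len(g$n_cols)) {
      vals <- c()
      for (b in bands) {
        if (!b$mask[r, c]) vals <- c(vals, b$values[r, c])
      }
      if (length(vals) > 0) out[r, c] <- sum(vals) / length(vals)
    }
  }
  out
}

# brute-force containment oracle: scan all cells for the one whose
# half-open extent ([left, right) x (bottom, top]) contains the point
oracle_cell_of <- function(grid, x, y) {
  for (r in seq_len(grid$n_rows)) {
    for (c in seq_len(grid$n_cols)) {
      left <- grid$origin_x + (c - 1) * grid$pixel_size
      top <- grid$origin_y - (r - 1) * grid$pixel_size
      if (x >= left && x < left + grid$pixel_size &&
          y <= top && y > top - grid$pixel_size) {
        return(c(r, c))
      }
    }
  }
  c(NA_integer_, NA_integer_)
}

regular_ngon <- function(n, radius = 1000) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(radius * cos(th), radius * sin(th))
}
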