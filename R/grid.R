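#' Define a common raster grid
#'
#' All rasters in a study share one `grid_spec`: an axis-aligned grid of
#' square cells anchored at the map coordinates of its upper-left corner.
#' The default ground sampling distance is 10 m, the grid every band is
#' aligned to before modelling.
#'
#' Coordinate convention (pixel registration): `origin_x`, `origin_y` are the
#' coordinates of the outer corner of cell (row 1, col 1). A map point (x, y)
#' falls in column `1 + floor((x - origin_x) / pixel_size)` and row
#' `1 + floor((origin_y - y) / pixel_size)`; cells are half-open, covering
#' `[left, right)` in x and `(bottom, top]` in y, so every in-extent point
#' belongs to exactly one cell. Cell centers are at
#' `origin_x + (col - 0.5) * pixel_size`, `origin_y - (row - 0.5) * pixel_size`.
#'
#' @param origin_x,origin_y Map coordinates of the grid's upper-left corner.
#' @param pixel_size Cell edge length in map units (metres); must be > 0.
#' @param n_rows,n_cols Positive integer grid dimensions.
#' @param crs_label Opaque identifier for the shared coordinate reference
#'   system. No reprojection is performed; all inputs must carry the same
#'   label.
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec(0, 2000, 10, 200, 200)
#' cell_at(g, 5, 1995) # row 1, col 1
#' @export
grid_spec <- function(origin_x, origin_y, pixel_size = 10, n_rows, n_cols,
                      crs_label = "local") {
  stopifnot(is.numeric(origin_x), is.numeric(origin_y), length(origin_x) == 1L,
            length(origin_y) == 1L)
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0) {
    stop("`pixel_size` must be a single positive number", call. = FALSE)
  }
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  if (is.na(n_rows) || is.na(n_cols) || n_rows < 1L || n_cols < 1L) {
    stop("`n_rows` and `n_cols` must be positive integers", call. = FALSE)
  }
  structure(
    list(origin_x = as.numeric(origin_x), origin_y = as.numeric(origin_y),
         pixel_size = as.numeric(pixel_size),
         n_rows = n_rows, n_cols = n_cols,
         crs_label = as.character(crs_label)),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d @ %g m, origin (%g, %g), crs '%s'\n",
              x$n_rows, x$n_cols, x$pixel_size, x$origin_x, x$origin_y,
              x$crs_label))
  invisible(x)
}

#' Test two grids for equality
#'
#' Grids compare equal iff every field (origin, pixel size, dimensions, CRS
#' label) is equal.
#'
#' @param a,b `grid_spec` objects.
#' @return `TRUE` or `FALSE`.
#' @export
grid_equal <- function(a, b) {
  stopifnot(inherits(a, "grid_spec"), inherits(b, "grid_spec"))
  isTRUE(a$origin_x == b$origin_x) && isTRUE(a$origin_y == b$origin_y) &&
    isTRUE(a$pixel_size == b$pixel_size) && a$n_rows == b$n_rows &&
    a$n_cols == b$n_cols && a$crs_label == b$crs_label
}

#' Map coordinates to grid cells
#'
#' Vectorised half-open cell containment (see [grid_spec()] for the
#' convention). Points outside the grid extent yield `NA` row/col.
#'
#' @param grid A `grid_spec`.
#' @param x,y Numeric vectors of map coordinates (recycled to a common
#'   length).
#' @return A tibble with integer columns `row`, `col` (`NA` outside the
#'   extent).
#' @export
cell_at <- function(grid, x, y) {
  stopifnot(inherits(grid, "grid_spec"))
  n <- max(length(x), length(y))
  x <- rep_len(as.numeric(x), n)
  y <- rep_len(as.numeric(y), n)
  col <- 1L + as.integer(floor((x - grid$origin_x) / grid$pixel_size))
  # y half-open (bottom, top]: row r covers (origin_y - r*px, origin_y - (r-1)*px]
  row <- 1L + as.integer(floor((grid$origin_y - y) / grid$pixel_size))
  bad <- col < 1L | col > grid$n_cols | row < 1L | row > grid$n_rows
  row[bad] <- NA_integer_
  col[bad] <- NA_integer_
  tibble::tibble(row = row, col = col)
}

#' Cell-center coordinates of a grid
#'
#' @param grid A `grid_spec`.
#' @return A list with `x` (length `n_cols`) and `y` (length `n_rows`)
#'   center coordinate vectors.
#' @export
cell_centers <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  list(
    x = grid$origin_x + (seq_len(grid$n_cols) - 0.5) * grid$pixel_size,
    y = grid$origin_y - (seq_len(grid$n_rows) - 0.5) * grid$pixel_size
  )
}

#' A single raster band on a grid
#'
#' Pairs an `n_rows x n_cols` numeric matrix with its [grid_spec()], a band
#' name, a unit tag, and an explicit nodata mask (no magic values). Cells
#' where `mask` is `TRUE` are nodata and their stored value is `NA`.
#'
#' @param grid A `grid_spec`.
#' @param name Band identifier, e.g. `"B4"` or `"VV"`.
#' @param values Numeric matrix of dimension `n_rows x n_cols`. Non-finite
#'   entries are treated as nodata.
#' @param mask Optional logical matrix of the same shape; `TRUE` marks
#'   nodata. Merged with non-finite `values`.
#' @param units One of `"reflectance"`, `"dB"`, `"linear_power"`, `"index"`,
#'   `"mg_per_L"`.
#' @return An object of class `raster_band`.
#' @export
raster_band <- function(grid, name, values, mask = NULL,
                        units = c("reflectance", "dB", "linear_power",
                                  "index", "mg_per_L")) {
  stopifnot(inherits(grid, "grid_spec"))
  units <- match.arg(units)
  values <- as.matrix(values)
  if (!all(dim(values) == c(grid$n_rows, grid$n_cols))) {
    stop(sprintf("band '%s': values are %d x %d but grid is %d x %d",
                 name, nrow(values), ncol(values), grid$n_rows, grid$n_cols),
         call. = FALSE)
  }
  storage.mode(values) <- "double"
  m <- !is.finite(values)
  if (!is.null(mask)) {
    mask <- as.matrix(mask)
    stopifnot(is.logical(mask), all(dim(mask) == dim(values)))
    m <- m | mask
  }
  values[m] <- NA_real_
  structure(list(grid = grid, name = as.character(name), values = values,
                 mask = m, units = units),
            class = "raster_band")
}

#' @export
print.raster_band <- function(x, ...) {
  cat(sprintf("<raster_band '%s'> %d x %d [%s], %d nodata cells\n",
              x$name, x$grid$n_rows, x$grid$n_cols, x$units, sum(x$mask)))
  invisible(x)
}

#' A dated stack of co-registered bands
#'
#' @param date Acquisition date (`Date` or ISO-8601 string).
#' @param bands Named list of [raster_band()] objects sharing one grid.
#' @param sensor Sensor tag, e.g. `"S2"` (optical) or `"S1"` (SAR).
#' @return An object of class `scene_stack`.
#' @export
scene_stack <- function(date, bands, sensor = "S2") {
  date <- as.Date(date)
  stopifnot(length(date) == 1L, !is.na(date), is.list(bands), length(bands) >= 1L)
  if (is.null(names(bands)) || any(names(bands) == "")) {
    names(bands) <- vapply(bands, function(b) b$name, character(1))
  }
  g <- bands[[1]]$grid
  ok <- vapply(bands, function(b) inherits(b, "raster_band") && grid_equal(b$grid, g),
               logical(1))
  if (!all(ok)) stop("all bands in a scene must share one grid_spec", call. = FALSE)
  structure(list(date = date, sensor = sensor, bands = bands, grid = g),
            class = "scene_stack")
}

#' @export
print.scene_stack <- function(x, ...) {
  cat(sprintf("<scene_stack %s/%s> bands: %s\n", x$sensor,
              format(x$date), paste(names(x$bands), collapse = ", ")))
  invisible(x)
}

#' Sample a band at map coordinates
#'
#' Returns the value of the cell containing each point under the pixel
#' registration documented in [grid_spec()]. Nodata cells yield `NA`.
#'
#' @param band A [raster_band()].
#' @param x,y Map coordinate vectors.
#' @return Numeric vector of sampled values (`NA` at nodata cells).
#' @export
point_sample <- function(band, x, y) {
  stopifnot(inherits(band, "raster_band"))
  rc <- cell_at(band$grid, x, y)
  if (anyNA(rc$row)) {
    i <- which(is.na(rc$row))[1]
    stop(sprintf("point (%g, %g) is outside the grid extent", x[i], y[i]),
         call. = FALSE)
  }
  band$values[cbind(rc$row, rc$col)]
}

#' Resample a band onto a target grid
#'
#' Aligns a band to a common grid, e.g. 20 m SAR bands onto the 10 m optical
#' grid. Nearest-neighbour assigns each target cell the value of the source
#' cell containing its center (categorical-safe; with an integer scale factor
#' every output value exists in the input). Bilinear interpolates between the
#' four surrounding source cell centers (edges clamped); a target cell is
#' nodata if any contributing source cell is nodata.
#'
#' @param band A [raster_band()].
#' @param target A `grid_spec` with the same `crs_label`.
#' @param method `"nearest"` (default) or `"bilinear"`.
#' @return A `raster_band` on `target`.
#' @export
resample_to_grid <- function(band, target, method = c("nearest", "bilinear")) {
  stopifnot(inherits(band, "raster_band"), inherits(target, "grid_spec"))
  method <- match.arg(method)
  src <- band$grid
  if (src$crs_label != target$crs_label) {
    stop("source and target grids use different CRS labels; reprojection is not supported",
         call. = FALSE)
  }
  if (grid_equal(src, target)) return(raster_band(target, band$name, band$values,
                                                  band$mask, band$units))
  # extent overlap check
  sx <- c(src$origin_x, src$origin_x + src$n_cols * src$pixel_size)
  sy <- c(src$origin_y - src$n_rows * src$pixel_size, src$origin_y)
  tx <- c(target$origin_x, target$origin_x + target$n_cols * target$pixel_size)
  ty <- c(target$origin_y - target$n_rows * target$pixel_size, target$origin_y)
  if (tx[1] >= sx[2] || tx[2] <= sx[1] || ty[1] >= sy[2] || ty[2] <= sy[1]) {
    stop("target grid extent is disjoint from the source band", call. = FALSE)
  }
  ctr <- cell_centers(target)
  out <- matrix(NA_real_, target$n_rows, target$n_cols)
  if (method == "nearest") {
    col <- 1L + floor((ctr$x - src$origin_x) / src$pixel_size)
    row <- 1L + floor((src$origin_y - ctr$y) / src$pixel_size)
    okc <- col >= 1L & col <= src$n_cols
    okr <- row >= 1L & row <= src$n_rows
    if (any(okr) && any(okc)) {
      out[okr, okc] <- band$values[row[okr], col[okc], drop = FALSE]
    }
  } else {
    # fractional position in source cell-center coordinates, clamped to edges
    fx <- (ctr$x - (src$origin_x + 0.5 * src$pixel_size)) / src$pixel_size
    fy <- ((src$origin_y - 0.5 * src$pixel_size) - ctr$y) / src$pixel_size
    fx <- pmin(pmax(fx, 0), src$n_cols - 1)
    fy <- pmin(pmax(fy, 0), src$n_rows - 1)
    c0 <- pmin(1L + floor(fx), src$n_cols); c1 <- pmin(c0 + 1L, src$n_cols)
    r0 <- pmin(1L + floor(fy), src$n_rows); r1 <- pmin(r0 + 1L, src$n_rows)
    wx <- fx - (c0 - 1L); wy <- fy - (r0 - 1L)
    v <- band$values
    WX <- matrix(wx, target$n_rows, target$n_cols, byrow = TRUE)
    WY <- matrix(wy, target$n_rows, target$n_cols)
    v00 <- v[r0, c0, drop = FALSE]; v01 <- v[r0, c1, drop = FALSE]
    v10 <- v[r1, c0, drop = FALSE]; v11 <- v[r1, c1, drop = FALSE]
    out <- (1 - WY) * ((1 - WX) * v00 + WX * v01) +
      WY * ((1 - WX) * v10 + WX * v11)
  }
  raster_band(target, band$name, out, units = band$units)
}
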