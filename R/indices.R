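# elementwise combination of aligned bands with a division-safe guard:
# any cell where `bad` is TRUE becomes nodata, never Inf/NaN.
band_math <- function(bands, f, name, units = "index", bad = NULL) {
  g <- bands[[1]]$grid
  for (b in bands[-1]) {
    if (!grid_equal(b$grid, g)) {
      stop(sprintf("bands '%s' and '%s' are not on the same grid",
                   bands[[1]]$name, b$name), call. = FALSE)
    }
  }
  vals <- lapply(bands, function(b) b$values)
  out <- do.call(f, vals)
  mask <- Reduce(`|`, lapply(bands, function(b) b$mask))
  if (!is.null(bad)) {
    bm <- do.call(bad, vals)
    bm[is.na(bm)] <- FALSE
    mask <- mask | bm
  }
  raster_band(g, name, out, mask = mask, units = units)
}

#' Normalized Difference Vegetation Index
#'
#' `(NIR - Red) / (NIR + Red)` on surface-reflectance bands. Cells where the
#' denominator is zero are nodata. For positive reflectances the result lies
#' in \[-1, 1\].
#'
#' @param nir,red Aligned reflectance [raster_band()]s (Sentinel-2 B8 and
#'   B4).
#' @return An index `raster_band` named `"NDVI"`.
#' @export
ndvi <- function(nir, red) {
  band_math(list(nir, red), function(n, r) (n - r) / (n + r), "NDVI",
            bad = function(n, r) (n + r) == 0)
}

#' Normalized Difference Water Index
#'
#' `(Green - NIR) / (Green + NIR)`; zero denominators are nodata.
#'
#' @param green,nir Aligned reflectance bands (Sentinel-2 B3 and B8).
#' @return An index `raster_band` named `"NDWI"`.
#' @export
ndwi <- function(green, nir) {
  band_math(list(green, nir), function(g, n) (g - n) / (g + n), "NDWI",
            bad = function(g, n) (g + n) == 0)
}

#' Enhanced Vegetation Index
#'
#' `2.5 * (NIR - Red) / (NIR + 6 Red - 7.5 Blue + 1)`; zero denominators are
#' nodata.
#'
#' @param nir,red,blue Aligned reflectance bands (Sentinel-2 B8, B4, B2).
#' @return An index `raster_band` named `"EVI"`.
#' @export
evi <- function(nir, red, blue) {
  band_math(list(nir, red, blue),
            function(n, r, b) 2.5 * (n - r) / (n + 6 * r - 7.5 * b + 1),
            "EVI",
            bad = function(n, r, b) (n + 6 * r - 7.5 * b + 1) == 0)
}

#' Convert SAR backscatter between dB and linear power
#'
#' Physical calculations (ratios, the radar vegetation index, temporal
#' means) are done on the linear power scale; sensors deliver dB.
#' `db_to_linear` computes `10^(x/10)`; `linear_to_db` is its inverse
#' `10 log10(x)`.
#'
#' @param band A `raster_band` with units `"dB"` (or `"linear_power"` for
#'   the inverse).
#' @return A `raster_band` on the other scale, same name.
#' @export
db_to_linear <- function(band) {
  stopifnot(inherits(band, "raster_band"))
  if (band$units != "dB") {
    stop(sprintf("band '%s' has units '%s', expected 'dB'", band$name,
                 band$units), call. = FALSE)
  }
  raster_band(band$grid, band$name, 10^(band$values / 10), mask = band$mask,
              units = "linear_power")
}

#' @rdname db_to_linear
#' @export
linear_to_db <- function(band) {
  stopifnot(inherits(band, "raster_band"))
  if (band$units != "linear_power") {
    stop(sprintf("band '%s' has units '%s', expected 'linear_power'",
                 band$name, band$units), call. = FALSE)
  }
  raster_band(band$grid, band$name, 10 * log10(band$values), mask = band$mask,
              units = "dB")
}

#' SAR polarisation ratios and the simplified radar vegetation index
#'
#' From co- (VV) and cross-polarised (VH) backscatter in linear power:
#' the VV/VH ratio, the cross-polarisation ratio VH/VV (elementwise
#' reciprocal of the former), and the simplified radar vegetation index
#' `SRVI = 4 aVV / (aVV + aVH)`, bounded in (0, 4) for positive powers.
#'
#' The conventional radar vegetation index places the cross-polarised
#' channel in the numerator; `srvi_numerator = "vh"` switches to
#' `4 aVH / (aVV + aVH)`. The default keeps the co-polarised numerator.
#'
#' @param vv_lin,vh_lin Aligned `raster_band`s with units
#'   `"linear_power"`.
#' @param srvi_numerator `"vv"` (default) or `"vh"`.
#' @return A named list of `raster_band`s: `vv_lin`, `vh_lin`,
#'   `vv_vh_ratio`, `cross_ratio`, `srvi`.
#' @export
sar_indices <- function(vv_lin, vh_lin, srvi_numerator = c("vv", "vh")) {
  srvi_numerator <- match.arg(srvi_numerator)
  for (b in list(vv_lin, vh_lin)) {
    if (b$units != "linear_power") {
      stop(sprintf("band '%s' must be in linear power (got '%s')",
                   b$name, b$units), call. = FALSE)
    }
    if (any(b$values[!b$mask] <= 0)) {
      stop(sprintf("band '%s' has non-positive power at valid cells", b$name),
           call. = FALSE)
    }
  }
  num <- if (srvi_numerator == "vv") vv_lin else vh_lin
  list(
    vv_lin = vv_lin,
    vh_lin = vh_lin,
    vv_vh_ratio = band_math(list(vv_lin, vh_lin), `/`, "VV_VH"),
    cross_ratio = band_math(list(vh_lin, vv_lin), `/`, "VH_VV"),
    srvi = band_math(list(num, vv_lin, vh_lin),
                     function(a, vv, vh) 4 * a / (vv + vh), "SRVI",
                     bad = function(a, vv, vh) (vv + vh) == 0)
  )
}

# ---- polygon morphometrics -------------------------------------------------

# shoelace area (signed, map units^2) and perimeter of an open or closed ring
ring_area_m2 <- function(ring) {
  ring <- close_ring(ring)
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring)
  abs(sum(x[-n] * y[-1] - x[-1] * y[-n])) / 2
}

ring_perimeter_m <- function(ring) {
  ring <- close_ring(ring)
  sum(sqrt(diff(ring[, 1])^2 + diff(ring[, 2])^2))
}

close_ring <- function(ring) {
  ring <- as.matrix(ring)
  stopifnot(ncol(ring) == 2, nrow(ring) >= 3)
  if (any(ring[1, ] != ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
  ring
}

# simplicity check. Fast O(n) path: a ring whose vertices wind monotonically
# about the centroid (star-shaped) cannot self-intersect. Only non-star
# rings pay for the O(n^2) proper-crossing test; above 4096 vertices that
# test is skipped (the star path covers every high-resolution ring the
# package produces).
ring_self_intersects <- function(ring) {
  ring <- close_ring(ring)
  n <- nrow(ring) - 1L
  if (n < 4L) return(FALSE)
  ang <- atan2(ring[1:n, 2] - mean(ring[1:n, 2]),
               ring[1:n, 1] - mean(ring[1:n, 1]))
  turns <- diff(c(ang, ang[1]))
  turns <- (turns + pi) %% (2 * pi) - pi
  winds_once <- isTRUE(all.equal(abs(sum(turns)), 2 * pi))
  if (winds_once && (all(turns > 0) || all(turns < 0))) return(FALSE)
  if (n > 4096L) {
    warning("ring has > 4096 vertices and is not star-shaped; skipping the exhaustive simplicity check",
            call. = FALSE)
    return(FALSE)
  }
  seg <- cbind(ring[1:n, , drop = FALSE], ring[2:(n + 1L), , drop = FALSE])
  cross <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in 1:(n - 2L)) {
    js <- (i + 2L):n
    js <- js[!(i == 1L & js == n)]  # first and last edge are adjacent
    if (length(js) == 0) next
    p <- seg[i, ]
    d1 <- cross(p[1], p[2], p[3], p[4], seg[js, 1], seg[js, 2])
    d2 <- cross(p[1], p[2], p[3], p[4], seg[js, 3], seg[js, 4])
    d3 <- cross(seg[js, 1], seg[js, 2], seg[js, 3], seg[js, 4], p[1], p[2])
    d4 <- cross(seg[js, 1], seg[js, 2], seg[js, 3], seg[js, 4], p[3], p[4])
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(TRUE)
  }
  FALSE
}

#' Wetland shape morphometrics
#'
#' Area and perimeter from the polygon ring coordinates (planar shoelace
#' formula; map units are metres), the Shape Complexity Index
#' `SCI = Perimeter / Area` (km per km2, scale-dependent), and the
#' Polsby-Popper score `PPS = 4 pi Area / Perimeter^2`, a dimensionless
#' compactness in (0, 1] that equals 1 only in the circular limit.
#'
#' @param ring A two-column matrix of ring coordinates in metres (closed or
#'   open; an open ring is closed implicitly). Self-intersecting rings are a
#'   geometry error.
#' @return A one-row tibble: `area_km2`, `perimeter_km`, `sci`, `pps`.
#' @examples
#' sq <- cbind(c(0, 1000, 1000, 0), c(0, 0, 1000, 1000))
#' morphometrics(sq) # area 1 km2, perimeter 4 km, sci 4, pps pi/4
#' @export
morphometrics <- function(ring) {
  ring <- close_ring(ring)
  if (ring_self_intersects(ring)) {
    stop("polygon ring is self-intersecting", call. = FALSE)
  }
  area_km2 <- ring_area_m2(ring) / 1e6
  per_km <- ring_perimeter_m(ring) / 1e3
  if (area_km2 <= 0 || per_km <= 0) {
    stop("degenerate polygon: zero area or perimeter", call. = FALSE)
  }
  tibble::tibble(
    area_km2 = area_km2,
    perimeter_km = per_km,
    sci = per_km / area_km2,
    pps = 4 * pi * area_km2 / per_km^2
  )
}
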