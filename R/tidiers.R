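#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted stage model
#'
#' One row per feature with its normalized importance score and rank
#' (descending score, ties broken by feature name).
#'
#' @param x A `stage_model`.
#' @param ... Unused.
#' @return A tibble: `stage`, `feature`, `importance`, `importance_raw`,
#'   `rank`.
#' @export
tidy.stage_model <- function(x, ...) {
  out <- tibble::tibble(
    stage = x$stage,
    feature = names(x$importance),
    importance = unname(x$importance),
    importance_raw = unname(x$importance_raw)
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$importance), .data$feature)
  out$rank <- seq_len(nrow(out))
  out
}

#' Tidy a two-stage model
#'
#' Stacks the per-feature importance tables of both stages.
#'
#' @param x A `two_stage_model`.
#' @param ... Unused.
#' @return A tibble (see [tidy.stage_model()]).
#' @export
tidy.two_stage_model <- function(x, ...) {
  dplyr::bind_rows(tidy(x$stage1), tidy(x$stage2))
}

#' One-row summary of a two-stage fit
#'
#' Hold-out metrics of the final combined prediction plus the stage-1
#' baseline r2, and the fit dimensions.
#'
#' @param x A `two_stage_model`.
#' @param ... Unused.
#' @return A one-row tibble: `r2_stage1`, `r2_final`, `rmse_final`,
#'   `mae_final`, `mbe_final`, `n_train`, `n_test`.
#' @export
glance.two_stage_model <- function(x, ...) {
  m <- x$metrics
  s1 <- m[m$stage == "stage1", ]
  fin <- m[m$stage == "final", ]
  tibble::tibble(
    r2_stage1 = s1$r2, r2_final = fin$r2, rmse_final = fin$rmse,
    mae_final = fin$mae, mbe_final = fin$mbe,
    n_train = x$split$n_train, n_test = x$split$n_test
  )
}

#' Raster band as a tibble of cell centers
#'
#' @param x A `raster_band`.
#' @param ... Unused.
#' @return A tibble: `x`, `y`, `value` (NA at nodata), `band`.
#' @export
tidy.raster_band <- function(x, ...) {
  ctr <- cell_centers(x$grid)
  tibble::tibble(
    x = rep(ctr$x, each = x$grid$n_rows),
    y = rep(ctr$y, times = x$grid$n_cols),
    value = as.vector(x$values),
    band = x$name
  )
}
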