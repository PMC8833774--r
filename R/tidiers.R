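# broom-style methods for fitted objects.

#' Tidy a damage-model fit
#'
#' @param x A `damage_fit` from [fit_threshold()] or [fit_poh()].
#' @param ... Unused.
#' @return The full SSE grid scan as a tibble (`parameter`, `value`, `sse`,
#'   `n_excluded`).
#' @method tidy damage_fit
#' @export
tidy.damage_fit <- function(x, ...) {
  residual_curve(x)
}

#' @rdname tidy.damage_fit
#' @method glance damage_fit
#' @export
glance.damage_fit <- function(x, ...) {
  tibble::tibble(
    parameter = x$parameter,
    best = x$best,
    uncertainty = x$uncertainty,
    min_sse = x$min_sse,
    n_grid = nrow(x$curve),
    basin_width = nrow(broad_minimum(x))
  )
}

#' Tidy a window-model fit
#'
#' @param x A `window_fit` from [fit_window()].
#' @param ... Unused.
#' @return Per-width summary tibble (`width`, `best_median`, `uncertainty`,
#'   `min_sse`).
#' @method tidy window_fit
#' @export
tidy.window_fit <- function(x, ...) {
  x$summary
}
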