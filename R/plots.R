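# ggplot2 figure methods. Every figure is regenerable from the exported
# tables alone; these helpers only restyle them.

#' Plot per-base statistics
#'
#' Mean deposited energy per decay, fraction of decays with a non-zero
#' deposit, and mean OH hits per decay, each against base index (distance from
#' the iodine), faceted by measure, coloured by strand.
#'
#' @param object A `per_base_stats` tibble from [per_base_statistics()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot per_base_stats
#' @export
autoplot.per_base_stats <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              c("mean_energy_per_decay", "frac_nonzero",
                                "mean_oh_hits"),
                              names_to = "measure", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$base, y = .data$value,
                                     colour = factor(.data$strand))) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(ggplot2::vars(.data$measure), scales = "free_y",
                        ncol = 1) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "base (distance from iodine)", y = NULL,
                  colour = "strand")
}

#' Plot a fragment-size distribution
#'
#' @param object A `fragment_distribution`.
#' @param ... Unused.
#' @return A ggplot (log-scale fractions against break site; the unbroken
#'   class, if present, is drawn at site -1).
#' @method autoplot fragment_distribution
#' @export
autoplot.fragment_distribution <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$site <- ifelse(is.na(df$site), -1L, df$site)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$site, y = .data$fraction)) +
    ggplot2::geom_col() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "break site (base index; -1 = unbroken)",
                  y = "fraction of fragments")
}

#' Plot a break-probability profile
#'
#' @param object A `break_profile`.
#' @param ... Unused.
#' @return A ggplot of per-base break probability per decay.
#' @method autoplot break_profile
#' @export
autoplot.break_profile <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$base, y = .data$p)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "base (distance from iodine)",
                  y = "break probability per decay")
}

#' Plot a fit's residual curve
#'
#' SSE against the scanned parameter, with the best-fitting value marked.
#'
#' @param object A `damage_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot damage_fit
#' @export
autoplot.damage_fit <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$value, y = .data$sse)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best, linetype = "dashed") +
    ggplot2::labs(x = object$parameter, y = "SSE (log fractions)")
}

#' Plot SSB/DSB yield curves
#'
#' @param object A `yield_curves` tibble from [yield_curves()].
#' @param ... Unused.
#' @return A ggplot of SSB/decay (strand 0) and DSB/decay against threshold.
#' @method autoplot yield_curves
#' @export
autoplot.yield_curves <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              c("ssb_per_decay", "dsb_per_decay"),
                              names_to = "kind", values_to = "yield")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$e_thresh, y = .data$yield,
                                     colour = .data$kind)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "energy threshold (eV)", y = "breaks per decay",
                  colour = NULL)
}

#' Plot an energy histogram
#'
#' @param object An `energy_histogram` tibble from [energy_histogram()].
#' @param ... Unused.
#' @return A ggplot; bins below the 0.25 eV cutoff are greyed.
#' @method autoplot energy_histogram
#' @export
autoplot.energy_histogram <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = (.data$bin_lo + .data$bin_hi) / 2,
                               y = .data$count, fill = .data$below_cutoff)) +
    ggplot2::geom_col(width = object$bin_hi - object$bin_lo) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey20", `TRUE` = "grey70"),
                               guide = "none") +
    ggplot2::labs(x = "energy (eV)", y = "count")
}
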