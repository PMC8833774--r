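# Grid-search fits of the damage-model parameters against observed fragment
# fractions. One scored dataset is reused across all grid points (one
# simulation, many thresholds); stochastic calls re-seed deterministically per
# grid point.

# Accumulated per-site energies on one strand out to max_base, ordered by
# base ascending so that a single indexed assignment yields the per-event
# maximum broken base (last write wins).
site_energies <- function(dataset, strand = 0L, max_base) {
  acc <- accumulate_energy(dataset)
  acc <- acc[acc$strand == strand & acc$base <= max_base, , drop = FALSE]
  acc <- acc[order(acc$base), , drop = FALSE]
  list(event_id = acc$event_id, base = acc$base, energy = acc$energy_eV)
}

# Fragment-class counts (most distant broken base per event) for a logical
# selection of broken site rows.
fragment_counts <- function(event_id, base, sel, n_decays, max_base) {
  cls <- rep(-1L, n_decays)
  cls[event_id[sel] + 1L] <- base[sel]
  counts <- tabulate(cls[cls >= 0L] + 1L, nbins = max_base + 1L)
  counts
}

model_fractions <- function(counts) {
  n <- sum(counts)
  if (n == 0L) return(NULL)
  counts / n
}

obs_max_site <- function(obs) {
  stopifnot(is.data.frame(obs), all(c("site", "fraction") %in% names(obs)))
  max(obs$site[!is.na(obs$site)])
}

check_scavenging <- function(obs, expected) {
  scav <- attr(obs, "scavenging")
  if (!is.null(scav) && !identical(scav, expected)) {
    warn(sprintf("observed data is tagged '%s' scavenging; this fit assumes '%s'",
                 scav, expected))
  }
}

sse_against_obs <- function(obs, fractions, max_base, zero_policy, floor) {
  if (is.null(fractions)) {
    return(list(sse = Inf, n_excluded = NA_integer_))
  }
  model <- fragment_distribution_tbl(0:max_base, fractions, mode = "breaks_only")
  sse <- sse_log(obs, model, zero_policy = zero_policy, floor = floor)
  list(sse = as.numeric(sse), n_excluded = attr(sse, "n_excluded"))
}

new_damage_fit <- function(parameter, curve, model, obs, extra = list()) {
  finite <- which(is.finite(curve$sse))
  if (!length(finite)) abort("no grid point produced a comparable distribution")
  best_i <- finite[which.min(curve$sse[finite])]
  ties <- sum(curve$sse[finite] == curve$sse[best_i])
  if (ties > 1L) {
    rlang::inform(sprintf(
      "%d grid points tie for the minimum SSE; reporting the lowest parameter value",
      ties))
  }
  step <- if (nrow(curve) > 1L) median(diff(curve$value)) else NA_real_
  structure(
    c(list(parameter = parameter, curve = curve, best = curve$value[best_i],
           uncertainty = step / 2, min_sse = curve$sse[best_i],
           model = model, obs = obs), extra),
    class = "damage_fit"
  )
}

#' @export
print.damage_fit <- function(x, ...) {
  cat(sprintf("<damage_fit> %s = %g +/- %g (min SSE %.4g over %d grid points)\n",
              x$parameter, x$best, x$uncertainty, x$min_sse, nrow(x$curve)))
  invisible(x)
}

#' Fit the direct-damage energy threshold
#'
#' Grid search for the break energy threshold against observed fragment
#' fractions from a fully scavenged (direct damage only) experiment. For each
#' candidate threshold, direct breaks are called on the labelled strand, the
#' fragment-size distribution out to the most distant measured site is formed,
#' and the log-scale SSE against the observation is computed; the best fit
#' minimises the SSE, with ties broken toward the lower threshold and an
#' uncertainty of half the grid step.
#'
#' @param dataset A [track_dataset()] of scored events.
#' @param obs Observed fragment fractions (see [observed_fragments()]),
#'   high-scavenging; its sites must cover `0..max(site)`.
#' @param grid Candidate thresholds in eV, sorted (default 10 to 40 eV in
#'   0.25 eV steps, matching the conventional scan range).
#' @param strand Strand fitted (default 0, the labelled strand).
#' @param zero_policy,floor Zero-fraction bin handling, see [sse_log()].
#' @return A `damage_fit` object; see [tidy.damage_fit()], [residual_curve()],
#'   [broad_minimum()].
#' @export
fit_threshold <- function(dataset, obs, grid = seq(10, 40, by = 0.25),
                          strand = 0L, zero_policy = c("exclude", "floor"),
                          floor = NULL) {
  stopifnot(inherits(dataset, "track_dataset"))
  zero_policy <- rlang::arg_match(zero_policy)
  if (!length(grid)) abort("`grid` must be non-empty")
  if (is.unsorted(grid, strictly = TRUE)) abort("`grid` must be sorted, increasing")
  check_scavenging(obs, "high")
  max_base <- obs_max_site(obs)
  se <- site_energies(dataset, strand, max_base)
  rows <- purrr::map(grid, function(e) {
    counts <- fragment_counts(se$event_id, se$base, se$energy > e,
                              dataset$n_decays, max_base)
    sse_against_obs(obs, model_fractions(counts), max_base, zero_policy, floor)
  })
  curve <- tibble::tibble(
    value = as.numeric(grid),
    sse = vapply(rows, `[[`, 1, "sse"),
    n_excluded = vapply(rows, `[[`, NA_integer_, "n_excluded")
  )
  best_i <- which.min(curve$sse)
  counts <- fragment_counts(se$event_id, se$base, se$energy > grid[best_i],
                            dataset$n_decays, max_base)
  model <- fragment_distribution_tbl(0:max_base, model_fractions(counts),
                                     mode = "breaks_only")
  new_damage_fit("e_thresh", curve, model, obs,
                 extra = list(strand = strand, zero_policy = zero_policy))
}

#' Fit the window-model median energy as a function of window width
#'
#' For each window width (the difference between the upper and lower energy
#' bounds of the linear break-probability ramp), grid-searches the window's
#' median energy. Width 0 is the threshold model and reproduces
#' [fit_threshold()] exactly. Stochastic window draws re-seed
#' deterministically per (width, grid point).
#'
#' @param dataset A [track_dataset()].
#' @param obs High-scavenging observed fragment fractions.
#' @param widths Window widths in eV (>= 0); e.g. width 32.5 about median
#'   21.25 gives the classical (5, 37.5) eV window.
#' @param grid Candidate median energies in eV.
#' @param seed RNG seed for the probabilistic draws.
#' @param strand,zero_policy,floor As in [fit_threshold()].
#' @return A `window_fit`: list with `fits` (one `damage_fit` per width) and
#'   `summary` (tibble of width, best median, uncertainty, min SSE).
#' @export
fit_window <- function(dataset, obs, widths, grid = seq(10, 40, by = 0.25),
                       seed = 1L, strand = 0L,
                       zero_policy = c("exclude", "floor"), floor = NULL) {
  stopifnot(inherits(dataset, "track_dataset"))
  zero_policy <- rlang::arg_match(zero_policy)
  if (any(widths < 0)) abort("window widths must be >= 0")
  check_scavenging(obs, "high")
  max_base <- obs_max_site(obs)
  se <- site_energies(dataset, strand, max_base)
  fits <- purrr::imap(setNames(as.list(widths), paste0("width_", widths)),
                      function(w, nm) {
    wi <- match(w, widths)
    rows_model <- purrr::map(seq_along(grid), function(gi) {
      m <- grid[gi]
      if (w == 0) {
        sel <- se$energy > m
      } else {
        e_low <- m - w / 2
        p <- clamp01((se$energy - e_low) / w)
        u <- withr::with_seed(derive_seed(seed, "window_fit", wi * 100000L + gi),
                              runif(length(p)))
        sel <- u < p
      }
      counts <- fragment_counts(se$event_id, se$base, sel, dataset$n_decays,
                                max_base)
      c(sse_against_obs(obs, model_fractions(counts), max_base, zero_policy,
                        floor),
        list(fractions = model_fractions(counts)))
    })
    curve <- tibble::tibble(
      value = as.numeric(grid),
      sse = vapply(rows_model, `[[`, 1, "sse"),
      n_excluded = vapply(rows_model, `[[`, NA_integer_, "n_excluded")
    )
    best_i <- which.min(curve$sse)
    model <- fragment_distribution_tbl(0:max_base,
                                       rows_model[[best_i]]$fractions,
                                       mode = "breaks_only")
    new_damage_fit("window_median", curve, model, obs,
                   extra = list(width = w, strand = strand,
                                zero_policy = zero_policy))
  })
  summary <- purrr::map_dfr(fits, function(f) {
    tibble::tibble(width = f$width, best_median = f$best,
                   uncertainty = f$uncertainty, min_sse = f$min_sse)
  })
  structure(list(fits = fits, summary = summary), class = "window_fit")
}

#' @export
print.window_fit <- function(x, ...) {
  cat("<window_fit>\n")
  print(x$summary)
  invisible(x)
}

#' Fit the OH-radical interaction probability
#'
#' Grid search for the per-hit OH break probability against observed fragment
#' fractions from a low-scavenging experiment. The direct component is fixed:
#' breaks are called at `e_thresh` (taken from the fully scavenged fit) and
#' merged with indirect breaks drawn at each candidate probability;
#' stochastic indirect draws re-seed deterministically per grid point.
#'
#' @param dataset A [track_dataset()].
#' @param obs Low-scavenging observed fragment fractions.
#' @param e_thresh Fixed direct-damage threshold in eV.
#' @param grid Candidate probabilities (default 0 to 1 in 0.01 steps).
#' @param seed RNG seed for the indirect draws.
#' @param strand,zero_policy,floor As in [fit_threshold()].
#' @return A `damage_fit` with `parameter == "p_oh"`.
#' @export
fit_poh <- function(dataset, obs, e_thresh, grid = seq(0, 1, by = 0.01),
                    seed = 1L, strand = 0L,
                    zero_policy = c("exclude", "floor"), floor = NULL) {
  stopifnot(inherits(dataset, "track_dataset"))
  zero_policy <- rlang::arg_match(zero_policy)
  if (!length(grid)) abort("`grid` must be non-empty")
  if (is.unsorted(grid, strictly = TRUE)) abort("`grid` must be sorted, increasing")
  check_scavenging(obs, "low")
  max_base <- obs_max_site(obs)
  se <- site_energies(dataset, strand, max_base)
  d_ev <- se$event_id[se$energy > e_thresh]
  d_base <- se$base[se$energy > e_thresh]
  hits <- oh_hits(dataset)
  hits <- hits[hits$strand == strand & hits$base <= max_base, , drop = FALSE]
  hits <- hits[order(hits$base), , drop = FALSE]
  rows_model <- purrr::map(seq_along(grid), function(gi) {
    p <- grid[gi]
    u <- withr::with_seed(derive_seed(seed, "poh_fit", gi), runif(nrow(hits)))
    sel <- u < p
    ev <- c(d_ev, hits$event_id[sel])
    bs <- c(d_base, hits$base[sel])
    o <- order(bs)
    counts <- fragment_counts(ev[o], bs[o], rep(TRUE, length(o)),
                              dataset$n_decays, max_base)
    c(sse_against_obs(obs, model_fractions(counts), max_base, zero_policy,
                      floor),
      list(fractions = model_fractions(counts)))
  })
  curve <- tibble::tibble(
    value = as.numeric(grid),
    sse = vapply(rows_model, `[[`, 1, "sse"),
    n_excluded = vapply(rows_model, `[[`, NA_integer_, "n_excluded")
  )
  best_i <- which.min(curve$sse)
  model <- fragment_distribution_tbl(0:max_base, rows_model[[best_i]]$fractions,
                                     mode = "breaks_only")
  new_damage_fit("p_oh", curve, model, obs,
                 extra = list(e_thresh = e_thresh, strand = strand,
                              zero_policy = zero_policy))
}

#' Residual (SSE) curve of a fit
#'
#' @param fit A `damage_fit`.
#' @return Tibble with columns `parameter`, `value`, `sse`, `n_excluded`; its
#'   minimum matches `fit$best`.
#' @export
residual_curve <- function(fit) {
  stopifnot(inherits(fit, "damage_fit"))
  dplyr::mutate(fit$curve, parameter = fit$parameter, .before = 1)
}

#' Broad-minimum diagnostic
#'
#' Because observed fragment distributions are normalised, they are
#' insensitive to the total break yield, which typically produces a broad
#' basin around the SSE minimum. This reports the grid values whose SSE lies
#' within `factor` times the minimum.
#'
#' @param fit A `damage_fit`.
#' @param factor Multiplier on the minimum SSE (default 2).
#' @return Tibble of grid values (and SSEs) inside the basin.
#' @export
broad_minimum <- function(fit, factor = 2) {
  stopifnot(inherits(fit, "damage_fit"), factor >= 1)
  dplyr::filter(fit$curve, is.finite(.data$sse),
                .data$sse <= factor * fit$min_sse)
}

#' SSB and DSB yields as a function of the energy threshold
#'
#' For each candidate threshold, calls direct breaks on both strands and
#' reports the strand-0 SSB yield and the DSB yield (opposite-strand breaks
#' within `dsb_max_sep` base pairs).
#'
#' @param dataset A [track_dataset()].
#' @param grid Thresholds in eV.
#' @param dsb_max_sep Maximum DSB separation in base pairs (default 10).
#' @return A tibble with columns `e_thresh`, `ssb_per_decay`, `ssb_se`,
#'   `dsb_per_decay`, `dsb_se`, of class `yield_curves`.
#' @export
yield_curves <- function(dataset, grid = seq(10, 40, by = 1),
                         dsb_max_sep = 10L) {
  stopifnot(inherits(dataset, "track_dataset"))
  acc <- accumulate_energy(dataset)
  out <- purrr::map_dfr(grid, function(e) {
    hit <- acc[acc$energy_eV > e, , drop = FALSE]
    call <- break_calls(
      tibble::tibble(event_id = hit$event_id, strand = hit$strand,
                     base = hit$base, cause = "direct"),
      n_decays = dataset$n_decays, n_bases = dataset$n_bases
    )
    ssb <- ssb_yield(call, strand = 0L)
    dsb <- dsb_yield(call, dsb_max_sep = dsb_max_sep)
    tibble::tibble(e_thresh = e, ssb_per_decay = ssb$yield, ssb_se = ssb$se,
                   dsb_per_decay = dsb$yield, dsb_se = dsb$se)
  })
  class(out) <- c("yield_curves", class(out))
  out
}

#' Synthetic observation from a generator replicate
#'
#' Emulates one fragment-fraction "experiment": generates an independent
#' scored dataset, calls direct breaks at `e_thresh` (plus indirect breaks at
#' `p_oh` for the low-scavenging condition), and returns the breaks-only
#' fragment distribution out to `max_site`, tagged with the scavenging
#' condition.
#'
#' @param config A [generator_config()] (its seed identifies the replicate).
#' @param n_decays Decays in the synthetic experiment.
#' @param e_thresh Generating direct-damage threshold in eV.
#' @param p_oh Generating OH probability; `NULL` gives the fully scavenged
#'   (direct-only, `"high"`) condition.
#' @param max_site Most distant measured site.
#' @return A `fragment_distribution` with a `scavenging` attribute.
#' @export
synthetic_observation <- function(config, n_decays, e_thresh, p_oh = NULL,
                                  max_site = 15L) {
  d <- generate_events(config, n_decays)
  calls <- call_direct_threshold(d, e_thresh)
  if (!is.null(p_oh)) {
    calls <- merge_breaks(calls,
                          call_indirect(d, p_oh,
                                        seed = derive_seed(config$seed, "obs_oh")))
  }
  f <- fragment_distribution(calls, strand = 0L, max_base = max_site,
                             mode = "breaks_only")
  attr(f, "scavenging") <- if (is.null(p_oh)) "high" else "low"
  f
}

#' Replicated parameter-recovery experiment
#'
#' Repeats the two-stage fitting procedure on independent synthetic
#' experiment/model dataset pairs: each replicate generates an observation at
#' the stated threshold (and OH probability), generates an independent model
#' dataset of the same size, fits the threshold on the fully scavenged
#' observation, then fits the OH probability on the low-scavenging
#' observation with the fitted threshold fixed. The distribution of recovered
#' values across replicates measures the identifiability of the parameters at
#' the chosen study size; note that because fragment fractions are
#' normalised, the threshold's SSE minimum is broad and its argmin
#' concentrates only slowly with increasing `n_decays`.
#'
#' @param n_replicates Number of replicate pairs (default 20).
#' @param n_decays Decays per dataset (default 200,000).
#' @param e_thresh,p_oh Generating parameter values (`p_oh = NULL` skips the
#'   indirect stage).
#' @param seed Master seed; every replicate derives its own streams.
#' @param max_site Most distant measured site (default 15).
#' @param threshold_grid,poh_grid Fit grids.
#' @param generator Named list of [generator_config()] overrides (without
#'   `seed`).
#' @return Tibble with one row per replicate: `replicate`, `e_thresh_hat`,
#'   `p_oh_hat` (`NA` when skipped).
#' @export
recovery_experiment <- function(n_replicates = 20L, n_decays = 200000L,
                                e_thresh = 29.5, p_oh = 0.16, seed = 1L,
                                max_site = 15L,
                                threshold_grid = seq(10, 40, by = 0.25),
                                poh_grid = seq(0, 1, by = 0.01),
                                generator = list()) {
  purrr::map_dfr(seq_len(n_replicates), function(r) {
    cfg_obs <- do.call(generator_config,
                       c(generator, list(seed = derive_seed(seed, "rec_obs", r))))
    cfg_mod <- do.call(generator_config,
                       c(generator, list(seed = derive_seed(seed, "rec_mod", r))))
    d_mod <- generate_events(cfg_mod, n_decays)
    obs_high <- synthetic_observation(cfg_obs, n_decays, e_thresh,
                                      max_site = max_site)
    ft <- fit_threshold(d_mod, obs_high, grid = threshold_grid)
    p_hat <- NA_real_
    if (!is.null(p_oh)) {
      obs_low <- synthetic_observation(cfg_obs, n_decays, e_thresh, p_oh,
                                       max_site = max_site)
      fp <- fit_poh(d_mod, obs_low, e_thresh = ft$best, grid = poh_grid,
                    seed = derive_seed(seed, "rec_poh", r))
      p_hat <- fp$best
    }
    tibble::tibble(replicate = r, e_thresh_hat = ft$best, p_oh_hat = p_hat)
  })
}
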