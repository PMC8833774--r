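#' Pipeline run configuration
#'
#' Bundles everything one end-to-end analysis needs: where the scored events
#' come from (a generator setup or an event file), the damage-model
#' parameters, the fit grids, optional observed fragment-fraction files, and
#' a single master seed from which every stochastic stage derives its own
#' stream. Round-trips through YAML via [write_run_config()] /
#' [read_run_config()].
#'
#' @param seed Master RNG seed (mandatory).
#' @param n_events Number of decays to generate when no event file is given.
#' @param events_path Optional scored-event file to analyse instead of
#'   generating.
#' @param generator Named list of [generator_config()] arguments (without
#'   `seed`); `NULL` uses the calibrated defaults.
#' @param e_thresh Direct-damage threshold in eV for the break-calling stage.
#' @param p_oh OH interaction probability for the indirect stage (`NULL`
#'   skips indirect damage).
#' @param dsb_max_sep Maximum DSB separation in base pairs.
#' @param max_site Most distant measured fragment site used for fragment
#'   distributions and fits.
#' @param threshold_grid,poh_grid Fit grids as `c(from, to, by)`.
#' @param fit If `TRUE`, run the threshold (and, with `p_oh`, the OH) fits.
#'   Observed data is taken from `observed_high_path` / `observed_low_path`
#'   when given; otherwise a self-fit observation is synthesised from an
#'   independent generator replicate (requires a generator, not an event
#'   file).
#' @param observed_high_path,observed_low_path Optional fragment-distribution
#'   files (see [read_fragment_distribution()]) for the fully scavenged and
#'   low-scavenging conditions.
#' @param label Run label.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed, n_events = 20000L, events_path = NULL,
                       generator = NULL, e_thresh = 29.5, p_oh = 0.16,
                       dsb_max_sep = 10L, max_site = 15L,
                       threshold_grid = c(10, 40, 0.25),
                       poh_grid = c(0, 1, 0.01), fit = TRUE,
                       observed_high_path = NULL, observed_low_path = NULL,
                       label = "iodamage-run") {
  if (missing(seed)) abort("`seed` is mandatory")
  structure(
    list(seed = as.integer(seed), n_events = as.integer(n_events),
         events_path = events_path, generator = generator,
         e_thresh = e_thresh, p_oh = p_oh,
         dsb_max_sep = as.integer(dsb_max_sep), max_site = as.integer(max_site),
         threshold_grid = as.numeric(threshold_grid),
         poh_grid = as.numeric(poh_grid), fit = isTRUE(fit),
         observed_high_path = observed_high_path,
         observed_low_path = observed_low_path, label = label),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

build_generator <- function(config) {
  args <- config$generator %||% list()
  if (!is.null(args$mixture) && !inherits(args$mixture, "energy_mixture")) {
    args$mixture <- do.call(energy_mixture, args$mixture)
  }
  args$seed <- derive_seed(config$seed, "dataset")
  do.call(generator_config, args)
}

expand_grid_spec <- function(spec) {
  stopifnot(length(spec) == 3L)
  seq(spec[1], spec[2], by = spec[3])
}

#' Run the full analysis pipeline
#'
#' End-to-end run: obtain scored events (generate or read), compute per-base
#' statistics and energy histograms, call direct and indirect strand breaks,
#' form fragment-size distributions, demonstrate the inversion degeneracy,
#' fit the energy threshold (and OH probability) when requested, and compute
#' SSB/DSB yield curves. All tables are written as tab-separated text, all
#' figures as PNG regenerable from the tables, plus a machine-readable
#' `summary.yaml` (tagged with a hash of the configuration) and a `log.txt`.
#' Two runs with the same configuration produce byte-identical tables.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @param figures Write PNG figures (default `TRUE`).
#' @return Invisibly, a list with the principal results (`dataset` stats,
#'   calls, distributions, fits, yields, summary).
#' @export
run_pipeline <- function(config, out_dir, figures = TRUE) {
  stopifnot(inherits(config, "run_config"))
  # pre-flight checks before any computation
  if (!is.null(config$events_path) && !file.exists(config$events_path)) {
    abort(sprintf("events file not found: %s", config$events_path))
  }
  for (p in c(config$observed_high_path, config$observed_low_path)) {
    if (!is.null(p) && !file.exists(p)) abort(sprintf("observed data not found: %s", p))
  }
  if (config$fit && !is.null(config$events_path) &&
      is.null(config$observed_high_path)) {
    abort("fit requested but no observed data given and no generator to synthesise it")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_hash <- rlang::hash(unclass(config))
  tag <- function(df) dplyr::mutate(df, config_hash = cfg_hash)
  save_tbl <- function(df, name) {
    readr::write_tsv(tag(tibble::as_tibble(df)), file.path(out_dir, name))
  }
  save_fig <- function(plot, name) {
    if (!figures) return(invisible(NULL))
    tryCatch(
      suppressMessages(ggplot2::ggsave(file.path(out_dir, name), plot,
                                       width = 7, height = 5, dpi = 120)),
      error = function(e) warn(sprintf("could not write figure %s: %s", name,
                                       conditionMessage(e)))
    )
  }

  dataset <- if (!is.null(config$events_path)) {
    read_scored_events(config$events_path)
  } else {
    generate_events(build_generator(config), config$n_events)
  }

  stats <- per_base_statistics(dataset)
  save_tbl(stats, "per_base_stats.tsv")
  save_fig(autoplot(stats), "per_base_stats.png")

  hist_int <- energy_histogram(dataset, "per_interaction", strand = NULL,
                               bin_width = 0.5)
  hist_b10 <- energy_histogram(dataset, "per_decay_per_base", base = 10L,
                               bin_width = 0.5)
  save_tbl(hist_int, "energy_per_interaction.tsv")
  save_tbl(hist_b10, "energy_per_decay_base10.tsv")
  save_fig(autoplot(hist_int), "energy_per_interaction.png")
  save_fig(autoplot(hist_b10), "energy_per_decay_base10.png")

  direct <- call_direct_threshold(dataset, config$e_thresh)
  calls <- if (!is.null(config$p_oh)) {
    merge_breaks(direct,
                 call_indirect(dataset, config$p_oh,
                               seed = derive_seed(config$seed, "indirect")))
  } else direct
  write_break_calls(calls, file.path(out_dir, "break_calls.tsv"))

  frag_bo <- fragment_distribution(calls, strand = 0L,
                                   max_base = config$max_site,
                                   mode = "breaks_only")
  frag_iu <- fragment_distribution(calls, strand = 0L,
                                   max_base = config$max_site,
                                   mode = "include_unbroken")
  save_tbl(frag_bo, "fragments_breaks_only.tsv")
  save_tbl(frag_iu, "fragments_include_unbroken.tsv")
  save_fig(autoplot(frag_bo), "fragments_breaks_only.png")

  # inversion degeneracy: true profile vs inverse from each normalisation
  profile <- break_profile(calls, strand = 0L, max_base = config$max_site)
  inv_full <- kandaiya_inverse(forward_fragment_model(profile,
                                                      "include_unbroken"))
  inv_bo <- kandaiya_inverse(frag_bo)
  degeneracy <- tibble::tibble(
    base = profile$base,
    p_true = profile$p,
    p_inverse_full = inv_full$p[match(profile$base, inv_full$base)],
    p_inverse_breaks_only = inv_bo$p[match(profile$base, inv_bo$base)]
  )
  save_tbl(degeneracy, "inversion_degeneracy.tsv")
  save_fig(
    autoplot(new_break_profile(tibble::tibble(base = degeneracy$base,
                                              p = degeneracy$p_inverse_breaks_only))) +
      ggplot2::geom_line(ggplot2::aes(y = degeneracy$p_true), linetype = "dashed"),
    "inversion_degeneracy.png"
  )
  innermost_occupied <- min(degeneracy$base[frag_bo$fraction > 0])
  degeneracy_p <- degeneracy$p_inverse_breaks_only[degeneracy$base ==
                                                     innermost_occupied]

  fits <- list()
  if (config$fit) {
    # without observed files this is a self-fit: the observation is built from
    # the analysed dataset itself, so the threshold fit must land exactly on
    # the generating value (an end-to-end consistency check, not a recovery
    # experiment; see recovery_experiment() for the latter)
    obs_high <- if (!is.null(config$observed_high_path)) {
      read_fragment_distribution(config$observed_high_path, scavenging = "high")
    } else {
      f <- fragment_distribution(direct, 0L, config$max_site, "breaks_only")
      attr(f, "scavenging") <- "high"
      f
    }
    fits$threshold <- fit_threshold(dataset, obs_high,
                                    grid = expand_grid_spec(config$threshold_grid))
    save_tbl(residual_curve(fits$threshold), "fit_threshold_curve.tsv")
    save_fig(autoplot(fits$threshold), "fit_threshold_curve.png")

    if (!is.null(config$p_oh)) {
      obs_low <- if (!is.null(config$observed_low_path)) {
        read_fragment_distribution(config$observed_low_path, scavenging = "low")
      } else {
        f <- fragment_distribution(calls, 0L, config$max_site, "breaks_only")
        attr(f, "scavenging") <- "low"
        f
      }
      fits$poh <- fit_poh(dataset, obs_low, e_thresh = fits$threshold$best,
                          grid = expand_grid_spec(config$poh_grid),
                          seed = derive_seed(config$seed, "poh"))
      save_tbl(residual_curve(fits$poh), "fit_poh_curve.tsv")
      save_fig(autoplot(fits$poh), "fit_poh_curve.png")
    }
  }

  yields <- yield_curves(dataset, grid = seq(config$threshold_grid[1],
                                             config$threshold_grid[2], by = 1),
                         dsb_max_sep = config$dsb_max_sep)
  save_tbl(yields, "yield_curves.tsv")
  save_fig(autoplot(yields), "yield_curves.png")

  ssb <- ssb_yield(calls, strand = 0L)
  dsb <- dsb_yield(calls, dsb_max_sep = config$dsb_max_sep)

  summary <- list(
    config_hash = cfg_hash,
    label = config$label,
    seed = config$seed,
    n_decays = dataset$n_decays,
    e_thresh = config$e_thresh,
    p_oh = config$p_oh,
    ssb_per_decay = ssb$yield,
    dsb_per_decay = dsb$yield,
    innermost_occupied_site = innermost_occupied,
    inverse_p_at_innermost = degeneracy_p,
    best_e_thresh = if (!is.null(fits$threshold)) fits$threshold$best,
    best_e_thresh_uncertainty = if (!is.null(fits$threshold)) fits$threshold$uncertainty,
    best_p_oh = if (!is.null(fits$poh)) fits$poh$best,
    best_p_oh_uncertainty = if (!is.null(fits$poh)) fits$poh$uncertainty
  )
  yaml::write_yaml(summary, file.path(out_dir, "summary.yaml"))
  writeLines(c(
    sprintf("iodamage %s", as.character(utils::packageVersion("iodamage"))),
    sprintf("R %s", R.version.string),
    sprintf("config hash: %s", cfg_hash),
    sprintf("master seed: %d", config$seed),
    yaml::as.yaml(unclass(config))
  ), file.path(out_dir, "log.txt"))

  invisible(list(dataset = dataset, stats = stats, calls = calls,
                 fragments = list(breaks_only = frag_bo,
                                  include_unbroken = frag_iu),
                 degeneracy = degeneracy, fits = fits, yields = yields,
                 summary = summary))
}
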