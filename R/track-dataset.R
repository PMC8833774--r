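#' Per-decay scored event dataset
#'
#' Container for per-decay scored events around a DNA-incorporated
#' \eqn{^{125}}I atom: individual energy-deposition interactions in backbone
#' volumes (`record_type == "EDEP"`, with an energy in eV) and scavenged
#' OH-radical hits (`record_type == "OH"`). Strand 0 is the iodine-proximal
#' strand (the strand quantified in the end-labelled assay); base 0 contains
#' the iodine. A decay that deposits nothing in the strand is a legitimate
#' event and simply has no rows, so the number of decays is carried
#' explicitly.
#'
#' @param records Tibble with columns `event_id` (0-based integer),
#'   `record_type` (`"EDEP"` or `"OH"`), `strand` (0 or 1), `base` (0-based
#'   integer `< n_bases`) and `energy_eV` (strictly positive for `EDEP`, `NA`
#'   for `OH`).
#' @param n_decays Number of decays scored (including decays with no records).
#' @param n_bases Number of base pairs in the strand (default 40).
#' @param label Free-text label, e.g. a physics-list name.
#' @return An object of class `track_dataset`.
#' @seealso [generate_events()], [read_scored_events()], [accumulate_energy()]
#' @export
track_dataset <- function(records, n_decays, n_bases = 40L, label = "") {
  n_decays <- assert_count(n_decays, "n_decays", min = 0L)
  n_bases <- assert_count(n_bases, "n_bases")
  records <- tibble::as_tibble(records)
  required <- c("event_id", "record_type", "strand", "base", "energy_eV")
  missing <- setdiff(required, names(records))
  if (length(missing)) {
    abort(paste0("records is missing columns: ", paste(missing, collapse = ", ")))
  }
  records <- dplyr::mutate(
    records[required],
    event_id = as.integer(.data$event_id),
    record_type = as.character(.data$record_type),
    strand = as.integer(.data$strand),
    base = as.integer(.data$base),
    energy_eV = as.numeric(.data$energy_eV)
  )
  validate_records(records, n_decays, n_bases)
  structure(
    list(records = records, n_decays = n_decays, n_bases = n_bases,
         label = as.character(label)),
    class = "track_dataset"
  )
}

validate_records <- function(records, n_decays, n_bases, line_offset = NULL) {
  where <- function(i) {
    if (is.null(line_offset)) sprintf("row %d", i) else sprintf("line %d", i + line_offset)
  }
  bad <- which(!records$record_type %in% c("EDEP", "OH"))
  if (length(bad)) {
    abort(sprintf("unknown record_type %s at %s",
                  records$record_type[bad[1]], where(bad[1])))
  }
  bad <- which(is.na(records$event_id) | records$event_id < 0L |
                 records$event_id >= n_decays)
  if (length(bad)) {
    abort(sprintf("event_id out of range [0, %d) at %s", n_decays, where(bad[1])))
  }
  bad <- which(!records$strand %in% c(0L, 1L))
  if (length(bad)) {
    abort(sprintf("strand must be 0 or 1 at %s", where(bad[1])))
  }
  bad <- which(is.na(records$base) | records$base < 0L | records$base >= n_bases)
  if (length(bad)) {
    abort(sprintf("base index out of range [0, %d) at %s", n_bases, where(bad[1])))
  }
  edep <- records$record_type == "EDEP"
  bad <- which(edep & (is.na(records$energy_eV) | records$energy_eV <= 0))
  if (length(bad)) {
    abort(sprintf("EDEP energy must be > 0 eV at %s", where(bad[1])))
  }
  invisible(records)
}

#' @export
print.track_dataset <- function(x, ...) {
  cat(sprintf("<track_dataset> %d decays, %d bp strand%s\n", x$n_decays, x$n_bases,
              if (nzchar(x$label)) paste0(" [", x$label, "]") else ""))
  n_edep <- sum(x$records$record_type == "EDEP")
  n_oh <- sum(x$records$record_type == "OH")
  cat(sprintf("  %d energy depositions, %d OH hits\n", n_edep, n_oh))
  invisible(x)
}

#' Extract interaction or OH-hit records
#'
#' @param dataset A [track_dataset()].
#' @return A tibble of `EDEP` rows (`interactions()`) or `OH` rows
#'   (`oh_hits()`), the latter without the (all-`NA`) energy column.
#' @export
interactions <- function(dataset) {
  stopifnot(inherits(dataset, "track_dataset"))
  dplyr::filter(dataset$records, .data$record_type == "EDEP")
}

#' @rdname interactions
#' @export
oh_hits <- function(dataset) {
  stopifnot(inherits(dataset, "track_dataset"))
  dplyr::select(
    dplyr::filter(dataset$records, .data$record_type == "OH"),
    -"energy_eV"
  )
}

#' Accumulate deposited energy per backbone site
#'
#' Sums all interaction energies per (event, strand, base), giving the
#' per-decay accumulated energy in each backbone volume that the direct-damage
#' models consume. Sites with no interactions are omitted unless
#' `dense = TRUE` (their accumulated energy is zero).
#'
#' @param dataset A [track_dataset()].
#' @param dense If `TRUE`, return the complete (event, strand, base) grid with
#'   explicit zeros. Intended for small datasets.
#' @return A tibble with columns `event_id`, `strand`, `base`, `energy_eV`.
#' @export
accumulate_energy <- function(dataset, dense = FALSE) {
  stopifnot(inherits(dataset, "track_dataset"))
  rec <- dataset$records
  i <- rec$record_type == "EDEP"
  # radix-sorted group sum over a packed (event, strand, base) key; far
  # cheaper than generic grouped summaries at millions of sparse sites
  key <- (rec$event_id[i] * 2 + rec$strand[i]) * dataset$n_bases + rec$base[i]
  o <- order(key, method = "radix")
  k <- key[o]
  if (length(k)) {
    last <- c(k[-1] != k[-length(k)], TRUE)
    csum <- cumsum(rec$energy_eV[i][o])[last]
    sums <- diff(c(0, csum))
    uk <- k[last]
    acc <- tibble::tibble(
      event_id = as.integer(uk %/% (2L * dataset$n_bases)),
      strand = as.integer((uk %/% dataset$n_bases) %% 2L),
      base = as.integer(uk %% dataset$n_bases),
      energy_eV = sums
    )
  } else {
    acc <- tibble::tibble(event_id = integer(), strand = integer(),
                          base = integer(), energy_eV = numeric())
  }
  if (dense) {
    grid <- tidyr::expand_grid(
      event_id = seq_len(dataset$n_decays) - 1L,
      strand = 0:1,
      base = seq_len(dataset$n_bases) - 1L
    )
    acc <- dplyr::left_join(grid, acc, by = c("event_id", "strand", "base")) |>
      dplyr::mutate(energy_eV = tidyr::replace_na(.data$energy_eV, 0))
  }
  acc # already in (event_id, strand, base) order
}

#' Per-base summary statistics over all decays
#'
#' Computes, for every (strand, base) site: the mean energy deposited per
#' decay, the fraction of decays depositing a non-zero amount of energy, and
#' the mean number of scavenged OH hits per decay. Denominators always count
#' all decays, including those that deposited nothing anywhere.
#'
#' @param dataset A [track_dataset()] with at least one decay.
#' @return A tibble with columns `strand`, `base`, `mean_energy_per_decay`
#'   (eV), `frac_nonzero`, `mean_oh_hits`, of class `per_base_stats`.
#' @export
per_base_statistics <- function(dataset) {
  stopifnot(inherits(dataset, "track_dataset"))
  if (dataset$n_decays < 1L) abort("dataset has no decays")
  grid <- tidyr::expand_grid(strand = 0:1, base = seq_len(dataset$n_bases) - 1L)
  edep <- accumulate_energy(dataset) |>
    dplyr::summarise(
      total_energy = sum(.data$energy_eV),
      n_nonzero = dplyr::n(),
      .by = c("strand", "base")
    )
  oh <- oh_hits(dataset) |>
    dplyr::summarise(n_hits = dplyr::n(), .by = c("strand", "base"))
  out <- grid |>
    dplyr::left_join(edep, by = c("strand", "base")) |>
    dplyr::left_join(oh, by = c("strand", "base")) |>
    dplyr::mutate(
      mean_energy_per_decay = tidyr::replace_na(.data$total_energy, 0) / dataset$n_decays,
      frac_nonzero = tidyr::replace_na(.data$n_nonzero, 0L) / dataset$n_decays,
      mean_oh_hits = tidyr::replace_na(.data$n_hits, 0L) / dataset$n_decays
    ) |>
    dplyr::select("strand", "base", "mean_energy_per_decay", "frac_nonzero",
                  "mean_oh_hits")
  class(out) <- c("per_base_stats", class(out))
  out
}

#' Histogram of deposited energies
#'
#' Either the spectrum of energy deposited per individual interaction, or the
#' per-decay accumulated energy in one chosen base (non-zero deposits only) --
#' the two views used to explain discontinuities in yield-versus-threshold
#' curves. Bins are half-open `[lo, hi)` of fixed width. Bins lying entirely
#' below `flag_below` (default 0.25 eV, the usual cutoff under which
#' vibrational/elastic deposits dominate but contribute <1% of energy) are
#' flagged, not removed, so counts always conserve the number of records.
#'
#' @param dataset A [track_dataset()].
#' @param level `"per_interaction"` or `"per_decay_per_base"`.
#' @param base Base index, required for `"per_decay_per_base"`.
#' @param strand Strand restriction (default 0, the iodine-proximal strand);
#'   use `NULL` for both strands at `"per_interaction"` level.
#' @param bin_width Bin width in eV (> 0).
#' @param flag_below Energy cutoff in eV below which bins are flagged.
#' @return A tibble with columns `bin_lo`, `bin_hi`, `count`, `below_cutoff`,
#'   of class `energy_histogram`.
#' @export
energy_histogram <- function(dataset,
                             level = c("per_interaction", "per_decay_per_base"),
                             base = NULL, strand = 0L, bin_width = 1,
                             flag_below = 0.25) {
  stopifnot(inherits(dataset, "track_dataset"))
  level <- rlang::arg_match(level)
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0) {
    abort("`bin_width` must be a single positive number.")
  }
  if (level == "per_interaction") {
    vals <- interactions(dataset)
    if (!is.null(strand)) vals <- dplyr::filter(vals, .data$strand == .env$strand)
    vals <- vals$energy_eV
  } else {
    if (is.null(base)) abort("`base` is required for per_decay_per_base histograms.")
    acc <- accumulate_energy(dataset)
    vals <- dplyr::filter(acc, .data$base == .env$base,
                          .data$strand == .env$strand)$energy_eV
  }
  if (!length(vals)) {
    out <- tibble::tibble(bin_lo = numeric(), bin_hi = numeric(),
                          count = integer(), below_cutoff = logical())
  } else {
    idx <- floor(vals / bin_width)
    tab <- table(idx)
    lo <- as.numeric(names(tab)) * bin_width
    out <- tibble::tibble(
      bin_lo = lo,
      bin_hi = lo + bin_width,
      count = as.integer(tab),
      below_cutoff = lo + bin_width <= flag_below
    ) |>
      dplyr::arrange(.data$bin_lo)
  }
  class(out) <- c("energy_histogram", class(out))
  attr(out, "level") <- level
  attr(out, "base") <- base
  out
}
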