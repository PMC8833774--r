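#' Fragment-size distributions
#'
#' In the end-labelled assay, each decay contributes at most one detected
#' fragment, whose size is set by the strand break most distant from the
#' iodine (equivalently, closest to the labelled end): additional breaks
#' nearer the iodine do not change the detected fragment. Fragment classes
#' are therefore indexed by break-site base (0 = the iodine base), not by
#' physical fragment length; the mapping to a gel-band length is a fixed
#' offset. Two normalisation modes exist: `breaks_only` (fractions over
#' decays with at least one detected break -- what a gel measurement
#' provides) and `include_unbroken` (an extra unbroken-fraction entry, stored
#' with `site = NA`, so that entries sum to 1 over all decays).
#'
#' @param call A [break_calls()].
#' @param strand Strand index (default 0, the labelled/proximal strand).
#' @param max_base Most distant measured site; breaks beyond it are ignored
#'   (they do not affect the observed distribution).
#' @param mode `"breaks_only"` or `"include_unbroken"`.
#' @return A tibble with columns `site` (0..`max_base`, plus an `NA` row for
#'   the unbroken class in `include_unbroken` mode) and `fraction`, of class
#'   `fragment_distribution` with a `mode` attribute.
#' @export
fragment_distribution <- function(call, strand = 0L, max_base = NULL,
                                  mode = c("breaks_only", "include_unbroken")) {
  stopifnot(inherits(call, "break_calls"))
  mode <- rlang::arg_match(mode)
  max_base <- max_base %||% (call$n_bases - 1L)
  if (max_base >= call$n_bases) abort("max_base must be < n_bases")
  b <- dplyr::filter(call$breaks, .data$strand == .env$strand,
                     .data$base <= max_base)
  cls <- max_base_per_event(b$event_id, b$base, call$n_decays)
  counts <- tabulate(cls[cls >= 0L] + 1L, nbins = max_base + 1L)
  n_contrib <- sum(counts)
  if (mode == "breaks_only") {
    if (n_contrib == 0L) {
      abort("no events with a detected break; cannot form a breaks_only distribution")
    }
    fragment_distribution_tbl(0:max_base, counts / n_contrib, mode = mode)
  } else {
    fragment_distribution_tbl(
      c(0:max_base, NA_integer_),
      c(counts, call$n_decays - n_contrib) / call$n_decays,
      mode = mode
    )
  }
}

fragment_distribution_tbl <- function(site, fraction, mode, scavenging = NULL) {
  stopifnot(length(site) == length(fraction))
  if (any(fraction < 0)) abort("fragment fractions must be >= 0")
  if (abs(sum(fraction) - 1) > 1e-6) {
    abort("fragment fractions must sum to 1")
  }
  n_na <- sum(is.na(site))
  if (mode == "breaks_only" && n_na > 0) {
    abort("breaks_only distributions cannot contain an unbroken (NA site) entry")
  }
  if (mode == "include_unbroken" && n_na != 1L) {
    abort("include_unbroken distributions need exactly one unbroken (NA site) entry")
  }
  out <- tibble::tibble(site = as.integer(site), fraction = as.numeric(fraction)) |>
    dplyr::arrange(.data$site) # NA (unbroken) entry sorts last
  class(out) <- c("fragment_distribution", class(out))
  attr(out, "mode") <- mode
  if (!is.null(scavenging)) attr(out, "scavenging") <- scavenging
  out
}

#' Observed experimental fragment fractions
#'
#' Wraps digitized experimental fragment fractions (a `breaks_only`
#' distribution by construction: the assay only sees decays that produced a
#' detectable fragment) together with the scavenging condition of the
#' incubation. Fractions are renormalised to sum to exactly 1 to absorb
#' digitisation rounding.
#'
#' @param site Break-site indices (0-based).
#' @param fraction Observed fragment fractions.
#' @param scavenging `"high"` (DMSO; direct damage only) or `"low"` (direct
#'   plus OH-mediated indirect damage).
#' @return A `fragment_distribution` with attributes `mode = "breaks_only"`
#'   and `scavenging`.
#' @export
observed_fragments <- function(site, fraction, scavenging = c("high", "low")) {
  scavenging <- rlang::arg_match(scavenging)
  if (any(fraction < 0) || sum(fraction) <= 0) {
    abort("observed fractions must be >= 0 with positive sum")
  }
  fragment_distribution_tbl(site, fraction / sum(fraction),
                            mode = "breaks_only", scavenging = scavenging)
}

#' Analytic forward fragment model
#'
#' Under independent per-site breaking with probabilities `p_i`, the
#' probability that the most-distant detected break sits at site `i` is
#' `F_i = p_i * prod_{j > i} (1 - p_j)`, and the probability of no break at
#' all is `prod_j (1 - p_j)`. In `breaks_only` mode the `F_i` are
#' renormalised over the break classes.
#'
#' @param p A break profile: a `break_profile` tibble, a `base`/`p` data
#'   frame, or a bare numeric vector of per-base probabilities (see
#'   [as_break_profile()]).
#' @param mode `"breaks_only"` or `"include_unbroken"`.
#' @return A `fragment_distribution`.
#' @export
forward_fragment_model <- function(p, mode = c("breaks_only", "include_unbroken")) {
  mode <- rlang::arg_match(mode)
  prof <- as_break_profile(p)
  prof <- dplyr::arrange(prof, .data$base)
  pv <- prof$p
  stopifnot(all(pv >= 0 & pv <= 1))
  q <- 1 - pv
  # suffix[i] = prod_{j > i} q_j
  suffix <- c(rev(cumprod(rev(q)))[-1], 1)
  f <- pv * suffix
  unbroken <- prod(q)
  if (mode == "include_unbroken") {
    fragment_distribution_tbl(c(prof$base, NA_integer_), c(f, unbroken),
                              mode = mode)
  } else {
    if (sum(f) <= 0) abort("all break probabilities are zero; no break classes")
    fragment_distribution_tbl(prof$base, f / sum(f), mode = mode)
  }
}

#' Iterative fragment-to-break-probability correction
#'
#' Converts a fragment-size distribution back into per-site break
#' probabilities by correcting the fraction at each site for breaks at all
#' more distant sites, iterating from the most distant site inward:
#' `p_i = f_i / (1 - sum_{j > i} f_j)`, clipped to \[0, 1\].
#'
#' When the distribution carries the unbroken fraction (`include_unbroken`
#' mode) this inversion is exact: it recovers the generating profile of
#' [forward_fragment_model()] identically. When only detected fragments are
#' available (`breaks_only` mode, as in gel data) the running sum exhausts the
#' distribution at the innermost occupied site, forcing a corrected
#' probability of exactly 1 there regardless of the true underlying rate --
#' the normalisation degeneracy that makes absolute yields unrecoverable from
#' fragment data alone.
#'
#' @param f A `fragment_distribution` (or `site`/`fraction` data frame; mode
#'   is then taken from the `mode` attribute, defaulting to `breaks_only`).
#' @return A `break_profile` tibble of corrected probabilities over the
#'   distribution's sites.
#' @export
kandaiya_inverse <- function(f) {
  stopifnot(is.data.frame(f), all(c("site", "fraction") %in% names(f)))
  sites <- f$site[!is.na(f$site)]
  frac <- f$fraction[!is.na(f$site)]
  unbroken <- sum(f$fraction[is.na(f$site)])
  o <- order(sites)
  sites <- sites[o]; frac <- frac[o]
  # denominator 1 - sum_{j > i} f_j, evaluated in the cancellation-free form
  # unbroken + sum_{j <= i} f_j (a sum of small positive terms, so the
  # forward-model round trip stays exact even for vanishing denominators);
  # the literal form is kept only to detect genuinely degenerate inputs
  total <- sum(frac) + unbroken
  denom <- unbroken + cumsum(frac)
  denom_literal <- 1 - (total - cumsum(frac) - unbroken)
  p <- numeric(length(frac))
  eps <- 1e-9
  for (i in seq_along(frac)) {
    if (denom_literal[i] <= eps && frac[i] > eps) {
      abort(sprintf(
        "degenerate inversion at site %d: more-distant fractions already sum to 1",
        sites[i]))
    }
    p[i] <- if (denom[i] > 0) clamp01(frac[i] / denom[i]) else 0
  }
  new_break_profile(tibble::tibble(base = sites, p = p))
}

#' Log-scale sum-of-squares goodness of fit
#'
#' `SSE = sum_i (log f_i - log F_i)^2` over fragment-size bins, comparing an
#' observed distribution with a modelled one. Natural logarithms are used;
#' any other base rescales the SSE by a constant and leaves fit ranks
#' unchanged. Because the log of a zero fraction is undefined, bins where
#' either distribution is zero are excluded by default (their count is
#' attached as the `n_excluded` attribute); alternatively a pseudo-fraction
#' floor can be substituted for zeros.
#'
#' @param f_obs,f_model Fragment distributions over matching site ranges
#'   (unbroken entries are ignored; the comparison is over break classes).
#' @param zero_policy `"exclude"` (default) or `"floor"`.
#' @param floor Pseudo-fraction substituted for zeros under the `"floor"`
#'   policy; a natural choice is `1 / (10 * n_decays)`.
#' @return The SSE as a single number, with attribute `n_excluded`.
#' @export
sse_log <- function(f_obs, f_model, zero_policy = c("exclude", "floor"),
                    floor = NULL) {
  zero_policy <- rlang::arg_match(zero_policy)
  obs <- f_obs[!is.na(f_obs$site), c("site", "fraction")]
  mod <- f_model[!is.na(f_model$site), c("site", "fraction")]
  if (!setequal(obs$site, mod$site)) {
    abort("observed and modelled distributions cover different site ranges")
  }
  j <- dplyr::inner_join(obs, mod, by = "site", suffix = c("_obs", "_mod"))
  fo <- j$fraction_obs
  fm <- j$fraction_mod
  if (zero_policy == "floor") {
    if (is.null(floor) || floor <= 0) {
      abort("`floor` must be a positive pseudo-fraction under the floor policy")
    }
    fo <- pmax(fo, floor)
    fm <- pmax(fm, floor)
    n_excluded <- 0L
    keep <- rep(TRUE, length(fo))
  } else {
    keep <- fo > 0 & fm > 0
    n_excluded <- sum(!keep)
  }
  if (!any(keep)) abort("all bins excluded; SSE undefined")
  sse <- sum((log(fo[keep]) - log(fm[keep]))^2)
  attr(sse, "n_excluded") <- n_excluded
  sse
}
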