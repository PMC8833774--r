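# Internal helpers shared across modules.

# Deterministic child seed: mixes a master seed with an operation tag and an
# index (e.g. a grid point) so that every stochastic stage draws from its own
# reproducible stream. Kept inside 32-bit integer range.
derive_seed <- function(seed, tag, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  tag_num <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  val <- (abs(as.numeric(seed)) * 48271 + tag_num * 7919 + as.numeric(index) * 104729)
  as.integer(val %% 2147483629) + 1L
}

clamp01 <- function(x) pmin(1, pmax(0, x))

# Largest broken base per event via one vectorised assignment: rows must be
# ordered by base ascending so the last write per event wins.
max_base_per_event <- function(event_id, base, n_events) {
  cls <- rep(-1L, n_events)
  if (length(event_id)) {
    o <- order(base)
    cls[event_id[o] + 1L] <- base[o]
  }
  cls
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  as.integer(x)
}

#' Fraction of iodine-125 decayed after a given time
#'
#' Exponential decay of \eqn{^{125}}I (half-life 59.4 days). Incubations of
#' end-labelled DNA with incorporated \eqn{^{125}}I typically run for up to 20
#' days, over which roughly 20% of the iodine decays.
#'
#' @param t_days Elapsed time in days.
#' @param half_life_days Half-life in days (default 59.4 for \eqn{^{125}}I).
#' @return Fraction of atoms decayed, in \[0, 1\].
#' @examples
#' i125_decayed_fraction(20) # ~0.21
#' @export
i125_decayed_fraction <- function(t_days, half_life_days = 59.4) {
  stopifnot(all(t_days >= 0), half_life_days > 0)
  1 - 2^(-t_days / half_life_days)
}
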