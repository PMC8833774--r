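# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (explicit loops, no shared code with the package
# internals) so that agreement is a meaningful check.

`%||%` <- function(a, b) if (is.null(a)) b else a

# internal constructor, used to build arbitrary distributions in tests
new_fragment_distribution <- getFromNamespace("fragment_distribution_tbl",
                                              "iodamage")

# build a track_dataset from loose vectors
make_dataset <- function(event_id, strand, base, energy = NULL, oh = NULL,
                         n_decays, n_bases = 40L) {
  records <- tibble::tibble(
    event_id = as.integer(event_id), record_type = "EDEP",
    strand = as.integer(strand), base = as.integer(base),
    energy_eV = as.numeric(energy)
  )
  if (!is.null(oh)) {
    records <- dplyr::bind_rows(records, tibble::tibble(
      event_id = as.integer(oh$event_id), record_type = "OH",
      strand = as.integer(oh$strand), base = as.integer(oh$base),
      energy_eV = NA_real_
    ))
  }
  track_dataset(records, n_decays = n_decays, n_bases = n_bases)
}

# random small dataset: a few events, a few interactions each
random_small_dataset <- function(n_events = 5, n_bases = 12, max_records = 8) {
  n_rec <- sample(0:max_records, 1)
  if (n_rec == 0) {
    return(make_dataset(integer(), integer(), integer(), numeric(),
                        n_decays = n_events, n_bases = n_bases))
  }
  make_dataset(
    event_id = sample(0:(n_events - 1), n_rec, replace = TRUE),
    strand = sample(0:1, n_rec, replace = TRUE),
    base = sample(0:(n_bases - 1), n_rec, replace = TRUE),
    energy = runif(n_rec, 0.3, 50),
    n_decays = n_events, n_bases = n_bases
  )
}

# group-by-sum with explicit loops
brute_accumulate <- function(dataset) {
  rec <- dataset$records[dataset$records$record_type == "EDEP", ]
  out <- list()
  for (i in seq_len(nrow(rec))) {
    key <- paste(rec$event_id[i], rec$strand[i], rec$base[i])
    out[[key]] <- (out[[key]] %||% 0) + rec$energy_eV[i]
  }
  out
}

# threshold calling per site via the accumulated map
brute_threshold_breaks <- function(dataset, e_thresh) {
  acc <- brute_accumulate(dataset)
  keys <- names(acc)[vapply(acc, function(e) e > e_thresh, TRUE)]
  if (!length(keys)) {
    return(tibble::tibble(event_id = integer(), strand = integer(),
                          base = integer()))
  }
  parts <- do.call(rbind, lapply(strsplit(keys, " "), as.integer))
  tibble::tibble(event_id = parts[, 1], strand = parts[, 2], base = parts[, 3]) |>
    dplyr::arrange(event_id, strand, base)
}

# per-event most distant break (<= max_base) by explicit loop
brute_fragment_classes <- function(breaks, n_decays, max_base) {
  cls <- rep(NA_integer_, n_decays)
  for (e in unique(breaks$event_id)) {
    b <- breaks$base[breaks$event_id == e & breaks$base <= max_base]
    if (length(b)) cls[e + 1] <- max(b)
  }
  cls
}

# exhaustive maximum matching of opposite-strand breaks within sep
brute_max_dsb <- function(b0, b1, sep) {
  if (!length(b0) || !length(b1)) return(0L)
  best <- 0L
  for (j in seq_along(b1)) {
    if (abs(b0[1] - b1[j]) <= sep) {
      best <- max(best, 1L + brute_max_dsb(b0[-1], b1[-j], sep))
    }
  }
  max(best, brute_max_dsb(b0[-1], b1, sep))
}

brute_sse <- function(fo, fm) {
  s <- 0
  for (i in seq_along(fo)) {
    if (fo[i] > 0 && fm[i] > 0) s <- s + (log(fo[i]) - log(fm[i]))^2
  }
  s
}

# independent re-implementation of the cylinder-and-arches classifier,
# working in rotated per-slab coordinates rather than angle differences
brute_classify_one <- function(x, y, z, gp) {
  r <- sqrt(x^2 + y^2)
  i <- floor(z / gp$slab_thickness)
  if (i < 0 || i >= gp$n_bases || r >= gp$outer_radius) {
    return(list(region = "outside", base = NA, strand = NA))
  }
  if (r < gp$base_radius) return(list(region = "base", base = i, strand = NA))
  a <- -i * gp$twist_step * pi / 180
  xr <- cos(a) * x - sin(a) * y
  yr <- sin(a) * x + cos(a) * y
  ang <- atan2(yr, xr) * 180 / pi # strand 0 arc centred at 0, strand 1 at 180
  half <- gp$arc_width / 2
  d0 <- min(abs(ang), 360 - abs(ang))
  d1 <- abs(abs(ang) - 180)
  if (d0 < half || d1 < half) {
    list(region = "backbone", base = i, strand = if (d0 <= d1) 0L else 1L)
  } else {
    list(region = "outside", base = NA, strand = NA)
  }
}

# a random breaks-only fragment distribution over a random subset of sites
random_breaks_only_distribution <- function(max_sites = 20) {
  n <- sample(3:max_sites, 1)
  w <- rexp(n)
  w[sample(n, sample(0:(n - 2), 1))] <- 0 # some empty sites
  if (sum(w) == 0) w[1] <- 1
  new_fragment_distribution(0:(n - 1), w / sum(w), mode = "breaks_only")
}
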