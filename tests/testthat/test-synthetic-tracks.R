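test_that("generator handles degenerate configurations exactly", {
  # all rates zero: every event is an empty decay
  cfg0 <- generator_config(interaction_rate = rep(0, 40), oh_rate = rep(0, 40),
                           seed = 1)
  d0 <- generate_events(cfg0, 100)
  expect_equal(d0$n_decays, 100L)
  expect_equal(nrow(d0$records), 0L)

  # deterministic single 32 eV interaction at (strand 0, base 0)
  rate <- matrix(0, 2, 40)
  rate[1, 1] <- 1
  cfg1 <- generator_config(
    interaction_rate = rate, oh_rate = rep(0, 40),
    mixture = energy_mixture(continuum_weight = 0, tail_weight = 0,
                             peak_weights = 1, peak_means = 32, peak_sd = 0),
    count_law = "fixed", seed = 2
  )
  d1 <- generate_events(cfg1, 50)
  expect_equal(nrow(d1$records), 50L)
  expect_true(all(d1$records$strand == 0L & d1$records$base == 0L &
                    d1$records$energy_eV == 32))
  expect_equal(sort(unique(d1$records$event_id)), 0:49)
})

test_that("generator is deterministic given (config, n_events, seed)", {
  cfg <- generator_config(seed = 77)
  expect_identical(generate_events(cfg, 500), generate_events(cfg, 500))
  cfg2 <- generator_config(seed = 78)
  expect_false(identical(generate_events(cfg, 500)$records,
                         generate_events(cfg2, 500)$records))
})

test_that("generator rejects invalid rates and weights", {
  expect_error(generator_config(interaction_rate = rep(-1, 40), seed = 1),
               ">= 0")
  expect_error(energy_mixture(continuum_weight = 0.9), "sum to 1")
  expect_error(energy_mixture(continuum_weight = -0.1, tail_weight = 0.75),
               ">= 0")
  expect_error(generator_config(seed = 1, interaction_rate = rep(0.1, 5)),
               "40")
  expect_error(generator_config(), "mandatory")
})

test_that("generated statistics match the configured laws (LLN calibration)", {
  withr::local_seed(11)
  cfg <- generator_config(seed = 101)
  n <- 100000
  d <- generate_events(cfg, n)
  s <- per_base_statistics(d)
  mu <- mixture_mean(cfg$mixture)
  for (b in c(5L, 10L, 25L)) {
    lam <- cfg$interaction_rate[1, b + 1]
    # mean accumulated energy per decay = lambda * mixture mean
    got <- s$mean_energy_per_decay[s$strand == 0 & s$base == b]
    se <- sqrt(lam * (mu^2 + 150) / n) # generous second-moment bound
    expect_lt(abs(got - lam * mu), 3 * se)
    # fraction of decays with any deposit = 1 - P(Poisson(lambda) = 0)
    p_nz <- 1 - exp(-lam)
    got_nz <- s$frac_nonzero[s$strand == 0 & s$base == b]
    expect_lt(abs(got_nz - p_nz), 3 * sqrt(p_nz * (1 - p_nz) / n))
    # OH hits per decay
    lam_oh <- cfg$oh_rate[1, b + 1]
    got_oh <- s$mean_oh_hits[s$strand == 0 & s$base == b]
    expect_lt(abs(got_oh - lam_oh), 3 * sqrt(lam_oh / n))
  }
  # default calibration anchor: 5% of decays deposit energy in base 10
  expect_equal(s$frac_nonzero[s$strand == 0 & s$base == 10], 0.05,
               tolerance = 0.05)
})

test_that("energy accumulation is an additive group-by-sum", {
  d <- make_dataset(c(0, 0), c(0, 0), c(5, 5), c(10, 12), n_decays = 1)
  acc <- accumulate_energy(d)
  expect_equal(nrow(acc), 1L)
  expect_equal(acc$energy_eV, 22)
  expect_equal(acc$base, 5L)

  empty <- make_dataset(integer(), integer(), integer(), numeric(), n_decays = 3)
  expect_equal(nrow(accumulate_energy(empty)), 0L)
  dense <- accumulate_energy(empty, dense = TRUE)
  expect_equal(nrow(dense), 3L * 2L * 40L)
  expect_true(all(dense$energy_eV == 0))

  withr::local_seed(42)
  for (i in 1:25) {
    d <- random_small_dataset()
    acc <- accumulate_energy(d)
    oracle <- brute_accumulate(d)
    expect_equal(nrow(acc), length(oracle))
    for (j in seq_len(nrow(acc))) {
      key <- paste(acc$event_id[j], acc$strand[j], acc$base[j])
      expect_equal(acc$energy_eV[j], oracle[[key]])
    }
    # conservation: site sums equal the event's interaction total
    expect_equal(sum(acc$energy_eV),
                 sum(interactions(d)$energy_eV))
  }
})

test_that("per-base statistics use all decays in denominators", {
  d <- make_dataset(c(0, 0), c(0, 0), c(10, 10), c(12, 10), n_decays = 2)
  s <- per_base_statistics(d)
  expect_equal(s$mean_energy_per_decay[s$strand == 0 & s$base == 10], 11)
  expect_equal(s$frac_nonzero[s$strand == 0 & s$base == 10], 0.5)

  empty <- make_dataset(integer(), integer(), integer(), numeric(), n_decays = 5)
  s0 <- per_base_statistics(empty)
  expect_true(all(s0$mean_energy_per_decay == 0))
  expect_true(all(s0$frac_nonzero == 0))
  expect_true(all(s0$mean_oh_hits == 0))

  zero <- track_dataset(empty$records, n_decays = 0, n_bases = 40)
  expect_error(per_base_statistics(zero), "no decays")
})

test_that("energy histograms conserve counts and flag the sub-0.25 eV bin", {
  d <- make_dataset(0, 0, 3, 32, n_decays = 1)
  h <- energy_histogram(d, "per_interaction", bin_width = 1)
  expect_equal(h$count[h$bin_lo == 32], 1L)
  expect_equal(sum(h$count), 1L)

  empty <- make_dataset(integer(), integer(), integer(), numeric(), n_decays = 2)
  expect_equal(sum(energy_histogram(empty, "per_interaction")$count), 0L)

  cfg <- generator_config(seed = 5)
  d <- generate_events(cfg, 2000)
  h <- energy_histogram(d, "per_interaction", strand = NULL, bin_width = 0.5)
  expect_equal(sum(h$count), nrow(interactions(d)))
  h10 <- energy_histogram(d, "per_decay_per_base", base = 10L, bin_width = 1)
  acc <- accumulate_energy(d)
  expect_equal(sum(h10$count), sum(acc$base == 10 & acc$strand == 0))
  expect_error(energy_histogram(d, "per_decay_per_base"), "base")
  expect_error(energy_histogram(d, "per_interaction", bin_width = 0), "positive")

  hl <- energy_histogram(make_dataset(0, 0, 0, 0.1, n_decays = 1),
                         "per_interaction", bin_width = 0.25)
  expect_true(hl$below_cutoff[1])
  expect_equal(sum(hl$count), 1L)
})

test_that("per-interaction spectrum matches the configured mixture", {
  withr::local_seed(202)
  mix <- energy_mixture()
  cfg <- generator_config(seed = 303, mixture = mix)
  d <- generate_events(cfg, 5000)
  got <- interactions(d)$energy_eV
  # independent direct sampler of the same mixture, written out explicitly
  n <- length(got)
  comp <- sample(1:4, n, replace = TRUE, prob = c(0.5, 0.15, 0.15, 0.2))
  ref <- numeric(n)
  ref[comp == 1] <- runif(sum(comp == 1), 0.25, 12)
  ref[comp == 2] <- 12 + rexp(sum(comp == 2), 1 / 8)
  ref[comp == 3] <- rnorm(sum(comp == 3), 17, 0.3)
  ref[comp == 4] <- rnorm(sum(comp == 4), 32, 0.3)
  ks <- suppressWarnings(stats::ks.test(got, ref))
  expect_gt(ks$p.value, 1e-4)
  expect_equal(mean(got), mixture_mean(mix), tolerance = 0.02)
})

test_that("scored-event files round-trip and validate on read", {
  path <- withr::local_tempfile(fileext = ".tsv")
  cfg <- generator_config(seed = 9)
  d <- generate_events(cfg, 300)
  write_scored_events(d, path)
  d2 <- read_scored_events(path)
  expect_equal(d2$n_decays, d$n_decays)
  expect_equal(d2$n_bases, d$n_bases)
  expect_equal(as.data.frame(d2$records), as.data.frame(d$records))
  expect_equal(per_base_statistics(d2), per_base_statistics(d))

  # a minimal hand-written file: one interaction
  one <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("event_id\trecord_type\tstrand\tbase\tenergy_eV",
               "0\tEDEP\t0\t3\t17.5"), one)
  d1 <- read_scored_events(one)
  expect_equal(d1$n_decays, 1L)
  expect_equal(d1$records$energy_eV, 17.5)

  # out-of-range base index names the offending line
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("event_id\trecord_type\tstrand\tbase\tenergy_eV",
               "0\tEDEP\t0\t40\t17.5"), bad)
  expect_error(read_scored_events(bad, n_bases = 40), "line 2")

  # negative energy rejected
  neg <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("event_id\trecord_type\tstrand\tbase\tenergy_eV",
               "0\tEDEP\t0\t3\t-2"), neg)
  expect_error(read_scored_events(neg), "> 0 eV")

  # unparseable energy names the line
  mal <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("event_id\trecord_type\tstrand\tbase\tenergy_eV",
               "0\tEDEP\t0\t3\t17.5",
               "1\tEDEP\t0\t4\tzzz"), mal)
  expect_error(read_scored_events(mal), "line 3")

  # sub-0.25 eV deposits accepted with a message
  sub <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("event_id\trecord_type\tstrand\tbase\tenergy_eV",
               "0\tEDEP\t0\t3\t0.1"), sub)
  expect_message(read_scored_events(sub), "0.25 eV")

  # row order does not affect the dataset
  shuf <- withr::local_tempfile(fileext = ".tsv")
  lines <- readLines(path)
  meta <- grep("^#", lines)
  hdr <- meta[length(meta)] + 1L
  body <- lines[(hdr + 1):length(lines)]
  writeLines(c(lines[meta], lines[hdr], sample(body)), shuf)
  d3 <- read_scored_events(shuf)
  expect_equal(per_base_statistics(d3), per_base_statistics(d))
})
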