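test_that("threshold calling breaks sites strictly above Ethresh", {
  d <- make_dataset(c(0, 0, 0), c(0, 0, 0), c(0, 1, 2), c(40, 10, 0.5),
                    n_decays = 1)
  b <- call_direct_threshold(d, 17.5)
  expect_equal(nrow(b$breaks), 1L)
  expect_equal(b$breaks$base, 0L)
  expect_true(all(b$breaks$cause == "direct"))

  # zero threshold: every site with any deposit breaks
  b0 <- call_direct_threshold(d, 0)
  expect_equal(sort(b0$breaks$base), c(0L, 1L, 2L))

  # strictly greater: a deposit exactly at the threshold does not break
  dq <- make_dataset(0, 0, 0, 17.5, n_decays = 1)
  expect_equal(nrow(call_direct_threshold(dq, 17.5)$breaks), 0L)
})

test_that("threshold calling matches a brute-force per-site comparison", {
  withr::local_seed(51)
  for (i in 1:30) {
    d <- random_small_dataset()
    e <- runif(1, 0, 40)
    got <- call_direct_threshold(d, e)$breaks
    oracle <- brute_threshold_breaks(d, e)
    expect_equal(got[c("event_id", "strand", "base")],
                 oracle, ignore_attr = TRUE)
  }
})

test_that("window model interpolates break probability linearly", {
  # certainty above the upper bound
  d_hi <- make_dataset(0, 0, 0, 38.5, n_decays = 1)
  expect_equal(nrow(call_direct_window(d_hi, 5, 37.5, seed = 1)$breaks), 1L)
  # impossibility at or below the lower bound
  d_lo <- make_dataset(0, 0, 0, 5, n_decays = 1)
  expect_equal(nrow(call_direct_window(d_lo, 5, 37.5, seed = 1)$breaks), 0L)
  expect_error(call_direct_window(d_lo, 10, 10, seed = 1), "e_low < e_high")

  # a narrow window around E* reproduces the threshold model at E*
  withr::local_seed(52)
  d <- random_small_dataset(n_events = 10, max_records = 12)
  thr <- call_direct_threshold(d, 20)
  win <- call_direct_window(d, 20 - 1e-9, 20 + 1e-9, seed = 3)
  expect_equal(win$breaks, thr$breaks)

  # midway energy breaks with the interpolated probability
  e_mid <- 21.25 # (21.25 - 5) / 32.5 = 0.5
  d_mid <- make_dataset(0:499, 0, 0, rep(e_mid, 500), n_decays = 500)
  hits <- vapply(1:40, function(s) {
    nrow(call_direct_window(d_mid, 5, 37.5, seed = s)$breaks)
  }, 1)
  p_hat <- sum(hits) / (500 * 40)
  p_true <- (e_mid - 5) / 32.5
  expect_lt(abs(p_hat - p_true), 3 * sqrt(p_true * (1 - p_true) / (500 * 40)))
})

test_that("indirect breaks apply POH independently per OH hit", {
  oh <- list(event_id = c(0L, 1L), strand = c(0L, 1L), base = c(3L, 7L))
  d <- make_dataset(integer(), integer(), integer(), numeric(), oh = oh,
                    n_decays = 2)
  expect_equal(nrow(call_indirect(d, 0, seed = 1)$breaks), 0L)
  b1 <- call_indirect(d, 1, seed = 1)
  expect_equal(nrow(b1$breaks), 2L)
  expect_true(all(b1$breaks$cause == "indirect"))

  # two hits at one site combine as 1 - (1 - p)^2
  oh2 <- list(event_id = rep(0:999, each = 2), strand = 0L,
              base = 5L)
  d2 <- make_dataset(integer(), integer(), integer(), numeric(), oh = oh2,
                     n_decays = 1000)
  hits <- vapply(1:30, function(s) {
    nrow(call_indirect(d2, 0.16, seed = s)$breaks)
  }, 1)
  p_hat <- sum(hits) / (1000 * 30)
  p_true <- 1 - 0.84^2
  expect_lt(abs(p_hat - p_true), 3 * sqrt(p_true * (1 - p_true) / (1000 * 30)))
})

test_that("merging break calls is a per-event union", {
  d <- make_dataset(c(0, 1), c(0, 1), c(2, 8), c(30, 35), n_decays = 2)
  x <- call_direct_threshold(d, 17.5)
  empty <- break_calls(x$breaks[0, ], n_decays = 2, n_bases = 40)
  expect_equal(merge_breaks(x, empty)$breaks, x$breaks)
  expect_equal(merge_breaks(x, x)$breaks, x$breaks)
  expect_equal(merge_breaks(x, empty)$breaks, merge_breaks(empty, x)$breaks)

  oh <- list(event_id = 0L, strand = 1L, base = 9L)
  d_oh <- make_dataset(integer(), integer(), integer(), numeric(), oh = oh,
                       n_decays = 2)
  y <- call_indirect(d_oh, 1, seed = 1)
  m <- merge_breaks(x, y)
  expect_equal(nrow(m$breaks), nrow(x$breaks) + nrow(y$breaks))

  # direct wins when both causes claim one site
  z <- break_calls(tibble::tibble(event_id = 0L, strand = 0L, base = 2L,
                                  cause = "indirect"),
                   n_decays = 2, n_bases = 40)
  mz <- merge_breaks(x, z)
  expect_equal(nrow(mz$breaks), nrow(x$breaks))
  expect_equal(mz$breaks$cause[mz$breaks$base == 2], "direct")

  other <- break_calls(x$breaks, n_decays = 3, n_bases = 40)
  expect_error(merge_breaks(x, other), "mismatched")
})

test_that("SSB yield counts broken sites per decay", {
  d <- make_dataset(c(0, 0), c(0, 0), c(2, 9), c(30, 35), n_decays = 1)
  call <- call_direct_threshold(d, 17.5)
  expect_equal(ssb_yield(call, 0)$yield, 2)
  expect_equal(ssb_yield(call, 1)$yield, 0)
  empty <- break_calls(call$breaks[0, ], n_decays = 4, n_bases = 40)
  expect_equal(ssb_yield(empty, 0)$yield, 0)

  withr::local_seed(53)
  for (i in 1:20) {
    d <- random_small_dataset()
    call <- call_direct_threshold(d, 10)
    n0 <- 0
    for (j in seq_len(nrow(call$breaks))) {
      if (call$breaks$strand[j] == 0) n0 <- n0 + 1
    }
    expect_equal(ssb_yield(call, 0)$yield, n0 / d$n_decays)
  }
})

test_that("DSB pairing respects the 10-bp rule and matches exhaustive matching", {
  mk_call <- function(strand, base) {
    break_calls(tibble::tibble(event_id = 0L, strand = strand, base = base,
                               cause = "direct"), n_decays = 1, n_bases = 40)
  }
  expect_equal(dsb_yield(mk_call(c(0L, 1L), c(3L, 12L)))$yield, 1) # |3-12| = 9
  expect_equal(dsb_yield(mk_call(c(0L, 1L), c(0L, 11L)))$yield, 0) # |0-11| = 11
  expect_equal(dsb_yield(mk_call(c(0L, 1L), c(3L, 13L)))$yield, 1) # exactly 10

  withr::local_seed(54)
  for (i in 1:60) {
    n0 <- sample(0:4, 1); n1 <- sample(0:4, 1)
    b0 <- sort(sample(0:25, n0)); b1 <- sort(sample(0:25, n1))
    sep <- sample(c(3L, 10L), 1)
    call <- break_calls(
      tibble::tibble(event_id = 0L,
                     strand = rep(c(0L, 1L), c(n0, n1)),
                     base = c(b0, b1), cause = "direct"),
      n_decays = 1, n_bases = 40
    )
    expect_equal(dsb_yield(call, sep)$n_dsb, brute_max_dsb(b0, b1, sep))
  }
})

test_that("break profiles are per-decay break rates and sum to the SSB yield", {
  br <- break_calls(tibble::tibble(event_id = 0L, strand = 0L, base = 2L,
                                   cause = "direct"),
                    n_decays = 4, n_bases = 40)
  prof <- break_profile(br, 0, max_base = 10)
  expect_equal(prof$p[prof$base == 2], 0.25)
  expect_equal(sum(prof$p), 0.25)

  all_broken <- break_calls(
    tidyr::expand_grid(event_id = 0:2, strand = 0:1, base = 0:39) |>
      dplyr::mutate(cause = "direct"),
    n_decays = 3, n_bases = 40
  )
  expect_true(all(break_profile(all_broken, 0)$p == 1))

  # counting identity: sum_i p_i equals the SSB yield restricted to i <= max
  withr::local_seed(55)
  d <- generate_events(generator_config(seed = 56), 2000)
  call <- call_direct_threshold(d, 25)
  prof <- break_profile(call, 0, max_base = 15)
  restricted <- call$breaks[call$breaks$strand == 0 & call$breaks$base <= 15, ]
  expect_equal(sum(prof$p), nrow(restricted) / call$n_decays)
})

test_that("SSB yield is non-increasing in the threshold and DSB is bounded", {
  d <- generate_events(generator_config(seed = 57), 5000)
  grid <- seq(5, 40, by = 2.5)
  yields <- vapply(grid, function(e) {
    ssb_yield(call_direct_threshold(d, e), 0)$yield
  }, 1)
  expect_true(all(diff(yields) <= 0))

  # DSB cannot exceed the per-event minimum of the two strands' SSB counts
  call <- call_direct_threshold(d, 20)
  per_event <- call$breaks |>
    dplyr::summarise(n = dplyr::n(), .by = c("event_id", "strand")) |>
    tidyr::pivot_wider(names_from = "strand", values_from = "n",
                       values_fill = 0L, names_prefix = "s")
  bound <- sum(pmin(per_event$s0, per_event$s1))
  expect_lte(dsb_yield(call)$n_dsb, bound)
})

test_that("a 32 eV spectral peak produces a sharp yield drop past 32 eV", {
  d <- generate_events(generator_config(seed = 58), 20000)
  y <- yield_curves(d, grid = c(29, 31, 33, 35))
  drop_peak <- y$ssb_per_decay[2] - y$ssb_per_decay[3] # crossing the peak
  drop_flat <- y$ssb_per_decay[1] - y$ssb_per_decay[2] # inside the gap
  expect_gt(drop_peak, 5 * max(drop_flat, 1e-9))
})
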