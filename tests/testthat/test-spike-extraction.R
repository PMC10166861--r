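make_trace <- function(mat, fs = 30000) voltage_trace(mat, fs)

test_that("common-median subtraction removes the across-channel median", {
  # identical channels collapse to zero
  x <- matrix(rep(sin(seq(0, 10, length.out = 1000)), 4), nrow = 4,
              byrow = TRUE)
  out <- subtract_common_median(make_trace(x))
  expect_equal(max(abs(out$samples)), 0)
  # constant channels {1,2,3}: median 2 leaves {-1, 0, 1}
  y <- matrix(c(1, 2, 3), nrow = 3, ncol = 50)
  out2 <- subtract_common_median(make_trace(y))
  expect_equal(out2$samples[, 1], c(-1, 0, 1))
  # across-channel median of the output is identically 0 for random input
  set.seed(5)
  z <- matrix(rnorm(5 * 400), nrow = 5)
  out3 <- subtract_common_median(make_trace(z))
  expect_equal(max(abs(apply(out3$samples, 2, median))), 0)
  expect_warning(subtract_common_median(make_trace(z[1, , drop = FALSE])),
                 "channels")
})

test_that("bandpass filter passes the spike band and rejects DC and mains", {
  fs <- 30000
  t <- seq(0, 1, by = 1 / fs)
  sin1k <- matrix(sin(2 * pi * 1000 * t), nrow = 1)
  out <- bandpass_filter(make_trace(sin1k, fs))
  mid <- seq(round(0.2 * fs), round(0.8 * fs))  # avoid edge transients
  expect_gt(max(out$samples[1, mid]), 0.95)
  dc <- matrix(rep(1, length(t)), nrow = 1)
  out_dc <- bandpass_filter(make_trace(dc, fs))
  expect_lt(abs(mean(out_dc$samples[1, mid])), 1e-3)
  sin50 <- matrix(sin(2 * pi * 50 * t), nrow = 1)
  out50 <- bandpass_filter(make_trace(sin50, fs))
  expect_lt(max(abs(out50$samples[1, mid])), 0.1)
  expect_error(bandpass_filter(make_trace(sin1k, fs), high = 2e4),
               "Nyquist")
})

test_that("threshold detection ignores silence and pure noise", {
  zeros <- make_trace(matrix(0, nrow = 2, ncol = 3000))
  expect_equal(nrow(detect_spikes(zeros)$events), 0)
  noise <- withr::with_seed(8L, matrix(rnorm(2 * 30000 * 20), nrow = 2))
  det <- detect_spikes(make_trace(noise))
  # 9 x raw MAD is ~6.07 sigma; expected Gaussian crossings over 2 x 20 s
  # of white noise are well below one event
  expect_lte(nrow(det$events), 1)
})

test_that("embedded high-amplitude templates are recovered at their times", {
  cfg <- sim_config(seed = 17L)
  st <- seq(0.2, 19.8, by = 0.25)
  tr <- generate_voltage_trace(
    list(list(spike_times = st, channel = 1, amplitude_sd = 10)),
    cfg, duration = 20, n_channels = 2)
  det <- detect_spikes(bandpass_filter(tr))
  ev <- det$events[det$events$channel == "ch1", ]
  recovered <- vapply(st, function(s) any(abs(ev$time_s - s) <= 5e-4),
                      logical(1))
  expect_gte(mean(recovered), 0.99)
  expect_lte(sum(det$events$channel != "ch1"), 2)
})

test_that("waveform features match designed geometry and scale invariance", {
  fs <- 30000
  # symmetric triangular trough, total width 0.4 ms -> half-amplitude 0.2 ms
  n_half <- round(0.2e-3 * fs)
  tri <- c(seq(0, -1, length.out = n_half + 1),
           seq(-1, 0, length.out = n_half + 1)[-1],
           rep(0, 10), 0.2, rep(0, 5))
  f <- waveform_features(tri, fs)
  expect_equal(unname(f["half_amp_ms"]), 0.2, tolerance = 0.02)
  # designed trough-to-peak recovered within one sample
  tmpl <- waveform_template(fs, half_amp_ms = 0.25, t2p_ms = 0.6)
  f2 <- waveform_features(tmpl, fs)
  expect_equal(unname(f2["t2p_ms"]), 0.6, tolerance = 1000 / fs + 1e-9)
  expect_equal(unname(f2["half_amp_ms"]), 0.25, tolerance = 0.05)
  # amplitude invariance
  expect_equal(waveform_features(5 * tmpl, fs), f2)
  expect_error(waveform_features(seq(0, 1, length.out = 30), fs), "trough")
})

test_that("duplicate pruning removes the higher-refractory twin", {
  base <- poisson_train(5, 60, seed = 2L)
  base <- base[c(TRUE, diff(base) > 2.5e-3)]
  contaminate <- function(t, n_viol, seed) {
    extra <- withr::with_seed(seed, sample(t, n_viol)) + 1e-3
    sort(c(t, extra))
  }
  a <- contaminate(base, 2, 3L)   # refractory fraction ~0.004
  b <- contaminate(base, 4, 4L)   # ~0.008 -> must be the one removed
  spikes <- data.frame(unit_id = rep(c(1L, 2L), c(length(a), length(b))),
                       time_s = c(a, b))
  out <- remove_duplicates(spikes)
  expect_equal(out$kept, 1L)
  expect_equal(out$removed$unit_id, 2L)
  expect_gt(out$removed$shared_fraction, 0.10)
})

test_that("disjoint units are all retained", {
  spikes <- data.frame(unit_id = rep(1:2, each = 50),
                       time_s = c(seq(0.1, 5, length.out = 50),
                                  seq(0.105, 5.005, length.out = 50) + 10))
  out <- remove_duplicates(spikes)
  expect_equal(sort(out$kept), 1:2)
  expect_equal(nrow(out$removed), 0)
})

test_that("pruning matches the O(n^2) oracle and is idempotent", {
  base <- poisson_train(8, 40, seed = 11L)
  base <- base[c(TRUE, diff(base) > 2.5e-3)]
  # A shares ~20% of its spikes with B; A is dirtier
  a_shared <- withr::with_seed(12L, sort(sample(base, round(0.2 * length(base)))))
  a_own <- poisson_train(6.4, 40, seed = 13L) + 2.3e-4
  a <- sort(c(a_shared, a_own, a_shared[1:3] + 1e-3))  # refractory violations
  b <- base
  c_ <- poisson_train(5, 40, seed = 14L) + 120   # unrelated unit
  trains <- list(`1` = a, `2` = b, `3` = c_)
  spikes <- data.frame(unit_id = rep(1:3, times = lengths(trains)),
                       time_s = unlist(trains))
  out <- remove_duplicates(spikes)
  expect_setequal(as.character(out$kept), oracle_dedup(trains))
  expect_true(2L %in% out$kept)   # cleaner twin survives
  expect_false(1L %in% out$kept)
  # idempotence
  again <- remove_duplicates(out$spikes)
  expect_equal(sort(again$kept), sort(out$kept))
  expect_equal(nrow(again$removed), 0)
})

test_that("true-spike recall is insensitive to median/bandpass order", {
  # With few channels the referenced-then-filtered order suppresses the
  # heavy-tailed residual of per-sample median subtraction, so false-event
  # counts legitimately differ between orders; recall of real spikes must
  # not.
  cfg <- sim_config(seed = 23L)
  st <- seq(0.3, 9.7, by = 0.45)
  tr <- generate_voltage_trace(
    list(list(spike_times = st, channel = 2, amplitude_sd = 10)),
    cfg, duration = 10, n_channels = 4)
  d1 <- detect_spikes(bandpass_filter(subtract_common_median(tr)))
  d2 <- detect_spikes(subtract_common_median(bandpass_filter(tr)))
  recall <- function(d) {
    t_ch2 <- d$events$time_s[d$events$channel == "ch2"]
    mean(vapply(st, function(s) any(abs(t_ch2 - s) <= 5e-4), logical(1)))
  }
  expect_gte(recall(d1), 0.99)
  expect_gte(recall(d2), 0.99)
})
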