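test_that("episode timelines are sorted, disjoint and hit the target duty", {
  tl <- generate_episode_timeline("freezing", duration = 300, mean_len = 5,
                                  duty = 0.3, seed = 42L)
  expect_s3_class(tl, "episode_timeline")
  expect_true(all(tl$offset_s > tl$onset_s))
  expect_true(all(tl$onset_s >= 0) && all(tl$offset_s <= 300))
  expect_false(is.unsorted(tl$onset_s, strictly = TRUE))
  if (nrow(tl) > 1)
    expect_true(all(tl$onset_s[-1] >= tl$offset_s[-nrow(tl)]))
  # coverage against the brute-force union oracle, and within the duty band
  cov <- episode_coverage(tl)
  expect_equal(cov, oracle_coverage(tl, 300), tolerance = 0.01)
  expect_gt(cov, 0.2 * 300)
  expect_lt(cov, 0.4 * 300)
})

test_that("zero duty gives an empty timeline and bad inputs are rejected", {
  tl <- generate_episode_timeline("freezing", 300, 5, duty = 0, seed = 1L)
  expect_equal(nrow(tl), 0)
  expect_error(generate_episode_timeline("freezing", 300, 5, 1, 1L), "duty")
  expect_error(generate_episode_timeline("freezing", 300, -2, 0.3, 1L),
               "mean_len")
  expect_error(generate_episode_timeline("freezing", 300, 400, 0.3, 1L),
               "duration")
})

test_that("different seeds give different intervals but similar coverage", {
  tls <- lapply(1:30, function(s)
    generate_episode_timeline("freezing", 300, 5, 0.3, seed = s))
  expect_false(identical(tls[[1]]$onset_s, tls[[2]]$onset_s))
  covs <- vapply(tls, episode_coverage, numeric(1)) / 300
  # mean coverage over replicates near the duty cycle
  expect_equal(mean(covs), 0.3, tolerance = 0.05)
})

test_that("unit sessions are reproducible and strictly increasing", {
  cfg <- sim_config(n_units = 6, seed = 7L)
  a <- generate_unit_sessions(cfg)
  b <- generate_unit_sessions(cfg)
  expect_identical(a, b)
  by_train <- split(a$spikes$time_s,
                    list(a$spikes$unit_id, a$spikes$session), drop = TRUE)
  for (t in by_train) expect_false(is.unsorted(t, strictly = TRUE))
  # refractory dead time honored
  for (t in by_train) if (length(t) > 1) expect_true(all(diff(t) >= 2e-3))
})

test_that("class quotas are exact and every unit carries one label of each kind", {
  cfg <- sim_config(n_units = 200, seed = 3L)
  sim <- generate_unit_sessions(cfg)
  expect_equal(unname(table(sim$truth$class)[c("fear_specific",
                                               "pain_specific", "common",
                                               "unspecific")]),
               rep(50L, 4), ignore_attr = TRUE)
  expect_equal(nrow(sim$truth), 200)
  expect_true(all(sim$truth$phenotype %in% c("principal", "interneuron")))
  expect_true(all(sim$truth$base_rate_hz >= 2 & sim$truth$base_rate_hz <= 6))
})

test_that("gain-1 units show session log ratios centered on zero", {
  cfg <- sim_config(n_units = 60, episode_gain = 1, seed = 21L)
  sim <- generate_unit_sessions(cfg)
  r1 <- vapply(1:60, function(u) mean_rate(
    sim$spikes$time_s[sim$spikes$unit_id == u &
                        sim$spikes$session == "baseline"], c(0, 300)),
    numeric(1))
  r2 <- vapply(1:60, function(u) mean_rate(
    sim$spikes$time_s[sim$spikes$unit_id == u &
                        sim$spikes$session == "fear"], c(0, 300)),
    numeric(1))
  L <- log(r2 / r1)
  expect_lt(abs(mean(L)), 3 * stats::sd(L) / sqrt(60))
})

test_that("matched units gain the configured factor inside episodes", {
  cfg <- sim_config(n_units = 40, episode_gain = 3, refractory_ms = 0,
                    class_fractions = c(fear_specific = 1, pain_specific = 0,
                                        common = 0, unspecific = 0),
                    seed = 13L)
  sim <- generate_unit_sessions(cfg)
  tl <- sim$timelines$fear
  fear <- sim$spikes[sim$spikes$session == "fear", ]
  in_ep <- vapply(fear$time_s, function(t)
    any(t >= tl$onset_s & t < tl$offset_s), logical(1))
  t_in <- episode_coverage(tl)
  t_out <- cfg$session_durations[["fear"]] - t_in
  rate_in <- sum(in_ep) / t_in
  rate_out <- sum(!in_ep) / t_out
  # pooled over 40 units the Poisson error on the ratio is ~2%
  expect_equal(rate_in / rate_out, 3, tolerance = 0.1)
})

test_that("voltage traces have the requested noise level and visible spikes", {
  cfg <- sim_config(noise_sigma = 1e-5, seed = 31L)
  tr <- generate_voltage_trace(list(), cfg, duration = 4, n_channels = 2)
  expect_equal(unname(noise_sigma_mad(tr)), rep(1e-5, 2), tolerance = 0.02)
  st <- seq(0.1, 3.9, by = 0.1)
  tr2 <- generate_voltage_trace(
    list(list(spike_times = st, channel = 1, amplitude_sd = 10)),
    cfg, duration = 4, n_channels = 2)
  thr <- 9 * stats::mad(tr2$samples[1, ], constant = 1)
  peaks <- vapply(st, function(s) {
    idx <- round(s * cfg$fs) + 1
    max(abs(tr2$samples[1, (idx - 5):(idx + 5)]))
  }, numeric(1))
  expect_true(all(peaks > thr))
  gt <- attr(tr2, "ground_truth")
  expect_equal(gt$time_s, st)
})

test_that("degenerate voltage-trace inputs are handled", {
  cfg <- sim_config(seed = 1L)
  tr <- generate_voltage_trace(list(), cfg, duration = 0, n_channels = 3)
  expect_equal(ncol(tr$samples), 0)
  expect_error(generate_voltage_trace(
    list(list(spike_times = 1, channel = 1, amplitude_sd = -2)),
    cfg, duration = 2), "amplitude_sd")
})

test_that("count tables follow independence when no overlap is imposed", {
  dens <- c(fos = 5935, tag = 3028, dapi = 150000)
  tabs <- do.call(rbind, lapply(1:200, function(s)
    generate_count_table(dens, NULL, volume = 0.1, seed = s)))
  expect_true(all(tabs$n_double <= pmin(tabs$n_fos, tabs$n_tag)))
  # sampled means reproduce the density expectations
  expect_equal(mean(tabs$n_fos) / 0.1, 5935, tolerance = 0.02)
  expect_equal(mean(tabs$n_tag) / 0.1, 3028, tolerance = 0.02)
  # double-positive mean matches the analytic independence product
  expect_equal(mean(tabs$n_double), 5935 * 3028 / 150000 * 0.1,
               tolerance = 0.1)
})

test_that("count-table edge cases are enforced", {
  dens <- c(fos = 100, tag = 50, dapi = 1000)
  expect_equal(generate_count_table(dens, NULL, volume = 0, seed = 1L)$n_dapi,
               0L)
  expect_error(generate_count_table(c(fos = -1, tag = 1, dapi = 10), NULL,
                                    1, 1L), "densities")
  expect_error(generate_count_table(dens, true_overlap = 2, 1, 1L),
               "true_overlap")
})
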