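#' Simulation configuration for synthetic three-session recordings
#'
#' Bundles and validates every parameter of the synthetic-data generator.
#' The generator emulates a three-session recording design: a neutral
#' baseline context, a cued fear-recall session with intermittent freezing
#' episodes, and a capsaicin tonic-pain session with intermittent
#' nocifensive episodes. Each simulated unit belongs to one coding class
#' (fear-specific, pain-specific, common, or unspecific) and spikes as an
#' inhomogeneous Poisson process whose rate is multiplied by `episode_gain`
#' inside behavioral episodes of its matched state(s).
#'
#' @param n_units Number of units to simulate.
#' @param class_fractions Named numeric vector of class probabilities for
#'   `fear_specific`, `pain_specific`, `common`, `unspecific`; must sum to 1.
#'   Units are assigned by largest-remainder quota so realized counts match
#'   the fractions as closely as integer counts allow.
#' @param base_rate_range Two-element vector, Hz. Per-unit base rates are
#'   drawn uniformly from this interval. The default 2-6 Hz keeps the
#'   Poisson counting noise of per-session rate estimates roughly
#'   homogeneous across units, so the pooled same-state log-ratio null is
#'   approximately normal, which is what the 2-s.d. global threshold assumes.
#' @param episode_gain Multiplicative rate factor inside matched episodes
#'   (>= 1). `episode_gain = 1` yields a null population with no coding.
#' @param session_durations Named numeric vector of session lengths in
#'   seconds for `baseline`, `fear`, `pain`.
#' @param episode_stats Named list with per-state episode statistics:
#'   `mean_len` (mean episode length, s) and `duty` (fraction of session
#'   time covered) for `freezing` and `nocifensive`.
#' @param pn_in_fraction Probability that a unit is an interneuron.
#' @param waveform_params Named list (`principal`, `interneuron`) of
#'   per-phenotype feature distributions; each holds `half_amp_ms`,
#'   `t2p_ms`, `rate_hz`, every entry a `c(mean, sd)` pair.
#' @param refractory_ms Absolute dead time enforced after each spike, ms.
#'   Set to 0 to disable.
#' @param noise_sigma Voltage-noise standard deviation for trace synthesis
#'   (volts).
#' @param fs Sampling rate for trace synthesis, Hz. Must exceed twice the
#'   upper band edge used in filtering (6 kHz).
#' @param paired_baseline If `TRUE`, a second neutral-context session
#'   (`baseline2`) is generated from the same base rates, mirroring the
#'   repeated same-state sessions used to calibrate the global null.
#' @param seed Integer seed; identical configurations and seeds give
#'   bit-identical output.
#'
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_units = 100,
                       class_fractions = c(fear_specific = 0.25,
                                           pain_specific = 0.25,
                                           common = 0.25,
                                           unspecific = 0.25),
                       base_rate_range = c(2, 6),
                       episode_gain = 3,
                       session_durations = c(baseline = 300,
                                             fear = 420,
                                             pain = 300),
                       episode_stats = list(
                         freezing = list(mean_len = 5, duty = 0.3),
                         nocifensive = list(mean_len = 5, duty = 0.3)),
                       pn_in_fraction = 0.115,
                       waveform_params = list(
                         principal = list(half_amp_ms = c(0.30, 0.05),
                                          t2p_ms = c(0.65, 0.12),
                                          rate_hz = c(2.5, 1.5)),
                         interneuron = list(half_amp_ms = c(0.15, 0.05),
                                            t2p_ms = c(0.29, 0.12),
                                            rate_hz = c(10, 2.5))),
                       refractory_ms = 2,
                       noise_sigma = 1e-5,
                       fs = 30000,
                       paired_baseline = TRUE,
                       seed = 1L) {
  stopifnot(n_units >= 1, length(base_rate_range) == 2)
  cls <- c("fear_specific", "pain_specific", "common", "unspecific")
  if (!all(cls %in% names(class_fractions)))
    stop("class_fractions must name all of: ", paste(cls, collapse = ", "))
  class_fractions <- class_fractions[cls]
  if (any(class_fractions < 0) || any(class_fractions > 1))
    stop("class fractions must lie in [0, 1]")
  if (abs(sum(class_fractions) - 1) > 1e-9)
    stop("class fractions must sum to 1 (within 1e-9)")
  if (episode_gain < 1) stop("episode_gain must be >= 1")
  if (any(session_durations <= 0)) stop("all session durations must be > 0")
  if (any(base_rate_range <= 0) || diff(base_rate_range) < 0)
    stop("base_rate_range must be positive and increasing")
  if (pn_in_fraction < 0 || pn_in_fraction > 1)
    stop("pn_in_fraction must be a probability")
  if (refractory_ms < 0) stop("refractory_ms must be >= 0")
  if (noise_sigma <= 0) stop("noise_sigma must be > 0")
  if (fs <= 2 * 6000) stop("fs must exceed twice the 6 kHz filter band edge")
  for (st in c("freezing", "nocifensive")) {
    es <- episode_stats[[st]]
    if (is.null(es$mean_len) || is.null(es$duty))
      stop("episode_stats$", st, " must provide mean_len and duty")
  }
  structure(list(n_units = as.integer(n_units),
                 class_fractions = class_fractions,
                 base_rate_range = base_rate_range,
                 episode_gain = episode_gain,
                 session_durations = session_durations,
                 episode_stats = episode_stats,
                 pn_in_fraction = pn_in_fraction,
                 waveform_params = waveform_params,
                 refractory_ms = refractory_ms,
                 noise_sigma = noise_sigma,
                 fs = fs,
                 paired_baseline = isTRUE(paired_baseline),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a behavioral-episode timeline
#'
#' Simulates intermittent behavioral bouts (freezing or nocifensive
#' episodes) as an alternating renewal process with exponential on and off
#' durations, truncated at the session boundaries. The off-duration mean is
#' chosen so that the long-run fraction of time spent inside episodes
#' equals `duty`; the initial phase is drawn from the stationary occupancy
#' so short sessions are unbiased.
#'
#' @param state Episode label, e.g. `"freezing"` or `"nocifensive"`.
#' @param duration Session length, s.
#' @param mean_len Mean episode length, s.
#' @param duty Target fraction of time covered by episodes, in `[0, 1)`.
#'   `duty = 0` returns an empty timeline.
#' @param seed Integer seed.
#'
#' @return A data frame of class `"episode_timeline"` with columns
#'   `state`, `onset_s`, `offset_s`; intervals are sorted, non-overlapping
#'   and contained in `[0, duration]`.
#' @export
generate_episode_timeline <- function(state, duration, mean_len, duty, seed) {
  if (duty < 0 || duty >= 1) stop("duty must lie in [0, 1)")
  if (mean_len <= 0) stop("mean_len must be > 0")
  if (duration <= 0) stop("duration must be > 0")
  empty <- data.frame(state = character(), onset_s = numeric(),
                      offset_s = numeric())
  if (duty == 0) return(as_episode_timeline(empty, state))
  if (mean_len >= duration)
    stop("mean_len must be smaller than the session duration")
  mean_off <- mean_len * (1 - duty) / duty
  onsets <- numeric(0); offsets <- numeric(0)
  withr::with_seed(seed, {
    inside <- stats::runif(1) < duty
    t <- 0
    while (t < duration) {
      if (inside) {
        len <- stats::rexp(1, rate = 1 / mean_len)
        onsets <- c(onsets, t)
        offsets <- c(offsets, min(t + len, duration))
        t <- t + len
      } else {
        t <- t + stats::rexp(1, rate = 1 / mean_off)
      }
      inside <- !inside
    }
  })
  as_episode_timeline(
    data.frame(state = rep(state, length(onsets)),
               onset_s = onsets, offset_s = offsets), state)
}

as_episode_timeline <- function(df, state) {
  attr(df, "state") <- state
  class(df) <- c("episode_timeline", "data.frame")
  validate_timeline(df)
  df
}

validate_timeline <- function(df) {
  if (nrow(df) == 0) return(invisible(df))
  if (any(df$offset_s <= df$onset_s))
    stop("episode offsets must exceed onsets (rows: ",
         paste(which(df$offset_s <= df$onset_s), collapse = ", "), ")")
  if (is.unsorted(df$onset_s, strictly = TRUE))
    stop("episode onsets must be strictly increasing")
  if (nrow(df) > 1 && any(df$onset_s[-1] < df$offset_s[-nrow(df)])) {
    bad <- which(df$onset_s[-1] < df$offset_s[-nrow(df)])
    stop("overlapping episodes (rows: ",
         paste(bad + 1, collapse = ", "), ")")
  }
  invisible(df)
}

#' Total time covered by a timeline's episodes
#' @param timeline An `episode_timeline` data frame.
#' @return Covered time in seconds.
#' @export
episode_coverage <- function(timeline) {
  if (nrow(timeline) == 0) return(0)
  sum(timeline$offset_s - timeline$onset_s)
}

## Piecewise-constant-rate Poisson sampler with optional absolute dead time.
## breaks: m+1 increasing knots; rates: m segment rates (Hz).
sim_piecewise_poisson <- function(breaks, rates, refractory_s = 0) {
  times <- unlist(lapply(seq_along(rates), function(i) {
    len <- breaks[i + 1] - breaks[i]
    n <- stats::rpois(1, rates[i] * len)
    if (n == 0) return(numeric(0))
    breaks[i] + sort(stats::runif(n, 0, len))
  }))
  times <- sort(times)
  if (refractory_s > 0 && length(times) > 1)
    times <- enforce_dead_time(times, refractory_s)
  times
}

## Remove spikes closer than dead_s to the previous *retained* spike.
## Iterative vectorized sweep: each pass removes the first violator of
## every violation run; converges in at most max-run-length passes.
enforce_dead_time <- function(times, dead_s) {
  repeat {
    bad <- which(diff(times) < dead_s) + 1L
    if (!length(bad)) return(times)
    times <- times[-bad[c(TRUE, diff(bad) > 1L)]]
  }
}

## Rate profile of a unit within one session: base rate everywhere, times
## gain inside matched episodes.
session_rate_breaks <- function(duration, base_rate, gain, timeline) {
  if (is.null(timeline) || nrow(timeline) == 0 || gain == 1)
    return(list(breaks = c(0, duration), rates = base_rate))
  on <- pmin(timeline$onset_s, duration)
  off <- pmin(timeline$offset_s, duration)
  knots <- sort(unique(c(0, on, off, duration)))
  mids <- (knots[-1] + knots[-length(knots)]) / 2
  inside <- vapply(mids, function(m) any(m >= on & m < off), logical(1))
  list(breaks = knots, rates = ifelse(inside, base_rate * gain, base_rate))
}

#' Generate ground-truth-labeled spike trains over three sessions
#'
#' For each unit: a coding class is assigned by largest-remainder quota
#' from `config$class_fractions`, a base rate is drawn uniformly from
#' `config$base_rate_range`, and spikes are drawn as an inhomogeneous
#' Poisson process in every session. The rate is multiplied by
#' `config$episode_gain` inside freezing episodes (fear session) for
#' fear-specific and common units, and inside nocifensive episodes (pain
#' session) for pain-specific and common units; unspecific units never
#' gain. A 2-ms absolute dead time (configurable) is applied after each
#' spike. Waveform phenotypes (principal vs interneuron) and their feature
#' values are drawn from `config$waveform_params`.
#'
#' @param config A [sim_config()] object.
#'
#' @return A list with elements
#'   \describe{
#'     \item{`spikes`}{data frame `unit_id`, `session`, `time_s` (sorted by
#'       unit, session, time).}
#'     \item{`timelines`}{list with `fear` (freezing) and `pain`
#'       (nocifensive) episode timelines.}
#'     \item{`truth`}{per-unit ground truth: `unit_id`, `class`,
#'       `phenotype`, `base_rate_hz`, `gain`, `half_amp_ms`, `t2p_ms`.}
#'     \item{`config`}{the configuration used.}
#'   }
#' @export
generate_unit_sessions <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_units
  counts <- quota_counts(config$class_fractions, n)
  classes <- rep(names(counts), counts)
  dur <- config$session_durations
  refr <- config$refractory_ms / 1000
  es <- config$episode_stats
  tl_fear <- generate_episode_timeline("freezing", dur[["fear"]],
                                       es$freezing$mean_len,
                                       es$freezing$duty,
                                       seed = config$seed + 1L)
  tl_pain <- generate_episode_timeline("nocifensive", dur[["pain"]],
                                       es$nocifensive$mean_len,
                                       es$nocifensive$duty,
                                       seed = config$seed + 2L)
  sessions <- c("baseline", if (config$paired_baseline) "baseline2",
                "fear", "pain")
  out <- withr::with_seed(config$seed, {
    classes <- sample(classes)
    base_rate <- stats::runif(n, config$base_rate_range[1],
                              config$base_rate_range[2])
    pheno <- ifelse(stats::runif(n) < config$pn_in_fraction,
                    "interneuron", "principal")
    wf <- t(vapply(pheno, function(p) {
      wp <- config$waveform_params[[p]]
      c(half_amp_ms = max(0.05, stats::rnorm(1, wp$half_amp_ms[1],
                                             wp$half_amp_ms[2])),
        t2p_ms = max(0.08, stats::rnorm(1, wp$t2p_ms[1], wp$t2p_ms[2])))
    }, c(half_amp_ms = 0, t2p_ms = 0)))
    spikes <- vector("list", n * length(sessions))
    k <- 0
    for (u in seq_len(n)) {
      gains <- c(baseline = 1, baseline2 = 1,
                 fear = if (classes[u] %in% c("fear_specific", "common"))
                   config$episode_gain else 1,
                 pain = if (classes[u] %in% c("pain_specific", "common"))
                   config$episode_gain else 1)
      for (s in sessions) {
        tl <- switch(s, fear = tl_fear, pain = tl_pain, NULL)
        prof <- session_rate_breaks(dur[[sub("2$", "", s)]], base_rate[u],
                                    gains[[s]], tl)
        tt <- sim_piecewise_poisson(prof$breaks, prof$rates, refr)
        k <- k + 1
        spikes[[k]] <- if (length(tt))
          data.frame(unit_id = u, session = s, time_s = tt) else NULL
      }
    }
    list(spikes = do.call(rbind, spikes),
         truth = data.frame(unit_id = seq_len(n), class = classes,
                            phenotype = pheno,
                            base_rate_hz = base_rate,
                            gain = config$episode_gain,
                            half_amp_ms = unname(wf[, "half_amp_ms"]),
                            t2p_ms = unname(wf[, "t2p_ms"])))
  })
  rownames(out$spikes) <- NULL
  list(spikes = out$spikes,
       timelines = list(fear = tl_fear, pain = tl_pain),
       truth = out$truth,
       config = config)
}

## Largest-remainder apportionment of n among fractions.
quota_counts <- function(fractions, n) {
  raw <- fractions * n
  base <- floor(raw)
  short <- n - sum(base)
  if (short > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(fractions))
}

#' Biphasic extracellular waveform template
#'
#' Builds a trough-then-peak template parameterized directly by the two
#' waveform features used for cell typing, so feature-recovery ground truth
#' is exact by construction: a negative Gaussian trough whose full width at
#' half depth equals `half_amp_ms`, followed by a positive Gaussian bump
#' peaking `t2p_ms` after the trough at 30% of the trough depth.
#'
#' @param fs Sampling rate, Hz.
#' @param half_amp_ms Designed half-amplitude (half-depth) duration, ms.
#' @param t2p_ms Designed trough-to-peak time, ms.
#' @param amplitude Trough depth in volts (positive number).
#' @return Numeric vector; element `attr(, "trough_index")` marks the trough.
#' @export
waveform_template <- function(fs, half_amp_ms = 0.25, t2p_ms = 0.5,
                              amplitude = 1) {
  if (amplitude <= 0) stop("amplitude must be > 0")
  tau1 <- (half_amp_ms / 1000) / (2 * sqrt(log(2)))
  tau2 <- tau1 * 1.5
  span <- (t2p_ms / 1000) + 4 * tau2
  t <- seq(-4 * tau1, span, by = 1 / fs)
  w <- -amplitude * exp(-(t / tau1)^2) +
    0.3 * amplitude * exp(-((t - t2p_ms / 1000) / tau2)^2)
  structure(w, trough_index = which.min(w))
}

#' Synthesize a multi-channel voltage trace from spike trains
#'
#' Adds biphasic templates at known spike times on assigned channels on top
#' of white Gaussian noise of standard deviation `config$noise_sigma`.
#' Template amplitudes are expressed as multiples of the noise sigma so
#' detectability is controlled directly.
#'
#' @param units A list of unit descriptions; each a list with
#'   `spike_times` (s), `channel` (1-based index), `amplitude_sd`
#'   (trough depth in noise-sigma units, > 0), and optionally
#'   `half_amp_ms`, `t2p_ms`.
#' @param config A [sim_config()] (uses `fs`, `noise_sigma`, `seed`).
#' @param duration Trace length, s. `0` gives an empty trace.
#' @param n_channels Number of channels.
#' @return A [voltage_trace()] with attribute `ground_truth`: a data frame
#'   of inserted spike times and channels.
#' @export
generate_voltage_trace <- function(units, config, duration, n_channels = 4) {
  stopifnot(inherits(config, "sim_config"))
  fs <- config$fs
  n_samp <- floor(duration * fs)
  if (n_samp == 0) {
    tr <- voltage_trace(matrix(numeric(0), nrow = n_channels, ncol = 0), fs)
    attr(tr, "ground_truth") <-
      data.frame(unit = integer(), time_s = numeric(), channel = integer())
    return(tr)
  }
  for (u in units) {
    if (is.null(u$amplitude_sd) || u$amplitude_sd <= 0)
      stop("each unit needs a positive amplitude_sd")
    if (u$channel < 1 || u$channel > n_channels)
      stop("unit channel out of range")
  }
  x <- withr::with_seed(config$seed, {
    x <- matrix(stats::rnorm(n_channels * n_samp, sd = config$noise_sigma),
                nrow = n_channels)
    for (ui in seq_along(units)) {
      u <- units[[ui]]
      tmpl <- waveform_template(fs,
                                half_amp_ms = u$half_amp_ms %||% 0.25,
                                t2p_ms = u$t2p_ms %||% 0.5,
                                amplitude = u$amplitude_sd * config$noise_sigma)
      ti <- attr(tmpl, "trough_index")
      L <- length(tmpl)
      for (st in u$spike_times) {
        centre <- round(st * fs) + 1L
        idx <- (centre - ti + 1L):(centre - ti + L)
        ok <- idx >= 1L & idx <= n_samp
        if (!any(ok)) next
        x[u$channel, idx[ok]] <- x[u$channel, idx[ok]] + tmpl[ok]
      }
    }
    x
  })
  gt <- do.call(rbind, lapply(seq_along(units), function(ui) {
    u <- units[[ui]]
    keep <- u$spike_times >= 0 & u$spike_times <= duration
    if (!any(keep)) return(NULL)
    data.frame(unit = ui, time_s = u$spike_times[keep], channel = u$channel)
  }))
  if (is.null(gt))
    gt <- data.frame(unit = integer(), time_s = numeric(), channel = integer())
  tr <- voltage_trace(x, fs)
  attr(tr, "ground_truth") <- gt
  tr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a synthetic dual-label cell-count table
#'
#' Samples per-region counts of Fos-positive, tag-positive (e.g. mCherry),
#' double-positive and DAPI nuclei from Poisson distributions around
#' density expectations, for testing the overlap statistics. Under
#' `true_overlap = NULL` (independent labeling) the double-positive
#' expectation is the independence product `fos * tag / dapi`; a numeric
#' `true_overlap` sets the expected double-positive fraction of all DAPI
#' nuclei directly, so values above the independence product
#' `(fos/dapi) * (tag/dapi)` simulate positive co-labeling.
#'
#' @param densities Named vector with `fos`, `tag`, `dapi` cell densities,
#'   cells per mm^3 (all >= 0).
#' @param true_overlap Either `NULL` (independent labeling) or the
#'   expected double-positive fraction of DAPI nuclei, in `[0, 1]`.
#' @param volume Sampled tissue volume, mm^3; `0` yields all-zero counts.
#' @param seed Integer seed.
#' @param region Region label for the table.
#' @return A one-row data frame with columns `region`, `n_fos`, `n_tag`,
#'   `n_double`, `n_dapi`, `volume_mm3`.
#' @export
generate_count_table <- function(densities, true_overlap = NULL, volume,
                                 seed, region = "PL") {
  need <- c("fos", "tag", "dapi")
  if (!all(need %in% names(densities)))
    stop("densities must name fos, tag and dapi")
  if (any(densities < 0)) stop("densities must be >= 0")
  if (volume < 0) stop("volume must be >= 0")
  if (!is.null(true_overlap) && (true_overlap < 0 || true_overlap > 1))
    stop("true_overlap must lie in [0, 1]")
  if (volume == 0) {
    return(data.frame(region = region, n_fos = 0L, n_tag = 0L,
                      n_double = 0L, n_dapi = 0L, volume_mm3 = 0))
  }
  withr::with_seed(seed, {
    n_dapi <- stats::rpois(1, densities[["dapi"]] * volume)
    n_fos <- stats::rpois(1, densities[["fos"]] * volume)
    n_tag <- stats::rpois(1, densities[["tag"]] * volume)
    n_fos <- min(n_fos, n_dapi)
    n_tag <- min(n_tag, n_dapi)
    mu_double <- if (is.null(true_overlap)) {
      if (densities[["dapi"]] > 0)
        densities[["fos"]] * densities[["tag"]] * volume /
          densities[["dapi"]] else 0
    } else {
      true_overlap * densities[["dapi"]] * volume
    }
    n_double <- min(stats::rpois(1, mu_double), n_fos, n_tag)
    data.frame(region = region, n_fos = n_fos, n_tag = n_tag,
               n_double = n_double, n_dapi = n_dapi, volume_mm3 = volume)
  })
}
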