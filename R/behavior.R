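#' Sliding-window binned firing rates
#'
#' Mean spike rate in overlapping windows (default 0.8 s wide, advanced in
#' 0.4-s steps). Bin onsets tile the span; only bins fully contained in
#' the span are emitted.
#'
#' @param spike_times Spike times, s.
#' @param span `c(start, end)` interval to tile, s.
#' @param width Bin width, s.
#' @param step Bin step, s; `0 < step <= width`.
#' @param normalize_to Optional reference rate (Hz); if given, a
#'   `norm_rate` column of rates divided by it is added (heat-map display
#'   normalization to the baseline-session mean).
#' @return Data frame of class `"binned_rates"`: `onset_s`, `offset_s`,
#'   `rate_hz` (count in `[onset, onset + width)` over `width`), plus
#'   `norm_rate` when requested.
#' @export
bin_rates <- function(spike_times, span, width = 0.8, step = 0.4,
                      normalize_to = NULL) {
  if (width <= 0 || step <= 0 || step > width)
    stop("need width > 0 and 0 < step <= width")
  if (diff(span) < width)
    stop("span is shorter than one bin width")
  onsets <- seq(span[1], span[2] - width, by = step)
  t <- sort(spike_times)
  # count in [onset, onset + width): #{t < offset} - #{t < onset}
  counts <- findInterval(onsets + width, t, left.open = TRUE) -
    findInterval(onsets, t, left.open = TRUE)
  out <- data.frame(onset_s = onsets, offset_s = onsets + width,
                    rate_hz = counts / width)
  if (!is.null(normalize_to)) out$norm_rate <- out$rate_hz / normalize_to
  class(out) <- c("binned_rates", "data.frame")
  attr(out, "width") <- width
  attr(out, "step") <- step
  out
}

#' Assign bins to in-episode and out-of-episode groups
#'
#' A bin is `"in"` iff both its onset and offset fall inside a single
#' behavioral episode, `"out"` iff both fall outside all episodes, and
#' `"excluded"` otherwise (bins straddling an episode boundary).
#'
#' @param bins A [bin_rates()] data frame.
#' @param timeline An `episode_timeline` data frame (possibly empty, in
#'   which case every bin is `"out"`).
#' @return Factor of length `nrow(bins)` with levels `in`, `out`,
#'   `excluded`.
#' @export
assign_bins <- function(bins, timeline) {
  if (nrow(timeline) == 0)
    return(factor(rep("out", nrow(bins)), levels = c("in", "out", "excluded")))
  inside <- function(t) {
    idx <- findInterval(t, timeline$onset_s)
    idx >= 1 & t <= timeline$offset_s[pmax(idx, 1)]
  }
  # both ends inside the *same* episode: the episode index must agree
  on_idx <- findInterval(bins$onset_s, timeline$onset_s)
  off_idx <- findInterval(bins$offset_s, timeline$onset_s)
  on_in <- inside(bins$onset_s)
  off_in <- inside(bins$offset_s)
  grp <- ifelse(on_in & off_in & on_idx == off_idx, "in",
                ifelse(!on_in & !off_in, "out", "excluded"))
  factor(grp, levels = c("in", "out", "excluded"))
}

#' Randomized permutation test for a difference in mean binned rate
#'
#' Tests whether the behavior-matched (in-episode) binned rates exceed the
#' reference bins (the binned rates of the unstimulated baseline period).
#' The observed statistic is `mean(x) - mean(y)`; the null is built by
#' pooling both groups and re-splitting at the original group sizes
#' `n_perm` times. The one-sided p-value is
#' `(1 + #\{null >= observed\}) / (n_perm + 1)`. The effect size is the
#' standardized mean difference with the pooled standard deviation as
#' denominator.
#'
#' @param x In-episode (behavior-matched) bin rates.
#' @param y Reference bin rates.
#' @param n_perm Number of permutations (>= 999).
#' @param seed Integer seed; fixed seeds give reproducible p-values.
#' @param block Optional block length (in bins) for block permutation of
#'   the pooled vector, for users who want exchangeability of overlapping
#'   bins; `NULL` (default) permutes single bins, matching the published
#'   analysis.
#' @return A list: `p`, `effect`, `observed`, `n_perm`.
#' @export
permutation_test <- function(x, y, n_perm = 10000, seed = 1L, block = NULL) {
  if (length(x) == 0 || length(y) == 0)
    stop("permutation test undefined for an empty group")
  if (n_perm < 999) stop("n_perm must be >= 999")
  obs <- mean(x) - mean(y)
  nx <- length(x); ny <- length(y)
  pooled_var <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) /
    (nx + ny - 2)
  if (pooled_var == 0) {
    if (obs == 0) return(list(p = 1, effect = 0, observed = 0,
                              n_perm = n_perm))
    # deterministic separation: no permutation can change group means
    eff <- sign(obs) * Inf
  } else {
    eff <- obs / sqrt(pooled_var)
  }
  z <- c(x, y)
  n <- nx + ny
  tot <- sum(z)
  null_ge <- withr::with_seed(seed, {
    if (is.null(block)) {
      draws <- vapply(seq_len(n_perm), function(i) {
        s1 <- sum(z[sample.int(n, nx)])
        s1 / nx - (tot - s1) / ny
      }, numeric(1))
    } else {
      nb <- ceiling(n / block)
      draws <- vapply(seq_len(n_perm), function(i) {
        ord <- unlist(lapply(sample.int(nb), function(b) {
          seq.int((b - 1) * block + 1, min(b * block, n))
        }))
        s1 <- sum(z[ord[seq_len(nx)]])
        s1 / nx - (tot - s1) / ny
      }, numeric(1))
    }
    sum(draws >= obs)
  })
  list(p = (1 + null_ge) / (n_perm + 1), effect = eff, observed = obs,
       n_perm = n_perm)
}

#' Classify behavior-locked coding from per-state test results
#'
#' A unit is significant for a state when its permutation p-value is below
#' `alpha` and its effect size exceeds `min_effect` (increases only).
#' Significant in fear only: `fear_specific`; pain only: `pain_specific`;
#' both: `common`; neither: `unspecific`.
#'
#' @param results Data frame with columns `unit_id`, `p_fear`,
#'   `effect_fear`, `p_pain`, `effect_pain`. Units with a missing state
#'   result are excluded with a message.
#' @param alpha Significance level (default the strict 0.001).
#' @param min_effect Minimum standardized effect size.
#' @return Data frame: `results` plus `sig_fear`, `sig_pain`, `category`.
#' @export
classify_behavior <- function(results, alpha = 0.001, min_effect = 0.5) {
  need <- c("unit_id", "p_fear", "effect_fear", "p_pain", "effect_pain")
  stopifnot(all(need %in% names(results)))
  miss <- is.na(results$p_fear) | is.na(results$p_pain)
  if (any(miss)) {
    message(sum(miss), " unit(s) excluded: missing a per-state test result")
    results <- results[!miss, , drop = FALSE]
  }
  sig_f <- results$p_fear < alpha & results$effect_fear > min_effect
  sig_p <- results$p_pain < alpha & results$effect_pain > min_effect
  results$sig_fear <- sig_f
  results$sig_pain <- sig_p
  results$category <- ifelse(sig_f & sig_p, "common",
                             ifelse(sig_f, "fear_specific",
                                    ifelse(sig_p, "pain_specific",
                                           "unspecific")))
  results
}

#' Behavior-episode-locked coding pipeline
#'
#' For every unit: bins the fear and pain sessions with the sliding
#' window, keeps the bins fully contained in freezing or nocifensive
#' episodes, and tests their mean rate against the binned rates of the
#' unstimulated baseline session with the randomized permutation test;
#' the two per-state results are then combined into coding categories.
#'
#' @param spikes Data frame `unit_id`, `session`, `time_s` with sessions
#'   `baseline`, `fear`, `pain`.
#' @param timelines List with `fear` (freezing) and `pain` (nocifensive)
#'   `episode_timeline`s.
#' @param session_durations Named vector of session lengths (s) used as
#'   binning spans.
#' @param width,step Sliding-window parameters, s.
#' @param n_perm Permutations per test.
#' @param alpha,min_effect Classification thresholds.
#' @param seed Integer seed (per-unit, per-state seeds are derived from it).
#' @return A list: `classification` (see [classify_behavior()]) and
#'   `tests` (per unit and state: p, effect, group sizes).
#' @export
code_behavior <- function(spikes, timelines,
                          session_durations = c(baseline = 300, fear = 420,
                                                pain = 300),
                          width = 0.8, step = 0.4, n_perm = 10000,
                          alpha = 0.001, min_effect = 0.5, seed = 1L) {
  ids <- sort(unique(spikes$unit_id))
  by_unit_sess <- split(spikes$time_s,
                        list(spikes$unit_id, spikes$session), drop = FALSE)
  times_of <- function(u, sess)
    by_unit_sess[[paste(u, sess, sep = ".")]] %||% numeric(0)
  res <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    u <- ids[k]
    base_bins <- bin_rates(times_of(u, "baseline"),
                           span = c(0, session_durations[["baseline"]]),
                           width = width, step = step)
    row <- list(unit_id = u)
    for (st in c("fear", "pain")) {
      bins <- bin_rates(times_of(u, st),
                        span = c(0, session_durations[[st]]), width = width,
                        step = step)
      grp <- assign_bins(bins, timelines[[st]])
      x <- bins$rate_hz[grp == "in"]
      if (length(x) == 0) {
        row[[paste0("p_", st)]] <- NA_real_
        row[[paste0("effect_", st)]] <- NA_real_
        row[[paste0("n_in_", st)]] <- 0L
      } else {
        pt <- permutation_test(x, base_bins$rate_hz, n_perm = n_perm,
                               seed = seed + 7L * k +
                                 (if (st == "fear") 0L else 3L))
        row[[paste0("p_", st)]] <- pt$p
        row[[paste0("effect_", st)]] <- pt$effect
        row[[paste0("n_in_", st)]] <- length(x)
      }
    }
    res[[k]] <- as.data.frame(row)
  }
  tests <- do.call(rbind, res)
  list(classification = classify_behavior(tests, alpha = alpha,
                                          min_effect = min_effect),
       tests = tests)
}
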