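#' Per-session analysis windows
#'
#' Windows over which global mean rates are computed: 4 min of the
#' unstimulated baseline, 7 min of the cued fear session, and the first
#' 3 min after the capsaicin injection.
#'
#' @param baseline,fear,pain `c(start, end)` intervals in seconds from the
#'   start of each session.
#' @return A named list of intervals, class `"session_windows"`.
#' @export
session_windows <- function(baseline = c(0, 240), fear = c(0, 420),
                            pain = c(0, 180)) {
  w <- list(baseline = baseline, fear = fear, pain = pain)
  for (nm in names(w)) {
    if (length(w[[nm]]) != 2 || diff(w[[nm]]) <= 0)
      stop(nm, " window must be a positive-length c(start, end) interval")
  }
  structure(w, class = "session_windows")
}

#' Mean firing rate in a window
#'
#' @param spike_times Spike times, s.
#' @param window `c(start, end)` interval, s; must have positive length.
#' @return Rate in Hz: spikes with `start <= t < end` divided by the
#'   window length.
#' @export
mean_rate <- function(spike_times, window) {
  if (length(window) != 2 || diff(window) <= 0)
    stop("window must have positive length")
  sum(spike_times >= window[1] & spike_times < window[2]) / diff(window)
}

#' Calibrate the same-state firing-rate null
#'
#' Estimates the variance of per-unit rate changes expected on a repeated
#' encounter of the same behavioral state. For each unit recorded in two
#' sessions of one state, the log ratio `L = log(r2 / r1)` of mean rates
#' is computed; units are pooled and the standard deviation of the pooled
#' (approximately normal, zero-centered) distribution sets the global
#' significance threshold at `2 * sigma`. Units with either rate below
#' `min_rate` are excluded, since log ratios of near-silent units dominate
#' the spread. The s.d. is taken about the sample mean; if the pooled mean
#' strays beyond `sigma / 2` from 0 a data-quality warning is raised.
#'
#' @param r1,r2 Paired per-unit mean rates (Hz) from the first and second
#'   same-state session.
#' @param min_rate Minimum rate (Hz) for inclusion.
#' @return A list of class `"same_state_null"`: `log_ratios`, `sigma`,
#'   `threshold` (= `2 * sigma`), `mean`, `n`.
#' @export
fit_same_state_null <- function(r1, r2, min_rate = 0.05) {
  stopifnot(length(r1) == length(r2))
  ok <- r1 >= min_rate & r2 >= min_rate
  L <- log(r2[ok] / r1[ok])
  if (length(L) < 10)
    stop("same-state null needs >= 10 usable rate pairs (got ",
         length(L), "); refusing an unstable calibration")
  sigma <- stats::sd(L)
  m <- mean(L)
  if (sigma > 0 && abs(m) > sigma / 2)
    warning(sprintf(paste0("pooled same-state log ratios are not centered ",
                           "on 0 (mean %.3f, sigma %.3f); possible drift"),
                    m, sigma))
  structure(list(log_ratios = L, sigma = sigma, threshold = 2 * sigma,
                 mean = m, n = length(L)),
            class = "same_state_null")
}

#' @export
print.same_state_null <- function(x, ...) {
  cat(sprintf(paste0("<same_state_null> n = %d units, sigma = %.4f, ",
                     "2-s.d. threshold = %.4f (pooled mean %.4f)\n"),
              x$n, x$sigma, x$threshold, x$mean))
  invisible(x)
}

#' Classify global rate coding against the same-state null
#'
#' For each unit, the log ratio of the fear-session and pain-session mean
#' rates over the baseline rate is compared with the calibrated 2-s.d.
#' same-state threshold: `increased` above it, `decreased` below its
#' negative, `none` otherwise. Categories combine the two per-state
#' directions: changes in fear only (`fear_only`), pain only
#' (`pain_only`), both states (`common`) or neither (`neither`). Units
#' with a baseline rate below `min_rate` are marked unclassifiable and
#' excluded from category totals.
#'
#' @param rates Data frame with columns `unit_id`, `baseline`, `fear`,
#'   `pain` (mean rates in Hz over the [session_windows()]).
#' @param null A fitted [fit_same_state_null()] object.
#' @param min_rate Minimum baseline rate (Hz) for classification.
#' @return Data frame: `unit_id`, `log_ratio_fear`, `log_ratio_pain`,
#'   `dir_fear`, `dir_pain`, `category`, `classifiable`.
#' @export
classify_global <- function(rates, null, min_rate = 0.05) {
  stopifnot(inherits(null, "same_state_null"),
            all(c("unit_id", "baseline", "fear", "pain") %in% names(rates)))
  thr <- null$threshold
  ok <- rates$baseline >= min_rate
  lr_f <- ifelse(ok, log(rates$fear / rates$baseline), NA_real_)
  lr_p <- ifelse(ok, log(rates$pain / rates$baseline), NA_real_)
  dir_of <- function(lr) {
    ifelse(is.na(lr), NA_character_,
           ifelse(lr > thr, "increased",
                  ifelse(lr < -thr, "decreased", "none")))
  }
  dir_f <- dir_of(lr_f)
  dir_p <- dir_of(lr_p)
  category <- ifelse(is.na(dir_f) | is.na(dir_p), NA_character_,
                     ifelse(dir_f != "none" & dir_p != "none", "common",
                            ifelse(dir_f != "none", "fear_only",
                                   ifelse(dir_p != "none", "pain_only",
                                          "neither"))))
  data.frame(unit_id = rates$unit_id,
             log_ratio_fear = lr_f, log_ratio_pain = lr_p,
             dir_fear = dir_f, dir_pain = dir_p,
             category = category, classifiable = ok)
}

#' Global rate-coding pipeline over simulated or recorded sessions
#'
#' Convenience wrapper: computes per-unit mean rates in the session
#' windows, fits the same-state null from the paired baseline sessions
#' (sessions `baseline` and `baseline2`), and classifies every unit.
#'
#' @param spikes Data frame `unit_id`, `session`, `time_s` containing at
#'   least sessions `baseline`, `baseline2`, `fear`, `pain`.
#' @param windows A [session_windows()] object.
#' @param min_rate Minimum rate (Hz) for null fitting and classification.
#' @return A list: `classification` (see [classify_global()]), `null`,
#'   `rates`.
#' @export
code_global <- function(spikes, windows = session_windows(),
                        min_rate = 0.05) {
  need <- c("baseline", "baseline2", "fear", "pain")
  if (!all(need %in% unique(spikes$session)))
    stop("spikes must contain sessions: ", paste(need, collapse = ", "))
  ids <- sort(unique(spikes$unit_id))
  by_unit_sess <- split(spikes$time_s,
                        list(spikes$unit_id, spikes$session), drop = FALSE)
  rate_in <- function(sess, win) {
    vapply(ids, function(u) {
      mean_rate(by_unit_sess[[paste(u, sess, sep = ".")]] %||% numeric(0),
                win)
    }, numeric(1))
  }
  r_b1 <- rate_in("baseline", windows$baseline)
  r_b2 <- rate_in("baseline2", windows$baseline)
  rates <- data.frame(unit_id = ids,
                      baseline = r_b1,
                      fear = rate_in("fear", windows$fear),
                      pain = rate_in("pain", windows$pain))
  null <- fit_same_state_null(r_b1, r_b2, min_rate = min_rate)
  list(classification = classify_global(rates, null, min_rate = min_rate),
       null = null, rates = rates)
}
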