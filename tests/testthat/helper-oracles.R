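# Independent brute-force oracles used across test files. These
# deliberately use the slowest, most literal formulation of each rule so
# they stay independent of the package's optimized code paths.

# Union length of a timeline's intervals by fine-grid indicator sum.
oracle_coverage <- function(timeline, duration, dt = 0.005) {
  if (nrow(timeline) == 0) return(0)
  grid <- seq(dt / 2, duration, by = dt)
  inside <- vapply(grid, function(g) {
    any(g >= timeline$onset_s & g < timeline$offset_s)
  }, logical(1))
  sum(inside) * dt
}

# Per-bin spike recount.
oracle_bin_counts <- function(times, onsets, width) {
  vapply(onsets, function(o) sum(times >= o & times < o + width), numeric(1))
}

# Literal containment rule for bin assignment.
oracle_assign <- function(bins, timeline) {
  vapply(seq_len(nrow(bins)), function(i) {
    on <- bins$onset_s[i]; off <- bins$offset_s[i]
    in_same <- any(on >= timeline$onset_s & on <= timeline$offset_s &
                     off >= timeline$onset_s & off <= timeline$offset_s)
    on_out <- !any(on >= timeline$onset_s & on <= timeline$offset_s)
    off_out <- !any(off >= timeline$onset_s & off <= timeline$offset_s)
    if (in_same) "in" else if (on_out && off_out) "out" else "excluded"
  }, character(1))
}

# O(n^2) duplicate-pruning oracle: literal pairwise coincidence counting
# (each spike of the smaller train matched at most once, greedily in time
# order) and iterated removal of the higher-refractory member of the
# worst >max_shared pair.
oracle_dedup <- function(trains, tol_s = 5e-4, max_shared = 0.10,
                         refractory_s = 2e-3) {
  refr <- vapply(trains, function(t) {
    if (length(t) < 2) 0 else mean(diff(sort(t)) < refractory_s)
  }, numeric(1))
  shared_count <- function(a, b) {
    used <- rep(FALSE, length(b))
    n <- 0L
    for (ai in sort(a)) {
      cand <- which(!used & abs(b - ai) <= tol_s)
      if (length(cand)) { used[cand[1]] <- TRUE; n <- n + 1L }
    }
    n
  }
  alive <- rep(TRUE, length(trains))
  repeat {
    live <- which(alive)
    if (length(live) < 2) break
    worst <- NULL; worst_frac <- max_shared
    for (a in seq_along(live)[-length(live)]) {
      for (b in (a + 1):length(live)) {
        i <- live[a]; j <- live[b]
        f <- shared_count(trains[[i]], trains[[j]]) /
          min(length(trains[[i]]), length(trains[[j]]))
        if (f > worst_frac) { worst <- c(i, j); worst_frac <- f }
      }
    }
    if (is.null(worst)) break
    alive[if (refr[worst[1]] >= refr[worst[2]]) worst[1] else worst[2]] <- FALSE
  }
  names(trains)[alive]
}

# Hand-built episode timeline carrying the class the package expects.
as_timeline_fixture <- function(df) {
  attr(df, "state") <- if (nrow(df)) df$state[1] else "none"
  class(df) <- c("episode_timeline", "data.frame")
  df
}

# Poisson spike train on [0, duration] for fixture construction.
poisson_train <- function(rate, duration, seed) {
  withr::with_seed(seed, {
    n <- stats::rpois(1, rate * duration)
    sort(stats::runif(n, 0, duration))
  })
}
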