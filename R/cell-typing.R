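#' Z-score a unit feature matrix
#'
#' Centers and scales the three cell-typing features (half-amplitude
#' duration, trough-to-peak time, mean firing rate) column-wise. Constant
#' columns (zero s.d.) carry no clustering information and are dropped
#' with a warning.
#'
#' @param features Data frame or matrix with columns `half_amp_ms`,
#'   `t2p_ms`, `mean_rate_hz` (any subset of numeric columns is accepted).
#' @return A numeric matrix of z-scored columns.
#' @export
zscore_features <- function(features) {
  m <- as.matrix(features)
  storage.mode(m) <- "double"
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant feature column(s): ",
            paste(colnames(m)[sds == 0], collapse = ", "))
    m <- m[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  if (ncol(m) == 0) stop("no non-constant feature columns left")
  scale(m)
}

#' Ward-linkage clustering of unit features
#'
#' Agglomerative hierarchical clustering with Ward's method on Euclidean
#' distances over the z-scored features, cut at the `k` most prominent
#' clusters (k = 2 splits putative principal neurons from interneurons).
#'
#' @param features Data frame/matrix of unit features (see
#'   [zscore_features()]).
#' @param k Number of clusters to cut the tree at.
#' @return Integer vector of cluster labels (1..k), one per unit.
#' @export
cluster_units <- function(features, k = 2) {
  if (nrow(as.matrix(features)) < k)
    stop("need at least k = ", k, " units to cluster")
  z <- zscore_features(features)
  hc <- stats::hclust(stats::dist(z, method = "euclidean"),
                      method = "ward.D2")
  unname(stats::cutree(hc, k = k))
}

#' Name the two clusters as principal neurons vs interneurons
#'
#' Applies the standard cortical convention: the cluster with the smaller
#' mean trough-to-peak time AND the higher mean firing rate is called
#' interneuron (narrow, fast-spiking); the other is principal. If the two
#' criteria conflict (the narrower cluster fires more slowly) the
#' assignment falls back to trough-to-peak alone and a warning flags the
#' ambiguity.
#'
#' @param labels Integer cluster labels from [cluster_units()] (exactly 2
#'   distinct values).
#' @param features The feature table used for clustering; must contain
#'   `t2p_ms` and `mean_rate_hz`.
#' @return Factor with levels `principal`, `interneuron`; attribute
#'   `ambiguous` is `TRUE` when the fallback was used.
#' @export
label_clusters <- function(labels, features) {
  u <- sort(unique(labels))
  if (length(u) != 2) stop("expected exactly 2 clusters, got ", length(u))
  stopifnot(all(c("t2p_ms", "mean_rate_hz") %in% colnames(features)))
  t2p <- tapply(features[, "t2p_ms"], labels, mean)
  rate <- tapply(features[, "mean_rate_hz"], labels, mean)
  narrow <- u[which.min(t2p[as.character(u)])]
  faster <- u[which.max(rate[as.character(u)])]
  ambiguous <- narrow != faster
  if (ambiguous)
    warning("cluster criteria conflict (narrower cluster fires more ",
            "slowly); assigning interneuron by trough-to-peak alone")
  ph <- factor(ifelse(labels == narrow, "interneuron", "principal"),
               levels = c("principal", "interneuron"))
  attr(ph, "ambiguous") <- ambiguous
  ph
}

#' Cell-type units from waveform and rate features
#'
#' Convenience wrapper: clusters with [cluster_units()] at `k = 2` and
#' names the clusters with [label_clusters()].
#'
#' @param features Data frame with columns `half_amp_ms`, `t2p_ms`,
#'   `mean_rate_hz`.
#' @return Factor of phenotypes (`principal` / `interneuron`) per unit.
#' @export
classify_cell_types <- function(features) {
  features <- as.matrix(features)
  label_clusters(cluster_units(features, k = 2), features)
}

#' Generate a synthetic feature matrix with phenotype ground truth
#'
#' Draws unit features from the per-phenotype Gaussian distributions of a
#' [sim_config()]: broad/slow/low-rate principal neurons vs
#' narrow/fast/high-rate interneurons.
#'
#' @param n_units Number of units.
#' @param config A [sim_config()] (uses `pn_in_fraction`,
#'   `waveform_params`).
#' @param seed Integer seed.
#' @return A list: `features` (matrix with columns `half_amp_ms`,
#'   `t2p_ms`, `mean_rate_hz`) and `phenotype` (ground-truth factor).
#' @export
generate_feature_matrix <- function(n_units, config = sim_config(),
                                    seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(seed, {
    pheno <- ifelse(stats::runif(n_units) < config$pn_in_fraction,
                    "interneuron", "principal")
    f <- t(vapply(pheno, function(p) {
      wp <- config$waveform_params[[p]]
      c(half_amp_ms = max(0.05, stats::rnorm(1, wp$half_amp_ms[1],
                                             wp$half_amp_ms[2])),
        t2p_ms = max(0.08, stats::rnorm(1, wp$t2p_ms[1], wp$t2p_ms[2])),
        mean_rate_hz = max(0.1, stats::rnorm(1, wp$rate_hz[1],
                                             wp$rate_hz[2])))
    }, c(half_amp_ms = 0, t2p_ms = 0, mean_rate_hz = 0)))
    rownames(f) <- NULL
    list(features = f,
         phenotype = factor(pheno, levels = c("principal", "interneuron")))
  })
}
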