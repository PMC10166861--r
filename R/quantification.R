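#' Chance level of dual-label overlap
#'
#' Expected double-positive percentage under independent labeling:
#' `(n_fos / n_dapi) * (n_tag / n_dapi) * 100`. Symmetric in the two
#' labels.
#'
#' @param table Data frame with columns `n_fos`, `n_tag`, `n_dapi`
#'   (one or more rows).
#' @return Chance overlap percentage per row.
#' @export
chance_overlap <- function(table) {
  stopifnot(all(c("n_fos", "n_tag", "n_dapi") %in% names(table)))
  if (any(table$n_dapi == 0))
    stop("chance overlap undefined for n_dapi = 0")
  validate_count_table(table)
  (table$n_fos / table$n_dapi) * (table$n_tag / table$n_dapi) * 100
}

#' Observed dual-label overlap
#'
#' Double-positive cells as a percentage of one single-label population:
#' of all tag-positive (e.g. mCherry) cells (`denominator = "tag"`), or of
#' all Fos-positive cells (`denominator = "fos"`).
#'
#' @param table Data frame with columns `n_double` and the denominator
#'   count column.
#' @param denominator `"tag"` or `"fos"`.
#' @return Observed overlap percentage per row.
#' @export
observed_overlap <- function(table, denominator = c("tag", "fos")) {
  denominator <- match.arg(denominator)
  col <- paste0("n_", denominator)
  stopifnot(all(c("n_double", col) %in% names(table)))
  if (any(table[[col]] == 0))
    stop("observed overlap undefined for a zero ", denominator, " count")
  validate_count_table(table)
  100 * table$n_double / table[[col]]
}

validate_count_table <- function(table) {
  cols <- intersect(c("n_fos", "n_tag", "n_double", "n_dapi"), names(table))
  counts <- table[cols]
  if (any(counts < 0)) stop("cell counts must be >= 0")
  if (all(c("n_double", "n_fos", "n_tag") %in% cols) &&
      any(table$n_double > pmin(table$n_fos, table$n_tag)))
    stop("n_double cannot exceed min(n_fos, n_tag)")
  if ("n_dapi" %in% cols) {
    other <- setdiff(cols, "n_dapi")
    if (length(other) && any(counts[other] > table$n_dapi))
      stop("label counts cannot exceed n_dapi")
  }
  invisible(table)
}

#' Labeled-cell density
#'
#' @param count Cell count (>= 0).
#' @param volume Tissue volume, mm^3 (> 0).
#' @return Cells per mm^3.
#' @export
cell_density <- function(count, volume) {
  if (any(volume <= 0)) stop("volume must be > 0")
  if (any(count < 0)) stop("count must be >= 0")
  count / volume
}

#' Projection-image pixel-intensity binning
#'
#' Piecewise-constant map used before rendering projection-intensity
#' colormaps: 10-wide bins from 0 to 50, then `[50, 100) -> 50`,
#' `[100, 150) -> 100`, `[150, 200) -> 150`, and `[200, 255] -> 200`.
#' Lower bin edges are inclusive; the top bin is closed at 255. The map is
#' idempotent and monotone with exactly 9 output levels.
#'
#' @param value Pixel intensities in `[0, 255]` (vectorized).
#' @return Binned intensities.
#' @export
bin_intensity <- function(value) {
  if (any(value < 0 | value > 255))
    stop("pixel intensities must lie in [0, 255]")
  edges <- c(0, 10, 20, 30, 40, 50, 100, 150, 200)
  edges[findInterval(value, edges, rightmost.closed = FALSE)]
}
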