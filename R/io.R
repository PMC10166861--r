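## File dialects
##
## Traces travel as flat little-endian int16, channel-interleaved
## (ch1 s1, ch2 s1, ..., chN s1, ch1 s2, ...), with a JSON sidecar
## {fs_hz, n_channels, volts_per_bit}. Tables travel as headered CSV with
## fixed column and row order; seconds are written with 6 decimals so the
## writers are byte-deterministic.

fmt6 <- function(x) sprintf("%.6f", x)

#' Write a voltage trace as flat int16 plus JSON sidecar
#'
#' @param trace A [voltage_trace()].
#' @param path Output path for the binary samples; the sidecar is written
#'   to `paste0(path, ".json")`.
#' @param volts_per_bit Quantization step; samples are rounded to the
#'   nearest multiple and clipped to the int16 range.
#' @return Invisibly, the sidecar list.
#' @export
write_trace <- function(trace, path, volts_per_bit = 1e-7) {
  stopifnot(inherits(trace, "voltage_trace"), volts_per_bit > 0)
  raw16 <- round(trace$samples / volts_per_bit)
  raw16 <- pmin(pmax(raw16, -32768), 32767)
  con <- file(path, "wb")
  on.exit(close(con))
  # column-major write of the channels x samples matrix = interleaved layout
  writeBin(as.integer(raw16), con, size = 2, endian = "little")
  sidecar <- list(fs_hz = trace$fs, n_channels = nrow(trace$samples),
                  volts_per_bit = volts_per_bit,
                  byte_order = "little", sample_layout = "channel-interleaved")
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(sidecar)
}

#' Read a flat int16 voltage trace with its JSON sidecar
#'
#' @param path Path to the binary samples; the sidecar is read from
#'   `sidecar_path` (default `paste0(path, ".json")`).
#' @param sidecar_path Optional explicit sidecar path.
#' @return A [voltage_trace()] in volts.
#' @export
read_trace <- function(path, sidecar_path = paste0(path, ".json")) {
  if (!file.exists(sidecar_path))
    stop("missing sidecar file: ", sidecar_path)
  sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  for (f in c("fs_hz", "n_channels", "volts_per_bit"))
    if (is.null(sc[[f]])) stop("sidecar lacks required field: ", f)
  bytes <- file.size(path)
  if (bytes %% (2 * sc$n_channels) != 0)
    stop("file size (", bytes, " bytes) is not divisible by 2 x n_channels (",
         sc$n_channels, "); truncated or mismatched sidecar")
  n_samp <- bytes / (2 * sc$n_channels)
  con <- file(path, "rb")
  on.exit(close(con))
  raw16 <- readBin(con, integer(), n = bytes / 2, size = 2, signed = TRUE,
                   endian = "little")
  voltage_trace(matrix(raw16 * sc$volts_per_bit, nrow = sc$n_channels),
                fs = sc$fs_hz)
}

#' Write per-unit spike times as CSV
#'
#' Columns `unit_id,time_s`; rows sorted by unit then time; times with 6
#' decimals, so output is byte-deterministic.
#'
#' @param spikes Data frame with `unit_id`, `time_s` (a `session` column,
#'   if present, is preserved as a third column).
#' @param path Output CSV path.
#' @export
write_spikes <- function(spikes, path) {
  stopifnot(all(c("unit_id", "time_s") %in% names(spikes)))
  has_sess <- "session" %in% names(spikes)
  ord <- if (has_sess) order(spikes$unit_id, spikes$session, spikes$time_s)
         else order(spikes$unit_id, spikes$time_s)
  spikes <- spikes[ord, , drop = FALSE]
  out <- data.frame(unit_id = spikes$unit_id)
  if (has_sess) out$session <- spikes$session
  out$time_s <- fmt6(spikes$time_s)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read per-unit spike times from CSV
#'
#' @param path CSV with header `unit_id,time_s` (optional `session`).
#' @return Validated data frame sorted by unit (and session) then time.
#' @export
read_spikes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("unit_id", "time_s") %in% names(df)))
    stop("spike CSV must have columns unit_id,time_s")
  df$time_s <- as.numeric(df$time_s)
  if (anyNA(df$time_s)) stop("non-numeric time_s entries in ", path)
  ord <- if ("session" %in% names(df))
    order(df$unit_id, df$session, df$time_s) else order(df$unit_id, df$time_s)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write an episode timeline as CSV
#'
#' Columns `state,onset_s,offset_s`, sorted by onset, 6-decimal seconds.
#'
#' @param timeline An `episode_timeline` data frame.
#' @param path Output CSV path.
#' @export
write_episodes <- function(timeline, path) {
  stopifnot(all(c("state", "onset_s", "offset_s") %in% names(timeline)))
  timeline <- timeline[order(timeline$onset_s), , drop = FALSE]
  out <- data.frame(state = timeline$state,
                    onset_s = fmt6(timeline$onset_s),
                    offset_s = fmt6(timeline$offset_s))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read episode timelines from CSV
#'
#' Validates ordering and non-overlap, naming offending rows.
#'
#' @param path CSV with header `state,onset_s,offset_s`.
#' @return A named list of `episode_timeline` data frames, one per state.
#' @export
read_episodes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("state", "onset_s", "offset_s") %in% names(df)))
    stop("episode CSV must have columns state,onset_s,offset_s")
  df$onset_s <- as.numeric(df$onset_s)
  df$offset_s <- as.numeric(df$offset_s)
  out <- lapply(split(df, df$state), function(d) {
    d <- d[order(d$onset_s), , drop = FALSE]
    rownames(d) <- NULL
    as_episode_timeline(d, d$state[1])
  })
  out
}

#' Read a cell-count table from CSV
#'
#' @param path CSV with columns `region,n_fos,n_tag,n_double,n_dapi,
#'   volume_mm3`.
#' @return Validated count-table data frame.
#' @export
read_count_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("region", "n_fos", "n_tag", "n_double", "n_dapi", "volume_mm3")
  if (!all(need %in% names(df)))
    stop("count table must have columns ", paste(need, collapse = ","))
  validate_count_table(df)
  if (any(df$volume_mm3 <= 0)) stop("volume_mm3 must be > 0")
  df
}

#' Write result tables deterministically
#'
#' Writes each named data frame to `<dir>/<name>.csv` with fixed column
#' order and 6-decimal numeric formatting.
#'
#' @param tables Named list of data frames.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the written paths.
#' @export
write_results <- function(tables, dir) {
  stopifnot(is.list(tables), !is.null(names(tables)))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(names(tables), function(nm) {
    df <- tables[[nm]]
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], fmt6)
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
    p
  }, character(1))
  invisible(paths)
}
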