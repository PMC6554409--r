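# Plain-text and flat-binary interchange: interval TSV, duration-sample
# TSV, LFP int16 binary + JSON sidecar (the flat .lfp convention), spike
# TSV, and map exports.

#' Read and write labeled interval sets as TSV
#'
#' Columns `start`, `stop`, `label`; the time units are recorded in a
#' `# units:` header comment.
#'
#' @param x an [interval_set()].
#' @param path file path.
#' @return `read_intervals()` returns an [interval_set()].
#' @export
write_intervals <- function(x, path) {
  stopifnot(is_interval_set(x))
  con <- file(path, "w")
  writeLines(paste0("# units: ", attr(x, "units")), con)
  write.table(as.data.frame(x), con, sep = "\t", row.names = FALSE,
              quote = FALSE)
  close(con)
  invisible(path)
}

#' @rdname write_intervals
#' @export
read_intervals <- function(path) {
  first <- readLines(path, n = 1)
  units <- if (startsWith(first, "# units:"))
    trimws(sub("# units:", "", first)) else "model"
  d <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  interval_set(d$start, d$stop, d$label, units = units)
}

#' Read and write duration samples as TSV
#'
#' Long format with columns `duration`, `label` (`UP`/`DOWN`).
#'
#' @param x a [duration_sample()].
#' @param path file path.
#' @export
write_durations <- function(x, path) {
  stopifnot(inherits(x, "duration_sample"))
  con <- file(path, "w")
  writeLines(paste0("# units: ", x$units), con)
  write.table(data.frame(duration = c(x$up, x$down),
                         label = c(rep("UP", length(x$up)),
                                   rep("DOWN", length(x$down)))),
              con, sep = "\t", row.names = FALSE, quote = FALSE)
  close(con)
  invisible(path)
}

#' @rdname write_durations
#' @export
read_durations <- function(path) {
  first <- readLines(path, n = 1)
  units <- if (startsWith(first, "# units:"))
    trimws(sub("# units:", "", first)) else "model"
  d <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  duration_sample(up = d$duration[d$label == "UP"],
                  down = d$duration[d$label == "DOWN"], units = units)
}

#' Write and read LFP as flat int16 binary with a JSON sidecar
#'
#' Channel-interleaved little-endian int16 samples (the flat `.lfp`/`.dat`
#' convention) with a `<path>.json` sidecar holding `n_channels`, `rate`,
#' `scale` (volts-per-unit equivalent: the float signal is `int16 * scale`)
#' and `start`. Writing quantizes the float signal by the stored scale;
#' a written file round-trips bit-exactly through read/write.
#'
#' @param lfp an [lfp_record()].
#' @param path output path for the binary payload.
#' @param scale quantization step; chosen from the signal range when `NULL`.
#' @export
write_lfp_binary <- function(lfp, path, scale = NULL) {
  if (is.null(scale)) scale <- max(abs(range(lfp$signal)), 1e-12) / 32000
  q <- t(round(lfp$signal / scale))          # interleave channels
  storage.mode(q) <- "integer"
  q <- pmax(pmin(q, 32767L), -32768L)
  con <- file(path, "wb")
  writeBin(as.integer(q), con, size = 2, endian = "little")
  close(con)
  jsonlite::write_json(list(n_channels = ncol(lfp$signal), rate = lfp$rate,
                            scale = scale, start = lfp$start,
                            channels = lfp$channels),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_lfp_binary
#' @export
read_lfp_binary <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  nbytes <- file.info(path)$size
  n <- nbytes / 2
  con <- file(path, "rb")
  raw <- readBin(con, "integer", n = n, size = 2, endian = "little")
  close(con)
  sig <- matrix(raw * meta$scale, ncol = meta$n_channels, byrow = TRUE)
  lfp_record(sig, rate = meta$rate, channels = meta$channels,
             start = meta$start)
}

#' Read and write spike rasters as TSV
#'
#' Columns `unit`, `time`, `class`.
#'
#' @param spikes a [spike_raster()].
#' @param path file path.
#' @export
write_spikes <- function(spikes, path) {
  d <- do.call(rbind, lapply(seq_along(spikes$times), function(u)
    if (length(spikes$times[[u]]))
      data.frame(unit = u, time = spikes$times[[u]],
                 class = spikes$class[u]) else NULL))
  write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spikes
#' @export
read_spikes <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t")
  units <- sort(unique(d$unit))
  spike_raster(lapply(units, function(u) sort(d$time[d$unit == u])),
               class = vapply(units, function(u)
                 as.character(d$class[d$unit == u][1]), character(1)))
}

#' Export a regime or duration map as TSV plus a JSON summary
#'
#' @param map a data frame of cells (e.g. from [regime_map()] or
#'   `duration_map()$cells`).
#' @param path TSV output path; the JSON summary goes to `<path>.json`.
#' @param summary optional list written as the JSON summary.
#' @export
write_map <- function(map, path, summary = NULL) {
  write.table(map, path, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(summary))
    jsonlite::write_json(summary, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  invisible(path)
}

#' Write a simulated trace as TSV
#'
#' Columns `time`, `r`, `a` (and `r_i` for E-I traces); parameters and the
#' seed in header comments.
#'
#' @param trace a `sim_trace`.
#' @param path file path.
#' @param thin write every `thin`-th sample.
#' @export
write_trace <- function(trace, path, thin = 1L) {
  ix <- seq(1L, length(trace$time), by = thin)
  d <- data.frame(time = trace$time[ix], r = trace$r[ix])
  if (!is.null(trace$r_i)) d$r_i <- trace$r_i[ix]
  d$a <- trace$a[ix]
  con <- file(path, "w")
  writeLines(sprintf("# seed: %d; dt: %g; duration: %g",
                     trace$seed, trace$dt, trace$duration), con)
  write.table(d, con, sep = "\t", row.names = FALSE, quote = FALSE)
  close(con)
  invisible(path)
}
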