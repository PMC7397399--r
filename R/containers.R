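#' Single-channel detector trace
#'
#' A fixed-rate 1D intensity signal as acquired by a single-channel detector
#' (FID) or derived from an MS scan stream (TIC).
#'
#' @param intensities Numeric vector of detector counts (finite, length >= 1).
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param channel Channel label, e.g. `"FID"` or `"MS"`.
#' @param start_time Acquisition delay before the first point (seconds).
#' @param sample_id Optional sample identifier.
#' @return An object of class `raw_trace`.
#' @export
raw_trace <- function(intensities, sampling_rate, channel = "FID",
                      start_time = 0, sample_id = NA_character_) {
  intensities <- as.numeric(intensities)
  if (length(intensities) < 1L) stop_config("intensities must be non-empty")
  if (!all(is.finite(intensities)))
    stop_config("intensities must all be finite")
  if (!is.finite(sampling_rate) || sampling_rate <= 0)
    stop_config("sampling_rate must be > 0")
  structure(list(intensities = intensities,
                 sampling_rate = as.numeric(sampling_rate),
                 channel = as.character(channel),
                 start_time = as.numeric(start_time),
                 sample_id = as.character(sample_id)),
            class = "raw_trace")
}

#' @export
print.raw_trace <- function(x, ...) {
  cat(sprintf("raw_trace [%s]: %d points at %g Hz (%.1f s)\n", x$channel,
              length(x$intensities), x$sampling_rate,
              length(x$intensities) / x$sampling_rate))
  invisible(x)
}

#' Mass-spectral scan stream
#'
#' A ragged sequence of centroided scans: per-scan m/z and intensity vectors
#' plus the per-scan total ion current.
#'
#' @param scan_times Numeric vector of scan acquisition times (seconds,
#'   strictly increasing).
#' @param mz List of per-scan m/z vectors, each sorted strictly ascending.
#' @param intensity List of per-scan intensity vectors (>= 0), each the same
#'   length as the matching m/z vector.
#' @param sample_id Optional sample identifier.
#' @return An object of class `scan_stream` with a recomputed
#'   `total_intensity` element.
#' @export
scan_stream <- function(scan_times, mz, intensity,
                        sample_id = NA_character_) {
  n <- length(scan_times)
  if (length(mz) != n || length(intensity) != n)
    stop_config("scan_times, mz and intensity must have equal length")
  if (n > 1 && any(diff(scan_times) <= 0))
    stop_config("scan_times must be strictly increasing")
  for (i in seq_len(n)) {
    m <- mz[[i]]
    v <- intensity[[i]]
    if (length(m) != length(v))
      stop_config(sprintf("scan %d: m/z and intensity lengths differ", i))
    if (length(m) > 1 && any(diff(m) <= 0))
      stop_config(sprintf("scan %d: m/z values must be strictly ascending",
                          i))
    if (length(v) && any(!is.finite(v) | v < 0))
      stop_config(sprintf("scan %d: intensities must be finite and >= 0", i))
  }
  structure(list(scan_times = as.numeric(scan_times),
                 mz = lapply(mz, as.numeric),
                 intensity = lapply(intensity, as.numeric),
                 total_intensity = vapply(intensity,
                                          function(v) sum(as.numeric(v)),
                                          numeric(1)),
                 sample_id = as.character(sample_id)),
            class = "scan_stream")
}

#' @export
print.scan_stream <- function(x, ...) {
  cat(sprintf("scan_stream: %d scans, %.2f-%.2f s, %d stored points\n",
              length(x$scan_times), min(x$scan_times), max(x$scan_times),
              sum(lengths(x$mz))))
  invisible(x)
}

#' Folded two-dimensional chromatogram
#'
#' The retention-plane intensity matrix: rows index the second-dimension
#' sampling grid within one modulation, columns index consecutive complete
#' modulations. Retention coordinates follow the contour-plot convention:
#' `1tR = (col - 1) * pm / 60` minutes (modulation start) and
#' `2tR = (row - 1) / rate` seconds from modulation start.
#'
#' @param values Numeric matrix of intensities (finite).
#' @param pm Modulation period (seconds).
#' @param rate Effective second-dimension sampling rate (Hz).
#' @param channel Channel label.
#' @param sample_id Optional sample identifier.
#' @return An object of class `chromatogram2d`.
#' @export
chromatogram2d <- function(values, pm, rate, channel = "FID",
                           sample_id = NA_character_) {
  if (!is.matrix(values)) stop_config("values must be a matrix")
  if (!all(is.finite(values))) stop_config("plane values must be finite")
  if (pm <= 0) stop_config("pm must be > 0")
  if (rate <= 0) stop_config("rate must be > 0")
  if (abs(nrow(values) - pm * rate) > 1 + 1e-9)
    stop_config(sprintf(
      "row count %d inconsistent with pm * rate = %.3f", nrow(values),
      pm * rate))
  structure(list(values = values, pm = as.numeric(pm),
                 rate = as.numeric(rate), channel = as.character(channel),
                 sample_id = as.character(sample_id)),
            class = "chromatogram2d")
}

#' @export
print.chromatogram2d <- function(x, ...) {
  cat(sprintf(
    "chromatogram2d [%s]: %d x %d (2D grid x modulations), pm %g s, %g Hz\n",
    x$channel, nrow(x$values), ncol(x$values), x$pm, x$rate))
  invisible(x)
}
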