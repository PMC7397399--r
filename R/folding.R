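# Conversion between 1D detector signals and the 2D retention plane defined
# by the modulation period, plus the retention-coordinate convention.

#' Total ion current trace of a scan stream
#'
#' The per-scan spectrum sum, with the sampling rate inferred from the median
#' scan-time spacing.
#'
#' @param scans A [scan_stream()].
#' @return A [raw_trace()] with channel `"MS"`.
#' @export
compute_tic <- function(scans) {
  stopifnot(inherits(scans, "scan_stream"))
  if (length(scans$scan_times) < 2)
    stop_config("cannot infer a scan rate from fewer than 2 scans")
  rate <- 1 / median(diff(scans$scan_times))
  raw_trace(scans$total_intensity, rate, channel = "MS",
            start_time = scans$scan_times[1], sample_id = scans$sample_id)
}

#' Fold a 1D trace into the 2D retention plane
#'
#' When `pm * rate` is an integer `n`, columns are consecutive `n`-sample
#' blocks and [unfold()] inverts the operation exactly. When it is not (e.g.
#' 41.5 scans/s at a 2.5 s period), each modulation's samples are linearly
#' interpolated onto a fixed grid of `ceiling(pm * rate)` rows at the native
#' sample spacing `1/rate`, measured from the modulation start. A trailing
#' partial modulation is discarded in both cases.
#'
#' @param trace A [raw_trace()].
#' @param pm Modulation period (seconds, > 0).
#' @return A [chromatogram2d()].
#' @export
fold <- function(trace, pm) {
  stopifnot(inherits(trace, "raw_trace"))
  if (!is.numeric(pm) || length(pm) != 1L || pm <= 0)
    stop_config("pm must be a positive scalar")
  x <- trace$intensities
  rate <- trace$sampling_rate
  npm <- pm * rate
  if (length(x) < npm)
    stop_config("trace shorter than one modulation")
  if (abs(npm - round(npm)) < 1e-6) {
    n <- as.integer(round(npm))
    ncols <- length(x) %/% n
    m <- matrix(x[seq_len(n * ncols)], nrow = n)
  } else {
    nrows <- as.integer(ceiling(npm))
    ncols <- as.integer(floor(length(x) / npm))
    ts <- (seq_along(x) - 1) / rate
    qt <- outer((seq_len(nrows) - 1) / rate, (seq_len(ncols) - 1) * pm, "+")
    m <- matrix(approx(ts, x, xout = as.vector(qt), rule = 2)$y,
                nrow = nrows)
  }
  chromatogram2d(m, pm, rate, channel = trace$channel,
                 sample_id = trace$sample_id)
}

#' Unfold a 2D plane back into a 1D trace
#'
#' Column-major concatenation; the exact inverse of [fold()] on integer-grid
#' planes. Used so that 1D baseline operators respect each channel's native
#' rate.
#'
#' @param plane A [chromatogram2d()].
#' @return A [raw_trace()].
#' @export
unfold <- function(plane) {
  stopifnot(inherits(plane, "chromatogram2d"))
  raw_trace(as.vector(plane$values), plane$rate, channel = plane$channel,
            sample_id = plane$sample_id)
}

#' Map plane indices to retention coordinates and back
#'
#' Indices are 1-based; `1tR = (col - 1) * pm / 60` minutes is assigned at
#' the modulation start (not apex-corrected) and `2tR = (row - 1) / rate`
#' seconds is measured from the modulation start with no hold-up-time
#' subtraction, matching the usual contour-plot convention.
#'
#' @param plane A [chromatogram2d()].
#' @param row,col Plane indices (vectors allowed).
#' @return `index_to_retention`: a list with numeric `t1` (minutes) and `t2`
#'   (seconds). `retention_to_index`: a list with integer `row` and `col`
#'   (nearest grid cell).
#' @export
index_to_retention <- function(plane, row, col) {
  stopifnot(inherits(plane, "chromatogram2d"))
  if (any(row < 1 | row > nrow(plane$values)) ||
      any(col < 1 | col > ncol(plane$values)))
    stop_config("index out of range")
  list(t1 = (col - 1) * plane$pm / 60, t2 = (row - 1) / plane$rate)
}

#' @rdname index_to_retention
#' @param t1 First-dimension retention (minutes).
#' @param t2 Second-dimension retention (seconds).
#' @export
retention_to_index <- function(plane, t1, t2) {
  stopifnot(inherits(plane, "chromatogram2d"))
  col <- as.integer(round(t1 * 60 / plane$pm)) + 1L
  row <- as.integer(round(t2 * plane$rate)) + 1L
  if (any(row < 1 | row > nrow(plane$values)) ||
      any(col < 1 | col > ncol(plane$values)))
    stop_config("retention outside plane extent")
  list(row = row, col = col)
}

# Retention extent covered by the plane's cell centers.
plane_extent <- function(plane) {
  list(t1 = c(0, (ncol(plane$values) - 1) * plane$pm / 60),
       t2 = c(0, (nrow(plane$values) - 1) / plane$rate))
}
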