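# Channel-specific baseline correction. Both operators work on the unfolded
# 1D signal so each channel's native rate is respected, and both are
# parameterized by the expected second-dimension peak width (default 0.35 s,
# re-derivable per dataset with estimate_peak_width()).

#' Baseline-correction parameters
#'
#' @param peak_width_2d Expected second-dimension peak width in seconds
#'   (default 0.35, a compromise across the dynamic range; see
#'   [estimate_peak_width()]).
#' @param dbc_window_factor Dynamic-baseline window as a multiple of the peak
#'   width (default 10).
#' @param tophat_factor TopHat structuring-element width as a multiple of the
#'   peak width (default 5).
#' @return An object of class `baseline_params`.
#' @export
baseline_params <- function(peak_width_2d = 0.35, dbc_window_factor = 10,
                            tophat_factor = 5) {
  if (peak_width_2d <= 0) stop_config("peak_width_2d must be > 0")
  if (dbc_window_factor < 1 || tophat_factor < 1)
    stop_config("window factors must be >= 1")
  structure(list(peak_width_2d = peak_width_2d,
                 dbc_window_factor = dbc_window_factor,
                 tophat_factor = tophat_factor),
            class = "baseline_params")
}

# Morphological opening (flat erosion then dilation) with edge-value padding.
opening <- function(x, width) {
  roll_max_pad(roll_min_pad(x, width), width)
}

#' Dynamic baseline correction (MS stream)
#'
#' The baseline is a morphological opening of the signal — a centered rolling
#' minimum followed by a centered rolling maximum of width
#' `round(dbc_window_factor * peak_width_2d * rate)` (forced odd) — which is
#' then subtracted. Tying the window to the second-dimension peak width makes
#' the correction adapt to each dataset: the opening is the identity on
#' monotone drift and column bleed and annihilates features narrower than the
#' window, so peaks up to several peak-widths wide ride on the estimated
#' baseline untouched. Edges are handled by nearest-value padding, which
#' keeps the opening exact on monotone baselines at the boundaries. The
#' subtraction is exactly idempotent: every window of the corrected signal
#' touches zero at the cell where its block minimum was attained.
#'
#' @param trace A [raw_trace()].
#' @param params A [baseline_params()].
#' @return A baseline-corrected [raw_trace()] of identical length.
#' @export
dbc <- function(trace, params = baseline_params()) {
  stopifnot(inherits(trace, "raw_trace"), inherits(params, "baseline_params"))
  rate <- trace$sampling_rate
  x <- trace$intensities
  W <- round(params$dbc_window_factor * params$peak_width_2d * rate)
  if (W < 3) stop_config("DBC window is below 3 samples; increase the peak width or rate")
  W <- make_odd(W)
  out <- trace
  out$intensities <- x - opening(x, W)
  out
}

#' TopHat baseline correction (FID stream)
#'
#' Subtracts the morphological opening (flat erosion then dilation) of the
#' signal with a structuring element of width
#' `round(tophat_factor * peak_width_2d * rate)`, incremented to odd. Since
#' the opening never exceeds the signal, the output is non-negative
#' everywhere.
#'
#' @param trace A [raw_trace()].
#' @param params A [baseline_params()].
#' @return A baseline-corrected [raw_trace()] of identical length.
#' @export
tophat <- function(trace, params = baseline_params()) {
  stopifnot(inherits(trace, "raw_trace"), inherits(params, "baseline_params"))
  rate <- trace$sampling_rate
  x <- trace$intensities
  S <- round(params$tophat_factor * params$peak_width_2d * rate)
  if (S < 3) stop_config("TopHat structuring element is below 3 samples; increase the peak width or rate")
  S <- make_odd(S)
  out <- trace
  out$intensities <- x - opening(x, S)
  out
}

#' Estimate the second-dimension peak width from a representative sample
#'
#' Implements the width-averaging procedure used to set the baseline
#' correction parameter: candidate peaks are detected, stratified into
#' `n_peaks` log-spaced height bins spanning the detected dynamic range, one
#' peak is taken per bin (the one nearest the bin's geometric-mean height;
#' ties resolved toward earlier first-dimension retention), the full width at
#' half maximum of each is measured along the second dimension, and the
#' arithmetic mean is returned.
#'
#' @param plane A baseline-corrected [chromatogram2d()].
#' @param n_peaks Number of peaks to average (default 10).
#' @param params A [detect_params()] used for candidate detection.
#' @return Mean FWHM in seconds.
#' @export
estimate_peak_width <- function(plane, n_peaks = 10,
                                params = detect_params()) {
  stopifnot(inherits(plane, "chromatogram2d"))
  pk <- detect_peaks(plane, params)
  if (nrow(pk) < n_peaks)
    stop_config(sprintf(
      "only %d candidate peaks detected; call with n_peaks <= %d",
      nrow(pk), nrow(pk)))
  h <- pk$height
  if (max(h) - min(h) < 1e-12 * max(h)) {
    sel <- order(pk$apex_col, pk$apex_row)[seq_len(n_peaks)]
  } else {
    edges <- exp(seq(log(min(h)), log(max(h)), length.out = n_peaks + 1))
    gm <- sqrt(edges[-1] * edges[-(n_peaks + 1)])
    chosen <- integer(0)
    for (b in seq_len(n_peaks)) {
      in_bin <- setdiff(which(h >= edges[b] & h <= edges[b + 1]), chosen)
      cand <- if (length(in_bin)) in_bin else
        setdiff(seq_along(h), chosen)
      d <- abs(log(h[cand]) - log(gm[b]))
      chosen <- c(chosen,
                  cand[order(d, pk$apex_col[cand], pk$apex_row[cand])[1]])
    }
    sel <- chosen
  }
  mean(pk$fwhm_2d[sel])
}
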