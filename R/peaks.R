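# 2D peak detection and delineation on a baseline-corrected retention plane.

#' Peak-detection parameters
#'
#' @param snr_min Minimum apex signal-to-noise ratio (default 10).
#' @param min_volume Minimum integrated volume in counts * s (default 0).
#' @param smooth_sigma_2d Second-dimension Gaussian pre-smoothing sigma in
#'   seconds; defaults to a quarter of the 0.35 s reference peak width.
#' @param boundary_fraction Footprint boundary as a fraction of apex height
#'   (default 0.05).
#' @return An object of class `detect_params`.
#' @export
detect_params <- function(snr_min = 10, min_volume = 0,
                          smooth_sigma_2d = 0.35 / 4,
                          boundary_fraction = 0.05) {
  if (snr_min <= 0) stop_config("snr_min must be > 0")
  if (boundary_fraction <= 0 || boundary_fraction >= 1)
    stop_config("boundary_fraction must be in (0, 1)")
  if (min_volume < 0) stop_config("min_volume must be >= 0")
  if (smooth_sigma_2d < 0) stop_config("smooth_sigma_2d must be >= 0")
  structure(list(snr_min = snr_min, min_volume = min_volume,
                 smooth_sigma_2d = smooth_sigma_2d,
                 boundary_fraction = boundary_fraction),
            class = "detect_params")
}

#' Robust noise estimate of a plane
#'
#' `1.4826 * median(|x - median(plane)|)` over the cells lying below the
#' plane's median, so that the sparse, strictly positive peaks do not inflate
#' the estimate. For half-Gaussian deviations this recovers the noise sigma.
#'
#' @param plane A [chromatogram2d()].
#' @return Noise level in counts (0 for a constant plane).
#' @export
estimate_noise <- function(plane) {
  stopifnot(inherits(plane, "chromatogram2d"))
  v <- as.vector(plane$values)
  m <- median(v)
  dev <- m - v[v < m]
  if (!length(dev)) return(0)
  1.4826 * median(dev)
}

# Separable Gaussian blur with nearest-value edge padding.
blur_dim1 <- function(m, sigma) {
  if (sigma <= 0) return(m)
  k <- max(1L, as.integer(ceiling(3 * sigma)))
  ker <- dnorm(seq(-k, k), sd = sigma)
  ker <- ker / sum(ker)
  n <- nrow(m)
  mp <- rbind(m[rep(1L, k), , drop = FALSE], m,
              m[rep(n, k), , drop = FALSE])
  f <- stats::filter(mp, ker, sides = 2)
  matrix(as.numeric(f[(k + 1):(k + n), ]), nrow = n)
}

gauss_blur2 <- function(m, sigma_row, sigma_col) {
  t(blur_dim1(t(blur_dim1(m, sigma_row)), sigma_col))
}

# 4-connected flood fill from (r0, c0) over cells with v >= thr; returns
# linear indices.
flood_fill <- function(v, r0, c0, thr) {
  nr <- nrow(v)
  nc <- ncol(v)
  seed <- (c0 - 1L) * nr + r0
  if (v[seed] < thr) return(seed)
  visited <- logical(nr * nc)
  visited[seed] <- TRUE
  queue <- seed
  out <- integer(0)
  while (length(queue)) {
    cur <- queue[length(queue)]
    queue <- queue[-length(queue)]
    out <- c(out, cur)
    r <- (cur - 1L) %% nr + 1L
    cl <- (cur - 1L) %/% nr + 1L
    nb <- c(if (r > 1L) cur - 1L, if (r < nr) cur + 1L,
            if (cl > 1L) cur - nr, if (cl < nc) cur + nr)
    nb <- nb[!visited[nb]]
    visited[nb] <- TRUE
    queue <- c(queue, nb[v[nb] >= thr])
  }
  sort(out)
}

# Interpolated full width at half maximum of a 1D profile around index i0.
fwhm_profile <- function(p, i0) {
  half <- p[i0] / 2
  n <- length(p)
  up <- NA_real_
  for (i in seq(i0, n)) {
    if (p[i] <= half) {
      up <- (i - 1 - i0) + (p[i - 1] - half) / (p[i - 1] - p[i])
      break
    }
  }
  if (is.na(up)) up <- n - i0 + 0.5
  dn <- NA_real_
  for (i in seq(i0, 1)) {
    if (p[i] <= half) {
      dn <- (i0 - i - 1) + (p[i + 1] - half) / (p[i + 1] - p[i])
      break
    }
  }
  if (is.na(dn)) dn <- i0 - 1 + 0.5
  up + dn
}

empty_peaks <- function() {
  df <- data.frame(id = character(0), apex_1tR = numeric(0),
                   apex_2tR = numeric(0), apex_row = integer(0),
                   apex_col = integer(0), height = numeric(0),
                   volume = numeric(0), fwhm_1d = numeric(0),
                   fwhm_2d = numeric(0), stringsAsFactors = FALSE)
  df$footprint <- list()
  df
}

#' Detect and delineate 2D peaks
#'
#' The plane is pre-smoothed with a separable 2D Gaussian (one modulation
#' along the first dimension, `smooth_sigma_2d` along the second); local
#' maxima of the smoothed plane above `snr_min * noise` are snapped to the
#' tallest unsmoothed cell within one cell and grown into 4-connected
#' footprints by flood fill on the unsmoothed plane down to
#' `max(boundary_fraction * apex, snr_min * noise)`. Maxima whose footprints
#' overlap are merged keeping the tallest (ties resolved toward smaller
#' column, then smaller row), footprints of distinct peaks are disjoint, and
#' peaks below `min_volume` are dropped. The result is ordered by apex
#' (column, row).
#'
#' @param plane A baseline-corrected [chromatogram2d()].
#' @param params A [detect_params()].
#' @return A data.frame of class `peak_set` with one row per peak:
#'   `apex_1tR` (minutes), `apex_2tR` (seconds), `apex_row`, `apex_col`,
#'   `height` (counts), `volume` (counts * s), `fwhm_1d` (modulations),
#'   `fwhm_2d` (seconds), and a `footprint` list column of linear cell
#'   indices.
#' @export
detect_peaks <- function(plane, params = detect_params()) {
  stopifnot(inherits(plane, "chromatogram2d"),
            inherits(params, "detect_params"))
  v <- plane$values
  nr <- nrow(v)
  nc <- ncol(v)
  noise <- estimate_noise(plane)
  sm <- gauss_blur2(v, sigma_row = params$smooth_sigma_2d * plane$rate,
                    sigma_col = 1)
  thr <- params$snr_min * noise
  # local maxima on the smoothed plane (8-neighborhood, edges padded -Inf)
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- sm
  is_max <- matrix(TRUE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    is_max <- is_max & sm >= pad[(2 + dr):(nr + 1 + dr),
                                 (2 + dc):(nc + 1 + dc)]
  }
  is_max <- is_max & sm > thr & sm > 0
  idx <- which(is_max, arr.ind = TRUE)
  if (!nrow(idx)) return(structure(empty_peaks(),
                                   class = c("peak_set", "data.frame")))
  # snap each maximum to the tallest raw cell within one cell
  ap <- t(apply(idx, 1, function(rc) {
    rr <- max(1, rc[1] - 1):min(nr, rc[1] + 1)
    cc <- max(1, rc[2] - 1):min(nc, rc[2] + 1)
    w <- v[rr, cc, drop = FALSE]
    k <- which(w == max(w), arr.ind = TRUE)[1, ]
    c(rr[k[1]], cc[k[2]])
  }))
  heights <- v[ap]
  ord <- order(-heights, ap[, 2], ap[, 1])
  claimed <- logical(nr * nc)
  keep <- list()
  for (i in ord) {
    h <- heights[i]
    if (h <= 0 || h < thr) next
    tfill <- max(params$boundary_fraction * h, thr)
    fp <- flood_fill(v, ap[i, 1], ap[i, 2], tfill)
    if (any(claimed[fp])) next # merged into an already-kept taller peak
    claimed[fp] <- TRUE
    keep[[length(keep) + 1]] <- list(row = ap[i, 1], col = ap[i, 2],
                                     height = h, fp = fp)
  }
  if (!length(keep)) return(structure(empty_peaks(),
                                      class = c("peak_set", "data.frame")))
  rows <- vapply(keep, `[[`, integer(1), "row")
  cols <- vapply(keep, `[[`, integer(1), "col")
  o <- order(cols, rows)
  keep <- keep[o]
  n <- length(keep)
  df <- data.frame(id = sprintf("P%04d", seq_len(n)),
                   apex_1tR = numeric(n), apex_2tR = numeric(n),
                   apex_row = integer(n), apex_col = integer(n),
                   height = numeric(n), volume = numeric(n),
                   fwhm_1d = numeric(n), fwhm_2d = numeric(n),
                   stringsAsFactors = FALSE)
  df$footprint <- vector("list", n)
  for (i in seq_len(n)) {
    k <- keep[[i]]
    ret <- index_to_retention(plane, k$row, k$col)
    df$apex_1tR[i] <- ret$t1
    df$apex_2tR[i] <- ret$t2
    df$apex_row[i] <- k$row
    df$apex_col[i] <- k$col
    df$height[i] <- k$height
    df$volume[i] <- sum(pmax(v[k$fp], 0)) / plane$rate
    df$fwhm_2d[i] <- fwhm_profile(v[, k$col], k$row) / plane$rate
    df$fwhm_1d[i] <- fwhm_profile(v[k$row, ], k$col)
    df$footprint[[i]] <- k$fp
  }
  df <- df[df$volume >= params$min_volume, , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("peak_set", "data.frame"))
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("peak_set: %d peaks\n", nrow(x)))
  if (nrow(x))
    print.data.frame(x[, setdiff(names(x), "footprint")], digits = 4)
  invisible(x)
}

#' Integrate the volume of a footprint
#'
#' Sum of the plane over the footprint cells times the second-dimension dwell
#' time `1/rate`; negative cells are clipped to 0.
#'
#' @param plane A [chromatogram2d()].
#' @param footprint Integer vector of linear cell indices (as stored in the
#'   `footprint` column of [detect_peaks()] output) or a two-column
#'   (row, col) matrix.
#' @return Volume in counts * s.
#' @export
integrate_volume <- function(plane, footprint) {
  stopifnot(inherits(plane, "chromatogram2d"))
  v <- plane$values
  if (is.matrix(footprint)) {
    if (ncol(footprint) != 2) stop_config("footprint matrix must have 2 columns")
    footprint <- (footprint[, 2] - 1L) * nrow(v) + footprint[, 1]
  }
  if (!length(footprint)) stop_config("footprint must be non-empty")
  if (any(footprint < 1 | footprint > length(v)))
    stop_config("footprint cells out of range")
  sum(pmax(v[footprint], 0)) / plane$rate
}
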