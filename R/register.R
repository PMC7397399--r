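# Estimating and applying the rigid retention-plane shift that aligns an
# MS-derived stencil onto the FID plane of the same sample. The channels run
# at different rates (e.g. 41.5 vs 120 Hz) and the MS operates under vacuum
# while the FID sits at atmospheric pressure, so a small translation is
# expected; no warping is performed.

#' Resample a plane's second-dimension grid to a target rate
#'
#' Each column (one modulation) is linearly interpolated onto the target
#' grid; the column count is unchanged.
#'
#' @param plane A [chromatogram2d()].
#' @param target_rate Target second-dimension sampling rate (Hz).
#' @return A [chromatogram2d()] at `target_rate`.
#' @export
resample_to_grid <- function(plane, target_rate) {
  stopifnot(inherits(plane, "chromatogram2d"))
  if (target_rate <= 0) stop_config("target_rate must be > 0")
  npm <- plane$pm * target_rate
  n_t <- if (abs(npm - round(npm)) < 1e-6) as.integer(round(npm))
  else as.integer(ceiling(npm))
  src_t <- (seq_len(nrow(plane$values)) - 1) / plane$rate
  tgt_t <- (seq_len(n_t) - 1) / target_rate
  if (length(src_t) == 1) {
    m <- matrix(rep(plane$values[1, ], each = n_t), nrow = n_t)
  } else {
    m <- apply(plane$values, 2, function(col)
      approx(src_t, col, xout = tgt_t, rule = 2)$y)
    m <- matrix(m, nrow = n_t)
  }
  chromatogram2d(m, plane$pm, target_rate, channel = plane$channel,
                 sample_id = plane$sample_id)
}

#' Shift transform between two planes
#'
#' @param d1t First-dimension shift (minutes, signed).
#' @param d2t Second-dimension shift (seconds, signed).
#' @param score Correlation achieved at this shift.
#' @return An object of class `shift_transform`.
#' @export
shift_transform <- function(d1t, d2t, score = NA_real_) {
  structure(list(d1t = d1t, d2t = d2t, score = score),
            class = "shift_transform")
}

#' @export
print.shift_transform <- function(x, ...) {
  cat(sprintf("shift_transform: d1t %+.4f min, d2t %+.4f s (score %.4f)\n",
              x$d1t, x$d2t, x$score))
  invisible(x)
}

#' Estimate the MS-to-FID retention shift
#'
#' Exhaustive normalized cross-correlation over integer (column, row) shifts
#' within the search bounds, computed on rank-transformed planes (robust to
#' the large dynamic-range difference between channels and to the unequal
#' detector split). The MS plane is first resampled onto the FID grid if the
#' rates differ. Ties are broken toward the smallest shift norm, then the
#' smaller first-dimension shift. A warning is raised when the optimum lies
#' on the search boundary.
#'
#' @param plane_ms Baseline-corrected MS [chromatogram2d()].
#' @param plane_fid Baseline-corrected FID [chromatogram2d()] of the same
#'   sample.
#' @param max_d1t Search half-range in modulations (default 5).
#' @param max_d2t Search half-range in seconds (default 0.25).
#' @return A [shift_transform()] such that a stencil built on the MS plane,
#'   translated by `(d1t, d2t)`, lands on the FID plane.
#' @export
estimate_shift <- function(plane_ms, plane_fid, max_d1t = 5,
                           max_d2t = 0.25) {
  stopifnot(inherits(plane_ms, "chromatogram2d"),
            inherits(plane_fid, "chromatogram2d"))
  if (abs(plane_ms$rate - plane_fid$rate) > 1e-9 * plane_fid$rate)
    plane_ms <- resample_to_grid(plane_ms, plane_fid$rate)
  A <- matrix(rank(plane_ms$values), nrow(plane_ms$values))
  B <- matrix(rank(plane_fid$values), nrow(plane_fid$values))
  if (sd(A) == 0 || sd(B) == 0)
    stop_config("cannot register a constant plane")
  R <- as.integer(round(max_d2t * plane_fid$rate))
  C <- as.integer(round(max_d1t))
  nrA <- nrow(A); ncA <- ncol(A)
  nrB <- nrow(B); ncB <- ncol(B)
  grid <- expand.grid(dr = -R:R, dc = -C:C)
  scores <- rep(NA_real_, nrow(grid))
  for (g in seq_len(nrow(grid))) {
    dr <- grid$dr[g]; dc <- grid$dc[g]
    # feature at A[r, c] appears at B[r + dr, c + dc]
    r0 <- max(1L, 1L - dr); r1 <- min(nrA, nrB - dr)
    c0 <- max(1L, 1L - dc); c1 <- min(ncA, ncB - dc)
    if (r1 - r0 < 2L || c1 - c0 < 2L) next
    rA <- r0:r1
    cA <- c0:c1
    a <- A[rA, cA]
    b <- B[rA + dr, cA + dc]
    if (sd(a) == 0 || sd(b) == 0) next
    scores[g] <- cor(as.vector(a), as.vector(b))
  }
  if (all(is.na(scores))) stop_config("no valid overlap in the search range")
  o <- order(-round(scores, 10), grid$dr^2 + grid$dc^2, abs(grid$dc),
             abs(grid$dr), na.last = TRUE)[1]
  dr <- grid$dr[o]; dc <- grid$dc[o]
  if (abs(dr) == R || abs(dc) == C)
    warning("best shift lies on the search boundary; widen max_d1t/max_d2t")
  shift_transform(d1t = dc * plane_fid$pm / 60, d2t = dr / plane_fid$rate,
                  score = scores[o])
}

#' Translate a stencil by a shift transform
#'
#' Every region is translated by `(d1t, d2t)`; ids, names and spectra are
#' unchanged. When `plane` is supplied, regions are clipped to its extent
#' (with a warning if any region loses more than half its area) and a region
#' falling fully outside the plane is an error.
#'
#' @param stn A [stencil()].
#' @param shift A [shift_transform()].
#' @param plane Optional target [chromatogram2d()] for clipping; its channel
#'   is adopted as the stencil's `source_channel` so the stencil is marked as
#'   registered to that channel.
#' @return The translated [stencil()].
#' @export
apply_shift <- function(stn, shift, plane = NULL) {
  stopifnot(inherits(stn, "stencil"), inherits(shift, "shift_transform"))
  rg <- stn$regions
  rg$t1_lo <- rg$t1_lo + shift$d1t
  rg$t1_hi <- rg$t1_hi + shift$d1t
  rg$t2_lo <- rg$t2_lo + shift$d2t
  rg$t2_hi <- rg$t2_hi + shift$d2t
  ch <- stn$source_channel
  if (!is.null(plane)) {
    stopifnot(inherits(plane, "chromatogram2d"))
    ext <- plane_extent(plane)
    outside <- rg$t1_hi < ext$t1[1] | rg$t1_lo > ext$t1[2] |
      rg$t2_hi < ext$t2[1] | rg$t2_lo > ext$t2[2]
    if (any(outside))
      stop_config(paste0("region(s) fully outside plane after shift: ",
                         paste(rg$id[outside], collapse = ", ")))
    area0 <- (rg$t1_hi - rg$t1_lo) * (rg$t2_hi - rg$t2_lo)
    rg$t1_lo <- pmax(rg$t1_lo, ext$t1[1])
    rg$t1_hi <- pmin(rg$t1_hi, ext$t1[2])
    rg$t2_lo <- pmax(rg$t2_lo, ext$t2[1])
    rg$t2_hi <- pmin(rg$t2_hi, ext$t2[2])
    area1 <- (rg$t1_hi - rg$t1_lo) * (rg$t2_hi - rg$t2_lo)
    if (any(area1 < 0.5 * area0))
      warning(paste0("region(s) clipped by more than 50%: ",
                     paste(rg$id[area1 < 0.5 * area0], collapse = ", ")))
    ch <- plane$channel
  }
  stencil(rg, source_channel = ch)
}

#' Snap one region onto the local intensity maximum
#'
#' If the tallest cell inside the region's tolerance-expanded window lies
#' outside the region, the region is re-centered on that cell (size
#' preserved); otherwise, and when the window holds no positive signal, the
#' region is returned unchanged.
#'
#' @param region A single-row slice of a stencil's `regions` data.frame.
#' @param plane_fid The registered-channel [chromatogram2d()].
#' @param tol_1t Window expansion in modulations (default 1).
#' @param tol_2t Window expansion in seconds (default 0.1).
#' @return The (possibly re-centered) single-row region.
#' @export
local_snap <- function(region, plane_fid, tol_1t = 1, tol_2t = 0.1) {
  stopifnot(inherits(plane_fid, "chromatogram2d"))
  v <- plane_fid$values
  pm_min <- plane_fid$pm / 60
  rate <- plane_fid$rate
  c_lo <- max(1L, as.integer(floor((region$t1_lo - tol_1t * pm_min) * 60 /
                                     plane_fid$pm)) + 1L)
  c_hi <- min(ncol(v), as.integer(ceiling((region$t1_hi + tol_1t * pm_min) *
                                            60 / plane_fid$pm)) + 1L)
  r_lo <- max(1L, as.integer(floor((region$t2_lo - tol_2t) * rate)) + 1L)
  r_hi <- min(nrow(v), as.integer(ceiling((region$t2_hi + tol_2t) * rate)) +
                1L)
  if (c_lo > c_hi || r_lo > r_hi) return(region)
  w <- v[r_lo:r_hi, c_lo:c_hi, drop = FALSE]
  if (max(w) <= 0) return(region)
  k <- which(w == max(w), arr.ind = TRUE)[1, ]
  ret <- index_to_retention(plane_fid, r_lo + k[1] - 1L, c_lo + k[2] - 1L)
  inside <- ret$t1 >= region$t1_lo && ret$t1 <= region$t1_hi &&
    ret$t2 >= region$t2_lo && ret$t2 <= region$t2_hi
  if (inside) return(region)
  d1 <- ret$t1 - (region$t1_lo + region$t1_hi) / 2
  d2 <- ret$t2 - (region$t2_lo + region$t2_hi) / 2
  region$t1_lo <- region$t1_lo + d1
  region$t1_hi <- region$t1_hi + d1
  region$t2_lo <- region$t2_lo + d2
  region$t2_hi <- region$t2_hi + d2
  region
}
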