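# Stencil construction from detected MS peaks: autostencils, apex spectra,
# spectral matching, and incremental merging across samples.

next_region_ids <- function(existing, n) {
  nums <- suppressWarnings(as.integer(sub("^R", "", existing)))
  start <- if (length(nums) && any(!is.na(nums))) max(nums, na.rm = TRUE)
  else 0L
  sprintf("R%04d", start + seq_len(n))
}

#' Apex mass spectrum of a detected peak
#'
#' The spectrum of the scan nearest the peak's apex retention time,
#' normalized so the base peak has relative intensity 1. The apex scan is
#' used (rather than a footprint average) because dynamic baseline correction
#' has already removed background and the apex maximizes analyte purity.
#'
#' @param scans The [scan_stream()] the MS plane was folded from.
#' @param peak A single-row subset of a [detect_peaks()] result.
#' @param plane The MS [chromatogram2d()] the peak was detected on.
#' @param mz_range Optional `c(min, max)` restriction of the returned m/z.
#' @return A two-column `mz` / `rel_int` matrix.
#' @export
region_spectrum <- function(scans, peak, plane, mz_range = NULL) {
  stopifnot(inherits(scans, "scan_stream"),
            inherits(plane, "chromatogram2d"))
  if (nrow(peak) != 1L) stop_config("peak must be a single row")
  t_apex <- peak$apex_1tR * 60 + peak$apex_2tR
  tt <- scans$scan_times
  if (t_apex < min(tt) - 1e-9 || t_apex > max(tt) + 1e-9)
    stop_config("apex retention maps outside the scan-time range")
  i <- which.min(abs(tt - t_apex))
  mz <- scans$mz[[i]]
  iv <- scans$intensity[[i]]
  if (!is.null(mz_range)) {
    keep <- mz >= mz_range[1] & mz <= mz_range[2]
    mz <- mz[keep]
    iv <- iv[keep]
  }
  if (!length(mz) || max(iv) <= 0)
    stop_config(sprintf("apex scan %d has an empty spectrum", i))
  cbind(mz = mz, rel_int = iv / max(iv))
}

#' Build a stencil automatically from detected peaks
#'
#' One axis-aligned rectangular region per peak: the bounding box of the
#' footprint expanded by half a grid cell plus `(pad_1t, pad_2t)`, clipped to
#' the plane extent. Regions are labelled `"R0001"`, ... in detection order
#' with names `"Unknown_<id>"`, and carry the apex spectrum when the scan
#' stream is supplied.
#'
#' @param peaks A [detect_peaks()] result from one MS sample.
#' @param scans The matching [scan_stream()], or `NULL` to omit spectra.
#' @param plane The [chromatogram2d()] the peaks were detected on.
#' @param pad_1t First-dimension padding in modulations (default 1).
#' @param pad_2t Second-dimension padding in seconds (default 0.05).
#' @param mz_range Optional m/z restriction passed to [region_spectrum()].
#' @return A [stencil()].
#' @export
autostencil <- function(peaks, scans = NULL, plane, pad_1t = 1,
                        pad_2t = 0.05, mz_range = NULL) {
  stopifnot(inherits(plane, "chromatogram2d"))
  n <- nrow(peaks)
  ids <- next_region_ids(character(0), n)
  if (!n) return(stencil(source_channel = plane$channel))
  ext <- plane_extent(plane)
  nr <- nrow(plane$values)
  pm_min <- plane$pm / 60
  cell2 <- 1 / plane$rate
  df <- data.frame(id = ids, name = paste0("Unknown_", ids),
                   t1_lo = numeric(n), t1_hi = numeric(n),
                   t2_lo = numeric(n), t2_hi = numeric(n),
                   origin_sample = rep(plane$sample_id, n),
                   stringsAsFactors = FALSE)
  spectra <- vector("list", n)
  for (i in seq_len(n)) {
    fp <- peaks$footprint[[i]]
    rr <- (fp - 1L) %% nr + 1L
    cc <- (fp - 1L) %/% nr + 1L
    df$t1_lo[i] <- max(ext$t1[1],
                       (min(cc) - 1 - 0.5 - pad_1t) * pm_min)
    df$t1_hi[i] <- min(ext$t1[2],
                       (max(cc) - 1 + 0.5 + pad_1t) * pm_min)
    df$t2_lo[i] <- max(ext$t2[1],
                       (min(rr) - 1 - 0.5) * cell2 - pad_2t)
    df$t2_hi[i] <- min(ext$t2[2],
                       (max(rr) - 1 + 0.5) * cell2 + pad_2t)
    if (!is.null(scans))
      spectra[[i]] <- region_spectrum(scans, peaks[i, , drop = FALSE],
                                      plane, mz_range)
  }
  df$spectrum <- spectra
  stencil(df, source_channel = plane$channel)
}

#' Cosine similarity between two mass spectra
#'
#' Intensity vectors are aligned on the union of integer (rounded) m/z
#' values before the cosine is taken.
#'
#' @param a,b Two-column `mz` / `rel_int` matrices.
#' @return Cosine similarity in `[0, 1]`.
#' @export
spectral_cosine <- function(a, b) {
  for (s in list(a, b))
    if (!is.matrix(s) || ncol(s) != 2 || !nrow(s))
      stop_config("spectra must be non-empty two-column matrices")
  key_a <- round(a[, 1])
  key_b <- round(b[, 1])
  union_mz <- sort(unique(c(key_a, key_b)))
  va <- vapply(union_mz, function(m) sum(a[key_a == m, 2]), numeric(1))
  vb <- vapply(union_mz, function(m) sum(b[key_b == m, 2]), numeric(1))
  na <- sqrt(sum(va^2))
  nb <- sqrt(sum(vb^2))
  if (na == 0 || nb == 0) stop_config("spectra must have non-zero intensity")
  sum(va * vb) / (na * nb)
}

#' Merge newly detected peaks into an existing stencil
#'
#' Each peak is matched to an existing region if its apex lies inside the
#' region, or if the apex lies within `(rt_tol_1t, rt_tol_2t)` of the region
#' center and — when both spectra exist — the spectral cosine is at least
#' `cos_min`. Matched peaks add nothing (duplicate-marker filtering);
#' unmatched peaks append autostencil-style regions with fresh ids. Base
#' regions are never removed or shrunk, so merging is idempotent and region
#' ids stay unique through arbitrary merge sequences.
#'
#' @param base The [stencil()] accumulated so far (same channel as `plane`).
#' @param peaks A [detect_peaks()] result for the new sample.
#' @param scans The new sample's [scan_stream()] (or `NULL`).
#' @param plane The new sample's [chromatogram2d()].
#' @param rt_tol_1t First-dimension matching tolerance in modulations
#'   (default 1).
#' @param rt_tol_2t Second-dimension matching tolerance in seconds
#'   (default 0.1).
#' @param cos_min Minimum spectral cosine for a proximity match (default 0.8).
#' @param pad_1t,pad_2t Padding for appended regions, as in [autostencil()].
#' @param mz_range Optional m/z restriction for appended spectra.
#' @return The merged [stencil()].
#' @export
merge_stencil <- function(base, peaks, scans = NULL, plane, rt_tol_1t = 1,
                          rt_tol_2t = 0.1, cos_min = 0.8, pad_1t = 1,
                          pad_2t = 0.05, mz_range = NULL) {
  stopifnot(inherits(base, "stencil"), inherits(plane, "chromatogram2d"))
  if (!identical(base$source_channel, plane$channel))
    stop_config(sprintf("channel mismatch: stencil is '%s', plane is '%s'",
                        base$source_channel, plane$channel))
  if (!nrow(peaks)) return(base)
  rg <- base$regions
  tol1 <- rt_tol_1t * plane$pm / 60
  new_idx <- integer(0)
  for (i in seq_len(nrow(peaks))) {
    t1 <- peaks$apex_1tR[i]
    t2 <- peaks$apex_2tR[i]
    matched <- FALSE
    for (j in seq_len(nrow(rg))) {
      inside <- t1 >= rg$t1_lo[j] && t1 <= rg$t1_hi[j] &&
        t2 >= rg$t2_lo[j] && t2 <= rg$t2_hi[j]
      if (inside) {
        matched <- TRUE
        break
      }
      near <- abs(t1 - (rg$t1_lo[j] + rg$t1_hi[j]) / 2) <= tol1 &&
        abs(t2 - (rg$t2_lo[j] + rg$t2_hi[j]) / 2) <= rt_tol_2t
      if (near) {
        sp_r <- rg$spectrum[[j]]
        sp_p <- if (!is.null(scans))
          tryCatch(region_spectrum(scans, peaks[i, , drop = FALSE], plane,
                                   mz_range),
                   dualflow_config_error = function(e) NULL)
        else NULL
        ok <- if (!is.null(sp_r) && !is.null(sp_p))
          spectral_cosine(sp_r, sp_p) >= cos_min
        else TRUE
        if (ok) {
          matched <- TRUE
          break
        }
      }
    }
    if (!matched) new_idx <- c(new_idx, i)
  }
  if (!length(new_idx)) return(base)
  add <- autostencil(peaks[new_idx, , drop = FALSE], scans, plane,
                     pad_1t = pad_1t, pad_2t = pad_2t, mz_range = mz_range)
  add$regions$id <- next_region_ids(rg$id, nrow(add$regions))
  add$regions$name <- paste0("Unknown_", add$regions$id)
  merged <- rbind(rg[, setdiff(names(rg), "spectrum"), drop = FALSE],
                  add$regions[, setdiff(names(add$regions), "spectrum"),
                              drop = FALSE])
  merged$spectrum <- c(rg$spectrum, add$regions$spectrum)
  stencil(merged, source_channel = base$source_channel)
}
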