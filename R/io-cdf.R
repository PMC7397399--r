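# ANDI/AIA netCDF interchange: the minimal common variable sets of the
# chromatography dialect (ordinate_values + actual_sampling_interval) and the
# MS dialect (scan_index, point_count, mass_values, intensity_values,
# scan_acquisition_time, total_intensity). Vendor extensions are ignored.
# Intensities are always read as 64-bit doubles; time unit is seconds.

nc_open_checked <- function(path) {
  if (!file.exists(path)) stop_format(paste0("no such file: ", path))
  nc <- tryCatch(ncdf4::nc_open(path),
                 error = function(e)
                   stop_format(paste0("not a readable netCDF file: ", path,
                                      " (", conditionMessage(e), ")")))
  nc
}

nc_has_var <- function(nc, name) name %in% names(nc$var)

#' Write a single-channel chromatogram to ANDI/AIA netCDF
#'
#' @param trace A [raw_trace()].
#' @param path Output path (conventionally `*.cdf`).
#' @return `path`, invisibly.
#' @export
write_fid_cdf <- function(trace, path) {
  stopifnot(inherits(trace, "raw_trace"))
  n <- length(trace$intensities)
  dpt <- ncdf4::ncdim_def("point_number", "", seq_len(n),
                          create_dimvar = FALSE)
  v_ord <- ncdf4::ncvar_def("ordinate_values", "counts", dpt, prec = "double")
  v_int <- ncdf4::ncvar_def("actual_sampling_interval", "seconds", list(),
                            prec = "double")
  v_del <- ncdf4::ncvar_def("actual_delay_time", "seconds", list(),
                            prec = "double")
  nc <- ncdf4::nc_create(path, list(v_ord, v_int, v_del))
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  ncdf4::ncvar_put(nc, v_ord, trace$intensities)
  ncdf4::ncvar_put(nc, v_int, 1 / trace$sampling_rate)
  ncdf4::ncvar_put(nc, v_del, trace$start_time)
  ncdf4::ncatt_put(nc, 0, "detector_name", trace$channel)
  ncdf4::ncatt_put(nc, 0, "experiment_title", trace$sample_id)
  invisible(path)
}

#' Read a single-channel ANDI/AIA netCDF chromatogram
#'
#' The sampling rate is taken from `actual_sampling_interval` when present;
#' otherwise it is inferred from the median spacing of `raw_data_retention`,
#' rejecting files whose abscissa jitters by more than 1%.
#'
#' @param path Path to a `*.cdf` file.
#' @return A [raw_trace()].
#' @export
read_fid_cdf <- function(path) {
  nc <- nc_open_checked(path)
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  if (!nc_has_var(nc, "ordinate_values"))
    stop_format("missing required variable 'ordinate_values'")
  y <- as.numeric(ncdf4::ncvar_get(nc, "ordinate_values"))
  if (nc_has_var(nc, "actual_sampling_interval")) {
    dt <- as.numeric(ncdf4::ncvar_get(nc, "actual_sampling_interval"))[1]
    if (!is.finite(dt) || dt <= 0)
      stop_format("'actual_sampling_interval' must be a positive scalar")
    rate <- 1 / dt
  } else if (nc_has_var(nc, "raw_data_retention")) {
    tt <- as.numeric(ncdf4::ncvar_get(nc, "raw_data_retention"))
    if (length(tt) < 2) stop_format("abscissa too short to infer a rate")
    d <- diff(tt)
    med <- median(d)
    if (med <= 0 || any(abs(d - med) > 0.01 * med))
      stop_format("non-uniform abscissa: spacing jitter exceeds 1%")
    rate <- 1 / med
  } else {
    stop_format(paste0("missing sampling metadata: need ",
                       "'actual_sampling_interval' or 'raw_data_retention'"))
  }
  delay <- if (nc_has_var(nc, "actual_delay_time"))
    as.numeric(ncdf4::ncvar_get(nc, "actual_delay_time"))[1] else 0
  ch <- ncdf4::ncatt_get(nc, 0, "detector_name")
  sid <- ncdf4::ncatt_get(nc, 0, "experiment_title")
  raw_trace(y, rate,
            channel = if (ch$hasatt) ch$value else "FID",
            start_time = delay,
            sample_id = if (sid$hasatt) sid$value else NA_character_)
}

#' Write a mass-spectral scan stream to ANDI/MS netCDF
#'
#' @param scans A [scan_stream()].
#' @param path Output path (conventionally `*.cdf`).
#' @return `path`, invisibly.
#' @export
write_ms_cdf <- function(scans, path) {
  stopifnot(inherits(scans, "scan_stream"))
  counts <- lengths(scans$mz)
  total <- sum(counts)
  mass <- unlist(scans$mz, use.names = FALSE)
  inten <- unlist(scans$intensity, use.names = FALSE)
  if (total == 0) { # netCDF dims must be >= 1; flag the pad with count 0
    mass <- 0
    inten <- 0
  }
  nscan <- length(scans$scan_times)
  dsc <- ncdf4::ncdim_def("scan_number", "", seq_len(nscan),
                          create_dimvar = FALSE)
  dpt <- ncdf4::ncdim_def("point_number", "", seq_len(max(1L, total)),
                          create_dimvar = FALSE)
  v_si <- ncdf4::ncvar_def("scan_index", "", dsc, prec = "integer")
  v_pc <- ncdf4::ncvar_def("point_count", "", dsc, prec = "integer")
  v_mv <- ncdf4::ncvar_def("mass_values", "m/z", dpt, prec = "double")
  v_iv <- ncdf4::ncvar_def("intensity_values", "counts", dpt, prec = "double")
  v_st <- ncdf4::ncvar_def("scan_acquisition_time", "seconds", dsc,
                           prec = "double")
  v_ti <- ncdf4::ncvar_def("total_intensity", "counts", dsc, prec = "double")
  nc <- ncdf4::nc_create(path, list(v_si, v_pc, v_mv, v_iv, v_st, v_ti))
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  ncdf4::ncvar_put(nc, v_si, cumsum(c(0L, head(counts, -1L))))
  ncdf4::ncvar_put(nc, v_pc, counts)
  ncdf4::ncvar_put(nc, v_mv, mass)
  ncdf4::ncvar_put(nc, v_iv, inten)
  ncdf4::ncvar_put(nc, v_st, scans$scan_times)
  ncdf4::ncvar_put(nc, v_ti, scans$total_intensity)
  ncdf4::ncatt_put(nc, 0, "experiment_title", scans$sample_id)
  invisible(path)
}

#' Read an ANDI/MS netCDF scan stream
#'
#' Reassembles the ragged per-scan spectra from the flat `mass_values` /
#' `intensity_values` arrays via `scan_index`. The total ion current is
#' recomputed as the per-scan spectrum sum; a stored `total_intensity`
#' differing by more than 1% (relative) triggers a warning.
#'
#' @param path Path to a `*.cdf` file.
#' @return A [scan_stream()].
#' @export
read_ms_cdf <- function(path) {
  nc <- nc_open_checked(path)
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  for (v in c("scan_index", "mass_values", "intensity_values",
              "scan_acquisition_time"))
    if (!nc_has_var(nc, v))
      stop_format(paste0("missing required variable '", v, "'"))
  idx <- as.integer(ncdf4::ncvar_get(nc, "scan_index"))
  mass <- as.numeric(ncdf4::ncvar_get(nc, "mass_values"))
  inten <- as.numeric(ncdf4::ncvar_get(nc, "intensity_values"))
  times <- as.numeric(ncdf4::ncvar_get(nc, "scan_acquisition_time"))
  nscan <- length(idx)
  npt <- length(mass)
  if (nc_has_var(nc, "point_count")) {
    cnt <- as.integer(ncdf4::ncvar_get(nc, "point_count"))
  } else {
    cnt <- diff(c(idx, npt))
  }
  if (any(diff(idx) < 0))
    stop_format("inconsistent scan index: offsets not non-decreasing")
  if (any(cnt < 0))
    stop_format("inconsistent scan index: negative point counts")
  if (sum(cnt) > 0L) {
    if (any(idx + cnt > npt))
      stop_format("inconsistent scan index: offsets exceed array length")
    if (nscan > 1 && any(idx[-1] < (idx + cnt)[-nscan]))
      stop_format("inconsistent scan index: overlapping scans")
  }
  mzl <- vector("list", nscan)
  ivl <- vector("list", nscan)
  for (i in seq_len(nscan)) {
    if (cnt[i] == 0L) {
      mzl[[i]] <- numeric(0)
      ivl[[i]] <- numeric(0)
    } else {
      sel <- (idx[i] + 1L):(idx[i] + cnt[i])
      mzl[[i]] <- mass[sel]
      ivl[[i]] <- inten[sel]
    }
  }
  sid <- ncdf4::ncatt_get(nc, 0, "experiment_title")
  out <- scan_stream(times, mzl, ivl,
                     sample_id = if (sid$hasatt) sid$value else NA_character_)
  if (nc_has_var(nc, "total_intensity")) {
    stored <- as.numeric(ncdf4::ncvar_get(nc, "total_intensity"))
    pos <- stored > 0
    if (any(pos) &&
        any(abs(out$total_intensity[pos] - stored[pos]) / stored[pos] > 0.01))
      warning("stored total_intensity differs from recomputed TIC by > 1%")
  }
  out
}

#' Write a folded chromatogram plane to a netCDF grid container
#'
#' Portable on-disk form of a [chromatogram2d()]: a 2D `intensity_values`
#' grid (second-dimension point x modulation) with the modulation period,
#' rate, channel, and sample id as global attributes.
#'
#' @param plane A [chromatogram2d()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plane_cdf <- function(plane, path) {
  stopifnot(inherits(plane, "chromatogram2d"))
  drow <- ncdf4::ncdim_def("second_dim_point", "", seq_len(nrow(plane$values)),
                           create_dimvar = FALSE)
  dcol <- ncdf4::ncdim_def("modulation", "", seq_len(ncol(plane$values)),
                           create_dimvar = FALSE)
  v <- ncdf4::ncvar_def("intensity_values", "counts", list(drow, dcol),
                        prec = "double")
  nc <- ncdf4::nc_create(path, list(v))
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  ncdf4::ncvar_put(nc, v, plane$values)
  ncdf4::ncatt_put(nc, 0, "modulation_period", plane$pm, prec = "double")
  ncdf4::ncatt_put(nc, 0, "sampling_rate", plane$rate, prec = "double")
  ncdf4::ncatt_put(nc, 0, "detector_name", plane$channel)
  ncdf4::ncatt_put(nc, 0, "experiment_title", plane$sample_id)
  invisible(path)
}

#' Read a folded chromatogram plane written by [write_plane_cdf()]
#'
#' @param path Path to the netCDF grid container.
#' @return A [chromatogram2d()].
#' @export
read_plane_cdf <- function(path) {
  nc <- nc_open_checked(path)
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  if (!nc_has_var(nc, "intensity_values"))
    stop_format("missing required variable 'intensity_values'")
  m <- ncdf4::ncvar_get(nc, "intensity_values", collapse_degen = FALSE)
  if (length(dim(m)) != 2) stop_format("'intensity_values' must be 2D")
  pm <- ncdf4::ncatt_get(nc, 0, "modulation_period")
  rate <- ncdf4::ncatt_get(nc, 0, "sampling_rate")
  if (!pm$hasatt || !rate$hasatt)
    stop_format("missing 'modulation_period'/'sampling_rate' attributes")
  ch <- ncdf4::ncatt_get(nc, 0, "detector_name")
  sid <- ncdf4::ncatt_get(nc, 0, "experiment_title")
  chromatogram2d(matrix(as.numeric(m), nrow = dim(m)[1]), pm$value,
                 rate$value,
                 channel = if (ch$hasatt) ch$value else "FID",
                 sample_id = if (sid$hasatt) sid$value else NA_character_)
}
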