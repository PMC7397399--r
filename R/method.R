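#' Oven temperature program
#'
#' A single-ramp GC oven program: an initial isothermal hold, a linear ramp,
#' and a final isothermal hold.
#'
#' @param initial_temp Initial oven temperature (degrees Celsius).
#' @param initial_hold Initial hold time (minutes, >= 0).
#' @param ramp_rate Ramp rate (degrees Celsius per minute, > 0).
#' @param final_temp Final oven temperature (degrees Celsius, must exceed
#'   `initial_temp`).
#' @param final_hold Final hold time (minutes, >= 0).
#' @return An object of class `oven_program`.
#' @examples
#' oven_program(60, 1, 5, 250, 10)
#' @export
oven_program <- function(initial_temp, initial_hold, ramp_rate, final_temp,
                         final_hold) {
  for (v in list(initial_temp, initial_hold, ramp_rate, final_temp,
                 final_hold)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop_config("oven program fields must be finite numeric scalars")
  }
  if (final_temp <= initial_temp)
    stop_config("final_temp must exceed initial_temp")
  if (ramp_rate <= 0) stop_config("ramp_rate must be > 0")
  if (initial_hold < 0 || final_hold < 0)
    stop_config("hold times must be >= 0")
  structure(list(initial_temp = initial_temp, initial_hold = initial_hold,
                 ramp_rate = ramp_rate, final_temp = final_temp,
                 final_hold = final_hold),
            class = "oven_program")
}

#' Acquisition method configuration
#'
#' Instrument/method metadata that parameterizes folding and file validation.
#'
#' @param modulation_period Modulation period of the thermal/flow modulator
#'   (seconds, > 0).
#' @param fid_rate FID sampling rate (Hz, > 0).
#' @param ms_scan_time Total quadrupole scan time (seconds, > 0); the MS
#'   acquisition rate is its reciprocal.
#' @param oven An [oven_program()].
#' @param mz_min,mz_max Scan range bounds (integer m/z, `mz_min < mz_max`).
#' @param flush_time Modulator flush time (milliseconds); metadata only.
#' @param split_ratio_fid_to_ms Effluent split between FID and MS
#'   (dimensionless); metadata only.
#' @return An object of class `acquisition_config`.
#' @examples
#' acquisition_config(2.5, 120, 0.0241, oven_program(60, 1, 5, 250, 10))
#' @export
acquisition_config <- function(modulation_period, fid_rate, ms_scan_time,
                               oven, mz_min = 40L, mz_max = 300L,
                               flush_time = 100, split_ratio_fid_to_ms = 4.5) {
  if (!inherits(oven, "oven_program"))
    stop_config("oven must be an oven_program")
  if (modulation_period <= 0) stop_config("modulation_period must be > 0")
  if (fid_rate <= 0) stop_config("fid_rate must be > 0")
  if (ms_scan_time <= 0) stop_config("ms_scan_time must be > 0")
  if (mz_min >= mz_max) stop_config("mz_min must be < mz_max")
  structure(list(modulation_period = modulation_period, fid_rate = fid_rate,
                 ms_scan_time = ms_scan_time, oven = oven,
                 mz_min = as.integer(mz_min), mz_max = as.integer(mz_max),
                 flush_time = flush_time,
                 split_ratio_fid_to_ms = split_ratio_fid_to_ms),
            class = "acquisition_config")
}

#' Total run time of an oven program
#'
#' `initial_hold + (final_temp - initial_temp) / ramp_rate + final_hold`.
#'
#' @param oven An [oven_program()].
#' @return Run time in minutes.
#' @examples
#' total_run_time(oven_program(60, 1, 5, 250, 10)) # 49 min
#' @export
total_run_time <- function(oven) {
  if (!inherits(oven, "oven_program"))
    stop_config("oven must be an oven_program")
  oven$initial_hold +
    (oven$final_temp - oven$initial_temp) / oven$ramp_rate +
    oven$final_hold
}

#' MS acquisition rate from the total scan time
#'
#' Stored at full precision; round only when reporting (summaries print it to
#' one decimal place).
#'
#' @param scan_time Total scan time (seconds, > 0).
#' @return Acquisition rate in Hz (scans per second).
#' @examples
#' round(acquisition_rate(0.0241), 1) # 41.5
#' @export
acquisition_rate <- function(scan_time) {
  if (!is.numeric(scan_time) || length(scan_time) != 1L ||
      !is.finite(scan_time) || scan_time <= 0)
    stop_config("scan_time must be a positive number")
  1 / scan_time
}

#' Expected number of complete modulations in a run
#'
#' A trailing partial modulation carries no complete second-dimension trace
#' and is discarded, hence the floor.
#'
#' @param cfg An [acquisition_config()].
#' @return Integer count of complete modulation cycles.
#' @export
expected_modulations <- function(cfg) {
  if (!inherits(cfg, "acquisition_config"))
    stop_config("cfg must be an acquisition_config")
  as.integer(floor(total_run_time(cfg$oven) * 60 / cfg$modulation_period +
                     1e-9))
}

#' Read a method configuration from YAML
#'
#' The file mirrors the [acquisition_config()] field names, with the oven
#' program nested under `oven`.
#'
#' @param path Path to a YAML file.
#' @return An [acquisition_config()].
#' @export
read_method_config <- function(path) {
  if (!file.exists(path)) stop_format(paste0("no such file: ", path))
  y <- yaml::read_yaml(path)
  req <- c("modulation_period", "fid_rate", "ms_scan_time", "oven")
  miss <- setdiff(req, names(y))
  if (length(miss))
    stop_format(paste0("method config missing field(s): ",
                       paste(miss, collapse = ", ")))
  ov <- y$oven
  req_o <- c("initial_temp", "initial_hold", "ramp_rate", "final_temp",
             "final_hold")
  miss <- setdiff(req_o, names(ov))
  if (length(miss))
    stop_format(paste0("oven program missing field(s): ",
                       paste(miss, collapse = ", ")))
  acquisition_config(
    modulation_period = y$modulation_period,
    fid_rate = y$fid_rate,
    ms_scan_time = y$ms_scan_time,
    oven = oven_program(ov$initial_temp, ov$initial_hold, ov$ramp_rate,
                        ov$final_temp, ov$final_hold),
    mz_min = y$mz_min %||% 40L,
    mz_max = y$mz_max %||% 300L,
    flush_time = y$flush_time %||% 100,
    split_ratio_fid_to_ms = y$split_ratio_fid_to_ms %||% 4.5
  )
}

#' Validate a method configuration and derive its summary quantities
#'
#' @param cfg An [acquisition_config()].
#' @param quiet Suppress the printed summary.
#' @return Invisibly, a list with `run_time_min`, `ms_rate_hz` (full
#'   precision), and `expected_modulations`.
#' @export
validate_method <- function(cfg, quiet = FALSE) {
  rt <- total_run_time(cfg$oven)
  rate <- acquisition_rate(cfg$ms_scan_time)
  nmod <- expected_modulations(cfg)
  if (!quiet) {
    cat(sprintf("total run time:       %g min\n", rt))
    cat(sprintf("MS acquisition rate:  %.1f scans/s\n", rate))
    cat(sprintf("FID sampling rate:    %g Hz\n", cfg$fid_rate))
    cat(sprintf("modulation period:    %g s\n", cfg$modulation_period))
    cat(sprintf("expected modulations: %d\n", nmod))
  }
  invisible(list(run_time_min = rt, ms_rate_hz = rate,
                 expected_modulations = nmod))
}

#' @export
print.oven_program <- function(x, ...) {
  cat(sprintf("oven program: %g C (%g min) -> %g C at %g C/min (%g min)\n",
              x$initial_temp, x$initial_hold, x$final_temp, x$ramp_rate,
              x$final_hold))
  invisible(x)
}

#' @export
print.acquisition_config <- function(x, ...) {
  cat("GCxGC dual-channel acquisition method\n")
  cat(sprintf("  modulation period %g s, flush %g ms\n", x$modulation_period,
              x$flush_time))
  cat(sprintf("  FID %g Hz; MS scan %g s (%0.1f scans/s), m/z %d-%d\n",
              x$fid_rate, x$ms_scan_time, 1 / x$ms_scan_time, x$mz_min,
              x$mz_max))
  print(x$oven)
  invisible(x)
}
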