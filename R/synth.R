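# Paired MS/FID synthetic samples with analytic ground truth. Peaks are pure
# 2D Gaussians (amplitude A, sigma1 in modulations, sigma2 in seconds) so the
# planted volume has the closed form 2*pi*A*sigma1*sigma2 counts*s on either
# channel's grid; the FID channel sees the same peaks scaled by the detector
# split gain, translated by a small inter-channel retention shift, and riding
# on linear drift plus an exponential column-bleed ramp with Gaussian noise.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Default acquisition method for synthetic samples
#'
#' The published detector rates, scan range and modulation period with a
#' short 4-minute oven program, so synthetic runs stay small while keeping
#' realistic grid geometry (96 modulations of 300 FID points / ~104 MS
#' points).
#'
#' @return An [acquisition_config()].
#' @export
synth_config <- function() {
  acquisition_config(modulation_period = 2.5, fid_rate = 120,
                     ms_scan_time = 0.0241,
                     oven = oven_program(60, 0.5, 50, 235, 0))
}

#' Planted-peak table
#'
#' @param t1 First-dimension retentions (minutes).
#' @param t2 Second-dimension retentions (seconds).
#' @param amplitude_ms Apex TIC amplitudes on the MS channel (counts).
#' @param sigma1 First-dimension sigma (modulations, default 1).
#' @param sigma2 Second-dimension sigma (seconds, default 0.05).
#' @param fid_gain FID/MS amplitude gain (default 4.5, the detector split).
#' @param spectrum List of two-column `mz` / `rel_int` matrices (max 1), one
#'   per peak, or `NULL` to draw 5-15 random fragment lines per peak in the
#'   scan range when the sample is generated.
#' @return A data.frame of class `planted_peaks`.
#' @export
planted_peaks <- function(t1, t2, amplitude_ms, sigma1 = 1, sigma2 = 0.05,
                          fid_gain = 4.5, spectrum = NULL) {
  n <- length(t1)
  if (length(t2) != n || length(amplitude_ms) != n)
    stop_config("t1, t2 and amplitude_ms must have equal length")
  if (any(amplitude_ms <= 0)) stop_config("amplitudes must be > 0")
  df <- data.frame(t1 = t1, t2 = t2, amplitude_ms = amplitude_ms,
                   sigma1 = rep_len(sigma1, n), sigma2 = rep_len(sigma2, n),
                   fid_gain = rep_len(fid_gain, n))
  if (any(df$sigma1 <= 0) || any(df$sigma2 <= 0))
    stop_config("sigmas must be > 0")
  df$spectrum <- if (is.null(spectrum))
    replicate(n, NULL, simplify = FALSE) else spectrum
  structure(df, class = c("planted_peaks", "data.frame"))
}

random_spectrum <- function(mz_min, mz_max) {
  nl <- sample(5:15, 1)
  mz <- sort(sample(seq(mz_min, mz_max), nl))
  ri <- runif(nl, 0.05, 1)
  ri <- ri / max(ri)
  cbind(mz = mz, rel_int = ri)
}

#' Ground truth for one synthetic dual-channel sample
#'
#' @param peaks A [planted_peaks()] table.
#' @param channel_shift `c(d1t, d2t)`: FID-minus-MS retention shift in
#'   (minutes, seconds); default one modulation and +0.05 s.
#' @param noise_sigma Named vector `c(ms = , fid = )`: per-line Gaussian
#'   noise sigma on MS spectra (Poisson-like jitter on counts, truncated at
#'   0) and additive Gaussian noise sigma on the FID trace. Defaults: clean
#'   MS (0), FID sigma 2.
#' @param drift_total Linear FID drift over the run (counts, default 400).
#' @param bleed_amp,bleed_tau Exponential column-bleed ramp on the FID:
#'   amplitude at end of run (counts, default 300) and time constant
#'   (seconds, default 60).
#' @param seed RNG seed; identical seeds give bit-identical samples.
#' @return An object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(peaks, channel_shift = c(2.5 / 60, 0.05),
                            noise_sigma = c(ms = 0, fid = 2),
                            drift_total = 400, bleed_amp = 300,
                            bleed_tau = 60, seed = 1L) {
  stopifnot(inherits(peaks, "planted_peaks"))
  structure(list(peaks = peaks, channel_shift = channel_shift,
                 noise_sigma = noise_sigma, drift_total = drift_total,
                 bleed_amp = bleed_amp, bleed_tau = bleed_tau,
                 seed = as.integer(seed)),
            class = "synthetic_truth")
}

# Folded-coordinate 2D Gaussian evaluated at global times tt (seconds).
gauss2d_at <- function(tt, pm, t1_min, t2_s, sigma1_mod, sigma2_s, amp) {
  m <- floor(tt / pm)
  tau <- tt - m * pm
  m_peak <- t1_min * 60 / pm
  amp * exp(-(m - m_peak)^2 / (2 * sigma1_mod^2)) *
    exp(-(tau - t2_s)^2 / (2 * sigma2_s^2))
}

#' Generate one paired MS/FID synthetic sample
#'
#' The MS channel is a scan stream at `1 / ms_scan_time` Hz whose per-scan
#' spectra distribute each peak's folded-coordinate 2D Gaussian over its
#' fragment lines (line weights normalized to sum 1, so the planted TIC apex
#' equals `amplitude_ms`). The FID channel is a fixed-rate trace of the same
#' Gaussians scaled by `fid_gain` and translated by the channel shift, plus
#' linear drift, exponential bleed, and Gaussian noise.
#'
#' @param truth A [synthetic_truth()].
#' @param cfg An [acquisition_config()] (default [synth_config()]).
#' @param sample_id Sample identifier stamped into both channels.
#' @return A list with `scans` ([scan_stream()]), `fid` ([raw_trace()]), and
#'   `truth_table` (per-peak analytic volumes per channel, in counts * s).
#' @export
synth_sample <- function(truth, cfg = synth_config(),
                         sample_id = "synthetic") {
  stopifnot(inherits(truth, "synthetic_truth"),
            inherits(cfg, "acquisition_config"))
  pm <- cfg$modulation_period
  T_s <- total_run_time(cfg$oven) * 60
  pk <- truth$peaks
  d1 <- truth$channel_shift[1]
  d2 <- truth$channel_shift[2]
  if (any(pk$t1 < 0 | pk$t1 * 60 > T_s | pk$t1 * 60 + d1 * 60 > T_s) ||
      any(pk$t2 < 0 | pk$t2 > pm | pk$t2 + d2 > pm | pk$t2 + d2 < 0))
    stop_config("planted peaks (after channel shift) fall outside the run extent")
  with_seed(truth$seed, {
    spectra <- pk$spectrum
    for (i in seq_len(nrow(pk)))
      if (is.null(spectra[[i]]))
        spectra[[i]] <- random_spectrum(cfg$mz_min, cfg$mz_max)
    # ---- MS channel -----------------------------------------------------
    st <- cfg$ms_scan_time
    n_scan <- as.integer(floor(T_s / st))
    scan_t <- (seq_len(n_scan) - 1) * st
    acc_scan <- integer(0)
    acc_mz <- numeric(0)
    acc_int <- numeric(0)
    for (i in seq_len(nrow(pk))) {
      g <- gauss2d_at(scan_t, pm, pk$t1[i], pk$t2[i], pk$sigma1[i],
                      pk$sigma2[i], pk$amplitude_ms[i])
      on <- which(g > pk$amplitude_ms[i] * 1e-5)
      if (!length(on)) next
      sp <- spectra[[i]]
      wts <- sp[, 2] / sum(sp[, 2])
      acc_scan <- c(acc_scan, rep(on, each = nrow(sp)))
      acc_mz <- c(acc_mz, rep(sp[, 1], times = length(on)))
      acc_int <- c(acc_int, as.vector(outer(wts, g[on])))
    }
    mzl <- replicate(n_scan, numeric(0), simplify = FALSE)
    ivl <- replicate(n_scan, numeric(0), simplify = FALSE)
    if (length(acc_scan)) {
      key <- acc_scan * 1000 + acc_mz
      agg <- rowsum(acc_int, group = key)
      k <- as.numeric(rownames(agg))
      o <- order(k)
      k <- k[o]
      val <- agg[o, 1]
      if (truth$noise_sigma[["ms"]] > 0)
        val <- pmax(0, val + rnorm(length(val),
                                   sd = truth$noise_sigma[["ms"]]))
      sc <- as.integer(floor(k / 1000))
      mz <- k - sc * 1000
      keep <- val > 0
      sc <- sc[keep]; mz <- mz[keep]; val <- val[keep]
      spl <- split(seq_along(sc), sc)
      for (nm in names(spl)) {
        sel <- spl[[nm]]
        s <- as.integer(nm)
        mzl[[s]] <- mz[sel]
        ivl[[s]] <- val[sel]
      }
    }
    scans <- scan_stream(scan_t, mzl, ivl, sample_id = sample_id)
    # ---- FID channel ----------------------------------------------------
    n_fid <- as.integer(floor(T_s * cfg$fid_rate))
    tt <- (seq_len(n_fid) - 1) / cfg$fid_rate
    y <- numeric(n_fid)
    for (i in seq_len(nrow(pk)))
      y <- y + gauss2d_at(tt, pm, pk$t1[i] + d1, pk$t2[i] + d2,
                          pk$sigma1[i], pk$sigma2[i],
                          pk$amplitude_ms[i] * pk$fid_gain[i])
    y <- y + truth$drift_total * tt / T_s +
      truth$bleed_amp * exp((tt - T_s) / truth$bleed_tau)
    if (truth$noise_sigma[["fid"]] > 0)
      y <- y + rnorm(n_fid, sd = truth$noise_sigma[["fid"]])
    fid <- raw_trace(y, cfg$fid_rate, channel = "FID",
                     sample_id = sample_id)
    truth_table <- data.frame(
      peak = seq_len(nrow(pk)), t1_min = pk$t1, t2_s = pk$t2,
      t1_fid_min = pk$t1 + d1, t2_fid_s = pk$t2 + d2,
      sigma1_mod = pk$sigma1, sigma2_s = pk$sigma2,
      amplitude_ms = pk$amplitude_ms,
      amplitude_fid = pk$amplitude_ms * pk$fid_gain,
      volume_ms = 2 * pi * pk$amplitude_ms * pk$sigma1 * pk$sigma2,
      volume_fid = 2 * pi * pk$amplitude_ms * pk$fid_gain * pk$sigma1 *
        pk$sigma2)
    list(scans = scans, fid = fid, truth_table = truth_table)
  })
}

#' Generate a synthetic batch with shared and class-specific compounds
#'
#' Compounds are assigned to well-separated slots on a retention grid (>= 8
#' sigma apart on both axes) with log-uniform MS amplitudes spanning two
#' orders of magnitude (5e2 to 5e4 counts) and random fragment spectra.
#' Every sample carries the shared compounds plus its class's specific
#' compounds; replicate amplitudes are jittered log-normally (sdlog 0.1).
#' Deterministic for a given seed.
#'
#' @param n_classes Number of sample classes (default 2).
#' @param n_per_class Replicates per class (default 3).
#' @param shared_compounds Compounds common to all classes (default 15).
#' @param class_compounds Compounds specific to each class (default 5).
#' @param seed RNG seed.
#' @param cfg An [acquisition_config()] (default [synth_config()]).
#' @return A list with `samples` (named list of [synth_sample()] outputs),
#'   `classes` (factor per sample), `compounds` (catalog with class
#'   membership), and `n_union` (total distinct planted compounds).
#' @export
synth_batch <- function(n_classes = 2, n_per_class = 3,
                        shared_compounds = 15, class_compounds = 5,
                        seed = 1L, cfg = synth_config()) {
  if (n_classes < 1 || n_per_class < 1)
    stop_config("counts must be >= 1")
  n_comp <- as.integer(shared_compounds + n_classes * class_compounds)
  pm <- cfg$modulation_period
  n_mod <- expected_modulations(cfg)
  with_seed(seed, {
    s1 <- 1
    s2 <- 0.05
    slots_c <- seq(6, n_mod - 6, by = 8 * s1)
    slots_r <- seq(8 * s2, pm - 0.45, by = 8 * s2)
    slots <- expand.grid(col = slots_c, t2 = slots_r)
    if (nrow(slots) < n_comp)
      stop_config("retention grid too small for the requested compound count")
    slots <- slots[sample.int(nrow(slots), n_comp), ]
    catalog <- data.frame(
      compound = sprintf("C%03d", seq_len(n_comp)),
      t1 = slots$col * pm / 60, t2 = slots$t2,
      amplitude = 10^runif(n_comp, log10(5e2), log10(5e4)),
      class = c(rep(0L, shared_compounds),
                rep(seq_len(n_classes), each = class_compounds)))
    spectra <- replicate(n_comp, random_spectrum(cfg$mz_min, cfg$mz_max),
                         simplify = FALSE)
    samples <- list()
    classes <- integer(0)
    for (cl in seq_len(n_classes)) {
      in_class <- catalog$class == 0L | catalog$class == cl
      for (rep_i in seq_len(n_per_class)) {
        sid <- sprintf("class%d_rep%d", cl, rep_i)
        idx <- which(in_class)
        jitter <- exp(rnorm(length(idx), sd = 0.1))
        pk <- planted_peaks(t1 = catalog$t1[idx], t2 = catalog$t2[idx],
                            amplitude_ms = catalog$amplitude[idx] * jitter,
                            sigma1 = s1, sigma2 = s2,
                            spectrum = spectra[idx])
        sample_seed <- (truth_seed_base(seed) + length(samples)) %%
          .Machine$integer.max
        truth <- synthetic_truth(pk, seed = sample_seed)
        out <- synth_sample(truth, cfg, sample_id = sid)
        out$compounds <- catalog$compound[idx]
        samples[[sid]] <- out
        classes <- c(classes, cl)
      }
    }
    list(samples = samples,
         classes = factor(classes,
                          labels = sprintf("class%d", seq_len(n_classes))),
         compounds = catalog, n_union = n_comp, cfg = cfg)
  })
}

truth_seed_base <- function(seed) (as.integer(seed) * 1009L) %% 2000000000L

#' Write a synthetic batch to disk as netCDF pairs plus truth tables
#'
#' @param batch A [synth_batch()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the sample manifest (data.frame with `sample_id`,
#'   `ms_path`, `fid_path`).
#' @export
write_synth_batch <- function(batch, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- names(batch$samples)
  manifest <- data.frame(sample_id = ids,
                         ms_path = file.path(dir, paste0(ids, "_ms.cdf")),
                         fid_path = file.path(dir, paste0(ids, "_fid.cdf")),
                         stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    s <- batch$samples[[i]]
    write_ms_cdf(s$scans, manifest$ms_path[i])
    write_fid_cdf(s$fid, manifest$fid_path[i])
    tt <- s$truth_table
    tt$compound <- s$compounds
    write.csv(tt, file.path(dir, paste0(ids[i], "_truth.csv")),
              row.names = FALSE)
  }
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
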