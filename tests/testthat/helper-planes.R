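# Shared fixtures, built in code: planes with planted 2D Gaussians at known
# cells, and the published acquisition method.

published_method <- function() {
  acquisition_config(modulation_period = 2.5, fid_rate = 120,
                     ms_scan_time = 0.0241,
                     oven = oven_program(60, 1, 5, 250, 10))
}

# Plant 2D Gaussians (sigma1 in columns, sigma2 in rows) on an nr x nc grid.
# Returns a chromatogram2d plus the truth table of apex cells and analytic
# volumes (2*pi*A*sigma1*sigma2_seconds counts*s).
make_gauss_plane <- function(apex_rows, apex_cols, amps, sigma1 = 1,
                             sigma2_s = 0.05, nr = 300, nc = 96, rate = 120,
                             pm = 2.5, noise_sd = 0, seed = 1,
                             channel = "FID") {
  stopifnot(pm * rate >= nr - 1)
  sigma2 <- sigma2_s * rate
  m <- matrix(0, nr, nc)
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  for (k in seq_along(apex_rows)) {
    m <- m + amps[k] * exp(-(rr - apex_rows[k])^2 / (2 * sigma2^2)) *
      exp(-(cc - apex_cols[k])^2 / (2 * rep_len(sigma1,
                                                length(amps))[k]^2))
  }
  if (noise_sd > 0) {
    set.seed(seed)
    m <- m + matrix(rnorm(nr * nc, sd = noise_sd), nr, nc)
  }
  plane <- chromatogram2d(m, pm = pm, rate = rate, channel = channel,
                          sample_id = "fixture")
  truth <- data.frame(row = apex_rows, col = apex_cols, amp = amps,
                      volume = 2 * pi * amps * rep_len(sigma1,
                                                       length(amps)) *
                        sigma2_s)
  list(plane = plane, truth = truth)
}

# Well-separated slot positions (>= 8 cells apart in scaled units).
slot_positions <- function(n, nr = 300, nc = 96, row_step = 48,
                           col_step = 8, seed = 1) {
  slots <- expand.grid(row = seq(40, nr - 40, by = row_step),
                       col = seq(6, nc - 6, by = col_step))
  set.seed(seed)
  slots[sample.int(nrow(slots), n), ]
}

# Translate a plane by integer (drow, dcol) with zero fill.
translate_plane <- function(plane, drow, dcol) {
  v <- plane$values
  out <- matrix(0, nrow(v), ncol(v))
  r_src <- seq_len(nrow(v))
  c_src <- seq_len(ncol(v))
  r_dst <- r_src + drow
  c_dst <- c_src + dcol
  keep_r <- r_dst >= 1 & r_dst <= nrow(v)
  keep_c <- c_dst >= 1 & c_dst <= ncol(v)
  out[r_dst[keep_r], c_dst[keep_c]] <- v[r_src[keep_r], c_src[keep_c]]
  chromatogram2d(out, plane$pm, plane$rate, channel = plane$channel,
                 sample_id = plane$sample_id)
}
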