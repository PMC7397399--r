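test_that("resampling is the identity at the native rate and linear between", {
  fx <- make_gauss_plane(150, 48, 1e4)
  same <- resample_to_grid(fx$plane, 120)
  expect_equal(same$values, fx$plane$values, tolerance = 1e-9)
  # two-row column [0, 1] interpolates linearly onto a finer grid
  p2 <- chromatogram2d(matrix(c(0, 1), 2, 1), pm = 2 / 120, rate = 120)
  r <- resample_to_grid(p2, 240)
  expect_equal(as.vector(r$values), c(0, 0.5, 1, 1))
  # a Gaussian column keeps its apex within one target cell
  ms <- make_gauss_plane(60, 10, 1e4, nr = 104, nc = 20,
                         rate = 1 / 0.0241, channel = "MS")$plane
  up <- resample_to_grid(ms, 120)
  r_src <- which.max(ms$values[, 10])
  r_tgt <- which.max(up$values[, 10])
  expect_lt(abs((r_tgt - 1) / 120 - (r_src - 1) * 0.0241), 1 / 120 + 1e-9)
})

test_that("identical planes register at zero shift with score 1", {
  fx <- make_gauss_plane(c(60, 150, 240), c(20, 48, 76), c(1e3, 1e4, 1e5),
                         noise_sd = 2, seed = 41)
  sh <- estimate_shift(fx$plane, fx$plane)
  expect_identical(c(sh$d1t, sh$d2t), c(0, 0))
  expect_equal(sh$score, 1)
  flat <- chromatogram2d(matrix(1, 300, 96), 2.5, 120)
  expect_error(estimate_shift(flat, fx$plane),
               class = "dualflow_config_error")
})

test_that("planted integer shifts are recovered exactly within bounds", {
  set.seed(43)
  for (case in 1:8) {
    nr <- 60
    nc <- 40
    base <- chromatogram2d(matrix(runif(nr * nc), nr), pm = nr / 120,
                           rate = 120)
    dr <- sample(-10:10, 1)
    dc <- sample(-4:4, 1)
    shifted <- translate_plane(base, dr, dc)
    sh <- withCallingHandlers(
      estimate_shift(base, shifted, max_d1t = 5, max_d2t = 12 / 120),
      warning = function(w) invokeRestart("muffleWarning"))
    expect_equal(sh$d1t, dc * base$pm / 60)
    expect_equal(sh$d2t, dr / 120)
  }
})

test_that("a shift outside the bounds returns the best in-bounds shift", {
  # smooth structure gives a unimodal correlation landscape, so the best
  # in-bounds shift sits on the boundary nearest the true (out-of-range) one
  base <- make_gauss_plane(c(60, 150, 240), c(20, 48, 76),
                           c(1e3, 1e4, 1e5))$plane
  shifted <- translate_plane(base, 20, 0) # beyond max_d2t = 12 rows
  expect_warning(sh <- estimate_shift(base, shifted, max_d1t = 2,
                                      max_d2t = 12 / 120),
                 "boundary")
  expect_lte(abs(sh$d2t) * 120, 12)
})

test_that("shifting a stencil is a translation group action on regions", {
  rg <- data.frame(id = "R0001", name = "x", t1_lo = 1, t1_hi = 1.2,
                   t2_lo = 0.8, t2_hi = 1.0, origin_sample = "s",
                   stringsAsFactors = FALSE)
  stn <- stencil(rg, source_channel = "MS")
  zero <- shift_transform(0, 0)
  expect_equal(apply_shift(stn, zero)$regions$t1_lo, 1)
  sh <- shift_transform(0.05, -0.02)
  inv <- shift_transform(-0.05, 0.02)
  back <- apply_shift(apply_shift(stn, sh), inv)
  expect_equal(back$regions$t1_lo, stn$regions$t1_lo, tolerance = 1e-9)
  expect_equal(back$regions$t2_hi, stn$regions$t2_hi, tolerance = 1e-9)
  # areas are preserved exactly before clipping
  moved <- apply_shift(stn, sh)
  expect_equal((moved$regions$t1_hi - moved$regions$t1_lo) *
                 (moved$regions$t2_hi - moved$regions$t2_lo),
               0.2 * 0.2)
  # a region shifted fully off the plane is an error naming the region
  plane <- make_gauss_plane(150, 48, 1e4)$plane
  err <- tryCatch(apply_shift(stn, shift_transform(1e3, 0), plane),
                  error = function(e) e)
  expect_s3_class(err, "dualflow_config_error")
  expect_match(conditionMessage(err), "R0001")
})

test_that("transferred regions contain the FID apexes of planted peaks", {
  b <- synth_batch(seed = 29)
  s <- b$samples[[1]]
  plane_ms <- fold(dbc(compute_tic(s$scans)), 2.5)
  plane_fid <- fold(tophat(s$fid), 2.5)
  pk <- detect_peaks(plane_ms)
  stn <- autostencil(pk, s$scans, plane_ms)
  sh <- estimate_shift(plane_ms, plane_fid)
  moved <- apply_shift(stn, sh, plane_fid)
  expect_identical(moved$source_channel, "FID")
  tt <- s$truth_table
  hits <- vapply(seq_len(nrow(tt)), function(k)
    any(tt$t1_fid_min[k] >= moved$regions$t1_lo &
          tt$t1_fid_min[k] <= moved$regions$t1_hi &
          tt$t2_fid_s[k] >= moved$regions$t2_lo &
          tt$t2_fid_s[k] <= moved$regions$t2_hi), logical(1))
  expect_true(all(hits))
})

test_that("local snap re-centers only when the maximum escapes the region", {
  fx <- make_gauss_plane(150, 48, 1e4, noise_sd = 0)
  plane <- fx$plane
  centered <- data.frame(id = "R1", name = "x",
                         t1_lo = (48 - 3) * 2.5 / 60,
                         t1_hi = (48 + 1) * 2.5 / 60,
                         t2_lo = 149 / 120 - 0.15, t2_hi = 149 / 120 + 0.15,
                         origin_sample = "s", stringsAsFactors = FALSE)
  expect_identical(local_snap(centered, plane), centered)
  # apex 0.05 s above the region: re-centered region contains the apex
  off <- centered
  off$t2_lo <- centered$t2_lo - 0.05 - 0.13
  off$t2_hi <- centered$t2_hi - 0.05 - 0.13
  snapped <- local_snap(off, plane, tol_2t = 0.1)
  expect_gte(149 / 120, snapped$t2_lo)
  expect_lte(149 / 120, snapped$t2_hi)
  # all-zero window: unchanged
  blank <- chromatogram2d(matrix(0, 300, 96), 2.5, 120)
  expect_identical(local_snap(centered, blank), centered)
})
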