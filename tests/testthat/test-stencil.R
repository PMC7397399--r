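# One synthetic sample with a known fragment pattern, reused across tests.
single_peak_sample <- function(spec = cbind(mz = c(41, 55, 70, 91, 120),
                                            rel_int = c(0.2, 1, 0.4, 0.6,
                                                        0.1)),
                               seed = 17) {
  synth_sample(synthetic_truth(
    planted_peaks(t1 = 1.5, t2 = 1.2, amplitude_ms = 1e4,
                  spectrum = list(spec)),
    seed = seed), sample_id = "one_peak")
}

ms_plane_of <- function(s) fold(dbc(compute_tic(s$scans)), 2.5)

test_that("the apex scan spectrum matches the planted fragment pattern", {
  spec <- cbind(mz = c(41, 55, 70, 91, 120),
                rel_int = c(0.2, 1, 0.4, 0.6, 0.1))
  s <- single_peak_sample(spec)
  plane <- ms_plane_of(s)
  pk <- detect_peaks(plane)
  expect_identical(nrow(pk), 1L)
  got <- region_spectrum(s$scans, pk[1, ], plane)
  expect_gte(spectral_cosine(got, spec), 0.99)
  expect_equal(max(got[, 2]), 1)
  # determinism: identical inputs give identical spectra
  expect_identical(got, region_spectrum(s$scans, pk[1, ], plane))
})

test_that("apex retentions outside the scan range or on empty scans fail", {
  s <- single_peak_sample()
  plane <- ms_plane_of(s)
  pk <- detect_peaks(plane)[1, ]
  pk$apex_1tR <- 99 # way past the run
  expect_error(region_spectrum(s$scans, pk, plane),
               class = "dualflow_config_error")
  pk2 <- detect_peaks(plane)[1, ]
  pk2$apex_1tR <- 0
  pk2$apex_2tR <- 0 # maps onto a signal-free (empty) scan
  expect_error(region_spectrum(s$scans, pk2, plane),
               class = "dualflow_config_error")
})

test_that("spectral cosine handles identity, disjoint and partial overlap", {
  a <- cbind(mz = 50, rel_int = 1)
  b <- cbind(mz = c(50, 60), rel_int = c(1, 1))
  d <- cbind(mz = c(70, 80), rel_int = c(1, 0.5))
  expect_equal(spectral_cosine(b, b), 1)
  expect_equal(spectral_cosine(a, d), 0)
  expect_equal(spectral_cosine(a, b), 1 / sqrt(2))
  expect_error(spectral_cosine(a, a[0, , drop = FALSE]),
               class = "dualflow_config_error")
})

test_that("autostencil produces one padded region per peak", {
  expect_identical(nrow(autostencil(detect_peaks(
    chromatogram2d(matrix(0, 104, 20), 2.5, 1 / 0.0241, channel = "MS")),
    plane = chromatogram2d(matrix(0, 104, 20), 2.5, 1 / 0.0241,
                           channel = "MS"))$regions), 0L)
  b <- synth_batch(seed = 19)
  s <- b$samples[[1]]
  plane <- ms_plane_of(s)
  pk <- detect_peaks(plane)
  stn <- autostencil(pk, s$scans, plane)
  expect_identical(nrow(stn$regions), nrow(pk))
  expect_identical(stn$regions$id[1], "R0001")
  expect_true(all(grepl("^Unknown_R\\d{4}$", stn$regions$name)))
  # every region contains its peak's apex, with the configured padding
  for (i in seq_len(nrow(pk))) {
    expect_gte(pk$apex_1tR[i], stn$regions$t1_lo[i])
    expect_lte(pk$apex_1tR[i], stn$regions$t1_hi[i])
    expect_gte(pk$apex_2tR[i], stn$regions$t2_lo[i])
    expect_lte(pk$apex_2tR[i], stn$regions$t2_hi[i])
    expect_false(is.null(stn$regions$spectrum[[i]]))
  }
})

test_that("region bounds follow the footprint bounding box plus padding", {
  fx <- make_gauss_plane(150, 48, 1e4, channel = "MS")
  pk <- detect_peaks(fx$plane)
  stn <- autostencil(pk, NULL, fx$plane, pad_1t = 1, pad_2t = 0.05)
  nr <- nrow(fx$plane$values)
  fp <- pk$footprint[[1]]
  cols <- (fp - 1) %/% nr + 1
  rows <- (fp - 1) %% nr + 1
  expect_equal(stn$regions$t1_lo, (min(cols) - 2.5) * 2.5 / 60)
  expect_equal(stn$regions$t1_hi, (max(cols) - 0.5 + 1) * 2.5 / 60)
  expect_equal(stn$regions$t2_lo, (min(rows) - 1.5) / 120 - 0.05)
  expect_equal(stn$regions$t2_hi, (max(rows) - 0.5) / 120 + 0.05)
})

test_that("merging adds only compounds not previously detected", {
  b <- synth_batch(seed = 23) # 15 shared + 5 per class
  s1 <- b$samples[["class1_rep1"]]
  s2 <- b$samples[["class2_rep1"]]
  p1 <- ms_plane_of(s1)
  p2 <- ms_plane_of(s2)
  pk1 <- detect_peaks(p1)
  pk2 <- detect_peaks(p2)
  stn <- autostencil(pk1, s1$scans, p1)
  expect_identical(nrow(stn$regions), 20L)
  # idempotence: merging the same sample adds nothing
  stn_again <- merge_stencil(stn, pk1, s1$scans, p1)
  expect_identical(nrow(stn_again$regions), 20L)
  # the second class shares 15 compounds and brings 5 new ones
  stn2 <- merge_stencil(stn, pk2, s2$scans, p2)
  expect_identical(nrow(stn2$regions), 25L)
  expect_identical(anyDuplicated(stn2$regions$id), 0L)
  # base regions are never removed or shrunk
  expect_identical(stn2$regions$id[1:20], stn$regions$id)
  expect_equal(stn2$regions$t1_lo[1:20], stn$regions$t1_lo)
  # merging the second sample twice equals merging once
  stn3 <- merge_stencil(stn2, pk2, s2$scans, p2)
  expect_identical(stn3$regions$id, stn2$regions$id)
})

test_that("an empty base stencil accumulates every peak", {
  s <- single_peak_sample()
  plane <- ms_plane_of(s)
  pk <- detect_peaks(plane)
  stn <- merge_stencil(stencil(source_channel = "MS"), pk, s$scans, plane)
  expect_identical(nrow(stn$regions), nrow(pk))
  expect_error(merge_stencil(stencil(source_channel = "FID"), pk, s$scans,
                             plane),
               class = "dualflow_config_error")
})
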