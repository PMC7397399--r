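test_that("FID netCDF writer/reader round-trips exactly", {
  set.seed(11)
  tr <- raw_trace(rnorm(300, 50, 5), 120, sample_id = "s1")
  f <- withr::local_tempfile(fileext = ".cdf")
  write_fid_cdf(tr, f)
  tr2 <- read_fid_cdf(f)
  expect_identical(tr2$intensities, tr$intensities)
  expect_equal(tr2$sampling_rate, 120)
  expect_identical(tr2$sample_id, "s1")
})

test_that("FID reader rejects malformed files rather than repairing them", {
  f <- withr::local_tempfile(fileext = ".cdf")
  write_fid_cdf(raw_trace(1:100, 120), f)
  raw <- readBin(f, "raw", file.size(f))
  writeBin(raw[1:50], f) # truncated file
  expect_error(read_fid_cdf(f), class = "dualflow_format_error")
  expect_error(read_fid_cdf(tempfile()), class = "dualflow_format_error")
})

test_that("MS netCDF round-trips scans, including empty scans", {
  ss <- scan_stream(c(0, 0.1, 0.2),
                    mz = list(c(50, 60), numeric(0), 70),
                    intensity = list(c(1, 2), numeric(0), 5),
                    sample_id = "s2")
  f <- withr::local_tempfile(fileext = ".cdf")
  write_ms_cdf(ss, f)
  ss2 <- read_ms_cdf(f)
  expect_identical(ss2$scan_times, ss$scan_times)
  expect_identical(ss2$mz, ss$mz)
  expect_identical(ss2$intensity, ss$intensity)
  expect_identical(ss2$total_intensity, c(3, 0, 5))
})

test_that("MS round-trip holds for arbitrary random ragged streams", {
  set.seed(42)
  for (case in 1:8) {
    n <- sample(2:40, 1)
    times <- cumsum(runif(n, 0.01, 0.05))
    mz <- lapply(seq_len(n), function(i) {
      k <- sample(0:12, 1)
      sort(sample(40:300, k))
    })
    iv <- lapply(mz, function(m) runif(length(m), 0, 1e5))
    ss <- scan_stream(times, mz, iv)
    f <- tempfile(fileext = ".cdf")
    write_ms_cdf(ss, f)
    ss2 <- read_ms_cdf(f)
    expect_identical(ss2$scan_times, ss$scan_times)
    expect_identical(ss2$mz, ss$mz)
    expect_identical(ss2$intensity, ss$intensity)
    unlink(f)
  }
})

test_that("MS reader rejects inconsistent scan indices", {
  ss <- scan_stream(c(0, 0.1), list(c(50, 60), 70), list(c(1, 2), 3))
  f <- withr::local_tempfile(fileext = ".cdf")
  write_ms_cdf(ss, f)
  nc <- ncdf4::nc_open(f, write = TRUE)
  ncdf4::ncvar_put(nc, "scan_index", c(2L, 0L)) # decreasing offsets
  ncdf4::nc_close(nc)
  expect_error(read_ms_cdf(f), class = "dualflow_format_error")
  write_ms_cdf(ss, f)
  nc <- ncdf4::nc_open(f, write = TRUE)
  ncdf4::ncvar_put(nc, "point_count", c(2L, 5L)) # exceeds array length
  ncdf4::nc_close(nc)
  expect_error(read_ms_cdf(f), class = "dualflow_format_error")
})

test_that("sample report CSVs round-trip losslessly with RFC 4180 quoting", {
  rep0 <- sample_report("kava_1", data.frame(
    region_id = c("R0001", "R0002", "R0003"),
    compound_name = c("Unknown_R0001", "linalool, (R)-", "x\"y\""),
    apex_1tR_min = c(1.23456789012345, 10, 40.5),
    apex_2tR_s = c(0.85, 1.2, 2.05),
    volume = c(1234.5678901234, 0, 17.1),
    stringsAsFactors = FALSE))
  f <- withr::local_tempfile(fileext = ".csv")
  write_report_csv(rep0, f)
  rep1 <- read_report_csv(f)
  expect_identical(attr(rep1, "sample_id"), "kava_1")
  expect_identical(rep1$compound_name, rep0$compound_name)
  expect_identical(rep1$volume, rep0$volume)
  expect_identical(rep1$apex_1tR_min, rep0$apex_1tR_min)
  # empty report: header only, reads back empty
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_report_csv(sample_report("empty", data.frame(
    region_id = character(0), compound_name = character(0),
    apex_1tR_min = numeric(0), apex_2tR_s = numeric(0),
    volume = numeric(0))), f2)
  expect_identical(nrow(read_report_csv(f2)), 0L)
  # duplicate region ids are a format error on read
  writeLines(c("sample_id,region_id,compound_name,apex_1tR_min,apex_2tR_s,volume",
               "s,R1,a,1,1,1", "s,R1,b,2,2,2"), f2)
  expect_error(read_report_csv(f2), class = "dualflow_format_error")
})

test_that("stencil JSON round-trips regions and spectra exactly", {
  sp <- cbind(mz = c(41, 55, 70, 91, 120),
              rel_int = c(0.2, 1, 0.33, 0.5, 0.05))
  rg <- data.frame(id = c("R0001", "R0002"),
                   name = c("Unknown_R0001", "alpha-pinene"),
                   t1_lo = c(1.1, 20.4), t1_hi = c(1.3, 20.7),
                   t2_lo = c(0.7, 1.5), t2_hi = c(0.95, 1.8),
                   origin_sample = c("s1", "s1"), stringsAsFactors = FALSE)
  rg$spectrum <- list(sp, NULL)
  stn <- stencil(rg, source_channel = "MS")
  f <- withr::local_tempfile(fileext = ".json")
  write_stencil(stn, f)
  stn2 <- read_stencil(f)
  expect_identical(stn2$source_channel, "MS")
  expect_identical(stn2$regions$id, rg$id)
  expect_equal(stn2$regions$t1_lo, rg$t1_lo)
  expect_equal(unname(stn2$regions$spectrum[[1]]), unname(sp))
  expect_null(stn2$regions$spectrum[[2]])
  # empty stencil round-trips
  f2 <- withr::local_tempfile(fileext = ".json")
  write_stencil(stencil(source_channel = "MS"), f2)
  expect_identical(nrow(read_stencil(f2)$regions), 0L)
})

test_that("stencil reader names the JSON path of a schema violation", {
  f <- withr::local_tempfile(fileext = ".json")
  writeLines('{"version":1,"source_channel":"MS",
    "regions":[{"id":"R0001","name":"x","t1_min_lo":1,
    "t2_s_lo":0.5,"t2_s_hi":0.9,"origin_sample":"s"}]}', f)
  err <- tryCatch(read_stencil(f), error = function(e) e)
  expect_s3_class(err, "dualflow_format_error")
  expect_match(conditionMessage(err), "regions\\[1\\]\\.t1_min_hi")
})

test_that("plane container round-trips the folded matrix and metadata", {
  set.seed(3)
  p <- chromatogram2d(matrix(rnorm(300 * 4), 300), pm = 2.5, rate = 120,
                      channel = "FID", sample_id = "sX")
  f <- withr::local_tempfile(fileext = ".cdf")
  write_plane_cdf(p, f)
  p2 <- read_plane_cdf(f)
  expect_identical(p2$values, p$values)
  expect_equal(p2$pm, 2.5)
  expect_equal(p2$rate, 120)
  expect_identical(p2$channel, "FID")
})

test_that("batch table CSVs round-trip values, names and flags", {
  m <- matrix(c(1.5, 0, 2.25, 1e-8), 2, 2,
              dimnames = list(c("s1", "s2"), c("R0001", "R0002")))
  bt <- batch_table(m, region_names = c("Unknown_R0001", "compound, odd"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_batch_csv(bt, f)
  bt2 <- read_batch_csv(f)
  expect_identical(bt2$values, m)
  expect_identical(bt2$region_names, bt$region_names)
  expect_identical(unname(bt2$flags),
                   c(FALSE, FALSE, FALSE))
})
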