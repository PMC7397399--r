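toy_table <- function(m, ids = sprintf("s%d", seq_len(nrow(m))),
                      regions = sprintf("R%04d", seq_len(ncol(m)))) {
  dimnames(m) <- list(ids, regions)
  batch_table(m)
}

test_that("empty and blank-area regions quantify to zero volume", {
  blank <- chromatogram2d(matrix(0, 300, 96), 2.5, 120, channel = "FID",
                          sample_id = "s")
  empty <- stencil(source_channel = "FID")
  rep0 <- quantify_stencil(blank, empty)
  expect_identical(nrow(rep0), 0L)
  rg <- data.frame(id = "R0001", name = "x", t1_lo = 1, t1_hi = 1.2,
                   t2_lo = 0.8, t2_hi = 1.0, origin_sample = "s",
                   stringsAsFactors = FALSE)
  rep1 <- quantify_stencil(blank, stencil(rg, source_channel = "FID"))
  expect_identical(rep1$volume, 0)
  # channel mismatch: the stencil must be registered first
  expect_error(quantify_stencil(blank, stencil(rg, source_channel = "MS")),
               class = "dualflow_config_error")
})

test_that("quantified volumes scale linearly with plane intensity", {
  fx <- make_gauss_plane(c(100, 220), c(30, 60), c(5e3, 2e4),
                         noise_sd = 0, channel = "FID")
  pk <- detect_peaks(fx$plane)
  stn <- autostencil(pk, NULL, fx$plane)
  stn$source_channel <- "FID"
  r1 <- quantify_stencil(fx$plane, stn)
  p2 <- fx$plane
  p2$values <- 3 * p2$values
  r2 <- quantify_stencil(p2, stn)
  expect_equal(r2$volume, 3 * r1$volume)
})

test_that("aligned batch tables zero-fill missing regions and keep order", {
  rg <- data.frame(id = c("R0001", "R0002", "R0003"),
                   name = paste0("c", 1:3),
                   t1_lo = 1:3, t1_hi = 1:3 + 0.2,
                   t2_lo = 0.5, t2_hi = 0.9,
                   origin_sample = "s", stringsAsFactors = FALSE)
  stn <- stencil(rg, source_channel = "FID")
  full <- sample_report("s1", data.frame(
    region_id = rg$id, compound_name = rg$name, apex_1tR_min = 1:3,
    apex_2tR_s = 0.7, volume = c(10, 20, 30)))
  partial <- sample_report("s2", data.frame(
    region_id = "R0002", compound_name = "c2", apex_1tR_min = 2,
    apex_2tR_s = 0.7, volume = 99))
  bt <- align_reports(list(full, partial), stn)
  expect_identical(dim(bt$values), c(2L, 3L))
  expect_identical(bt$values["s1", ], c(R0001 = 10, R0002 = 20, R0003 = 30))
  expect_identical(bt$values["s2", ], c(R0001 = 0, R0002 = 99, R0003 = 0))
  one <- align_reports(list(full), stn)
  expect_identical(unname(one$values[1, ]), full$volume)
  stray <- sample_report("s3", data.frame(
    region_id = "R9999", compound_name = "?", apex_1tR_min = 1,
    apex_2tR_s = 0.7, volume = 1))
  expect_error(align_reports(list(stray), stn),
               class = "dualflow_config_error")
})

test_that("unit-vector normalization yields exact unit rows", {
  bt <- toy_table(matrix(c(3, 4, 1, 0), 2, 2, byrow = TRUE))
  nb <- unit_vector_normalize(bt)
  expect_equal(unname(nb$values[1, ]), c(0.6, 0.8))
  expect_true(nb$flags[["normalized"]])
  # idempotence on already-unit rows
  nb2 <- unit_vector_normalize(nb)
  expect_equal(nb2$values, nb$values, tolerance = 1e-12)
  set.seed(51)
  big <- unit_vector_normalize(toy_table(matrix(runif(60, 1, 100), 6)))
  expect_equal(unname(sqrt(rowSums(big$values^2))), rep(1, 6),
               tolerance = 1e-9)
  err <- tryCatch(unit_vector_normalize(toy_table(matrix(c(1, 1, 0, 0), 2,
                                                         byrow = TRUE))),
                  error = function(e) e)
  expect_s3_class(err, "dualflow_config_error")
  expect_match(conditionMessage(err), "s2")
})

test_that("autoscaling gives zero-mean unit-sd columns with ddof 1", {
  bt <- toy_table(matrix(c(1, 3), 2, 1))
  sc <- autoscale(bt)
  expect_equal(unname(sc$values[, 1]), c(-1, 1) / sqrt(2))
  expect_true(all(sc$flags[c("centered", "scaled")]))
  expect_warning(cz <- autoscale(toy_table(matrix(c(5, 5, 1, 2), 2))),
                 "zero-variance")
  expect_identical(unname(cz$values[, 1]), c(0, 0))
  expect_error(autoscale(toy_table(matrix(1, 1, 3))),
               class = "dualflow_config_error")
  set.seed(52)
  big <- autoscale(toy_table(matrix(runif(80), 8)))
  expect_equal(unname(colMeans(big$values)), rep(0, 10), tolerance = 1e-9)
  expect_equal(unname(apply(big$values, 2, sd)), rep(1, 10),
               tolerance = 1e-9)
})

test_that("PCA reconstructs the pretreated matrix and orders variance", {
  set.seed(53)
  bt <- autoscale(unit_vector_normalize(toy_table(
    matrix(runif(6 * 9, 1, 50), 6))))
  k <- min(nrow(bt$values) - 1, ncol(bt$values))
  pc <- batch_pca(bt, k = k)
  expect_lt(max(abs(pc$scores %*% t(pc$loadings) - bt$values)), 1e-8)
  expect_lt(max(abs(crossprod(pc$loadings) - diag(k))), 1e-8)
  expect_true(all(diff(pc$explained_variance_ratio) <= 1e-12))
  expect_error(batch_pca(bt, k = 10), class = "dualflow_config_error")
  expect_error(batch_pca(toy_table(matrix(runif(12), 3)), k = 1),
               class = "dualflow_config_error")
})

test_that("data on a single axis loads entirely on PC1", {
  m <- matrix(0, 4, 3)
  m[, 2] <- c(-3, -1, 1, 3)
  pc <- batch_pca(toy_table(m), k = 1, force = TRUE)
  expect_equal(pc$explained_variance_ratio[1], 1)
  expect_equal(abs(pc$loadings[2, 1]), 1)
})

test_that("PCA is invariant to sample row order up to the sign convention", {
  set.seed(54)
  bt <- autoscale(unit_vector_normalize(toy_table(
    matrix(runif(6 * 8, 1, 50), 6))))
  pc <- batch_pca(bt, k = 2)
  perm <- c(4, 2, 6, 1, 3, 5)
  bt2 <- bt
  bt2$values <- bt$values[perm, ]
  pc2 <- batch_pca(bt2, k = 2)
  expect_equal(pc2$scores[rownames(pc$scores), ], pc$scores,
               tolerance = 1e-9)
  expect_equal(pc2$loadings, pc$loadings, tolerance = 1e-9)
})

test_that("pretreatment is required before PCA unless forced", {
  bt <- toy_table(matrix(runif(12, 1, 5), 3))
  expect_error(batch_pca(bt, k = 2), class = "dualflow_config_error")
  expect_s3_class(batch_pca(autoscale(unit_vector_normalize(bt)), k = 2),
                  "pca_result")
})
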