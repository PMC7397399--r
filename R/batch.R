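# Region quantification on corrected FID planes, zero-filled batch tables,
# pretreatment (row unit-vector normalization, then column autoscaling), and
# PCA. Pretreatment order matters: sample-wise normalization must precede the
# column statistics for the latter to be meaningful, and that order is
# enforced by the flags.

#' Quantify stencil regions on a corrected plane
#'
#' Per region, the apex is the tallest cell inside the region; if it falls
#' below `snr_min * noise` the region's volume is recorded as 0 (zero-fill
#' for peaks not detected), otherwise the apex is grown into a footprint by
#' flood fill clipped to the region and integrated as in [detect_peaks()].
#' Region order is preserved.
#'
#' @param plane A baseline-corrected [chromatogram2d()], registered to the
#'   stencil's channel.
#' @param stn A [stencil()] registered to this plane's channel.
#' @param params A [detect_params()] (the SNR gate and boundary fraction).
#' @return A [sample_report()].
#' @export
quantify_stencil <- function(plane, stn, params = detect_params()) {
  stopifnot(inherits(plane, "chromatogram2d"), inherits(stn, "stencil"))
  if (!identical(stn$source_channel, plane$channel))
    stop_config(sprintf(
      "stencil channel '%s' does not match plane channel '%s'; register the stencil first",
      stn$source_channel, plane$channel))
  v <- plane$values
  nr <- nrow(v)
  rg <- stn$regions
  n <- nrow(rg)
  noise <- estimate_noise(plane)
  thr <- params$snr_min * noise
  out <- data.frame(region_id = rg$id, compound_name = rg$name,
                    apex_1tR_min = (rg$t1_lo + rg$t1_hi) / 2,
                    apex_2tR_s = (rg$t2_lo + rg$t2_hi) / 2,
                    volume = numeric(n), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    c_lo <- max(1L, as.integer(ceiling(rg$t1_lo[i] * 60 / plane$pm -
                                         1e-9)) + 1L)
    c_hi <- min(ncol(v), as.integer(floor(rg$t1_hi[i] * 60 / plane$pm +
                                            1e-9)) + 1L)
    r_lo <- max(1L, as.integer(ceiling(rg$t2_lo[i] * plane$rate - 1e-9)) + 1L)
    r_hi <- min(nr, as.integer(floor(rg$t2_hi[i] * plane$rate + 1e-9)) + 1L)
    if (c_lo > c_hi || r_lo > r_hi) next
    w <- v[r_lo:r_hi, c_lo:c_hi, drop = FALSE]
    apex <- max(w)
    if (apex <= 0 || apex < thr) next
    k <- which(w == apex, arr.ind = TRUE)[1, ]
    tfill <- max(params$boundary_fraction * apex, thr)
    fp_local <- flood_fill(w, k[1], k[2], tfill)
    out$volume[i] <- sum(pmax(w[fp_local], 0)) / plane$rate
    rr <- r_lo + (fp_local - 1L) %% nrow(w)
    cc <- c_lo + (fp_local - 1L) %/% nrow(w)
    apex_ret <- index_to_retention(plane, r_lo + k[1] - 1L, c_lo + k[2] - 1L)
    out$apex_1tR_min[i] <- apex_ret$t1
    out$apex_2tR_s[i] <- apex_ret$t2
  }
  sample_report(plane$sample_id, out)
}

#' Combine per-sample reports into a zero-filled batch table
#'
#' Rows are samples in input order; columns are stencil regions in stencil
#' order; any (sample, region) pair absent from a report is filled with 0.
#' Report volumes are never altered.
#'
#' @param reports A list of [sample_report()]s quantified against `stn`.
#' @param stn The common [stencil()].
#' @return A [batch_table()] of volumes (counts * s), flags all unset.
#' @export
align_reports <- function(reports, stn) {
  stopifnot(inherits(stn, "stencil"))
  ids <- stn$regions$id
  sample_ids <- unname(vapply(reports, function(r) attr(r, "sample_id"),
                              character(1)))
  m <- matrix(0, nrow = length(reports), ncol = length(ids),
              dimnames = list(sample_ids, ids))
  for (i in seq_along(reports)) {
    r <- reports[[i]]
    j <- match(r$region_id, ids)
    if (anyNA(j))
      stop_config(paste0("report '", sample_ids[i],
                         "' contains region ids absent from the stencil: ",
                         paste(r$region_id[is.na(j)], collapse = ", ")))
    m[i, j] <- r$volume
  }
  batch_table(m, region_names = stn$regions$name)
}

#' Unit-vector normalization of a batch table
#'
#' Each sample row is divided by its Euclidean norm, normalizing each
#' chromatogram against its overall signal before variables are compared.
#'
#' @param bt A [batch_table()].
#' @return The normalized [batch_table()] (`normalized` flag set).
#' @export
unit_vector_normalize <- function(bt) {
  stopifnot(inherits(bt, "batch_table"))
  norms <- sqrt(rowSums(bt$values^2))
  if (any(norms == 0))
    stop_config(paste0("all-zero sample row(s): ",
                       paste(rownames(bt$values)[norms == 0],
                             collapse = ", ")))
  bt$values <- bt$values / norms
  bt$flags[["normalized"]] <- TRUE
  bt
}

#' Autoscaling (mean centering and unit-variance scaling) of a batch table
#'
#' Each column is mean-centered and divided by its sample standard deviation
#' (n - 1 denominator). Zero-variance columns are centered but left unscaled,
#' with a warning.
#'
#' @param bt A [batch_table()] with at least two samples.
#' @return The autoscaled [batch_table()] (`centered` and `scaled` flags
#'   set).
#' @export
autoscale <- function(bt) {
  stopifnot(inherits(bt, "batch_table"))
  if (nrow(bt$values) < 2)
    stop_config("autoscaling requires at least 2 samples")
  mu <- colMeans(bt$values)
  sdv <- apply(bt$values, 2, sd)
  zero <- sdv == 0
  if (any(zero))
    warning(paste0("zero-variance column(s) centered but not scaled: ",
                   paste(colnames(bt$values)[zero], collapse = ", ")))
  sdv[zero] <- 1
  bt$values <- sweep(sweep(bt$values, 2, mu, "-"), 2, sdv, "/")
  bt$flags[["centered"]] <- TRUE
  bt$flags[["scaled"]] <- TRUE
  bt
}

#' Principal component analysis of a pretreated batch table
#'
#' Singular value decomposition of the pretreated matrix: scores are the left
#' singular vectors scaled by the singular values, loadings the right
#' singular vectors (orthonormal columns). The sign convention makes each
#' loading column's largest-magnitude element positive so results are
#' invariant to sample row order.
#'
#' @param bt A [batch_table()] with all pretreatment flags set (override with
#'   `force = TRUE`).
#' @param k Number of components, at most `min(samples - 1, variables)`.
#' @param force Skip the pretreatment-flag check.
#' @return An object of class `pca_result`: `scores` (samples x k),
#'   `loadings` (variables x k), `explained_variance_ratio`.
#' @export
batch_pca <- function(bt, k = 2, force = FALSE) {
  stopifnot(inherits(bt, "batch_table"))
  if (!force && !all(bt$flags))
    stop_config(paste0(
      "batch table is not fully pretreated (",
      paste(names(bt$flags)[!bt$flags], collapse = ", "),
      " unset); normalize and autoscale first, or use force = TRUE"))
  X <- bt$values
  kmax <- min(nrow(X) - 1L, ncol(X))
  if (k < 1 || k > kmax)
    stop_config(sprintf("k must be in 1..%d", kmax))
  s <- svd(X)
  evr <- s$d^2 / sum(s$d^2)
  scores <- s$u[, seq_len(k), drop = FALSE] %*%
    diag(s$d[seq_len(k)], nrow = k)
  loadings <- s$v[, seq_len(k), drop = FALSE]
  # sign convention: largest-|.| element of each loading column is positive
  for (j in seq_len(k)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  dimnames(scores) <- list(rownames(X), paste0("PC", seq_len(k)))
  dimnames(loadings) <- list(colnames(X), paste0("PC", seq_len(k)))
  structure(list(scores = scores, loadings = loadings,
                 explained_variance_ratio = evr[seq_len(k)]),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("pca_result: %d samples, %d components (%s%% variance)\n",
              nrow(x$scores), ncol(x$scores),
              paste(sprintf("%.1f", 100 * x$explained_variance_ratio),
                    collapse = " + ")))
  invisible(x)
}
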