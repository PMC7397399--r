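# End-to-end batch workflow: read -> TIC -> fold -> DBC (MS) / TopHat (FID)
# -> detect (MS) -> sequential stencil merge -> per-sample shift estimate +
# transfer -> quantify (FID) -> align -> pretreat -> PCA. Every intermediate
# is written; a rerun with the same inputs is bit-identical (the run log
# carries parameters and package version, never timestamps).

#' Pipeline configuration
#'
#' @param acq An [acquisition_config()].
#' @param manifest Data.frame with columns `sample_id`, `ms_path`,
#'   `fid_path`; sample ids must be unique.
#' @param baseline A [baseline_params()].
#' @param detect A [detect_params()].
#' @param stencil_samples Sample ids used for incremental stencil building
#'   (default all samples; large batches may use one or two per class, and
#'   the chosen subset is recorded in the run log).
#' @param rt_tol_1t,rt_tol_2t,cos_min Stencil merge tolerances (see
#'   [merge_stencil()]).
#' @param max_d1t,max_d2t Shift search bounds (see [estimate_shift()]).
#' @param snap Re-center each transferred region on its local maximum (see
#'   [local_snap()]); default FALSE. Enable only when residual channel
#'   misalignment exceeds the region margins: snapping searches beyond the
#'   region, so with an accurate global shift it can drag a legitimately
#'   empty region onto a neighboring peak's tail.
#' @param n_components PCA components (default 2).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(acq, manifest, baseline = baseline_params(),
                            detect = detect_params(),
                            stencil_samples = NULL, rt_tol_1t = 1,
                            rt_tol_2t = 0.1, cos_min = 0.8, max_d1t = 5,
                            max_d2t = 0.25, snap = FALSE, n_components = 2) {
  stopifnot(inherits(acq, "acquisition_config"))
  req <- c("sample_id", "ms_path", "fid_path")
  if (!is.data.frame(manifest) || !all(req %in% names(manifest)) ||
      !nrow(manifest))
    stop_config("manifest must be a non-empty data.frame with sample_id, ms_path, fid_path")
  if (anyDuplicated(manifest$sample_id))
    stop_config("manifest sample ids must be unique")
  if (is.null(stencil_samples)) stencil_samples <- manifest$sample_id
  if (!all(stencil_samples %in% manifest$sample_id))
    stop_config("stencil_samples must be a subset of manifest sample ids")
  structure(list(acq = acq, manifest = manifest, baseline = baseline,
                 detect = detect, stencil_samples = stencil_samples,
                 rt_tol_1t = rt_tol_1t, rt_tol_2t = rt_tol_2t,
                 cos_min = cos_min, max_d1t = max_d1t, max_d2t = max_d2t,
                 snap = snap, n_components = n_components),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The file holds the method fields (as in [read_method_config()]) plus
#' optional `baseline`, `detect`, `pipeline` blocks and a `samples` list of
#' `{sample_id, ms_path, fid_path}` entries (paths relative to the YAML
#' file).
#'
#' @param path Path to a YAML file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  acq <- read_method_config(path)
  if (is.null(y$samples) || !length(y$samples))
    stop_config("pipeline config must list samples")
  base_dir <- dirname(normalizePath(path))
  manifest <- do.call(rbind, lapply(y$samples, function(s)
    data.frame(sample_id = s$sample_id,
               ms_path = file.path(base_dir, s$ms_path),
               fid_path = file.path(base_dir, s$fid_path),
               stringsAsFactors = FALSE)))
  b <- y$baseline %||% list()
  d <- y$detect %||% list()
  p <- y$pipeline %||% list()
  pipeline_config(
    acq, manifest,
    baseline = baseline_params(
      peak_width_2d = b$peak_width_2d %||% 0.35,
      dbc_window_factor = b$dbc_window_factor %||% 10,
      tophat_factor = b$tophat_factor %||% 5),
    detect = detect_params(
      snr_min = d$snr_min %||% 10,
      min_volume = d$min_volume %||% 0,
      smooth_sigma_2d = d$smooth_sigma_2d %||% ((b$peak_width_2d %||%
                                                   0.35) / 4),
      boundary_fraction = d$boundary_fraction %||% 0.05),
    stencil_samples = unlist(p$stencil_samples) %||% NULL,
    rt_tol_1t = p$rt_tol_1t %||% 1, rt_tol_2t = p$rt_tol_2t %||% 0.1,
    cos_min = p$cos_min %||% 0.8, max_d1t = p$max_d1t %||% 5,
    max_d2t = p$max_d2t %||% 0.25, snap = p$snap %||% FALSE,
    n_components = p$n_components %||% 2)
}

log_line <- function(con, stage, ...) {
  rec <- c(list(stage = stage), list(...))
  writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
}

#' Run the full dual-channel batch workflow
#'
#' @param cfg A [pipeline_config()].
#' @param out_dir Output directory; receives `planes/`, `stencil.json`,
#'   `stencil_<sample>.json` (registered), `report_<sample>.csv`,
#'   `batch_raw.csv`, `batch_pretreated.csv`, `pca_scores.csv`,
#'   `pca_loadings.csv`, `pca_variance.csv`, and `run_log.jsonl`.
#' @return Invisibly, a list with the stencil, reports, batch tables, PCA
#'   result, and per-sample shifts.
#' @export
run_pipeline <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "pipeline_config"))
  man <- cfg$manifest
  missing_files <- !file.exists(man$ms_path) | !file.exists(man$fid_path)
  if (any(missing_files))
    stop_config(paste0("manifest files missing for: ",
                       paste(man$sample_id[missing_files], collapse = ", ")))
  dir.create(file.path(out_dir, "planes"), showWarnings = FALSE,
             recursive = TRUE)
  logcon <- file(file.path(out_dir, "run_log.jsonl"), "w", encoding = "UTF-8")
  on.exit(close(logcon), add = TRUE)
  log_line(logcon, "start",
           package_version = as.character(utils::packageVersion("dualflow")),
           n_samples = nrow(man),
           modulation_period = cfg$acq$modulation_period,
           fid_rate = cfg$acq$fid_rate, ms_scan_time = cfg$acq$ms_scan_time,
           peak_width_2d = cfg$baseline$peak_width_2d,
           dbc_window_factor = cfg$baseline$dbc_window_factor,
           tophat_factor = cfg$baseline$tophat_factor,
           snr_min = cfg$detect$snr_min,
           boundary_fraction = cfg$detect$boundary_fraction,
           stencil_samples = cfg$stencil_samples,
           rt_tol_1t = cfg$rt_tol_1t, rt_tol_2t = cfg$rt_tol_2t,
           cos_min = cfg$cos_min, max_d1t = cfg$max_d1t,
           max_d2t = cfg$max_d2t, snap = cfg$snap,
           n_components = cfg$n_components)
  stage <- function(name, sid, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed for sample '%s': %s", name,
                   sid, conditionMessage(e)), call. = FALSE)
    })
  }
  pm <- cfg$acq$modulation_period
  planes_ms <- list()
  planes_fid <- list()
  scans_all <- list()
  for (i in seq_len(nrow(man))) {
    sid <- man$sample_id[i]
    scans <- stage("read_ms", sid, read_ms_cdf(man$ms_path[i]))
    scans$sample_id <- sid
    tic <- stage("tic", sid, compute_tic(scans))
    tic_c <- stage("dbc", sid, dbc(tic, cfg$baseline))
    plane_ms <- stage("fold_ms", sid, fold(tic_c, pm))
    fidtr <- stage("read_fid", sid, read_fid_cdf(man$fid_path[i]))
    fidtr$sample_id <- sid
    fid_c <- stage("tophat", sid, tophat(fidtr, cfg$baseline))
    plane_fid <- stage("fold_fid", sid, fold(fid_c, pm))
    write_plane_cdf(plane_ms, file.path(out_dir, "planes",
                                        paste0(sid, "_ms.cdf")))
    write_plane_cdf(plane_fid, file.path(out_dir, "planes",
                                         paste0(sid, "_fid.cdf")))
    planes_ms[[sid]] <- plane_ms
    planes_fid[[sid]] <- plane_fid
    scans_all[[sid]] <- scans
    log_line(logcon, "folded", sample_id = sid,
             ms_dims = dim(plane_ms$values),
             fid_dims = dim(plane_fid$values))
  }
  mz_range <- c(cfg$acq$mz_min, cfg$acq$mz_max)
  stn <- NULL
  for (sid in cfg$stencil_samples) {
    pk <- stage("detect", sid, detect_peaks(planes_ms[[sid]], cfg$detect))
    if (is.null(stn)) {
      stn <- stage("autostencil", sid,
                   autostencil(pk, scans_all[[sid]], planes_ms[[sid]],
                               mz_range = mz_range))
    } else {
      stn <- stage("merge_stencil", sid,
                   merge_stencil(stn, pk, scans_all[[sid]], planes_ms[[sid]],
                                 rt_tol_1t = cfg$rt_tol_1t,
                                 rt_tol_2t = cfg$rt_tol_2t,
                                 cos_min = cfg$cos_min,
                                 mz_range = mz_range))
    }
    log_line(logcon, "stencil", sample_id = sid, n_peaks = nrow(pk),
             n_regions = nrow(stn$regions))
  }
  write_stencil(stn, file.path(out_dir, "stencil.json"))
  reports <- list()
  shifts <- list()
  for (sid in man$sample_id) {
    sh <- stage("estimate_shift", sid,
                estimate_shift(planes_ms[[sid]], planes_fid[[sid]],
                               max_d1t = cfg$max_d1t, max_d2t = cfg$max_d2t))
    st_fid <- stage("apply_shift", sid,
                    apply_shift(stn, sh, planes_fid[[sid]]))
    if (cfg$snap) {
      snapped <- lapply(seq_len(nrow(st_fid$regions)), function(j)
        local_snap(st_fid$regions[j, , drop = FALSE], planes_fid[[sid]],
                   tol_1t = cfg$rt_tol_1t, tol_2t = cfg$rt_tol_2t))
      st_fid <- stencil(do.call(rbind, snapped), st_fid$source_channel)
    }
    write_stencil(st_fid, file.path(out_dir,
                                    paste0("stencil_", sid, ".json")))
    rep_i <- stage("quantify", sid,
                   quantify_stencil(planes_fid[[sid]], st_fid, cfg$detect))
    write_report_csv(rep_i, file.path(out_dir,
                                      paste0("report_", sid, ".csv")))
    reports[[sid]] <- rep_i
    shifts[[sid]] <- sh
    log_line(logcon, "quantified", sample_id = sid, d1t = sh$d1t,
             d2t = sh$d2t, score = sh$score,
             n_nonzero = sum(rep_i$volume > 0))
  }
  bt <- align_reports(reports, stn)
  write_batch_csv(bt, file.path(out_dir, "batch_raw.csv"))
  bt_p <- autoscale(unit_vector_normalize(bt))
  write_batch_csv(bt_p, file.path(out_dir, "batch_pretreated.csv"))
  k_eff <- min(cfg$n_components, nrow(bt_p$values) - 1L,
               ncol(bt_p$values))
  pc <- batch_pca(bt_p, k = k_eff)
  write.csv(data.frame(sample_id = rownames(pc$scores),
                       apply(pc$scores, 2, num_chr),
                       stringsAsFactors = FALSE, check.names = FALSE),
            file.path(out_dir, "pca_scores.csv"), row.names = FALSE)
  write.csv(data.frame(region_id = rownames(pc$loadings),
                       apply(pc$loadings, 2, num_chr),
                       stringsAsFactors = FALSE, check.names = FALSE),
            file.path(out_dir, "pca_loadings.csv"), row.names = FALSE)
  write.csv(data.frame(component = colnames(pc$scores),
                       explained_variance_ratio =
                         num_chr(pc$explained_variance_ratio),
                       stringsAsFactors = FALSE),
            file.path(out_dir, "pca_variance.csv"), row.names = FALSE)
  log_line(logcon, "done", n_regions = nrow(stn$regions),
           batch_dims = dim(bt$values))
  invisible(list(stencil = stn, reports = reports, batch_raw = bt,
                 batch_pretreated = bt_p, pca = pc, shifts = shifts))
}
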