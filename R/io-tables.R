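# Report CSVs, stencil JSON, and batch-table CSVs. All writer/reader pairs
# are exact round-trips on valid objects; numerics are written with 17
# significant digits so doubles survive the trip.

#' Per-sample quantification report
#'
#' One row per stencil region: region id, compound name, apex retentions, and
#' integrated peak volume (0 for regions in which no peak was detected).
#'
#' @param sample_id Sample identifier.
#' @param rows A data.frame with columns `region_id`, `compound_name`,
#'   `apex_1tR_min`, `apex_2tR_s`, `volume`.
#' @return An object of class `sample_report` (a data.frame with a
#'   `sample_id` attribute).
#' @export
sample_report <- function(sample_id, rows) {
  req <- c("region_id", "compound_name", "apex_1tR_min", "apex_2tR_s",
           "volume")
  if (!is.data.frame(rows) || !all(req %in% names(rows)))
    stop_config(paste0("rows must have columns: ", paste(req, collapse = ", ")))
  rows <- rows[, req, drop = FALSE]
  if (anyDuplicated(rows$region_id))
    stop_config("region ids must be unique within a report")
  if (nrow(rows) && any(rows$volume < 0))
    stop_config("volumes must be >= 0")
  rownames(rows) <- NULL
  structure(rows, sample_id = as.character(sample_id),
            class = c("sample_report", "data.frame"))
}

#' @export
print.sample_report <- function(x, ...) {
  cat(sprintf("sample_report '%s': %d regions, %d with non-zero volume\n",
              attr(x, "sample_id"), nrow(x), sum(x$volume > 0)))
  NextMethod()
}

#' Write / read a sample report as CSV
#'
#' UTF-8, header row, RFC 4180 quoting; numeric fields carry 17 significant
#' digits so the round-trip is lossless.
#'
#' @param report A [sample_report()].
#' @param path CSV path.
#' @return `write_report_csv`: `path`, invisibly. `read_report_csv`: a
#'   [sample_report()].
#' @export
write_report_csv <- function(report, path) {
  stopifnot(inherits(report, "sample_report"))
  out <- data.frame(sample_id = rep(attr(report, "sample_id"),
                                    nrow(report)),
                    region_id = report$region_id,
                    compound_name = report$compound_name,
                    apex_1tR_min = num_chr(report$apex_1tR_min),
                    apex_2tR_s = num_chr(report$apex_2tR_s),
                    volume = num_chr(report$volume),
                    stringsAsFactors = FALSE)
  if (!nrow(report))
    out <- out[0, , drop = FALSE]
  write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_report_csv
#' @export
read_report_csv <- function(path) {
  if (!file.exists(path)) stop_format(paste0("no such file: ", path))
  d <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                fileEncoding = "UTF-8")
  req <- c("sample_id", "region_id", "compound_name", "apex_1tR_min",
           "apex_2tR_s", "volume")
  miss <- setdiff(req, names(d))
  if (length(miss))
    stop_format(paste0("report CSV missing column(s): ",
                       paste(miss, collapse = ", ")))
  if (anyDuplicated(d$region_id))
    stop_format("duplicate region_id in report CSV")
  sid <- if (nrow(d)) d$sample_id[1] else NA_character_
  sample_report(sid, data.frame(
    region_id = d$region_id, compound_name = d$compound_name,
    apex_1tR_min = as.numeric(d$apex_1tR_min),
    apex_2tR_s = as.numeric(d$apex_2tR_s),
    volume = as.numeric(d$volume), stringsAsFactors = FALSE))
}

# ---- stencils ---------------------------------------------------------------

#' Stencil: an ordered set of named retention-plane regions
#'
#' Axis-aligned rectangles in the (1tR, 2tR) plane, each optionally carrying
#' a mass spectrum; the unit of cross-sample and cross-channel compound
#' identity.
#'
#' @param regions A data.frame with columns `id`, `name`, `t1_lo`, `t1_hi`
#'   (minutes), `t2_lo`, `t2_hi` (seconds), `origin_sample`, and a list
#'   column `spectrum` (each element a two-column `mz` / `rel_int` matrix
#'   with maximum relative intensity 1, or `NULL`).
#' @param source_channel Label of the channel the regions were defined on.
#' @return An object of class `stencil`.
#' @export
stencil <- function(regions = NULL, source_channel = "MS") {
  if (is.null(regions))
    regions <- data.frame(id = character(0), name = character(0),
                          t1_lo = numeric(0), t1_hi = numeric(0),
                          t2_lo = numeric(0), t2_hi = numeric(0),
                          origin_sample = character(0),
                          stringsAsFactors = FALSE)
  req <- c("id", "name", "t1_lo", "t1_hi", "t2_lo", "t2_hi", "origin_sample")
  if (!all(req %in% names(regions)))
    stop_config(paste0("regions must have columns: ",
                       paste(req, collapse = ", ")))
  if (is.null(regions$spectrum))
    regions$spectrum <- replicate(nrow(regions), NULL, simplify = FALSE)
  if (anyDuplicated(regions$id)) stop_config("region ids must be unique")
  if (nrow(regions)) {
    if (any(regions$t1_lo >= regions$t1_hi) ||
        any(regions$t2_lo >= regions$t2_hi))
      stop_config("region bounds must satisfy lo < hi on both axes")
    for (sp in regions$spectrum) {
      if (is.null(sp)) next
      if (!is.matrix(sp) || ncol(sp) != 2 || any(sp[, 2] <= 0) ||
          max(sp[, 2]) > 1 + 1e-9)
        stop_config("spectra must be 2-column matrices with 0 < rel_int <= 1")
    }
  }
  rownames(regions) <- NULL
  structure(list(regions = regions,
                 source_channel = as.character(source_channel)),
            class = "stencil")
}

#' @export
print.stencil <- function(x, ...) {
  cat(sprintf("stencil [%s]: %d regions (%d with spectra)\n",
              x$source_channel, nrow(x$regions),
              sum(!vapply(x$regions$spectrum, is.null, logical(1)))))
  invisible(x)
}

#' Write / read a stencil as JSON
#'
#' Schema: `{version, source_channel, regions: [{id, name, t1_min_lo,
#' t1_min_hi, t2_s_lo, t2_s_hi, spectrum: [[mz, rel_int], ...] | null,
#' origin_sample}]}`.
#'
#' @param stn A [stencil()].
#' @param path JSON path.
#' @return `write_stencil`: `path`, invisibly. `read_stencil`: a [stencil()].
#' @export
write_stencil <- function(stn, path) {
  stopifnot(inherits(stn, "stencil"))
  rg <- stn$regions
  regions <- lapply(seq_len(nrow(rg)), function(i) {
    sp <- rg$spectrum[[i]]
    list(id = jsonlite::unbox(rg$id[i]),
         name = jsonlite::unbox(rg$name[i]),
         t1_min_lo = jsonlite::unbox(rg$t1_lo[i]),
         t1_min_hi = jsonlite::unbox(rg$t1_hi[i]),
         t2_s_lo = jsonlite::unbox(rg$t2_lo[i]),
         t2_s_hi = jsonlite::unbox(rg$t2_hi[i]),
         spectrum = if (is.null(sp)) NULL else unname(sp),
         origin_sample = jsonlite::unbox(rg$origin_sample[i]))
  })
  obj <- list(version = jsonlite::unbox(1L),
              source_channel = jsonlite::unbox(stn$source_channel),
              regions = regions)
  jsonlite::write_json(obj, path, digits = NA, null = "null",
                       auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

jreq <- function(x, field, jpath) {
  if (is.null(x[[field]]))
    stop_format(paste0("stencil JSON: missing field at ", jpath, ".", field))
  x[[field]]
}

#' @rdname write_stencil
#' @export
read_stencil <- function(path) {
  if (!file.exists(path)) stop_format(paste0("no such file: ", path))
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    stop_format(paste0("not valid JSON: ",
                                       conditionMessage(e))))
  jreq(obj, "version", "$")
  ch <- jreq(obj, "source_channel", "$")
  regs <- obj$regions
  if (is.null(regs)) stop_format("stencil JSON: missing field at $.regions")
  n <- length(regs)
  df <- data.frame(id = character(n), name = character(n),
                   t1_lo = numeric(n), t1_hi = numeric(n),
                   t2_lo = numeric(n), t2_hi = numeric(n),
                   origin_sample = character(n), stringsAsFactors = FALSE)
  spectra <- vector("list", n)
  for (i in seq_len(n)) {
    r <- regs[[i]]
    jp <- sprintf("$.regions[%d]", i)
    df$id[i] <- as.character(jreq(r, "id", jp))
    df$name[i] <- as.character(jreq(r, "name", jp))
    df$t1_lo[i] <- as.numeric(jreq(r, "t1_min_lo", jp))
    df$t1_hi[i] <- as.numeric(jreq(r, "t1_min_hi", jp))
    df$t2_lo[i] <- as.numeric(jreq(r, "t2_s_lo", jp))
    df$t2_hi[i] <- as.numeric(jreq(r, "t2_s_hi", jp))
    og <- r$origin_sample
    df$origin_sample[i] <- if (is.null(og)) NA_character_ else
      as.character(og)
    sp <- r$spectrum
    if (!is.null(sp)) {
      if (!length(sp))
        stop_format(paste0("stencil JSON: empty spectrum at ", jp,
                           ".spectrum"))
      mat <- do.call(rbind, lapply(seq_along(sp), function(k) {
        pair <- sp[[k]]
        if (length(pair) != 2)
          stop_format(sprintf(
            "stencil JSON: spectrum entry is not an [mz, rel_int] pair at %s.spectrum[%d]",
            jp, k))
        as.numeric(unlist(pair))
      }))
      colnames(mat) <- c("mz", "rel_int")
      spectra[[i]] <- mat
    }
  }
  df$spectrum <- spectra
  tryCatch(stencil(df, source_channel = as.character(ch)),
           dualflow_config_error = function(e)
             stop_format(paste0("stencil JSON: ", conditionMessage(e),
                                " (at $.regions)")))
}

# ---- batch tables -----------------------------------------------------------

#' Batch quantification table
#'
#' Samples x regions matrix of peak volumes (counts * s) or pretreated,
#' dimensionless values; always rectangular and zero-filled. Pretreatment
#' state is carried in monotone flags that are never unset.
#'
#' @param values Numeric matrix with sample ids as row names and region ids
#'   as column names.
#' @param region_names Character vector of compound names, one per column.
#' @param flags Named logical vector `c(normalized, centered, scaled)`.
#' @return An object of class `batch_table`.
#' @export
batch_table <- function(values, region_names = NULL,
                        flags = c(normalized = FALSE, centered = FALSE,
                                  scaled = FALSE)) {
  if (!is.matrix(values) || is.null(rownames(values)) ||
      is.null(colnames(values)))
    stop_config("values must be a matrix with sample/region dimnames")
  if (any(!is.finite(values))) stop_config("batch table cells must be finite")
  if (is.null(region_names)) region_names <- colnames(values)
  if (length(region_names) != ncol(values))
    stop_config("region_names must match the number of columns")
  structure(list(values = values, region_names = as.character(region_names),
                 flags = flags),
            class = "batch_table")
}

#' @export
print.batch_table <- function(x, ...) {
  cat(sprintf("batch_table: %d samples x %d regions [%s]\n",
              nrow(x$values), ncol(x$values),
              paste(names(x$flags)[x$flags], collapse = ", ")))
  invisible(x)
}

#' Write / read a batch table as CSV
#'
#' Layout: a `#flags=` comment line, then two header rows (region ids, then
#' compound names), then one row per sample with `sample_id` in the first
#' column.
#'
#' @param bt A [batch_table()].
#' @param path CSV path.
#' @return `write_batch_csv`: `path`, invisibly. `read_batch_csv`: a
#'   [batch_table()].
#' @export
write_batch_csv <- function(bt, path) {
  stopifnot(inherits(bt, "batch_table"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con), add = TRUE)
  writeLines(sprintf("#flags=normalized:%s,centered:%s,scaled:%s",
                     bt$flags[["normalized"]], bt$flags[["centered"]],
                     bt$flags[["scaled"]]), con)
  quote_csv <- function(x) {
    need <- grepl('[",\n]', x)
    x[need] <- paste0('"', gsub('"', '""', x[need]), '"')
    x
  }
  writeLines(paste(c("sample_id", quote_csv(colnames(bt$values))),
                   collapse = ","), con)
  writeLines(paste(c("", quote_csv(bt$region_names)), collapse = ","), con)
  for (i in seq_len(nrow(bt$values)))
    writeLines(paste(c(quote_csv(rownames(bt$values)[i]),
                       num_chr(bt$values[i, ])), collapse = ","), con)
  invisible(path)
}

#' @rdname write_batch_csv
#' @export
read_batch_csv <- function(path) {
  if (!file.exists(path)) stop_format(paste0("no such file: ", path))
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 3 || !startsWith(lines[1], "#flags="))
    stop_format("batch CSV must start with a #flags= line and two headers")
  fl <- sub("^#flags=", "", lines[1])
  kv <- strsplit(strsplit(fl, ",")[[1]], ":")
  flags <- setNames(vapply(kv, function(p) as.logical(p[2]), logical(1)),
                    vapply(kv, `[`, character(1), 1))
  body <- read.csv(text = lines[-1], header = FALSE, stringsAsFactors = FALSE,
                   colClasses = "character")
  ids <- as.character(body[1, -1])
  nms <- as.character(body[2, -1])
  rows <- body[-(1:2), , drop = FALSE]
  vals <- as.matrix(rows[, -1, drop = FALSE])
  m <- matrix(as.numeric(vals), nrow = nrow(rows),
              dimnames = list(rows[, 1], ids))
  batch_table(m, region_names = nms,
              flags = flags[c("normalized", "centered", "scaled")])
}
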