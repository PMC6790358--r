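#' Construct a centroided LC-MS run
#'
#' A `plantmet_run` is the internal model of one centroided UPLC-HRMS
#' acquisition: an ordered list of MS1 scans, each a set of (m/z, intensity)
#' centroids at one retention time. Retention times are stored in minutes,
#' m/z in Da.
#'
#' @param sample_id character scalar identifying the sample.
#' @param group_label character scalar naming the experimental group.
#' @param scans list of scans; each scan is a list with numeric fields
#'   `rt` (minutes), `mz` (strictly increasing, Da) and `intensity`
#'   (non-negative, same length as `mz`).
#' @return an object of class `plantmet_run`.
#' @export
new_run <- function(sample_id, group_label, scans) {
  run <- structure(
    list(sample_id = as.character(sample_id),
         group_label = as.character(group_label),
         scans = scans),
    class = "plantmet_run")
  validate_run(run)
  run
}

validate_run <- function(run) {
  if (length(run$scans) < 2)
    stop("run '", run$sample_id, "' needs at least 2 scans")
  rts <- vapply(run$scans, function(s) s$rt, numeric(1))
  if (any(rts < 0)) stop("negative retention time in run '", run$sample_id, "'")
  if (any(diff(rts) <= 0))
    stop("scan retention times must be strictly increasing")
  for (s in run$scans) {
    if (length(s$mz) != length(s$intensity))
      stop("scan mz/intensity length mismatch")
    if (length(s$mz) > 1 && any(diff(s$mz) <= 0))
      stop("centroid m/z values must be strictly increasing within a scan")
    if (any(s$intensity < 0)) stop("negative intensity")
  }
  invisible(run)
}

#' @export
print.plantmet_run <- function(x, ...) {
  cat(sprintf("<plantmet_run> sample '%s' (group '%s'), %d MS1 scans, rt %.3f-%.3f min\n",
              x$sample_id, x$group_label, length(x$scans),
              x$scans[[1]]$rt, x$scans[[length(x$scans)]]$rt))
  invisible(x)
}

run_rts <- function(run) vapply(run$scans, function(s) s$rt, numeric(1))

#' Read a centroided mzXML/mzML run
#'
#' Reads MS1 centroid scans from an mzXML or mzML file (the format is
#' detected by the parser). MS2 and higher-level scans are skipped. Scan
#' times are converted from seconds to minutes; scans are sorted by
#' retention time and centroids by m/z.
#'
#' @param path path to an mzXML or mzML file.
#' @param sample_id sample identifier to attach; defaults to the file name
#'   without extension.
#' @param group_label experimental group label (default `"unknown"`).
#' @return a [new_run()] object.
#' @export
read_run <- function(path, sample_id = NULL,
                     group_label = "unknown") {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]+$", "", basename(path))
  ms <- tryCatch(mzR::openMSfile(path),
                 error = function(e) stop("cannot parse '", path, "': ",
                                          conditionMessage(e)))
  on.exit(try(mzR::close(ms), silent = TRUE))
  hdr <- mzR::header(ms)
  ms1 <- which(hdr$msLevel == 1L)
  if (length(ms1) == 0)
    stop("no MS1 scans in '", path, "'")
  if (any(!is.na(hdr$centroided[ms1]) & !hdr$centroided[ms1]))
    stop("profile-mode MS1 data in '", path,
         "'; centroided input is required")
  scans <- lapply(ms1, function(i) {
    pk <- mzR::peaks(ms, i)
    o <- order(pk[, 1])
    list(rt = hdr$retentionTime[i] / 60,
         mz = as.numeric(pk[o, 1]),
         intensity = as.numeric(pk[o, 2]))
  })
  scans <- scans[order(vapply(scans, function(s) s$rt, numeric(1)))]
  new_run(sample_id, group_label, scans)
}

#' Write a run as mzXML
#'
#' Emits a minimal centroided mzXML file readable by [read_run()].
#' Retention times are written in seconds, following the format convention.
#'
#' @param run a [new_run()] object.
#' @param path output file path (conventionally `.mzXML`).
#' @return `path`, invisibly.
#' @export
write_run <- function(run, path) {
  validate_run(run)
  n <- length(run$scans)
  pks <- lapply(run$scans, function(s) cbind(mz = s$mz, intensity = s$intensity))
  npk <- vapply(pks, nrow, integer(1))
  bp <- function(s, f) if (length(s$intensity)) f(s) else 0
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n), msLevel = 1L,
    polarity = 1L, peaksCount = npk,
    totIonCurrent = vapply(run$scans, function(s) sum(s$intensity), numeric(1)),
    retentionTime = run_rts(run) * 60,
    basePeakMZ = vapply(run$scans, function(s)
      bp(s, function(z) z$mz[which.max(z$intensity)]), numeric(1)),
    basePeakIntensity = vapply(run$scans, function(s)
      bp(s, function(z) max(z$intensity)), numeric(1)),
    collisionEnergy = 0, ionisationEnergy = 0,
    lowMZ = vapply(run$scans, function(s) bp(s, function(z) min(z$mz)), numeric(1)),
    highMZ = vapply(run$scans, function(s) bp(s, function(z) max(z$mz)), numeric(1)),
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = paste0("scan=", seq_len(n)), centroided = TRUE,
    ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_, isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_, scanWindowLowerLimit = NA_real_,
    scanWindowUpperLimit = NA_real_)
  mzR::writeMSData(object = pks, file = path, header = hdr,
                   outformat = "mzxml")
  invisible(path)
}

#' Write a registered component table as TSV
#'
#' One row per registered component with its identifiers, mean m/z and
#' retention time, per-sample heights and areas, and (when present) the
#' Meta ID, annotation role and final metabolite id. Peaks not detected in
#' a sample are written as empty fields, not zero, so downstream statistics
#' can distinguish "not detected" from "zero response".
#'
#' @param table a `component_table` (see [nnc_register()]).
#' @param path output TSV path.
#' @param screen optional screening results ([anova_screen()]) to merge.
#' @param metas optional Meta ID assignments ([assign_meta_ids()]).
#' @param annotations optional metabolite assignments
#'   ([reconcile_with_screening()]).
#' @return `path`, invisibly.
#' @export
write_component_table <- function(table, path, screen = NULL, metas = NULL,
                                  annotations = NULL) {
  df <- component_table_df(table, screen = screen, metas = metas,
                           annotations = annotations)
  utils::write.table(df, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE)
  invisible(path)
}

# Flat data.frame view of a component table with optional result columns.
component_table_df <- function(table, screen = NULL, metas = NULL,
                               annotations = NULL) {
  comp <- table$components
  df <- data.frame(component_id = comp$component_id,
                   mean_mz = comp$mean_mz, mean_rt = comp$mean_rt,
                   n_members = comp$n_members)
  for (s in table$samples) df[[paste0("height_", s)]] <- table$heights[, s]
  for (s in table$samples) df[[paste0("area_", s)]] <- table$areas[, s]
  if (!is.null(screen)) {
    i <- match(df$component_id, screen$component_id)
    df$f_statistic <- screen$f_statistic[i]
    df$p_value <- screen$p_value[i]
    df$significant <- screen$significant[i]
  }
  if (!is.null(metas)) {
    i <- match(df$component_id, metas$component_id)
    df$meta_id <- metas$meta_id[i]
  }
  if (!is.null(annotations)) {
    i <- match(df$component_id, annotations$component_id)
    df$role <- annotations$role[i]
    df$metabolite_id <- annotations$metabolite_id[i]
  }
  df
}

#' Write derived mass spectra in NIST MSP text format
#'
#' @param spectra list of derived spectra as returned by
#'   [derive_spectrum()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_msp <- function(spectra, path) {
  if (length(spectra) == 0) stop("no spectra to write")
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in spectra) {
    writeLines(c(
      sprintf("Name: metabolite_%d", sp$metabolite_id),
      sprintf("Comment: source_sample=%s rt=%.4f", sp$source_sample, sp$rt),
      sprintf("Num Peaks: %d", nrow(sp$entries)),
      sprintf("%.5f %.1f \"%s\"", sp$entries$mz, sp$entries$intensity,
              sp$entries$role),
      ""), con)
  }
  invisible(path)
}

# --- plain-text serialization of peak tables (pipeline intermediates) ----

# Peak tables carry shape vectors as list-columns; for TSV round-trips the
# shapes are flattened to comma-joined numeric strings.
write_peak_table <- function(peaks, path) {
  df <- peaks
  df$shape_rt <- vapply(peaks$shape, function(s)
    paste(sprintf("%.6f", s$rt), collapse = ","), character(1))
  df$shape_int <- vapply(peaks$shape, function(s)
    paste(sprintf("%.4f", s$intensity), collapse = ","), character(1))
  df$shape <- NULL
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_peak_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  split_num <- function(x) as.numeric(strsplit(x, ",", fixed = TRUE)[[1]])
  df$shape <- Map(function(r, i) list(rt = split_num(r), intensity = split_num(i)),
                  df$shape_rt, df$shape_int)
  names(df$shape) <- NULL
  df$shape_rt <- NULL
  df$shape_int <- NULL
  df
}
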