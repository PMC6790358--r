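#' Pipeline configuration
#'
#' Collects every tolerance and threshold of the five analysis stages with
#' the platform's defaults: EIC construction within 0.01 Da, alignment
#' candidates within 0.01 Da and 0.5 min, registration within 0.01 Da and
#' 0.1 min, a 0.9 correlation threshold for Meta grouping, and isotope
#' seeding at a 0.9 shape cut-off within 0.02 min. Validation is
#' exhaustive: every violated constraint is reported at once.
#'
#' @param ... overrides of the default fields.
#' @return validated parameter list of class `plantmet_config`.
#' @export
plantmet_config <- function(...) {
  cfg <- list(
    # EIC extraction
    mz_tol = 0.01, min_points = 10L, baseline_window_min = 2,
    sigmas = 1:10, min_ridge_length = 3L, min_snr = 3,
    # time alignment
    align_mz_tol = 0.01, align_rt_tol = 0.5, min_match = 0.5,
    resample_points = 50L, anchor_min_snr = 10,
    # registration
    reg_mz_tol = 0.01, reg_rt_tol = 0.1,
    # screening
    alpha = 0.05, corr_threshold = 0.9, mcd_support = 0.75,
    coelution_rt_tol = 0.1, response = "height", p_adjust = "none",
    mcd_seed = 1L,
    # annotation
    shape_cutoff0 = 0.9, anno_rt_tol = 0.02, iso_mz_tol = 0.005,
    margin = 0.02, cutoff_floor = 0.8, min_votes = NULL,
    adduct_table = default_adduct_table())
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  validate_config(cfg)
  structure(cfg, class = "plantmet_config")
}

validate_config <- function(cfg) {
  errs <- character(0)
  pos <- c("mz_tol", "align_mz_tol", "align_rt_tol", "reg_mz_tol",
           "reg_rt_tol", "anno_rt_tol", "iso_mz_tol", "min_snr",
           "baseline_window_min", "coelution_rt_tol")
  for (f in pos)
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0)
      errs <- c(errs, paste0(f, " must be > 0"))
  unit <- c("corr_threshold", "shape_cutoff0", "cutoff_floor", "alpha",
            "mcd_support", "min_match")
  for (f in unit)
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0 || cfg[[f]] > 1)
      errs <- c(errs, paste0(f, " must be in (0, 1]"))
  if (!cfg$response %in% c("height", "area"))
    errs <- c(errs, "response must be 'height' or 'area'")
  if (!cfg$p_adjust %in% c("none", "BH"))
    errs <- c(errs, "p_adjust must be 'none' or 'BH'")
  if (length(errs))
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "))
  invisible(cfg)
}

#' Run the five-stage analysis pipeline
#'
#' Executes extraction, time-shift correction, registration, screening and
#' ion-clustering annotation end to end on a set of runs, optionally
#' writing per-stage artifacts (TSV/JSON/MSP) to an output directory. With
#' fewer than two groups the screening and annotation stages are skipped
#' and the result stops at the registered component table.
#'
#' @param runs named list of [new_run()] objects, or a character vector of
#'   mzXML/mzML paths (read with [read_run()]).
#' @param groups named character vector sample id -> group label; defaults
#'   to each run's `group_label`.
#' @param params a [plantmet_config()].
#' @param out_dir optional output directory for stage artifacts.
#' @param verbose log per-stage counts via [message()] (default TRUE).
#' @return list with `peaks` (raw per-sample peak tables), `aligned`
#'   (alignment result), `table` (component table), `screen`, `metas`,
#'   `sample_annotations`, `annotation` (reconciled assignments) and
#'   `spectra` (derived spectra of confirmed metabolites).
#' @export
run_pipeline <- function(runs, groups = NULL,
                         params = plantmet_config(), out_dir = NULL,
                         verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  if (is.character(runs)) {
    paths <- runs
    runs <- lapply(paths, read_run)
    names(runs) <- vapply(runs, `[[`, character(1), "sample_id")
  }
  if (length(runs) < 2) stop("pipeline needs at least 2 samples")
  if (is.null(groups))
    groups <- vapply(runs, `[[`, character(1), "group_label")
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  art <- function(name) if (is.null(out_dir)) NULL else
    file.path(out_dir, name)

  # stage 1: EIC peak extraction
  peaks <- lapply(runs, extract_sample_peaks, params = params)
  say("extract: %s peaks across %d samples",
      paste(vapply(peaks, nrow, integer(1)), collapse = "/"), length(peaks))
  if (!is.null(out_dir))
    for (sid in names(peaks))
      write_peak_table(peaks[[sid]], art(paste0("peaks_", sid, ".tsv")))

  # stage 2: time-shift correction
  aligned <- align_samples(peaks, params = params)
  say("align: reference '%s', anchors %s", aligned$reference_id,
      paste(vapply(aligned$anchors, function(a)
        if (is.null(a)) 0L else nrow(a), integer(1)), collapse = "/"))

  # stage 3: registration
  all_pk <- do.call(rbind, aligned$peaks)
  tab <- nnc_register(all_pk, samples = names(runs),
                      mz_tol = params$reg_mz_tol, rt_tol = params$reg_rt_tol)
  say("register: %d components", nrow(tab$components))

  res <- list(peaks = peaks, aligned = aligned, table = tab,
              groups = groups, params = params)
  if (length(unique(groups)) < 2) {
    say("screen: skipped (single experimental group)")
    if (!is.null(out_dir)) write_component_table(tab, art("components.tsv"))
    return(res)
  }

  # stage 4: screening
  scr <- anova_screen(tab, groups, alpha = params$alpha,
                      response = params$response,
                      p_adjust = params$p_adjust)
  metas <- assign_meta_ids(scr, tab, corr_threshold = params$corr_threshold,
                           coelution_rt_tol = params$coelution_rt_tol,
                           response = params$response,
                           mcd_support = params$mcd_support,
                           mcd_seed = params$mcd_seed)
  say("screen: %d testable, %d significant, %d Meta IDs",
      nrow(scr), sum(scr$significant),
      length(unique(metas$assignments$meta_id)))

  # stage 5: ion-clustering annotation
  sample_annotations <- lapply(aligned$peaks, annotate_sample,
                               params = params)
  anno <- reconcile_with_screening(sample_annotations, metas, tab,
                                   min_votes = params$min_votes)
  say("annotate: %d confirmed metabolites, %d partial-evidence pairs",
      length(unique(anno$assignments$metabolite_id)), nrow(anno$partial))
  spectra <- lapply(unique(anno$assignments$metabolite_id),
                    derive_spectrum, assignments = anno$assignments,
                    table = tab, all_peaks = all_pk)

  res$screen <- scr
  res$metas <- metas
  res$sample_annotations <- sample_annotations
  res$annotation <- anno
  res$spectra <- spectra
  if (!is.null(out_dir)) {
    write_component_table(tab, art("components.tsv"), screen = scr,
                          metas = metas$assignments,
                          annotations = anno$assignments)
    if (length(spectra)) write_msp(spectra, art("spectra.msp"))
    utils::write.table(anno$partial, art("partial_evidence.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  res
}
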