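#' Score pipeline outputs against generator ground truth
#'
#' Computes benchmark metrics by matching pipeline results back to a
#' [generate_dataset()] ground truth:
#' \describe{
#'   \item{peak_recall / peak_precision}{a true ion in a sample counts as
#'     recovered when a detected peak lies within 0.01 Da and 0.05 min of
#'     its true (m/z, warped rt); precision treats unmatched detected
#'     peaks that also fail to match any noise ion location as false
#'     positives of the true-ion set.}
#'   \item{alignment_rt_rmse}{root-mean-square deviation, over true ions
#'     and samples, of aligned apex rts from the reference sample's
#'     aligned apex rt for the same ion (minutes).}
#'   \item{registration_ari}{adjusted Rand index between the partition of
#'     truth-matched detected peaks into registered components and their
#'     true ion identities.}
#'   \item{screening_sensitivity / screening_specificity}{ANOVA
#'     significance vs the ground-truth group-effect flag of the matched
#'     metabolite.}
#'   \item{confirmation_recall}{fraction of effect-carrying metabolites
#'     with at least one confirmed metabolite group (>= 2 components) whose
#'     components all map to that metabolite.}
#'   \item{confirmation_purity}{fraction of confirmed groups whose
#'     components map to a single true metabolite; `cross_merges` counts
#'     the offending groups.}
#' }
#'
#' @param results output of [run_pipeline()] (or a list with the same
#'   `aligned`, `table`, `screen`, `metas`, `annotation` fields).
#' @param truth a `ground_truth`.
#' @param mz_tol,rt_tol truth-matching tolerances (0.01 Da, 0.05 min).
#' @return named list of metrics, all in \[0, 1\] except the RMSE.
#' @export
score_against_truth <- function(results, truth, mz_tol = 0.01,
                                rt_tol = 0.05) {
  samples <- truth$samples$sample_id
  ions <- truth$ions
  out <- list()

  # --- peak detection, per sample against true (mz, warped rt) ----------
  matched <- list()   # per sample: detected peak index -> ion_id (or NA)
  n_true_present <- 0L; n_true_found <- 0L
  n_det <- 0L; n_det_true <- 0L
  # features above the detector noise floor (quantifiable features)
  major_cut <- 10 * (truth$config$noise_floor_sd %||% 0)
  n_major <- 0L; n_major_true <- 0L
  for (s in seq_along(samples)) {
    sid <- samples[s]
    pk <- results$peaks[[sid]]
    det_ion <- rep(NA_integer_, nrow(pk))
    for (k in seq_len(nrow(ions))) {
      if (truth$heights[k, sid] < truth$config$emission_floor) next
      n_true_present <- n_true_present + 1L
      tr_rt <- truth$true_rt[ions$metabolite_id[k], sid]
      hit <- which(abs(pk$apex_mz - ions$mz[k]) <= mz_tol &
                     abs(pk$apex_rt - tr_rt) <= rt_tol)
      if (length(hit)) {
        n_true_found <- n_true_found + 1L
        best <- hit[which.max(pk$height[hit])]
        det_ion[best] <- ions$ion_id[k]
      }
    }
    # detections matching a generated noise ion are legitimate, not FPs
    is_noise <- rep(FALSE, nrow(pk))
    nz <- truth$noise_ions
    if (!is.null(nz)) {
      nz <- nz[nz$sample_id == sid, , drop = FALSE]
      for (q in which(is.na(det_ion))) {
        is_noise[q] <- any(abs(nz$mz - pk$apex_mz[q]) <= mz_tol &
                             abs(nz$rt - pk$apex_rt[q]) <= rt_tol)
      }
    }
    matched[[sid]] <- det_ion
    n_det <- n_det + nrow(pk)
    n_det_true <- n_det_true + sum(!is.na(det_ion)) + sum(is_noise)
    maj <- pk$height >= major_cut
    n_major <- n_major + sum(maj)
    n_major_true <- n_major_true + sum(maj & (!is.na(det_ion) | is_noise))
  }
  out$peak_recall <- n_true_found / max(n_true_present, 1L)
  out$peak_precision <- n_det_true / max(n_det, 1L)
  out$peak_precision_major <- n_major_true / max(n_major, 1L)

  # --- alignment residual ----------------------------------------------
  if (!is.null(results$aligned)) {
    ref <- results$aligned$reference_id
    al <- results$aligned$peaks
    rts <- matrix(NA_real_, nrow(ions), length(samples),
                  dimnames = list(NULL, samples))
    for (sid in samples) {
      pk <- al[[sid]]
      det_ion <- match_peaks_to_ions(pk, results$peaks[[sid]], matched[[sid]])
      ok <- !is.na(det_ion)
      rts[det_ion[ok], sid] <- pk$apex_rt[ok]
    }
    resid <- rts - rts[, ref]
    resid <- resid[, setdiff(samples, ref), drop = FALSE]
    out$alignment_rt_rmse <- sqrt(mean(resid^2, na.rm = TRUE))
  }

  # --- registration ARI -------------------------------------------------
  if (!is.null(results$table)) {
    mem <- results$table$membership
    pid2comp <- stats::setNames(mem$component_id, mem$peak_id)
    lab_true <- integer(0); lab_pred <- integer(0)
    for (sid in samples) {
      pk <- results$peaks[[sid]]
      det_ion <- matched[[sid]]
      ok <- !is.na(det_ion) & pk$peak_id %in% names(pid2comp)
      lab_true <- c(lab_true, det_ion[ok])
      lab_pred <- c(lab_pred, pid2comp[pk$peak_id[ok]])
    }
    out$registration_ari <- if (length(lab_true) > 1)
      mclust::adjustedRandIndex(lab_true, lab_pred) else NA_real_
    # map components to true ions by majority vote for screening metrics
    comp_ion <- comp_to_ion_map(results, matched, samples)
  }

  # --- screening --------------------------------------------------------
  if (!is.null(results$screen) && !is.null(results$table)) {
    scr <- results$screen
    ion_met <- stats::setNames(ions$metabolite_id, ions$ion_id)
    met_eff <- stats::setNames(truth$metabolites$effect,
                               truth$metabolites$metabolite_id)
    scr_ion <- comp_ion[as.character(scr$component_id)]
    ok <- !is.na(scr_ion)
    eff <- met_eff[as.character(ion_met[as.character(scr_ion[ok])])]
    sig <- scr$significant[ok]
    out$screening_sensitivity <- if (any(eff)) mean(sig[eff]) else NA_real_
    out$screening_specificity <- if (any(!eff)) mean(!sig[!eff]) else NA_real_
  }

  # --- metabolite confirmation -----------------------------------------
  if (!is.null(results$annotation)) {
    asg <- results$annotation$assignments
    ion_met <- stats::setNames(ions$metabolite_id, ions$ion_id)
    eff_mets <- truth$metabolites$metabolite_id[truth$metabolites$effect]
    confirmed_of <- integer(0)
    cross <- 0L
    for (mid in unique(asg$metabolite_id)) {
      comps <- asg$component_id[asg$metabolite_id == mid]
      true_m <- unique(stats::na.omit(
        ion_met[as.character(comp_ion[as.character(comps)])]))
      if (length(true_m) == 1 && length(comps) >= 2)
        confirmed_of <- c(confirmed_of, true_m)
      if (length(true_m) > 1) cross <- cross + 1L
    }
    out$confirmation_recall <-
      if (length(eff_mets)) mean(eff_mets %in% confirmed_of) else NA_real_
    out$confirmation_purity <- if (length(unique(asg$metabolite_id)))
      1 - cross / length(unique(asg$metabolite_id)) else NA_real_
    out$cross_merges <- cross
  }
  out
}

# carry the per-sample ion matching from the raw to the aligned table
# (same peak ids, so the match carries over directly)
match_peaks_to_ions <- function(aligned_pk, raw_pk, det_ion) {
  det_ion[match(aligned_pk$peak_id, raw_pk$peak_id)]
}

# component -> true ion id by majority over member peaks (NA if unmatched)
comp_to_ion_map <- function(results, matched, samples) {
  mem <- results$table$membership
  ionof <- rep(NA_integer_, nrow(mem))
  for (sid in samples) {
    pk <- results$peaks[[sid]]
    sel <- mem$sample_id == sid
    ionof[sel] <- matched[[sid]][match(mem$peak_id[sel], pk$peak_id)]
  }
  vapply(split(ionof, mem$component_id), function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) return(NA_integer_)
    as.integer(names(sort(table(v), decreasing = TRUE))[1])
  }, integer(1))
}
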