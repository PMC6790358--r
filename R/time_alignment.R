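#' Select the alignment reference sample
#'
#' The sample whose EIC peak list holds the most detected peaks is taken as
#' the reference all others are aligned to; ties break to the
#' lexicographically smallest sample id.
#'
#' @param peak_tables named list of per-sample peak data.frames
#'   ([extract_sample_peaks()]).
#' @return the reference sample id (character scalar).
#' @export
select_reference <- function(peak_tables) {
  if (length(peak_tables) < 2)
    stop("need at least 2 samples to align")
  counts <- vapply(peak_tables, nrow, integer(1))
  ids <- names(peak_tables)
  ids[order(-counts, ids)][1]
}

#' Pearson similarity of two EIC peaks
#'
#' Candidate peak pairs must satisfy both the m/z tolerance and the
#' retention-time tolerance; pairs outside either are invalid (`NA`). Valid
#' pairs are scored by the Pearson correlation of their elution profiles,
#' each linearly resampled to `npoints` over +/- 2x its own half-width
#' around its apex (zero outside the peak's support). A constant profile
#' yields correlation 0.
#'
#' @param p,q single-row peak data.frames with `shape` list-columns.
#' @param mz_tol m/z tolerance in Da (default 0.01).
#' @param rt_tol retention-time tolerance in minutes (default 0.5).
#' @param npoints resampling grid size (default 50).
#' @return correlation in \[-1, 1\], or `NA_real_` for an invalid pair.
#' @export
peak_similarity <- function(p, q, mz_tol = 0.01, rt_tol = 0.5,
                            npoints = 50L) {
  if (abs(p$apex_mz - q$apex_mz) > mz_tol ||
      abs(p$apex_rt - q$apex_rt) > rt_tol) return(NA_real_)
  shape_similarity_relative(p$shape[[1]], p$apex_rt,
                            q$shape[[1]], q$apex_rt, npoints)
}

shape_similarity_relative <- function(sp, apex_p, sq, apex_q, npoints = 50L) {
  # a degenerate (constant) profile carries no shape information
  if (stats::sd(sp$intensity) == 0 || stats::sd(sq$intensity) == 0) return(0)
  half_p <- max(apex_p - sp$rt[1], sp$rt[length(sp$rt)] - apex_p)
  half_q <- max(apex_q - sq$rt[1], sq$rt[length(sq$rt)] - apex_q)
  a <- resample_shape(sp$rt, sp$intensity, apex_p, 2 * half_p, npoints)
  b <- resample_shape(sq$rt, sq$intensity, apex_q, 2 * half_q, npoints)
  pearson_safe(a, b)
}

#' Similarity matrix between reference and test peak lists
#'
#' Rows are reference peaks and columns test peaks, both in retention-time
#' order; entries are [peak_similarity()] values, `NA` where the pair
#' violates the m/z or rt tolerance.
#'
#' @param ref_peaks,test_peaks peak data.frames, rt-sorted.
#' @inheritParams peak_similarity
#' @return numeric matrix `nrow(ref_peaks)` x `nrow(test_peaks)`.
#' @export
similarity_matrix <- function(ref_peaks, test_peaks, mz_tol = 0.01,
                              rt_tol = 0.5, npoints = 50L) {
  m <- nrow(ref_peaks); n <- nrow(test_peaks)
  S <- matrix(NA_real_, m, n)
  if (m == 0 || n == 0) return(S)
  for (i in seq_len(m)) {
    dmz <- abs(test_peaks$apex_mz - ref_peaks$apex_mz[i])
    drt <- abs(test_peaks$apex_rt - ref_peaks$apex_rt[i])
    for (j in which(dmz <= mz_tol & drt <= rt_tol)) {
      S[i, j] <- shape_similarity_relative(
        ref_peaks$shape[[i]], ref_peaks$apex_rt[i],
        test_peaks$shape[[j]], test_peaks$apex_rt[j], npoints)
    }
  }
  S
}

#' Dynamic-programming alignment over a similarity matrix
#'
#' Finds the monotone matching (strictly increasing in both row and column
#' index) maximizing the accumulated Pearson similarity of matched pairs,
#' with unmatched rows and columns allowed at zero gain and invalid pairs
#' unmatchable. Matched pairs scoring at least `min_match` are flagged as
#' anchors for warp fitting.
#'
#' @param S similarity matrix from [similarity_matrix()]; `NA` = invalid.
#' @param min_match minimum similarity for a matched pair to serve as a
#'   warp anchor (default 0.5).
#' @return data.frame with `ref_idx`, `test_idx`, `similarity`, `anchor`;
#'   attribute `"score"` holds the accumulated optimum.
#' @export
align_dp <- function(S, min_match = 0.5) {
  m <- nrow(S); n <- ncol(S)
  M <- matrix(0, m + 1, n + 1)
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      best <- max(M[i, j + 1], M[i + 1, j])
      if (!is.na(S[i, j])) best <- max(best, M[i, j] + S[i, j])
      M[i + 1, j + 1] <- best
    }
  }
  # traceback, preferring a match at ties
  i <- m; j <- n
  ri <- integer(0); tj <- integer(0)
  while (i > 0 && j > 0) {
    if (!is.na(S[i, j]) && M[i + 1, j + 1] == M[i, j] + S[i, j]) {
      ri <- c(i, ri); tj <- c(j, tj)
      i <- i - 1; j <- j - 1
    } else if (M[i + 1, j + 1] == M[i, j + 1]) {
      i <- i - 1
    } else {
      j <- j - 1
    }
  }
  sim <- if (length(ri)) S[cbind(ri, tj)] else numeric(0)
  # zero-gain matches picked up at traceback ties carry no evidence; drop
  out <- data.frame(ref_idx = ri, test_idx = tj,
                    similarity = sim)[sim > 0, , drop = FALSE]
  out$anchor <- out$similarity >= min_match
  attr(out, "score") <- M[m + 1, n + 1]
  rownames(out) <- NULL
  out
}

#' Fit a piecewise-linear retention-time warp from aligned anchors
#'
#' Maps test-sample retention times onto the reference time axis by linear
#' interpolation through the anchor pairs; outside the anchor range the
#' shift at the nearest anchor is held constant. Monotonicity is enforced
#' by iteratively dropping the lower-similarity anchor of any inverted or
#' duplicated pair. Because retention drift is smooth, anchors whose
#' implied shift jumps away from the running median of their neighbours
#' (beyond 4 robust standard deviations, with a floor of 0.02 min that
#' allows for apex discretisation on typical scan grids) are discarded as
#' spurious matches before the warp is built. With zero anchors the warp
#' is the identity.
#'
#' @param anchors data.frame with `test_rt`, `ref_rt` and optionally
#'   `similarity` (defaults to 1).
#' @return an object of class `warp_function`; call it via [warp_rt()].
#' @export
fit_warp <- function(anchors) {
  if (is.null(anchors) || nrow(anchors) == 0) {
    return(structure(list(test_rt = numeric(0), ref_rt = numeric(0)),
                     class = "warp_function"))
  }
  if (is.null(anchors$similarity)) anchors$similarity <- 1
  a <- anchors[order(anchors$test_rt, -anchors$similarity), , drop = FALSE]
  a <- a[!duplicated(a$test_rt), , drop = FALSE]
  if (nrow(a) >= 5) {
    shift <- a$ref_rt - a$test_rt
    med <- stats::runmed(shift, 2 * min(3L, (nrow(a) - 1L) %/% 2L) + 1L)
    dev <- abs(shift - med)
    tol <- max(4 * stats::mad(shift - med), 0.02)
    a <- a[dev <= tol, , drop = FALSE]
  }
  repeat {
    bad <- which(diff(a$ref_rt) <= 0)
    if (length(bad) == 0) break
    b <- bad[1]
    drop <- if (a$similarity[b] < a$similarity[b + 1]) b else b + 1L
    a <- a[-drop, , drop = FALSE]
  }
  structure(list(test_rt = a$test_rt, ref_rt = a$ref_rt), class = "warp_function")
}

#' Apply a warp function to retention times
#'
#' @param warp a `warp_function` from [fit_warp()].
#' @param rt numeric vector of test-sample retention times (minutes).
#' @return corrected retention times on the reference axis.
#' @export
warp_rt <- function(warp, rt) {
  k <- length(warp$test_rt)
  if (k == 0) return(rt)
  if (k == 1) return(rt + (warp$ref_rt - warp$test_rt))
  out <- stats::approx(warp$test_rt, warp$ref_rt, xout = rt, rule = 1)$y
  lo <- rt < warp$test_rt[1]
  hi <- rt > warp$test_rt[k]
  out[lo] <- rt[lo] + (warp$ref_rt[1] - warp$test_rt[1])
  out[hi] <- rt[hi] + (warp$ref_rt[k] - warp$test_rt[k])
  out
}

#' @export
print.warp_function <- function(x, ...) {
  cat(sprintf("<warp_function> %d anchors", length(x$test_rt)))
  if (length(x$test_rt))
    cat(sprintf(", shift range [%.4f, %.4f] min",
                min(x$ref_rt - x$test_rt), max(x$ref_rt - x$test_rt)))
  cat("\n")
  invisible(x)
}

#' Align all samples to the reference
#'
#' For each test sample, builds the peak similarity matrix against the
#' reference, runs the dynamic-programming alignment, fits a warp from the
#' anchor pairs and remaps all retention-time fields (apex, boundaries and
#' shape supports) onto the reference time axis. Only peaks of
#' signal-to-noise ratio `anchor_min_snr` or better take part in the
#' matching - the apex of a feature near the noise floor is too poorly
#' localised to serve as a time reference - but the fitted warp is applied
#' to every peak. The reference sample is returned unchanged. A sample
#' sharing no valid anchors with the reference keeps its original
#' retention times and a warning is issued.
#'
#' @param peak_tables named list of per-sample peak data.frames.
#' @param reference_id reference sample id; default from
#'   [select_reference()].
#' @param params parameter list ([plantmet_config()]); keys `align_mz_tol`,
#'   `align_rt_tol`, `min_match`, `resample_points`.
#' @return list with `peaks` (aligned tables), `reference_id`, `warps`
#'   (named list of `warp_function`) and `anchors` (per-sample anchor
#'   data.frames).
#' @export
align_samples <- function(peak_tables, reference_id = NULL,
                          params = plantmet_config()) {
  if (is.null(reference_id)) reference_id <- select_reference(peak_tables)
  ref <- peak_tables[[reference_id]]
  ref_anch <- tst_anchor_view(ref, params)
  warps <- list(); anchors_out <- list()
  for (sid in names(peak_tables)) {
    if (sid == reference_id) {
      warps[[sid]] <- fit_warp(NULL)
      anchors_out[[sid]] <- NULL
      next
    }
    tst <- peak_tables[[sid]]
    tst_anch <- tst_anchor_view(tst, params)
    S <- similarity_matrix(ref_anch, tst_anch,
                           mz_tol = params$align_mz_tol,
                           rt_tol = params$align_rt_tol,
                           npoints = params$resample_points)
    path <- align_dp(S, min_match = params$min_match)
    anc <- path[path$anchor, , drop = FALSE]
    if (nrow(anc) == 0) {
      warning("sample '", sid, "' shares no alignable peaks with the ",
              "reference '", reference_id, "'; keeping original times")
      warps[[sid]] <- fit_warp(NULL)
      anchors_out[[sid]] <- anc
      next
    }
    anc_df <- data.frame(test_rt = tst_anch$apex_rt[anc$test_idx],
                         ref_rt = ref_anch$apex_rt[anc$ref_idx],
                         similarity = anc$similarity)
    w <- fit_warp(anc_df)
    warps[[sid]] <- w
    anchors_out[[sid]] <- anc_df
    tst$apex_rt <- warp_rt(w, tst$apex_rt)
    tst$left_rt <- warp_rt(w, tst$left_rt)
    tst$right_rt <- warp_rt(w, tst$right_rt)
    tst$shape <- lapply(tst$shape, function(s)
      list(rt = warp_rt(w, s$rt), intensity = s$intensity))
    o <- order(tst$apex_rt, tst$apex_mz)
    peak_tables[[sid]] <- tst[o, , drop = FALSE]
  }
  list(peaks = peak_tables, reference_id = reference_id, warps = warps,
       anchors = anchors_out)
}

# peaks reliable enough to serve as alignment anchors
tst_anchor_view <- function(pk, params) {
  thr <- params$anchor_min_snr %||% 0
  if (!("snr" %in% names(pk)) || is.null(thr) || thr <= 0) return(pk)
  out <- pk[pk$snr >= thr, , drop = FALSE]
  if (nrow(out) < 5) pk else out
}
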