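#' Build extracted ion chromatograms by ion density clustering
#'
#' Ions emitted by a metabolite keep almost identical m/z from scan to scan,
#' so within a small m/z tolerance the ion density along the m/z axis is far
#' higher than for scattered background signals. All centroids of the run
#' are pooled, sorted by m/z and split wherever the gap between neighbours
#' exceeds `mz_tol`; clusters with fewer than `min_points` members are
#' discarded as background. Each surviving cluster becomes one ion trace
#' (EIC), padded with zero intensity over its contiguous scan window so
#' every trace is defined on a gap-free retention-time grid.
#'
#' @param run a [new_run()] object.
#' @param mz_tol m/z gap (Da) above which neighbouring centroids are split
#'   into different traces. Default 0.01 Da.
#' @param min_points minimum number of member centroids for a trace to be
#'   kept (default 10, floor 5).
#' @return list of `ion_trace` objects, each with fields `mz_center`
#'   (intensity-weighted mean m/z), `scan_idx`, `rt`, `intensity` (zero-padded),
#'   `mz_at_scan` (member m/z per covered scan, NA where padded) and
#'   `members` (data.frame scan/mz/intensity).
#' @export
build_eics <- function(run, mz_tol = 0.01, min_points = 10L) {
  min_points <- max(5L, as.integer(min_points))
  rts <- run_rts(run)
  nscan <- length(rts)
  scan_i <- rep(seq_len(nscan),
                vapply(run$scans, function(s) length(s$mz), integer(1)))
  mz <- unlist(lapply(run$scans, `[[`, "mz"), use.names = FALSE)
  int <- unlist(lapply(run$scans, `[[`, "intensity"), use.names = FALSE)
  if (length(mz) == 0) return(list())
  o <- order(mz)
  mz <- mz[o]; int <- int[o]; scan_i <- scan_i[o]
  cl <- cumsum(c(1L, as.integer(diff(mz) > mz_tol)))
  keep <- which(tabulate(cl) >= min_points)
  traces <- lapply(keep, function(k) {
    sel <- which(cl == k)
    make_trace(scan_i[sel], mz[sel], int[sel], rts)
  })
  traces[order(vapply(traces, `[[`, numeric(1), "mz_center"))]
}

make_trace <- function(scan, mz, intensity, rts) {
  rng <- range(scan)
  idx <- rng[1]:rng[2]
  y <- numeric(length(idx))
  mzs <- rep(NA_real_, length(idx))
  pos <- scan - rng[1] + 1L
  # multiple member centroids in one scan: intensities sum, m/z of the
  # most intense member represents the scan (ascending-intensity order so
  # the strongest member writes last)
  o <- order(intensity)
  for (j in o) mzs[pos[j]] <- mz[j]
  for (j in seq_along(scan)) y[pos[j]] <- y[pos[j]] + intensity[j]
  structure(list(
    mz_center = sum(mz * intensity) / max(sum(intensity), .Machine$double.eps),
    scan_idx = idx, rt = rts[idx], intensity = y, mz_at_scan = mzs,
    members = data.frame(scan = scan, mz = mz, intensity = intensity)),
    class = "ion_trace")
}

#' Local-minimum baseline drift correction
#'
#' Estimates the baseline of an ion trace from local minima: the trace is
#' tiled into retention-time windows of `window_min` minutes, the minimum
#' point of each window is taken as a baseline anchor at its actual
#' retention time, and anchors are connected by linear interpolation
#' (constant extension past the outermost anchors). The interpolated
#' baseline is subtracted and negative residuals are clipped to zero. The
#' procedure is applied `iterations` times; a flat trace maps to all-zero.
#'
#' @param trace an `ion_trace`.
#' @param window_min anchor window width in minutes (default 2).
#' @param iterations number of estimate-subtract passes (default 2).
#' @return the trace with corrected `intensity` (original kept as
#'   `raw_intensity`).
#' @export
correct_baseline <- function(trace, window_min = 2, iterations = 2L) {
  y <- trace$intensity
  rt <- trace$rt
  if (length(y) < 3) {
    trace$raw_intensity <- trace$intensity
    trace$intensity <- pmax(y - min(y), 0)
    return(trace)
  }
  raw <- y
  for (it in seq_len(iterations)) {
    brk <- seq(rt[1], rt[length(rt)] + window_min, by = window_min)
    win <- findInterval(rt, brk)
    a_rt <- tapply(seq_along(y), win, function(ii) rt[ii[which.min(y[ii])]])
    a_y <- tapply(y, win, min)
    base <- if (length(a_y) == 1) rep(a_y, length(y))
            else stats::approx(as.numeric(a_rt), as.numeric(a_y), xout = rt,
                               rule = 2)$y
    y <- pmax(y - base, 0)
  }
  trace$raw_intensity <- raw
  trace$intensity <- y
  trace
}

#' Detect chromatographic peaks by scale-space ridge lines
#'
#' The baseline-corrected trace is smoothed with Gaussian kernels of
#' successively increasing scale; local maxima are linked across scales into
#' ridge lines (a maximum at the next scale within +/-(sigma + 2) scan steps
#' extends the ridge). A ridge persisting over at least `min_ridge_length`
#' scales whose apex signal-to-noise ratio reaches `min_snr` is reported as
#' one peak. The apex is the ridge's local maximum at the smallest scale;
#' elution boundaries are the nearest flanking local minima of the trace
#' smoothed at the smallest scale. Height is the baseline-corrected
#' intensity at the apex and area the sum of baseline-corrected responses
#' over the elution window. Noise is estimated robustly as the
#' median-absolute-deviation of the first differences of the corrected
#' trace outside candidate peak windows (scaled to a standard deviation);
#' the signal entering the ratio is the apex of the trace smoothed at the
#' scale a ridge must persist to, so random excursions that die under
#' smoothing cannot reach the threshold however sharp their raw apex.
#'
#' @param trace a baseline-corrected `ion_trace`.
#' @param sigmas increasing smoothing scales in scan steps (default 1:10).
#' @param min_ridge_length minimum number of scales a ridge must persist
#'   (default 3).
#' @param min_snr minimum apex signal-to-noise ratio (default 3).
#' @param sample_id sample identifier stamped on each peak.
#' @param trace_ref identifier of the parent trace.
#' @return data.frame of peaks (possibly 0 rows): `sample_id`, `trace_ref`,
#'   `apex_mz`, `apex_rt`, `left_rt`, `right_rt`, `height`, `area`,
#'   `ridge_length`, `snr` and a `shape` list-column holding the
#'   baseline-corrected intensities on the peak's rt support.
#' @export
detect_peaks <- function(trace, sigmas = 1:10, min_ridge_length = 3L,
                         min_snr = 3, sample_id = "sample",
                         trace_ref = NA_integer_) {
  y <- trace$intensity
  n <- length(y)
  empty <- empty_peak_table()
  if (n < 5 || all(y <= 0)) return(empty)
  sigmas <- sort(sigmas)
  sm <- lapply(sigmas, function(s) gaussian_smooth(y, s))
  maxima <- lapply(sm, local_maxima)
  if (length(maxima[[1]]) == 0) return(empty)

  # ridge linking, bottom-up from the smallest scale
  ridges <- lapply(maxima[[1]], function(i) list(apex = i, pos = i, len = 1L))
  for (si in seq_along(sigmas)[-1]) {
    cand <- maxima[[si]]
    used <- logical(length(cand))
    for (ri in seq_along(ridges)) {
      r <- ridges[[ri]]
      if (r$len < si - 1L) next  # ridge already terminated
      if (length(cand) == 0) next
      d <- abs(cand - r$pos)
      ok <- which(!used & d <= sigmas[si] + 2)
      if (length(ok) == 0) next
      j <- ok[which.min(d[ok])]
      used[j] <- TRUE
      r$pos <- cand[j]
      r$len <- r$len + 1L
      ridges[[ri]] <- r
    }
  }
  # tie-break ridges claiming the same apex scan: longer ridge, then higher
  # apex (before any length filtering, so the noise estimate and the
  # surviving ridge set do not depend on min_ridge_length)
  apexes <- vapply(ridges, `[[`, integer(1), "apex")
  lens <- vapply(ridges, `[[`, integer(1), "len")
  ord <- order(apexes, -lens, -y[apexes])
  ridges <- ridges[ord][!duplicated(apexes[ord])]

  light <- sm[[1]]
  mins <- local_minima(light)
  bounds <- lapply(ridges, function(r) {
    a <- r$apex
    l <- mins[mins < a]
    l <- if (length(l)) max(l) else 1L
    rgt <- mins[mins > a]
    rgt <- if (length(rgt)) min(rgt) else n
    c(l, a, rgt)
  })
  keep <- vapply(bounds, function(b) b[1] < b[2] && b[2] < b[3], logical(1))
  ridges <- ridges[keep]; bounds <- bounds[keep]
  if (length(ridges) == 0) return(empty)

  # noise from first differences outside candidate peak windows
  inpeak <- logical(n)
  for (b in bounds) inpeak[b[1]:b[3]] <- TRUE
  quiet <- y[!inpeak]
  noise <- if (length(quiet) >= 4) stats::mad(diff(quiet)) / sqrt(2) else 0
  if (!is.finite(noise) || noise <= 0) {
    # short traces fully occupied by a peak: high-frequency residual
    # against the lightly smoothed trace (0.68 is the residual sd factor
    # of white noise under a sigma = 1 step Gaussian kernel)
    noise <- stats::mad(y - sm[[1]]) / 0.68
  }
  if (!is.finite(noise) || noise <= 0) noise <- .Machine$double.eps

  # apex signal relative to the smoothed trace's median: a residual DC
  # offset (imperfect baseline removal) must not count as signal
  y_snr <- sm[[min(min_ridge_length, length(sigmas))]]
  sig <- pmax(y_snr - stats::median(y_snr), 0)
  accept <- vapply(seq_along(bounds), function(i) {
    b <- bounds[[i]]
    y[b[2]] > 0 && sig[b[2]] / noise >= min_snr &&
      (b[3] - b[1] + 1L) >= 3L &&
      ridges[[i]]$len >= min_ridge_length
  }, logical(1))
  ridges <- ridges[accept]; bounds <- bounds[accept]
  if (length(ridges) == 0) return(empty)
  out <- do.call(rbind, lapply(seq_along(ridges), function(i) {
    b <- bounds[[i]]
    a <- b[2]
    apex_mz <- trace$mz_at_scan[a]
    if (is.na(apex_mz)) apex_mz <- trace$mz_center
    data.frame(sample_id = sample_id, trace_ref = trace_ref,
               apex_mz = apex_mz, apex_rt = trace$rt[a],
               left_rt = trace$rt[b[1]], right_rt = trace$rt[b[3]],
               height = y[a], area = sum(y[b[1]:b[3]]),
               ridge_length = ridges[[i]]$len, snr = sig[a] / noise)
  }))
  out$shape <- lapply(bounds, function(b) {
    seg <- b[1]:b[3]
    list(rt = trace$rt[seg], intensity = y[seg])
  })
  out <- out[order(out$apex_rt), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_peak_table <- function() {
  df <- data.frame(sample_id = character(0), trace_ref = integer(0),
                   apex_mz = numeric(0), apex_rt = numeric(0),
                   left_rt = numeric(0), right_rt = numeric(0),
                   height = numeric(0), area = numeric(0),
                   ridge_length = integer(0), snr = numeric(0))
  df$shape <- list()
  df
}

#' Extract the per-sample EIC peak list
#'
#' Composition of [build_eics()], [correct_baseline()] and [detect_peaks()]
#' over every trace of a run: the per-sample EIC peak list table, sorted by
#' apex retention time, with peak ids assigned in (apex_rt, apex_mz) order.
#'
#' @param run a [new_run()] object.
#' @param params parameter list, see [plantmet_config()]; relevant keys:
#'   `mz_tol`, `min_points`, `baseline_window_min`, `sigmas`,
#'   `min_ridge_length`, `min_snr`.
#' @return peak data.frame as in [detect_peaks()], plus `peak_id`.
#' @export
extract_sample_peaks <- function(run, params = plantmet_config()) {
  traces <- build_eics(run, mz_tol = params$mz_tol,
                       min_points = params$min_points)
  tabs <- lapply(seq_along(traces), function(i) {
    tr <- correct_baseline(traces[[i]],
                           window_min = params$baseline_window_min)
    detect_peaks(tr, sigmas = params$sigmas,
                 min_ridge_length = params$min_ridge_length,
                 min_snr = params$min_snr,
                 sample_id = run$sample_id, trace_ref = i)
  })
  out <- do.call(rbind, c(tabs, list(empty_peak_table())))
  out <- out[order(out$apex_rt, out$apex_mz), , drop = FALSE]
  if (nrow(out))
    out$peak_id <- paste0(run$sample_id, "_p", seq_len(nrow(out)))
  else out$peak_id <- character(0)
  rownames(out) <- NULL
  out
}
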