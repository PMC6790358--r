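#' Candidate peaks for registration
#'
#' Candidates of a peak are all peaks from other entries of the pool that
#' satisfy both the m/z tolerance and the (time-shift-corrected)
#' retention-time tolerance, presented in ascending order of absolute
#' retention-time difference; ties break by ascending m/z difference.
#'
#' @param mz,rt query coordinates (Da, minutes).
#' @param pool_mz,pool_rt coordinates of the candidate pool.
#' @param mz_tol m/z tolerance in Da (default 0.01).
#' @param rt_tol retention-time tolerance in minutes (default 0.1).
#' @return integer indices into the pool, best candidate first.
#' @export
candidate_peaks <- function(mz, rt, pool_mz, pool_rt,
                            mz_tol = 0.01, rt_tol = 0.1) {
  dmz <- abs(pool_mz - mz)
  drt <- abs(pool_rt - rt)
  ok <- which(dmz <= mz_tol & drt <= rt_tol)
  ok[order(drt[ok], dmz[ok])]
}

#' Register EIC peaks across samples (nearest-neighbour-connecting)
#'
#' Groups time-aligned EIC peaks from all samples into registered
#' components. Each peak (or, after merges, each group represented by its
#' member means) looks up its first candidate under the m/z and rt
#' tolerances; a pair in which each is the other's first candidate is
#' merged, unless the merge would place two peaks from the same sample in
#' one group (such a pair is skipped). Scanning repeats until no pair
#' merges. Every unmerged peak ends as a singleton component. Component
#' ids are assigned in (mean rt, mean m/z) order. The result is
#' independent of the input row order.
#'
#' @param all_peaks data.frame of peaks from all samples (needs
#'   `sample_id`, `peak_id`, `apex_mz`, `apex_rt`, `height`, `area`).
#' @param samples character vector fixing the sample column order;
#'   defaults to the sorted unique sample ids.
#' @param mz_tol,rt_tol registration tolerances (default 0.01 Da, 0.1 min).
#' @return a `component_table`: list with `components` (data.frame
#'   `component_id`, `mean_mz`, `mean_rt`, `n_members`), `samples`,
#'   `heights` and `areas` (component x sample matrices, `NA` where a
#'   sample has no member peak) and `membership` (data.frame
#'   `component_id`, `sample_id`, `peak_id`).
#' @export
nnc_register <- function(all_peaks, samples = NULL, mz_tol = 0.01,
                         rt_tol = 0.1) {
  if (is.null(samples)) samples <- sort(unique(all_peaks$sample_id))
  # canonical ordering makes the scan independent of input row order
  p <- all_peaks[order(all_peaks$apex_rt, all_peaks$apex_mz,
                       all_peaks$sample_id), , drop = FALSE]
  n <- nrow(p)
  groups <- lapply(seq_len(n), function(i)
    list(members = i, samples = p$sample_id[i],
         mz = p$apex_mz[i], rt = p$apex_rt[i]))
  if (n > 1) {
    for (iter in seq_len(n)) {
      g_mz <- vapply(groups, `[[`, numeric(1), "mz")
      g_rt <- vapply(groups, `[[`, numeric(1), "rt")
      ng <- length(groups)
      first <- integer(ng)
      for (i in seq_len(ng)) {
        cand <- candidate_peaks(g_mz[i], g_rt[i], g_mz, g_rt, mz_tol, rt_tol)
        cand <- cand[cand != i]
        first[i] <- if (length(cand)) cand[1] else 0L
      }
      pair_a <- which(first > 0 & first[pmax(first, 1L)] == seq_len(ng) &
                        seq_len(ng) < first)
      merged <- FALSE
      drop <- logical(ng)
      for (a in pair_a) {
        b <- first[a]
        if (drop[a] || drop[b]) next
        if (length(intersect(groups[[a]]$samples, groups[[b]]$samples)) > 0)
          next  # a group cannot hold two peaks from one sample
        mem <- c(groups[[a]]$members, groups[[b]]$members)
        groups[[a]] <- list(members = mem,
                            samples = p$sample_id[mem],
                            mz = mean(p$apex_mz[mem]),
                            rt = mean(p$apex_rt[mem]))
        drop[b] <- TRUE
        merged <- TRUE
      }
      groups <- groups[!drop]
      if (!merged) break
    }
  }
  g_rt <- vapply(groups, `[[`, numeric(1), "rt")
  g_mz <- vapply(groups, `[[`, numeric(1), "mz")
  groups <- groups[order(g_rt, g_mz)]
  k <- length(groups)
  heights <- matrix(NA_real_, k, length(samples),
                    dimnames = list(NULL, samples))
  areas <- heights
  membership <- vector("list", k)
  for (ci in seq_len(k)) {
    mem <- groups[[ci]]$members
    heights[ci, p$sample_id[mem]] <- p$height[mem]
    areas[ci, p$sample_id[mem]] <- p$area[mem]
    membership[[ci]] <- data.frame(component_id = ci,
                                   sample_id = p$sample_id[mem],
                                   peak_id = p$peak_id[mem])
  }
  structure(list(
    components = data.frame(
      component_id = seq_len(k),
      mean_mz = vapply(groups, `[[`, numeric(1), "mz"),
      mean_rt = vapply(groups, `[[`, numeric(1), "rt"),
      n_members = vapply(groups, function(g) length(g$members), integer(1))),
    samples = samples, heights = heights, areas = areas,
    membership = do.call(rbind, membership)),
    class = "component_table")
}

#' @export
print.component_table <- function(x, ...) {
  cat(sprintf("<component_table> %d components x %d samples (%d peaks)\n",
              nrow(x$components), length(x$samples), nrow(x$membership)))
  invisible(x)
}
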