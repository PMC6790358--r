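# Shared in-code fixtures and independent oracles.

# A run with Gaussian ions: `ions` is a data.frame mz / rt / sigma / height.
# Optional noise centroids are single random points, one per scan.
make_gaussian_run <- function(ions, rt_max = 6, dt = 0.01, sample_id = "S1",
                              group = "G1", noise_n = 0, noise_mz = c(100, 600),
                              floor = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  st <- seq(0, rt_max, by = dt)
  scans <- lapply(st, function(t) {
    mz <- numeric(0); int <- numeric(0)
    for (k in seq_len(nrow(ions))) {
      y <- ions$height[k] * exp(-(t - ions$rt[k])^2 / (2 * ions$sigma[k]^2))
      if (y >= floor) { mz <- c(mz, ions$mz[k]); int <- c(int, y) }
    }
    if (noise_n > 0) {
      nm <- runif(noise_n, noise_mz[1], noise_mz[2])
      mz <- c(mz, nm); int <- c(int, runif(noise_n, 50, 200))
    }
    o <- order(mz)
    list(rt = t, mz = mz[o], intensity = int[o])
  })
  new_run(sample_id, group, scans)
}

# One-row peak data.frame with a Gaussian shape vector.
make_peak <- function(peak_id, mz, rt, sigma = 0.03, height = 1e5,
                      sample_id = "S1", dt = 0.01, halfspan = 4) {
  g <- seq(rt - halfspan * sigma, rt + halfspan * sigma, by = dt)
  df <- data.frame(sample_id = sample_id, trace_ref = 1L, apex_mz = mz,
                   apex_rt = rt, left_rt = g[1], right_rt = g[length(g)],
                   height = height, area = height * sigma * sqrt(2 * pi) / dt,
                   ridge_length = 5L, snr = 100, peak_id = peak_id)
  df$shape <- list(list(rt = g,
                        intensity = height * exp(-(g - rt)^2 / (2 * sigma^2))))
  df
}

make_peak_table <- function(...) {
  do.call(rbind, list(...))
}

# Component table built directly from a heights matrix (components x samples).
make_component_table <- function(heights, rts = NULL, mzs = NULL,
                                 areas = NULL) {
  k <- nrow(heights)
  samples <- colnames(heights)
  if (is.null(rts)) rts <- seq_len(k) * 0.5
  if (is.null(mzs)) mzs <- 200 + seq_len(k)
  mem <- do.call(rbind, lapply(seq_len(k), function(ci) {
    ok <- !is.na(heights[ci, ])
    data.frame(component_id = ci, sample_id = samples[ok],
               peak_id = paste0("c", ci, "_", samples[ok]))
  }))
  structure(list(
    components = data.frame(component_id = seq_len(k), mean_mz = mzs,
                            mean_rt = rts,
                            n_members = rowSums(!is.na(heights))),
    samples = samples, heights = heights,
    areas = if (is.null(areas)) heights * 2 else areas,
    membership = mem), class = "component_table")
}

# --- independent oracles -------------------------------------------------

# naive O(n^2) single-linkage grouping of centroids: join any two within
# mz_tol by label propagation, then apply the size filter
oracle_gap_cluster <- function(mz, min_points, mz_tol = 0.01) {
  n <- length(mz)
  lab <- seq_len(n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (abs(mz[i] - mz[j]) <= mz_tol && lab[i] != lab[j]) {
        l <- min(lab[i], lab[j])
        lab[lab == lab[i] | lab == lab[j]] <- l
      }
    }
  }
  sizes <- table(lab)
  keep <- as.integer(names(sizes)[sizes >= min_points])
  out <- lapply(keep, function(l) sort(mz[lab == l]))
  out[order(vapply(out, min, numeric(1)))]
}

# exhaustive maximum over all monotone matchings of an m x n matrix
# (enumerates row and column subsets; within a subset pair the monotone
# assignment is unique)
oracle_dp_enum <- function(S) {
  m <- nrow(S); n <- ncol(S)
  best <- 0
  for (k in seq_len(min(m, n))) {
    rows <- utils::combn(m, k)
    cols <- utils::combn(n, k)
    for (a in seq_len(ncol(rows))) {
      for (b in seq_len(ncol(cols))) {
        v <- S[cbind(rows[, a], cols[, b])]
        if (anyNA(v)) next
        s <- sum(v)
        if (s > best) best <- s
      }
    }
  }
  best
}

# brute-force mutual-first-candidate grouping (reference NNC): each
# scanning round finds every mutual-first pair over the current group
# means and merges the sample-disjoint ones, until a round changes nothing
oracle_nnc <- function(peaks, mz_tol, rt_tol) {
  ord <- order(peaks$apex_rt, peaks$apex_mz, peaks$sample_id)
  g <- lapply(ord, function(i)
    list(idx = i, s = peaks$sample_id[i], mz = peaks$apex_mz[i],
         rt = peaks$apex_rt[i]))
  repeat {
    ng <- length(g)
    first <- rep(0L, ng)
    for (i in seq_len(ng)) {
      dmz <- abs(vapply(g, `[[`, numeric(1), "mz") - g[[i]]$mz)
      drt <- abs(vapply(g, `[[`, numeric(1), "rt") - g[[i]]$rt)
      ok <- setdiff(which(dmz <= mz_tol & drt <= rt_tol), i)
      if (length(ok))
        first[i] <- ok[order(drt[ok], dmz[ok], ok)][1]
    }
    merged_any <- FALSE
    gone <- logical(ng)
    for (i in seq_len(ng)) {
      j <- first[i]
      if (j > i && first[j] == i && !gone[i] && !gone[j] &&
          !any(g[[i]]$s %in% g[[j]]$s)) {
        idx <- c(g[[i]]$idx, g[[j]]$idx)
        g[[i]] <- list(idx = idx, s = peaks$sample_id[idx],
                       mz = mean(peaks$apex_mz[idx]),
                       rt = mean(peaks$apex_rt[idx]))
        gone[j] <- TRUE
        merged_any <- TRUE
      }
    }
    g <- g[!gone]
    if (!merged_any) break
  }
  # canonical form: sorted member index sets
  sets <- lapply(g, function(x) sort(x$idx))
  sets[order(vapply(sets, min, integer(1)))]
}

# textbook one-way fixed-effects ANOVA
oracle_anova <- function(v, g) {
  g <- factor(g)
  gm <- tapply(v, g, mean)
  ni <- tapply(v, g, length)
  ssb <- sum(ni * (gm - mean(v))^2)
  ssw <- sum((v - gm[g])^2)
  df1 <- nlevels(g) - 1
  df2 <- length(v) - nlevels(g)
  f <- (ssb / df1) / (ssw / df2)
  c(f = f, p = stats::pf(f, df1, df2, lower.tail = FALSE))
}

# canonical form of a component table partition for oracle comparison
partition_sets <- function(tab, peaks) {
  sets <- split(tab$membership$peak_id, tab$membership$component_id)
  sets <- lapply(sets, function(s) sort(match(s, peaks$peak_id)))
  unname(sets[order(vapply(sets, min, integer(1)))])
}
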