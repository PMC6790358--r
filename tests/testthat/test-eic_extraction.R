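test_that("density clustering isolates a real ion from scattered noise", {
  set.seed(71)
  st <- seq(0, 1, by = 0.01)
  scans <- lapply(seq_along(st), function(i) {
    mz <- numeric(0); int <- numeric(0)
    if (i <= 30) {   # 30 consecutive scans of one ion
      mz <- 301.1410 + runif(1, -0.002, 0.002)
      int <- 1e4
    }
    nm <- runif(1, 100, 600)   # one scattered noise centroid per scan
    mz <- c(mz, nm); int <- c(int, 100)
    o <- order(mz)
    list(rt = st[i], mz = mz[o], intensity = int[o])
  })
  run <- new_run("S1", "G1", scans)
  traces <- build_eics(run, mz_tol = 0.01, min_points = 5)
  expect_length(traces, 1)
  expect_lt(abs(traces[[1]]$mz_center - 301.1410), 0.002)
  # matches the naive single-linkage oracle
  mz_all <- unlist(lapply(scans, `[[`, "mz"))
  orc <- oracle_gap_cluster(mz_all, min_points = 5, mz_tol = 0.01)
  expect_length(orc, 1)
  expect_equal(sort(traces[[1]]$members$mz), orc[[1]])
})

test_that("species separated by more than twice the tolerance split", {
  st <- seq(0, 0.3, by = 0.01)
  scans <- lapply(st, function(t) list(
    rt = t, mz = c(301.1410, 301.1650), intensity = c(1e4, 8e3)))
  run <- new_run("S1", "G1", scans)
  traces <- build_eics(run, mz_tol = 0.01, min_points = 5)
  expect_length(traces, 2)
  expect_equal(sort(vapply(traces, `[[`, numeric(1), "mz_center")),
               c(301.1410, 301.1650), tolerance = 1e-6)
  orc <- oracle_gap_cluster(unlist(lapply(scans, `[[`, "mz")), 5, 0.01)
  expect_length(orc, 2)
})

test_that("the size filter discards sparse clusters", {
  scans <- list(list(rt = 0, mz = 300, intensity = 1e3),
                list(rt = 0.01, mz = 400, intensity = 1e3))
  run <- new_run("S1", "G1", scans)
  expect_length(build_eics(run, min_points = 5), 0)
})

test_that("baseline correction removes flat and ramp baselines", {
  st <- seq(0, 6, by = 0.01)
  mk <- function(y) structure(list(mz_center = 300, scan_idx = seq_along(st),
                                   rt = st, intensity = y,
                                   mz_at_scan = rep(300, length(st)),
                                   members = NULL), class = "ion_trace")
  # constant trace -> all zero
  flat <- correct_baseline(mk(rep(500, length(st))))
  expect_true(all(flat$intensity == 0))
  # Gaussian on a linear ramp: amplitude recovered within 5%
  amp <- 1e5
  ramp <- 200 + 300 * st
  gs <- amp * exp(-(st - 3)^2 / (2 * 0.05^2))
  corr <- correct_baseline(mk(gs + ramp))
  expect_lt(abs(max(corr$intensity) - amp) / amp, 0.05)
  # already clean Gaussian: apex unchanged within 1%
  clean <- correct_baseline(mk(gs))
  expect_lt(abs(max(clean$intensity) - amp) / amp, 0.01)
})

test_that("ridge detection finds noiseless peaks at the right place", {
  st <- seq(0, 2, by = 0.01)
  y <- 1e5 * exp(-(st - 1)^2 / (2 * 0.05^2))
  tr <- structure(list(mz_center = 300, scan_idx = seq_along(st), rt = st,
                       intensity = y, mz_at_scan = rep(300, length(st)),
                       members = NULL), class = "ion_trace")
  pk <- detect_peaks(tr, sample_id = "S1")
  expect_equal(nrow(pk), 1)
  expect_lte(abs(pk$apex_rt - 1), 0.01)          # within one scan step
  expect_lt(abs(pk$height - 1e5) / 1e5, 0.02)
  # two Gaussians 4 sigma apart resolve into two peaks (oracle: the
  # analytic sum has exactly two local maxima)
  y2 <- 1e5 * (exp(-(st - 0.9)^2 / (2 * 0.05^2)) +
                 exp(-(st - 1.1)^2 / (2 * 0.05^2)))
  n_true <- length(local_max_count <- which(diff(sign(diff(y2))) == -2))
  expect_equal(n_true, 2)
  tr2 <- tr; tr2$intensity <- y2
  expect_equal(nrow(detect_peaks(tr2, sample_id = "S1")), 2)
})

test_that("quantification identity holds exactly", {
  st <- seq(0, 2, by = 0.01)
  set.seed(5)
  y <- 1e5 * exp(-(st - 1)^2 / (2 * 0.05^2)) * exp(rnorm(length(st), 0, 0.05))
  tr <- structure(list(mz_center = 300, scan_idx = seq_along(st), rt = st,
                       intensity = y, mz_at_scan = rep(300, length(st)),
                       members = NULL), class = "ion_trace")
  pk <- detect_peaks(tr, sample_id = "S1")
  for (i in seq_len(nrow(pk))) {
    sh <- pk$shape[[i]]
    expect_identical(pk$area[i], sum(sh$intensity))
    expect_identical(pk$height[i], sh$intensity[which(sh$rt == pk$apex_rt[i])])
    expect_gte(pk$area[i], pk$height[i])
    expect_gte(length(sh$rt), 3)
    expect_true(pk$left_rt[i] < pk$apex_rt[i] &&
                  pk$apex_rt[i] < pk$right_rt[i])
  }
})

test_that("requiring longer ridges never yields more peaks", {
  set.seed(9)
  st <- seq(0, 3, by = 0.01)
  y <- 5e4 * exp(-(st - 1)^2 / (2 * 0.04^2)) +
    2e4 * exp(-(st - 2)^2 / (2 * 0.03^2)) +
    pmax(rnorm(length(st), 100, 30), 0)
  tr <- structure(list(mz_center = 300, scan_idx = seq_along(st), rt = st,
                       intensity = y, mz_at_scan = rep(300, length(st)),
                       members = NULL), class = "ion_trace")
  tr <- correct_baseline(tr)
  n_prev <- Inf
  for (L in c(1, 3, 5, 8)) {
    n <- nrow(detect_peaks(tr, min_ridge_length = L, sample_id = "S1"))
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("white-noise traces rarely produce peaks", {
  set.seed(123)
  fp <- replicate(40, {
    st <- seq(0, 3, by = 0.01)
    y <- pmax(rnorm(length(st), 100, 30), 0)
    tr <- structure(list(mz_center = 300, scan_idx = seq_along(st), rt = st,
                         intensity = y, mz_at_scan = rep(300, length(st)),
                         members = NULL), class = "ion_trace")
    nrow(detect_peaks(correct_baseline(tr), min_snr = 3, sample_id = "S1"))
  })
  expect_gte(mean(fp == 0), 0.95)
})

test_that("constant column bleed yields no peaks and empty runs propagate", {
  st <- seq(0, 2, by = 0.01)
  scans <- lapply(st, function(t) list(rt = t, mz = 371.1,
                                       intensity = 3000))
  run <- new_run("S1", "G1", scans)
  expect_equal(nrow(extract_sample_peaks(run)), 0)
  empty <- new_run("S2", "G1", lapply(c(0, 0.01), function(t)
    list(rt = t, mz = numeric(0), intensity = numeric(0))))
  expect_equal(nrow(extract_sample_peaks(empty)), 0)
})

test_that("a synthetic run's ions are recovered at the right coordinates", {
  set.seed(31)
  ions <- data.frame(mz = sort(runif(10, 150, 600)),
                     rt = seq(0.5, 5.0, length.out = 10),
                     sigma = runif(10, 0.03, 0.05),
                     height = runif(10, 5e4, 5e5))
  run <- make_gaussian_run(ions, rt_max = 5.5, noise_n = 1, seed = 32)
  pk <- extract_sample_peaks(run)
  found <- vapply(seq_len(nrow(ions)), function(k)
    any(abs(pk$apex_mz - ions$mz[k]) <= 0.01 &
          abs(pk$apex_rt - ions$rt[k]) <= 0.05), logical(1))
  expect_gte(sum(found), 9)
})
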