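test_that("the reference is the sample with the most peaks", {
  tabs <- list(A = make_peak("a1", 300, 1),
               B = rbind(make_peak("b1", 300, 1), make_peak("b2", 310, 2)),
               C = make_peak("c1", 300, 1))
  expect_equal(select_reference(tabs), "B")
  tabs2 <- list(B = make_peak("b1", 300, 1), A = make_peak("a1", 300, 1))
  expect_equal(select_reference(tabs2), "A")   # tie -> lexicographic
  expect_error(select_reference(tabs["A"]), "at least 2")
})

test_that("peak similarity honours tolerances and matches direct Pearson", {
  p <- make_peak("p", 301.141, 2.0, sigma = 0.04)
  expect_equal(peak_similarity(p, p), 1.0)
  q <- make_peak("q", 301.191, 2.0, sigma = 0.04)   # +0.05 Da
  expect_true(is.na(peak_similarity(p, q)))
  r <- make_peak("r", 301.141, 2.6, sigma = 0.04)   # +0.6 min
  expect_true(is.na(peak_similarity(p, r)))
  # asymmetric shape: tailed peak vs its time-reverse, brute-force value
  g <- seq(1.8, 2.2, by = 0.01)
  asym <- exp(-(g - 2)^2 / (2 * ifelse(g < 2, 0.09, 0.03)^2))
  s <- make_peak("s", 301.141, 2.0)
  s$shape <- list(list(rt = g, intensity = asym))
  t <- make_peak("t", 301.141, 2.0)
  t$shape <- list(list(rt = g, intensity = rev(asym)))
  got <- peak_similarity(s, t)
  half <- max(2 - g[1], g[length(g)] - 2)
  grid <- seq(2 - 2 * half, 2 + 2 * half, length.out = 50)
  a <- approx(g, asym, grid, yleft = 0, yright = 0)$y
  b <- approx(g, rev(asym), grid, yleft = 0, yright = 0)$y
  expect_equal(got, cor(a, b), tolerance = 1e-12)
  expect_true(got < 1 && got > -1)
})

test_that("constant shapes get similarity zero, not NA", {
  g <- seq(1.9, 2.1, by = 0.01)
  p <- make_peak("p", 300, 2)
  p$shape <- list(list(rt = g, intensity = rep(5, length(g))))
  q <- make_peak("q", 300, 2)
  expect_equal(peak_similarity(p, q), 0)
})

test_that("the DP alignment is optimal and monotone", {
  # forced diagonal
  S <- matrix(NA_real_, 5, 5)
  diag(S) <- 0.9
  path <- align_dp(S)
  expect_equal(nrow(path), 5)
  expect_equal(attr(path, "score"), 4.5)
  expect_equal(path$ref_idx, 1:5)
  # two tests competing for one reference: only one match possible
  S2 <- matrix(NA_real_, 1, 2)
  S2[1, ] <- 0.95
  expect_equal(nrow(align_dp(S2)), 1)
  # all invalid -> empty
  expect_equal(nrow(align_dp(matrix(NA_real_, 3, 3))), 0)
  # random matrices vs exhaustive enumeration
  set.seed(20)
  for (rep in 1:10) {
    m <- sample(3:6, 1); n <- sample(3:6, 1)
    S3 <- matrix(runif(m * n, -0.5, 1), m, n)
    S3[runif(m * n) < 0.3] <- NA
    expect_equal(attr(align_dp(S3), "score"), oracle_dp_enum(S3),
                 tolerance = 1e-9)
  }
  # a strictly increasing path in both indices
  S4 <- matrix(runif(36, 0.5, 1), 6, 6)
  p4 <- align_dp(S4)
  expect_true(all(diff(p4$ref_idx) > 0) && all(diff(p4$test_idx) > 0))
})

test_that("similar-shape peaks stay in elution order through the DP", {
  # two identical-shape peaks 0.3 min apart in both runs: matched in
  # order, never crossed
  ref <- rbind(make_peak("r1", 301.141, 2.0), make_peak("r2", 301.141, 2.3))
  tst <- rbind(make_peak("t1", 301.141, 2.05), make_peak("t2", 301.141, 2.35))
  S <- similarity_matrix(ref, tst)
  path <- align_dp(S)
  expect_equal(path$ref_idx, c(1, 2))
  expect_equal(path$test_idx, c(1, 2))
})

test_that("warp fitting interpolates, extrapolates flatly and stays monotone", {
  expect_equal(warp_rt(fit_warp(NULL), c(1, 2, 3)), c(1, 2, 3))
  w <- fit_warp(data.frame(test_rt = c(1, 2), ref_rt = c(1.1, 2.1)))
  expect_equal(warp_rt(w, 1.5), 1.6)
  expect_equal(warp_rt(w, 0.5), 0.6)    # edge shift held constant
  expect_equal(warp_rt(w, 3.0), 3.1)
  # inverted anchor with lower similarity is dropped
  w2 <- fit_warp(data.frame(test_rt = c(1, 1.1, 2), ref_rt = c(1, 0.4, 2),
                            similarity = c(0.9, 0.6, 0.9)))
  rtq <- seq(0.5, 2.5, by = 0.05)
  expect_true(all(diff(warp_rt(w2, rtq)) > 0))
  # property: random monotone anchors always give a monotone warp
  set.seed(8)
  for (rep in 1:20) {
    n <- sample(3:12, 1)
    anc <- data.frame(test_rt = sort(runif(n, 0, 10)),
                      ref_rt = sort(runif(n, 0, 10)),
                      similarity = runif(n, 0.5, 1))
    wr <- fit_warp(anc)
    q <- seq(-1, 11, by = 0.1)
    expect_true(all(diff(warp_rt(wr, q)) > 0))
  }
})

test_that("a smooth injected warp is recovered from peak anchors", {
  set.seed(40)
  n <- 35
  mzs <- sort(runif(n, 150, 600))
  rts <- sort(runif(n, 0.5, 9.5))
  ref <- do.call(rbind, lapply(seq_len(n), function(i)
    make_peak(paste0("r", i), mzs[i], rts[i], sigma = 0.04,
              sample_id = "REF")))
  warp_true <- function(t) t + 0.2 * sin(t)
  tst <- do.call(rbind, lapply(seq_len(n), function(i)
    make_peak(paste0("t", i), mzs[i], warp_true(rts[i]), sigma = 0.04,
              sample_id = "TST")))
  al <- align_samples(list(REF = ref, TST = tst), reference_id = "REF")
  expect_gte(nrow(al$anchors$TST), 30)
  corrected <- al$peaks$TST$apex_rt
  expect_lt(max(abs(sort(corrected) - rts)), 0.02)
})

test_that("align_samples fixes a constant shift and leaves the reference alone", {
  set.seed(41)
  n <- 25
  ref <- do.call(rbind, lapply(seq_len(n), function(i)
    make_peak(paste0("r", i), 150 + i * 10, 0.4 + i * 0.35, sigma = 0.04,
              sample_id = "REF")))
  tst <- ref
  tst$sample_id <- "TST"
  tst$peak_id <- paste0("t", seq_len(n))
  tst$apex_rt <- tst$apex_rt + 0.3
  tst$left_rt <- tst$left_rt + 0.3
  tst$right_rt <- tst$right_rt + 0.3
  tst$shape <- lapply(tst$shape, function(s)
    list(rt = s$rt + 0.3, intensity = s$intensity))
  al <- align_samples(list(REF = ref, TST = tst), reference_id = "REF")
  expect_identical(al$peaks$REF$apex_rt, ref$apex_rt)
  expect_lt(median(abs(sort(al$peaks$TST$apex_rt) - ref$apex_rt)), 0.02)
})

test_that("a sample sharing nothing with the reference keeps its times", {
  ref <- rbind(make_peak("r1", 200, 1), make_peak("r2", 300, 2))
  tst <- rbind(make_peak("t1", 450, 5, sample_id = "T"),
               make_peak("t2", 500, 6, sample_id = "T"))
  expect_warning(al <- align_samples(list(REF = ref, T = tst),
                                     reference_id = "REF"),
                 "no alignable peaks")
  expect_equal(sort(al$peaks$T$apex_rt), sort(tst$apex_rt))
})
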