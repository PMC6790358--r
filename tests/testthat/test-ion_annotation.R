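# Two-ion isotope pattern helper: [M+H]+ and its 13C partner.
iso_pair <- function(mz = 611.1607, rt = 2.29, ratio = 0.30,
                     rt_shift = 0, sigma = 0.04, h = 1e5) {
  rbind(make_peak("mh", mz, rt, sigma, h),
        make_peak("m1", mz + 1.00336, rt + rt_shift, sigma, h * ratio))
}

test_that("isotope seeding finds the pair and enforces its gates", {
  pr <- seed_isotope_pairs(iso_pair())
  expect_equal(nrow(pr), 1)
  expect_equal(pr$mh_id, "mh")
  expect_equal(pr$m1_id, "m1")
  expect_gt(pr$similarity, 0.99)
  # isotopologue displaced by 0.05 min: outside the 0.02-min tolerance
  expect_equal(nrow(seed_isotope_pairs(iso_pair(rt_shift = 0.05))), 0)
  # reversed intensities: the putative M+1 must be weaker
  expect_equal(nrow(seed_isotope_pairs(iso_pair(ratio = 1.4))), 0)
  # wrong spacing
  off <- iso_pair(); off$apex_mz[2] <- off$apex_mz[2] + 0.02
  expect_equal(nrow(seed_isotope_pairs(off)), 0)
})

test_that("the adaptive cut-off follows its formula", {
  expect_equal(adaptive_cutoff(0.999), 0.9)    # min(0.9, 0.979) = 0.9
  expect_equal(adaptive_cutoff(0.93), 0.9)     # capped at the initial 0.9
  expect_equal(adaptive_cutoff(0.87), 0.85)    # 0.87 - 0.02, above floor
  expect_equal(adaptive_cutoff(0.80), 0.8)     # floor engaged
  expect_equal(adaptive_cutoff(c(0.999, 0.87, 0.80)), c(0.9, 0.85, 0.8))
})

test_that("adducts and higher isotopologues are annotated within gates", {
  pk <- rbind(iso_pair(),
              make_peak("na", 611.1607 + 21.98194, 2.29, 0.04, 3e4),
              make_peak("m2", 611.1607 + 2.00671, 2.29, 0.04, 8e3),
              make_peak("far", 611.1607 + 21.98194, 2.50, 0.04, 3e4))
  pairs <- seed_isotope_pairs(pk)
  ann <- extend_annotations(pairs, pk)
  expect_setequal(ann$peak_id[ann$role == "Na_adduct"], "na")
  expect_setequal(ann$peak_id[ann$role == "M2H"], "m2")
  expect_false("far" %in% ann$peak_id)   # rt gate
  # a dissimilar shape at the adduct mass stays unannotated
  g <- seq(2.0, 2.6, by = 0.01)
  odd <- make_peak("odd", 611.1607 + 21.98194, 2.29, 0.04, 3e4)
  odd$shape <- list(list(rt = g, intensity = runif(length(g), 0, 100)))
  pk2 <- rbind(iso_pair(), odd)
  ann2 <- extend_annotations(seed_isotope_pairs(pk2), pk2)
  expect_false("odd" %in% ann2$peak_id)
})

test_that("a contested satellite goes to the more similar parent", {
  mh_a <- iso_pair(mz = 400.2000, rt = 2.29, sigma = 0.040)
  mh_b <- iso_pair(mz = 400.2120, rt = 2.29, sigma = 0.055)
  mh_b$peak_id <- c("mh2", "m12")
  # one sodium-adduct peak reachable from both parents
  sat <- make_peak("na", 400.2000 + 21.98194, 2.29, 0.040, 1e4)
  sat2 <- sat; sat2$apex_mz <- 400.2120 + 21.98194 - 0.012  # same point
  pk <- rbind(mh_a, mh_b, sat)
  pairs <- seed_isotope_pairs(pk)
  expect_equal(nrow(pairs), 2)
  ann <- extend_annotations(pairs, pk)
  na_row <- ann[ann$peak_id == "na", ]
  expect_equal(nrow(na_row), 1)
  expect_equal(na_row$mh_id, "mh")   # shape matches the sigma 0.040 parent
})

test_that("clustering keeps rt-separated and shape-distinct ions apart", {
  # single MH ion, no satellites -> singleton cluster
  one <- iso_pair()
  res <- annotate_sample(one)
  expect_equal(nrow(res$clusters), 1)
  # two metabolites 0.5 min apart never merge, same shapes
  a <- iso_pair(mz = 400.2, rt = 2.0)
  b <- iso_pair(mz = 500.3, rt = 2.5)
  b$peak_id <- c("mh2", "m12")
  res2 <- annotate_sample(rbind(a, b))
  expect_equal(nrow(res2$clusters), 2)
  # co-eluting but shape-distinct (width ratio 2): separate clusters
  cc <- iso_pair(mz = 400.2, rt = 2.29, sigma = 0.02)
  dd <- iso_pair(mz = 500.3, rt = 2.29, sigma = 0.06)
  dd$peak_id <- c("mh2", "m12")
  res3 <- annotate_sample(rbind(cc, dd))
  expect_equal(nrow(res3$clusters), 2)
  mem <- res3$members
  expect_equal(length(unique(mem$cluster_id[mem$peak_id %in% c("mh", "m1")])), 1)
  expect_false(unique(mem$cluster_id[mem$peak_id == "mh"]) ==
                 unique(mem$cluster_id[mem$peak_id == "mh2"]))
})

test_that("coeluting fragments join their metabolite's cluster", {
  pk <- rbind(iso_pair(mz = 611.1607, rt = 2.29, h = 2e5),
              make_peak("f1", 465.1028, 2.29, 0.04, 8e4),
              make_peak("f2", 303.0499, 2.29, 0.04, 5e4))
  res <- annotate_sample(pk)
  expect_equal(nrow(res$clusters), 1)
  expect_setequal(res$members$peak_id, c("mh", "m1", "f1", "f2"))
  expect_setequal(res$members$role[res$members$peak_id %in% c("f1", "f2")],
                  "fragment")
})

test_that("reconciliation requires both shape and height evidence", {
  H <- matrix(rlnorm(18, 11, 0.6), nrow = 3,
              dimnames = list(NULL, sprintf("S%d", 1:6)))
  H[2, ] <- H[1, ] * 0.4 * exp(rnorm(6, 0, 0.02))   # correlated with 1
  tab <- make_component_table(H, rts = c(2.29, 2.295, 2.30))
  metas <- list(assignments = data.frame(component_id = c(1L, 2L),
                                         meta_id = c(1L, 1L)))
  # clusters: components 1+2 co-cluster in every sample; 3 never does
  mk_members <- function(cids, cluster)
    data.frame(cluster_id = cluster,
               peak_id = paste0("c", cids, "_", "X"), role = "MH")
  sample_ann <- lapply(sprintf("S%d", 1:6), function(s) {
    m <- rbind(
      data.frame(cluster_id = 1L, peak_id = paste0("c", 1:2, "_", s),
                 role = c("MH", "fragment")),
      data.frame(cluster_id = 2L, peak_id = paste0("c", 3, "_", s),
                 role = "MH"))
    list(members = m)
  })
  names(sample_ann) <- sprintf("S%d", 1:6)
  rec <- reconcile_with_screening(sample_ann, metas, tab)
  expect_equal(sort(rec$assignments$component_id), c(1L, 2L))
  expect_equal(length(unique(rec$assignments$metabolite_id)), 1)
  # co-clustered but different Meta ID -> partial evidence only
  metas2 <- list(assignments = data.frame(component_id = c(1L, 2L),
                                          meta_id = c(1L, 2L)))
  rec2 <- reconcile_with_screening(sample_ann, metas2, tab)
  expect_equal(nrow(rec2$assignments), 0)
  expect_true(any(rec2$partial$evidence == "shape_only"))
  # same Meta ID but never co-clustered -> partial evidence only
  metas3 <- list(assignments = data.frame(component_id = c(1L, 3L),
                                          meta_id = c(1L, 1L)))
  rec3 <- reconcile_with_screening(sample_ann, metas3, tab)
  expect_equal(nrow(rec3$assignments), 0)
  expect_true(any(rec3$partial$evidence == "height_only"))
})

test_that("derived spectra come from the tallest-MH sample, sorted by m/z", {
  samples <- sprintf("S%d", 1:3)
  H <- matrix(c(9e4, 12e4, 7e4,
                2.7e4, 3.6e4, 2.1e4,
                4e4, 5e4, 3e4), nrow = 3, byrow = TRUE,
              dimnames = list(NULL, samples))
  tab <- make_component_table(H, rts = c(2.29, 2.291, 2.292),
                              mzs = c(611.1607, 612.1641, 303.0499))
  asg <- data.frame(component_id = 1:3, metabolite_id = 1L,
                    role = c("MH", "M1H", "fragment"))
  all_pk <- do.call(rbind, lapply(seq_len(3), function(ci)
    do.call(rbind, lapply(samples, function(s) {
      p <- make_peak(paste0("c", ci, "_", s), tab$components$mean_mz[ci],
                     2.29, 0.04, H[ci, s], sample_id = s)
      p
    }))))
  sp <- derive_spectrum(1L, asg, tab, all_pk)
  expect_equal(sp$source_sample, "S2")   # tallest MH
  expect_equal(sp$entries$mz, sort(sp$entries$mz))
  expect_equal(nrow(sp$entries), 3)
  expect_equal(sp$entries$role[sp$entries$mz == 611.1607], "MH")
  # single-ion metabolite
  asg1 <- data.frame(component_id = 1L, metabolite_id = 1L, role = "MH")
  expect_equal(nrow(derive_spectrum(1L, asg1, tab, all_pk)$entries), 1)
  # near-duplicate m/z entries stay distinct
  tab2 <- tab
  tab2$components$mean_mz[2] <- 611.1612
  all_pk2 <- all_pk
  all_pk2$apex_mz[all_pk2$peak_id %in% paste0("c2_", samples)] <- 611.1612
  sp2 <- derive_spectrum(1L, asg, tab2, all_pk2)
  expect_equal(nrow(sp2$entries), 3)
  expect_error(derive_spectrum(9L, asg, tab, all_pk), "unknown")
})
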