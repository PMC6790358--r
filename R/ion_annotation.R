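#' Default positive-mode adduct table
#'
#' Mass shifts relative to the protonated molecular ion \[M+H\]+, from
#' standard monoisotopic atomic masses: replacing the proton by Na+ or K+,
#' or adding NH3 (ammonium adduct).
#'
#' @return data.frame with `role` and `delta` (Da).
#' @export
default_adduct_table <- function() {
  data.frame(role = c("NH4_adduct", "Na_adduct", "K_adduct"),
             delta = c(17.02655, 21.98194, 37.95588))
}

C13_C12_DELTA <- 1.00336

# Shape similarity on a common absolute retention-time grid spanning the
# union of both peaks' supports, zero outside each support. Unlike the
# apex-relative resampling used for cross-sample alignment, the absolute
# grid preserves width and asymmetry differences between co-eluting peaks,
# which is exactly what within-sample deconvolution relies on.
shape_similarity_absolute <- function(sp, sq, npoints = 80L) {
  lo <- min(sp$rt[1], sq$rt[1])
  hi <- max(sp$rt[length(sp$rt)], sq$rt[length(sq$rt)])
  if (hi <= lo) return(0)
  grid <- seq(lo, hi, length.out = npoints)
  a <- stats::approx(sp$rt, sp$intensity, xout = grid, yleft = 0, yright = 0)$y
  b <- stats::approx(sq$rt, sq$intensity, xout = grid, yleft = 0, yright = 0)$y
  pearson_safe(a, b)
}

#' Seed isotope pairs within one sample
#'
#' Finds (\[M+H\]+, \[M+1+H\]+) pairs: two peaks whose m/z difference
#' matches the 13C-12C spacing within `iso_mz_tol`, whose apexes co-elute
#' within `rt_tol`, whose elution profiles correlate at least
#' `shape_cutoff0`, and whose intensities are ordered (the isotopologue is
#' weaker than the monoisotopic ion). When several candidates qualify the
#' highest-similarity pairing wins, and a peak serves in at most one pair.
#'
#' @param peaks one sample's peak data.frame with `shape` list-column.
#' @param shape_cutoff0 initial shape-similarity cut-off (default 0.9).
#' @param rt_tol apex retention-time tolerance in minutes (default 0.02).
#' @param iso_mz_delta isotopologue spacing in Da (default 1.00336).
#' @param iso_mz_tol m/z matching tolerance in Da (default 0.005).
#' @return data.frame with `mh_id`, `m1_id`, `similarity`, `cutoff` (the
#'   per-ion adaptive threshold from [adaptive_cutoff()]).
#' @export
seed_isotope_pairs <- function(peaks, shape_cutoff0 = 0.9, rt_tol = 0.02,
                               iso_mz_delta = C13_C12_DELTA,
                               iso_mz_tol = 0.005) {
  n <- nrow(peaks)
  cand <- list()
  if (n > 1) {
    for (i in seq_len(n)) {
      dmz <- peaks$apex_mz - peaks$apex_mz[i]
      drt <- abs(peaks$apex_rt - peaks$apex_rt[i])
      js <- which(abs(dmz - iso_mz_delta) <= iso_mz_tol & drt <= rt_tol &
                    peaks$height < peaks$height[i])
      for (j in js) {
        sim <- shape_similarity_absolute(peaks$shape[[i]], peaks$shape[[j]])
        if (sim >= shape_cutoff0)
          cand[[length(cand) + 1]] <- data.frame(
            mh_id = peaks$peak_id[i], m1_id = peaks$peak_id[j],
            similarity = sim)
      }
    }
  }
  if (length(cand) == 0)
    return(data.frame(mh_id = character(0), m1_id = character(0),
                      similarity = numeric(0), cutoff = numeric(0)))
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand$similarity), , drop = FALSE]
  cand <- cand[!duplicated(cand$mh_id) & !duplicated(cand$m1_id), , drop = FALSE]
  # an ion cannot be both monoisotopic parent and isotopologue
  cand <- cand[!(cand$mh_id %in% cand$m1_id), , drop = FALSE]
  cand$cutoff <- adaptive_cutoff(cand$similarity,
                                 shape_cutoff0 = shape_cutoff0)
  rownames(cand) <- NULL
  cand
}

#' Adaptive per-ion shape-similarity cut-off
#'
#' The admission threshold for further ions of an \[M+H\]+ ion's cluster is
#' derived from the observed similarity of its own isotope pair - a clean
#' peak keeps the initial cut-off, a noisier one relaxes proportionally:
#' `max(cutoff_floor, min(shape_cutoff0, similarity - margin))`.
#'
#' @param similarity observed MH-M1H shape similarity (vectorised).
#' @param shape_cutoff0 initial cut-off (default 0.9).
#' @param margin tolerance below the observed similarity (default 0.02).
#' @param cutoff_floor hard lower bound (default 0.8).
#' @return per-ion threshold(s).
#' @export
adaptive_cutoff <- function(similarity, shape_cutoff0 = 0.9, margin = 0.02,
                            cutoff_floor = 0.8) {
  pmax(cutoff_floor, pmin(shape_cutoff0, similarity - margin))
}

#' Recognize further isotopologues and adduct ions
#'
#' For each seeded \[M+H\]+ ion, peaks at the \[M+2+H\]+ and \[M+3+H\]+
#' spacings and at the configured adduct mass shifts are annotated with the
#' matching role when they fall within the m/z tolerance, co-elute within
#' `rt_tol` and pass the ion's adaptive shape threshold. A satellite peak
#' claimed by two parents goes to the higher-similarity one.
#'
#' @param pairs seeded pairs from [seed_isotope_pairs()].
#' @param peaks the sample's peak data.frame.
#' @param adduct_table data.frame `role`/`delta`
#'   (default [default_adduct_table()]).
#' @param rt_tol apex tolerance in minutes (default 0.02).
#' @param iso_mz_tol m/z tolerance in Da (default 0.005).
#' @return annotation data.frame: `peak_id`, `role`, `mh_id`, `similarity`,
#'   containing the MH and M1H rows plus all recognized satellites.
#' @export
extend_annotations <- function(pairs, peaks,
                               adduct_table = default_adduct_table(),
                               rt_tol = 0.02, iso_mz_tol = 0.005) {
  base <- rbind(
    data.frame(peak_id = pairs$mh_id, role = "MH", mh_id = pairs$mh_id,
               similarity = 1),
    data.frame(peak_id = pairs$m1_id, role = "M1H", mh_id = pairs$mh_id,
               similarity = pairs$similarity))
  deltas <- rbind(
    data.frame(role = c("M2H", "M3H"), delta = c(2.00671, 3.01007)),
    adduct_table)
  taken <- base$peak_id
  sat <- list()
  for (k in seq_len(nrow(pairs))) {
    i <- match(pairs$mh_id[k], peaks$peak_id)
    for (d in seq_len(nrow(deltas))) {
      js <- which(abs(peaks$apex_mz - peaks$apex_mz[i] - deltas$delta[d]) <=
                    iso_mz_tol &
                  abs(peaks$apex_rt - peaks$apex_rt[i]) <= rt_tol &
                  !(peaks$peak_id %in% taken))
      for (j in js) {
        sim <- shape_similarity_absolute(peaks$shape[[i]], peaks$shape[[j]])
        if (sim >= pairs$cutoff[k])
          sat[[length(sat) + 1]] <- data.frame(
            peak_id = peaks$peak_id[j], role = deltas$role[d],
            mh_id = pairs$mh_id[k], similarity = sim)
      }
    }
  }
  if (length(sat)) {
    sat <- do.call(rbind, sat)
    sat <- sat[order(-sat$similarity), , drop = FALSE]
    sat <- sat[!duplicated(sat$peak_id), , drop = FALSE]
    base <- rbind(base, sat)
  }
  rownames(base) <- NULL
  base
}

#' Cluster \[M+H\]+ ions within a sample
#'
#' Bottom-up (agglomerative, average-linkage) clustering of seeded
#' \[M+H\]+ ions under hard gates: two clusters may merge only if every
#' cross pair of their MH ions co-elutes within `rt_tol` and correlates at
#' least as strongly as both ions' adaptive thresholds demand; among
#' allowed merges the highest average cross-similarity is performed first,
#' until no merge is allowed. Each MH ion drags its annotated satellites
#' into its cluster. Remaining unannotated peaks are admitted to a cluster
#' as in-source fragments when they co-elute with the cluster consensus
#' and their profile passes the adaptive threshold of every MH member;
#' ties go to the cluster with the highest mean similarity.
#'
#' @param annotations output of [extend_annotations()].
#' @param pairs seeded pairs (for the per-ion thresholds).
#' @param peaks the sample's peak data.frame.
#' @param rt_tol retention-time gate in minutes (default 0.02).
#' @return list with `clusters` (data.frame `cluster_id`, `apex_rt`,
#'   `governing_cutoff`, `n_members`) and `members` (data.frame
#'   `cluster_id`, `peak_id`, `role`).
#' @export
cluster_mh_ions <- function(annotations, pairs, peaks, rt_tol = 0.02) {
  mh <- pairs$mh_id
  k <- length(mh)
  if (k == 0)
    return(list(clusters = data.frame(cluster_id = integer(0),
                                      apex_rt = numeric(0),
                                      governing_cutoff = numeric(0),
                                      n_members = integer(0)),
                members = data.frame(cluster_id = integer(0),
                                     peak_id = character(0),
                                     role = character(0))))
  mi <- match(mh, peaks$peak_id)
  rt <- peaks$apex_rt[mi]
  cut <- pairs$cutoff
  sim <- diag(1, k)
  if (k > 1) {
    for (i in seq_len(k - 1)) for (j in (i + 1):k)
      sim[i, j] <- sim[j, i] <-
        if (abs(rt[i] - rt[j]) <= rt_tol)
          shape_similarity_absolute(peaks$shape[[mi[i]]], peaks$shape[[mi[j]]])
        else -1
  }
  cl <- as.list(seq_len(k))
  repeat {
    nb <- length(cl)
    if (nb < 2) break
    best <- NULL; best_avg <- -Inf
    for (a in seq_len(nb - 1)) {
      for (b in (a + 1):nb) {
        ia <- cl[[a]]; ib <- cl[[b]]
        cross <- sim[ia, ib, drop = FALSE]
        need <- outer(cut[ia], cut[ib], pmax)
        rt_ok <- all(abs(outer(rt[ia], rt[ib], `-`)) <= rt_tol)
        if (rt_ok && all(cross >= need) && mean(cross) > best_avg) {
          best_avg <- mean(cross); best <- c(a, b)
        }
      }
    }
    if (is.null(best)) break
    cl[[best[1]]] <- c(cl[[best[1]]], cl[[best[2]]])
    cl <- cl[-best[2]]
  }
  # assemble members: MH ions + their satellites
  members <- list()
  crt <- numeric(length(cl)); gcut <- numeric(length(cl))
  for (ci in seq_along(cl)) {
    ions <- mh[cl[[ci]]]
    ann <- annotations[annotations$mh_id %in% ions, , drop = FALSE]
    members[[ci]] <- data.frame(cluster_id = ci, peak_id = ann$peak_id,
                                role = ann$role)
    crt[ci] <- mean(rt[cl[[ci]]])
    gcut[ci] <- min(cut[cl[[ci]]])
  }
  members <- do.call(rbind, members)
  # orphan peaks: candidate in-source fragments
  orphans <- setdiff(peaks$peak_id, members$peak_id)
  frag <- list()
  for (pid in orphans) {
    p <- match(pid, peaks$peak_id)
    best_ci <- 0L; best_mean <- -Inf
    for (ci in seq_along(cl)) {
      if (abs(peaks$apex_rt[p] - crt[ci]) > rt_tol) next
      ions_i <- cl[[ci]]
      sims <- vapply(ions_i, function(ii)
        shape_similarity_absolute(peaks$shape[[mi[ii]]], peaks$shape[[p]]),
        numeric(1))
      if (all(sims >= cut[ions_i]) && mean(sims) > best_mean) {
        best_mean <- mean(sims); best_ci <- ci
      }
    }
    if (best_ci > 0)
      frag[[length(frag) + 1]] <- data.frame(cluster_id = best_ci,
                                             peak_id = pid,
                                             role = "fragment")
  }
  if (length(frag)) members <- rbind(members, do.call(rbind, frag))
  # number clusters by consensus rt
  ord <- order(crt)
  remap <- integer(length(cl)); remap[ord] <- seq_along(cl)
  members$cluster_id <- remap[members$cluster_id]
  members <- members[order(members$cluster_id, members$peak_id), , drop = FALSE]
  rownames(members) <- NULL
  list(clusters = data.frame(cluster_id = seq_along(cl),
                             apex_rt = crt[ord],
                             governing_cutoff = gcut[ord],
                             n_members = as.integer(table(
                               factor(members$cluster_id,
                                      levels = seq_along(cl))))),
       members = members)
}

#' Annotate one sample by ion clustering
#'
#' Convenience composition of [seed_isotope_pairs()],
#' [extend_annotations()] and [cluster_mh_ions()] for one sample's
#' (aligned) peak table.
#'
#' @param peaks one sample's peak data.frame.
#' @param params parameter list ([plantmet_config()]).
#' @return list with `pairs`, `annotations`, `clusters`, `members`.
#' @export
annotate_sample <- function(peaks, params = plantmet_config()) {
  pairs <- seed_isotope_pairs(peaks,
                              shape_cutoff0 = params$shape_cutoff0,
                              rt_tol = params$anno_rt_tol,
                              iso_mz_tol = params$iso_mz_tol)
  pairs$cutoff <- adaptive_cutoff(pairs$similarity,
                                  shape_cutoff0 = params$shape_cutoff0,
                                  margin = params$margin,
                                  cutoff_floor = params$cutoff_floor)
  ann <- extend_annotations(pairs, peaks,
                            adduct_table = params$adduct_table,
                            rt_tol = params$anno_rt_tol,
                            iso_mz_tol = params$iso_mz_tol)
  cl <- cluster_mh_ions(ann, pairs, peaks, rt_tol = params$anno_rt_tol)
  c(list(pairs = pairs, annotations = ann), cl)
}

#' Reconcile within-sample ion clusters with cross-sample Meta IDs
#'
#' Two registered components are ultimately attributed to one metabolite
#' only if their ions co-cluster within a sample in at least `min_votes`
#' samples (peak-shape evidence) AND they share a Meta ID (peak-height
#' evidence across samples). Component pairs with only one kind of
#' evidence are reported as partial evidence. Confirmed groups receive
#' final metabolite ids in retention-time order; each component's role is
#' the majority role over its per-sample annotations.
#'
#' @param sample_annotations named list (by sample id) of
#'   [annotate_sample()] results.
#' @param metas Meta ID assignments from [assign_meta_ids()].
#' @param table the `component_table`.
#' @param min_votes minimum number of samples in which a component pair
#'   must co-cluster; default `ceiling(n_samples / 2)`.
#' @return list with `assignments` (data.frame `component_id`,
#'   `metabolite_id`, `role`), `partial` (data.frame `component_a`,
#'   `component_b`, `evidence`) and `votes` (co-clustering counts).
#' @export
reconcile_with_screening <- function(sample_annotations, metas, table,
                                     min_votes = NULL) {
  if (is.null(min_votes)) min_votes <- ceiling(length(table$samples) / 2)
  peak2comp <- stats::setNames(table$membership$component_id,
                               table$membership$peak_id)
  votes <- list()
  roles <- list()
  for (sid in names(sample_annotations)) {
    mem <- sample_annotations[[sid]]$members
    if (is.null(mem) || nrow(mem) == 0) next
    mem$component <- peak2comp[mem$peak_id]
    mem <- mem[!is.na(mem$component), , drop = FALSE]
    roles[[sid]] <- mem[, c("component", "role")]
    for (ci in unique(mem$cluster_id)) {
      comps <- sort(unique(mem$component[mem$cluster_id == ci]))
      if (length(comps) < 2) next
      prs <- utils::combn(comps, 2)
      for (q in seq_len(ncol(prs))) {
        key <- paste(prs[1, q], prs[2, q], sep = "-")
        votes[[key]] <- (votes[[key]] %||% 0L) + 1L
      }
    }
  }
  vote_df <- if (length(votes)) {
    ab <- do.call(rbind, strsplit(names(votes), "-", fixed = TRUE))
    data.frame(component_a = as.integer(ab[, 1]),
               component_b = as.integer(ab[, 2]),
               n_samples = unlist(votes, use.names = FALSE))
  } else data.frame(component_a = integer(0), component_b = integer(0),
                    n_samples = integer(0))
  meta_of <- stats::setNames(metas$assignments$meta_id,
                             metas$assignments$component_id)
  vote_df$shape_evidence <- vote_df$n_samples >= min_votes
  ma <- meta_of[as.character(vote_df$component_a)]
  mb <- meta_of[as.character(vote_df$component_b)]
  vote_df$height_evidence <- !is.na(ma) & !is.na(mb) & ma == mb
  # height evidence also exists for meta pairs never co-clustered
  meta_pairs <- list()
  for (m in unique(metas$assignments$meta_id)) {
    comps <- metas$assignments$component_id[metas$assignments$meta_id == m]
    if (length(comps) < 2) next
    prs <- utils::combn(sort(comps), 2)
    meta_pairs[[length(meta_pairs) + 1]] <-
      data.frame(component_a = prs[1, ], component_b = prs[2, ])
  }
  if (length(meta_pairs)) {
    mp <- do.call(rbind, meta_pairs)
    key_v <- paste(vote_df$component_a, vote_df$component_b)
    key_m <- paste(mp$component_a, mp$component_b)
    extra <- mp[!(key_m %in% key_v), , drop = FALSE]
    if (nrow(extra)) {
      extra$n_samples <- 0L
      extra$shape_evidence <- FALSE
      extra$height_evidence <- TRUE
      vote_df <- rbind(vote_df, extra)
    }
  }
  confirmed <- vote_df[vote_df$shape_evidence & vote_df$height_evidence, ,
                       drop = FALSE]
  partial <- vote_df[xor(vote_df$shape_evidence, vote_df$height_evidence), ,
                     drop = FALSE]
  partial$evidence <- ifelse(partial$shape_evidence,
                             "shape_only", "height_only")
  # connected components of the confirmed graph
  verts <- sort(unique(c(confirmed$component_a, confirmed$component_b)))
  assignments <- data.frame(component_id = integer(0),
                            metabolite_id = integer(0),
                            role = character(0))
  if (length(verts)) {
    g <- igraph::graph_from_data_frame(
      data.frame(a = as.character(confirmed$component_a),
                 b = as.character(confirmed$component_b)),
      directed = FALSE, vertices = data.frame(name = as.character(verts)))
    memb <- igraph::components(g)$membership
    grp <- memb[as.character(verts)]
    rt <- table$components$mean_rt[match(verts,
                                         table$components$component_id)]
    grp_rt <- tapply(rt, grp, mean)
    met_rank <- rank(grp_rt, ties.method = "first")
    role_df <- do.call(rbind, roles)
    maj_role <- function(cid) {
      rr <- role_df$role[role_df$component == cid]
      if (length(rr) == 0) return("unknown")
      names(sort(table(rr), decreasing = TRUE))[1]
    }
    assignments <- data.frame(
      component_id = verts,
      metabolite_id = as.integer(met_rank[as.character(grp)]),
      role = vapply(verts, maj_role, character(1)))
    assignments <- assignments[order(assignments$metabolite_id,
                                     assignments$component_id), , drop = FALSE]
    rownames(assignments) <- NULL
  }
  list(assignments = assignments,
       partial = partial[, c("component_a", "component_b", "evidence")],
       votes = vote_df)
}

#' Derive the mass spectrum of a confirmed metabolite
#'
#' The spectrum is assembled in the single sample where the metabolite's
#' \[M+H\]+ component is tallest: one entry (m/z, height, role) per member
#' component detected in that sample, in ascending m/z. Entries with
#' near-identical m/z are kept distinct.
#'
#' @param metabolite_id confirmed metabolite id.
#' @param assignments assignment table from [reconcile_with_screening()].
#' @param table the `component_table`.
#' @param all_peaks data.frame of all samples' aligned peaks (rbind of the
#'   per-sample tables).
#' @return list of class `derived_spectrum`: `metabolite_id`,
#'   `source_sample`, `rt`, `entries` (data.frame `mz`, `intensity`,
#'   `role`).
#' @export
derive_spectrum <- function(metabolite_id, assignments, table, all_peaks) {
  comps <- assignments[assignments$metabolite_id == metabolite_id, ,
                       drop = FALSE]
  if (nrow(comps) == 0) stop("unknown metabolite id ", metabolite_id)
  idx <- match(comps$component_id, table$components$component_id)
  mh_row <- which(comps$role == "MH")[1]
  if (is.na(mh_row)) mh_row <- 1L
  h <- table$heights[idx[mh_row], ]
  if (all(is.na(h)))
    stop("metabolite ", metabolite_id, " has no detected peak in any sample")
  src <- names(h)[which.max(h)]
  mem <- table$membership
  entries <- list()
  for (r in seq_len(nrow(comps))) {
    pid <- mem$peak_id[mem$component_id == comps$component_id[r] &
                         mem$sample_id == src]
    if (length(pid) == 0) next
    p <- all_peaks[match(pid, all_peaks$peak_id), , drop = FALSE]
    entries[[length(entries) + 1]] <-
      data.frame(mz = p$apex_mz, intensity = p$height, role = comps$role[r])
  }
  entries <- do.call(rbind, entries)
  entries <- entries[order(entries$mz), , drop = FALSE]
  rownames(entries) <- NULL
  rt <- mean(table$components$mean_rt[idx])
  structure(list(metabolite_id = metabolite_id, source_sample = src,
                 rt = rt, entries = entries),
            class = "derived_spectrum")
}

#' @export
print.derived_spectrum <- function(x, ...) {
  cat(sprintf("<derived_spectrum> metabolite %d (rt %.3f min, sample '%s')\n",
              x$metabolite_id, x$rt, x$source_sample))
  print(x$entries)
  invisible(x)
}
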