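#' One-way ANOVA screen of registered components
#'
#' Tests each registered component for between-group differences in mean
#' response (peak height by default) with a fixed-effects one-way ANOVA.
#' Missing cells (peak not detected in a sample) are dropped, giving an
#' unbalanced design; a component is testable only if at least two groups
#' each retain two or more observed samples. Degenerate variance cases are
#' resolved explicitly: zero between-group variance gives F = 0, p = 1;
#' zero within-group variance with a real group difference gives
#' F = Inf, p = 0.
#'
#' @param table a `component_table` from [nnc_register()].
#' @param groups named character vector mapping sample id to group label.
#' @param alpha significance level (default 0.05).
#' @param response `"height"` or `"area"` (default height; the apex
#'   response is less sensitive to boundary errors than the area).
#' @param p_adjust `"none"` (default) or `"BH"` for Benjamini-Hochberg.
#' @return data.frame sorted by ascending p: `component_id`,
#'   `f_statistic`, `p_value` (adjusted when `p_adjust = "BH"`),
#'   `significant`, `n_used`. Untestable components are excluded.
#' @export
anova_screen <- function(table, groups, alpha = 0.05,
                         response = c("height", "area"),
                         p_adjust = c("none", "BH")) {
  response <- match.arg(response)
  p_adjust <- match.arg(p_adjust)
  if (length(unique(groups)) < 2)
    stop("ANOVA screening needs at least 2 experimental groups")
  M <- if (response == "height") table$heights else table$areas
  glab <- groups[colnames(M)]
  res <- lapply(seq_len(nrow(M)), function(ci) {
    v <- M[ci, ]
    ok <- !is.na(v)
    g <- factor(glab[ok])
    if (sum(table(g) >= 2) < 2) return(NULL)
    fp <- oneway_f(v[ok], g)
    data.frame(component_id = table$components$component_id[ci],
               f_statistic = fp[1], p_value = fp[2], n_used = sum(ok))
  })
  res <- do.call(rbind, Filter(Negate(is.null), res))
  if (is.null(res))
    return(data.frame(component_id = integer(0), f_statistic = numeric(0),
                      p_value = numeric(0), significant = logical(0),
                      n_used = integer(0)))
  if (p_adjust == "BH") res$p_value <- stats::p.adjust(res$p_value, "BH")
  res$significant <- res$p_value < alpha
  res <- res[order(res$p_value, res$component_id), , drop = FALSE]
  rownames(res) <- NULL
  res[, c("component_id", "f_statistic", "p_value", "significant", "n_used")]
}

# F statistic and p with explicit degenerate-variance handling; the
# regular path delegates to stats::lm/anova.
oneway_f <- function(v, g) {
  gm <- tapply(v, g, mean)
  ssb <- sum(tapply(v, g, length) * (gm - mean(v))^2)
  ssw <- sum((v - gm[g])^2)
  eps <- .Machine$double.eps * max(sum(v^2), 1)
  if (ssb <= eps) return(c(0, 1))
  if (ssw <= eps) return(c(Inf, 0))
  a <- stats::anova(stats::lm(v ~ g))
  c(a$`F value`[1], a$`Pr(>F)`[1])
}

#' Outlier-robust Pearson correlation of two response vectors
#'
#' Correlation of two components' peak heights across samples, made
#' resistant to outlying samples through the minimum covariance determinant
#' (MCD): the MCD scatter of the bivariate sample locates the outliers
#' (robust distances, scaled by their median against the chi-square
#' reference), grossly outlying points are removed, and the Pearson
#' correlation of the retained points is returned. Below 10 paired
#' observations the MCD is unstable and plain Pearson is used. Pairs with
#' fewer than `min_pairs` complete observations are undefined (`NA`); a
#' zero-variance vector gives 0.
#'
#' @param x,y numeric vectors of equal length; `NA` marks a missing peak.
#' @param mcd_support fraction of the sample the MCD subset must cover
#'   (default 0.75).
#' @param min_pairs minimum complete pairs (default 5).
#' @param mcd_seed integer seed for the MCD subset search, applied locally
#'   so results are reproducible without touching the caller's RNG.
#' @return correlation in \[-1, 1\] or `NA_real_`.
#' @export
robust_pairwise_correlation <- function(x, y, mcd_support = 0.75,
                                        min_pairs = 5L, mcd_seed = 1L) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < min_pairs) return(NA_real_)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  if (n < 10) return(stats::cor(x, y))
  X <- cbind(x, y)
  h <- max(ceiling(mcd_support * n), floor((n + 3) / 2))
  nsamp <- if (choose(n, 3) <= 5000) "best" else "sample"
  cv <- with_local_seed(mcd_seed, {
    mcd <- function(Z) suppressWarnings(
      MASS::cov.rob(Z, method = "mcd", quantile.used = h, nsamp = nsamp))
    tryCatch(mcd(X), error = function(e) {
      # exactly collinear majority: break the degeneracy with an
      # infinitesimal jitter for the subset search only; the reweighted
      # correlation below is still computed on the original points
      mcd(X + stats::rnorm(2 * n) * 1e-4 *
            (apply(X, 2, stats::sd) + 1)[col(X)])
    })
  })
  C0 <- cv$cov + diag(1e-8 * mean(diag(cv$cov)) + .Machine$double.xmin, 2)
  md <- stats::mahalanobis(X, cv$center, C0)
  # the raw MCD scatter is not consistency-scaled; normalise distances by
  # their median before reweighting so clean points are essentially all kept
  md <- md * stats::qchisq(0.5, 2) / max(stats::median(md), .Machine$double.xmin)
  # reject only points that are both beyond the chi-square bound and far
  # outside the core's own spread (the h-th smallest robust distance): a
  # gross outlier sits orders of magnitude out, a legitimate extreme of a
  # clean sample does not
  core_q <- sort(md)[h]
  keep <- md <= max(stats::qchisq(0.9999, 2), 30 * core_q)
  if (sum(keep) < min_pairs) keep <- rep(TRUE, n)
  xk <- x[keep]; yk <- y[keep]
  if (stats::sd(xk) == 0 || stats::sd(yk) == 0) return(0)
  stats::cor(xk, yk)
}

#' Group screened components into putative metabolites (Meta IDs)
#'
#' Ions of a single metabolite follow the metabolite's abundance across
#' samples, so their peak heights are strongly linearly related. Screened
#' (significant) components are connected whenever their robust Pearson
#' correlation reaches `corr_threshold` and their mean retention times
#' co-elute within `coelution_rt_tol`; connected components of this graph
#' share one Meta ID (transitive merging). Meta IDs are numbered by
#' ascending mean retention time of the group.
#'
#' @param screened data.frame from [anova_screen()] (only rows with
#'   `significant == TRUE` are used).
#' @param table the `component_table`.
#' @param corr_threshold correlation threshold (default 0.9).
#' @param coelution_rt_tol maximum difference of component mean retention
#'   times for an edge, minutes (default 0.1); `Inf` disables the gate.
#' @param response `"height"` (default) or `"area"`.
#' @inheritParams robust_pairwise_correlation
#' @return list with `assignments` (data.frame `component_id`, `meta_id`)
#'   and `edges` (data.frame of correlated pairs).
#' @export
assign_meta_ids <- function(screened, table, corr_threshold = 0.9,
                            coelution_rt_tol = 0.1,
                            response = c("height", "area"),
                            mcd_support = 0.75, mcd_seed = 1L) {
  response <- match.arg(response)
  sig <- screened$component_id[screened$significant]
  if (length(sig) == 0)
    return(list(assignments = data.frame(component_id = integer(0),
                                         meta_id = integer(0)),
                edges = data.frame(a = integer(0), b = integer(0),
                                   correlation = numeric(0))))
  M <- if (response == "height") table$heights else table$areas
  idx <- match(sig, table$components$component_id)
  rt <- table$components$mean_rt[idx]
  k <- length(sig)
  edges <- list()
  if (k > 1) {
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        if (abs(rt[i] - rt[j]) > coelution_rt_tol) next
        r <- robust_pairwise_correlation(M[idx[i], ], M[idx[j], ],
                                         mcd_support = mcd_support,
                                         mcd_seed = mcd_seed)
        if (!is.na(r) && r >= corr_threshold)
          edges[[length(edges) + 1]] <-
            data.frame(a = sig[i], b = sig[j], correlation = r)
      }
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges)
           else data.frame(a = integer(0), b = integer(0),
                           correlation = numeric(0))
  g <- igraph::graph_from_data_frame(
    edges[, c("a", "b")], directed = FALSE,
    vertices = data.frame(name = as.character(sig)))
  memb <- igraph::components(g)$membership
  comp_of <- memb[as.character(sig)]
  grp_rt <- tapply(rt, comp_of, mean)
  meta_rank <- rank(grp_rt, ties.method = "first")
  assignments <- data.frame(component_id = sig,
                            meta_id = as.integer(meta_rank[as.character(comp_of)]))
  assignments <- assignments[order(assignments$meta_id,
                                   assignments$component_id), , drop = FALSE]
  rownames(assignments) <- NULL
  list(assignments = assignments, edges = edges)
}
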