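#' Generator configuration for synthetic UPLC-HRMS runs
#'
#' Defaults describe a small two-group benchmark experiment: 2 groups x 3
#' samples, 20 metabolites, each emitting a protonated molecular ion with
#' its 13C isotopologues (binomial carbon model), one alkali/ammonium
#' adduct and up to two in-source fragments sharing the metabolite's
#' elution profile, on a 0.01-min scan grid over a 10-min gradient with
#' 5x as many low-intensity noise ions as true ions, smooth per-sample
#' retention-time warps, m/z jitter and slow baseline drift under a
#' fraction of the true traces. All metabolites carry a 4-fold group
#' effect in a random direction, so every stage through screening and
#' annotation is exercised.
#'
#' @param ... overrides of the default fields (see source for the full
#'   list and units).
#' @return a named list of generator parameters.
#' @export
generator_config <- function(...) {
  cfg <- list(
    n_groups = 2L, samples_per_group = 3L, n_metabolites = 20L,
    effect_fraction = 1.0,    # fraction of metabolites with a group effect
    effect_size = 4,          # fold change, direction randomised
    scan_interval = 0.01,     # minutes
    run_length = 10,          # minutes of acquisition
    rt_range = c(0.8, 9.2),   # metabolite apexes placed in here
    min_rt_separation = 0.15, # minimum apex spacing (0 allows co-elution)
    sigma_range = c(0.02, 0.05),  # chromatographic peak sigma, minutes
    tailing_tau = 0,          # exponential tailing constant, minutes
    mz_range = c(250, 600),   # [M+H]+ m/z
    carbon_range = c(15L, 40L),
    adduct_fraction = 1.0,    # metabolites carrying one adduct ion
    fragment_range = c(0L, 2L),
    fragment_rf = c(0.2, 0.6),
    adduct_rf = c(0.15, 0.4),
    base_height_meanlog = log(3e5), base_height_sdlog = 0.7,
    biological_cv = 0.25,     # per-sample abundance variation (sdlog)
    intensity_cv = 0.1,       # per-ion response noise (sdlog)
    shape_noise = 0.02,       # per-centroid multiplicative noise (sdlog)
    noise_floor_sd = 8,       # additive detector noise per centroid (counts)
    mz_jitter_sd = 0.001,     # Da, per centroid
    noise_ion_factor = 5,     # noise ions per true ion
    noise_height = c(150, 1200),
    baseline_fraction = 0.3,  # true ions sitting on a drifting baseline
    baseline_level = c(20, 60),
    warp_amplitude = 0.05,    # minutes, sinusoidal rt warp scale
    warp_period = 8,          # minutes
    emission_floor = 20       # minimum intensity for a centroid to appear
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown generator fields: ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

validate_generator_config <- function(cfg) {
  if (diff(cfg$rt_range) <= 8 * max(cfg$sigma_range))
    stop("rt_range is shorter than the widest configured peak")
  if (cfg$rt_range[1] < 0 || cfg$rt_range[2] > cfg$run_length)
    stop("rt_range must lie inside the acquisition window")
  if (cfg$scan_interval <= 0 || cfg$n_metabolites < 1)
    stop("invalid generator configuration")
  invisible(cfg)
}

# apex placement with a minimum mutual separation, so the benchmark's
# ground truth stays identifiable; deliberate co-elution is produced by
# the dedicated scenario generator instead
draw_rt_centers <- function(n, rt_range, min_sep) {
  for (attempt in 1:200) {
    rt <- sort(stats::runif(n, rt_range[1], rt_range[2]))
    if (n < 2 || min(diff(rt)) >= min_sep) return(rt)
  }
  # dense case: even spacing with jitter
  rt <- seq(rt_range[1], rt_range[2], length.out = n)
  sort(rt + stats::runif(n, -0.25, 0.25) * min(diff(rt)))
}

# exponentially modified Gaussian elution profile, max-normalised on the
# evaluation grid; computed in log space to avoid overflow deep in the
# leading flank
elution_profile <- function(t, center, sigma, tau) {
  if (tau <= 0) return(exp(-(t - center)^2 / (2 * sigma^2)))
  ly <- sigma^2 / (2 * tau^2) - (t - center) / tau +
    stats::pnorm((t - center) / sigma - sigma / tau, log.p = TRUE)
  m <- max(ly)
  if (!is.finite(m)) return(exp(-(t - center)^2 / (2 * sigma^2)))
  exp(ly - m)
}

#' Generate a ground-truth-annotated synthetic dataset
#'
#' Emits one centroided run per sample plus a `ground_truth` object that
#' fully determines the data: the metabolite and ion catalogue (m/z, role,
#' response factor), per-sample abundances and true ion heights, the
#' per-sample monotone retention-time warps and the noise model. The same
#' seed and configuration always reproduce identical output.
#'
#' @param config a [generator_config()].
#' @param seed integer RNG seed.
#' @return list with `runs` (named list of [new_run()] objects) and
#'   `truth` (class `ground_truth`).
#' @export
generate_dataset <- function(config = generator_config(), seed = 1L) {
  validate_generator_config(config)
  with_local_seed(seed, generate_dataset_impl(config, seed))
}

generate_dataset_impl <- function(cfg, seed) {
  n_samp <- cfg$n_groups * cfg$samples_per_group
  samples <- data.frame(
    sample_id = sprintf("S%02d", seq_len(n_samp)),
    group = rep(sprintf("G%d", seq_len(cfg$n_groups)),
                each = cfg$samples_per_group))

  mets <- data.frame(
    metabolite_id = seq_len(cfg$n_metabolites),
    rt_center = draw_rt_centers(cfg$n_metabolites, cfg$rt_range,
                                cfg$min_rt_separation),
    sigma = stats::runif(cfg$n_metabolites, cfg$sigma_range[1],
                         cfg$sigma_range[2]),
    tau = rep(cfg$tailing_tau, cfg$n_metabolites),
    carbons = sample(cfg$carbon_range[1]:cfg$carbon_range[2],
                     cfg$n_metabolites, replace = TRUE),
    mh_mz = stats::runif(cfg$n_metabolites, cfg$mz_range[1], cfg$mz_range[2]),
    base_height = stats::rlnorm(cfg$n_metabolites, cfg$base_height_meanlog,
                                cfg$base_height_sdlog))
  mets$effect <- stats::runif(cfg$n_metabolites) < cfg$effect_fraction
  mets$effect_mult <- ifelse(mets$effect,
                             ifelse(stats::runif(cfg$n_metabolites) < 0.5,
                                    cfg$effect_size, 1 / cfg$effect_size), 1)

  p13 <- 0.0107   # natural 13C abundance
  ions <- list()
  for (m in seq_len(cfg$n_metabolites)) {
    C <- mets$carbons[m]
    iso_rf <- stats::dbinom(1:3, C, p13) / stats::dbinom(0, C, p13)
    add <- function(mz, role, rf)
      ions[[length(ions) + 1]] <<- data.frame(
        metabolite_id = m, mz = mz, role = role, rf = rf)
    add(mets$mh_mz[m], "MH", 1)
    add(mets$mh_mz[m] + C13_C12_DELTA, "M1H", iso_rf[1])
    if (iso_rf[2] >= 0.02) add(mets$mh_mz[m] + 2.00671, "M2H", iso_rf[2])
    if (stats::runif(1) < cfg$adduct_fraction) {
      at <- default_adduct_table()
      ai <- sample(nrow(at), 1)
      add(mets$mh_mz[m] + at$delta[ai], at$role[ai],
          stats::runif(1, cfg$adduct_rf[1], cfg$adduct_rf[2]))
    }
    nfrag <- sample(cfg$fragment_range[1]:cfg$fragment_range[2], 1)
    for (f in seq_len(nfrag))
      add(max(mets$mh_mz[m] - stats::runif(1, 60, 200), 80), "fragment",
          stats::runif(1, cfg$fragment_rf[1], cfg$fragment_rf[2]))
  }
  ions <- do.call(rbind, ions)
  ions$ion_id <- seq_len(nrow(ions))

  # shared per-sample abundance (bilinear structure) and ion heights
  abund <- matrix(0, cfg$n_metabolites, n_samp,
                  dimnames = list(NULL, samples$sample_id))
  for (m in seq_len(cfg$n_metabolites)) {
    mult <- ifelse(samples$group == "G1", 1, mets$effect_mult[m])
    abund[m, ] <- mets$base_height[m] * mult *
      stats::rlnorm(n_samp, 0, cfg$biological_cv)
  }
  heights <- matrix(0, nrow(ions), n_samp,
                    dimnames = list(NULL, samples$sample_id))
  for (k in seq_len(nrow(ions)))
    heights[k, ] <- abund[ions$metabolite_id[k], ] * ions$rf[k] *
      stats::rlnorm(n_samp, 0, cfg$intensity_cv)

  # smooth monotone per-sample warps: rt' = rt + a sin(2 pi rt / P + phi)
  warps <- lapply(seq_len(n_samp), function(s) {
    a <- cfg$warp_amplitude * stats::runif(1, 0.3, 1) *
      sample(c(-1, 1), 1)
    list(a = a, period = cfg$warp_period * stats::runif(1, 0.8, 1.2),
         phase = stats::runif(1, 0, 2 * pi))
  })
  names(warps) <- samples$sample_id

  baseline_on <- stats::runif(nrow(ions)) < cfg$baseline_fraction
  base_lvl <- stats::runif(nrow(ions), cfg$baseline_level[1],
                           cfg$baseline_level[2])

  n_noise <- round(cfg$noise_ion_factor * nrow(ions))
  scan_t0 <- seq(0, cfg$run_length, by = cfg$scan_interval)

  runs <- list()
  noise_ions <- list()
  true_rt <- matrix(0, cfg$n_metabolites, n_samp,
                    dimnames = list(NULL, samples$sample_id))
  for (s in seq_len(n_samp)) {
    sid <- samples$sample_id[s]
    w <- warps[[s]]
    # irregular scan grid
    st <- scan_t0 + stats::runif(length(scan_t0), -0.1, 0.1) *
      cfg$scan_interval
    st <- sort(pmax(st, 0))
    st <- st[c(TRUE, diff(st) > 0)]
    nsc <- length(st)
    apply_w <- function(t) t + w$a * sin(2 * pi * t / w$period + w$phase)
    true_rt[, s] <- apply_w(mets$rt_center)

    cent_scan <- list(); cent_mz <- list(); cent_int <- list()
    emit <- function(scan_sel, mzv, intv) {
      keep <- intv >= cfg$emission_floor
      if (!any(keep)) return()
      k <- length(cent_scan) + 1
      cent_scan[[k]] <<- scan_sel[keep]
      cent_mz[[k]] <<- mzv[keep]
      cent_int[[k]] <<- intv[keep]
    }
    for (k in seq_len(nrow(ions))) {
      m <- ions$metabolite_id[k]
      ctr <- true_rt[m, s]
      sg <- mets$sigma[m]; tau <- mets$tau[m]
      span <- 4.5 * sg + 5 * tau
      sel <- if (baseline_on[k]) seq_len(nsc)
             else which(st >= ctr - span & st <= ctr + span)
      if (length(sel) == 0) next
      y <- heights[k, s] * elution_profile(st[sel], ctr, sg, tau)
      if (baseline_on[k]) {
        # baseline drift rides the same flow fluctuations as retention,
        # so it is expressed in warped time as well
        tg <- st[sel] - w$a * sin(2 * pi * st[sel] / w$period + w$phase)
        y <- y + base_lvl[k] *
          (1 + 0.4 * sin(2 * pi * tg / cfg$run_length + k))
      }
      y <- y * stats::rlnorm(length(sel), 0, cfg$shape_noise) +
        stats::rnorm(length(sel), 0, cfg$noise_floor_sd)
      emit(sel, ions$mz[k] + stats::rnorm(length(sel), 0, cfg$mz_jitter_sd), y)
    }
    if (n_noise > 0) {
      nz_mz <- stats::runif(n_noise, 100, 650)
      nz_rt <- stats::runif(n_noise, 0, cfg$run_length)
      nz_sg <- stats::runif(n_noise, 0.01, 0.03)
      nz_h <- stats::runif(n_noise, cfg$noise_height[1], cfg$noise_height[2])
      noise_ions[[sid]] <- data.frame(sample_id = sid, mz = nz_mz,
                                      rt = nz_rt, sigma = nz_sg,
                                      height = nz_h)
      for (k in seq_len(n_noise)) {
        sel <- which(st >= nz_rt[k] - 4 * nz_sg[k] &
                       st <= nz_rt[k] + 4 * nz_sg[k])
        if (length(sel) == 0) next
        y <- nz_h[k] * exp(-(st[sel] - nz_rt[k])^2 / (2 * nz_sg[k]^2)) *
          stats::rlnorm(length(sel), 0, cfg$shape_noise) +
          stats::rnorm(length(sel), 0, cfg$noise_floor_sd)
        emit(sel, nz_mz[k] + stats::rnorm(length(sel), 0, cfg$mz_jitter_sd), y)
      }
    }
    scan_v <- unlist(cent_scan); mz_v <- unlist(cent_mz)
    int_v <- unlist(cent_int)
    scans <- vector("list", nsc)
    ord <- order(scan_v, mz_v)
    scan_v <- scan_v[ord]; mz_v <- mz_v[ord]; int_v <- int_v[ord]
    split_idx <- split(seq_along(scan_v), scan_v)
    for (i in seq_len(nsc)) {
      ii <- split_idx[[as.character(i)]]
      if (is.null(ii)) {
        scans[[i]] <- list(rt = st[i], mz = numeric(0),
                           intensity = numeric(0))
      } else {
        mzi <- mz_v[ii]; ini <- int_v[ii]
        dup <- duplicated(mzi)
        if (any(dup)) { mzi <- mzi[!dup]; ini <- ini[!dup] }
        scans[[i]] <- list(rt = st[i], mz = mzi, intensity = ini)
      }
    }
    runs[[sid]] <- new_run(sid, samples$group[s], scans)
  }

  truth <- structure(list(
    config = cfg, seed = seed, samples = samples, metabolites = mets,
    ions = ions, abundance = abund, heights = heights, warps = warps,
    true_rt = true_rt, baseline_on = baseline_on,
    noise_ions = if (length(noise_ions)) do.call(rbind, noise_ions)
                 else NULL), class = "ground_truth")
  list(runs = runs, truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d metabolites, %d ions, %d samples (seed %d)\n",
              nrow(x$metabolites), nrow(x$ions), nrow(x$samples), x$seed))
  invisible(x)
}

#' Simulate a registered component table directly
#'
#' Draws peak heights from the generator's bilinear abundance model
#' (metabolite abundance x ion response factor x lognormal noise) without
#' synthesising raw scans, producing a `component_table` ready for
#' [anova_screen()] and [assign_meta_ids()]. Intended for statistical
#' calibration of the screening stage, where hundreds of replicate tables
#' are needed.
#'
#' @param config a [generator_config()].
#' @param seed integer RNG seed.
#' @return list with `table` (a `component_table`) and `truth` (data.frame
#'   `component_id`, `metabolite_id`, `role`, `effect`).
#' @export
simulate_component_table <- function(config = generator_config(),
                                     seed = 1L) {
  validate_generator_config(config)
  with_local_seed(seed, {
    d <- generate_dataset_impl_table(config)
    d
  })
}

generate_dataset_impl_table <- function(cfg) {
  n_samp <- cfg$n_groups * cfg$samples_per_group
  samples <- data.frame(
    sample_id = sprintf("S%02d", seq_len(n_samp)),
    group = rep(sprintf("G%d", seq_len(cfg$n_groups)),
                each = cfg$samples_per_group))
  mets <- data.frame(
    metabolite_id = seq_len(cfg$n_metabolites),
    rt_center = sort(stats::runif(cfg$n_metabolites, cfg$rt_range[1],
                                  cfg$rt_range[2])),
    mh_mz = stats::runif(cfg$n_metabolites, cfg$mz_range[1], cfg$mz_range[2]),
    base_height = stats::rlnorm(cfg$n_metabolites, cfg$base_height_meanlog,
                                cfg$base_height_sdlog))
  mets$effect <- stats::runif(cfg$n_metabolites) < cfg$effect_fraction
  mets$effect_mult <- ifelse(mets$effect,
                             ifelse(stats::runif(cfg$n_metabolites) < 0.5,
                                    cfg$effect_size, 1 / cfg$effect_size), 1)
  nio <- pmax(1L, sample(2:4, cfg$n_metabolites, replace = TRUE))
  comp <- list(); hts <- list()
  for (m in seq_len(cfg$n_metabolites)) {
    mult <- ifelse(samples$group == "G1", 1, mets$effect_mult[m])
    ab <- mets$base_height[m] * mult * stats::rlnorm(n_samp, 0,
                                                     cfg$biological_cv)
    rf <- c(1, stats::runif(nio[m] - 1, 0.2, 0.8))
    for (k in seq_len(nio[m])) {
      comp[[length(comp) + 1]] <- data.frame(
        metabolite_id = m,
        role = if (k == 1) "MH" else "fragment",
        mean_mz = mets$mh_mz[m] + (k - 1) * 0.5,
        mean_rt = mets$rt_center[m],
        effect = mets$effect[m])
      hts[[length(hts) + 1]] <- ab * rf[k] *
        stats::rlnorm(n_samp, 0, cfg$intensity_cv)
    }
  }
  comp <- do.call(rbind, comp)
  H <- do.call(rbind, hts)
  colnames(H) <- samples$sample_id
  k <- nrow(comp)
  tab <- structure(list(
    components = data.frame(component_id = seq_len(k),
                            mean_mz = comp$mean_mz, mean_rt = comp$mean_rt,
                            n_members = n_samp),
    samples = samples$sample_id, heights = H, areas = H * 3,
    membership = data.frame(
      component_id = rep(seq_len(k), each = n_samp),
      sample_id = rep(samples$sample_id, k),
      peak_id = paste0("sim_", rep(seq_len(k), each = n_samp), "_",
                       rep(seq_len(n_samp), k)))),
    class = "component_table")
  list(table = tab,
       truth = data.frame(component_id = seq_len(k),
                          metabolite_id = comp$metabolite_id,
                          role = comp$role, effect = comp$effect),
       groups = stats::setNames(samples$group, samples$sample_id))
}

#' Generator scenario: two shape-distinct co-eluting metabolites
#'
#' Builds a configuration-plus-override bundle reproducing the classic
#' deconvolution situation: two metabolites whose apexes coincide (within
#' the annotation rt tolerance) but whose elution profiles differ - one a
#' symmetric Gaussian, the other strongly tailed - with uncorrelated
#' abundances across samples. Used to demonstrate that within-sample ion
#' clustering separates tightly co-eluted ions of different metabolites.
#'
#' @param seed integer RNG seed.
#' @param rt_offset apex offset between the two metabolites in minutes
#'   (default 0.01, well inside the 0.02-min clustering gate).
#' @return list with `runs` and `truth` as in [generate_dataset()].
#' @export
generate_coelution_pair <- function(seed = 1L, rt_offset = 0.01) {
  cfg <- generator_config(n_metabolites = 2L, noise_ion_factor = 0,
                          fragment_range = c(2L, 2L),
                          effect_fraction = 0, biological_cv = 0.6,
                          run_length = 5, rt_range = c(2.0, 2.6))
  out <- with_local_seed(seed, {
    d <- generate_dataset_impl(cfg, seed)
    d
  })
  # pin the two metabolites onto one apex with distinct shapes, then
  # regenerate deterministically from the edited truth; the tailed
  # profile's mode shift is compensated so the apexes truly coincide and
  # only the profile shapes can separate the clusters
  tr <- out$truth
  sg <- 0.025; tau <- 0.06
  ts <- seq(-0.3, 0.5, by = 1e-4)
  mode_shift <- ts[which.max(elution_profile(ts, 0, sg, tau))]
  tr$metabolites$rt_center <- c(2.29, 2.29 + rt_offset - mode_shift)
  tr$metabolites$sigma <- c(sg, sg)
  tr$metabolites$tau <- c(0, tau)
  regenerate_from_truth(tr)
}

# Re-emit runs from an (edited) ground_truth, reusing its heights, warps
# and catalogue; scan-level randomness is re-drawn from the stored seed.
regenerate_from_truth <- function(truth) {
  cfg <- truth$config
  with_local_seed(truth$seed + 1000003L, {
    n_samp <- nrow(truth$samples)
    scan_t0 <- seq(0, cfg$run_length, by = cfg$scan_interval)
    runs <- list()
    for (s in seq_len(n_samp)) {
      sid <- truth$samples$sample_id[s]
      w <- truth$warps[[s]]
      st <- sort(pmax(scan_t0 + stats::runif(length(scan_t0), -0.1, 0.1) *
                        cfg$scan_interval, 0))
      st <- st[c(TRUE, diff(st) > 0)]
      apply_w <- function(t) t + w$a * sin(2 * pi * t / w$period + w$phase)
      truth$true_rt[, s] <- apply_w(truth$metabolites$rt_center)
      cs <- list(); cm <- list(); ci <- list()
      for (k in seq_len(nrow(truth$ions))) {
        m <- truth$ions$metabolite_id[k]
        ctr <- truth$true_rt[m, s]
        sg <- truth$metabolites$sigma[m]; tau <- truth$metabolites$tau[m]
        span <- 4.5 * sg + 5 * tau
        sel <- which(st >= ctr - span & st <= ctr + span)
        if (length(sel) == 0) next
        y <- truth$heights[k, s] * elution_profile(st[sel], ctr, sg, tau) *
          stats::rlnorm(length(sel), 0, cfg$shape_noise) +
          stats::rnorm(length(sel), 0, cfg$noise_floor_sd)
        keep <- y >= cfg$emission_floor
        if (!any(keep)) next
        j <- length(cs) + 1
        cs[[j]] <- sel[keep]
        cm[[j]] <- truth$ions$mz[k] +
          stats::rnorm(sum(keep), 0, cfg$mz_jitter_sd)
        ci[[j]] <- y[keep]
      }
      scan_v <- unlist(cs); mz_v <- unlist(cm); int_v <- unlist(ci)
      ord <- order(scan_v, mz_v)
      scan_v <- scan_v[ord]; mz_v <- mz_v[ord]; int_v <- int_v[ord]
      split_idx <- split(seq_along(scan_v), scan_v)
      scans <- lapply(seq_along(st), function(i) {
        ii <- split_idx[[as.character(i)]]
        if (is.null(ii)) list(rt = st[i], mz = numeric(0),
                              intensity = numeric(0))
        else {
          dup <- duplicated(mz_v[ii])
          list(rt = st[i], mz = mz_v[ii][!dup], intensity = int_v[ii][!dup])
        }
      })
      runs[[sid]] <- new_run(sid, truth$samples$group[s], scans)
    }
    list(runs = runs, truth = truth)
  })
}
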