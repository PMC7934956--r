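#' Configuration for the synthetic transplant experiment
#'
#' Defaults reproduce the structure of a ten-genotype by eight-site
#' reciprocal transplant with 10 replicate fragments per combination, one
#' genotype x site combination never planted, 122 fragments lost to early
#' transplantation stress, three survey timepoints, and 13,337 genotyped loci
#' of which 58 are causal with per-locus dosage-phenotype correlations
#' targeted inside `target_r_range`.
#'
#' Variance components are on the latent bleaching scale. The defaults put
#' most structured variance on site, a moderate genotype x site interaction
#' and a smaller genotype main effect, against residual fragment noise --
#' the ordering observed in multi-site coral transplant ANOVAs, where site F
#' statistics dwarf genotype and interaction F statistics.
#'
#' @param n_genotypes,n_sites,n_replicates,n_timepoints design dimensions.
#' @param n_loci,n_causal total and causal locus counts.
#' @param var_genotype,var_site,var_gxe,var_noise variance components of the
#'   latent fragment value (effects are rescaled so their realized sample
#'   variance equals the configured value exactly).
#' @param sd_timepoint sd of per-timepoint jitter added to the fragment
#'   latent before ordinal scoring.
#' @param target_r_range interval in (0,1): realized correlation between
#'   causal-locus dosage and genotype-level residual phenotype.
#' @param depth_mean,depth_dispersion negative-binomial read-depth model per
#'   sample x locus cell; depth drives triplet sharpness.
#' @param depth_scale e-folding depth of triplet concentration: weight on the
#'   true genotype is `1 - exp(-depth/depth_scale)`.
#' @param maf_range secondary-allele frequency range, inside (0, 0.5).
#' @param missing_combination length-2 character (genotype, site) combination
#'   absent from the design, or `NULL` for a fully crossed design.
#' @param n_early_mortality fragments flagged as early transplant mortality
#'   and excluded from the analysis set.
#' @param missing_cell_rate fraction of sample x locus cells forced to be
#'   entirely uninformative (prior triplet).
#' @param survival_intercept,survival_slope logistic model of December
#'   mortality on the latent bleaching value.
#' @param score_thresholds cut points on the latent scale mapping to ordinal
#'   scores 0-3; default is the quartiles of the latent marginal.
#' @param seed master seed; every stage derives its own stream from it.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_genotypes = 10, n_sites = 8, n_replicates = 10,
                       n_timepoints = 3, n_loci = 13337, n_causal = 58,
                       var_genotype = 0.015, var_site = 0.11, var_gxe = 0.03,
                       var_noise = 0.5, sd_timepoint = 0.3,
                       target_r_range = c(0.73, 0.89),
                       depth_mean = 12, depth_dispersion = 2, depth_scale = 3,
                       maf_range = c(0.05, 0.45),
                       missing_combination = c("g10", "s8"),
                       n_early_mortality = 122,
                       missing_cell_rate = 0,
                       survival_intercept = 5.5, survival_slope = 4.5,
                       score_thresholds = NULL, seed = 1) {
  cfg <- list(n_genotypes = n_genotypes, n_sites = n_sites,
              n_replicates = n_replicates, n_timepoints = n_timepoints,
              n_loci = n_loci, n_causal = n_causal,
              var_genotype = var_genotype, var_site = var_site,
              var_gxe = var_gxe, var_noise = var_noise,
              sd_timepoint = sd_timepoint, target_r_range = target_r_range,
              depth_mean = depth_mean, depth_dispersion = depth_dispersion,
              depth_scale = depth_scale, maf_range = maf_range,
              missing_combination = missing_combination,
              n_early_mortality = n_early_mortality,
              missing_cell_rate = missing_cell_rate,
              survival_intercept = survival_intercept,
              survival_slope = survival_slope,
              score_thresholds = score_thresholds, seed = seed)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    stopifnot(n_genotypes >= 1, n_sites >= 1, n_replicates >= 1,
              n_timepoints >= 1, n_loci >= 1)
    if (n_causal > n_loci) stop("n_causal must not exceed n_loci")
    if (any(c(var_genotype, var_site, var_gxe, var_noise) < 0))
      stop("variance components must be non-negative")
    if (!(maf_range[1] > 0 && maf_range[1] <= maf_range[2] &&
          maf_range[2] < 0.5))
      stop("maf_range must satisfy 0 < low <= high < 0.5")
    if (!(target_r_range[1] > 0 && target_r_range[2] < 1 &&
          target_r_range[1] <= target_r_range[2]))
      stop("target_r_range must lie within (0,1) with low <= high")
    if (missing_cell_rate < 0 || missing_cell_rate >= 1)
      stop("missing_cell_rate must be in [0, 1)")
    if (!is.null(missing_combination) && length(missing_combination) != 2)
      stop("missing_combination must be NULL or a (genotype, site) pair")
  })
  invisible(cfg)
}

genotype_ids <- function(n) sprintf("g%02d", seq_len(n))
site_ids <- function(n) sprintf("s%d", seq_len(n))

#' Simulate the transplant design, ordinal bleaching surveys and survival
#'
#' Each fragment gets a latent bleaching value = genotype effect + site
#' effect + interaction + fragment noise. Per timepoint the latent is
#' jittered and cut at fixed thresholds into an ordinal score 0-3 (higher =
#' more bleached). December survival follows a logistic model on the latent
#' value; early mortality is assigned uniformly at random (transplantation
#' stress, independent of thermal phenotype).
#'
#' @param cfg a [sim_config()].
#' @return a list with `surveys` (one row per fragment x timepoint:
#'   fragment_id, genotype_id, site_id, timepoint, score, early_mortality,
#'   survived_december) and `truth` (ground-truth effects, per-fragment
#'   latent values, and expected genotype-level residual phenotypes).
#' @export
simulate_design <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(stream_seed(cfg$seed, 1L))
  gids <- genotype_ids(cfg$n_genotypes)
  sids <- site_ids(cfg$n_sites)

  g_eff <- stats::setNames(centre_scale(stats::rnorm(cfg$n_genotypes),
                                        cfg$var_genotype), gids)
  s_eff <- stats::setNames(centre_scale(stats::rnorm(cfg$n_sites),
                                        cfg$var_site), sids)
  gs <- matrix(stats::rnorm(cfg$n_genotypes * cfg$n_sites),
               cfg$n_genotypes, cfg$n_sites, dimnames = list(gids, sids))
  if (cfg$n_genotypes > 1 && cfg$n_sites > 1) {
    gs <- centre_scale_interaction(gs, cfg$var_gxe)
  } else gs[] <- 0

  design <- expand.grid(genotype_id = gids, site_id = sids,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (!is.null(cfg$missing_combination)) {
    mc <- cfg$missing_combination
    keep <- !(design$genotype_id == mc[1] & design$site_id == mc[2])
    if (all(keep)) warning("missing_combination not found in design grid")
    design <- design[keep, , drop = FALSE]
  }
  frags <- design[rep(seq_len(nrow(design)), each = cfg$n_replicates), ]
  n_frag <- nrow(frags)
  if (cfg$n_early_mortality >= n_frag)
    stop(sprintf("n_early_mortality (%d) must be < total fragments (%d)",
                 cfg$n_early_mortality, n_frag))
  frags$fragment_id <- sprintf("f%04d", seq_len(n_frag))

  latent <- g_eff[frags$genotype_id] + s_eff[frags$site_id] +
    gs[cbind(frags$genotype_id, frags$site_id)] +
    stats::rnorm(n_frag, sd = sqrt(cfg$var_noise))
  names(latent) <- frags$fragment_id

  total_var <- cfg$var_genotype + cfg$var_site + cfg$var_gxe +
    cfg$var_noise + cfg$sd_timepoint^2
  thr <- cfg$score_thresholds
  if (is.null(thr)) thr <- stats::qnorm(c(.25, .5, .75), 0, sqrt(total_var))

  early <- rep(FALSE, n_frag)
  early[sample.int(n_frag, cfg$n_early_mortality)] <- TRUE
  p_die <- stats::plogis(cfg$survival_intercept + cfg$survival_slope * latent)
  survived <- stats::runif(n_frag) > p_die
  survived[early] <- FALSE

  surveys <- do.call(rbind, lapply(seq_len(cfg$n_timepoints), function(tp) {
    lt <- latent + stats::rnorm(n_frag, sd = cfg$sd_timepoint)
    data.frame(fragment_id = frags$fragment_id,
               genotype_id = frags$genotype_id,
               site_id = frags$site_id,
               timepoint = tp,
               score = findInterval(lt, thr),
               early_mortality = early,
               survived_december = survived,
               stringsAsFactors = FALSE)
  }))
  surveys <- surveys[order(surveys$fragment_id, surveys$timepoint), ]
  rownames(surveys) <- NULL

  # expected residual phenotype per genotype: its own effect plus the mean
  # interaction over the sites where it was actually planted
  site_present <- lapply(gids, function(g)
    unique(frags$site_id[frags$genotype_id == g]))
  true_resid <- vapply(seq_along(gids), function(i)
    g_eff[i] + mean(gs[gids[i], site_present[[i]]]), numeric(1))
  names(true_resid) <- gids

  truth <- list(genotype_effects = g_eff, site_effects = s_eff,
                interaction_effects = gs,
                latent_by_fragment = latent,
                score_thresholds = thr,
                true_residual_by_genotype = true_resid,
                causal_loci = NULL)
  list(surveys = surveys, truth = truth)
}

# draw one candidate causal genotype vector: a noisy Gaussian copy of the
# standardized phenotype cut at Hardy-Weinberg quantiles for frequency q
causal_candidate <- function(z, t, q) {
  c_lat <- t * z + sqrt(1 - t^2) * stats::rnorm(length(z))
  cuts <- stats::qnorm(cumsum(c((1 - q)^2, 2 * q * (1 - q))))
  findInterval(c_lat, cuts)
}

#' Simulate a genotype-probability table with a causal locus subset
#'
#' One sample per genotype. True genotypes are drawn under Hardy-Weinberg
#' equilibrium at locus-specific secondary-allele frequencies; each
#' sample x locus cell receives a probability triplet concentrated on the
#' true genotype, with sharpness set by a simulated negative-binomial read
#' depth (weight `1 - exp(-depth/depth_scale)` on the true genotype, the
#' remainder on the Hardy-Weinberg prior). Causal loci are constructed by a
#' best-of-candidates search so that the realized correlation between true
#' genotype dosage and the genotype-level residual phenotype lands inside
#' `cfg$target_r_range`.
#'
#' @param cfg a [sim_config()].
#' @param truth ground truth from [simulate_design()].
#' @return list with `geno` (a `geno_prob` object: markers, samples,
#'   probability array, informative flags, allele frequencies) and `causal`
#'   (data frame of causal locus IDs with target and realized correlations).
#' @export
simulate_genotypes <- function(cfg, truth) {
  validate_sim_config(cfg)
  if (cfg$n_causal > 0 && cfg$n_genotypes < 4)
    stop("targeting causal correlations needs at least 4 genotypes")
  set.seed(stream_seed(cfg$seed, 2L))
  L <- cfg$n_loci; S <- cfg$n_genotypes
  samples <- names(truth$true_residual_by_genotype)
  markers <- sprintf("locus_%05d", seq_len(L))
  z <- as.vector(scale(truth$true_residual_by_genotype))
  if (cfg$n_causal > 0 && any(!is.finite(z)))
    stop("residual phenotypes are constant; causal correlations unattainable")

  maf <- stats::runif(L, cfg$maf_range[1], cfg$maf_range[2])
  causal_idx <- sort(sample.int(L, cfg$n_causal))
  # informative causal loci need intermediate frequencies
  maf[causal_idx] <- stats::runif(cfg$n_causal,
                                  max(cfg$maf_range[1], 0.2),
                                  cfg$maf_range[2])

  geno <- matrix(stats::rbinom(L * S, 2, rep(maf, S)), L, S)

  depth <- matrix(stats::rnbinom(L * S, mu = cfg$depth_mean,
                                 size = cfg$depth_dispersion), L, S)
  if (cfg$missing_cell_rate > 0) {
    depth[stats::runif(L * S) < cfg$missing_cell_rate] <- 0L
  }
  # causal loci emulate the screened set, which by construction is called in
  # every sample
  depth[causal_idx, ] <- pmax(depth[causal_idx, ], 1L)
  w <- 1 - exp(-depth / cfg$depth_scale)

  # candidate search targets the correlation of the *dosage* the pipeline
  # will see (true genotype shrunk toward the allele-frequency prior by the
  # cell's depth weight), so depth noise cannot push realized r off target
  tgt <- stats::runif(cfg$n_causal,
                      cfg$target_r_range[1] + 0.02,
                      cfg$target_r_range[2] - 0.02)
  realized <- numeric(cfg$n_causal)
  margin <- min(0.02, (cfg$target_r_range[2] - cfg$target_r_range[1]) / 2)
  for (k in seq_len(cfg$n_causal)) {
    li <- causal_idx[k]; wk <- w[li, ]
    best <- NULL; best_gap <- Inf; best_q <- maf[li]
    q <- maf[li]
    # some phenotype shapes are hard to match at a given allele frequency;
    # redraw the frequency when the candidate search cannot get close
    for (attempt in seq_len(8)) {
      for (cand in seq_len(300)) {
        g <- causal_candidate(z, stats::runif(1, 0.6, 0.995), q)
        dos <- wk * g + (1 - wk) * 2 * q
        if (stats::var(dos) == 0) next
        gap <- abs(stats::cor(dos, z) - tgt[k])
        if (gap < best_gap) { best <- g; best_gap <- gap; best_q <- q }
      }
      if (best_gap <= margin * 0.75) break
      q <- stats::runif(1, max(cfg$maf_range[1], 0.25), cfg$maf_range[2])
    }
    maf[li] <- best_q
    geno[li, ] <- best
    realized[k] <- stats::cor(wk * best + (1 - wk) * 2 * best_q, z)
  }
  prior <- cbind((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
  p <- array(0, dim = c(L, S, 3))
  for (j in 1:3) {
    p[, , j] <- w * (geno == (j - 1)) + (1 - w) * prior[, j]
  }
  gp <- geno_prob(markers, samples, p, informative = depth > 0,
                  freq = maf)
  causal <- data.frame(locus = markers[causal_idx],
                       target_r = tgt, realized_r = realized,
                       stringsAsFactors = FALSE)
  list(geno = gp, causal = causal)
}

#' Simulate hourly site temperature series
#'
#' Per site: baseline + half-sine seasonal ramp over the span + sinusoidal
#' diel cycle + Gaussian noise, at hourly cadence. Deterministic given the
#' seed.
#'
#' @param site_params data frame with columns site_id, baseline,
#'   seasonal_amplitude, diel_range, noise_sd.
#' @param start,end Date (or coercible) span, inclusive of `start`,
#'   exclusive of `end` + 1 day.
#' @param seed integer seed.
#' @param gap_schedule optional data frame (site_id, date) of whole days to
#'   drop from the output.
#' @return data frame (site_id, timestamp POSIXct UTC, temp_c).
#' @export
simulate_temperature <- function(site_params, start, end, seed = 1,
                                 gap_schedule = NULL) {
  check_columns(site_params,
                c("site_id", "baseline", "seasonal_amplitude",
                  "diel_range", "noise_sd"), "site_params")
  start <- as.Date(start); end <- as.Date(end)
  if (end < start) stop("end date is before start date")
  set.seed(stream_seed(seed, 3L))
  hours <- seq(as.POSIXct(paste(start, "00:00:00"), tz = "UTC"),
               as.POSIXct(paste(end, "23:00:00"), tz = "UTC"),
               by = "hour")
  n <- length(hours)
  frac <- as.numeric(hours - hours[1], units = "days") /
    max(1e-9, as.numeric(hours[n] - hours[1], units = "days"))
  hod <- as.integer(format(hours, "%H", tz = "UTC"))
  out <- do.call(rbind, lapply(seq_len(nrow(site_params)), function(i) {
    sp <- site_params[i, ]
    temp <- sp$baseline + sp$seasonal_amplitude * sin(pi * frac) +
      (sp$diel_range / 2) * sin(2 * pi * (hod - 9) / 24) +
      stats::rnorm(n, sd = sp$noise_sd)
    data.frame(site_id = sp$site_id, timestamp = hours, temp_c = temp,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(gap_schedule)) {
    check_columns(gap_schedule, c("site_id", "date"), "gap_schedule")
    key <- paste(out$site_id, as.Date(out$timestamp, tz = "UTC"))
    drop <- paste(gap_schedule$site_id, as.Date(gap_schedule$date))
    out <- out[!(key %in% drop), ]
  }
  rownames(out) <- NULL
  out
}

#' Simulate a locus-to-category annotation table
#'
#' Random GO-style category memberships over a locus universe, optionally
#' with one planted category whose members are a supplied locus set (used to
#' verify enrichment detection).
#'
#' @param locus_ids universe of locus IDs.
#' @param n_categories number of random categories.
#' @param mean_size mean category size (Poisson, floored at 2).
#' @param planted optional list(category =, loci =) planted membership.
#' @param namespaces namespaces sampled per category.
#' @param seed integer seed.
#' @return data frame (locus_id, category, namespace, name).
#' @export
simulate_annotations <- function(locus_ids, n_categories = 50,
                                 mean_size = 15, planted = NULL,
                                 namespaces = c("BP", "MF", "CC"),
                                 seed = 1) {
  set.seed(stream_seed(seed, 4L))
  cats <- sprintf("GO:%07d", sample.int(9999999, n_categories))
  ns <- sample(namespaces, n_categories, replace = TRUE)
  rows <- lapply(seq_len(n_categories), function(i) {
    size <- max(2, stats::rpois(1, mean_size))
    size <- min(size, length(locus_ids))
    data.frame(locus_id = sample(locus_ids, size), category = cats[i],
               namespace = ns[i], name = paste("random category", i),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(planted)) {
    out <- rbind(out, data.frame(locus_id = planted$loci,
                                 category = planted$category,
                                 namespace = "BP",
                                 name = "planted category",
                                 stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Synthetic dataset matched to the screened-locus prediction structure
#'
#' Convenience wrapper producing the benchmark used to characterize the
#' genomic predictor: 10 genotype-level phenotypes and 58 predictor loci
#' whose realized dosage-phenotype correlations lie in the configured target
#' range -- the structure of a screened locus set feeding the forest.
#'
#' @param seed master seed.
#' @param n_loci number of predictor loci (all causal).
#' @param ... further overrides passed to [sim_config()].
#' @return list: `X` (samples x loci dosage matrix), `y` (named phenotype
#'   vector), `realized_r` (per-locus dosage-phenotype correlations),
#'   `causal` (locus table), `cfg`.
#' @export
benchmark_dataset <- function(seed, n_loci = 58, ...) {
  cfg <- sim_config(n_loci = n_loci, n_causal = n_loci, seed = seed, ...)
  design <- simulate_design(cfg)
  gen <- simulate_genotypes(cfg, design$truth)
  dosages <- compute_dosage(gen$geno)
  list(X = t(dosages), y = design$truth$true_residual_by_genotype,
       realized_r = gen$causal$realized_r, causal = gen$causal, cfg = cfg)
}
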