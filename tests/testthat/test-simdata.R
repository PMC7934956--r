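test_that("fragment counts follow the design arithmetic for any configuration", {
  grid <- list(
    list(ng = 5, ns = 3, nr = 4, miss = NULL, em = 3),
    list(ng = 6, ns = 4, nr = 5, miss = c("g03", "s2"), em = 10),
    list(ng = 4, ns = 2, nr = 2, miss = c("g01", "s1"), em = 0))
  for (g in grid) {
    cfg <- sim_config(n_genotypes = g$ng, n_sites = g$ns,
                      n_replicates = g$nr, n_loci = 10, n_causal = 0,
                      missing_combination = g$miss,
                      n_early_mortality = g$em, seed = 3)
    d <- simulate_design(cfg)
    n_miss <- if (is.null(g$miss)) 0 else 1
    expected <- g$ng * g$ns * g$nr - g$nr * n_miss - g$em
    analysed <- unique(d$surveys$fragment_id[!d$surveys$early_mortality])
    expect_length(analysed, expected)
    combos <- unique(d$surveys[, c("genotype_id", "site_id")])
    expect_equal(nrow(combos), g$ng * g$ns - n_miss)
    # every fragment has every timepoint
    expect_true(all(table(d$surveys$fragment_id) == cfg$n_timepoints))
  }
})

test_that("degenerate variances give identical scores and bounds error", {
  cfg <- small_cfg(var_genotype = 0, var_site = 0, var_gxe = 0,
                   var_noise = 0, sd_timepoint = 0)
  d <- simulate_design(cfg)
  expect_length(unique(d$surveys$score), 1)

  expect_error(simulate_design(small_cfg(n_early_mortality = 1000)),
               "early_mortality")
  expect_error(sim_config(n_causal = 50, n_loci = 10), "n_causal")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
})

test_that("ground-truth effects are centred with exact variances and the
           latent decomposition is recoverable by method of moments", {
  est <- sapply(1:3, function(s) {
    cfg <- sim_config(n_replicates = 50, var_genotype = 0.2, var_site = 0.3,
                      var_gxe = 0.15, var_noise = 0.5, n_loci = 10,
                      n_causal = 0, missing_combination = NULL,
                      n_early_mortality = 0, seed = 40 + s)
    d <- simulate_design(cfg)
    expect_equal(sum(d$truth$genotype_effects), 0, tolerance = 1e-9)
    expect_equal(sum(d$truth$site_effects), 0, tolerance = 1e-9)
    expect_equal(var(d$truth$genotype_effects), 0.2, tolerance = 1e-9)
    fr <- unique(d$surveys[, c("fragment_id", "genotype_id", "site_id")])
    fr$lat <- d$truth$latent_by_fragment[fr$fragment_id]
    ms <- summary(aov(lat ~ genotype_id * site_id, data = fr))[[1]]$`Mean Sq`
    # effects are fixed and exactly double-centred, so main-effect mean
    # squares carry no interaction leakage: subtract the error MS
    c((ms[1] - ms[4]) / (8 * 50), (ms[2] - ms[4]) / (10 * 50),
      (ms[3] - ms[4]) / 50, ms[4])
  })
  mom <- rowMeans(est)
  # 15% relative error (expect_equal's tolerance is relative here)
  expect_equal(mom[1], 0.2, tolerance = 0.15)
  expect_equal(mom[2], 0.3, tolerance = 0.15)
  expect_equal(mom[3], 0.15, tolerance = 0.15)
  expect_equal(mom[4], 0.5, tolerance = 0.15)
})

test_that("probability triplets are valid, sharpen with depth, and flag
           uninformative cells", {
  cfg <- small_cfg(missing_cell_rate = 0.1, seed = 5)
  d <- simulate_design(cfg)
  g <- simulate_genotypes(cfg, d$truth)
  sums <- g$geno$p[, , 1] + g$geno$p[, , 2] + g$geno$p[, , 3]
  expect_true(all(abs(sums - 1) < 1e-9))
  dos <- compute_dosage(g$geno)
  expect_true(all(dos >= 0 & dos <= 2, na.rm = TRUE))
  expect_true(any(!g$geno$informative))
  expect_true(all(is.na(dos[!g$geno$informative])))

  # effectively infinite depth: triplets one-hot on true genotypes
  cfg_hi <- small_cfg(depth_mean = 1e5, depth_dispersion = 1e5,
                      missing_cell_rate = 0, seed = 6)
  d_hi <- simulate_design(cfg_hi)
  g_hi <- simulate_genotypes(cfg_hi, d_hi$truth)
  expect_true(all(abs(apply(g_hi$geno$p, c(1, 2), max) - 1) < 1e-6))
  dos_hi <- compute_dosage(g_hi$geno)
  expect_true(all(abs(dos_hi - round(dos_hi)) < 1e-6))

  expect_error(simulate_genotypes(small_cfg(n_genotypes = 3, n_sites = 2),
                                  d$truth),
               "at least 4 genotypes")
})

test_that("causal loci hit the target correlation range and null loci
           hover near zero", {
  in_range <- sapply(1:10, function(s) {
    cfg <- sim_config(n_loci = 58, n_causal = 58, seed = 300 + s)
    d <- simulate_design(cfg)
    g <- simulate_genotypes(cfg, d$truth)
    dos <- compute_dosage(g$geno)
    z <- d$truth$true_residual_by_genotype
    r <- apply(dos, 1, function(x) cor(x, z))
    mean(abs(r) >= 0.73 & abs(r) <= 0.89)
  })
  expect_true(all(in_range >= 0.9))

  cfg0 <- sim_config(n_loci = 400, n_causal = 0, n_early_mortality = 0,
                     seed = 11)
  d0 <- simulate_design(cfg0)
  g0 <- simulate_genotypes(cfg0, d0$truth)
  dos0 <- compute_dosage(g0$geno)
  z0 <- d0$truth$true_residual_by_genotype
  r0 <- apply(dos0, 1, function(x)
    if (sd(x, na.rm = TRUE) > 0) cor(x, z0, use = "complete.obs") else NA)
  expect_lt(mean(abs(r0), na.rm = TRUE), 2 / sqrt(cfg0$n_genotypes))
})

test_that("temperature generator is deterministic with exact degenerate
           behaviour and honours gap schedules", {
  sp <- data.frame(site_id = c("sA", "sB"), baseline = c(29, 30),
                   seasonal_amplitude = 0, diel_range = 0, noise_sd = 0)
  ts1 <- simulate_temperature(sp, "2015-05-01", "2015-05-10", seed = 2)
  ts2 <- simulate_temperature(sp, "2015-05-01", "2015-05-10", seed = 2)
  expect_identical(ts1, ts2)
  expect_true(all(ts1$temp_c[ts1$site_id == "sA"] == 29))
  expect_equal(nrow(ts1), 2 * 10 * 24)

  expect_error(simulate_temperature(sp, "2015-06-01", "2015-05-01"),
               "before start")

  gaps <- data.frame(site_id = "sA", date = as.Date("2015-05-03"))
  tsg <- simulate_temperature(sp, "2015-05-01", "2015-05-10", seed = 2,
                              gap_schedule = gaps)
  a_days <- unique(as.Date(tsg$timestamp[tsg$site_id == "sA"], tz = "UTC"))
  expect_false(as.Date("2015-05-03") %in% a_days)
  expect_equal(sum(tsg$site_id == "sA"), 9 * 24)
})

test_that("master seed reproduces every stage bit-for-bit", {
  cfg <- small_cfg(seed = 77)
  d1 <- simulate_design(cfg); d2 <- simulate_design(cfg)
  expect_identical(d1, d2)
  g1 <- simulate_genotypes(cfg, d1$truth)
  g2 <- simulate_genotypes(cfg, d2$truth)
  expect_identical(g1, g2)
})
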