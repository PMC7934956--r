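# a dosage matrix with one informative locus and pure-noise companions
signal_matrix <- function(seed, n = 30, p_noise = 57) {
  set.seed(seed)
  x1 <- seq(0, 2, length.out = n) + rnorm(n, sd = 0.01)
  X <- cbind(signal = x1,
             matrix(runif(n * p_noise, 0, 2), n, p_noise,
                    dimnames = list(NULL, sprintf("noise%02d", 1:p_noise))))
  rownames(X) <- sprintf("g%02d", 1:n)
  X
}

test_that("a single exact signal locus dominates cross-validated skill and
           importance", {
  # every predictor is a split candidate here: with one informative locus
  # among 58 and a single random candidate per split, almost all splits
  # would be noise by construction, which tests the sampler, not the
  # operation; bagging isolates planted-signal recovery
  res <- sapply(1:10, function(s) {
    X <- signal_matrix(s)
    y <- setNames(2 * X[, "signal"] - 1, rownames(X))  # exact monotone map
    fit <- fit_and_crossvalidate(X, y,
                                 model_config(mtry = ncol(X), seed = s))
    c(cv = mean(fit$cv_r2), top = names(fit$importance)[1] == "signal")
  })
  expect_gte(mean(res["cv", ]), 0.8)
  expect_true(all(res["top", ] == 1))
})

test_that("permuted phenotypes give near-null cross-validated skill at a
           sample size where the null baseline is small", {
  r2s <- sapply(1:10, function(s) {
    bench <- benchmark_dataset(700 + s, n_genotypes = 30)
    set.seed(s)
    y_perm <- setNames(sample(bench$y), names(bench$y))
    fit <- fit_and_crossvalidate(bench$X, y_perm,
                                 model_config(n_repeats = 5, seed = s))
    mean(fit$cv_r2)
  })
  expect_lte(mean(r2s), 0.15)
})

test_that("fitting is reproducible and mean skill is stable under locus
           reordering", {
  bench <- benchmark_dataset(42)
  cfg <- model_config(seed = 9)
  f1 <- fit_and_crossvalidate(bench$X, bench$y, cfg)
  f2 <- fit_and_crossvalidate(bench$X, bench$y, cfg)
  expect_identical(f1$cv_r2, f2$cv_r2)
  expect_identical(predict(f1$forest, bench$X), predict(f2$forest, bench$X))

  set.seed(1)
  Xp <- bench$X[, sample(ncol(bench$X))]
  f3 <- fit_and_crossvalidate(Xp, bench$y, cfg)
  expect_equal(mean(f1$cv_r2), mean(f3$cv_r2), tolerance = 0.05)

  expect_error(fit_and_crossvalidate(bench$X[1:3, ], bench$y[1:3], cfg),
               "at least 4")
  Xna <- bench$X; Xna[1, 1] <- NA
  expect_error(fit_and_crossvalidate(Xna, bench$y, cfg), "missing")
})

test_that("missing-data robustness equals the final fit at fraction 0,
           collapses at fraction 1, and decreases monotonically", {
  bench <- benchmark_dataset(42)
  fit <- fit_and_crossvalidate(bench$X, bench$y, model_config(seed = 9))
  rob <- missing_data_robustness(fit, fractions = c(0, 0.25, 0.5, 0.75, 1),
                                 n_replicates = 40, seed = 5)
  expect_equal(rob$mean_ve[rob$fraction == 0], fit$final_r2,
               tolerance = 1e-12)
  expect_equal(rob$sd_ve[rob$fraction == 0], 0)
  expect_lte(rob$mean_ve[rob$fraction == 1], 0.05)
  # non-increasing in expectation; allow replicate noise
  expect_true(all(diff(rob$mean_ve) <= 0.02))
  trend <- cor.test(rob$fraction, rob$mean_ve, method = "spearman",
                    alternative = "less", exact = FALSE)
  expect_lt(trend$p.value, 0.05)
})

test_that("causal loci out-rank null loci in variable importance", {
  pvals <- sapply(1:10, function(s) {
    cfg <- sim_config(n_loci = 150, n_causal = 15, n_sites = 4,
                      n_replicates = 5, missing_combination = NULL,
                      n_early_mortality = 0, seed = 7300 + s)
    d <- simulate_design(cfg)
    g <- simulate_genotypes(cfg, d$truth)
    dos <- compute_dosage(g$geno)
    keep <- rowSums(is.na(dos)) == 0
    X <- t(dos[keep, ])
    y <- d$truth$true_residual_by_genotype
    fit <- fit_and_crossvalidate(X, y, model_config(n_repeats = 1,
                                                    seed = s))
    causal <- colnames(X) %in% g$causal$locus
    wilcox.test(fit$importance[colnames(X)[causal]],
                fit$importance[colnames(X)[!causal]],
                alternative = "greater")$p.value
  })
  expect_lt(median(pvals), 0.01)
  # aggregate evidence across the 10 seeds (Fisher combination)
  fisher_p <- pchisq(-2 * sum(log(pvals)), df = 2 * length(pvals),
                     lower.tail = FALSE)
  expect_lt(fisher_p, 0.01)
})

test_that("novel-sample prediction applies the calling filter, imputation
           and per-reef subsampling contracts", {
  bench <- benchmark_dataset(11)
  fit <- fit_and_crossvalidate(bench$X, bench$y,
                               model_config(n_repeats = 2, seed = 3))
  # identical, fully called matrix reproduces the final-fit predictions
  pred <- predict_novel(fit, bench$X, min_called = 30)
  expect_equal(pred$predicted_residual,
               unname(predict(fit$forest, bench$X)), tolerance = 1e-12)
  expect_true(all(pred$n_called_loci == 58))

  # 29 called loci -> dropped; 30 -> kept
  newX <- bench$X[1:4, ]
  rownames(newX) <- sprintf("novel%d", 1:4)
  newX[1, 1:29] <- NA   # 29 called
  newX[2, 1:28] <- NA   # 30 called
  newX[3, ] <- NA       # nothing called
  expect_message(p2 <- predict_novel(fit, newX, min_called = 30),
                 "dropped")
  expect_setequal(p2$sample_id, c("novel2", "novel4"))
  expect_equal(p2$n_called_loci[p2$sample_id == "novel2"], 30)

  # imputation uses the no-information dosage: a fully uninformative sample
  # (if forced through) would predict at the prior; check via fraction-1
  # robustness equivalence instead of special-casing
  expect_error(predict_novel(fit, bench$X[, 1:40]), "missing model loci")

  reefs <- setNames(rep(c("north", "south"), 5), rownames(bench$X))
  p3 <- predict_novel(fit, bench$X, one_per_reef = TRUE, reef_map = reefs,
                      seed = 21)
  expect_equal(nrow(p3), 2)
  expect_setequal(p3$reef, c("north", "south"))
  p3b <- predict_novel(fit, bench$X, one_per_reef = TRUE, reef_map = reefs,
                       seed = 21)
  expect_identical(p3, p3b)
})

test_that("regional comparison is calibrated under random assignment and
           detects a shifted region", {
  set.seed(14)
  p_rand <- sapply(1:100, function(i) {
    preds <- data.frame(sample_id = sprintf("s%d", 1:30),
                        predicted_residual = rnorm(30))
    regions <- setNames(sample(rep(c("A", "B", "C"), 10)), preds$sample_id)
    compare_regions(preds, regions)$anova$p_value[1]
  })
  expect_gt(mean(p_rand < 0.05), 0.05 - 3 * sqrt(0.05 * 0.95 / 100))
  expect_lt(mean(p_rand < 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / 100))

  preds <- data.frame(sample_id = sprintf("s%d", 1:30),
                      predicted_residual = c(rnorm(15), rnorm(15) + 2))
  regions <- setNames(rep(c("A", "B"), each = 15), preds$sample_id)
  out <- compare_regions(preds, regions,
                         training_residuals = rnorm(10))
  expect_lt(out$anova$p_value[1], 0.001)
  expect_s3_class(out$distribution_test, "htest")

  expect_error(compare_regions(preds, setNames(rep("A", 30),
                                               preds$sample_id)),
               "at least 2 regions")
})

test_that("external validation recovers exact linear relationships and
           rejects tiny overlaps", {
  preds <- data.frame(sample_id = sprintf("s%d", 1:11),
                      predicted_residual = seq(-1, 1, length.out = 11))
  decline <- setNames(3 * preds$predicted_residual - 10, preds$sample_id)
  v <- suppressWarnings(validate_external(preds, decline))  # exact fit
  expect_equal(v$r_squared, 1, tolerance = 1e-12)
  expect_equal(v$slope, 3, tolerance = 1e-9)
  expect_equal(v$n, 11)

  expect_error(validate_external(preds[1:2, ], decline), "at least 3")

  set.seed(2)
  p_null <- sapply(1:60, function(i) {
    dec <- setNames(rnorm(11), preds$sample_id)
    validate_external(preds, dec)$p_value
  })
  expect_gt(mean(p_null < 0.05), 0.05 - 3 * sqrt(0.05 * 0.95 / 60))
  expect_lt(mean(p_null < 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / 60))
})
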