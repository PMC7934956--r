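test_that("fragment means, transforms and site-corrected residuals are exact
           on constructed tables", {
  fr <- data.frame(fragment_id = c("f1", "f2", "f3"),
                   genotype_id = c("g1", "g2", "g1"),
                   site_id = c("sA", "sA", "sB"),
                   survived = TRUE)
  sv <- make_survey(fr, list(c(1, 1, 1), c(2, 2, 2), c(0, 1, 2)))
  ph <- suppressWarnings(compute_phenotypes(sv))  # sB has one fragment
  expect_equal(ph$mean_score[ph$fragment_id == "f1"], 1.0)
  expect_equal(ph$transformed_score[ph$fragment_id == "f1"], 1.0)
  # two fragments at sA with means 1 and 2 -> residuals -0.5, +0.5
  expect_equal(ph$residual[ph$fragment_id == "f1"], -0.5)
  expect_equal(ph$residual[ph$fragment_id == "f2"], 0.5)
  expect_equal(ph$transformed_score^2, ph$mean_score, tolerance = 1e-12)

  # all fragments at a site sharing one mean -> all residuals zero
  fr2 <- data.frame(fragment_id = c("f1", "f2"), genotype_id = c("g1", "g2"),
                    site_id = "sA", survived = TRUE)
  ph2 <- compute_phenotypes(make_survey(fr2, list(2, 2)))
  expect_true(all(ph2$residual == 0))
})

test_that("per-site residuals sum to zero on simulated data", {
  d <- simulate_design(small_cfg(seed = 21, n_early_mortality = 12))
  ph <- compute_phenotypes(d$surveys)
  sums <- tapply(ph$residual, ph$site_id, sum)
  expect_true(all(abs(sums) < 1e-9))
  gr <- genotype_residuals(ph)
  expect_length(gr, 6)
  expect_true(!is.null(names(gr)))
})

test_that("degenerate survey tables are rejected with informative errors", {
  fr <- data.frame(fragment_id = "f1", genotype_id = "g1", site_id = "sA",
                   survived = TRUE)
  sv <- make_survey(fr, list(c(1, 2, 3)))
  sv$score <- NA_real_
  expect_error(compute_phenotypes(sv), "f1")

  lone <- make_survey(data.frame(fragment_id = c("f1", "f2"),
                                 genotype_id = c("g1", "g2"),
                                 site_id = c("sA", "sB"), survived = TRUE),
                      list(1, 2))
  expect_warning(compute_phenotypes(lone), "fewer than 2")

  bad <- make_survey(fr, list(c(1, 2, 3)))
  names(bad)[names(bad) == "score"] <- "value"
  expect_error(compute_phenotypes(bad), "score")
})

test_that("two-way ANOVA decomposes the total sum of squares on balanced
           designs and is shift invariant", {
  d <- simulate_design(small_cfg(seed = 31))
  ph <- compute_phenotypes(d$surveys)
  tab <- gxe_anova(ph)
  expect_identical(tab$term,
                   c("genotype", "site", "genotype:site", "Residuals"))
  ss_total <- sum((ph$transformed_score - mean(ph$transformed_score))^2)
  expect_equal(sum(tab$sumsq), ss_total, tolerance = 1e-8)
  expect_true(all(tab$sumsq >= 0))
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1, na.rm = TRUE))

  ph_shift <- ph
  ph_shift$transformed_score <- ph$transformed_score + 5
  tab_shift <- gxe_anova(ph_shift)
  expect_equal(tab$statistic, tab_shift$statistic, tolerance = 1e-10)
  expect_equal(tab$p_value, tab_shift$p_value, tolerance = 1e-10)
})

test_that("interaction power and genotype-effect calibration behave as the
           variance components dictate", {
  # strong interaction detected nearly always
  p_strong <- sapply(1:20, function(s) {
    cfg <- small_cfg(var_gxe = 1.5, var_noise = 0.2, seed = 400 + s)
    gxe_anova(compute_phenotypes(simulate_design(cfg)$surveys))$p_value[3]
  })
  expect_gte(mean(p_strong < 0.001), 0.95)

  # residuals permuted across genotypes: one-way rejection near alpha
  d <- simulate_design(small_cfg(seed = 51))
  ph <- compute_phenotypes(d$surveys)
  set.seed(8)
  p_perm <- sapply(1:100, function(i) {
    ph$residual <- sample(ph$residual)
    genotype_effect_anova(ph)$p_value[1]
  })
  expect_gt(mean(p_perm < 0.05), 0.05 - 3 * sqrt(0.05 * 0.95 / 100))
  expect_lt(mean(p_perm < 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / 100))

  # one genotype shifted by +1 on the residual scale is detected
  ph2 <- compute_phenotypes(simulate_design(small_cfg(seed = 52))$surveys)
  ph2$residual[ph2$genotype_id == "g01"] <-
    ph2$residual[ph2$genotype_id == "g01"] + 1
  expect_lt(genotype_effect_anova(ph2)$p_value[1], 0.01)
})

test_that("constant responses and single-level factors follow the NA/error
           contract", {
  fr <- data.frame(fragment_id = sprintf("f%d", 1:8),
                   genotype_id = rep(c("g1", "g2"), 4),
                   site_id = rep(c("sA", "sB"), each = 4),
                   survived = TRUE)
  sv <- make_survey(fr, as.list(rep(2, 8)))
  ph <- compute_phenotypes(sv)
  expect_warning(tab <- gxe_anova(ph), "constant")
  expect_true(all(is.na(tab$statistic)))

  ph_one <- ph[ph$genotype_id == "g1", ]
  expect_error(genotype_effect_anova(ph_one), "single level")
  expect_error(gxe_anova(ph_one), "single level")
})

test_that("bleaching-mortality summaries match constructed outcomes", {
  # mortality a step function of score: combinations below the step have a
  # perfectly explained (zero) mortality fraction
  fr <- expand.grid(genotype_id = sprintf("g%d", 1:4),
                    site_id = sprintf("s%s", c("A", "B")),
                    rep = 1:6, stringsAsFactors = FALSE)
  fr$fragment_id <- sprintf("f%03d", seq_len(nrow(fr)))
  scores <- ifelse(fr$genotype_id %in% c("g1", "g2"), 0, 3)
  fr$survived <- scores < 2
  sv <- make_survey(fr[, c("fragment_id", "genotype_id", "site_id",
                           "survived")],
                    as.list(scores))
  ph <- compute_phenotypes(sv)
  rep_ <- bleaching_mortality(ph, sv)
  expect_equal(rep_$full_mortality_fraction, 0.5)
  expect_lt(rep_$wilcox$p.value, 0.01)
  # below the step everything survives: mortality fraction constant at 0,
  # so the regression is skipped (zero variance in the response handled by lm)
  expect_true(all(rep_$combination_table$mortality %in% c(0, 1)))

  # all combinations fully dead: regression skipped, fraction = 1
  fr$survived <- FALSE
  sv_dead <- make_survey(fr[, c("fragment_id", "genotype_id", "site_id",
                                "survived")], as.list(scores))
  ph_dead <- compute_phenotypes(sv_dead)
  expect_message(rep_dead <- bleaching_mortality(ph_dead, sv_dead),
                 "skipped")
  expect_equal(rep_dead$full_mortality_fraction, 1.0)
  expect_null(rep_dead$regression)
  expect_null(rep_dead$wilcox)
})
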