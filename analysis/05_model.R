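#!/usr/bin/env Rscript
# Stage 5: random-forest prediction of bleaching residuals from the
# retained loci -- repeated 2-fold cross-validation (20 repeats, mtry = 1),
# missing-data robustness at the no-information dosage, prediction of a
# synthetic novel cohort with the >= 30-called-loci filter and one-per-reef
# subsampling, a regional ANOVA, and a synthetic external-validation
# regression.

library(coralGxE)

seed <- 42
geno <- read_beagle("results/data/genotypes.beagle.tsv")
gr_tab <- read.csv("results/phenotype/genotype_residuals.csv")
gr <- setNames(gr_tab$mean_residual, gr_tab$genotype_id)
screen <- read.delim("results/screen/locus_screen.tsv")
out <- "results/model"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

dos <- compute_dosage(geno)
kept <- screen$locus[screen$retained]
X <- t(dos[kept, , drop = FALSE])

fit <- fit_and_crossvalidate(X, gr, model_config(seed = seed))
print(fit)
write.table(data.frame(resample = seq_along(fit$cv_r2), r2 = fit$cv_r2),
            file.path(out, "cv_r2.tsv"), sep = "\t", row.names = FALSE,
            quote = FALSE)
write.table(data.frame(locus = names(fit$importance),
                       importance = unname(fit$importance)),
            file.path(out, "importances.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)

rob <- missing_data_robustness(fit, fractions = c(0.1, 0.25, 0.5),
                               n_replicates = 100, seed = seed)
write.table(rob, file.path(out, "robustness.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
cat(sprintf(paste0("variance explained with half the loci at the ",
                   "no-information dosage: %.1f +/- %.1f%% ",
                   "(100 replicates)\n"),
            100 * rob$mean_ve[rob$fraction == 0.5],
            100 * rob$sd_ve[rob$fraction == 0.5]))

# synthetic novel cohort: genotypes drawn at the model loci's estimated
# allele frequencies (no phenotype link), heavy per-cell missingness as in
# opportunistically sequenced restoration samples
set.seed(stream_seed(seed, 21L))
n_new <- 60
freq <- fit$no_info / 2
newX <- sapply(kept, function(l) rbinom(n_new, 2, freq[l]))
rownames(newX) <- sprintf("novel%03d", seq_len(n_new))
newX[matrix(runif(length(newX)) < 0.40, nrow(newX))] <- NA
reefs <- setNames(sample(sprintf("reef%02d", 1:20), n_new, replace = TRUE),
                  rownames(newX))
region_of_reef <- setNames(
  sample(c("north", "central", "south"), 20, replace = TRUE),
  sprintf("reef%02d", 1:20))

preds <- predict_novel(fit, newX, min_called = 30, one_per_reef = TRUE,
                       reef_map = reefs, seed = seed)
preds$region <- unname(region_of_reef[preds$reef])
write.csv(preds, file.path(out, "novel_predictions.csv"),
          row.names = FALSE, quote = FALSE)
cat(sprintf(paste0("novel cohort: %d samples predicted after filtering ",
                   "and one-per-reef subsampling\n"), nrow(preds)))

reg <- compare_regions(preds, setNames(preds$region, preds$sample_id),
                       training_residuals = gr)
write.table(reg$anova, file.path(out, "region_anova.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
cat(sprintf(paste0("regional ANOVA: F = %.2f, p = %.3g; predictions vs ",
                   "training distribution: p = %.3g\n"),
            reg$anova$statistic[1], reg$anova$p_value[1],
            reg$distribution_test$p.value))

# synthetic external validation: a physiological decline proxy built as a
# noisy linear function of the true phenotype for 11 held-out-style samples
set.seed(stream_seed(seed, 22L))
val_pred <- predict_novel(fit, newX, min_called = 30)
val_pred <- val_pred[seq_len(min(11, nrow(val_pred))), ]
signal <- 15 * val_pred$predicted_residual
decline <- setNames(-20 + signal + rnorm(length(signal),
                                         sd = 1.6 * sd(signal)),
                    val_pred$sample_id)
val <- validate_external(val_pred, decline)
cat(sprintf("synthetic validation regression: R^2 = %.3f, p = %.3g, n = %d\n",
            val$r_squared, val$p_value, val$n))
write.csv(val$data, file.path(out, "validation_scatter.csv"),
          row.names = FALSE, quote = FALSE)
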