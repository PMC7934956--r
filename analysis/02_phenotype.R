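#!/usr/bin/env Rscript
# Stage 2: fragment phenotypes, site-corrected residuals, the genotype x
# environment ANOVA, the genotype-effect ANOVA on residuals, and the
# bleaching-mortality relationships.

library(coralGxE)

surveys <- read_survey("results/data/surveys.csv")
out <- "results/phenotype"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

phenos <- compute_phenotypes(surveys)
write.csv(phenos, file.path(out, "phenotypes.csv"), row.names = FALSE,
          quote = FALSE)
gr <- genotype_residuals(phenos)
write.csv(data.frame(genotype_id = names(gr), mean_residual = unname(gr)),
          file.path(out, "genotype_residuals.csv"), row.names = FALSE,
          quote = FALSE)

gxe <- gxe_anova(phenos)
gea <- genotype_effect_anova(phenos)
write.table(gxe, file.path(out, "anova_gxe.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(gea, file.path(out, "anova_genotype_residual.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)

cat("two-way ANOVA of sqrt-transformed mean scores:\n")
cat(sprintf("  genotype      F = %5.2f, p = %.3g\n", gxe$statistic[1],
            gxe$p_value[1]))
cat(sprintf("  site          F = %5.2f, p = %.3g\n", gxe$statistic[2],
            gxe$p_value[2]))
cat(sprintf("  genotype:site F = %5.2f, p = %.3g\n", gxe$statistic[3],
            gxe$p_value[3]))
cat(sprintf("one-way ANOVA of residuals on genotype: F = %.2f, p = %.3g\n",
            gea$statistic[1], gea$p_value[1]))

mort <- bleaching_mortality(phenos, surveys)
write.csv(mort$combination_table, file.path(out, "combination_mortality.csv"),
          row.names = FALSE, quote = FALSE)
cat(sprintf("bleaching score, died vs survived: Wilcoxon p = %.3g\n",
            mort$wilcox$p.value))
cat(sprintf("combinations with 100%% mortality: %.1f%%\n",
            100 * mort$full_mortality_fraction))
if (!is.null(mort$regression))
  cat(sprintf(paste0("mortality ~ bleaching among partial-mortality",
                     " combinations: R^2 = %.2f, p = %.3g (n = %d)\n"),
              mort$regression$r_squared, mort$regression$p_value,
              mort$regression$n))
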