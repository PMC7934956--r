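#!/usr/bin/env Rscript
# Stage 4: expected secondary-allele dosages from the genotype-probability
# table and the per-locus correlation screen against genotype mean
# residuals (simple linear regression, loci with p >= 0.01 removed).

library(coralGxE)

geno <- read_beagle("results/data/genotypes.beagle.tsv")
gr_tab <- read.csv("results/phenotype/genotype_residuals.csv")
gr <- setNames(gr_tab$mean_residual, gr_tab$genotype_id)
out <- "results/screen"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

dos <- compute_dosage(geno)
screen <- screen_loci(dos, gr, p_threshold = 0.01)
write.table(screen, file.path(out, "locus_screen.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)

kept <- screen[screen$retained, ]
cat(sprintf(paste0("screened %d loci (of %d; %d dropped for missing calls, ",
                   "%d constant): retained %d at p < 0.01\n"),
            nrow(screen), length(geno$markers),
            attr(screen, "n_dropped_missing"),
            attr(screen, "n_dropped_constant"), nrow(kept)))
cat(sprintf("retained |r| range: %.3f - %.3f\n",
            min(abs(kept$r)), max(abs(kept$r))))

# true causal loci among the retained set, for the parameter-recovery record
causal <- read.delim("results/data/causal_loci.tsv")
cat(sprintf("%d of %d causal loci retained\n",
            sum(causal$locus %in% kept$locus), nrow(causal)))
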