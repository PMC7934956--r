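# coralGxE

Genotype-by-environment analysis of coral bleaching tolerance, as a tested,
reusable R pipeline.

Reef restoration increasingly depends on moving coral genotypes between
sites, which only works if a genotype's heat tolerance measured in one
environment says something about its performance in another. The analysis
implemented here addresses that question for a reciprocal transplant of
*Acropora cervicornis*: 10 genotypes outplanted to 8 sites (one genotype
missing at one site), 10 replicate fragments per combination, scored 0-3
for bleaching at three timepoints during a severe warming event, with
hourly temperature loggers per site and reduced-representation sequencing
of the 10 genotypes. The package is for quantitative ecologists and
restoration geneticists who want to run, extend, or stress-test this kind
of analysis: every stage also runs on a synthetic-data generator with known
ground truth, so the whole pipeline is verifiable without the original
field data.

## What it computes

* **Site-corrected phenotype.** Per fragment, the mean bleaching score
  over timepoints; the *residual bleaching score* is that mean minus the
  site mean, so high values mean "bleached more than its neighbours".
  Averaged over a genotype's fragments across all sites it becomes a
  multi-site integrative measure of relative heat tolerance.
* **ANOVAs.** A fixed-effects two-way ANOVA (genotype, site,
  genotype x site, Type-I sequential SS) of the square-root-transformed
  mean score tests for a genotype-by-environment interaction; a one-way
  ANOVA of residuals tests for a genotype effect. Rank-sum tests and a
  mortality~bleaching regression link the phenotype to December survival.
* **Thermal stress.** Per-site summary statistics, exceedance hours above
  30.5/31/32/33 degrees C, degree heating weeks accumulated as `T - MMM`
  over hours with `T >= MMM + 1` (MMM = 28.7 C; an alternative accumulation
  rule is a config switch), and a PCA of daily mean temperatures across
  sites.
* **Dosage and screen.** Genotype-probability triplets (p_aa, p_ab, p_bb)
  become expected secondary-allele dosages `p_ab + 2 p_bb` in [0, 2];
  per-locus regressions of the genotype residual phenotype on dosage keep
  loci with two-sided p < 0.01.
* **Genomic prediction.** A random-forest regression (mtry = 1, 500 trees)
  of residuals on the retained dosages, with repeated 2-fold
  cross-validation (20 repeats; per-fold R-squared = squared correlation of
  held-out predictions vs observations), a missing-data robustness
  procedure that sets random locus subsets to the no-information dosage
  (2 x allele frequency), novel-sample prediction with a >= 30-called-loci
  filter and one-per-reef subsampling, a regional ANOVA and an external
  validation regression.
* **Enrichment.** Flat rank-based Mann-Whitney enrichment of the per-locus
  correlation coefficients over GO-style categories, BH-adjusted within
  namespace, flagged at FDR 0.05 and 0.1.

## Worked example

```r
library(coralGxE)

cfg    <- sim_config(seed = 42)          # the full study dimensions
design <- simulate_design(cfg)
phenos <- compute_phenotypes(design$surveys)
gxe_anova(phenos)
#>            term  df      sumsq statistic      p_value
#> 1      genotype   9   3.814183  1.429774 1.716392e-01
#> 2          site   7  22.907448 11.040458 3.786280e-13
#> 3 genotype:site  62  26.546515  1.444522 1.807698e-02
#> 4     Residuals 589 174.584969        NA           NA
```

At this seed the interaction is clear (p = 0.018): genotypes rank
differently at different sites, so a single-site phenotype would mislead a
restoration choice. The genomic predictor on the matched screened-locus
structure (58 loci whose dosage correlations with the phenotype lie in
0.73-0.89):

```r
bench <- benchmark_dataset(seed = 42)
fit   <- fit_and_crossvalidate(bench$X, bench$y, model_config(seed = 42))
print(fit)
#> random-forest tolerance predictor: 58 loci, 10 samples
#> mean resampled R^2 = 0.927 (n = 40), final-fit R^2 = 0.958
missing_data_robustness(fit, fractions = 0.5, n_replicates = 100, seed = 42)
#>   fraction   mean_ve       sd_ve n_replicates
#> 1      0.5 0.9551489 0.009691247          100
```

Mean resampled R-squared of 0.93 means held-out genotypes' relative heat
tolerance is predicted almost to the precision of the phenotype itself, and
the prediction survives half the loci reverting to their no-information
dosage -- the polygenic signal is heavily redundant.

## The analysis workflow

Numbered drivers under `analysis/` run the full study end to end and write
their tables under `results/`:

| script | what it does |
| --- | --- |
| `01_simulate.R` | synthetic experiment: surveys, genotype probabilities (beagle TSV), hourly temperatures, ground truth |
| `02_phenotype.R` | phenotypes, residuals, two-way and one-way ANOVAs, bleaching-mortality summaries |
| `03_thermal.R` | per-site thermal table, experiment-wide DHW, daily-mean PCA |
| `04_screen.R` | dosages and the p < 0.01 locus screen |
| `05_model.R` | forest fit + repeated CV, robustness, novel-cohort predictions, regional ANOVA, synthetic validation |
| `06_enrich.R` | rank-based enrichment with a planted positive-control category |

```sh
for f in analysis/0*.R; do Rscript "$f"; done
```

On the default seed this prints, among other things: 790 fragments in 79
combinations with 668 in the analysis set; site F = 11.0 (p < 1e-12) and
interaction F = 1.44 (p = 0.018); per-site DHW between 6.3 and 13.7
C-weeks; 155 of 13,337 loci retained; mean resampled R-squared 0.914 with
96.3 +/- 0.6% variance explained at half-missing loci; and the planted
enrichment category recovered at adjusted p ~ 1e-26.

`run_pipeline(pipeline_config(), out_dir)` runs the same stages as one call
with a deterministic directory layout, a resolved-config record, and a
`_FAILED` sentinel naming the stage on error.

## File formats

CSV/TSV with explicit headers throughout; every writer round-trips through
its reader. Genotype probabilities use the beagle genotype-likelihood
dialect: tab-separated, header `marker allele1 allele2` followed by each
sample ID repeated three times, one row per locus holding the (aa, ab, bb)
triplets. A small conformance fixture ships at
`inst/extdata/example.beagle.tsv`:

```r
gp <- read_beagle(system.file("extdata", "example.beagle.tsv",
                              package = "coralGxE"))
compute_dosage(gp)
```

Surveys: `fragment_id, genotype_id, site_id, timepoint, score,
early_mortality, survived_december`. Temperatures: `site_id, timestamp`
(ISO-8601), `temp_c`.

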