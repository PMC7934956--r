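#' Read and write pipeline tables
#'
#' Plain CSV/TSV readers and writers with explicit headers and named-column
#' validation, so every table round-trips through its reader without loss.
#'
#' @param path file path.
#' @name table_io
NULL

#' @rdname table_io
#' @export
read_survey <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("fragment_id", "genotype_id", "site_id", "timepoint",
                      "score", "early_mortality", "survived_december"),
                "survey CSV")
  df$early_mortality <- as.logical(df$early_mortality)
  df$survived_december <- as.logical(df$survived_december)
  df
}

#' @rdname table_io
#' @param surveys survey table.
#' @export
write_survey <- function(surveys, path) {
  utils::write.csv(surveys, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_temperature <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("site_id", "timestamp", "temp_c"), "temperature CSV")
  df$timestamp <- as.POSIXct(df$timestamp, tz = "UTC",
                             format = "%Y-%m-%dT%H:%M:%S")
  if (any(is.na(df$timestamp)))
    stop("temperature CSV has unparseable ISO-8601 timestamps")
  df
}

#' @rdname table_io
#' @param series temperature table.
#' @export
write_temperature <- function(series, path) {
  out <- series
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Default pipeline configuration
#'
#' Nested configuration for [run_pipeline()]: the synthetic-design section,
#' model section, screening threshold, robustness fractions and enrichment
#' settings. Unknown keys in `overrides` are rejected.
#'
#' @param overrides named list of overrides, nested like the defaults.
#' @param seed master seed propagated to every stage.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(overrides = list(), seed = 1) {
  defaults <- list(
    sim = list(),
    model = list(n_folds = 2, n_repeats = 20, trees = 500, mtry = 1),
    screen = list(p_threshold = 0.01),
    robustness = list(fractions = c(0.1, 0.25, 0.5), n_replicates = 100),
    enrichment = list(min_size = 5, max_frac = 0.10,
                      fdr_levels = c(0.05, 0.1), n_categories = 60),
    seed = seed)
  allowed <- list(sim = setdiff(names(formals(sim_config)), "seed"),
                  model = names(defaults$model),
                  screen = names(defaults$screen),
                  robustness = names(defaults$robustness),
                  enrichment = names(defaults$enrichment))
  cfg <- defaults
  for (section in names(overrides)) {
    if (!section %in% names(defaults))
      stop("unknown configuration section: ", section)
    if (section == "seed") { next }
    bad <- setdiff(names(overrides[[section]]), allowed[[section]])
    if (length(bad) > 0)
      stop("unknown key(s) in section '", section, "': ",
           paste(bad, collapse = ", "))
    cfg[[section]] <- utils::modifyList(defaults[[section]],
                                        overrides[[section]],
                                        keep.null = TRUE)
  }
  cfg$seed <- if ("seed" %in% names(overrides)) overrides$seed else seed
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full synthetic analysis pipeline
#'
#' simulate -> phenotypes and ANOVAs -> dosage and locus screen -> forest
#' fit with repeated cross-validation -> missing-data robustness ->
#' rank-based enrichment, writing every table, the resolved configuration
#' and the seed into a deterministic directory layout. A failed stage
#' leaves a `_FAILED` sentinel file naming the stage.
#'
#' @param cfg a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param quiet suppress progress messages.
#' @return (invisibly) a list with the in-memory results of every stage.
#' @export
run_pipeline <- function(cfg = pipeline_config(), out_dir, quiet = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sentinel <- file.path(out_dir, "_FAILED")
  if (file.exists(sentinel)) unlink(sentinel)
  log_path <- file.path(out_dir, "pipeline.log")
  t0 <- Sys.time()
  logline <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                   paste0(...))
    cat(msg, "\n", file = log_path, append = TRUE)
    if (!quiet) message(msg)
  }
  stage <- "configuration"
  result <- tryCatch({
    stage <- "simulate"
    scfg <- do.call(sim_config, c(cfg$sim, list(seed = cfg$seed)))
    jsonlite::write_json(
      list(config = unclass(cfg), resolved_sim = unclass(scfg),
           seed = cfg$seed),
      file.path(out_dir, "resolved_config.json"),
      auto_unbox = TRUE, digits = NA, null = "null", force = TRUE)
    design <- simulate_design(scfg)
    write_survey(design$surveys, file.path(out_dir, "surveys.csv"))
    gen <- simulate_genotypes(scfg, design$truth)
    write_beagle(gen$geno, file.path(out_dir, "genotypes.beagle.tsv"))
    jsonlite::write_json(
      list(genotype_effects = as.list(design$truth$genotype_effects),
           site_effects = as.list(design$truth$site_effects),
           true_residual_by_genotype =
             as.list(design$truth$true_residual_by_genotype),
           causal_loci = gen$causal),
      file.path(out_dir, "ground_truth.json"), auto_unbox = TRUE,
      digits = NA)
    logline("simulate: ", nrow(design$surveys), " survey rows, ",
            length(gen$geno$markers), " loci")

    stage <- "phenotype"
    phenos <- compute_phenotypes(design$surveys)
    utils::write.csv(phenos, file.path(out_dir, "phenotypes.csv"),
                     row.names = FALSE, quote = FALSE)
    gxe <- gxe_anova(phenos)
    gea <- genotype_effect_anova(phenos)
    utils::write.table(gxe, file.path(out_dir, "anova_gxe.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(gea, file.path(out_dir, "anova_genotype.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    mort <- bleaching_mortality(phenos, design$surveys)
    logline("phenotype: ", nrow(phenos), " fragments; interaction p = ",
            signif(gxe$p_value[3], 3))

    stage <- "screen"
    dos <- compute_dosage(gen$geno)
    gr <- genotype_residuals(phenos)
    screen <- NULL; fit <- NULL; rob <- NULL; enr <- NULL
    if (length(gr) < 3) {
      warning("fewer than 3 genotypes: locus screen, model and enrichment ",
              "stages skipped (low power)")
      logline("screen: skipped (low power)")
    } else {
    screen <- screen_loci(dos, gr, p_threshold = cfg$screen$p_threshold)
    utils::write.table(screen, file.path(out_dir, "locus_screen.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    logline("screen: ", sum(screen$retained), " loci retained of ",
            nrow(screen))

    stage <- "fit"
    kept <- screen$locus[screen$retained]
    X <- t(dos[kept, , drop = FALSE])
    mcfg <- do.call(model_config, c(cfg$model, list(seed = cfg$seed)))
    if (nrow(X) < 2 * mcfg$n_folds || length(kept) < 2) {
      warning("too few samples or retained loci for a cross-validated ",
              "model; fit and robustness stages skipped (low power)")
      logline("fit: skipped (low power)")
    } else {
    fit <- fit_and_crossvalidate(X, gr, mcfg)
    utils::write.table(
      data.frame(locus = names(fit$importance),
                 importance = unname(fit$importance)),
      file.path(out_dir, "importances.tsv"), sep = "\t",
      row.names = FALSE, quote = FALSE)
    utils::write.table(
      data.frame(resample = seq_along(fit$cv_r2), r2 = fit$cv_r2),
      file.path(out_dir, "cv_r2.tsv"), sep = "\t", row.names = FALSE,
      quote = FALSE)
    logline("fit: mean resampled R^2 = ", round(mean(fit$cv_r2), 3),
            ", final-fit R^2 = ", round(fit$final_r2, 3))

    stage <- "robustness"
    rob <- missing_data_robustness(
      fit, fractions = cfg$robustness$fractions,
      n_replicates = cfg$robustness$n_replicates, seed = cfg$seed)
    utils::write.table(rob, file.path(out_dir, "robustness.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    }

    stage <- "enrichment"
    annot <- simulate_annotations(
      screen$locus, n_categories = cfg$enrichment$n_categories,
      planted = list(category = "GO:0000001",
                     loci = utils::head(screen$locus[
                       order(-abs(screen$r))], 40)),
      seed = cfg$seed)
    r_by_locus <- stats::setNames(screen$r, screen$locus)
    enr <- mwu_enrichment(r_by_locus, annot,
                          min_size = cfg$enrichment$min_size,
                          max_frac = cfg$enrichment$max_frac,
                          fdr_levels = cfg$enrichment$fdr_levels)
    utils::write.table(enr, file.path(out_dir, "enrichment.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    logline("enrichment: ", sum(enr$padj < 0.1), " categories at FDR < 0.1")
    }
    logline("done in ",
            round(as.numeric(Sys.time() - t0, units = "secs"), 1), " s")

    list(config = cfg, design = design, genotypes = gen, phenos = phenos,
         anova_gxe = gxe, anova_genotype = gea, mortality = mort,
         screen = screen, fit = fit, robustness = rob, enrichment = enr)
  }, error = function(e) {
    writeLines(paste0("stage: ", stage, "\n", conditionMessage(e)),
               sentinel)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}
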