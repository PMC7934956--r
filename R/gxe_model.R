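#' Configuration for the genomic tolerance predictor
#'
#' Repeated 2-fold cross-validation (20 repeats -> 40 held-out folds) of a
#' random-forest regression with one candidate predictor per split
#' (mtry = 1), which restricts the ensemble toward additive effects -- the
#' conservative protocol appropriate at ten samples with dozens of
#' correlated predictors. 500 trees is large enough that resampled R^2
#' changes by well under 0.01 between tree-count doublings on the default
#' synthetic data.
#'
#' @param n_folds folds per repeat (>= 2).
#' @param n_repeats number of repeats of the fold split.
#' @param trees trees per forest.
#' @param mtry candidate predictors per split.
#' @param seed integer seed for the fold splits and forests.
#' @return list of class `model_config`.
#' @export
model_config <- function(n_folds = 2, n_repeats = 20, trees = 500,
                         mtry = 1, seed = 1) {
  stopifnot(n_folds >= 2, n_repeats >= 1, trees >= 1, mtry >= 1)
  structure(list(n_folds = n_folds, n_repeats = n_repeats, trees = trees,
                 mtry = mtry, seed = seed), class = "model_config")
}

cor_r2 <- function(pred, obs) {
  if (stats::sd(pred) == 0 || stats::sd(obs) == 0) return(NA_real_)
  stats::cor(pred, obs)^2
}

# randomForest warns about regression on tiny training folds; that is the
# protocol here (5-sample folds), so the specific warning is muffled
quiet_forest <- function(...) {
  withCallingHandlers(
    randomForest::randomForest(...),
    warning = function(w) {
      if (grepl("five or fewer unique values", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
}

#' Fit the random-forest tolerance predictor with repeated cross-validation
#'
#' For each repeat, samples are split at random into `n_folds` (nearly)
#' equal folds; a forest trained on each fold's complement predicts the held
#' -out fold and the squared Pearson correlation between held-out
#' predictions and observations is recorded (one R^2 per held-out fold;
#' `n_folds * n_repeats` in total). A resample whose held-out predictions
#' are constant is recorded as R^2 = 0 and flagged. The final model is
#' trained on all samples; its in-sample R^2 and sorted variable
#' importances (node-purity) are reported.
#'
#' @param X samples x loci dosage matrix (no missing cells), rows named by
#'   sample, columns by locus.
#' @param y named numeric vector of genotype mean residuals, aligned to
#'   `rownames(X)`.
#' @param cfg a [model_config()].
#' @return object of class `gxe_forest_fit`: forest, loci, cv_r2 (length
#'   `n_folds * n_repeats`), cv_flagged, final_r2, importance (sorted
#'   decreasing), no_info (per-locus no-information dosage = column mean =
#'   2 x estimated secondary-allele frequency), config.
#' @export
fit_and_crossvalidate <- function(X, y, cfg = model_config()) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("X must have no missing cells; impute or drop first")
  if (!is.null(names(y)) && !is.null(rownames(X))) y <- y[rownames(X)]
  n <- nrow(X)
  if (n < 2 * cfg$n_folds)
    stop(sprintf("need at least %d samples for %d-fold cross-validation",
                 2 * cfg$n_folds, cfg$n_folds))
  set.seed(stream_seed(cfg$seed, 11L))
  cv_r2 <- numeric(0); flagged <- logical(0)
  for (rep_i in seq_len(cfg$n_repeats)) {
    fold <- sample(rep(seq_len(cfg$n_folds), length.out = n))
    for (f in seq_len(cfg$n_folds)) {
      train <- fold != f
      rf <- quiet_forest(x = X[train, , drop = FALSE], y = y[train],
                         ntree = cfg$trees, mtry = cfg$mtry)
      pred <- stats::predict(rf, X[!train, , drop = FALSE])
      r2 <- cor_r2(pred, y[!train])
      flagged <- c(flagged, is.na(r2))
      cv_r2 <- c(cv_r2, ifelse(is.na(r2), 0, r2))
    }
  }
  forest <- quiet_forest(x = X, y = y, ntree = cfg$trees, mtry = cfg$mtry,
                         importance = FALSE)
  final_pred <- stats::predict(forest, X)
  final_r2 <- cor_r2(final_pred, y)
  imp <- randomForest::importance(forest)[, "IncNodePurity"]
  structure(list(forest = forest, loci = colnames(X),
                 cv_r2 = cv_r2, cv_flagged = flagged,
                 final_r2 = ifelse(is.na(final_r2), 0, final_r2),
                 importance = sort(imp, decreasing = TRUE),
                 no_info = colMeans(X), training_X = X, training_y = y,
                 config = cfg),
            class = "gxe_forest_fit")
}

#' @export
print.gxe_forest_fit <- function(x, ...) {
  cat(sprintf(paste0("random-forest tolerance predictor: %d loci, %d",
                     " samples\nmean resampled R^2 = %.3f (n = %d),",
                     " final-fit R^2 = %.3f\n"),
              length(x$loci), nrow(x$training_X), mean(x$cv_r2),
              length(x$cv_r2), x$final_r2))
  invisible(x)
}

#' Robustness of predictions to missing genotype data
#'
#' For each missing fraction f and each replicate, a random subset of
#' `round(f * n_loci)` model loci is replaced -- for every sample -- by the
#' no-information dosage (the dosage implied by the genotype prior alone),
#' the fitted forest predicts, and the variance explained is the squared
#' correlation of predictions with the observed phenotypes. Constant
#' predictions score 0 by contract.
#'
#' @param fit a [fit_and_crossvalidate()] result.
#' @param X,y training matrix and phenotypes (default: those stored in the
#'   fit).
#' @param fractions missing fractions in `[0, 1]`.
#' @param n_replicates replicates per fraction (default 100).
#' @param noinfo `"frequency"` uses 2 x the locus secondary-allele
#'   frequency (the posterior mean under a frequency prior when no reads are
#'   observed); `"flat"` uses dosage 1.
#' @param seed integer seed.
#' @return data frame (fraction, mean_ve, sd_ve, n_replicates).
#' @export
missing_data_robustness <- function(fit, X = fit$training_X,
                                    y = fit$training_y,
                                    fractions = c(0.1, 0.25, 0.5),
                                    n_replicates = 100,
                                    noinfo = c("frequency", "flat"),
                                    seed = fit$config$seed) {
  noinfo <- match.arg(noinfo)
  stopifnot(all(fractions >= 0 & fractions <= 1))
  X <- as.matrix(X)
  ni <- if (noinfo == "frequency") fit$no_info else
    stats::setNames(rep(1, length(fit$loci)), fit$loci)
  set.seed(stream_seed(seed, 12L))
  p <- length(fit$loci)
  rows <- lapply(fractions, function(f) {
    k <- round(f * p)
    ve <- vapply(seq_len(n_replicates), function(rep_i) {
      Xm <- X
      if (k > 0) {
        sel <- sample.int(p, k)
        Xm[, sel] <- matrix(ni[sel], nrow(X), k, byrow = TRUE)
      }
      pred <- stats::predict(fit$forest, Xm)
      r2 <- cor_r2(pred, y)
      ifelse(is.na(r2), 0, r2)
    }, numeric(1))
    data.frame(fraction = f, mean_ve = mean(ve), sd_ve = stats::sd(ve),
               n_replicates = n_replicates)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Predict bleaching tolerance for novel samples
#'
#' Aligns a new dosage matrix to the model loci, drops samples with fewer
#' than `min_called` informative loci, imputes remaining missing cells with
#' the no-information dosage, optionally keeps one randomly chosen sample
#' per reef (to limit sampling bias), and predicts.
#'
#' @param fit a [fit_and_crossvalidate()] result.
#' @param newX samples x loci matrix; `NA` marks uninformative cells.
#'   Columns must include every model locus.
#' @param min_called minimum informative model loci per sample (default 30).
#' @param one_per_reef keep one sample per reef (seeded uniform choice).
#' @param reef_map named character vector sample -> reef (required when
#'   `one_per_reef`, used for the reef column otherwise if given).
#' @param seed seed for the per-reef subsampling.
#' @return data frame (sample_id, predicted_residual, n_called_loci, reef).
#' @export
predict_novel <- function(fit, newX, min_called = 30, one_per_reef = FALSE,
                          reef_map = NULL, seed = fit$config$seed) {
  newX <- as.matrix(newX)
  absent <- setdiff(fit$loci, colnames(newX))
  if (length(absent) > 0)
    stop("newX is missing model loci: ",
         paste(utils::head(absent, 5), collapse = ", "),
         if (length(absent) > 5) sprintf(" (and %d more)",
                                         length(absent) - 5) else "")
  newX <- newX[, fit$loci, drop = FALSE]
  n_called <- rowSums(!is.na(newX))
  drop <- n_called < min_called
  if (any(drop))
    message(sum(drop), " sample(s) dropped with fewer than ", min_called,
            " called loci")
  newX <- newX[!drop, , drop = FALSE]
  n_called <- n_called[!drop]
  if (nrow(newX) == 0)
    return(data.frame(sample_id = character(0),
                      predicted_residual = numeric(0),
                      n_called_loci = integer(0), reef = character(0)))
  for (j in seq_len(ncol(newX))) {
    miss <- is.na(newX[, j])
    if (any(miss)) newX[miss, j] <- fit$no_info[j]
  }
  reef <- if (!is.null(reef_map)) unname(reef_map[rownames(newX)]) else
    rep(NA_character_, nrow(newX))
  if (one_per_reef) {
    if (is.null(reef_map)) stop("one_per_reef requires reef_map")
    set.seed(stream_seed(seed, 13L))
    keep <- unlist(lapply(split(seq_len(nrow(newX)), reef), function(idx)
      idx[sample.int(length(idx), 1)]))
    keep <- sort(unname(keep))
    newX <- newX[keep, , drop = FALSE]
    n_called <- n_called[keep]
    reef <- reef[keep]
  }
  data.frame(sample_id = rownames(newX),
             predicted_residual = unname(stats::predict(fit$forest, newX)),
             n_called_loci = unname(n_called), reef = reef,
             stringsAsFactors = FALSE)
}

#' Regional comparison of predicted tolerance
#'
#' One-way ANOVA of predicted residuals on region, plus (optionally) a
#' Welch two-sample t-test comparing the prediction distribution with the
#' training residual distribution.
#'
#' @param predictions data frame from [predict_novel()].
#' @param region_map named character vector sample -> region.
#' @param training_residuals optional numeric vector of training phenotypes.
#' @return list: `anova` (table as in [gxe_anova()]), `distribution_test`
#'   (htest or NULL), `n_regions_used`.
#' @export
compare_regions <- function(predictions, region_map,
                            training_residuals = NULL) {
  region <- region_map[predictions$sample_id]
  ok <- !is.na(region)
  y <- predictions$predicted_residual[ok]
  region <- region[ok]
  tab <- table(region)
  small <- names(tab)[tab < 2]
  if (length(small) > 0) {
    message("region(s) with fewer than 2 samples skipped: ",
            paste(small, collapse = ", "))
    keep <- !(region %in% small)
    y <- y[keep]; region <- region[keep]
  }
  if (length(unique(region)) < 2)
    stop("need at least 2 regions with at least 2 samples each")
  if (stats::sd(y) == 0) stop("constant predictions: ANOVA undefined")
  fit <- stats::aov(y ~ factor(region))
  out <- anova_table(fit)
  out$term <- c("region", "Residuals")
  dt <- NULL
  if (!is.null(training_residuals))
    dt <- stats::t.test(y, training_residuals)
  list(anova = out, distribution_test = dt,
       n_regions_used = length(unique(region)))
}

#' External validation against an independent bleaching proxy
#'
#' Linear regression of an external physiological decline measure (e.g.
#' relative decline in fv/fm, the photosystem-II maximum quantum yield)
#' on predicted bleaching residuals for the overlapping samples.
#'
#' @param predictions data frame from [predict_novel()] (or any frame with
#'   sample_id and predicted_residual).
#' @param phenotype_decline named numeric vector sample -> percent change.
#' @return list: r_squared, p_value, n, slope, intercept, data (scatter
#'   frame for plotting).
#' @export
validate_external <- function(predictions, phenotype_decline) {
  common <- intersect(predictions$sample_id, names(phenotype_decline))
  if (length(common) < 3)
    stop("need at least 3 overlapping samples; found ", length(common))
  pred <- predictions$predicted_residual[match(common,
                                               predictions$sample_id)]
  dec <- phenotype_decline[common]
  fit <- stats::lm(dec ~ pred)
  sm <- summary(fit)
  list(r_squared = sm$r.squared,
       p_value = stats::coef(sm)["pred", "Pr(>|t|)"],
       n = length(common),
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       data = data.frame(sample_id = common, predicted_residual = pred,
                         decline = unname(dec), stringsAsFactors = FALSE))
}
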