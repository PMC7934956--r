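#' Fragment-level phenotypes and site-corrected bleaching residuals
#'
#' For each fragment: the mean ordinal bleaching score over its timepoints,
#' its square-root transform (the ANOVA response), the mean of fragment
#' means at its site (site mean), and the residual bleaching score =
#' fragment mean - site mean. High residuals indicate more bleaching than
#' the site average; the residual is the site-corrected, multi-site
#' integrative phenotype ("relative heat tolerance"). Residuals are computed
#' on the untransformed mean-score scale; the square-root transform is
#' applied only to the two-way ANOVA response.
#'
#' @param surveys survey table (fragment_id, genotype_id, site_id,
#'   timepoint, score, early_mortality, survived_december).
#' @param drop_early_mortality exclude fragments flagged as early
#'   transplant mortality (default `TRUE`).
#' @return data frame, one row per fragment, with columns fragment_id,
#'   genotype_id, site_id, n_timepoints, mean_score, transformed_score,
#'   site_mean, residual; attribute `genotype_residuals` holds the named
#'   vector of per-genotype mean residuals.
#' @export
compute_phenotypes <- function(surveys, drop_early_mortality = TRUE) {
  check_columns(surveys, c("fragment_id", "genotype_id", "site_id",
                           "timepoint", "score"), "survey table")
  if (drop_early_mortality && "early_mortality" %in% names(surveys))
    surveys <- surveys[!surveys$early_mortality, , drop = FALSE]
  if (nrow(surveys) == 0) stop("no fragments remain after filtering")
  valid <- !is.na(surveys$score)
  empty <- setdiff(unique(surveys$fragment_id),
                   unique(surveys$fragment_id[valid]))
  if (length(empty) > 0)
    stop("fragment(s) with zero scored timepoints: ",
         paste(empty, collapse = ", "))
  if (any(!is.finite(surveys$score[valid]) | surveys$score[valid] < 0 |
            surveys$score[valid] > 3))
    stop("scores must be finite and within [0, 3]")

  agg <- stats::aggregate(score ~ fragment_id + genotype_id + site_id,
                          data = surveys[valid, ],
                          FUN = function(x) c(mean(x), length(x)))
  phenos <- data.frame(fragment_id = agg$fragment_id,
                       genotype_id = agg$genotype_id,
                       site_id = agg$site_id,
                       n_timepoints = agg$score[, 2],
                       mean_score = agg$score[, 1],
                       stringsAsFactors = FALSE)
  phenos$transformed_score <- sqrt(phenos$mean_score)

  site_n <- table(phenos$site_id)
  if (any(site_n < 2))
    warning("site(s) with fewer than 2 fragments: ",
            paste(names(site_n)[site_n < 2], collapse = ", "))
  sm <- tapply(phenos$mean_score, phenos$site_id, mean)
  phenos$site_mean <- as.numeric(sm[phenos$site_id])
  phenos$residual <- phenos$mean_score - phenos$site_mean
  phenos <- phenos[order(phenos$fragment_id), ]
  rownames(phenos) <- NULL
  gr <- tapply(phenos$residual, phenos$genotype_id, mean)
  attr(phenos, "genotype_residuals") <- stats::setNames(as.numeric(gr),
                                                        names(gr))
  phenos
}

#' Per-genotype mean residual bleaching scores
#'
#' @param phenos output of [compute_phenotypes()].
#' @return named numeric vector, one mean residual per genotype.
#' @export
genotype_residuals <- function(phenos) {
  gr <- attr(phenos, "genotype_residuals")
  if (is.null(gr)) {
    g <- tapply(phenos$residual, phenos$genotype_id, mean)
    gr <- stats::setNames(as.numeric(g), names(g))
  }
  gr
}

anova_table <- function(fit) {
  s <- summary(fit)[[1]]
  data.frame(term = trimws(rownames(s)), df = s$Df, sumsq = s$`Sum Sq`,
             statistic = s$`F value`, p_value = s$`Pr(>F)`,
             stringsAsFactors = FALSE)
}

#' Two-way genotype x site ANOVA of transformed bleaching scores
#'
#' Fixed-effects ANOVA of the square-root-transformed fragment mean score on
#' genotype, site and their interaction, with Type-I (sequential) sums of
#' squares in that order. The design may have one missing genotype x site
#' cell; at that mild imbalance the sequential decomposition is essentially
#' order-insensitive.
#'
#' @param phenos output of [compute_phenotypes()].
#' @return data frame with one row per term (genotype, site, interaction,
#'   residuals): df, sum of squares, F, p. If the response is constant the F
#'   and p columns are `NA` with a warning.
#' @export
gxe_anova <- function(phenos) {
  g <- factor(phenos$genotype_id); s <- factor(phenos$site_id)
  if (nlevels(g) < 2) stop("genotype factor has a single level")
  if (nlevels(s) < 2) stop("site factor has a single level")
  y <- phenos$transformed_score
  if (stats::sd(y) == 0) {
    warning("constant response: F statistics undefined")
    return(data.frame(term = c("genotype", "site", "genotype:site",
                               "Residuals"),
                      df = NA_integer_, sumsq = 0,
                      statistic = NA_real_, p_value = NA_real_))
  }
  fit <- stats::aov(y ~ g + s + g:s)
  out <- anova_table(fit)
  out$term <- c("genotype", "site", "genotype:site", "Residuals")
  out
}

#' One-way ANOVA of residual bleaching scores on genotype
#'
#' @param phenos output of [compute_phenotypes()].
#' @return ANOVA table as in [gxe_anova()].
#' @export
genotype_effect_anova <- function(phenos) {
  g <- factor(phenos$genotype_id)
  if (nlevels(g) < 2) stop("genotype factor has a single level")
  y <- phenos$residual
  if (stats::sd(y) == 0) {
    warning("constant response: F statistics undefined")
    return(data.frame(term = c("genotype", "Residuals"), df = NA_integer_,
                      sumsq = 0, statistic = NA_real_, p_value = NA_real_))
  }
  fit <- stats::aov(y ~ g)
  out <- anova_table(fit)
  out$term <- c("genotype", "Residuals")
  out
}

#' Bleaching-mortality relationships
#'
#' Three summaries linking the bleaching phenotype to December survival:
#' (i) a two-sided Wilcoxon rank-sum test of fragment mean score between
#' fragments that died and fragments that survived; (ii) among genotype x
#' site combinations without complete mortality, a linear regression of the
#' combination's mortality fraction on its mean bleaching score; (iii) the
#' fraction of combinations with 100% mortality.
#'
#' @param phenos output of [compute_phenotypes()].
#' @param surveys the survey table carrying `survived_december`.
#' @return list: `wilcox` (htest or NULL), `regression`
#'   (list(r_squared, p_value, n) or NULL), `full_mortality_fraction`,
#'   `combination_table`.
#' @export
bleaching_mortality <- function(phenos, surveys) {
  check_columns(surveys, c("fragment_id", "survived_december"),
                "survey table")
  surv <- surveys[!duplicated(surveys$fragment_id),
                  c("fragment_id", "survived_december")]
  m <- merge(phenos, surv, by = "fragment_id")
  wt <- NULL
  if (length(unique(m$survived_december)) < 2) {
    message("one survival class is empty; rank-sum test skipped")
  } else {
    # normal approximation with continuity correction (ordinal scores tie)
    wt <- stats::wilcox.test(m$mean_score[!m$survived_december],
                             m$mean_score[m$survived_december],
                             exact = FALSE, correct = TRUE)
  }
  combo <- stats::aggregate(
    cbind(mortality = !m$survived_december, score = m$mean_score),
    by = list(genotype_id = m$genotype_id, site_id = m$site_id), FUN = mean)
  full_frac <- mean(combo$mortality == 1)
  reg <- NULL
  partial <- combo[combo$mortality < 1, , drop = FALSE]
  if (nrow(partial) >= 3 && stats::sd(partial$score) > 0) {
    fit <- stats::lm(mortality ~ score, data = partial)
    sm <- summary(fit)
    reg <- list(r_squared = sm$r.squared,
                p_value = stats::coef(sm)["score", "Pr(>|t|)"],
                n = nrow(partial))
  } else {
    message("too few partial-mortality combinations; regression skipped")
  }
  list(wilcox = wt, regression = reg,
       full_mortality_fraction = full_frac, combination_table = combo)
}
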