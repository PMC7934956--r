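#' Read a locus-to-category annotation table
#'
#' Two-column TSV (locus_id, semicolon-separated category IDs), optionally
#' joined to a category-name table (category, namespace, name).
#'
#' @param path annotation TSV with header.
#' @param names_path optional category-name TSV with header.
#' @return data frame (locus_id, category, namespace, name), one row per
#'   locus-category pair.
#' @export
read_annotations <- function(path, names_path = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  check_columns(df, c("locus_id", "categories"), "annotation table")
  cats <- strsplit(df$categories, ";", fixed = TRUE)
  out <- data.frame(locus_id = rep(df$locus_id, lengths(cats)),
                    category = trimws(unlist(cats)),
                    stringsAsFactors = FALSE)
  out <- out[out$category != "", ]
  if (!is.null(names_path)) {
    nm <- utils::read.table(names_path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    check_columns(nm, c("category", "namespace", "name"),
                  "category-name table")
    out <- merge(out, nm, by = "category", all.x = TRUE)
  }
  if (!"namespace" %in% names(out)) out$namespace <- "BP"
  if (!"name" %in% names(out)) out$name <- out$category
  out[, c("locus_id", "category", "namespace", "name")]
}

#' Rank-based Mann-Whitney category enrichment of locus correlations
#'
#' A flat analogue of rank-based GO enrichment on a continuous per-locus
#' statistic: loci are ranked by their dosage-phenotype correlation
#' coefficient and each category's members are compared with non-members by
#' a one-sided Mann-Whitney U (Wilcoxon rank-sum) test in the direction of
#' high correlations; the opposite tail is reported as a separate column.
#' Ties are handled by midranks (the test is computed on the r values
#' directly, so any strictly monotone transform of r gives identical
#' results). Benjamini-Hochberg adjustment is applied within each category
#' namespace. Categories smaller than `min_size`, larger than
#' `max_frac` of the universe, or spanning the whole universe are excluded.
#'
#' @param r_by_locus named numeric vector locus -> correlation coefficient;
#'   the names define the universe.
#' @param annot annotation data frame (locus_id, category, namespace, name);
#'   annotations for loci outside the universe are dropped.
#' @param min_size minimum category size (default 5).
#' @param max_frac maximum category size as a fraction of the universe
#'   (default 0.10).
#' @param fdr_levels FDR levels at which significance flags are emitted.
#' @return data frame per category: category, namespace, name, n_loci,
#'   U statistic, p_high (one-sided, members enriched for high r), p_low
#'   (opposite tail), direction, padj (BH on p_high within namespace), and
#'   one logical column per FDR level.
#' @export
mwu_enrichment <- function(r_by_locus, annot, min_size = 5, max_frac = 0.10,
                           fdr_levels = c(0.05, 0.1)) {
  if (is.null(names(r_by_locus))) stop("r_by_locus must be named by locus")
  if (any(!is.finite(r_by_locus))) stop("r values must be finite")
  universe <- names(r_by_locus)
  annot <- annot[annot$locus_id %in% universe, , drop = FALSE]
  annot <- annot[!duplicated(annot[, c("locus_id", "category")]), ]
  sizes <- table(annot$category)
  keep <- names(sizes)[sizes >= min_size &
                         sizes <= max_frac * length(universe) &
                         sizes < length(universe)]
  annot <- annot[annot$category %in% keep, , drop = FALSE]
  if (length(unique(annot$category)) < 2)
    stop("fewer than 2 categories remain after size filtering")
  info <- annot[!duplicated(annot$category),
                c("category", "namespace", "name")]
  members <- split(annot$locus_id, annot$category)
  rows <- lapply(names(members), function(cat) {
    inset <- universe %in% members[[cat]]
    wt_hi <- stats::wilcox.test(r_by_locus[inset], r_by_locus[!inset],
                                alternative = "greater", exact = FALSE,
                                correct = TRUE)
    wt_lo <- stats::wilcox.test(r_by_locus[inset], r_by_locus[!inset],
                                alternative = "less", exact = FALSE,
                                correct = TRUE)
    data.frame(category = cat, n_loci = sum(inset),
               statistic = unname(wt_hi$statistic),
               p_high = wt_hi$p.value, p_low = wt_lo$p.value,
               direction = ifelse(wt_hi$p.value <= wt_lo$p.value,
                                  "high_r", "low_r"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- merge(info, out, by = "category")
  out$padj <- NA_real_
  for (ns in unique(out$namespace)) {
    idx <- out$namespace == ns
    out$padj[idx] <- stats::p.adjust(out$p_high[idx], method = "BH")
  }
  for (q in fdr_levels)
    out[[sprintf("sig_fdr_%g", q)]] <- out$padj < q
  out <- out[order(out$padj, out$p_high), ]
  rownames(out) <- NULL
  out
}
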