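#' Genotype-probability table
#'
#' Container for per-sample, per-locus posterior probabilities of the three
#' diploid genotypes (aa, ab, bb) at biallelic loci, as exported by
#' genotype-likelihood callers in the beagle genotype-likelihood dialect.
#'
#' @param markers character vector of locus IDs.
#' @param samples character vector of sample IDs.
#' @param p numeric array `length(markers) x length(samples) x 3` of
#'   (p_aa, p_ab, p_bb); each triplet must sum to 1 within 1e-6.
#' @param informative optional logical matrix marking cells backed by
#'   sequencing evidence (default all `TRUE`).
#' @param freq optional per-locus secondary-allele frequency.
#' @return an object of class `geno_prob`.
#' @export
geno_prob <- function(markers, samples, p, informative = NULL, freq = NULL) {
  stopifnot(length(dim(p)) == 3, dim(p)[1] == length(markers),
            dim(p)[2] == length(samples), dim(p)[3] == 3)
  if (any(p < -1e-9 | p > 1 + 1e-9))
    stop("genotype probabilities must lie in [0, 1]")
  sums <- matrix(p[, , 1] + p[, , 2] + p[, , 3],
                 length(markers), length(samples))
  if (any(abs(sums - 1) > 1e-6)) {
    bad <- which(abs(sums - 1) > 1e-6, arr.ind = TRUE)[1, ]
    stop(sprintf("triplet does not sum to 1 at locus %s, sample %s",
                 markers[bad[1]], samples[bad[2]]))
  }
  if (is.null(informative))
    informative <- matrix(TRUE, length(markers), length(samples))
  structure(list(markers = markers, samples = samples, p = p,
                 informative = informative, freq = freq),
            class = "geno_prob")
}

#' @export
print.geno_prob <- function(x, ...) {
  cat(sprintf("geno_prob: %d loci x %d samples (%.1f%% informative cells)\n",
              length(x$markers), length(x$samples),
              100 * mean(x$informative)))
  invisible(x)
}

#' Write a genotype-probability table in beagle genotype-likelihood format
#'
#' Tab-separated; header `marker allele1 allele2` followed by each sample ID
#' repeated three times; one row per locus with the (aa, ab, bb) triplets.
#'
#' @param x a [geno_prob()] object.
#' @param path output file.
#' @export
write_beagle <- function(x, path) {
  L <- length(x$markers); S <- length(x$samples)
  m <- matrix(0, L, 3 * S)
  for (s in seq_len(S)) m[, 3 * (s - 1) + 1:3] <- x$p[, s, ]
  df <- data.frame(marker = x$markers, allele1 = 0L, allele2 = 1L,
                   m, check.names = FALSE)
  names(df)[-(1:3)] <- rep(x$samples, each = 3)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a beagle genotype-likelihood file
#'
#' @param path beagle-dialect TSV (see [write_beagle()]).
#' @return a [geno_prob()] object; cells whose triplet equals the locus-mean
#'   triplet exactly are still marked informative (the format carries no
#'   missingness flag).
#' @export
read_beagle <- function(path) {
  hdr <- strsplit(readLines(path, n = 1), "\t")[[1]]
  if (length(hdr) < 6 || hdr[1] != "marker")
    stop("not a beagle genotype-likelihood file: header must start with 'marker'")
  df <- utils::read.table(path, sep = "\t", header = TRUE, skip = 0,
                          check.names = FALSE, stringsAsFactors = FALSE)
  samples <- unique(hdr[-(1:3)])
  S <- length(samples); L <- nrow(df)
  if (ncol(df) != 3 + 3 * S)
    stop("beagle file has a malformed sample-triplet layout")
  vals <- as.matrix(df[, -(1:3)])
  p <- array(0, dim = c(L, S, 3))
  for (s in seq_len(S)) p[, s, ] <- vals[, 3 * (s - 1) + 1:3]
  geno_prob(df$marker, samples, p)
}

#' Expected secondary-allele dosage from genotype probabilities
#'
#' dosage = P(ab) + 2 P(bb), a real number in `[0, 2]` that carries genotype
#' uncertainty into downstream analysis without hard-calling. Uninformative
#' cells are returned as `NA`.
#'
#' @param probs a [geno_prob()] object.
#' @param tol maximum tolerated deviation of a triplet sum from 1.
#' @return numeric matrix loci x samples with a `"freq"` attribute holding
#'   the per-locus estimated secondary-allele frequency (mean dosage / 2,
#'   over informative cells).
#' @export
compute_dosage <- function(probs, tol = 1e-3) {
  stopifnot(inherits(probs, "geno_prob"))
  L <- length(probs$markers); S <- length(probs$samples)
  sums <- matrix(probs$p[, , 1] + probs$p[, , 2] + probs$p[, , 3], L, S)
  if (any(abs(sums - 1) > tol)) {
    bad <- which(abs(sums - 1) > tol, arr.ind = TRUE)[1, ]
    stop(sprintf("triplet sum off by more than %g at locus %s, sample %s",
                 tol, probs$markers[bad[1]], probs$samples[bad[2]]))
  }
  d <- matrix(probs$p[, , 2] + 2 * probs$p[, , 3], L, S)
  d[!probs$informative] <- NA_real_
  dimnames(d) <- list(probs$markers, probs$samples)
  attr(d, "freq") <- rowMeans(d, na.rm = TRUE) / 2
  d
}

#' Screen loci by correlation with genotype-level bleaching residuals
#'
#' Per locus, a simple linear regression of the genotype mean residual on
#' dosage across genotypes; the two-sided regression p-value (t test on the
#' correlation, n-2 df) drives retention. Loci with any missing genotype are
#' dropped (a complete-cases requirement mirroring callers that demand a
#' locus be present in all samples), as are zero-variance loci.
#'
#' @param dosages loci x samples matrix from [compute_dosage()].
#' @param genotype_residuals named numeric vector, one value per sample.
#' @param p_threshold retention threshold on the two-sided p (default 0.01).
#' @return data frame (locus, r, p, retained) with attributes
#'   `n_dropped_missing` and `n_dropped_constant`.
#' @export
screen_loci <- function(dosages, genotype_residuals, p_threshold = 0.01) {
  samples <- colnames(dosages)
  if (is.null(samples) || !all(samples %in% names(genotype_residuals)))
    stop("dosage columns must be named and present in genotype_residuals")
  y <- genotype_residuals[samples]
  n <- length(y)
  if (n < 3) stop("need at least 3 genotypes with dosage and residual")
  complete <- rowSums(is.na(dosages)) == 0
  n_missing <- sum(!complete)
  d <- dosages[complete, , drop = FALSE]
  sd_d <- apply(d, 1, stats::sd)
  nonconst <- sd_d > 0 & stats::sd(y) > 0
  n_const <- sum(!nonconst)
  d <- d[nonconst, , drop = FALSE]
  dz <- (d - rowMeans(d)) / apply(d, 1, stats::sd)
  yz <- as.vector(scale(y))
  r <- as.vector(dz %*% yz) / (n - 1)
  r <- pmin(1, pmax(-1, r))
  tstat <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  out <- data.frame(locus = rownames(d), r = r, p = p,
                    retained = p < p_threshold, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_dropped_missing") <- n_missing
  attr(out, "n_dropped_constant") <- n_const
  out
}
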