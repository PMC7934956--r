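#' Derive a stream-specific seed from a master seed
#'
#' All randomness in the package flows from a single master seed. Each stage
#' (design, genotypes, temperature, annotations, model fitting, ...) draws its
#' own seed from the master via a fixed multiplicative hash, so any stage can
#' be reproduced in isolation without replaying the stages before it.
#'
#' @param seed master seed (integer).
#' @param stream small integer identifying the consumer stream.
#' @return an integer seed in [1, 2^31 - 2].
#' @export
stream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  # Lehmer-style step keeps everything inside 32-bit integer range
  x <- (abs(as.double(seed)) * 48271 + 3923 * as.double(stream)) %% 2147483629
  as.integer(x + 1)
}

# rescale a vector of draws to mean 0 and an exact sample variance
centre_scale <- function(x, target_var) {
  x <- x - mean(x)
  if (target_var == 0 || length(x) < 2) return(x * 0)
  v <- sum(x^2) / (length(x) - 1)
  if (v == 0) stop("degenerate draw: cannot scale zero-variance effects")
  x * sqrt(target_var / v)
}

# double-centre a matrix and rescale so sum(m^2)/((nr-1)(nc-1)) == target_var
centre_scale_interaction <- function(m, target_var) {
  m <- sweep(m, 1, rowMeans(m))
  m <- sweep(m, 2, colMeans(m))
  if (target_var == 0) return(m * 0)
  denom <- (nrow(m) - 1) * (ncol(m) - 1)
  v <- sum(m^2) / denom
  if (v == 0) stop("degenerate draw: cannot scale zero-variance interactions")
  m * sqrt(target_var / v)
}

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}
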