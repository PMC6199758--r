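#' Column z-scoring with an invertible standardizer
#'
#' Centers each column to mean zero and scales to unit sample standard
#' deviation (`n - 1` denominator), the normalization applied to both the
#' predictor and response blocks before regression so that no variable is
#' weighted by its raw magnitude.  Zero-variance columns are mapped to
#' all-zeros and flagged rather than producing division by zero.
#'
#' @param M Numeric matrix with at least two rows.
#' @return A list of class `standardizer`: `z` (the standardized matrix),
#'   `center`, `scale` (per column; `scale` reported as 0 for flagged
#'   columns), and `constant` (logical flags).
#' @export
standardize_columns <- function(M) {
  M <- as.matrix(M)
  if (nrow(M) < 2) stop_bad("standardization needs at least 2 rows, got %d", nrow(M))
  ctr <- colMeans(M)
  s <- apply(M, 2, sd)
  constant <- s == 0
  s_safe <- ifelse(constant, 1, s)
  Z <- sweep(sweep(M, 2, ctr), 2, s_safe, "/")
  Z[, constant] <- 0
  structure(list(z = Z, center = ctr, scale = ifelse(constant, 0, s),
                 constant = constant),
            class = "standardizer")
}

## apply a fitted standardizer to new data (columns already aligned)
std_transform <- function(st, M) {
  s_safe <- ifelse(st$constant, 1, st$scale)
  Z <- sweep(sweep(as.matrix(M), 2, st$center), 2, s_safe, "/")
  Z[, st$constant] <- 0
  Z
}

## invert: standardized scale back to original units; constant columns
## return their training value
std_invert <- function(st, Z) {
  s_safe <- ifelse(st$constant, 0, st$scale)   # 0 wipes any z in constant cols
  sweep(sweep(as.matrix(Z), 2, s_safe, "*"), 2, st$center, "+")
}
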