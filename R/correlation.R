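## Correlation primitives used by the screens.  p-values come from the
## t transform t = r * sqrt((n-2) / (1-r^2)) on n-2 degrees of freedom
## (two-sided), the form used throughout the screening analysis; Spearman
## is the Pearson coefficient of mid-ranks (average ranks for ties).

cor_t_pvalue <- function(r, n) {
  r2 <- pmin(r^2, 1 - 1e-300)
  tt <- r * sqrt((n - 2) / (1 - r2))
  2 * pt(-abs(tt), n - 2)
}

#' Pearson correlation with a t-based two-sided p-value
#'
#' @param x,y Numeric vectors of equal length `n >= 3`.
#' @return A one-row tibble: `estimate` (clipped to \[-1, 1\] against
#'   rounding), `p.value`, `n`, `evaluable`.  Zero variance in either
#'   argument yields `evaluable = FALSE` with `NA` statistics rather than
#'   an error, so screens can skip degenerate cells.
#' @export
cor_pearson <- function(x, y) {
  if (length(x) != length(y)) stop_bad("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop_bad("need n >= 3 observations, got %d", n)
  if (sd(x) == 0 || sd(y) == 0) {
    return(tibble(estimate = NA_real_, p.value = NA_real_, n = n, evaluable = FALSE))
  }
  r <- max(-1, min(1, cor(x, y)))
  tibble(estimate = r, p.value = cor_t_pvalue(r, n), n = n, evaluable = TRUE)
}

#' Spearman rank correlation with a t-approximation p-value
#'
#' Computes the Pearson coefficient of mid-ranks (ties receive average
#' ranks) and a two-sided p-value from the t approximation on `n - 2`
#' degrees of freedom.  The approximation is asymptotic; with few wells
#' and heavily tied covariates its extreme tail is optimistic (see the
#' package vignette).
#'
#' @inheritParams cor_pearson
#' @return A one-row tibble: `estimate`, `p.value`, `n`, `evaluable`.
#' @export
cor_spearman <- function(x, y) {
  if (length(x) != length(y)) stop_bad("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop_bad("need n >= 3 observations, got %d", n)
  rx <- rank(x)
  ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) {
    return(tibble(estimate = NA_real_, p.value = NA_real_, n = n, evaluable = FALSE))
  }
  r <- max(-1, min(1, cor(rx, ry)))
  tibble(estimate = r, p.value = cor_t_pvalue(r, n), n = n, evaluable = TRUE)
}
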