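## Biomarker identification from the fitted regression: analytes whose
## loading vectors sit closest to the survival-timepoint loading vectors,
## and the consensus with the Pearson screen.

#' Rank analytes by loading-vector proximity to the survival timepoints
#'
#' For each analyte, computes the similarity between its two-dimensional
#' loading vector and every timepoint loading vector and keeps the
#' maximum.  The default metric is the cosine of the angle (in \[-1, 1\]):
#' loading magnitude conflates variance with direction, so the angle alone
#' measures how co-directed an analyte is with the survival block.  A
#' Euclidean option (`proximity = -min distance`, ranks unchanged in
#' spirit) is available for sensitivity analysis.  Analytes whose
#' similarity to every timepoint is negative are flagged
#' `anti_correlated`.  Degenerate analytes (zero-length loading vectors,
#' e.g. constant columns) are excluded with a warning, as are zero-length
#' timepoint vectors from the comparison set.
#'
#' @param model A `plsr_fit` with at least 2 components.
#' @param top_k Optionally return only the `top_k` closest analytes.
#' @param metric `"cosine"` (default) or `"euclidean"`.
#' @return Tibble ordered by rank: `analyte`, `proximity`, `rank`
#'   (1 = closest; ties broken by analyte name), `anti_correlated`.
#'   Attribute `metric` records the choice.
#' @export
rank_biomarkers <- function(model, top_k = NULL, metric = c("cosine", "euclidean")) {
  stopifnot(inherits(model, "plsr_fit"))
  metric <- match.arg(metric)
  if (model$ncomp < 2) stop_bad("proximity ranking needs at least 2 components")
  XL <- model$x_loadings[, 1:2, drop = FALSE]
  YL <- model$y_loadings[, 1:2, drop = FALSE]
  xn <- sqrt(rowSums(XL^2))
  yn <- sqrt(rowSums(YL^2))
  keep_y <- yn > 0
  if (!any(keep_y)) stop_bad("all timepoint loading vectors are zero")
  degenerate <- xn == 0
  if (any(degenerate))
    rlang::warn(sprintf("excluding %d degenerate analyte(s) with zero loading: %s",
                        sum(degenerate), paste(model$analytes[degenerate], collapse = ", ")))
  YLk <- YL[keep_y, , drop = FALSE]
  ynk <- yn[keep_y]
  res <- purrr::map_dfr(which(!degenerate), function(j) {
    if (metric == "cosine") {
      sims <- (YLk %*% XL[j, ]) / (ynk * xn[j])
      tibble(analyte = model$analytes[j], proximity = max(sims),
             anti_correlated = all(sims < 0))
    } else {
      d <- sqrt(rowSums(sweep(YLk, 2, XL[j, ])^2))
      sims <- (YLk %*% XL[j, ]) / (ynk * xn[j])
      tibble(analyte = model$analytes[j], proximity = -min(d),
             anti_correlated = all(sims < 0))
    }
  })
  res <- res |>
    dplyr::arrange(dplyr::desc(.data$proximity), .data$analyte) |>
    dplyr::mutate(rank = dplyr::row_number(), .after = "proximity")
  if (!is.null(top_k)) res <- head(res, top_k)
  attr(res, "metric") <- metric
  res
}

#' Consensus biomarkers of the Pearson screen and the PLSR ranking
#'
#' The intersection of the two hit lists, ordered by analyte name —
#' analytes flagged by two independent statistical routes are the
#' strongest survival-correlated candidates.
#'
#' @param pearson_hits Character vector of aggregate hits from the
#'   per-timepoint Pearson screen.
#' @param plsr_hits Character vector of top-ranked analytes from the
#'   loading-proximity ranking (conventionally the top `k` with `k` equal
#'   to the Pearson hit-list size).
#' @return Sorted character vector of the overlap; attributes
#'   `n_pearson`, `n_plsr`, `n_overlap` report the sizes.
#' @export
consensus_biomarkers <- function(pearson_hits, plsr_hits) {
  out <- sort(intersect(pearson_hits, plsr_hits))
  attr(out, "n_pearson") <- length(unique(pearson_hits))
  attr(out, "n_plsr") <- length(unique(plsr_hits))
  attr(out, "n_overlap") <- length(out)
  out
}
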