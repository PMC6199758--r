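## The two correlation screens: per-timepoint Pearson correlation of
## analyte expression against survival proportions, and a Spearman rank
## screen of per-well expression against substratum stiffness under
## Bonferroni correction.

#' Per-timepoint Pearson screen of expression against survival
#'
#' For every (analyte, timepoint) pair, correlates the analyte's
#' concentrations across groups with the groups' survival proportions at
#' that timepoint.  A cell *hits* when the joint criterion
#' `|rho| > rho_threshold` and `p < alpha` holds; an analyte is an
#' aggregate hit when the criterion holds at at least the aggregation
#' fraction of *evaluable* timepoints.  Timepoints where survival does not
#' vary across groups (e.g. every group still at 1.0 early on) are
#' non-evaluable and excluded — Pearson correlation is undefined there —
#' as are analytes with zero variance.
#'
#' Note that with five groups the two-sided critical `|rho|` at
#' `alpha = 0.05` is about 0.878 (t distribution, 3 df), so the default
#' joint criterion behaves as a single constraint at that design size;
#' both thresholds are still applied literally.
#'
#' @param expr Expression tibble (groups x analytes).
#' @param surv Survival tibble sharing `expr`'s group labels and order.
#' @param rho_threshold Minimum `|rho|` for a cell hit (default 0.875).
#' @param alpha Significance threshold for a cell hit (default 0.05).
#' @param aggregation `"majority"` (criterion at >= 50% of evaluable
#'   timepoints; the default), `"all"`, `"any"`, or a numeric fraction in
#'   (0, 1].
#' @return An object of class `survival_screen`: list with `cells`
#'   (tibble: analyte, timepoint, rho, p.value, n, evaluable, hit),
#'   `analytes` (tibble: analyte, n_evaluable, frac_hit, hit) and the
#'   thresholds used.  [tidy()] returns the cell table, [glance()] the
#'   threshold/summary row, [screen_hits()] the aggregate hit names.
#' @export
screen_survival_correlation <- function(expr, surv, rho_threshold = 0.875,
                                        alpha = 0.05, aggregation = "majority") {
  expr <- validate_expression(expr)
  surv <- validate_survival(surv)
  if (!identical(expr$group, surv$group))
    stop_bad("expression and survival tables must share group labels and order")
  n <- nrow(expr)
  if (n < 3) stop_bad("need at least 3 groups, got %d", n)
  frac <- switch(as.character(aggregation),
                 majority = 0.5, all = 1, any = .Machine$double.eps,
                 {
                   f <- suppressWarnings(as.numeric(aggregation))
                   if (is.na(f) || f <= 0 || f > 1)
                     stop_bad("aggregation must be 'majority', 'all', 'any' or a fraction in (0,1]")
                   f
                 })
  X <- wide_matrix(expr)
  S <- wide_matrix(surv)
  tp <- survival_timepoints(surv)
  sd_x <- apply(X, 2, sd)
  sd_s <- apply(S, 2, sd)
  evaluable <- outer(sd_x > 0, sd_s > 0, `&`)
  R <- suppressWarnings(cor(X, S))          # p x q, NaN where degenerate
  R[!evaluable] <- NA_real_
  R <- pmin(pmax(R, -1), 1)
  P <- cor_t_pvalue(R, n)
  hit <- !is.na(R) & abs(R) > rho_threshold & P < alpha
  cells <- tibble(
    analyte = rep(colnames(X), times = length(tp)),
    timepoint = rep(tp, each = ncol(X)),
    rho = as.vector(R), p.value = as.vector(P), n = n,
    evaluable = as.vector(evaluable), hit = as.vector(hit))
  analytes <- cells |>
    dplyr::group_by(.data$analyte) |>
    dplyr::summarise(n_evaluable = sum(.data$evaluable),
                     frac_hit = ifelse(sum(.data$evaluable) > 0,
                                       sum(.data$hit) / sum(.data$evaluable), 0),
                     hit = .data$n_evaluable > 0 & .data$frac_hit >= frac,
                     .groups = "drop") |>
    dplyr::arrange(match(.data$analyte, colnames(X)))
  if (all(!evaluable)) rlang::warn("no evaluable (analyte, timepoint) cells: survival never varies across groups")
  structure(list(cells = cells, analytes = analytes,
                 rho_threshold = rho_threshold, alpha = alpha,
                 aggregation = aggregation, aggregation_fraction = frac),
            class = "survival_screen")
}

#' Aggregate hits of a survival screen
#'
#' @param screen A `survival_screen` object.
#' @return Character vector of analytes meeting the aggregate criterion,
#'   in panel order.
#' @export
screen_hits <- function(screen) {
  stopifnot(inherits(screen, "survival_screen"))
  screen$analytes$analyte[screen$analytes$hit]
}

#' @export
print.survival_screen <- function(x, ...) {
  cat(sprintf("Survival correlation screen: |rho| > %g and p < %g, aggregation '%s'\n",
              x$rho_threshold, x$alpha, x$aggregation))
  hits <- screen_hits(x)
  cat(sprintf("%d/%d analytes hit: %s\n", length(hits), nrow(x$analytes),
              paste(hits, collapse = ", ")))
  invisible(x)
}

#' @rdname screen_survival_correlation
#' @param x A `survival_screen` object.
#' @param ... Unused.
#' @export
tidy.survival_screen <- function(x, ...) x$cells

#' @rdname screen_survival_correlation
#' @export
glance.survival_screen <- function(x, ...) {
  tibble(n_analytes = nrow(x$analytes),
         n_hits = sum(x$analytes$hit),
         n_evaluable_cells = sum(x$cells$evaluable),
         rho_threshold = x$rho_threshold, alpha = x$alpha,
         aggregation = as.character(x$aggregation))
}

#' @rdname screen_survival_correlation
#' @param object A `survival_screen` object.
#' @export
autoplot.survival_screen <- function(object, ...) {
  ggplot2::ggplot(object$cells,
                  ggplot2::aes(x = .data$timepoint, y = .data$analyte, fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "steelblue",
                                  mid = "white", high = "firebrick", na.value = "grey85") +
    ggplot2::labs(x = "day", y = NULL, fill = expression(rho),
                  title = "Per-timepoint Pearson correlation with survival") +
    ggplot2::theme_minimal()
}

#' Spearman rank screen of expression against substratum stiffness
#'
#' Pools all wells per analyte and correlates concentration with
#' substratum stiffness (stiffness entering as the rank covariate, so any
#' monotone coding of the levels gives identical results).  Significance
#' is Bonferroni-corrected across the analytes tested: an analyte hits
#' when `p < alpha / m`.
#'
#' @param wells Stiffness tibble (see [validate_stiffness()]).
#' @param alpha Family-wise significance level (default 0.05).
#' @return A tibble with one row per analyte: `analyte`, `rho`,
#'   `p.value`, `n`, `threshold` (= `alpha/m`), `hit`, `direction`
#'   (`"increases_with_softening"` / `"increases_with_stiffness"` /
#'   `NA`).  Attributes `alpha` and `m` record the correction.
#' @export
screen_stiffness_correlation <- function(wells, alpha = 0.05) {
  wells <- validate_stiffness(wells)
  if (length(unique(wells$stiffness_kpa)) < 2)
    stop_bad("stiffness column is constant; need >= 2 levels")
  analytes <- unique(wells$analyte)
  m <- length(analytes)
  res <- purrr::map_dfr(analytes, function(an) {
    d <- wells[wells$analyte == an, ]
    if (nrow(d) < 3) stop_bad("analyte '%s' has fewer than 3 wells", an)
    s <- cor_spearman(d$stiffness_kpa, d$concentration * d$norm_factor)
    tibble(analyte = an, rho = s$estimate, p.value = s$p.value, n = s$n,
           evaluable = s$evaluable)
  })
  res$threshold <- alpha / m
  res$hit <- !is.na(res$p.value) & res$p.value < res$threshold
  res$direction <- dplyr::case_when(
    is.na(res$rho) ~ NA_character_,
    res$rho < 0 ~ "increases_with_softening",
    res$rho > 0 ~ "increases_with_stiffness",
    TRUE ~ NA_character_)
  attr(res, "alpha") <- alpha
  attr(res, "m") <- m
  res
}
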