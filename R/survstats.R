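## Validation statistics for the in vivo cohorts: Kaplan-Meier curves,
## median survival, Mantel-Cox log-rank, Mantel-Haenszel hazard ratio,
## one-tailed Welch t tests and family-wise p adjustment.  The estimators
## are the standard ones from the survival package; the wrappers fix the
## conventions (tie pooling, reference group, median rule) and return
## tidy tibbles.

events_to_surv <- function(events) {
  survival::Surv(events$time, events$status)
}

#' Kaplan-Meier (product-limit) survival curve
#'
#' `S(t)` is the product over death times `t_i <= t` of `(1 - d_i/n_i)`;
#' censored subjects leave the risk set after their censoring time.
#'
#' @param events Event tibble (see [validate_events()]).
#' @param group Optional single group label to restrict to; by default a
#'   curve is returned for every group present.
#' @return Tibble: `group`, `time`, `n_risk`, `n_event`, `n_censor`,
#'   `estimate` (survival proportion after `time`).  A `time = 0` row with
#'   `estimate = 1` leads each curve.
#' @export
km_curve <- function(events, group = NULL) {
  events <- validate_events(events)
  if (!is.null(group)) {
    events <- events[events$group %in% group, ]
    if (nrow(events) == 0L) stop_bad("no subjects in group '%s'", paste(group, collapse = ", "))
  }
  purrr::map_dfr(unique(events$group), function(g) {
    d <- events[events$group == g, ]
    fit <- survival::survfit(events_to_surv(d) ~ 1, conf.type = "none")
    tibble(group = g,
           time = c(0, fit$time),
           n_risk = c(nrow(d), fit$n.risk),
           n_event = c(0L, fit$n.event),
           n_censor = c(0L, fit$n.censor),
           estimate = c(1, fit$surv))
  })
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' Step-function evaluation (right-continuous): the estimate after the
#' last event time at or before each query time.
#'
#' @param curve Output of [km_curve()] (single group).
#' @param times Numeric query times.
#' @return Numeric vector of survival proportions.
#' @export
km_at <- function(curve, times) {
  stopifnot(length(unique(curve$group)) == 1L)
  idx <- findInterval(times, curve$time)
  curve$estimate[pmax(idx, 1L)]
}

#' Median survival time
#'
#' The first event time at which the product-limit estimate falls to 0.5
#' or below; `NA` ("undefined") when the curve never reaches 0.5 within
#' follow-up.
#'
#' @param events Event tibble.
#' @param group Optional group restriction, as in [km_curve()].
#' @return Tibble: `group`, `median` (days, `NA` if undefined).
#' @export
median_survival <- function(events, group = NULL) {
  curves <- km_curve(events, group)
  curves |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(median = {
      i <- which(.data$estimate <= 0.5)
      if (length(i)) min(.data$time[i]) else NA_real_
    }, .groups = "drop")
}

logrank_oev <- function(events, group_a, group_b) {
  events <- validate_events(events)
  d <- events[events$group %in% c(group_a, group_b), ]
  if (!any(d$status == 1L)) stop_bad("test undefined: no deaths in either group")
  if (!any(d$group == group_a) || !any(d$group == group_b))
    stop_bad("both groups must have subjects; got '%s' vs '%s'", group_a, group_b)
  g <- factor(d$group, levels = c(group_a, group_b))
  fit <- survival::survdiff(events_to_surv(d) ~ g, rho = 0)
  list(O = unname(fit$obs), E = unname(fit$exp), V = fit$var[1, 1],
       chisq = unname(fit$chisq))
}

#' Mantel-Cox (log-rank) test between two groups
#'
#' At each distinct death time the expected deaths and hypergeometric
#' variance are computed from the 2 x 2 risk table (tied deaths pooled
#' into one stratum); the statistic is `(sum O_A - sum E_A)^2 / sum V`,
#' referred to a chi-square with 1 degree of freedom.
#'
#' @param events Event tibble.
#' @param group_a,group_b Group labels to compare.
#' @return One-row tibble: `statistic`, `p.value`, `df`, `observed_a`,
#'   `expected_a`, `observed_b`, `expected_b`, `variance`.
#' @export
logrank_test <- function(events, group_a, group_b) {
  r <- logrank_oev(events, group_a, group_b)
  tibble(statistic = r$chisq, p.value = pchisq(r$chisq, df = 1, lower.tail = FALSE),
         df = 1L, observed_a = r$O[1], expected_a = r$E[1],
         observed_b = r$O[2], expected_b = r$E[2], variance = r$V)
}

#' Mantel-Haenszel hazard ratio between two groups
#'
#' Default method: `HR = exp((O_A - E_A) / V)` with the log-rank
#' observed/expected/variance sums, and 95% CI
#' `exp((O_A - E_A)/V +/- 1.96/sqrt(V))`.  The alternative `"logrank-oe"`
#' method reports `(O_A/E_A) / (O_B/E_B)` (same CI form).  The second
#' argument is the reference group: `hazard_ratio(e, A, B) > 1` means
#' subjects in `A` die faster than in `B`.
#'
#' @inheritParams logrank_test
#' @param method `"mantel-haenszel"` (default) or `"logrank-oe"`.
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return One-row tibble: `hr`, `conf.low`, `conf.high`, `method`,
#'   `group`, `reference`.
#' @export
hazard_ratio <- function(events, group_a, group_b,
                         method = c("mantel-haenszel", "logrank-oe"),
                         conf_level = 0.95) {
  method <- match.arg(method)
  r <- logrank_oev(events, group_a, group_b)
  if (r$V <= 0) stop_bad("hazard ratio undefined: log-rank variance is zero")
  z <- qnorm(1 - (1 - conf_level) / 2)
  if (method == "mantel-haenszel") {
    loghr <- (r$O[1] - r$E[1]) / r$V
  } else {
    loghr <- log((r$O[1] / r$E[1]) / (r$O[2] / r$E[2]))
  }
  tibble(hr = exp(loghr),
         conf.low = exp(loghr - z / sqrt(r$V)),
         conf.high = exp(loghr + z / sqrt(r$V)),
         method = method, group = group_a, reference = group_b)
}

#' Welch unequal-variance t test
#'
#' Student's t with the Satterthwaite degrees of freedom, as used for the
#' blood-count and weight-recovery comparisons (typically one-tailed).
#'
#' @param a,b Numeric samples, each of size >= 2 with finite variance.
#' @param alternative `"two.sided"`, `"greater"` (mean of `a` greater) or
#'   `"less"`.
#' @return One-row tibble: `statistic`, `df`, `p.value`, `estimate`
#'   (mean difference a - b), `alternative`.
#' @export
welch_t <- function(a, b, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(a) < 2 || length(b) < 2) stop_bad("each sample needs n >= 2")
  ht <- t.test(a, b, alternative = alternative, var.equal = FALSE)
  tibble(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p.value = ht$p.value, estimate = unname(ht$estimate[1] - ht$estimate[2]),
         alternative = alternative)
}

#' Family-wise p-value adjustment
#'
#' Holm's step-down procedure (default; uniformly more powerful than
#' Bonferroni at the same family-wise error rate) or the plain Bonferroni
#' `min(1, m * p)`.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param method `"holm"` (default) or `"bonferroni"`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
adjust_pvalues <- function(p, method = c("holm", "bonferroni")) {
  method <- match.arg(method)
  if (any(!is.finite(p) | p < 0 | p > 1)) stop_bad("p-values must lie in [0, 1]")
  p.adjust(p, method = method)
}
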