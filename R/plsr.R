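## Two-component multivariate-response partial least squares regression by
## the SIMPLS algorithm (de Jong 1993), the deterministic PLSR used by
## standard numerical toolboxes: weights are computed directly from the
## deflated cross-covariance matrix, scores are orthonormal, and no
## response deflation is needed.  Both blocks are z-scored first.

#' Fit a multivariate-response PLSR (SIMPLS) of survival on expression
#'
#' Standardizes the expression block (groups x analytes) and the survival
#' block (groups x timepoints) column-wise, then extracts `ncomp` SIMPLS
#' components.  The model stores weights, loadings, orthonormal scores,
#' per-component variance explained in each block, the fitted
#' standardizers, and an intercept-augmented coefficient matrix of shape
#' `(p + 1) x q` (intercept row first) mapping standardized expression to
#' standardized survival.  Predictions apply that matrix and then invert
#' the survival standardizer.
#'
#' Components are sign-fixed so the largest-magnitude entry of each
#' X-weight vector is positive, making loadings and rankings reproducible.
#' If the cross-covariance is exhausted before `ncomp` components (data of
#' lower rank), the remaining components are returned as all-zero with a
#' warning.
#'
#' @param expr Expression tibble (n groups x p analytes).
#' @param surv Survival tibble (same groups, q timepoints).
#' @param ncomp Number of latent components (default 2; must satisfy
#'   `ncomp <= min(n - 1, p)`).
#' @return An object of class `plsr_fit` with elements `weights` (p x A),
#'   `x_loadings` (p x A), `y_loadings` (q x A), `scores` (n x A),
#'   `coefficients` ((p+1) x q, standardized scale, intercept row first),
#'   `explained` (per-component variance fractions), `x_standardizer`,
#'   `y_standardizer`, `analytes`, `timepoints`, `groups`, `ncomp`,
#'   `ncomp_attained`.
#' @export
fit_plsr <- function(expr, surv, ncomp = 2) {
  expr <- validate_expression(expr)
  surv <- validate_survival(surv)
  if (!identical(expr$group, surv$group))
    stop_bad("expression and survival tables must share group labels and order")
  X <- wide_matrix(expr)
  Y <- wide_matrix(surv)
  n <- nrow(X); p <- ncol(X); q <- ncol(Y)
  if (n < 3) stop_bad("need at least 3 groups, got %d", n)
  if (ncomp > min(n - 1, p))
    stop_bad("ncomp = %d exceeds min(n - 1, p) = %d", ncomp, min(n - 1, p))
  sx <- standardize_columns(X)
  sy <- standardize_columns(Y)
  if (all(sx$constant)) stop_bad("all analyte columns are constant; nothing to regress on")
  Xs <- sx$z; Ys <- sy$z
  S <- crossprod(Xs, Ys)
  s0 <- sqrt(sum(S^2))
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Q <- matrix(0, q, ncomp); TT <- matrix(0, n, ncomp)
  V <- matrix(0, p, 0)
  attained <- 0L
  for (a in seq_len(ncomp)) {
    sv <- svd(S, nu = 1, nv = 0)
    if (!is.finite(sv$d[1]) || sv$d[1] <= 1e-12 * max(s0, 1e-300)) {
      rlang::warn(sprintf(
        "cross-covariance exhausted after %d component(s); component(s) %s returned as zero",
        attained, paste(a:ncomp, collapse = ", ")))
      break
    }
    r <- sv$u[, 1]
    imax <- which.max(abs(r))
    if (r[imax] < 0) r <- -r                       # deterministic sign
    tvec <- Xs %*% r
    nt <- sqrt(sum(tvec^2))
    tvec <- tvec / nt; r <- r / nt
    pl <- crossprod(Xs, tvec)
    ql <- crossprod(Ys, tvec)
    v <- pl
    if (ncol(V)) v <- v - V %*% crossprod(V, pl)   # orthogonalize basis
    v <- v / sqrt(sum(v^2))
    S <- S - v %*% crossprod(v, S)
    W[, a] <- r; P[, a] <- pl; Q[, a] <- ql; TT[, a] <- tvec
    V <- cbind(V, v)
    attained <- a
  }
  ss_x <- sum(Xs^2); ss_y <- sum(Ys^2)
  explained <- tibble(
    component = seq_len(ncomp),
    x_variance = colSums(P^2) / ss_x,
    y_variance = colSums(Q^2) / ss_y)
  B <- W %*% t(Q)                                  # p x q, standardized scale
  Baug <- rbind(intercept = rep(0, q), B)          # both blocks centred
  rownames(Baug) <- c("(Intercept)", colnames(X))
  colnames(Baug) <- colnames(Y)
  dimnames(W) <- dimnames(P) <- list(colnames(X), paste0("comp", seq_len(ncomp)))
  dimnames(Q) <- list(colnames(Y), paste0("comp", seq_len(ncomp)))
  dimnames(TT) <- list(expr$group, paste0("comp", seq_len(ncomp)))
  structure(list(weights = W, x_loadings = P, y_loadings = Q, scores = TT,
                 coefficients = Baug, explained = explained,
                 x_standardizer = sx[c("center", "scale", "constant")],
                 y_standardizer = sy[c("center", "scale", "constant")],
                 analytes = colnames(X), timepoints = survival_timepoints(surv),
                 groups = expr$group, ncomp = ncomp, ncomp_attained = attained),
            class = "plsr_fit")
}

#' @export
print.plsr_fit <- function(x, ...) {
  cum <- dplyr::summarise(x$explained, x = sum(.data$x_variance), y = sum(.data$y_variance))
  cat(sprintf("SIMPLS fit: %d groups, %d analytes -> %d timepoints, %d component(s)\n",
              length(x$groups), length(x$analytes), length(x$timepoints), x$ncomp))
  cat(sprintf("variance captured: %.1f%% of expression, %.1f%% of survival\n",
              100 * cum$x, 100 * cum$y))
  invisible(x)
}

#' Per-component variance explained
#'
#' Fractions of each standardized block's sum of squares captured by each
#' component (scores are orthonormal, so per-component contributions are
#' additive), plus cumulative totals.  Constant columns — standardized to
#' zero — contribute nothing to either denominator.
#'
#' @param model A `plsr_fit`.
#' @return Tibble: `component`, `x_variance`, `y_variance`,
#'   `x_cumulative`, `y_cumulative`.
#' @export
variance_explained <- function(model) {
  stopifnot(inherits(model, "plsr_fit"))
  dplyr::mutate(model$explained,
                x_cumulative = cumsum(.data$x_variance),
                y_cumulative = cumsum(.data$y_variance))
}

#' Extract the intercept-augmented coefficient matrix
#'
#' @param object A `plsr_fit`.
#' @param scale `"standardized"` (default): coefficients map z-scored
#'   expression to z-scored survival, intercept row exactly zero.
#'   `"original"`: coefficients map raw pg/mL concentrations to survival
#'   proportions, the standardizers folded in.
#' @param ... Unused.
#' @return A `(p + 1) x q` matrix, intercept row first.
#' @export
coef.plsr_fit <- function(object, scale = c("standardized", "original"), ...) {
  scale <- match.arg(scale)
  B <- object$coefficients
  if (scale == "standardized") return(B)
  sx <- object$x_standardizer; sy <- object$y_standardizer
  sxs <- ifelse(sx$constant, 1, sx$scale)
  sys <- ifelse(sy$constant, 0, sy$scale)
  slopes <- (B[-1, , drop = FALSE] / sxs) %*% diag(sys, length(sys))
  intercept <- sy$center - as.vector(crossprod(slopes, sx$center))
  out <- rbind(intercept, slopes)
  dimnames(out) <- dimnames(B)
  out
}

#' Predict survival curves for new expression data
#'
#' Standardizes the new expression block with the *training* X
#' standardizer, applies the coefficient matrix, and inverts the training
#' Y standardizer back to survival-proportion scale.  Columns are matched
#' to the model's analyte set by name (any order); a mismatch errors with
#' the missing/extra analytes listed.  Timepoint columns that were
#' constant in training (e.g. day 0, all groups at 1) are predicted as
#' their training constant.
#'
#' @param object A `plsr_fit`.
#' @param newdata Expression tibble with the model's analyte set.
#' @param clip Project predictions into \[0, 1\] (default `TRUE`).
#' @param monotone Replace each curve by its best non-increasing
#'   least-squares approximation (pool-adjacent-violators; default
#'   `FALSE`).
#' @param scale `"response"` (survival proportions, default) or
#'   `"standardized"` (z-scale predictions; `clip`/`monotone` not
#'   applied).
#' @param ... Unused.
#' @return A wide tibble (`group` + timepoint columns).  Attribute
#'   `postprocessing` records which of clip/monotone were applied.
#' @export
predict.plsr_fit <- function(object, newdata, clip = TRUE, monotone = FALSE,
                             scale = c("response", "standardized"), ...) {
  scale <- match.arg(scale)
  newdata <- validate_expression(newdata)
  have <- names(newdata)[-1]
  missing_an <- setdiff(object$analytes, have)
  extra_an <- setdiff(have, object$analytes)
  if (length(missing_an) || length(extra_an))
    stop_bad("analyte set mismatch; missing: [%s]; extra: [%s]",
             paste(missing_an, collapse = ", "), paste(extra_an, collapse = ", "))
  X <- wide_matrix(newdata)[, object$analytes, drop = FALSE]
  sx <- object$x_standardizer
  Z <- std_transform(structure(sx, class = "standardizer"), X)
  Yhat <- cbind(1, Z) %*% object$coefficients
  post <- character(0)
  if (scale == "response") {
    Yhat <- std_invert(object$y_standardizer, Yhat)
    if (monotone) {
      Yhat <- t(apply(Yhat, 1, pava_nonincreasing))
      post <- c(post, "monotone")
    }
    if (clip) {
      Yhat <- pmin(pmax(Yhat, 0), 1)
      post <- c(post, "clip")
    }
  }
  out <- as_tibble(cbind(tibble(group = newdata$group), as.data.frame(Yhat)))
  names(out) <- c("group", as.character(object$timepoints))
  attr(out, "postprocessing") <- post
  out
}

## best non-increasing least-squares approximation (PAVA), via the
## isotonic regression of the negated sequence
pava_nonincreasing <- function(y) {
  -isoreg(seq_along(y), -y)$yf
}

#' Two-dimensional loading map of analytes and timepoints
#'
#' Coordinates are the first two columns of the X-loadings (analytes) and
#' Y-loadings (timepoints), under the fit's sign convention.  Predictor
#' and response variables whose loading vectors sit close together are
#' strongly correlated — the basis of the proximity-based biomarker
#' ranking.
#'
#' @param model A `plsr_fit` with at least 2 components.
#' @return Tibble: `variable`, `role` (`"analyte"`/`"timepoint"`),
#'   `comp1`, `comp2`.
#' @export
loading_map <- function(model) {
  stopifnot(inherits(model, "plsr_fit"))
  if (model$ncomp < 2) stop_bad("loading map needs at least 2 components, model has %d", model$ncomp)
  dplyr::bind_rows(
    tibble(variable = model$analytes, role = "analyte",
           comp1 = model$x_loadings[, 1], comp2 = model$x_loadings[, 2]),
    tibble(variable = as.character(model$timepoints), role = "timepoint",
           comp1 = model$y_loadings[, 1], comp2 = model$y_loadings[, 2]))
}

#' @rdname loading_map
#' @param object A `plsr_fit`.
#' @param ... Unused.
#' @export
autoplot.plsr_fit <- function(object, ...) {
  lm_ <- loading_map(object)
  ggplot2::ggplot(lm_, ggplot2::aes(x = .data$comp1, y = .data$comp2,
                                    colour = .data$role, shape = .data$role)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "component 1 loading", y = "component 2 loading",
                  title = "PLSR loading map") +
    ggplot2::theme_minimal()
}

#' @rdname fit_plsr
#' @param x A `plsr_fit`.
#' @param what One of `"loadings"`, `"scores"`, `"coefficients"`,
#'   `"variance"`.
#' @param ... Unused.
#' @export
tidy.plsr_fit <- function(x, what = c("loadings", "scores", "coefficients", "variance"), ...) {
  what <- match.arg(what)
  switch(what,
    loadings = loading_map(x) |>
      tidyr::pivot_longer(c("comp1", "comp2"), names_to = "component",
                          values_to = "loading"),
    scores = as_tibble(x$scores) |>
      dplyr::mutate(group = x$groups, .before = 1) |>
      tidyr::pivot_longer(-"group", names_to = "component", values_to = "score"),
    coefficients = as_tibble(x$coefficients, rownames = "term") |>
      tidyr::pivot_longer(-"term", names_to = "timepoint", values_to = "estimate") |>
      dplyr::mutate(timepoint = as.numeric(.data$timepoint)),
    variance = variance_explained(x))
}

#' @rdname fit_plsr
#' @export
glance.plsr_fit <- function(x, ...) {
  ve <- variance_explained(x)
  tibble(n_groups = length(x$groups), n_analytes = length(x$analytes),
         n_timepoints = length(x$timepoints), ncomp = x$ncomp,
         ncomp_attained = x$ncomp_attained,
         x_variance_cum = ve$x_cumulative[x$ncomp],
         y_variance_cum = ve$y_cumulative[x$ncomp])
}
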