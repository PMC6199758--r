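## JSON persistence for fitted models.  Numbers are written at full
## double precision so a reloaded model predicts bit-identically.

#' Write a fitted PLSR model to JSON
#'
#' All matrices are stored with their row/column labels; numeric values
#' keep full precision, so [read_plsr_json()] reproduces predictions
#' bit-identically.
#'
#' @param model A `plsr_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plsr_json <- function(model, path) {
  stopifnot(inherits(model, "plsr_fit"))
  mat <- function(M) list(values = unname(as.matrix(M)), rows = rownames(M), cols = colnames(M))
  payload <- list(
    format = "secretopls_plsr", version = 1L,
    ncomp = model$ncomp, ncomp_attained = model$ncomp_attained,
    analytes = model$analytes, timepoints = model$timepoints, groups = model$groups,
    weights = mat(model$weights), x_loadings = mat(model$x_loadings),
    y_loadings = mat(model$y_loadings), scores = mat(model$scores),
    coefficients = mat(model$coefficients),
    explained = as.list(model$explained),
    x_standardizer = model$x_standardizer, y_standardizer = model$y_standardizer)
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' Read a fitted PLSR model from JSON
#'
#' @param path Path written by [write_plsr_json()].
#' @return A `plsr_fit`.
#' @export
read_plsr_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$format, "secretopls_plsr")) stop_bad("'%s' is not a secretopls model file", path)
  unmat <- function(m) {
    M <- as.matrix(m$values)
    dimnames(M) <- list(m$rows, m$cols)
    M
  }
  std <- function(s) list(center = unlist(s$center), scale = unlist(s$scale),
                          constant = as.logical(unlist(s$constant)))
  structure(list(weights = unmat(x$weights), x_loadings = unmat(x$x_loadings),
                 y_loadings = unmat(x$y_loadings), scores = unmat(x$scores),
                 coefficients = unmat(x$coefficients),
                 explained = as_tibble(x$explained),
                 x_standardizer = std(x$x_standardizer),
                 y_standardizer = std(x$y_standardizer),
                 analytes = x$analytes, timepoints = x$timepoints, groups = x$groups,
                 ncomp = x$ncomp, ncomp_attained = x$ncomp_attained),
            class = "plsr_fit")
}
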