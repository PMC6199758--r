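## Internal validators shared by the readers, writers and simulators.
## Every error names the offending row/column so corrupt CSVs are
## diagnosable without re-opening the file.

stop_bad <- function(msg, ...) rlang::abort(sprintf(msg, ...), class = "secretopls_error")

#' Validate a wide expression table
#'
#' An expression table holds one row per MSC preparation (`group`) and one
#' numeric column per secreted analyte, in pg/mL.  Values must be finite
#' and non-negative and group labels unique.
#'
#' @param x A data frame: first column `group` (character), remaining
#'   columns numeric analyte concentrations.
#' @return `x` as a tibble, invisibly validated (the input is returned so
#'   validation can sit inside a pipe).
#' @export
validate_expression <- function(x) {
  x <- as_tibble(x)
  if (ncol(x) < 2L) stop_bad("expression table needs a 'group' column plus at least one analyte column")
  if (names(x)[1] != "group") stop_bad("first column must be named 'group', got '%s'", names(x)[1])
  if (nrow(x) == 0L) stop_bad("no groups: expression table has an empty data section")
  x$group <- as.character(x$group)
  dup <- x$group[duplicated(x$group)]
  if (length(dup)) stop_bad("duplicate group labels: %s", paste(unique(dup), collapse = ", "))
  an <- names(x)[-1]
  if (anyDuplicated(an)) stop_bad("duplicate analyte names: %s", paste(unique(an[duplicated(an)]), collapse = ", "))
  if (any(!nzchar(an))) stop_bad("empty analyte name in header")
  for (j in an) {
    v <- x[[j]]
    if (!is.numeric(v)) stop_bad("non-numeric values in analyte column '%s'", j)
    bad <- which(!is.finite(v))
    if (length(bad)) stop_bad("non-finite value for group '%s', analyte '%s'", x$group[bad[1]], j)
    neg <- which(v < 0)
    if (length(neg)) stop_bad("negative concentration for group '%s', analyte '%s'", x$group[neg[1]], j)
  }
  x
}

#' Validate a wide survival-curve table
#'
#' One row per group, one column per timepoint (column names are days).
#' Proportions must lie in \[0, 1\], each row must be non-increasing along
#' time (within `tol`), and the day-0 column, when present, must be 1.
#'
#' @param x Data frame: `group` column plus numeric timepoint columns whose
#'   names parse as strictly increasing days >= 0.
#' @param tol Monotonicity tolerance.  Product-limit survival proportions
#'   are exactly non-increasing, so any real violation signals corrupt
#'   input; the tolerance only absorbs decimal-representation jitter.
#' @param allow_nonmonotone If `TRUE`, monotonicity violations beyond `tol`
#'   are kept (with a warning) instead of rejected.
#' @return The validated tibble.
#' @export
validate_survival <- function(x, tol = 1e-9, allow_nonmonotone = FALSE) {
  x <- as_tibble(x)
  if (names(x)[1] != "group") stop_bad("first column must be named 'group', got '%s'", names(x)[1])
  if (nrow(x) == 0L) stop_bad("no groups: survival table has an empty data section")
  x$group <- as.character(x$group)
  dup <- x$group[duplicated(x$group)]
  if (length(dup)) stop_bad("duplicate group labels: %s", paste(unique(dup), collapse = ", "))
  tp <- suppressWarnings(as.numeric(names(x)[-1]))
  if (anyNA(tp)) stop_bad("timepoint column names must be numeric days; offending: %s",
                          paste(names(x)[-1][is.na(tp)], collapse = ", "))
  if (any(tp < 0)) stop_bad("negative timepoint: %s", tp[tp < 0][1])
  if (is.unsorted(tp, strictly = TRUE)) stop_bad("timepoints must be strictly increasing")
  M <- as.matrix(x[-1])
  if (!is.numeric(M)) stop_bad("non-numeric survival values")
  bad <- which(!is.finite(M) | M < 0 | M > 1, arr.ind = TRUE)
  if (nrow(bad)) stop_bad("survival value outside [0,1] for group '%s' at day %s",
                          x$group[bad[1, 1]], tp[bad[1, 2]])
  if (ncol(M) >= 2) {
    incr <- which(M[, -1, drop = FALSE] - M[, -ncol(M), drop = FALSE] > tol, arr.ind = TRUE)
    if (nrow(incr)) {
      msg <- sprintf("survival increases for group '%s' between day %s and day %s",
                     x$group[incr[1, 1]], tp[incr[1, 2]], tp[incr[1, 2] + 1])
      if (allow_nonmonotone) rlang::warn(msg) else stop_bad("%s", msg)
    }
  }
  if (tp[1] == 0 && any(abs(M[, 1] - 1) > tol)) {
    g <- x$group[which(abs(M[, 1] - 1) > tol)[1]]
    stop_bad("survival at day 0 must equal 1 (group '%s')", g)
  }
  x
}

#' Validate a subject-level event table
#'
#' @param x Data frame with columns `subject`, `group`, `time` (days > 0)
#'   and `status` (1 = death, 0 = censored).
#' @return The validated tibble.
#' @export
validate_events <- function(x) {
  x <- as_tibble(x)
  need <- c("subject", "group", "time", "status")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop_bad("event table missing column(s): %s", paste(miss, collapse = ", "))
  x <- x[need]
  x$subject <- as.character(x$subject)
  x$group <- as.character(x$group)
  dup <- x$subject[duplicated(x$subject)]
  if (length(dup)) stop_bad("duplicate subject ids: %s", paste(unique(dup), collapse = ", "))
  bad <- which(!is.finite(x$time) | x$time <= 0)
  if (length(bad)) stop_bad("time must be finite and > 0 (subject '%s')", x$subject[bad[1]])
  if (!all(x$status %in% c(0L, 1L))) {
    bad <- which(!x$status %in% c(0L, 1L))[1]
    stop_bad("status must be 0 (censored) or 1 (death); subject '%s' has '%s'",
             x$subject[bad], x$status[bad])
  }
  x$status <- as.integer(x$status)
  x
}

#' Validate a stiffness-expression table
#'
#' Long-format records of per-well analyte concentrations measured on
#' culture substrata of known stiffness.
#'
#' @param x Data frame with columns `well`, `stiffness_kpa` (> 0),
#'   `analyte`, `concentration` (pg/mL, >= 0) and optionally `norm_factor`
#'   (> 0, default 1).
#' @return The validated tibble (with `norm_factor` filled in).
#' @export
validate_stiffness <- function(x) {
  x <- as_tibble(x)
  need <- c("well", "stiffness_kpa", "analyte", "concentration")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop_bad("stiffness table missing column(s): %s", paste(miss, collapse = ", "))
  if (!"norm_factor" %in% names(x)) x$norm_factor <- 1
  x <- x[c(need, "norm_factor")]
  x$well <- as.character(x$well)
  x$analyte <- as.character(x$analyte)
  if (any(!is.finite(x$stiffness_kpa) | x$stiffness_kpa <= 0))
    stop_bad("stiffness must be finite and > 0 (well '%s')",
             x$well[which(!is.finite(x$stiffness_kpa) | x$stiffness_kpa <= 0)[1]])
  if (any(!is.finite(x$concentration) | x$concentration < 0))
    stop_bad("concentration must be finite and >= 0 (well '%s', analyte '%s')",
             x$well[which(!is.finite(x$concentration) | x$concentration < 0)[1]],
             x$analyte[which(!is.finite(x$concentration) | x$concentration < 0)[1]])
  if (any(!is.finite(x$norm_factor) | x$norm_factor <= 0))
    stop_bad("norm_factor must be finite and > 0 (well '%s')",
             x$well[which(!is.finite(x$norm_factor) | x$norm_factor <= 0)[1]])
  x
}

## numeric timepoints of a survival tibble
survival_timepoints <- function(surv) as.numeric(names(surv)[-1])

## groups x analytes numeric matrix from a wide tibble
wide_matrix <- function(x) {
  M <- as.matrix(x[-1])
  rownames(M) <- x$group
  M
}
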