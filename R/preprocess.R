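## Preprocessing of raw multiplex immunoassay readouts: technical-replicate
## collapsing, cell-number normalization, and the below-detection-limit
## policy.  Each step records what it did in table attributes so a
## downstream reader can audit the provenance of the matrix that entered
## the regression.

#' Collapse technical replicates to one concentration per group/analyte
#'
#' Multiplex panels are typically assayed in technical duplicate; the
#' representative concentration for each (group, analyte) cell is the
#' arithmetic mean of its replicate wells.
#'
#' @param wells Long tibble with columns `group`, `analyte`,
#'   `concentration` (one row per replicate well).
#' @return A wide expression tibble (`group` + analyte columns), with a
#'   `replicate_counts` attribute holding the per-cell replicate count and
#'   a `preprocessing` attribute logging the step.  Analyte columns follow
#'   first-appearance order; groups keep first-appearance order.
#' @export
collapse_technical_replicates <- function(wells) {
  wells <- as_tibble(wells)
  need <- c("group", "analyte", "concentration")
  miss <- setdiff(need, names(wells))
  if (length(miss)) stop_bad("replicate table missing column(s): %s", paste(miss, collapse = ", "))
  if (nrow(wells) == 0L) stop_bad("no groups: replicate table is empty")
  groups <- unique(as.character(wells$group))
  analytes <- unique(as.character(wells$analyte))
  full <- tidyr::expand_grid(group = groups, analyte = analytes)
  agg <- wells |>
    dplyr::group_by(.data$group, .data$analyte) |>
    dplyr::summarise(concentration = mean(.data$concentration), n_rep = dplyr::n(),
                     .groups = "drop")
  missing_cells <- dplyr::anti_join(full, agg, by = c("group", "analyte"))
  if (nrow(missing_cells)) {
    stop_bad("missing replicate(s) for: %s",
             paste(sprintf("(%s, %s)", missing_cells$group, missing_cells$analyte), collapse = ", "))
  }
  wide <- agg |>
    dplyr::select(-"n_rep") |>
    tidyr::pivot_wider(names_from = "analyte", values_from = "concentration") |>
    dplyr::arrange(match(.data$group, groups))
  wide <- wide[c("group", analytes)]
  counts <- agg |>
    dplyr::select("group", "analyte", "n_rep") |>
    tidyr::pivot_wider(names_from = "analyte", values_from = "n_rep") |>
    dplyr::arrange(match(.data$group, groups))
  out <- validate_expression(wide)
  attr(out, "replicate_counts") <- counts[c("group", analytes)]
  attr(out, "preprocessing") <- c(attr(wells, "preprocessing"), "collapse_technical_replicates")
  out
}

#' Normalize concentrations by per-group cell numbers
#'
#' Conditioned-media concentrations scale with the number of cells that
#' conditioned the medium; each group's row is multiplied by its
#' cell-number normalization factor.
#'
#' @param expr Expression tibble.
#' @param factors Named numeric vector (names = group labels) or a tibble
#'   with columns `group`, `factor`.  One positive factor per group.
#' @return The normalized expression tibble; the `preprocessing` attribute
#'   records the step and the factors applied.
#' @export
normalize_by_cell_count <- function(expr, factors) {
  expr <- validate_expression(expr)
  if (is.data.frame(factors)) factors <- setNames(factors$factor, factors$group)
  miss <- setdiff(expr$group, names(factors))
  if (length(miss)) stop_bad("no normalization factor for group(s): %s", paste(miss, collapse = ", "))
  f <- as.numeric(factors[expr$group])
  if (any(!is.finite(f) | f <= 0))
    stop_bad("normalization factor must be > 0 (group '%s')", expr$group[which(!is.finite(f) | f <= 0)[1]])
  out <- expr
  out[-1] <- expr[-1] * f
  attr(out, "replicate_counts") <- attr(expr, "replicate_counts")
  attr(out, "preprocessing") <- c(attr(expr, "preprocessing"),
                                  sprintf("normalize_by_cell_count[%s]",
                                          paste(sprintf("%s=%g", expr$group, f), collapse = ",")))
  out
}

#' Apply a below-detection-limit policy
#'
#' Immunoassay panels report a lower limit of detection (LOD) per analyte;
#' readouts below it are unreliable.  The default policy mirrors common
#' practice for panels in which some analytes are entirely undetectable:
#' an analyte is dropped only when *every* sample falls below its LOD,
#' rather than imputing values.
#'
#' @param expr Expression tibble.
#' @param lod Named numeric vector of per-analyte detection limits
#'   (pg/mL).  Analytes without an entry are left untouched.
#' @param policy One of `"drop_if_all_below"` (default),
#'   `"substitute_half_lod"` (below-LOD cells replaced by `lod/2`), or
#'   `"keep"` (no-op).
#' @return The filtered/modified expression tibble.  Attribute
#'   `lod_dropped` lists removed analytes; `preprocessing` logs the step.
#' @export
apply_lod_policy <- function(expr, lod = NULL,
                             policy = c("drop_if_all_below", "substitute_half_lod", "keep")) {
  policy <- match.arg(policy)
  expr <- validate_expression(expr)
  dropped <- character(0)
  out <- expr
  if (policy != "keep") {
    if (is.null(lod) || !length(lod)) stop_bad("policy '%s' requires per-analyte detection limits", policy)
    if (any(lod < 0)) stop_bad("detection limits must be >= 0")
    for (j in intersect(names(lod), names(expr)[-1])) {
      below <- expr[[j]] < lod[[j]]
      if (policy == "drop_if_all_below" && all(below)) {
        dropped <- c(dropped, j)
      } else if (policy == "substitute_half_lod" && any(below)) {
        out[[j]][below] <- lod[[j]] / 2
      }
    }
    if (length(dropped)) {
      out <- out[setdiff(names(out), dropped)]
      rlang::inform(sprintf("dropped %d analyte(s) entirely below LOD: %s",
                            length(dropped), paste(dropped, collapse = ", ")))
    }
  }
  attr(out, "replicate_counts") <- attr(expr, "replicate_counts")
  attr(out, "lod_dropped") <- dropped
  attr(out, "preprocessing") <- c(attr(expr, "preprocessing"), sprintf("apply_lod_policy[%s]", policy))
  out
}
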