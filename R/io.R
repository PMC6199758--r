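## CSV readers and writers for the four table types.  One canonical
## dialect throughout: UTF-8, comma-separated, header row, "." decimal.
## The writers emit a canonical byte form so write(read(f)) round-trips.

## base read.csv: its double parser is correctly rounded, which the
## byte-identical round-trip contract of the writers relies on
read_csv_strict <- function(path) {
  as_tibble(utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE))
}

#' Read an expression CSV
#'
#' Expects a header row of analyte names with the first column holding the
#' group (preparation) label.  All concentrations are in pg/mL.
#'
#' @param path Path to a CSV file.
#' @return A validated expression tibble (`group` + analyte columns).
#' @seealso [write_expression_csv()]
#' @export
read_expression_csv <- function(path) {
  x <- read_csv_strict(path)
  names(x)[1] <- "group"
  for (j in seq_along(x)[-1]) {
    if (is.character(x[[j]])) {
      v <- suppressWarnings(as.numeric(x[[j]]))
      if (anyNA(v)) stop_bad("non-numeric cell in column '%s' (e.g. '%s')",
                             names(x)[j], x[[j]][which(is.na(v))[1]])
      x[[j]] <- v
    }
  }
  validate_expression(x)
}

#' Write an expression table to CSV in canonical form
#'
#' @param x Expression tibble.
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_expression_csv <- function(x, path) {
  x <- validate_expression(x)
  readr::write_csv(x, path, progress = FALSE)
  invisible(x)
}

#' Read a survival-curve CSV
#'
#' The header row gives the timepoints in days; the first column is the
#' group label; every other cell is a survival proportion in \[0, 1\].
#'
#' @inheritParams read_expression_csv
#' @inheritParams validate_survival
#' @return A validated survival tibble.
#' @export
read_survival_csv <- function(path, allow_nonmonotone = FALSE) {
  x <- read_csv_strict(path)
  names(x)[1] <- "group"
  validate_survival(x, allow_nonmonotone = allow_nonmonotone)
}

#' Write a survival-curve table to CSV in canonical form
#'
#' @param x Survival tibble.
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_survival_csv <- function(x, path) {
  x <- validate_survival(x)
  readr::write_csv(x, path, progress = FALSE)
  invisible(x)
}

#' Read a subject-level event CSV
#'
#' Expects columns `subject,group,time,status`.  Status tokens are mapped
#' to the internal 0/1 coding through `status_map`; by default `"1"` and
#' `"death"` denote an event and `"0"` and `"censored"` a censoring.
#'
#' @inheritParams read_expression_csv
#' @param status_map Named vector mapping status tokens to 0/1, e.g.
#'   `c(alive = 0)` to accept an `alive` token as censored (merged with
#'   the defaults).
#' @return A validated event tibble.
#' @export
read_event_csv <- function(path, status_map = NULL) {
  defaults <- c("0" = 0L, "1" = 1L, censored = 0L, death = 1L)
  map <- c(status_map, defaults)
  map <- map[!duplicated(names(map))]
  x <- read_csv_strict(path)
  need <- c("subject", "group", "time", "status")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop_bad("event CSV missing column(s): %s", paste(miss, collapse = ", "))
  tok <- as.character(x$status)
  unknown <- setdiff(unique(tok), names(map))
  if (length(unknown)) stop_bad("unknown status token(s): %s", paste(unknown, collapse = ", "))
  x$status <- as.integer(map[tok])
  validate_events(x)
}

#' Write an event table to CSV in canonical form
#'
#' @param x Event tibble.
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_event_csv <- function(x, path) {
  x <- validate_events(x)
  readr::write_csv(x, path, progress = FALSE)
  invisible(x)
}

#' Read a stiffness-expression CSV
#'
#' Long-format per-well records: `well,stiffness_kpa,analyte,concentration`
#' with an optional `norm_factor` column.
#'
#' @inheritParams read_expression_csv
#' @return A validated stiffness tibble.
#' @export
read_stiffness_csv <- function(path) {
  validate_stiffness(read_csv_strict(path))
}

#' Write a stiffness-expression table to CSV in canonical form
#'
#' @param x Stiffness tibble.
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_stiffness_csv <- function(x, path) {
  x <- validate_stiffness(x)
  readr::write_csv(x, path, progress = FALSE)
  invisible(x)
}
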