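## Config-driven orchestration of the full analysis: simulate (or load) ->
## screen -> fit -> predict -> validate, with seeded reproducibility and a
## machine-readable report.  Each stage's artifacts are written as CSV or
## JSON so any run is auditable and byte-reproducible from config + seed.

#' Build a pipeline configuration
#'
#' Defaults reproduce the reference design: a five-preparation,
#' 35-analyte panel with 21 survival timepoints and 8 potency-linked
#' analytes.  Paths, when given, override the corresponding simulation.
#'
#' @param seed Integer master seed; every stage derives its randomness
#'   from it (events use `seed + 1000`).
#' @param expression_csv,survival_csv Optional input CSV paths; when
#'   `NULL` the cohort is simulated.
#' @param events_csv Optional subject-level event CSV for the validation
#'   stage; when `NULL` and `simulate_events_lambda` is given, events are
#'   simulated.
#' @param simulate Named list of [simulate_cohort()] arguments.
#' @param screen Named list: `rho_threshold`, `alpha`, `aggregation`.
#' @param plsr Named list: `ncomp`, `clip`, `monotone`, `metric`, `top_k`
#'   (`NULL` = Pearson hit-list size).
#' @param simulate_events_lambda Optional named per-group hazard vector
#'   for a simulated validation cohort.
#' @param events_n_per_group,events_censor_time Event-simulation design.
#' @param hr_method Hazard-ratio method for the validation stage.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1,
                            expression_csv = NULL, survival_csv = NULL,
                            events_csv = NULL,
                            simulate = list(),
                            screen = list(),
                            plsr = list(),
                            simulate_events_lambda = NULL,
                            events_n_per_group = 9, events_censor_time = 50,
                            hr_method = "mantel-haenszel") {
  cfg <- list(
    seed = as.integer(seed),
    expression_csv = expression_csv, survival_csv = survival_csv,
    events_csv = events_csv,
    simulate = modifyList(list(n_groups = 5, n_analytes = 35, n_timepoints = 21,
                               n_informative = 8, noise_sd = 10), simulate),
    screen = modifyList(list(rho_threshold = 0.875, alpha = 0.05,
                             aggregation = "majority"), screen),
    plsr = modifyList(list(ncomp = 2, clip = TRUE, monotone = FALSE,
                           metric = "cosine", top_k = NULL), plsr),
    simulate_events_lambda = simulate_events_lambda,
    events_n_per_group = events_n_per_group,
    events_censor_time = events_censor_time,
    hr_method = hr_method)
  if (cfg$screen$rho_threshold < 0 || cfg$screen$rho_threshold > 1)
    stop_bad("rho_threshold must lie in [0, 1]")
  if (cfg$screen$alpha <= 0 || cfg$screen$alpha > 1) stop_bad("alpha must lie in (0, 1]")
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path Config file; keys as in [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) stop_bad("yaml package required for YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(pipeline_config, raw)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: data acquisition (simulation or CSV load), the
#' per-timepoint Pearson screen, the SIMPLS fit, training-data prediction
#' (the observed-vs-fitted parity table), biomarker ranking and consensus,
#' and — when an event table is configured — the Kaplan-Meier/log-rank/
#' hazard-ratio validation statistics.  Every intermediate table is
#' written under `out_dir`; a failure leaves the completed artifacts in
#' place together with a `FAILED` marker naming the stage.
#'
#' @param config A `pipeline_config`.
#' @param out_dir Output directory (created if needed).
#' @return A list of class `run_report`: config echo, per-stage dimensions,
#'   hit lists, consensus set, parity slope, file paths, and validation
#'   statistics (or `NULL`).  Also written as `report.json`.
#' @export
run_pipeline <- function(config, out_dir = tempfile("secretopls_run_")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fail_marker <- file.path(out_dir, "FAILED")
  if (file.exists(fail_marker)) unlink(fail_marker)
  on_fail <- function(stage_name, e) {
    writeLines(sprintf("stage: %s\nerror: %s", stage_name, conditionMessage(e)), fail_marker)
    rlang::abort(sprintf("pipeline stage '%s' failed: %s", stage_name, conditionMessage(e)),
                 class = "secretopls_error")
  }
  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) on_fail(name, e))
  }
  paths <- list()

  dat <- run_stage("data", function() {
    if (is.null(config$expression_csv) != is.null(config$survival_csv))
      stop_bad("expression_csv and survival_csv must be given together")
    if (!is.null(config$expression_csv)) {
      if (!file.exists(config$expression_csv))
        stop_bad("expression file not found: %s", config$expression_csv)
      if (!file.exists(config$survival_csv))
        stop_bad("survival file not found: %s", config$survival_csv)
      list(expression = read_expression_csv(config$expression_csv),
           survival = read_survival_csv(config$survival_csv), truth = NULL)
    } else {
      sim <- do.call(simulate_cohort, c(config$simulate, list(seed = config$seed)))
      unclass(sim)
    }
  })
  paths$expression <- file.path(out_dir, "expression.csv")
  paths$survival <- file.path(out_dir, "survival.csv")
  write_expression_csv(dat$expression, paths$expression)
  write_survival_csv(dat$survival, paths$survival)

  scr <- run_stage("screen", function() {
    do.call(screen_survival_correlation,
            c(list(expr = dat$expression, surv = dat$survival), config$screen))
  })
  paths$screen <- file.path(out_dir, "screen_cells.csv")
  readr::write_csv(tidy(scr), paths$screen, progress = FALSE)
  pearson_hits <- screen_hits(scr)

  model <- run_stage("fit", function() {
    fit_plsr(dat$expression, dat$survival, ncomp = config$plsr$ncomp)
  })
  paths$model <- file.path(out_dir, "model.json")
  write_plsr_json(model, paths$model)

  pred <- run_stage("predict", function() {
    predict(model, dat$expression, clip = config$plsr$clip,
            monotone = config$plsr$monotone)
  })
  paths$predictions <- file.path(out_dir, "predicted_survival.csv")
  readr::write_csv(pred, paths$predictions, progress = FALSE)
  slope <- parity_slope(dat$survival, pred)

  ranking <- run_stage("biomarkers", function() {
    rank_biomarkers(model, metric = config$plsr$metric)
  })
  top_k <- config$plsr$top_k %||% length(pearson_hits)
  plsr_hits <- head(ranking$analyte, top_k)
  consensus <- consensus_biomarkers(pearson_hits, plsr_hits)
  paths$ranking <- file.path(out_dir, "biomarker_ranking.csv")
  readr::write_csv(ranking, paths$ranking, progress = FALSE)

  stats <- NULL
  if (!is.null(config$events_csv) || !is.null(config$simulate_events_lambda)) {
    stats <- run_stage("validate", function() {
      ev <- if (!is.null(config$events_csv)) {
        if (!file.exists(config$events_csv))
          stop_bad("events file not found: %s", config$events_csv)
        read_event_csv(config$events_csv)
      } else {
        simulate_events(config$simulate_events_lambda,
                        n_per_group = config$events_n_per_group,
                        censor_time = config$events_censor_time,
                        seed = config$seed + 1000L)
      }
      gs <- unique(ev$group)
      if (length(gs) < 2) stop_bad("validation needs at least 2 groups")
      lr <- logrank_test(ev, gs[1], gs[2])
      hr <- hazard_ratio(ev, gs[1], gs[2], method = config$hr_method)
      med <- median_survival(ev)
      paths$events <<- file.path(out_dir, "events.csv")
      write_event_csv(ev, paths$events)
      list(logrank = lr, hazard_ratio = hr, median = med)
    })
  }

  report <- structure(list(
    package_version = as.character(utils::packageVersion("secretopls")),
    seed = config$seed,
    config = unclass(config),
    dims = list(expression = dim(dat$expression) - c(0L, 1L),
                survival = dim(dat$survival) - c(0L, 1L)),
    pearson_hits = pearson_hits,
    plsr_top = plsr_hits,
    consensus = as.character(consensus),
    variance_explained = variance_explained(model),
    parity_slope = slope,
    paths = paths,
    stats = stats), class = "run_report")
  jsonlite::write_json(
    purrr::map(report, function(x) if (inherits(x, "tbl_df")) as.data.frame(x) else x),
    file.path(out_dir, "report.json"), digits = I(17), auto_unbox = TRUE, force = TRUE,
    null = "null")
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("secretopls run (seed %d): %d groups x %d analytes -> %d timepoints\n",
              x$seed, x$dims$expression[1], x$dims$expression[2], x$dims$survival[2]))
  cat(sprintf("Pearson hits (%d): %s\n", length(x$pearson_hits),
              paste(x$pearson_hits, collapse = ", ")))
  cat(sprintf("consensus (%d): %s\n", length(x$consensus),
              paste(x$consensus, collapse = ", ")))
  cat(sprintf("parity slope (fitted vs observed): %.4f\n", x$parity_slope))
  invisible(x)
}

#' Least-squares parity slope of fitted against observed curves
#'
#' Pools every (group, timepoint) pair of the two wide tables and regresses
#' fitted on observed; a slope near one indicates the model reproduces the
#' training curves without systematic shrinkage or inflation.
#'
#' @param observed,fitted Wide survival tibbles with matching shape.
#' @return The regression slope (scalar).
#' @export
parity_slope <- function(observed, fitted) {
  o <- as.vector(wide_matrix(as_tibble(observed)))
  f <- as.vector(wide_matrix(as_tibble(fitted)))
  if (length(o) != length(f)) stop_bad("observed and fitted shapes differ")
  unname(coef(lm(f ~ o))[2])
}

#' Plot observed and predicted survival curves
#'
#' @param observed Wide survival tibble.
#' @param predicted Optional wide tibble of predictions (dashed lines).
#' @return A ggplot object.
#' @export
plot_survival_curves <- function(observed, predicted = NULL) {
  longify <- function(x, kind) {
    as_tibble(x) |>
      tidyr::pivot_longer(-"group", names_to = "day", values_to = "survival") |>
      dplyr::mutate(day = as.numeric(.data$day), kind = kind)
  }
  d <- longify(observed, "observed")
  if (!is.null(predicted)) d <- dplyr::bind_rows(d, longify(predicted, "predicted"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$day, y = .data$survival,
                                  colour = .data$group, linetype = .data$kind)) +
    ggplot2::geom_line() +
    ggplot2::scale_linetype_manual(values = c(observed = "solid", predicted = "dashed")) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "days post-irradiation", y = "survival proportion") +
    ggplot2::theme_minimal()
}
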