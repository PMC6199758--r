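## Seeded generators emulating the structure the analysis assumes: a latent
## potency score links secreted-analyte concentrations to post-irradiation
## survival curves, and subject-level event tables follow proportional
## hazards with administrative censoring.

#' Simulate a potency-linked secretome/survival cohort
#'
#' Each preparation (group) `g` carries a latent potency score
#' `theta_g`, by default equally spaced on \[0, 1\] so that even small
#' designs span the potency range.  Informative analytes follow
#' `a_j + b_j * theta_g + eps` with `eps ~ N(0, noise_sd)` truncated at
#' zero (concentrations are physical); non-informative analytes are
#' potency-independent (`a_j + eps`).  Survival follows a proportional-
#' hazards law `S_g(t) = exp(-exp(-beta * theta_g) * Lambda(t))` with a
#' piecewise-linear baseline cumulative hazard that is flat before
#' `lag_days` (a lag phase mimicking radiation-injury kinetics) and rises
#' with slope `lambda0` per day thereafter.  Higher-potency groups
#' therefore have uniformly higher curves.
#'
#' @param n_groups Number of preparations (>= 3).
#' @param n_analytes Number of secreted analytes.
#' @param n_timepoints Number of survival timepoints (day 0 .. `follow_up`,
#'   equally spaced).
#' @param n_informative Number of potency-linked analytes
#'   (1 .. `n_analytes`).
#' @param noise_sd Assay noise standard deviation in pg/mL (>= 0).
#' @param seed Integer seed; identical seeds give byte-identical output.
#' @param random_theta Draw `theta` uniformly on \[0, 1\] instead of the
#'   equally spaced default.
#' @param beta Potency effect on the log hazard (default 3: the weakest
#'   and strongest groups reach roughly 20% and 92% survival at day 50).
#' @param lambda0 Baseline hazard slope per day after the lag.
#' @param lag_days Days with no deaths at the start of follow-up.
#' @param follow_up Duration of follow-up in days.
#' @return A list of class `secreto_sim` with elements `expression` (wide
#'   tibble), `survival` (wide tibble) and `truth` (list: `theta`,
#'   `informative` analyte names, `intercepts`, `slopes`, `noise_sd`,
#'   `beta`, `cum_hazard`, `timepoints`, `seed`).
#' @export
simulate_cohort <- function(n_groups = 5, n_analytes = 35, n_timepoints = 21,
                            n_informative = 8, noise_sd = 10, seed = 1,
                            random_theta = FALSE, beta = 3, lambda0 = 0.0381,
                            lag_days = 8, follow_up = 50) {
  if (n_groups < 3) stop_bad("n_groups must be >= 3")
  if (n_informative < 1 || n_informative > n_analytes)
    stop_bad("n_informative must be in 1..n_analytes")
  if (noise_sd < 0) stop_bad("noise_sd must be >= 0")
  set.seed(seed)
  groups <- sprintf("prep%d", seq_len(n_groups))
  analytes <- sprintf("A%02d", seq_len(n_analytes))
  theta <- if (random_theta) sort(runif(n_groups)) else seq(0, 1, length.out = n_groups)
  tp <- seq(0, follow_up, length.out = n_timepoints)
  Lam <- lambda0 * pmax(0, tp - lag_days)
  S <- vapply(Lam, function(L) exp(-exp(-beta * theta) * L), numeric(n_groups))
  informative <- sort(sample.int(n_analytes, n_informative))
  a <- runif(n_analytes, 50, 500)
  b <- numeric(n_analytes)
  b[informative] <- runif(n_informative, 100, 400)
  X <- matrix(0, n_groups, n_analytes)
  for (j in seq_len(n_analytes)) {
    eps <- if (noise_sd > 0) rnorm(n_groups, 0, noise_sd) else 0
    X[, j] <- pmax(0, a[j] + b[j] * theta + eps)
  }
  expression <- as_tibble(cbind(tibble(group = groups), as.data.frame(X)))
  names(expression) <- c("group", analytes)
  survival <- as_tibble(cbind(tibble(group = groups), as.data.frame(S)))
  names(survival) <- c("group", as.character(tp))
  structure(
    list(expression = validate_expression(expression),
         survival = validate_survival(survival),
         truth = list(theta = setNames(theta, groups),
                      informative = analytes[informative],
                      intercepts = setNames(a, analytes),
                      slopes = setNames(b, analytes),
                      noise_sd = noise_sd, beta = beta,
                      cum_hazard = setNames(Lam, tp), timepoints = tp,
                      seed = seed)),
    class = "secreto_sim")
}

#' Simulate a noise-free cohort driven by exactly two latent factors
#'
#' Diagnostic generator for the two-component regression: both blocks are
#' exact affine functions of a two-dimensional latent potency score, so
#' the centred predictor and response matrices have rank two and a
#' two-component fit reproduces the response exactly.  Survival rows are
#' built as `C(t) + u1_g A(t) + u2_g B(t)` with non-increasing basis
#' curves chosen so every row is a valid survival curve.
#'
#' @inheritParams simulate_cohort
#' @return A list of class `secreto_sim` (see [simulate_cohort()]); the
#'   truth element records the latent scores and basis curves.
#' @export
simulate_rank2_cohort <- function(n_groups = 5, n_analytes = 35, n_timepoints = 21,
                                  seed = 1, follow_up = 50) {
  if (n_groups < 4) stop_bad("n_groups must be >= 4 for a rank-2 design")
  set.seed(seed)
  groups <- sprintf("prep%d", seq_len(n_groups))
  analytes <- sprintf("A%02d", seq_len(n_analytes))
  tp <- seq(0, follow_up, length.out = n_timepoints)
  u <- cbind(runif(n_groups), runif(n_groups))
  ## non-increasing basis curves, zero at day 0
  base <- 1 - 0.8 * (tp / follow_up)                 # 1 -> 0.2
  bump1 <- -0.1 * (tp / follow_up)                   # 0 -> -0.1
  bump2 <- -0.1 * (tp / follow_up)^2                 # 0 -> -0.1, distinct shape
  S <- outer(rep(1, n_groups), base) + u[, 1] %o% bump1 + u[, 2] %o% bump2
  a <- runif(n_analytes, 50, 500)
  B <- matrix(runif(n_analytes * 2, 20, 200), n_analytes, 2)
  X <- outer(rep(1, n_groups), a) + u %*% t(B)
  expression <- as_tibble(cbind(tibble(group = groups), as.data.frame(X)))
  names(expression) <- c("group", analytes)
  survival <- as_tibble(cbind(tibble(group = groups), as.data.frame(S)))
  names(survival) <- c("group", as.character(tp))
  structure(
    list(expression = validate_expression(expression),
         survival = validate_survival(survival),
         truth = list(latent = u, basis = list(base = base, bump1 = bump1, bump2 = bump2),
                      intercepts = setNames(a, analytes), loadings = B, seed = seed)),
    class = "secreto_sim")
}

#' Simulate subject-level event tables under exponential hazards
#'
#' Death times are exponential with the group's hazard rate and subjects
#' still alive at `censor_time` are administratively censored, emulating a
#' fixed-duration survival study.  The true hazard ratio between two
#' groups is the ratio of their rates.
#'
#' @param lambda Named numeric vector of per-day hazard rates (> 0), one
#'   per group.
#' @param n_per_group Subjects per group (single value or vector matching
#'   `lambda`).
#' @param censor_time Administrative censoring time in days (default 50).
#' @param seed Integer seed.
#' @return A validated event tibble (`subject`, `group`, `time`, `status`).
#' @export
simulate_events <- function(lambda, n_per_group = 9, censor_time = 50, seed = 1) {
  if (is.null(names(lambda)) || any(!nzchar(names(lambda))))
    stop_bad("lambda must be a named vector (names = group labels)")
  if (any(!is.finite(lambda) | lambda <= 0)) stop_bad("hazard rates must be > 0")
  n_per_group <- rep(n_per_group, length.out = length(lambda))
  if (any(n_per_group < 1)) stop_bad("n_per_group must be >= 1")
  set.seed(seed)
  recs <- purrr::map2(names(lambda), seq_along(lambda), function(g, i) {
    t_death <- rexp(n_per_group[i], lambda[[i]])
    tibble(subject = sprintf("%s_s%d", g, seq_len(n_per_group[i])),
           group = g,
           time = pmin(t_death, censor_time),
           status = as.integer(t_death <= censor_time))
  })
  validate_events(dplyr::bind_rows(recs))
}

#' Simulate per-well expression across substratum stiffness
#'
#' Concentration follows `intercept + slope * (-log10(stiffness)) + eps`,
#' truncated at zero, so analytes with positive `slope` increase as the
#' substratum softens (the mechanopriming direction of interest) and a
#' zero slope is potency-null.
#'
#' @param slopes Named numeric vector of per-analyte trend slopes (pg/mL
#'   per decade of softening); names become analyte labels.
#' @param stiffness_kpa Stiffness levels in kPa (>= 2 distinct values).
#' @param reps_per_level Replicate wells per stiffness level (>= 1;
#'   default 3, the scale of a typical substratum experiment).
#' @param intercepts Optional named vector of baseline concentrations;
#'   defaults to 200 pg/mL for every analyte.
#' @param noise_sd Assay noise sd in pg/mL.
#' @param seed Integer seed.
#' @return A validated stiffness tibble.
#' @export
simulate_stiffness <- function(slopes, stiffness_kpa = c(1, 10, 100),
                               reps_per_level = 3, intercepts = NULL,
                               noise_sd = 10, seed = 1) {
  if (length(unique(stiffness_kpa)) < 2) stop_bad("need >= 2 stiffness levels")
  if (reps_per_level < 1) stop_bad("reps_per_level must be >= 1")
  if (noise_sd < 0) stop_bad("noise_sd must be >= 0")
  if (is.null(names(slopes))) names(slopes) <- sprintf("A%02d", seq_along(slopes))
  if (is.null(intercepts)) intercepts <- setNames(rep(200, length(slopes)), names(slopes))
  set.seed(seed)
  stiff <- rep(stiffness_kpa, each = reps_per_level)
  wells <- sprintf("w%d", seq_along(stiff))
  recs <- purrr::imap(slopes, function(b, an) {
    eps <- if (noise_sd > 0) rnorm(length(stiff), 0, noise_sd) else 0
    tibble(well = wells, stiffness_kpa = stiff, analyte = an,
           concentration = pmax(0, intercepts[[an]] + b * (-log10(stiff)) + eps),
           norm_factor = 1)
  })
  validate_stiffness(dplyr::bind_rows(recs))
}

#' @export
print.secreto_sim <- function(x, ...) {
  cat(sprintf("Synthetic secretome cohort: %d groups x %d analytes; %d timepoints (seed %s)\n",
              nrow(x$expression), ncol(x$expression) - 1L,
              ncol(x$survival) - 1L, format(x$truth$seed)))
  invisible(x)
}
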