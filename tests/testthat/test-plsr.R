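test_that("column standardization matches its contract and inverts exactly", {
  s <- standardize_columns(matrix(c(1, 2, 3), ncol = 1))
  expect_equal(as.vector(s$z), c(-1, 0, 1))

  s2 <- standardize_columns(matrix(c(4, 4, 4), ncol = 1))
  expect_equal(as.vector(s2$z), c(0, 0, 0))
  expect_true(s2$constant)

  set.seed(17)
  M <- matrix(runif(5 * 35, 0, 100), 5, 35)
  s3 <- standardize_columns(M)
  expect_equal(unname(colMeans(s3$z)), rep(0, 35), tolerance = 1e-12)
  expect_equal(unname(apply(s3$z, 2, sd)), rep(1, 35), tolerance = 1e-12)
  back <- secretopls:::std_invert(s3, s3$z)
  expect_equal(back, M, tolerance = 1e-12, ignore_attr = TRUE)

  expect_error(standardize_columns(matrix(1, 1, 3)), "at least 2 rows")
})

test_that("the coefficient matrix has an intercept row plus one row per analyte", {
  sim <- simulate_cohort(seed = 4)
  m <- fit_plsr(sim$expression, sim$survival, ncomp = 2)
  expect_equal(dim(m$coefficients), c(36L, 21L))
  expect_identical(rownames(m$coefficients)[1], "(Intercept)")
  expect_equal(m$coefficients[1, ], setNames(rep(0, 21), colnames(m$coefficients)))
  ## original-scale coefficients reproduce the same predictions
  Bo <- coef(m, scale = "original")
  expect_equal(dim(Bo), c(36L, 21L))
  X <- as.matrix(sim$expression[-1])
  pred_raw <- cbind(1, X) %*% Bo
  pred_fun <- as.matrix(predict(m, sim$expression, clip = FALSE)[-1])
  expect_equal(unname(pred_raw), unname(pred_fun), tolerance = 1e-9)
})

test_that("a response tracking the predictor is fit exactly with one component", {
  ## single-analyte block whose standardized column equals the standardized
  ## response: the one component carries the entire association
  set.seed(23)
  y <- sort(runif(6, 0.1, 0.95), decreasing = TRUE)
  expr <- tibble::tibble(group = sprintf("g%d", 1:6), A01 = 900 * y + 20)
  surv <- tibble::tibble(group = expr$group, `10` = y, `20` = y * 0.9)
  m <- fit_plsr(expr, surv, ncomp = 1)
  ve <- variance_explained(m)
  expect_equal(ve$y_variance[1], 1, tolerance = 1e-9)
  pred <- predict(m, expr, clip = FALSE)
  expect_equal(as.matrix(pred[-1]), as.matrix(surv[-1]), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("variance-explained fractions are within bounds and additive", {
  for (seed in 1:10) {
    expr <- rand_expression(n = 7, p = 9, seed = seed)
    surv <- rand_survival(n = 7, q = 5, seed = seed + 100)
    surv$group <- expr$group
    m <- fit_plsr(expr, surv, ncomp = 6)   # A = n - 1
    ve <- variance_explained(m)
    expect_true(all(ve$x_variance >= -1e-12 & ve$x_variance <= 1 + 1e-9))
    expect_true(all(ve$y_variance >= -1e-12 & ve$y_variance <= 1 + 1e-9))
    expect_lte(ve$x_cumulative[6], 1 + 1e-9)
    expect_lte(ve$y_cumulative[6], 1 + 1e-9)
  }
})

test_that("training fit improves monotonically with more components", {
  expr <- rand_expression(n = 7, p = 10, seed = 55)
  surv <- rand_survival(n = 7, q = 6, seed = 56)
  surv$group <- expr$group
  Y <- as.matrix(surv[-1])
  rss <- sapply(1:6, function(a) {
    m <- fit_plsr(expr, surv, ncomp = a)
    sum((as.matrix(predict(m, expr, clip = FALSE)[-1]) - Y)^2)
  })
  expect_true(all(diff(rss) <= 1e-9))
})

test_that("predictions are invariant to positive rescaling of predictor columns", {
  sim <- simulate_cohort(seed = 31, n_analytes = 10)
  m <- fit_plsr(sim$expression, sim$survival)
  base <- predict(m, sim$expression)
  scaled <- sim$expression
  scaled[[4]] <- scaled[[4]] * 1000       # e.g. ng/mL recorded as pg/mL
  m2 <- fit_plsr(scaled, sim$survival)
  expect_equal(as.matrix(predict(m2, scaled)[-1]), as.matrix(base[-1]),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("prediction clips to [0,1], restores constant training columns, and errors on mismatch", {
  sim <- simulate_cohort(seed = 8, n_analytes = 6, n_informative = 3)
  m <- fit_plsr(sim$expression, sim$survival)
  shifted <- sim$expression
  shifted[-1] <- shifted[-1] * 3          # push predictions far out of range
  pred <- predict(m, shifted)
  expect_true(all(as.matrix(pred[-1]) >= 0 & as.matrix(pred[-1]) <= 1))
  expect_equal(pred[["0"]], rep(1, 5))    # day 0 constant in training
  raw <- predict(m, shifted, clip = FALSE)
  expect_gt(max(as.matrix(raw[-1])), 1)

  reordered <- sim$expression[c(1, sample(2:7))]
  expect_equal(predict(m, reordered), predict(m, sim$expression))

  bad <- sim$expression[-3]
  expect_error(predict(m, bad), "analyte set mismatch; missing: \\[A02\\]")
  extra <- sim$expression; extra$NEW <- 1:5
  expect_error(predict(m, extra), "extra: \\[NEW\\]")
})

test_that("monotone post-processing equals the brute-force non-increasing projection", {
  set.seed(77)
  for (i in 1:50) {
    y <- rnorm(5)
    expect_equal(secretopls:::pava_nonincreasing(y), oracle_pava_nonincreasing(y),
                 tolerance = 1e-12)
  }
  sim <- simulate_cohort(seed = 12, noise_sd = 40)
  m <- fit_plsr(sim$expression, sim$survival)
  wig <- sim$expression
  wig[-1] <- wig[-1] * 1.7
  pred <- predict(m, wig, monotone = TRUE)
  M <- as.matrix(pred[-1])
  expect_true(all(M[, -1] - M[, -ncol(M)] <= 1e-12))
  expect_identical(attr(pred, "postprocessing"), c("monotone", "clip"))
})

test_that("fit guards reject impossible shapes", {
  sim <- simulate_cohort(seed = 2, n_analytes = 4, n_informative = 2)
  expect_error(fit_plsr(sim$expression, sim$survival, ncomp = 5), "exceeds min")
  const <- sim$expression
  const[-1] <- lapply(const[-1], function(x) rep(1, length(x)))
  expect_error(fit_plsr(const, sim$survival), "all analyte columns are constant")
})

test_that("a model reloaded from JSON predicts bit-identically", {
  sim <- simulate_cohort(seed = 19)
  m <- fit_plsr(sim$expression, sim$survival)
  f <- withr::local_tempfile(fileext = ".json")
  write_plsr_json(m, f)
  m2 <- read_plsr_json(f)
  p1 <- predict(m, sim$expression)
  p2 <- predict(m2, sim$expression)
  expect_identical(as.matrix(p1[-1]), as.matrix(p2[-1]))
  expect_identical(m2$analytes, m$analytes)
})
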