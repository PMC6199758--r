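nine_mice <- function(deaths = c(10, 13, 16, 20), n = 9, censor = 50, group = "D") {
  tibble::tibble(
    subject = sprintf("m%d", seq_len(n)),
    group = group,
    time = c(deaths, rep(censor, n - length(deaths))),
    status = c(rep(1L, length(deaths)), rep(0L, n - length(deaths))))
}

test_that("the product-limit estimate for the 9-mouse cohort is 5/9 at day 50", {
  curve <- km_curve(nine_mice())
  expect_equal(km_at(curve, 50), 5 / 9)
  expect_equal(km_at(curve, 50) * 100, 55.6, tolerance = 1e-3)
  ## explicit product form (8/9)(7/8)(6/7)(5/6)
  expect_equal(km_at(curve, 50), (8 / 9) * (7 / 8) * (6 / 7) * (5 / 6))
})

test_that("KM with no deaths stays at 1 and a death strictly lowers the curve", {
  ev <- nine_mice(deaths = numeric(0))
  expect_true(all(km_curve(ev)$estimate == 1))
  ev2 <- nine_mice(deaths = 12)
  c2 <- km_curve(ev2)
  expect_lt(km_at(c2, 13), 1)
  expect_equal(km_at(c2, 11), 1)
})

test_that("KM without censoring equals the empirical fraction alive", {
  set.seed(33)
  for (i in 1:10) {
    times <- round(rexp(30, 0.05) + 0.1, 3)
    ev <- tibble::tibble(subject = sprintf("s%d", 1:30), group = "G",
                         time = times, status = 1L)
    curve <- km_curve(ev)
    for (t in c(5, 20, 40)) expect_equal(km_at(curve, t), oracle_km_counting(times, t))
  }
})

test_that("median survival follows the first-crossing convention, undefined when unreached", {
  ev <- nine_mice(deaths = c(9, 10, 11, 12, 13, 15, 16, 17, 18), n = 9)
  expect_equal(median_survival(ev)$median, 13)
  expect_true(is.na(median_survival(nine_mice(deaths = numeric(0)))$median))
  ## S hits exactly 0.5 at a death time: that time is the median
  ev3 <- tibble::tibble(subject = sprintf("s%d", 1:4), group = "G",
                        time = c(3, 3, 10, 10), status = 1L)
  expect_equal(median_survival(ev3)$median, 3)
})

test_that("log-rank matches the single-stratum hand tabulation", {
  ## one death time, 10 vs 10 at risk, the death in A: O-E = 0.5, V = 0.25
  ev <- dplyr::bind_rows(
    tibble::tibble(subject = sprintf("a%d", 1:10), group = "A",
                   time = c(5, rep(50, 9)), status = c(1L, rep(0L, 9))),
    tibble::tibble(subject = sprintf("b%d", 1:10), group = "B",
                   time = rep(50, 10), status = 0L))
  lr <- logrank_test(ev, "A", "B")
  expect_equal(lr$observed_a - lr$expected_a, 0.5)
  expect_equal(lr$variance, 0.25)
  expect_equal(lr$statistic, 1.0)
  expect_equal(lr$p.value, pchisq(1, 1, lower.tail = FALSE))
})

test_that("log-rank is symmetric in group labels, conserves totals, and degenerates to p = 1", {
  ev <- rand_events(n = 40, seed = 3)
  ab <- logrank_test(ev, "A", "B")
  ba <- logrank_test(ev, "B", "A")
  expect_equal(ab$statistic, ba$statistic)
  expect_equal(ab$p.value, ba$p.value)
  expect_equal(ab$observed_a + ab$observed_b, ab$expected_a + ab$expected_b)

  ## identical event histories in both groups
  mirror <- dplyr::bind_rows(
    tibble::tibble(subject = sprintf("a%d", 1:6), group = "A",
                   time = c(3, 8, 12, 20, 50, 50), status = c(1L, 1L, 1L, 1L, 0L, 0L)),
    tibble::tibble(subject = sprintf("b%d", 1:6), group = "B",
                   time = c(3, 8, 12, 20, 50, 50), status = c(1L, 1L, 1L, 1L, 0L, 0L)))
  lr <- logrank_test(mirror, "A", "B")
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  expect_equal(lr$p.value, 1)
  expect_error(logrank_test(nine_mice(deaths = numeric(0)), "D", "D"), "no deaths")
})

test_that("hazard ratio matches a manual hypergeometric tabulation and inverts exactly", {
  ## 3 vs 3, A dies at 1,2,3; B dies at 4,5,6 — strata (n_A, n_B, death in A):
  ## (3,3,A),(2,3,A),(1,3,A),(0,3,B)x3; E_A = 1/2+2/5+1/4; V = 1/4+6/25+3/16
  ev <- dplyr::bind_rows(
    tibble::tibble(subject = sprintf("a%d", 1:3), group = "A", time = c(1, 2, 3), status = 1L),
    tibble::tibble(subject = sprintf("b%d", 1:3), group = "B", time = c(4, 5, 6), status = 1L))
  E_A <- 3 / 6 + 2 / 5 + 1 / 4
  V <- (3 * 3) / 36 + (2 * 3) / 25 + (1 * 3) / 16
  hr <- hazard_ratio(ev, "A", "B")
  expect_equal(hr$hr, exp((3 - E_A) / V), tolerance = 1e-12)
  expect_true(hr$conf.low < hr$hr & hr$hr < hr$conf.high)

  ev2 <- rand_events(n = 40, seed = 11)
  expect_equal(hazard_ratio(ev2, "A", "B")$hr * hazard_ratio(ev2, "B", "A")$hr,
               1, tolerance = 1e-9)
  same <- dplyr::bind_rows(
    tibble::tibble(subject = sprintf("a%d", 1:5), group = "A",
                   time = c(2, 4, 6, 50, 50), status = c(1L, 1L, 1L, 0L, 0L)),
    tibble::tibble(subject = sprintf("b%d", 1:5), group = "B",
                   time = c(2, 4, 6, 50, 50), status = c(1L, 1L, 1L, 0L, 0L)))
  expect_equal(hazard_ratio(same, "A", "B")$hr, 1, tolerance = 1e-12)
  oe <- hazard_ratio(ev2, "A", "B", method = "logrank-oe")
  lr <- logrank_test(ev2, "A", "B")
  expect_equal(oe$hr, (lr$observed_a / lr$expected_a) / (lr$observed_b / lr$expected_b))
})

test_that("Welch t test handles symmetry, tails, and matches the reference routine", {
  sym <- welch_t(c(1, 2, 3), c(1, 2, 3), alternative = "greater")
  expect_equal(sym$statistic, 0)
  expect_equal(sym$p.value, 0.5)

  set.seed(44)
  a <- rnorm(12, 1); b <- rnorm(9, 0, 2)
  for (alt in c("two.sided", "greater", "less")) {
    got <- welch_t(a, b, alternative = alt)
    ref <- t.test(a, b, alternative = alt, var.equal = FALSE)
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(got$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(got$p.value, ref$p.value, tolerance = 1e-10)
  }
  ## converges to the pooled t at equal variances and large n
  set.seed(45)
  a <- rnorm(500); b <- rnorm(500)
  expect_equal(welch_t(a, b)$p.value,
               t.test(a, b, var.equal = TRUE)$p.value, tolerance = 1e-3)
  expect_error(welch_t(1, c(1, 2)), "n >= 2")
})

test_that("p adjustment: identity at m = 1, Bonferroni arithmetic, Holm dominance", {
  expect_equal(adjust_pvalues(0.03), 0.03)
  expect_equal(adjust_pvalues(c(0.01, 0.02), method = "bonferroni"), c(0.02, 0.04))
  set.seed(46)
  for (i in 1:100) {
    p <- runif(sample(2:10, 1))
    expect_true(all(adjust_pvalues(p, "holm") <= adjust_pvalues(p, "bonferroni") + 1e-15))
  }
  expect_error(adjust_pvalues(c(0.5, 1.2)), "\\[0, 1\\]")
})
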