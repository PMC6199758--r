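test_that("technical replicates collapse to the arithmetic mean", {
  wells <- tibble::tibble(
    group = c("g1", "g1", "g1", "g2", "g2", "g2"),
    analyte = c("IL6", "IL6", "VEGF", "IL6", "IL6", "VEGF"),
    concentration = c(10, 12, 7.3, 4, 6, 2))
  out <- collapse_technical_replicates(wells)
  expect_equal(out$IL6, c(11, 5))
  expect_equal(out$VEGF, c(7.3, 2))
  counts <- attr(out, "replicate_counts")
  expect_equal(counts$IL6, c(2L, 2L))
  expect_equal(counts$VEGF, c(1L, 1L))
})

test_that("collapsing matches a direct sum/count oracle on random replicate sets", {
  set.seed(42)
  for (i in 1:100) {
    g <- sample(2:4, 1); a <- sample(2:5, 1)
    wells <- tidyr::expand_grid(group = sprintf("g%d", 1:g),
                                analyte = sprintf("an%d", 1:a)) |>
      dplyr::slice(rep(seq_len(g * a), times = sample(1:4, g * a, replace = TRUE))) |>
      dplyr::mutate(concentration = runif(dplyr::n(), 0, 100))
    out <- collapse_technical_replicates(wells)
    for (an in sprintf("an%d", 1:a)) {
      for (gr in sprintf("g%d", 1:g)) {
        sub <- wells$concentration[wells$group == gr & wells$analyte == an]
        expect_equal(out[[an]][out$group == gr], sum(sub) / length(sub))
      }
    }
  }
})

test_that("a missing (group, analyte) pair is reported by name", {
  wells <- tibble::tibble(group = c("g1", "g1", "g2"),
                          analyte = c("IL6", "VEGF", "IL6"),
                          concentration = c(1, 2, 3))
  expect_error(collapse_technical_replicates(wells), "\\(g2, VEGF\\)")
})

test_that("cell-count normalization scales rows and matches an elementwise oracle", {
  x <- rand_expression(n = 4, p = 6, seed = 3)
  expect_equal(normalize_by_cell_count(x, setNames(rep(1, 4), x$group)),
               x, ignore_attr = TRUE)
  f <- setNames(c(2, 1, 1, 1), x$group)
  out <- normalize_by_cell_count(x, f)
  expect_equal(as.matrix(out[-1]), as.matrix(x[-1]) * c(2, 1, 1, 1), ignore_attr = TRUE)
  set.seed(9)
  fr <- setNames(runif(4, 0.5, 2), x$group)
  out2 <- normalize_by_cell_count(x, fr)
  for (i in 1:4) for (j in 2:7)
    expect_equal(out2[[j]][i], x[[j]][i] * fr[[x$group[i]]])
  expect_error(normalize_by_cell_count(x, setNames(c(0, 1, 1, 1), x$group)), "must be > 0")
  expect_error(normalize_by_cell_count(x, fr[-1]), "no normalization factor")
})

test_that("below-LOD policy drops all-below analytes, substitutes half-LOD, or keeps", {
  x <- tibble::tibble(group = c("g1", "g2"), BMP2 = c(0.5, 0.8), IL6 = c(50, 60),
                      THPO = c(0, 1))
  lod <- c(BMP2 = 2, IL6 = 1, THPO = 4)
  expect_message(out <- apply_lod_policy(x, lod), "BMP2, THPO")
  expect_identical(names(out), c("group", "IL6"))
  expect_identical(attr(out, "lod_dropped"), c("BMP2", "THPO"))

  clean <- tibble::tibble(group = c("g1", "g2"), IL6 = c(50, 60))
  expect_equal(apply_lod_policy(clean, c(IL6 = 1)), clean, ignore_attr = TRUE)

  sub <- apply_lod_policy(x, lod, policy = "substitute_half_lod")
  expect_equal(sub$THPO, c(2, 2))      # 0 -> lod/2 = 2; 1 < 4 -> 2 as well
  expect_equal(sub$BMP2, c(1, 1))
  expect_equal(sub$IL6, c(50, 60))

  expect_equal(apply_lod_policy(x, policy = "keep"), x, ignore_attr = TRUE)
  expect_error(apply_lod_policy(x, NULL, policy = "drop_if_all_below"), "requires per-analyte")
})

test_that("collapse -> normalize -> lod with neutral parameters is idempotent and logged", {
  wells <- tidyr::expand_grid(group = sprintf("g%d", 1:3), analyte = sprintf("an%d", 1:4)) |>
    dplyr::mutate(concentration = runif(dplyr::n(), 10, 100))
  step1 <- collapse_technical_replicates(wells)
  step2 <- normalize_by_cell_count(step1, setNames(rep(1, 3), step1$group))
  step3 <- apply_lod_policy(step2, policy = "keep")
  expect_equal(step3, step1, ignore_attr = TRUE)
  expect_identical(attr(step3, "preprocessing")[1], "collapse_technical_replicates")
  expect_match(attr(step3, "preprocessing")[2], "normalize_by_cell_count")
  expect_match(attr(step3, "preprocessing")[3], "apply_lod_policy\\[keep\\]")
  ## re-applying the neutral tail leaves the table unchanged
  again <- apply_lod_policy(
    normalize_by_cell_count(step3, setNames(rep(1, 3), step3$group)), policy = "keep")
  expect_equal(again, step3, ignore_attr = TRUE)
})
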