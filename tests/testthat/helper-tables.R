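## Programmatic fixtures and brute-force oracles shared across the suite.

rand_expression <- function(n = 5, p = 8, seed = 1, prefix = "A") {
  set.seed(seed)
  M <- matrix(round(runif(n * p, 1, 1000), 4), n, p)
  out <- tibble::as_tibble(as.data.frame(M))
  names(out) <- sprintf("%s%02d", prefix, seq_len(p))
  dplyr::bind_cols(tibble::tibble(group = sprintf("g%d", seq_len(n))), out)
}

## valid survival table: per-row sorted-decreasing uniforms on a shared grid
rand_survival <- function(n = 5, q = 8, seed = 1, with_day0 = FALSE) {
  set.seed(seed)
  days <- if (with_day0) seq(0, 50, length.out = q) else sort(sample(1:200, q))
  M <- matrix(runif(n * q), n, q)
  if (q > 1) M <- t(apply(M, 1, function(r) sort(r, decreasing = TRUE)))
  if (with_day0) M[, 1] <- 1
  M <- round(M, 6)
  if (q > 1) M <- t(apply(M, 1, cummin))  # rounding must not break monotonicity
  out <- tibble::as_tibble(as.data.frame(M))
  names(out) <- as.character(days)
  dplyr::bind_cols(tibble::tibble(group = sprintf("g%d", seq_len(n))), out)
}

rand_events <- function(n = 20, groups = c("A", "B"), seed = 1, censor = 50) {
  set.seed(seed)
  tibble::tibble(
    subject = sprintf("s%d", seq_len(n)),
    group = sample(groups, n, replace = TRUE),
    time = round(pmin(rexp(n, 0.05), censor), 3),
    status = as.integer(runif(n) < 0.7))
}

## direct-formula Pearson oracle: covariance over sd product, t transform
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tt), n - 2))
}

## explicit mid-rank construction (no rank()): average position among sorted
oracle_midrank <- function(x) {
  sapply(x, function(v) mean(which(sort(x) == v)))
}

## brute-force best non-increasing least-squares fit by enumerating the
## 2^(k-1) contiguous block partitions of a short sequence
oracle_pava_nonincreasing <- function(y) {
  k <- length(y)
  best <- NULL; best_sse <- Inf
  for (mask in 0:(2^(k - 1) - 1)) {
    cuts <- which(bitwAnd(mask, 2^(0:(k - 2))) > 0)
    bounds <- c(0, cuts, k)
    fit <- numeric(k)
    for (b in seq_len(length(bounds) - 1)) {
      idx <- (bounds[b] + 1):bounds[b + 1]
      fit[idx] <- mean(y[idx])
    }
    if (all(diff(fit) <= 1e-12)) {
      sse <- sum((y - fit)^2)
      if (sse < best_sse - 1e-15) { best_sse <- sse; best <- fit }
    }
  }
  best
}

## no-censoring product-limit oracle: fraction alive just after t
oracle_km_counting <- function(times, t) mean(times > t)
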