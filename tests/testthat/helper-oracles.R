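# independent per-epoch loop oracle for the weighted-window operator
naive_window_score <- function(x, offsets, weights, scale) {
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (k in seq_along(offsets)) {
      j <- i + offsets[k]
      if (j >= 1 && j <= n) s <- s + weights[k] * x[j]
    }
    out[i] <- scale * s
  }
  out
}

# independent loop oracle for the Sadeh discriminant
naive_sadeh <- function(x) {
  x <- pmin(x, 300)
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    win <- sapply(-5:5, function(k) {
      j <- i + k
      if (j >= 1 && j <= n) x[j] else 0
    })
    avg <- mean(win)
    nats <- sum(win >= 50 & win < 100)
    sd6 <- stats::sd(win[1:6])
    lg <- log(x[i] + 1)
    out[i] <- 7.601 - 0.065 * avg - 1.08 * nats - 0.056 * sd6 - 0.703 * lg
  }
  out
}

random_counts_series <- function(n, max_count = 500) {
  epoch_series(sample(0:max_count, n, replace = TRUE), "activity_counts")
}

# random binary series with runs, to exercise rescoring rules
random_binary_runs <- function(n_runs, max_run = 25) {
  v <- unlist(lapply(seq_len(n_runs), function(i)
    rep(i %% 2, sample.int(max_run, 1))))
  if (sample(c(TRUE, FALSE), 1)) v <- 1 - v
  v
}

expect_rel_equal <- function(actual, expected, tol = 1e-12) {
  denom <- pmax(abs(expected), 1)
  expect_true(all(abs(actual - expected) / denom <= tol))
}
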