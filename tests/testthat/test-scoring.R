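test_that("Cole-Kripke worked examples match hand computation", {
  spec <- algorithm_spec("cole_kripke")
  zero <- epoch_series(rep(0, 12), "activity_counts")
  expect_equal(weighted_window_score(zero, spec)$values, rep(0, 12))
  expect_equal(classify(weighted_window_score(zero, spec), spec)$values,
               rep(1, 12))  # D = 0 < 1 everywhere: sleep

  # single count of 100 at the scored epoch: D = 0.0001 * 121 * 100 = 1.21
  cnt <- epoch_series(c(0, 0, 0, 0, 100, 0, 0), "activity_counts")
  s <- weighted_window_score(cnt, spec)
  expect_rel_equal(s$values[5], 1.21)
  expect_equal(classify(s, spec)$values[5], 0)  # D >= 1: wake
  # neighbours pick up the off-center weights: 0.0001 * 28 * 100 at +1
  expect_rel_equal(s$values[6], 0.28)
})

test_that("UCSD worked examples match hand computation", {
  spec <- algorithm_spec("ucsd")
  # center weight: D = 0.05 * 0.085 * 100 = 0.425 -> sleep
  cnt <- epoch_series(c(0, 0, 0, 0, 100, 0, 0), "activity_counts")
  s <- weighted_window_score(cnt, spec)
  expect_rel_equal(s$values[5], 0.425)
  expect_equal(classify(s, spec)$values[5], 1)
  # uniform counts of 200: D = 0.05 * 0.194 * 200 = 1.94 -> wake (interior)
  u <- epoch_series(rep(200, 20), "activity_counts")
  su <- weighted_window_score(u, spec)
  expect_rel_equal(su$values[10], 0.05 * 0.194 * 200)
  expect_equal(classify(su, spec)$values[10], 0)
  expect_equal(weighted_window_score(
    epoch_series(rep(0, 5), "activity_counts"), spec)$values, rep(0, 5))
})

test_that("Kripke 2010 worked examples match hand computation", {
  spec <- algorithm_spec("kripke2010")
  # count 50 one epoch before the scored epoch: 0.30 * 0.0664 * 50 = 0.996
  cnt <- epoch_series(c(0, 50, 0), "activity_counts")
  s <- weighted_window_score(cnt, spec)
  expect_rel_equal(s$values[3], 0.996)
  expect_equal(classify(s, spec)$values[3], 1)  # < 1: sleep
  # scored epoch itself: 0.30 * 0.0300 * 50 = 0.45
  expect_rel_equal(s$values[2], 0.45)
  expect_equal(weighted_window_score(
    epoch_series(rep(0, 15), "activity_counts"), spec)$values, rep(0, 15))
})

test_that("Philips worked examples and threshold variants", {
  spec <- algorithm_spec("philips")
  # single count 30 at the scored epoch: A = 2 * 30 = 60
  cnt <- epoch_series(c(rep(0, 5), 30, rep(0, 5)), "activity_counts")
  s <- weighted_window_score(cnt, spec)
  expect_rel_equal(s$values[6], 60)
  expect_equal(classify(s, spec, threshold = 40)$values[6], 0)  # A > 40: wake
  expect_equal(classify(s, spec, threshold = 80)$values[6], 1)  # A <= 80
  # neighbour at -2 carries weight 0.2: A = 0.2 * 30 = 6 <= 20: sleep
  expect_rel_equal(s$values[8], 6)
  expect_equal(classify(s, spec, threshold = 20)$values[8], 1)
  expect_equal(weighted_window_score(
    epoch_series(rep(0, 9), "activity_counts"), spec)$values, rep(0, 9))
})

test_that("Sadeh worked examples match hand computation", {
  # all-zero series: AVG = NATS = SD = LG = 0, PS = 7.601 -> sleep
  zero <- epoch_series(rep(0, 8), "activity_counts")
  s0 <- sadeh_score(zero)
  expect_rel_equal(s0$values, rep(7.601, 8))
  expect_equal(classify(s0, algorithm_spec("sadeh"))$values, rep(1, 8))

  # NATS counts window epochs with activity >= 50 and < 100
  cnt <- c(50, 99, 100, 49, rep(0, 7))
  ps <- sadeh_score(epoch_series(cnt, "activity_counts"))$values[6]
  avg <- sum(cnt[1:4]) / 11
  sd6 <- stats::sd(c(50, 99, 100, 49, 0, 0))
  expected <- 7.601 - 0.065 * avg - 1.08 * 2 - 0.056 * sd6 - 0.703 * log(1)
  expect_rel_equal(ps, expected)

  # counts above 300 are clipped to 300 before every feature
  big <- epoch_series(c(400), "activity_counts")
  ps_big <- sadeh_score(big)$values
  expected_big <- 7.601 - 0.065 * (300 / 11) - 1.08 * 0 -
    0.056 * stats::sd(c(0, 0, 0, 0, 0, 300)) - 0.703 * log(301)
  expect_rel_equal(ps_big, expected_big)
  expect_identical(sadeh_score(epoch_series(300, "activity_counts"))$values,
                   ps_big)
})

test_that("weighted scoring is linear and monotone in the counts", {
  set.seed(101)
  for (alg in c("cole_kripke", "ucsd", "kripke2010", "philips")) {
    spec <- algorithm_spec(alg)
    x <- random_counts_series(50)
    s1 <- weighted_window_score(x, spec)$values
    x3 <- x; x3$values <- 3 * x$values
    expect_rel_equal(weighted_window_score(x3, spec)$values, 3 * s1)
    # raising one count never lowers any score (all weights nonnegative)
    xb <- x; xb$values[25] <- xb$values[25] + 100
    expect_true(all(weighted_window_score(xb, spec)$values >= s1 - 1e-12))
  }
})

test_that("classification direction matches each decision rule", {
  s <- epoch_series(c(0.5, 1, 1.5), "raw_score")
  expect_equal(classify(s, algorithm_spec("cole_kripke"))$values, c(1, 0, 0))
  ps <- epoch_series(c(-0.1, 0, 4), "raw_score")
  expect_equal(classify(ps, algorithm_spec("sadeh"))$values, c(0, 1, 1))
  bad <- algorithm_spec("cole_kripke"); bad$decision <- NULL
  expect_error(classify(s, bad), "configuration error")
})

test_that("scoring agrees with the naive loop oracle on random series", {
  set.seed(202)
  reg <- algorithm_registry()
  for (rep in 1:25) {
    x <- random_counts_series(sample(15:60, 1))
    for (alg in c("cole_kripke", "ucsd", "kripke2010", "philips")) {
      spec <- reg[[alg]]
      expect_rel_equal(
        weighted_window_score(x, spec)$values,
        naive_window_score(x$values, unlist(spec$window_offsets),
                           unlist(spec$weights), spec$scale))
    }
    expect_rel_equal(sadeh_score(x)$values, naive_sadeh(x$values))
  }
})

test_that("registry spec invariants hold and overrides load", {
  reg <- algorithm_registry()
  expect_setequal(names(reg), c("cole_kripke", "ucsd", "kripke2010",
                                "philips", "sadeh"))
  for (alg in c("cole_kripke", "ucsd", "kripke2010", "philips")) {
    expect_equal(length(reg[[alg]]$weights),
                 length(reg[[alg]]$window_offsets))
    expect_gt(reg[[alg]]$scale, 0)
  }
  expect_equal(sort(reg$philips$thresholds), c(20, 40, 80))
  expect_error(algorithm_spec("nonexistent"), "unknown algorithm")

  # a custom registry file stands in for the shipped one
  f <- withr::local_tempfile(fileext = ".json")
  writeLines('{"algorithms": {"cole_kripke": {"window_offsets": [0],
    "weights": [1], "scale": 2, "threshold": 1,
    "decision": "sleep_if_score_lt_threshold"}}}', f)
  custom <- algorithm_spec("cole_kripke", registry_path = f)
  expect_equal(custom$scale, 2)
})
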