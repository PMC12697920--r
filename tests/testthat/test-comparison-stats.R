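test_that("two-condition RM-ANOVA collapses to the squared paired t test", {
  set.seed(701)
  for (rep in 1:10) {
    Y <- matrix(stats::rnorm(2 * 15, mean = c(0, 0.4)), 15, 2, byrow = TRUE)
    a <- rm_anova(Y)
    tt <- stats::t.test(Y[, 1], Y[, 2], paired = TRUE)
    expect_equal(a$F, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(a$p_uncorrected, tt$p.value, tolerance = 1e-10)
    expect_equal(a$epsilon_gg, 1)  # epsilon bound for k = 2
  }
})

test_that("RM-ANOVA matches the multivariate-model route", {
  set.seed(702)
  n <- 20; k <- 5
  Y <- matrix(stats::rnorm(n * k), n, k)
  Y <- Y + stats::rnorm(n)            # subject effect
  Y[, 2] <- Y[, 2] + 0.5              # condition effect
  a <- rm_anova(Y)

  fit <- stats::lm(Y ~ 1)
  idata <- data.frame(cond = factor(seq_len(k)))
  av <- stats::anova(fit, M = ~cond, X = ~1, idata = idata,
                     test = "Spherical")
  expect_equal(a$F, av[["F"]][1], tolerance = 1e-10)
  expect_equal(a$p_uncorrected, av[["Pr(>F)"]][1], tolerance = 1e-10)
  expect_equal(a$p_adjusted, av[["G-G Pr"]][1], tolerance = 1e-10)
  # the printed GG epsilon of the multivariate route, via its SSD matrix
  eps_ref <- actisleep:::gg_epsilon(stats::SSD(fit)$SSD / (n - 1))
  expect_equal(a$epsilon_gg, eps_ref, tolerance = 1e-10)

  mt <- stats::mauchly.test(fit, M = ~cond, X = ~1, idata = idata)
  expect_equal(a$mauchly_w, unname(mt$statistic), tolerance = 1e-10)
  expect_equal(a$mauchly_p, mt$p.value, tolerance = 1e-10)
})

test_that("epsilon is 1 for constructed compound-symmetric covariance", {
  set.seed(703)
  n <- 2000; k <- 4
  b <- stats::rnorm(n, sd = 2)
  Y <- matrix(stats::rnorm(n * k), n, k) + b
  a <- rm_anova(Y)
  expect_gt(a$epsilon_gg, 0.99)  # estimate converges to 1 under sphericity

  # identical condition columns give F = 0; constant data error out
  Yid <- matrix(rep(stats::rnorm(10), 3), 10, 3)
  expect_equal(rm_anova(Yid)$F, 0)
  expect_error(rm_anova(matrix(1, 5, 3)), "degenerate-variance")
})

test_that("post hoc pairs apply Bonferroni and Hedges g conventions", {
  set.seed(704)
  Y <- matrix(stats::rnorm(40), 20, 2)
  Y <- cbind(Y, Y[, 1])
  colnames(Y) <- c("a", "b", "c")
  ph <- posthoc_pairs(Y)
  expect_equal(nrow(ph), 3)
  # identical pair: g = 0, p = 1
  ac <- ph[ph$a == "a" & ph$b == "c", ]
  expect_equal(ac$hedges_g, 0)
  expect_equal(ac$p_bonferroni, 1)
  # Bonferroni is min(1, p * m)
  ph21 <- posthoc_pairs(Y, m = 21)
  expect_equal(ph21$p_bonferroni, pmin(1, ph21$p_raw * 21))
  expect_equal(actisleep:::effect_size_label(c(0.1, 0.3, 0.6, 1.2)),
               c("very small", "small", "medium", "large"))
  # raw p matches the paired t test it wraps
  tt <- stats::t.test(Y[, "a"], Y[, "b"], paired = TRUE)
  ab <- ph[ph$a == "a" & ph$b == "b", ]
  expect_equal(ab$p_raw, tt$p.value, tolerance = 1e-12)
})

test_that("Hedges g uses the averaged-SD standardizer with correction", {
  x <- c(1, 2, 3, 4, 5); y <- c(2, 3, 4, 5, 6)
  s_av <- sqrt((var(x) + var(y)) / 2)
  J <- 1 - 3 / (4 * 4 - 1)
  expect_equal(hedges_g(y, x), J * 1 / s_av, tolerance = 1e-12)
  expect_equal(hedges_g(x, x), 0)
})

test_that("Bland-Altman limits and proportional bias match hand values", {
  ba0 <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ba0$mean_difference, 0)
  expect_equal(c(ba0$loa_low, ba0$loa_high), c(0, 0))

  # differences {-5, 0, 5}: MD 0, SD 5, LoA +/- 9.8
  ba <- bland_altman(c(95, 100, 105), c(100, 100, 100))
  expect_equal(ba$mean_difference, 0)
  expect_equal(ba$sd_difference, 5)
  expect_equal(c(ba$loa_low, ba$loa_high), c(-9.8, 9.8))

  # planted proportional bias: slope recovered
  set.seed(705)
  m <- stats::runif(200, 50, 150)
  d <- 0.5 * m + stats::rnorm(200, sd = 1)
  a <- m + d / 2; b <- m - d / 2
  bap <- bland_altman(a, b)
  expect_equal(bap$prop_bias_slope, 0.5, tolerance = 0.02)
  expect_lt(bap$prop_bias_p, 1e-6)
  expect_gt(bap$prop_bias_r2, 0.9)

  # constant pair means: slope undefined and flagged
  bac <- bland_altman(c(1, 2, 3), c(3, 2, 1))
  expect_true(is.na(bac$prop_bias_slope))
  expect_error(bland_altman(1:2, 1:2), "length >= 3")
})

test_that("two-tier outlier rule flags shifted participants only", {
  set.seed(706)
  counts <- lapply(1:20, function(i) stats::rgamma(500, 1, scale = 100))
  names(counts) <- paste0("p", 1:20)
  metrics_fn <- function(ids) c(metric = mean(unlist(counts[ids])) / 100)

  rep0 <- outlier_sensitivity(counts, metrics_fn)
  expect_equal(rep0$n_flagged, 0)
  expect_true(all(rep0$metrics$within_criterion))

  # one participant with mean shifted far above the sample: z-rule flags it
  sds <- stats::sd(vapply(counts, mean, numeric(1)))
  counts$p20 <- counts$p20 + 8 * sds
  rep1 <- outlier_sensitivity(counts, metrics_fn)
  expect_true("p20" %in% rep1$flagged$participant_id)
  expect_match(rep1$flagged$rule[rep1$flagged$participant_id == "p20"], "z")

  expect_error(outlier_sensitivity(counts[1:5], metrics_fn), "at least 10")
})

test_that("relative change arithmetic matches the 5% criterion", {
  counts <- lapply(1:12, function(i) rep(c(0, 100), 50))
  names(counts) <- paste0("q", 1:12)
  vals <- c(0.80, 0.78)
  metrics_fn <- local({
    call_n <- 0
    function(ids) {
      call_n <<- call_n + 1
      c(acc = vals[min(call_n, 2)])
    }
  })
  rep <- outlier_sensitivity(counts, metrics_fn)
  expect_equal(rep$metrics$relative_change, abs(0.80 - 0.78) / 0.80)
  expect_true(rep$metrics$within_criterion)
})
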