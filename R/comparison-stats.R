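orthonormal_contrasts <- function(k) {
  # columns of Helmert contrasts, orthonormalized; rows index conditions
  C <- stats::contr.helmert(k)
  qr.Q(qr(C))
}

# Greenhouse-Geisser epsilon from a k x k condition covariance matrix:
# eps = tr(E)^2 / ((k-1) * tr(E^2)) with E the orthonormally contrasted
# covariance; equals 1 iff the contrasted covariance is spherical (e.g. for
# any compound-symmetric S), and is bounded below by 1/(k-1).
gg_epsilon <- function(S) {
  k <- ncol(S)
  C <- orthonormal_contrasts(k)
  E <- t(C) %*% S %*% C
  trE <- sum(diag(E))
  if (trE <= .Machine$double.eps * k) return(1)
  min(1, max(trE^2 / ((k - 1) * sum(E^2)), 1 / (k - 1)))
}

#' One-way repeated-measures ANOVA with sphericity handling
#'
#' Classical within-subject decomposition for a participants-by-conditions
#' matrix: `SS_total = SS_subject + SS_condition + SS_error`, with
#' `F = MS_condition / MS_error` on `(k-1, (k-1)(n-1))` degrees of freedom.
#' Mauchly's sphericity test and the Greenhouse-Geisser epsilon are computed
#' from the covariance of the orthonormally contrasted conditions; the
#' adjusted degrees of freedom (`epsilon * df`) and adjusted p value are
#' reported alongside the uncorrected ones, together with generalized eta
#' squared `SS_condition / (SS_condition + SS_subject + SS_error)`.
#'
#' @param values numeric matrix, participants in rows, conditions in
#'   columns (complete cases; at least 3 participants and 2 conditions).
#' @param metric optional label carried into the result.
#' @return object of class `rm_anova`: list with `ss_condition`,
#'   `ss_subject`, `ss_error`, `ms_condition`, `ms_error`, `F`, `df`,
#'   `eta2g`, `epsilon_gg`, `mauchly_w`, `mauchly_p`, `p_uncorrected`,
#'   `df_adjusted`, `p_adjusted`, `n`, `k`.
#' @examples
#' set.seed(1)
#' y <- matrix(rnorm(60), 15, 4) + rnorm(15)  # subject effect, no condition
#' rm_anova(y)$p_adjusted
#' @export
rm_anova <- function(values, metric = "metric") {
  Y <- as.matrix(values)
  if (anyNA(Y)) stop("complete cases required", call. = FALSE)
  n <- nrow(Y); k <- ncol(Y)
  if (k < 2 || n < 3)
    stop("need at least 2 conditions and 3 participants", call. = FALSE)
  if (stats::var(as.vector(Y)) == 0)
    stop("degenerate-variance error: all values identical", call. = FALSE)

  gm <- mean(Y)
  cond_m <- colMeans(Y)
  subj_m <- rowMeans(Y)
  ss_cond <- n * sum((cond_m - gm)^2)
  ss_subj <- k * sum((subj_m - gm)^2)
  ss_tot <- sum((Y - gm)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1; df2 <- (k - 1) * (n - 1)
  ms_cond <- ss_cond / df1
  ms_err <- ss_err / df2
  F <- if (ms_cond == 0) 0 else ms_cond / ms_err

  # Greenhouse-Geisser epsilon and Mauchly W on contrasted covariance
  S <- stats::cov(Y)
  eps <- gg_epsilon(S)
  C <- orthonormal_contrasts(k)
  E <- t(C) %*% S %*% C
  trE <- sum(diag(E))
  if (trE <= .Machine$double.eps * k) {
    mauchly_w <- NA_real_; mauchly_p <- NA_real_
  } else {
    detE <- det(E)
    mauchly_w <- detE / (trE / df1)^df1
    if (mauchly_w <= 0 || df1 < 2) {
      mauchly_p <- NA_real_
      if (df1 < 2) { mauchly_w <- NA_real_ }
    } else {
      # chi-square approximation with the second-order term, using the same
      # coefficient convention as stats::mauchly.test (its 3p + 2 term takes
      # p as the untransformed dimension, i.e. the number of conditions)
      p <- df1; nr <- n - 1
      rho <- 1 - (2 * p^2 + p + 2) / (6 * p * nr)
      w2 <- (p + 2) * (p - 1) * (p - 2) * (2 * p^3 + 6 * p^2 + 3 * k + 2) /
        (288 * p^2 * nr^2 * rho^2)
      z <- -nr * rho * log(mauchly_w)
      f <- p * (p + 1) / 2 - 1
      mauchly_p <- stats::pchisq(z, f, lower.tail = FALSE) +
        w2 * (stats::pchisq(z, f + 4, lower.tail = FALSE) -
                stats::pchisq(z, f, lower.tail = FALSE))
    }
  }

  p_unc <- if (ms_err > 0) stats::pf(F, df1, df2, lower.tail = FALSE) else
    ifelse(F == 0, 1, 0)
  p_adj <- if (ms_err > 0)
    stats::pf(F, eps * df1, eps * df2, lower.tail = FALSE) else p_unc

  structure(list(
    metric = metric,
    ss_condition = ss_cond, ss_subject = ss_subj, ss_error = ss_err,
    ms_condition = ms_cond, ms_error = ms_err,
    F = F, df = c(df1, df2),
    eta2g = ss_cond / (ss_cond + ss_subj + ss_err),
    epsilon_gg = eps, mauchly_w = mauchly_w, mauchly_p = mauchly_p,
    p_uncorrected = p_unc,
    df_adjusted = eps * c(df1, df2), p_adjusted = p_adj,
    n = n, k = k), class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA (%s): F(%g, %g) = %.3f, p = %.4g\n",
              x$metric, x$df[1], x$df[2], x$F, x$p_uncorrected))
  cat(sprintf("  Greenhouse-Geisser eps = %.3f, adj df (%.2f, %.2f), adj p = %.4g\n",
              x$epsilon_gg, x$df_adjusted[1], x$df_adjusted[2], x$p_adjusted))
  if (!is.na(x$mauchly_w))
    cat(sprintf("  Mauchly W = %.4f, p = %.4g; eta2g = %.4f\n",
                x$mauchly_w, x$mauchly_p, x$eta2g))
  invisible(x)
}

#' Hedges' g standardized mean difference
#'
#' For paired designs the standardizer is the averaged condition standard
#' deviation `sqrt((sd_x^2 + sd_y^2) / 2)` (not the SD of difference
#' scores), multiplied by the small-sample correction
#' `J = 1 - 3 / (4 df - 1)` with `df = n - 1`.
#'
#' @param x,y paired numeric vectors (condition values per participant).
#' @return Hedges' g (y and x entered as `mean(x) - mean(y)`).
#' @export
hedges_g <- function(x, y) {
  n <- length(x)
  if (n != length(y) || n < 2) stop("paired vectors of length >= 2 required",
                                    call. = FALSE)
  s_av <- sqrt((stats::var(x) + stats::var(y)) / 2)
  if (s_av == 0) return(0)
  J <- 1 - 3 / (4 * (n - 1) - 1)
  J * (mean(x) - mean(y)) / s_av
}

effect_size_label <- function(g) {
  ag <- abs(g)
  ifelse(ag < 0.2, "very small",
         ifelse(ag < 0.5, "small", ifelse(ag < 0.8, "medium", "large")))
}

#' Pairwise post hoc comparisons with Bonferroni correction
#'
#' All pairwise paired t tests between conditions, with Bonferroni-adjusted
#' p values (`min(1, p * m)`) and Hedges' g effect sizes labelled by the
#' 0.2 / 0.5 / 0.8 convention (very small / small / medium / large).  All
#' pairs are always computed; gate on the omnibus test yourself if desired.
#'
#' @param values participants-by-conditions numeric matrix with column
#'   names.
#' @param m number of comparisons used for the Bonferroni correction;
#'   defaults to the number of pairs.
#' @return data frame with one row per condition pair: `a`, `b`,
#'   `mean_diff` (a - b), `t`, `p_raw`, `p_bonferroni`, `hedges_g`,
#'   `effect_size`.
#' @export
posthoc_pairs <- function(values, m = NULL) {
  Y <- as.matrix(values)
  n <- nrow(Y); k <- ncol(Y)
  if (n < 2) stop("need at least 2 participants", call. = FALSE)
  if (is.null(colnames(Y))) colnames(Y) <- paste0("cond", seq_len(k))
  pairs <- utils::combn(k, 2)
  if (is.null(m)) m <- ncol(pairs)
  res <- lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    d <- Y[, i1] - Y[, i2]
    if (stats::sd(d) == 0) {
      tt <- list(statistic = c(t = if (mean(d) == 0) 0 else Inf),
                 p.value = if (mean(d) == 0) 1 else 0)
    } else {
      tt <- stats::t.test(Y[, i1], Y[, i2], paired = TRUE)
    }
    g <- hedges_g(Y[, i1], Y[, i2])
    data.frame(a = colnames(Y)[i1], b = colnames(Y)[i2],
               mean_diff = mean(d),
               t = unname(tt$statistic),
               p_raw = tt$p.value,
               p_bonferroni = min(1, tt$p.value * m),
               hedges_g = g,
               effect_size = effect_size_label(g),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Bland-Altman agreement analysis
#'
#' For paired per-participant measurements (actigraphy minus
#' polysomnography by convention), computes the mean difference, the SD of
#' differences, the 95% limits of agreement `MD +/- 1.96 SD`, and the
#' proportional-bias regression of the differences on the pair means
#' (ordinary least squares slope, R-squared and two-sided slope p value).
#'
#' @param a,b paired numeric vectors of equal length >= 3 (`a` is typically
#'   the actigraphy-derived metric, `b` the polysomnography metric).
#' @param metric,method optional labels carried into the result.
#' @return object of class `bland_altman`: list with `mean_difference`,
#'   `sd_difference`, `loa_low`, `loa_high`, `prop_bias_slope`,
#'   `prop_bias_r2`, `prop_bias_p`, `n`, plus the per-pair `means` and
#'   `differences`.  With zero variance in the pair means the slope is `NA`
#'   and flagged via the `undefined` attribute.
#' @examples
#' ba <- bland_altman(c(100, 105, 110), c(105, 105, 105))
#' c(ba$mean_difference, ba$loa_low, ba$loa_high)
#' @export
bland_altman <- function(a, b, metric = "metric", method = "method") {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b) || length(a) < 3)
    stop("paired vectors of equal length >= 3 required", call. = FALSE)
  d <- a - b
  mns <- (a + b) / 2
  md <- mean(d)
  sdd <- stats::sd(d)
  res <- list(metric = metric, method = method, n = length(d),
              mean_difference = md, sd_difference = sdd,
              loa_low = md - 1.96 * sdd, loa_high = md + 1.96 * sdd,
              means = mns, differences = d)
  if (stats::var(mns) == 0) {
    res$prop_bias_slope <- NA_real_
    res$prop_bias_r2 <- NA_real_
    res$prop_bias_p <- NA_real_
    attr(res, "undefined") <- "proportional bias (constant pair means)"
  } else {
    fit <- stats::lm(d ~ mns)
    sm <- summary(fit)
    res$prop_bias_slope <- unname(stats::coef(fit)[2])
    res$prop_bias_r2 <- sm$r.squared
    res$prop_bias_p <- sm$coefficients[2, 4]
  }
  class(res) <- "bland_altman"
  res
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (%s, %s): MD = %.3f, SD = %.3f, LoA [%.3f, %.3f], n = %d\n",
              x$metric, x$method, x$mean_difference, x$sd_difference,
              x$loa_low, x$loa_high, x$n))
  if (!is.na(x$prop_bias_slope))
    cat(sprintf("  proportional bias: slope = %.4f, R2 = %.4f, p = %.4g\n",
                x$prop_bias_slope, x$prop_bias_r2, x$prop_bias_p))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, ...) {
  graphics::plot(x$means, x$differences,
                 xlab = "Mean of methods", ylab = "Difference (a - b)",
                 main = sprintf("%s: %s", x$method, x$metric), ...)
  graphics::abline(h = x$mean_difference, col = "blue")
  graphics::abline(h = c(x$loa_low, x$loa_high), col = "red", lty = 2)
  if (!is.na(x$prop_bias_slope)) {
    graphics::abline(stats::lm(x$differences ~ x$means), col = "darkgreen",
                     lty = 3)
  }
  invisible(x)
}

#' Two-tier outlier sensitivity analysis
#'
#' Identifies outlying participants from their raw 30-second activity
#' counts in two steps: (1) participants whose individual count IQR falls
#' outside the Tukey fences (1.5 IQR below the first / above the third
#' quartile) of the sample's distribution of participant IQRs; (2)
#' participants whose mean count has `|z| >= 2` relative to the sample mean
#' and SD of participant means.  The flag set is the union of the two
#' rules.  The supplied metrics pipeline is then re-run without the flagged
#' participants and the relative change of every metric is tabulated
#' against a 5% criterion.
#'
#' @param counts named list of numeric vectors: raw 30-s activity counts
#'   per participant (at least 10 participants).
#' @param metrics_fn function taking a character vector of participant ids
#'   and returning a named numeric vector of summary metrics.
#' @param z_cut z-score cutoff for rule 2 (default 2).
#' @param criterion relative-change criterion (default 0.05).
#' @return object of class `outlier_report`: list with `flagged` (data
#'   frame id / rule), `metrics` (data frame metric / with_outliers /
#'   without_outliers / relative_change / within_criterion), `n_flagged`,
#'   `criterion`.
#' @export
outlier_sensitivity <- function(counts, metrics_fn, z_cut = 2,
                                criterion = 0.05) {
  if (length(counts) < 10)
    stop("need at least 10 participants", call. = FALSE)
  ids <- names(counts)
  if (is.null(ids)) ids <- as.character(seq_along(counts))
  iqr_i <- vapply(counts, stats::IQR, numeric(1))
  mean_i <- vapply(counts, mean, numeric(1))
  q <- stats::quantile(iqr_i, c(0.25, 0.75))
  fence <- 1.5 * (q[2] - q[1])
  rule1 <- iqr_i < q[1] - fence | iqr_i > q[2] + fence
  sd_means <- stats::sd(mean_i)
  z <- if (sd_means == 0) rep(0, length(mean_i)) else
    (mean_i - mean(mean_i)) / sd_means
  rule2 <- abs(z) >= z_cut
  flagged <- rule1 | rule2
  rules <- ifelse(rule1 & rule2, "iqr_fence+z",
                  ifelse(rule1, "iqr_fence", ifelse(rule2, "z", "")))

  with_m <- metrics_fn(ids)
  keep <- ids[!flagged]
  without_m <- if (length(keep)) metrics_fn(keep) else with_m * NA_real_
  rel <- ifelse(with_m == 0, ifelse(without_m == 0, 0, NA_real_),
                abs(with_m - without_m) / abs(with_m))
  structure(list(
    flagged = data.frame(participant_id = ids[flagged],
                         rule = rules[flagged], z = z[flagged],
                         iqr = iqr_i[flagged], row.names = NULL,
                         stringsAsFactors = FALSE),
    metrics = data.frame(metric = names(with_m),
                         with_outliers = unname(with_m),
                         without_outliers = unname(without_m),
                         relative_change = unname(rel),
                         within_criterion = unname(rel) < criterion,
                         stringsAsFactors = FALSE),
    n_flagged = sum(flagged), criterion = criterion),
    class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf("Outlier sensitivity: %d participant(s) flagged\n", x$n_flagged))
  if (nrow(x$flagged)) print(x$flagged)
  ok <- all(x$metrics$within_criterion, na.rm = TRUE)
  cat(sprintf("All metric relative changes < %.0f%%: %s\n",
              100 * x$criterion, ifelse(ok, "yes", "NO")))
  invisible(x)
}
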