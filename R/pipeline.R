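#' Run the full actigraphy-vs-polysomnography validation study
#'
#' Orchestrates the end-to-end analysis on a cohort of paired nights:
#' synchronizes each pair, scores the 30-second activity counts with every
#' requested algorithm variant, collapses raw scores and polysomnography
#' labels to 1-minute epochs (summed raw scores with the original
#' threshold; wake-wins for labels), optionally applies Webster's rescoring
#' rules, and computes the complete comparison suite: per-participant and
#' epoch-weighted pooled confusion/kappa/MCC metrics, pooled ROC/AUC per
#' variant, night-level sleep metrics (TST, SE, WASO) with Bland-Altman
#' agreement against polysomnography, repeated-measures ANOVA with
#' Greenhouse-Geisser correction and Bonferroni post hocs across variants,
#' the polysomnography pair-distribution audit, the two-tier outlier
#' sensitivity analysis, and per-subgroup pooled summaries when subgroup
#' labels are present.
#'
#' The pipeline itself draws no random numbers: a cohort (config + seed)
#' fully determines every output table.
#'
#' @param cohort a [simulate_cohort()] result, a [read_cohort()] result, or
#'   a directory path holding a cohort bundle.
#' @param variants data frame as returned by [algorithm_variants()]
#'   (subsettable to fewer variants).
#' @param rescore if `TRUE` (default) both nonrescored (NRS) and rescored
#'   (RS) result sets are produced; if `FALSE`, NRS only.
#' @param collapse_mode `"sum_raw"` (default: sum 30-s raw scores, apply
#'   the original threshold to the minute sum) or `"classify_then_pair"`
#'   (threshold at 30 s, wake-wins collapse of the binary labels), the
#'   latter for sensitivity analyses.
#' @param anova_metrics per-participant metrics fed to the RM-ANOVA /
#'   post hoc stage.
#' @return object of class `sleep_validation`; see Details.
#' @details The returned object contains `epoch_results` (one row per
#'   participant x variant x rescoring flag), `pooled` (epoch-weighted mean
#'   and SD per metric), `roc` (named list of [roc_auc()] results, NRS raw
#'   scores), `auc` (data frame), `night_metrics`, `bland_altman` (named
#'   list of [bland_altman()] objects, names `metric.variant.flag`),
#'   `anova` and `posthoc` (named lists by flag then metric),
#'   `pair_distribution`, `outliers` (an [outlier_sensitivity()] report),
#'   `subgroups`, and `config`.
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(night_config(n_participants = 8, seed = 42))
#' fit <- run_validation(cohort)
#' print(fit)
#' }
#' @export
run_validation <- function(cohort,
                           variants = algorithm_variants(),
                           rescore = TRUE,
                           collapse_mode = c("sum_raw", "classify_then_pair"),
                           anova_metrics = c("accuracy", "kappa", "mcc")) {
  collapse_mode <- match.arg(collapse_mode)
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  nights <- cohort$nights
  if (is.null(nights) || !length(nights))
    stop("cohort has no nights", call. = FALSE)
  bad <- setdiff(variants$algorithm, names(algorithm_registry()))
  if (length(bad))
    stop("unknown algorithm name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  flags <- if (isTRUE(rescore)) c("NRS", "RS") else "NRS"

  metric_names <- c("accuracy", "sensitivity", "specificity", "precision",
                    "f1", "kappa", "mcc")
  epoch_rows <- list()
  night_rows <- list()
  roc_scores <- stats::setNames(vector("list", nrow(variants)),
                                variants$variant)
  roc_labels <- stats::setNames(vector("list", nrow(variants)),
                                variants$variant)
  pair_counts <- c(both_sleep = 0, both_wake = 0, mixed = 0)
  counts_by_id <- list()

  for (night in nights) {
    aligned <- synchronize(night$act, night$psg, night$sync,
                           crop_to_in_bed = TRUE)
    act <- aligned$act; psg <- aligned$psg
    pid <- act$participant_id
    counts_by_id[[pid]] <- act$values
    psg60 <- collapse_psg_to_minutes(psg)
    n_pairs <- length(psg$values) %/% 2L
    pair_counts <- pair_counts + pair_distribution(psg) * n_pairs

    night_rows[[paste0(pid, ".PSG")]] <-
      compute_night_metrics(psg60, method = "PSG")

    for (j in seq_len(nrow(variants))) {
      vn <- variants$variant[j]
      spec <- algorithm_spec(variants$algorithm[j],
                             threshold = variants$threshold[j])
      raw30 <- score_epochs(act, variants$algorithm[j])
      raw60 <- collapse_scores_to_minutes(raw30)
      nrs <- if (collapse_mode == "sum_raw") {
        classify(raw60, spec)
      } else {
        bin30 <- classify(raw30, spec)
        collapse_psg_to_minutes(bin30)
      }
      roc_scores[[vn]] <- c(roc_scores[[vn]], raw60$values)
      roc_labels[[vn]] <- c(roc_labels[[vn]], psg60$values)

      series <- list(NRS = nrs)
      if ("RS" %in% flags) series$RS <- webster_rescore(nrs)
      for (fl in flags) {
        m <- agreement_metrics(confusion(series[[fl]], psg60))
        cc <- confusion(series[[fl]], psg60)
        epoch_rows[[paste(pid, vn, fl, sep = ".")]] <- data.frame(
          participant_id = pid, variant = vn, flag = fl,
          n = unname(m[["n"]]),
          tp = cc[["tp"]], fp = cc[["fp"]], tn = cc[["tn"]], fn = cc[["fn"]],
          t(m[metric_names]), stringsAsFactors = FALSE)
        nm <- compute_night_metrics(series[[fl]],
                                    method = paste(vn, fl, sep = "_"))
        night_rows[[paste(pid, vn, fl, sep = ".")]] <- nm
      }
    }
  }

  epoch_results <- do.call(rbind, c(epoch_rows, make.row.names = FALSE))
  night_metrics <- do.call(rbind, c(night_rows, make.row.names = FALSE))

  # epoch-weighted pooled summaries
  pooled <- list()
  for (vn in variants$variant) for (fl in flags) {
    sub <- epoch_results[epoch_results$variant == vn &
                           epoch_results$flag == fl, ]
    for (mn in metric_names) {
      ws <- weighted_summary(sub[[mn]], sub$n)
      pooled[[paste(vn, fl, mn, sep = ".")]] <- data.frame(
        variant = vn, flag = fl, metric = mn,
        mean = ws[["mean"]], sd = ws[["sd"]],
        n_participants = ws[["n_used"]], stringsAsFactors = FALSE)
    }
  }
  pooled <- do.call(rbind, c(pooled, make.row.names = FALSE))

  # pooled ROC per variant on NRS minute raw scores
  roc <- lapply(variants$variant, function(vn) {
    orient <- score_orientation(
      variants$algorithm[variants$variant == vn][1])
    roc_auc(roc_scores[[vn]], roc_labels[[vn]], orientation = orient)
  })
  names(roc) <- variants$variant
  auc <- data.frame(variant = variants$variant,
                    auc = vapply(roc, `[[`, numeric(1), "auc"),
                    stringsAsFactors = FALSE)

  # Bland-Altman per sleep metric x variant x flag (vs PSG)
  psg_nm <- night_metrics[night_metrics$method == "PSG", ]
  psg_nm <- psg_nm[order(psg_nm$participant_id), ]
  ba <- list()
  if (nrow(psg_nm) >= 3) {
    for (vn in variants$variant) for (fl in flags) {
      meth <- paste(vn, fl, sep = "_")
      sub <- night_metrics[night_metrics$method == meth, ]
      sub <- sub[order(sub$participant_id), ]
      for (mn in c("tst", "se", "waso")) {
        ba[[paste(mn, vn, fl, sep = ".")]] <-
          bland_altman(sub[[mn]], psg_nm[[mn]], metric = mn, method = meth)
      }
    }
  }
  ba_summary <- do.call(rbind, c(lapply(names(ba), function(k) {
    x <- ba[[k]]
    data.frame(metric = x$metric, method = x$method,
               mean_difference = x$mean_difference,
               sd_difference = x$sd_difference,
               loa_low = x$loa_low, loa_high = x$loa_high,
               prop_bias_slope = x$prop_bias_slope,
               prop_bias_p = x$prop_bias_p, stringsAsFactors = FALSE)
  }), make.row.names = FALSE))

  # RM-ANOVA + Bonferroni post hocs across variants, per metric and flag
  anova_res <- list(); posthoc_res <- list()
  ids <- sort(unique(epoch_results$participant_id))
  if (length(ids) >= 3 && nrow(variants) >= 2) {
    for (fl in flags) {
      for (mn in anova_metrics) {
        Y <- sapply(variants$variant, function(vn) {
          sub <- epoch_results[epoch_results$variant == vn &
                                 epoch_results$flag == fl, ]
          sub[[mn]][match(ids, sub$participant_id)]
        })
        if (anyNA(Y)) next  # incomplete cases (degenerate metric) skipped
        key <- paste(fl, mn, sep = ".")
        anova_res[[key]] <- tryCatch(rm_anova(Y, metric = key),
                                     error = function(e) NULL)
        posthoc_res[[key]] <- posthoc_pairs(Y)
      }
    }
  }

  # outlier sensitivity on pooled NRS accuracy/kappa/mcc per variant
  outliers <- NULL
  if (length(counts_by_id) >= 10) {
    er <- epoch_results
    metrics_fn <- function(keep_ids) {
      sub <- er[er$participant_id %in% keep_ids & er$flag == "NRS", ]
      out <- c()
      for (vn in unique(sub$variant)) for (mn in c("accuracy", "kappa",
                                                   "mcc")) {
        s2 <- sub[sub$variant == vn, ]
        out[paste(vn, mn, sep = ".")] <-
          weighted_summary(s2[[mn]], s2$n)[["mean"]]
      }
      out
    }
    outliers <- outlier_sensitivity(counts_by_id, metrics_fn)
  }

  # subgroup pooled summaries
  subgroups <- NULL
  labels <- cohort$labels
  if (!is.null(labels) && any(labels$subgroup != "none")) {
    rows <- list()
    for (sg in setdiff(unique(labels$subgroup), "none")) {
      sg_ids <- labels$participant_id[labels$subgroup == sg]
      sub <- epoch_results[epoch_results$participant_id %in% sg_ids, ]
      if (!nrow(sub)) next
      for (vn in unique(sub$variant)) for (fl in unique(sub$flag)) {
        s2 <- sub[sub$variant == vn & sub$flag == fl, ]
        for (mn in c("accuracy", "kappa", "mcc")) {
          ws <- weighted_summary(s2[[mn]], s2$n)
          rows[[paste(sg, vn, fl, mn, sep = ".")]] <- data.frame(
            subgroup = sg, variant = vn, flag = fl, metric = mn,
            mean = ws[["mean"]], sd = ws[["sd"]],
            n_participants = ws[["n_used"]], stringsAsFactors = FALSE)
        }
      }
    }
    if (length(rows))
      subgroups <- do.call(rbind, c(rows, make.row.names = FALSE))
  }

  structure(list(
    epoch_results = epoch_results,
    pooled = pooled,
    roc = roc, auc = auc,
    night_metrics = night_metrics,
    bland_altman = ba, bland_altman_summary = ba_summary,
    anova = anova_res, posthoc = posthoc_res,
    pair_distribution = pair_counts / sum(pair_counts),
    outliers = outliers,
    subgroups = subgroups,
    variants = variants, flags = flags,
    collapse_mode = collapse_mode,
    config = cohort$config), class = "sleep_validation")
}

#' @export
print.sleep_validation <- function(x, ...) {
  cat(sprintf("Actigraphy validation: %d participants, %d variant(s), %s\n",
              length(unique(x$epoch_results$participant_id)),
              nrow(x$variants), paste(x$flags, collapse = "+")))
  acc <- x$pooled[x$pooled$metric %in% c("accuracy", "kappa"), ]
  wide <- stats::reshape(acc[, c("variant", "flag", "metric", "mean")],
                         direction = "wide",
                         idvar = c("variant", "flag"), timevar = "metric")
  names(wide) <- sub("mean\\.", "", names(wide))
  wide <- merge(wide, x$auc, by = "variant", all.x = TRUE)
  print(wide[order(wide$variant, wide$flag), ], row.names = FALSE,
        digits = 3)
  cat(sprintf("PSG pair distribution: %.1f%% both sleep, %.1f%% both wake, %.1f%% mixed\n",
              100 * x$pair_distribution[["both_sleep"]],
              100 * x$pair_distribution[["both_wake"]],
              100 * x$pair_distribution[["mixed"]]))
  invisible(x)
}

#' @export
summary.sleep_validation <- function(object, ...) {
  print(object)
  cat("\nBland-Altman (TST, NRS):\n")
  bs <- object$bland_altman_summary
  if (!is.null(bs))
    print(bs[bs$metric == "tst" & grepl("_NRS$", bs$method), ],
          row.names = FALSE, digits = 3)
  if (length(object$anova)) {
    cat("\nRepeated-measures ANOVA across variants:\n")
    for (k in names(object$anova)) print(object$anova[[k]])
  }
  if (!is.null(object$outliers)) print(object$outliers)
  invisible(object)
}

#' @param type `"roc"` or `"bland_altman"`.
#' @param variant algorithm variant to plot.
#' @param metric sleep metric for Bland-Altman plots.
#' @param flag `"NRS"` or `"RS"`.
#' @rdname run_validation
#' @export
plot.sleep_validation <- function(x, type = c("roc", "bland_altman"),
                                  variant = x$variants$variant[1],
                                  metric = "tst", flag = "NRS", ...) {
  type <- match.arg(type)
  if (type == "roc") {
    plot(x$roc[[variant]], main = paste("ROC:", variant), ...)
  } else {
    key <- paste(metric, variant, flag, sep = ".")
    if (is.null(x$bland_altman[[key]]))
      stop("no Bland-Altman result for ", key, call. = FALSE)
    plot(x$bland_altman[[key]], ...)
  }
  invisible(x)
}
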