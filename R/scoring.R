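.registry_env <- new.env(parent = emptyenv())

#' Sleep-wake scoring algorithm registry
#'
#' The five classical actigraphy scoring algorithms are weighted-window
#' operators on 30-second activity counts: Cole-Kripke, UCSD and Kripke 2010
#' compute a scaled weighted sum `D` and score sleep when `D < 1`;
#' Philips-Respironics computes a total activity value `A` and scores wake
#' when `A > T` for a wake threshold `T` in \{20, 40, 80\}; Sadeh computes a
#' probability-of-sleep discriminant `PS` over an 11-epoch window and scores
#' sleep when `PS >= 0`.  All weights, scales, thresholds and decision rules
#' live in a versioned JSON registry (data, not code) so corrected values can
#' be swapped without code changes; `registry_path` points at an alternative
#' file.
#'
#' Three published weights are typographically ambiguous in the primary
#' sources; the registry ships the readings most consistent with the
#' surrounding terms (Cole-Kripke center weight 121; Kripke 2010 final weight
#' 0.0100; Philips final term at offset +4, completing the symmetric 9-term
#' window).  Being registry entries, they are overridable.
#'
#' @param registry_path optional path to a registry JSON file; defaults to
#'   the registry shipped with the package.
#' @return `algorithm_registry()` returns the full registry as a named list;
#'   `algorithm_spec()` returns one algorithm's spec.
#' @examples
#' names(algorithm_registry())
#' algorithm_spec("cole_kripke")$weights
#' @export
algorithm_registry <- function(registry_path = NULL) {
  if (is.null(registry_path)) {
    if (!is.null(.registry_env$default)) return(.registry_env$default)
    registry_path <- system.file("extdata", "algorithms.json",
                                 package = "actisleep")
  }
  reg <- jsonlite::read_json(registry_path, simplifyVector = TRUE)
  algs <- reg$algorithms
  for (nm in names(algs)) algs[[nm]]$name <- nm
  if (is.null(.registry_env$default) &&
      grepl("algorithms.json", registry_path, fixed = TRUE))
    .registry_env$default <- algs
  algs
}

#' @param name algorithm name: `"cole_kripke"`, `"ucsd"`, `"kripke2010"`,
#'   `"philips"` or `"sadeh"`.
#' @param threshold optional threshold override (used for the Philips wake
#'   threshold variants).
#' @rdname algorithm_registry
#' @export
algorithm_spec <- function(name, threshold = NULL, registry_path = NULL) {
  reg <- algorithm_registry(registry_path)
  if (!name %in% names(reg))
    stop("unknown algorithm: ", name, "; available: ",
         paste(names(reg), collapse = ", "), call. = FALSE)
  spec <- reg[[name]]
  if (!is.null(threshold)) spec$threshold <- threshold
  spec
}

#' The seven algorithm variants of the validation study
#'
#' Five algorithms, with Philips-Respironics evaluated at each of its three
#' wake thresholds, give seven scoring variants.
#'
#' @return data frame with columns `variant`, `algorithm`, `threshold`.
#' @export
algorithm_variants <- function() {
  data.frame(
    variant = c("cole_kripke", "ucsd", "kripke2010",
                "philips_20", "philips_40", "philips_80", "sadeh"),
    algorithm = c("cole_kripke", "ucsd", "kripke2010",
                  "philips", "philips", "philips", "sadeh"),
    threshold = c(1, 1, 1, 20, 40, 80, 0),
    stringsAsFactors = FALSE)
}

# shift x by k epochs (value at position i comes from x[i + k]); zero padding
shift_pad <- function(x, k) {
  n <- length(x)
  out <- numeric(n)
  src <- seq_len(n) + k
  ok <- src >= 1L & src <= n
  out[ok] <- x[src[ok]]
  out
}

#' Weighted-window raw scores
#'
#' Computes `score[i] = scale * sum_k weights[k] * counts[i + offset[k]]` for
#' every epoch, with window positions falling outside the series contributing
#' zero activity.  This is the scoring operator shared by Cole-Kripke, UCSD,
#' Kripke 2010 and Philips-Respironics; Sadeh's nonlinear discriminant is
#' computed by [sadeh_score()].
#'
#' @param counts an [epoch_series()] of kind `activity_counts` (30-s epochs).
#' @param spec an algorithm spec from [algorithm_spec()] carrying
#'   `window_offsets`, `weights` and `scale`.
#' @return an [epoch_series()] of kind `raw_score`, same length as `counts`,
#'   with attribute `algorithm`.
#' @examples
#' cnt <- epoch_series(c(0, 0, 100, 0, 0), "activity_counts")
#' weighted_window_score(cnt, algorithm_spec("cole_kripke"))$values
#' @export
weighted_window_score <- function(counts, spec) {
  stopifnot(inherits(counts, "epoch_series"))
  if (counts$kind != "activity_counts")
    stop("weighted_window_score expects activity counts", call. = FALSE)
  offs <- as.numeric(spec$window_offsets)
  w <- as.numeric(spec$weights)
  if (length(offs) != length(w))
    stop("spec weights and window_offsets differ in length", call. = FALSE)
  x <- counts$values
  s <- numeric(length(x))
  for (k in seq_along(offs)) s <- s + w[k] * shift_pad(x, offs[k])
  s <- spec$scale * s
  out <- epoch_series(s, kind = "raw_score",
                      epoch_length_s = counts$epoch_length_s,
                      start_time = counts$start_time,
                      participant_id = counts$participant_id)
  attr(out, "algorithm") <- spec$name
  out
}

#' Sadeh probability-of-sleep scores
#'
#' Computes the Sadeh discriminant
#' `PS = 7.601 - 0.065 AVG - 1.08 NATS - 0.056 SD - 0.703 LG`
#' per epoch over an 11-epoch window (5 before, the scored epoch, 5 after).
#' Counts above 300 are clipped to 300 before feature extraction.  Window
#' positions outside the series contribute zero activity.  `AVG` is the mean
#' of the window counts, `NATS` the number of window epochs with counts in
#' `[50, 100)`, `SD` the sample standard deviation of the first 6 window
#' epochs (offsets -5 through 0), and `LG` the natural logarithm of the
#' scored epoch's count plus one (the +1 keeps zero-activity epochs finite;
#' configurable through the registry's `log_offset`).
#'
#' @inheritParams weighted_window_score
#' @param spec the Sadeh spec from the registry (defaults to the shipped
#'   one).
#' @return an [epoch_series()] of kind `raw_score` (`PS` values).
#' @examples
#' # an all-zero night scores PS = 7.601 everywhere (sleep)
#' sadeh_score(epoch_series(rep(0, 4), "activity_counts"))$values
#' @export
sadeh_score <- function(counts, spec = algorithm_spec("sadeh")) {
  stopifnot(inherits(counts, "epoch_series"))
  if (counts$kind != "activity_counts")
    stop("sadeh_score expects activity counts", call. = FALSE)
  x <- pmin(counts$values, spec$clip)
  n <- length(x)
  offs <- seq.int(-spec$window_before, spec$window_after)
  win <- vapply(offs, function(k) shift_pad(x, k), numeric(n))
  if (n == 1L) win <- matrix(win, nrow = 1L)
  avg <- rowMeans(win)
  nats <- rowSums(win >= spec$nats_low & win < spec$nats_high)
  first6 <- win[, seq_len(spec$sd_epochs), drop = FALSE]
  m6 <- rowMeans(first6)
  sd6 <- sqrt(pmax(0, rowSums((first6 - m6)^2) / (spec$sd_epochs - 1)))
  lg <- log(x + spec$log_offset)
  ps <- spec$intercept - spec$coef_avg * avg - spec$coef_nats * nats -
    spec$coef_sd * sd6 - spec$coef_lg * lg
  out <- epoch_series(ps, kind = "raw_score",
                      epoch_length_s = counts$epoch_length_s,
                      start_time = counts$start_time,
                      participant_id = counts$participant_id)
  attr(out, "algorithm") <- "sadeh"
  out
}

#' Score an activity series with a named algorithm
#'
#' Dispatches to [weighted_window_score()] or [sadeh_score()] by algorithm
#' name.
#'
#' @inheritParams weighted_window_score
#' @param algorithm algorithm name (see [algorithm_registry()]).
#' @return raw-score [epoch_series()].
#' @export
score_epochs <- function(counts, algorithm) {
  spec <- algorithm_spec(algorithm)
  if (identical(spec$special, "sadeh")) sadeh_score(counts, spec)
  else weighted_window_score(counts, spec)
}

#' Threshold raw scores into sleep-wake labels
#'
#' Applies the algorithm's decision rule: Cole-Kripke, UCSD and Kripke 2010
#' score sleep when the score is below the threshold (`D < 1`); Philips
#' scores sleep when total activity does not exceed the wake threshold
#' (`A <= T`); Sadeh scores sleep when `PS >= 0`.
#'
#' @param score a raw-score [epoch_series()] (30-s or collapsed 1-minute).
#' @param spec the algorithm spec the scores came from, or an algorithm name.
#' @param threshold optional threshold override (Philips variants).
#' @return binary sleep-wake [epoch_series()] (wake = 0, sleep = 1).
#' @export
classify <- function(score, spec, threshold = NULL) {
  stopifnot(inherits(score, "epoch_series"))
  if (is.character(spec)) spec <- algorithm_spec(spec)
  thr <- if (!is.null(threshold)) threshold else spec$threshold
  dec <- spec$decision
  if (is.null(dec)) stop("configuration error: decision rule unset",
                         call. = FALSE)
  v <- switch(dec,
    sleep_if_score_lt_threshold = as.numeric(score$values < thr),
    sleep_if_score_le_threshold = as.numeric(score$values <= thr),
    sleep_if_score_ge_threshold = as.numeric(score$values >= thr),
    stop("configuration error: unknown decision rule ", dec, call. = FALSE))
  out <- epoch_series(v, kind = "binary_sleep_wake",
                      epoch_length_s = score$epoch_length_s,
                      start_time = score$start_time,
                      participant_id = score$participant_id)
  attr(out, "algorithm") <- attr(score, "algorithm")
  out
}

#' Score orientation for ROC sweeps
#'
#' For the sleep-positive ROC sweep, algorithms whose decision rule is
#' "sleep when the score is low" (Cole-Kripke, UCSD, Kripke 2010, Philips)
#' have their scores negated; Sadeh's PS already points toward sleep.
#'
#' @param spec algorithm spec or name.
#' @return `"higher_is_sleep"` or `"lower_is_sleep"`.
#' @export
score_orientation <- function(spec) {
  if (is.character(spec)) spec <- algorithm_spec(spec)
  if (identical(spec$decision, "sleep_if_score_ge_threshold"))
    "higher_is_sleep" else "lower_is_sleep"
}
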