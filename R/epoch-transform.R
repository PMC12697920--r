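#' Collapse 30-second raw scores to 1-minute epochs
#'
#' Minute score = sum of the two constituent 30-second scores.  Pairs are
#' formed from epoch 0, i.e. (0,1), (2,3), ...; an unpaired trailing epoch is
#' dropped (and reported via the `dropped_trailing` attribute).  The
#' algorithm's original per-epoch threshold is applied unchanged to the
#' minute sums by the downstream [classify()] call.
#'
#' @param score a 30-second raw-score [epoch_series()].
#' @return a 1-minute raw-score [epoch_series()].
#' @examples
#' s <- epoch_series(c(0.4, 0.5, 0.7), "raw_score")
#' collapse_scores_to_minutes(s)$values  # 0.9; trailing 0.7 dropped
#' @export
collapse_scores_to_minutes <- function(score) {
  stopifnot(inherits(score, "epoch_series"))
  if (score$epoch_length_s != 30L)
    stop("expected a 30-second series", call. = FALSE)
  v <- score$values
  if (length(v) < 1L) stop("empty input", call. = FALSE)
  n_pairs <- length(v) %/% 2L
  if (n_pairs < 1L)
    stop("need at least two 30-second epochs to form a minute", call. = FALSE)
  dropped <- length(v) - 2L * n_pairs
  keep <- v[seq_len(2L * n_pairs)]
  mins <- keep[c(TRUE, FALSE)] + keep[c(FALSE, TRUE)]
  out <- epoch_series(mins, kind = "raw_score", epoch_length_s = 60L,
                      start_time = score$start_time,
                      participant_id = score$participant_id)
  attr(out, "algorithm") <- attr(score, "algorithm")
  attr(out, "dropped_trailing") <- dropped
  out
}

#' Collapse 30-second sleep-wake labels to minutes (wake wins)
#'
#' A minute is sleep only when both constituent 30-second epochs are sleep;
#' if either is wake the minute is wake.  This is the standard rule for
#' harmonizing polysomnography labels with minute-based actigraphy scoring.
#'
#' @param psg a 30-second binary sleep-wake [epoch_series()].
#' @return a 1-minute binary sleep-wake [epoch_series()]; unpaired trailing
#'   epoch dropped as in [collapse_scores_to_minutes()].
#' @export
collapse_psg_to_minutes <- function(psg) {
  stopifnot(inherits(psg, "epoch_series"))
  if (psg$epoch_length_s != 30L)
    stop("expected a 30-second series", call. = FALSE)
  if (psg$kind != "binary_sleep_wake")
    stop("validation error: expected binary sleep-wake labels", call. = FALSE)
  v <- psg$values
  n_pairs <- length(v) %/% 2L
  if (n_pairs < 1L)
    stop("need at least two 30-second epochs to form a minute", call. = FALSE)
  keep <- v[seq_len(2L * n_pairs)]
  mins <- as.numeric(keep[c(TRUE, FALSE)] == 1 & keep[c(FALSE, TRUE)] == 1)
  out <- epoch_series(mins, kind = "binary_sleep_wake", epoch_length_s = 60L,
                      start_time = psg$start_time,
                      participant_id = psg$participant_id)
  attr(out, "dropped_trailing") <- length(v) - 2L * n_pairs
  out
}

#' Audit the distribution of adjacent 30-second label pairs
#'
#' Reports the proportions of non-overlapping adjacent polysomnography label
#' pairs that are both sleep, both wake, or mixed.  A low mixed fraction
#' indicates the wake-wins collapse has limited effect on the label stream.
#'
#' @param psg a 30-second binary sleep-wake [epoch_series()], or a plain 0/1
#'   vector.
#' @return named numeric vector `both_sleep`, `both_wake`, `mixed`, summing
#'   to 1.
#' @export
pair_distribution <- function(psg) {
  v <- if (inherits(psg, "epoch_series")) psg$values else as.numeric(psg)
  if (!all(v %in% c(0, 1)))
    stop("validation error: expected binary labels", call. = FALSE)
  n_pairs <- length(v) %/% 2L
  if (n_pairs < 1L) stop("need at least one pair", call. = FALSE)
  a <- v[seq_len(2L * n_pairs)][c(TRUE, FALSE)]
  b <- v[seq_len(2L * n_pairs)][c(FALSE, TRUE)]
  c(both_sleep = mean(a == 1 & b == 1),
    both_wake = mean(a == 0 & b == 0),
    mixed = mean(a != b))
}
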