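#' Night-level sleep metrics from a minute hypnogram
#'
#' Given a 1-minute binary sleep-wake series already cropped to the in-bed
#' interval, computes:
#' \describe{
#'   \item{onset}{minute index (1-based) of the first minute scored sleep;}
#'   \item{offset}{minute index of the last minute scored sleep;}
#'   \item{TST}{total sleep time: minutes scored sleep between onset and
#'     offset inclusive;}
#'   \item{WASO}{wake after sleep onset: minutes scored wake between onset
#'     and offset;}
#'   \item{SE}{sleep efficiency, `100 * TST / in_bed` percent.}
#' }
#' `TST + WASO = offset - onset + 1` holds whenever an onset exists.  Sleep
#' onset is the first single minute scored sleep (no consecutive-minutes
#' criterion); `onset_run` imposes a run-of-N-minutes onset rule for
#' sensitivity analyses.
#'
#' @param binary 1-minute binary sleep-wake [epoch_series()] or 0/1 vector,
#'   cropped to the in-bed interval.
#' @param in_bed_minutes in-bed duration in minutes (the SE denominator);
#'   defaults to the series length.
#' @param method label for the scoring method (carried through to output).
#' @param onset_run minimum consecutive sleep minutes defining onset
#'   (default 1).
#' @return an object of class `night_metrics`: a one-row data frame with
#'   columns `participant_id`, `method`, `onset`, `offset`, `tst`, `waso`,
#'   `in_bed`, `se`, `no_sleep` (flag for nights without any sleep minute,
#'   for which TST = WASO = SE = 0 and onset/offset are `NA`).
#' @examples
#' compute_night_metrics(c(0, 0, 1, 1, 0, 1), in_bed_minutes = 6)
#' @export
compute_night_metrics <- function(binary, in_bed_minutes = NULL,
                                  method = "unknown", onset_run = 1L) {
  if (inherits(binary, "epoch_series")) {
    if (binary$epoch_length_s != 60L)
      stop("compute_night_metrics expects a 1-minute series", call. = FALSE)
    pid <- binary$participant_id
    v <- binary$values
  } else {
    pid <- "p1"
    v <- as.numeric(binary)
  }
  if (!all(v %in% c(0, 1)))
    stop("expected binary sleep-wake labels", call. = FALSE)
  if (is.null(in_bed_minutes)) in_bed_minutes <- length(v)

  onset <- NA_integer_
  if (onset_run <= 1L) {
    s <- which(v == 1)
    if (length(s)) onset <- s[1L]
  } else {
    r <- rle(v)
    ends <- cumsum(r$lengths)
    i <- which(r$values == 1 & r$lengths >= onset_run)
    if (length(i)) onset <- ends[i[1L]] - r$lengths[i[1L]] + 1L
  }

  if (is.na(onset)) {
    res <- data.frame(participant_id = pid, method = method,
                      onset = NA_integer_, offset = NA_integer_,
                      tst = 0, waso = 0, in_bed = in_bed_minutes, se = 0,
                      no_sleep = TRUE, stringsAsFactors = FALSE)
  } else {
    offset <- max(which(v == 1))
    span <- v[onset:offset]
    tst <- sum(span == 1)
    waso <- sum(span == 0)
    res <- data.frame(participant_id = pid, method = method,
                      onset = onset, offset = offset,
                      tst = tst, waso = waso, in_bed = in_bed_minutes,
                      se = 100 * tst / in_bed_minutes,
                      no_sleep = FALSE, stringsAsFactors = FALSE)
  }
  class(res) <- c("night_metrics", "data.frame")
  res
}
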