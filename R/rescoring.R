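#' Webster's rescoring rules
#'
#' The five rules convert short sleep runs adjacent to long wake runs into
#' wake, countering the tendency of count-threshold algorithms to score
#' quiet wakefulness as sleep:
#'
#' 1. after at least 4 minutes scored wake, the next 1 minute scored sleep
#'    is rescored wake;
#' 2. after at least 10 minutes wake, the next 3 minutes sleep are rescored
#'    wake;
#' 3. after at least 15 minutes wake, the next 4 minutes sleep are rescored
#'    wake;
#' 4. 6 minutes or less scored sleep surrounded by at least 10 minutes wake
#'    on both sides are rescored wake;
#' 5. 10 minutes or less scored sleep surrounded by at least 20 minutes wake
#'    on both sides are rescored wake.
#'
#' Rules are applied sequentially (1 through 5), each operating on the
#' output of the previous rule.  Within one rule's pass, run lengths are
#' taken from the series as it stood at the start of that pass, and all of
#' the pass's changes are applied together: a strictly in-place sweep would
#' let each rescored minute extend the preceding wake run and rule 1 alone
#' would then consume any sleep run following four wake minutes, which is
#' not the published behaviour.  "After at least N minutes wake" means a
#' maximal run of at least N consecutive wake minutes immediately precedes
#' the sleep minutes in question.  A sleep run at the start or end of the
#' record has no preceding/following wake run and is never touched by rules
#' 4-5.  Only sleep-to-wake changes ever occur, so the rescored wake set
#' always contains the original wake set.
#'
#' @param binary a 1-minute binary sleep-wake [epoch_series()] or 0/1 vector.
#' @return an object of the same type with rescored labels; attribute
#'   `rule_changes` gives the number of minutes changed by each rule, and
#'   `fixed_point` is `TRUE` when a second full pass would change nothing.
#' @examples
#' webster_rescore(c(0, 0, 0, 0, 1, 1, 1))  # rule 1 kills the first sleep min
#' @export
webster_rescore <- function(binary) {
  is_series <- inherits(binary, "epoch_series")
  if (is_series) {
    if (binary$epoch_length_s != 60L)
      stop("webster_rescore expects a 1-minute series", call. = FALSE)
    if (binary$kind != "binary_sleep_wake")
      stop("webster_rescore expects binary sleep-wake labels", call. = FALSE)
    v <- binary$values
  } else {
    v <- as.numeric(binary)
    if (!all(v %in% c(0, 1)))
      stop("webster_rescore expects binary labels", call. = FALSE)
  }

  changes <- integer(5)
  for (r in 1:5) {
    before <- v
    v <- apply_webster_rule(v, r)
    changes[r] <- sum(before != v)
  }
  # fixed-point audit: would a second sequential pass change anything?
  v2 <- v
  for (r in 1:5) v2 <- apply_webster_rule(v2, r)
  fixed <- identical(v2, v)

  out <- if (is_series) {
    y <- binary
    y$values <- v
    y
  } else v
  attr(out, "rule_changes") <- stats::setNames(changes, paste0("rule", 1:5))
  attr(out, "fixed_point") <- fixed
  out
}

# one rule pass over a snapshot run-length encoding; marks applied together
apply_webster_rule <- function(v, rule) {
  after <- list(c(4L, 1L), c(10L, 3L), c(15L, 4L))
  surrounded <- list(c(6L, 10L), c(10L, 20L))
  r <- rle(v)
  n_runs <- length(r$lengths)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  mark <- logical(length(v))

  if (rule <= 3L) {
    N <- after[[rule]][1L]; M <- after[[rule]][2L]
    for (i in seq_len(n_runs)) {
      if (r$values[i] == 1 && i > 1L &&
          r$values[i - 1L] == 0 && r$lengths[i - 1L] >= N) {
        k <- min(M, r$lengths[i])
        mark[starts[i]:(starts[i] + k - 1L)] <- TRUE
      }
    }
  } else {
    L <- surrounded[[rule - 3L]][1L]; F <- surrounded[[rule - 3L]][2L]
    for (i in seq_len(n_runs)) {
      if (r$values[i] == 1 && r$lengths[i] <= L &&
          i > 1L && i < n_runs &&
          r$values[i - 1L] == 0 && r$lengths[i - 1L] >= F &&
          r$values[i + 1L] == 0 && r$lengths[i + 1L] >= F) {
        mark[starts[i]:ends[i]] <- TRUE
      }
    }
  }
  v[mark] <- 0
  v
}
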