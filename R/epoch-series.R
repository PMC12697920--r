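#' Epoch series objects
#'
#' An `epoch_series` is one participant-night of fixed-length epochs carrying
#' either nonnegative activity counts, binary sleep-wake labels (wake = 0,
#' sleep = 1), or raw algorithm scores.  Epochs are indexed 0-based; epoch
#' `i` covers the half-open interval `[start + i * len, start + (i + 1) * len)`.
#'
#' @param values numeric vector, one value per epoch (length >= 1).
#' @param kind one of `"activity_counts"`, `"binary_sleep_wake"`,
#'   `"raw_score"`.
#' @param epoch_length_s epoch length in seconds, 30 or 60.
#' @param start_time `POSIXct` timestamp of the first epoch's start (UTC), or
#'   a string parseable as ISO 8601.
#' @param participant_id opaque participant identifier.
#'
#' @return an object of class `epoch_series`.
#' @examples
#' es <- epoch_series(c(0, 10, 0), "activity_counts",
#'                    start_time = "2022-01-01T22:00:00")
#' length(es$values)
#' @export
epoch_series <- function(values, kind = c("activity_counts",
                                          "binary_sleep_wake",
                                          "raw_score"),
                         epoch_length_s = 30L,
                         start_time = as.POSIXct("2000-01-01 00:00:00",
                                                 tz = "UTC"),
                         participant_id = "p1") {
  kind <- match.arg(kind)
  values <- as.numeric(values)
  if (length(values) < 1L)
    stop("epoch_series requires at least one epoch", call. = FALSE)
  if (!epoch_length_s %in% c(30L, 60L))
    stop("epoch_length_s must be 30 or 60", call. = FALSE)
  if (is.character(start_time)) start_time <- parse_epoch_time(start_time)
  x <- structure(
    list(participant_id = as.character(participant_id),
         start_time = start_time,
         epoch_length_s = as.integer(epoch_length_s),
         kind = kind,
         values = values),
    class = "epoch_series")
  validate_epoch_series(x)
  x
}

#' @export
print.epoch_series <- function(x, ...) {
  cat(sprintf("<epoch_series> %s: %d x %ds epochs of %s, start %s\n",
              x$participant_id, length(x$values), x$epoch_length_s, x$kind,
              format_epoch_time(x$start_time)))
  invisible(x)
}

#' @export
length.epoch_series <- function(x) length(x$values)

validate_epoch_series <- function(x) {
  v <- x$values
  if (anyNA(v) || any(!is.finite(v)))
    stop("epoch_series values must be finite and non-missing", call. = FALSE)
  if (x$kind == "activity_counts" && any(v < 0)) {
    bad <- which(v < 0)[1L]
    stop(sprintf("negative activity count at epoch %d (0-based %d)",
                 bad, bad - 1L), call. = FALSE)
  }
  if (x$kind == "binary_sleep_wake" && !all(v %in% c(0, 1))) {
    bad <- which(!v %in% c(0, 1))[1L]
    stop(sprintf("non-binary sleep-wake value %g at epoch %d", v[bad], bad),
         call. = FALSE)
  }
  invisible(x)
}

parse_epoch_time <- function(s) {
  s <- sub("T", " ", s, fixed = TRUE)
  t <- as.POSIXct(s, tz = "UTC", format = "%Y-%m-%d %H:%M:%S")
  if (anyNA(t)) {
    bad <- which(is.na(t))
    stop(sprintf("unparseable timestamp(s): %s",
                 paste(utils::head(s[bad], 3L), collapse = ", ")),
         call. = FALSE)
  }
  t
}

format_epoch_time <- function(t) format(t, "%Y-%m-%dT%H:%M:%S", tz = "UTC")

epoch_times <- function(x) {
  x$start_time + (seq_along(x$values) - 1L) * x$epoch_length_s
}

#' Read an epoch series from delimited text
#'
#' Reads a headered CSV holding one participant-night of epochs.  Column
#' names are mapped through `schema`, so arbitrary export layouts can be
#' ingested without rewriting files.  Timestamps must be ISO 8601 and evenly
#' spaced at the declared epoch length; violations are reported with the
#' offending data row number (header = line 1).
#'
#' @param path path to a delimited text file with a header row.
#' @param kind value kind stored in the file; see [epoch_series()].
#' @param schema named list mapping the roles `timestamp`, `value` and
#'   (optionally) `participant_id` to column names in the file.
#' @param participant_id overrides the id column (required when the file has
#'   none).
#' @param sep field separator.
#' @return an [epoch_series()].
#' @seealso [write_epoch_series()]
#' @export
read_epoch_series <- function(path,
                              kind = "activity_counts",
                              schema = list(timestamp = "timestamp",
                                            value = "value",
                                            participant_id = "participant_id"),
                              participant_id = NULL,
                              sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE)
  need <- c(schema$timestamp, schema$value)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), " in ", path, call. = FALSE)
  n <- nrow(df)
  if (n < 1L) stop("no data rows in ", path, call. = FALSE)

  ts <- parse_epoch_time(df[[schema$timestamp]])
  vals <- suppressWarnings(as.numeric(df[[schema$value]]))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1L]
    stop(sprintf("validation error: non-numeric value %s at data row %d (line %d)",
                 df[[schema$value]][bad], bad, bad + 1L), call. = FALSE)
  }
  if (kind == "activity_counts" && any(vals < 0)) {
    bad <- which(vals < 0)[1L]
    stop(sprintf("validation error: negative count %g at data row %d (line %d)",
                 vals[bad], bad, bad + 1L), call. = FALSE)
  }

  if (n > 1L) {
    gaps <- as.numeric(diff(ts), units = "secs")
    len <- gaps[1L]
    off <- which(gaps != len)
    if (length(off))
      stop(sprintf("timing error: epoch spacing %gs at data row %d (line %d), expected %gs",
                   gaps[off[1L]], off[1L] + 1L, off[1L] + 2L, len),
           call. = FALSE)
    if (!len %in% c(30, 60))
      stop(sprintf("timing error: epoch spacing %gs is not 30 or 60 seconds",
                   len), call. = FALSE)
  } else {
    len <- 30
  }

  pid <- participant_id
  if (is.null(pid)) {
    idc <- schema$participant_id
    pid <- if (!is.null(idc) && idc %in% names(df)) df[[idc]][1L] else "p1"
  }
  epoch_series(vals, kind = kind, epoch_length_s = as.integer(len),
               start_time = ts[1L], participant_id = pid)
}

#' Write an epoch series to CSV
#'
#' Writes columns `participant_id`, `timestamp` (ISO 8601, UTC) and `value`.
#' Values are written with 17 significant digits so that
#' `read_epoch_series(write_epoch_series(x))` round-trips doubles exactly.
#'
#' @param x an [epoch_series()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_epoch_series <- function(x, path) {
  stopifnot(inherits(x, "epoch_series"))
  df <- data.frame(
    participant_id = x$participant_id,
    timestamp = format_epoch_time(epoch_times(x)),
    value = formatC(x$values, digits = 17, format = "g"),
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Synchronization record for one participant-night
#'
#' Mirrors a per-participant synchronization document: the signed offset (in
#' 30-second epochs) of the polysomnography start relative to the actigraphy
#' start, and the in-bed interval.  A positive `psg_offset_epochs` means the
#' polysomnography recording starts later than the actigraphy recording.
#'
#' @param participant_id participant identifier.
#' @param psg_offset_epochs signed integer offset in 30-s epochs.
#' @param in_bed_start,in_bed_end in-bed interval bounds (`POSIXct` or ISO
#'   8601 strings); `in_bed_start < in_bed_end`.
#' @return an object of class `sync_spec`.
#' @export
sync_spec <- function(participant_id, psg_offset_epochs = 0L,
                      in_bed_start, in_bed_end) {
  if (is.character(in_bed_start)) in_bed_start <- parse_epoch_time(in_bed_start)
  if (is.character(in_bed_end)) in_bed_end <- parse_epoch_time(in_bed_end)
  if (!(in_bed_start < in_bed_end))
    stop("in_bed_start must precede in_bed_end", call. = FALSE)
  structure(list(participant_id = as.character(participant_id),
                 psg_offset_epochs = as.integer(psg_offset_epochs),
                 in_bed_start = in_bed_start,
                 in_bed_end = in_bed_end),
            class = "sync_spec")
}

#' Read a synchronization table
#'
#' @param path CSV with columns `participant_id`, `psg_offset_epochs`,
#'   `in_bed_start`, `in_bed_end`.
#' @return named list of [sync_spec()] objects keyed by participant id.
#' @export
read_sync_table <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  need <- c("participant_id", "psg_offset_epochs", "in_bed_start", "in_bed_end")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("sync table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  specs <- lapply(seq_len(nrow(df)), function(i)
    sync_spec(df$participant_id[i], as.integer(df$psg_offset_epochs[i]),
              df$in_bed_start[i], df$in_bed_end[i]))
  names(specs) <- df$participant_id
  specs
}

#' Align paired actigraphy and polysomnography series
#'
#' Crops both 30-second series to their overlapping window after applying the
#' polysomnography start offset, and optionally to the in-bed interval.  With
#' a zero offset and equal lengths both series are returned unchanged, so the
#' operation is idempotent.
#'
#' @param act actigraphy [epoch_series()] (30-s epochs).
#' @param psg polysomnography [epoch_series()] (30-s epochs).
#' @param sync a [sync_spec()].
#' @param crop_to_in_bed if `TRUE`, additionally crop the aligned pair to the
#'   epochs fully contained in `[in_bed_start, in_bed_end)`.
#' @return list with elements `act` and `psg`, equal-length aligned series.
#' @export
synchronize <- function(act, psg, sync, crop_to_in_bed = FALSE) {
  stopifnot(inherits(act, "epoch_series"), inherits(psg, "epoch_series"),
            inherits(sync, "sync_spec"))
  if (act$epoch_length_s != 30L || psg$epoch_length_s != 30L)
    stop("synchronize expects 30-second epoch series", call. = FALSE)
  off <- sync$psg_offset_epochs
  na <- length(act$values); np <- length(psg$values)
  # actigraphy timeline: act covers epochs [0, na); psg covers [off, off + np)
  lo <- max(0L, off)
  hi <- min(na, off + np)
  if (hi - lo < 1L)
    stop("synchronization error: no overlapping epochs (offset ", off, ")",
         call. = FALSE)
  a_idx <- (lo + 1L):hi
  p_idx <- (lo - off + 1L):(hi - off)
  start <- act$start_time + lo * 30L

  if (crop_to_in_bed) {
    t0 <- as.numeric(difftime(sync$in_bed_start, start, units = "secs"))
    t1 <- as.numeric(difftime(sync$in_bed_end, start, units = "secs"))
    nw <- length(a_idx)
    first <- max(0L, as.integer(ceiling(t0 / 30)))
    last <- min(nw, as.integer(floor(t1 / 30)))
    if (last - first < 1L)
      stop("synchronization error: in-bed interval overlaps no aligned epochs",
           call. = FALSE)
    keep <- (first + 1L):last
    a_idx <- a_idx[keep]; p_idx <- p_idx[keep]
    start <- start + first * 30L
  }

  list(
    act = epoch_series(act$values[a_idx], kind = act$kind,
                       epoch_length_s = 30L, start_time = start,
                       participant_id = act$participant_id),
    psg = epoch_series(psg$values[p_idx], kind = psg$kind,
                       epoch_length_s = 30L, start_time = start,
                       participant_id = psg$participant_id))
}
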