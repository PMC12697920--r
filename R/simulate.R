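#' Configuration for the synthetic paired-night generator
#'
#' Describes a cohort of single-night recordings: each participant
#' contributes one in-bed interval with paired 30-second actigraphy counts
#' and polysomnography sleep-wake labels.  The ground-truth hypnogram is
#' built at 1-minute resolution (sleep-onset latency, a sleep period
#' interrupted by wake bouts from a two-state bout process, and a terminal
#' wake segment) and replicated to 30-second epochs, so the wake-wins
#' collapse can reconstruct it exactly.  Activity counts are sampled
#' conditional on state: wake counts from a gamma distribution, sleep counts
#' from a zero-inflated gamma burst model.  Setting a shape parameter to
#' `Inf` makes the corresponding draw deterministic at its mean, which is
#' how noiseless recovery cohorts are configured.
#'
#' Phenotype presets adjust fragmentation: `"fragmented"` raises the wake
#' bout rate and duration (emulating disrupted sleep as in apnea),
#' `"long_latency"` triples the mean latency (emulating insomnia-like
#' nights).  Presets only fill parameters the caller did not set.
#'
#' @param n_participants cohort size.
#' @param in_bed_minutes in-bed duration per night, minutes.
#' @param latency_mean,latency_shape gamma mean (minutes) and shape of
#'   sleep-onset latency; `latency_shape = Inf` fixes latency at the mean.
#' @param wake_bout_rate wake bouts per hour of sleep period.
#' @param wake_bout_mean mean wake bout duration, minutes (geometric).
#' @param terminal_wake_mean mean terminal wake duration, minutes.
#' @param counts_wake_mean,counts_wake_shape gamma mean and shape of wake
#'   epoch counts; shape `Inf` gives constant counts.
#' @param sleep_zero_prob zero-inflation probability for sleep epochs.
#' @param counts_sleep_mean,counts_sleep_shape gamma burst mean and shape
#'   for nonzero sleep-epoch counts.
#' @param phenotype `"typical"`, `"fragmented"` or `"long_latency"`.
#' @param frac_fragmented,frac_long_latency cohort fractions assigned the
#'   fragmented (labelled `apnea`) and long-latency (labelled `insomnia`)
#'   phenotypes; the remainder is typical.
#' @param seed integer seed; identical config + seed give byte-identical
#'   cohorts.
#' @return object of class `night_config` (a validated list).
#' @export
night_config <- function(n_participants = 50L,
                         in_bed_minutes = 480L,
                         latency_mean = 15,
                         latency_shape = 2,
                         wake_bout_rate = 1.5,
                         wake_bout_mean = 2,
                         terminal_wake_mean = 5,
                         counts_wake_mean = 150,
                         counts_wake_shape = 1,
                         sleep_zero_prob = 0.85,
                         counts_sleep_mean = 20,
                         counts_sleep_shape = 1,
                         phenotype = c("typical", "fragmented",
                                       "long_latency"),
                         frac_fragmented = 0.07,
                         frac_long_latency = 0.06,
                         seed = 1L) {
  phenotype <- match.arg(phenotype)
  if (phenotype == "fragmented") {
    if (missing(wake_bout_rate)) wake_bout_rate <- 4
    if (missing(wake_bout_mean)) wake_bout_mean <- 4
  } else if (phenotype == "long_latency") {
    if (missing(latency_mean)) latency_mean <- 45
  }
  cfg <- list(n_participants = as.integer(n_participants),
              in_bed_minutes = as.integer(in_bed_minutes),
              latency_mean = latency_mean, latency_shape = latency_shape,
              wake_bout_rate = wake_bout_rate,
              wake_bout_mean = wake_bout_mean,
              terminal_wake_mean = terminal_wake_mean,
              counts_wake_mean = counts_wake_mean,
              counts_wake_shape = counts_wake_shape,
              sleep_zero_prob = sleep_zero_prob,
              counts_sleep_mean = counts_sleep_mean,
              counts_sleep_shape = counts_sleep_shape,
              phenotype = phenotype,
              frac_fragmented = frac_fragmented,
              frac_long_latency = frac_long_latency,
              seed = as.integer(seed))
  stopifnot(cfg$n_participants >= 1, cfg$in_bed_minutes >= 10,
            cfg$latency_mean >= 0, cfg$wake_bout_rate >= 0,
            cfg$wake_bout_mean >= 0, cfg$counts_wake_mean >= 0,
            cfg$sleep_zero_prob >= 0, cfg$sleep_zero_prob <= 1)
  class(cfg) <- "night_config"
  cfg
}

night_seed <- function(seed, i) {
  as.integer((as.numeric(seed) %% 1e6 * 1009 + i * 7919) %% 2147483647)
}

draw_gamma <- function(n, mean, shape) {
  if (mean == 0) return(rep(0, n))
  if (is.infinite(shape)) return(rep(mean, n))
  stats::rgamma(n, shape = shape, scale = mean / shape)
}

# geometric run length with given mean, support >= 1
draw_runlen <- function(n, mean) {
  if (mean <= 1) return(rep(1L, n))
  1L + stats::rgeom(n, prob = 1 / mean)
}

simulate_hypnogram <- function(cfg) {
  m <- cfg$in_bed_minutes
  lat <- if (is.infinite(cfg$latency_shape)) cfg$latency_mean else
    draw_gamma(1, cfg$latency_mean, cfg$latency_shape)
  lat <- min(as.integer(round(lat)), m - 2L)  # cap: at least 2 sleep minutes
  lat <- max(lat, 0L)
  term <- min(draw_runlen(1L, cfg$terminal_wake_mean + 1) - 1L,
              m - lat - 2L)
  term <- max(term, 0L)
  sp <- m - lat - term  # sleep-period length, >= 2

  state <- rep(1, sp)
  if (cfg$wake_bout_rate > 0) {
    mean_sleep_run <- 60 / cfg$wake_bout_rate
    pos <- 1L
    repeat {
      srun <- draw_runlen(1L, mean_sleep_run)
      pos <- pos + srun
      if (pos > sp - 1L) break
      wrun <- draw_runlen(1L, cfg$wake_bout_mean)
      wend <- min(pos + wrun - 1L, sp - 1L)  # keep last minute sleep
      state[pos:wend] <- 0
      pos <- wend + 1L
      if (pos > sp - 1L) break
    }
  }
  c(rep(0, lat), state, rep(0, term))
}

#' Simulate one paired actigraphy/polysomnography night
#'
#' @param cfg a [night_config()].
#' @param participant_index integer index within the cohort; together with
#'   `cfg$seed` it determines the night's private RNG stream, so any night
#'   can be regenerated independently.
#' @param phenotype optional phenotype override for this night.
#' @return list with elements `act` (30-s activity [epoch_series()]), `psg`
#'   (30-s binary labels), `sync` ([sync_spec()] covering the in-bed
#'   interval), `truth` (generator-truth [compute_night_metrics()] row
#'   computed from the minute hypnogram), and `hypnogram` (the minute
#'   truth vector).
#' @examples
#' night <- simulate_night(night_config(seed = 7), 1)
#' night$truth$tst + night$truth$waso ==
#'   night$truth$offset - night$truth$onset + 1
#' @export
simulate_night <- function(cfg, participant_index, phenotype = NULL) {
  stopifnot(inherits(cfg, "night_config"))
  if (!is.null(phenotype) && phenotype != cfg$phenotype) {
    override <- switch(phenotype,
      typical = list(),
      fragmented = list(wake_bout_rate = 4, wake_bout_mean = 4),
      long_latency = list(latency_mean = 45),
      stop("unknown phenotype: ", phenotype, call. = FALSE))
    for (nm in names(override)) cfg[[nm]] <- override[[nm]]
    cfg$phenotype <- phenotype
  }
  set.seed(night_seed(cfg$seed, participant_index))
  pid <- sprintf("sim%04d", participant_index)
  hyp <- simulate_hypnogram(cfg)
  m <- length(hyp)
  labels30 <- rep(hyp, each = 2L)

  n30 <- length(labels30)
  counts <- numeric(n30)
  wake_idx <- which(labels30 == 0)
  sleep_idx <- which(labels30 == 1)
  counts[wake_idx] <- draw_gamma(length(wake_idx), cfg$counts_wake_mean,
                                 cfg$counts_wake_shape)
  if (length(sleep_idx)) {
    burst <- stats::runif(length(sleep_idx)) >= cfg$sleep_zero_prob
    counts[sleep_idx[burst]] <- draw_gamma(sum(burst), cfg$counts_sleep_mean,
                                           cfg$counts_sleep_shape)
  }
  counts <- round(counts)

  start <- as.POSIXct("2022-01-01 22:00:00", tz = "UTC")
  act <- epoch_series(counts, "activity_counts", 30L, start, pid)
  psg <- epoch_series(labels30, "binary_sleep_wake", 30L, start, pid)
  sync <- sync_spec(pid, 0L, start, start + m * 60)
  truth <- compute_night_metrics(hyp, in_bed_minutes = m, method = "truth")
  truth$participant_id <- pid
  list(act = act, psg = psg, sync = sync, truth = truth,
       hypnogram = hyp, phenotype = cfg$phenotype)
}

#' Simulate a cohort of paired nights
#'
#' Generates `cfg$n_participants` nights.  The first
#' `round(frac_fragmented * n)` participants receive the fragmented
#' phenotype (subgroup label `apnea`), the next `round(frac_long_latency *
#' n)` the long-latency phenotype (label `insomnia`); the rest are typical
#' (label `none`).  With `dir` given, per-participant CSVs, a sync table, a
#' subgroup label table and a manifest JSON (config + seed) are written in
#' the same formats [read_epoch_series()] and [read_sync_table()] consume.
#'
#' @param cfg a [night_config()].
#' @param dir optional output directory for the on-disk cohort bundle.
#' @param overwrite allow writing into an existing non-empty directory.
#' @return object of class `sim_cohort`: list with `nights` (list of
#'   [simulate_night()] results), `labels` (data frame participant_id /
#'   subgroup), `truth` (stacked truth metrics), `config`.
#' @export
simulate_cohort <- function(cfg, dir = NULL, overwrite = FALSE) {
  stopifnot(inherits(cfg, "night_config"))
  n <- cfg$n_participants
  n_frag <- round(cfg$frac_fragmented * n)
  n_lat <- round(cfg$frac_long_latency * n)
  phen <- c(rep("fragmented", n_frag), rep("long_latency", n_lat),
            rep(cfg$phenotype, max(0L, n - n_frag - n_lat)))[seq_len(n)]
  sub <- c(fragmented = "apnea", long_latency = "insomnia",
           typical = "none")[phen]

  nights <- lapply(seq_len(n), function(i)
    simulate_night(cfg, i, phenotype = phen[i]))
  labels <- data.frame(
    participant_id = vapply(nights, function(x) x$act$participant_id, ""),
    subgroup = unname(sub), stringsAsFactors = FALSE)
  truth <- do.call(rbind, lapply(nights, `[[`, "truth"))

  out <- structure(list(nights = nights, labels = labels, truth = truth,
                        config = cfg), class = "sim_cohort")
  if (!is.null(dir)) write_cohort(out, dir, overwrite = overwrite)
  out
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("<sim_cohort> %d nights x %d in-bed minutes (seed %d)\n",
              length(x$nights), x$config$in_bed_minutes, x$config$seed))
  print(table(x$labels$subgroup))
  invisible(x)
}

write_cohort <- function(cohort, dir, overwrite = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) && !overwrite)
    stop("output directory exists and is not empty; use overwrite = TRUE",
         call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sync_rows <- list()
  for (night in cohort$nights) {
    pid <- night$act$participant_id
    write_epoch_series(night$act, file.path(dir, paste0(pid, "_act.csv")))
    write_epoch_series(night$psg, file.path(dir, paste0(pid, "_psg.csv")))
    sync_rows[[pid]] <- data.frame(
      participant_id = pid,
      psg_offset_epochs = night$sync$psg_offset_epochs,
      in_bed_start = format_epoch_time(night$sync$in_bed_start),
      in_bed_end = format_epoch_time(night$sync$in_bed_end),
      stringsAsFactors = FALSE)
  }
  utils::write.csv(do.call(rbind, c(sync_rows, make.row.names = FALSE)),
                   file.path(dir, "sync_table.csv"), row.names = FALSE)
  utils::write.csv(cohort$labels, file.path(dir, "subgroups.csv"),
                   row.names = FALSE)
  cfg <- unclass(cohort$config)
  cfg$counts_wake_shape <- as.character(cfg$counts_wake_shape)
  cfg$counts_sleep_shape <- as.character(cfg$counts_sleep_shape)
  cfg$latency_shape <- as.character(cfg$latency_shape)
  jsonlite::write_json(
    list(config = cfg,
         n_participants = length(cohort$nights),
         package = "actisleep",
         version = as.character(utils::packageVersion("actisleep"))),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read a cohort bundle written by [simulate_cohort()]
#'
#' @param dir directory holding `*_act.csv`, `*_psg.csv`, `sync_table.csv`
#'   and optionally `subgroups.csv`.
#' @return list with `nights` (each `act`, `psg`, `sync`) and `labels`.
#' @export
read_cohort <- function(dir) {
  syncs <- read_sync_table(file.path(dir, "sync_table.csv"))
  labels_path <- file.path(dir, "subgroups.csv")
  labels <- if (file.exists(labels_path))
    utils::read.csv(labels_path, colClasses = "character") else NULL
  nights <- lapply(names(syncs), function(pid) {
    list(act = read_epoch_series(file.path(dir, paste0(pid, "_act.csv")),
                                 kind = "activity_counts"),
         psg = read_epoch_series(file.path(dir, paste0(pid, "_psg.csv")),
                                 kind = "binary_sleep_wake"),
         sync = syncs[[pid]])
  })
  names(nights) <- names(syncs)
  list(nights = nights, labels = labels)
}

#' Noiseless recovery configuration
#'
#' A cohort configuration with deterministic counts (wake epochs at 200,
#' sleep epochs at 0), a fixed 10-minute sleep-onset latency and a fully
#' consolidated sleep period.  Used for end-to-end recovery checks: with
#' perfectly state-separated counts, every scoring algorithm should
#' reconstruct the truth hypnogram up to the shoulder of its scoring window
#' at the single onset transition (1-4 minutes depending on window width).
#'
#' @param n_participants cohort size.
#' @param seed integer seed.
#' @return a [night_config()].
#' @export
noiseless_config <- function(n_participants = 50L, seed = 1L) {
  night_config(n_participants = n_participants,
               latency_mean = 10, latency_shape = Inf,
               wake_bout_rate = 0, terminal_wake_mean = 0,
               counts_wake_mean = 200, counts_wake_shape = Inf,
               sleep_zero_prob = 1,
               frac_fragmented = 0, frac_long_latency = 0,
               seed = seed)
}
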