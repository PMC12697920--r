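test_that("identical config and seed give byte-identical nights", {
  cfg <- night_config(n_participants = 3, seed = 11)
  a <- simulate_night(cfg, 2)
  b <- simulate_night(cfg, 2)
  expect_identical(a$act$values, b$act$values)
  expect_identical(a$psg$values, b$psg$values)
  expect_identical(a$truth, b$truth)
  # a different participant index gives a different night
  c2 <- simulate_night(cfg, 3)
  expect_false(identical(a$act$values, c2$act$values))
})

test_that("zero latency and zero wake bouts give a fully asleep night", {
  cfg <- night_config(n_participants = 1, latency_mean = 0,
                      latency_shape = Inf, wake_bout_rate = 0,
                      terminal_wake_mean = 0, seed = 5)
  night <- simulate_night(cfg, 1)
  expect_equal(night$truth$tst, cfg$in_bed_minutes)
  expect_equal(night$truth$waso, 0)
  expect_equal(night$truth$se, 100)
})

test_that("generator truth is recovered by the metrics module exactly", {
  for (seed in 1:5) {
    for (phen in c("typical", "fragmented", "long_latency")) {
      cfg <- night_config(n_participants = 1, phenotype = phen, seed = seed)
      night <- simulate_night(cfg, 1)
      re <- compute_night_metrics(night$hypnogram,
                                  in_bed_minutes = length(night$hypnogram),
                                  method = "truth")
      re$participant_id <- night$truth$participant_id
      expect_identical(re, night$truth)
      # conservation on every generated night
      expect_equal(night$truth$tst + night$truth$waso,
                   night$truth$offset - night$truth$onset + 1)
      # 30-s labels are the minute hypnogram replicated
      expect_identical(night$psg$values, rep(night$hypnogram, each = 2))
    }
  }
})

test_that("activity counts are state-conditional", {
  cfg <- night_config(n_participants = 1, seed = 21)
  night <- simulate_night(cfg, 1)
  wake <- night$act$values[night$psg$values == 0]
  sleep <- night$act$values[night$psg$values == 1]
  expect_true(all(night$act$values >= 0))
  expect_gt(mean(wake), mean(sleep) + 50)
  expect_gt(mean(sleep == 0), 0.5)  # zero-inflated sleep counts
})

test_that("mixed 30-second pairs arise only at bout boundaries", {
  for (seed in 1:5) {
    cfg <- night_config(n_participants = 1, phenotype = "fragmented",
                        seed = seed)
    night <- simulate_night(cfg, 1)
    pd <- pair_distribution(night$psg)
    n_pairs <- length(night$psg$values) %/% 2
    n_bouts <- length(rle(night$hypnogram)$lengths)
    expect_lte(pd[["mixed"]], 2 * n_bouts / n_pairs)
  }
})

test_that("fragmented nights carry more WASO than typical at matched seeds", {
  waso_typ <- waso_frag <- numeric(200)
  for (i in 1:200) {
    waso_typ[i] <- simulate_night(night_config(seed = 31), i,
                                  phenotype = "typical")$truth$waso
    waso_frag[i] <- simulate_night(night_config(seed = 31), i,
                                   phenotype = "fragmented")$truth$waso
  }
  expect_gt(mean(waso_frag), mean(waso_typ))
  # long-latency phenotype delays onset
  lat <- replicate(50, simulate_night(night_config(seed = 32), 1,
                                      phenotype = "long_latency")$truth$onset)
  expect_gt(mean(lat), 30)
})

test_that("cohort bundles round-trip through disk with a manifest", {
  dir <- withr::local_tempdir()
  cfg <- night_config(n_participants = 5, seed = 41)
  cohort <- simulate_cohort(cfg, dir = file.path(dir, "cohort"))
  files <- list.files(file.path(dir, "cohort"))
  expect_equal(sum(grepl("_act.csv$", files)), 5)
  expect_equal(sum(grepl("_psg.csv$", files)), 5)
  expect_true(all(c("sync_table.csv", "subgroups.csv", "manifest.json")
                  %in% files))
  man <- jsonlite::read_json(file.path(dir, "cohort", "manifest.json"))
  expect_equal(man$config$seed, 41)

  back <- read_cohort(file.path(dir, "cohort"))
  expect_equal(length(back$nights), 5)
  pid <- cohort$nights[[3]]$act$participant_id
  expect_identical(back$nights[[pid]]$act$values,
                   cohort$nights[[3]]$act$values)
  expect_identical(back$nights[[pid]]$psg$values,
                   cohort$nights[[3]]$psg$values)

  # refuses to clobber without overwrite
  expect_error(simulate_cohort(cfg, dir = file.path(dir, "cohort")),
               "overwrite")
  expect_silent(simulate_cohort(cfg, dir = file.path(dir, "cohort"),
                                overwrite = TRUE))
})

test_that("cohort subgroup labels follow the configured fractions", {
  cohort <- simulate_cohort(night_config(n_participants = 100, seed = 51))
  tab <- table(cohort$labels$subgroup)
  expect_equal(unname(tab[["apnea"]]), 7)
  expect_equal(unname(tab[["insomnia"]]), 6)
})
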