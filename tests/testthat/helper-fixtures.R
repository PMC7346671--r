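# Shared fixture builders: tiny epoch streams and minute series constructed
# in code, plus cached mid-size cohorts reused across test files.

origin_utc <- as.POSIXct("2012-01-02 00:00:00", tz = "UTC")

# one participant's epoch stream from a vector of per-epoch counts
make_epochs <- function(counts, participant_id = 1L, start = origin_utc) {
  data.table::data.table(
    participant_id = participant_id,
    time = start + (seq_along(counts) - 1L) * 15,
    vm_counts = as.integer(counts)
  )
}

# a minute-count series for Choi tests
make_minutes <- function(counts, participant_id = 1L, start = origin_utc) {
  data.table::data.table(
    participant_id = participant_id,
    minute = start + (seq_along(counts) - 1L) * 60,
    counts = as.numeric(counts)
  )
}

# a full-day epoch count vector from per-minute class codes
# (0 = zero counts, "sed" = 10, "light" = 100, "mvpa" = 600)
minutes_to_epochs <- function(codes) {
  per_min <- c(zero = 0L, sed = 10L, light = 100L, mvpa = 600L)
  rep(per_min[codes], each = 4L)
}

# zero-noise generator configuration: exact archetype curves, wake on the
# hour, no non-wear, no sleep-log missingness
zero_noise_config <- function(n = 24L, seed = 101L) {
  cfg <- default_config(n_participants = n, seed = seed)
  cfg$archetype_noise_sd <- 0
  cfg$nonwear_bout_rate <- 0
  cfg$sleeplog_missing_rate <- 0
  cfg$full_sleeplog_missing_rate <- 0
  cfg$wake_time_distribution <- c(mean = 7 * 60, sd = 0)
  cfg$sleep_time_distribution <- c(mean = 22 * 60, sd = 0)
  cfg
}

# run the accelerometer stages (no association) on a cohort
run_accel_stages <- function(cohort, alignment = "wake", k_range = 2:6,
                             K_range = 2:8, seed = 7L) {
  minutes <- aggregate_minutes(cohort$epochs)
  wear <- choi_nonwear(minutes)
  bt <- resolve_bed_times(cohort$sleep_log)
  cl <- classify_epochs(cohort$epochs, wear, bt)
  f <- filter_cohort(cl$days)
  hb <- hourly_sb(cl)
  hb <- hb[f$days[, .(participant_id, date)],
           on = c("participant_id", "date"), nomatch = NULL]
  tr <- extract_trajectories(hb, bt, alignment = alignment)
  tri <- copy_mean_impute(tr)
  sel <- pr <- pat <- NULL
  if (!is.null(k_range)) {
    sel <- select_k_phase1(tri, k_range = k_range, seed = seed)
    pr <- profiles_from_assignments(sel$model)
    pat <- hier_cluster(pr, K_range = K_range)
  }
  list(classified = cl, filtered = f, hourly = hb, trajectories = tri,
       selection = sel, profiles = pr, patterns = pat, bedtimes = bt,
       wear = wear, minutes = minutes)
}

# cache for expensive shared fixtures (built once per test run)
.fixture_env <- new.env(parent = emptyenv())

cached_default_run <- function() {
  if (is.null(.fixture_env$default_run)) {
    coh <- generate_cohort(default_config(n_participants = 120L, seed = 314L))
    .fixture_env$default_cohort <- coh
    .fixture_env$default_run <- run_accel_stages(coh)
  }
  list(cohort = .fixture_env$default_cohort, run = .fixture_env$default_run)
}
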