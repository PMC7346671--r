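# Synthetic cohort generator: epoch-level accelerometer streams, sleep logs,
# baseline covariates and a longitudinal physical-functioning panel, all with
# known ground truth so every downstream stage can be validated end to end.

EPOCHS_PER_DAY <- 24L * 60L * 4L   # 15-s epochs
STUDY_ORIGIN <- as.POSIXct("2012-01-02 00:00:00", tz = "UTC")

# Intensity cutpoints (vector-magnitude counts per 15-s epoch) from the
# OPACH laboratory calibration for older women: sedentary <= 18, MVPA > 519.
SEDENTARY_CUTPOINT <- 18L
MVPA_CUTPOINT <- 519L

#' Default day-archetype curves
#'
#' Four hourly sedentary-minute curves over the first 14 waking hours:
#' * A — high SB throughout the day, gently rising (~50–58 min/h);
#' * B — moderate SB, low in the first hours, rising steeply to end of day;
#' * C — moderate SB, high first hours, ~6-hour decline, then rising;
#' * D — low SB throughout the day (~25–33 min/h).
#'
#' Values are integers so that zero-noise days reproduce the curve exactly.
#'
#' @return A 4 x 14 numeric matrix, rows named A–D.
#' @export
default_archetypes <- function() {
  rbind(
    A = c(50, 51, 51, 52, 52, 53, 53, 54, 55, 55, 56, 56, 57, 58),
    B = c(24, 26, 28, 30, 33, 36, 39, 42, 45, 47, 49, 50, 51, 52),
    C = c(48, 46, 43, 40, 37, 35, 34, 35, 37, 40, 43, 45, 47, 48),
    D = c(26, 27, 27, 28, 28, 29, 30, 30, 31, 31, 32, 32, 33, 33)
  )
}

#' Default truth for the physical-functioning outcome model
#'
#' Baseline PF (0–100) and annual slope (PF points/year) per diurnal pattern
#' x MVPA stratum, person random-intercept SD, residual SD and number of
#' annual assessments. The cells reflect the ordering reported for a large
#' cohort of older women: lower baselines and steeper declines in the low-MVPA
#' stratum, with the steepest decline for the low-morning/high-evening SB
#' pattern under low MVPA.
#'
#' @return A list with elements `baseline_by_stratum` and `slope_by_stratum`
#'   (each a 2-row matrix, rows `low`/`high` MVPA, one column per pattern),
#'   `covariate_effects`, `random_intercept_sd`, `residual_sd`, `n_years`.
#' @export
default_pf_truth <- function() {
  list(
    baseline_by_stratum = rbind(
      low  = c(70.6, 75.1, 74.4, 74.0),
      high = c(78.9, 81.5, 78.6, 80.5)
    ),
    slope_by_stratum = rbind(
      low  = c(-2.3, -3.0, -2.5, -2.0),
      high = c(-2.1, -1.9, -1.6, -1.7)
    ),
    covariate_effects = list(
      age_per_year = -0.45,   # centred at 79 y
      bmi_per_unit = -0.35,   # centred at 28.1 kg/m^2
      smoker = -4,
      education = c(hs_or_less = 0, some_college = 1, college_grad = 2),
      alcohol = c(none = 0, lt1_wk = 0.5, ge1_wk = 1, unknown = 0),
      morbidity = c(`0` = 0, `1` = -2, `2` = -4, `3+` = -8),
      self_rated_health = c(excellent_vg = 0, good = -5, fair_poor = -14),
      race_ethnicity = c(White = 0, Black = 0, Hispanic = 0)
    ),
    random_intercept_sd = 10,
    residual_sd = 6,
    n_years = 7L
  )
}

#' Default generator configuration
#'
#' Emulates a cohort of older women wearing hip accelerometers 24 h/day for 7
#' days: four day archetypes (A–D), four participant-level patterns whose
#' day-type mixtures are dominated by the corresponding archetype (median
#' dominance ~0.6), wake/sleep clock-time distributions, sporadic sleep-log
#' missingness, occasional long non-wear bouts, pattern-specific MVPA levels,
#' and a PF outcome panel generated from a known random-intercept model.
#'
#' `target_mean_daily_sb` is the analytically implied mean daily sedentary
#' minutes under the configuration (mixture-weighted curve totals over the
#' mean waking span, minus expected non-wear overlap); the generator is
#' validated against it.
#'
#' @param n_participants number of participants (default 500).
#' @param seed integer root seed.
#' @return A list of class `sb_generator_config`.
#' @export
default_config <- function(n_participants = 500L, seed = 20120102L) {
  arch <- default_archetypes()
  mixtures <- rbind(
    p1 = c(0.65, 0.20, 0.15, 0.00),
    p2 = c(0.07, 0.57, 0.29, 0.07),
    p3 = c(0.14, 0.14, 0.58, 0.14),
    p4 = c(0.00, 0.20, 0.20, 0.60)
  )
  cfg <- list(
    n_participants = as.integer(n_participants),
    n_days = 7L,
    epoch_seconds = 15L,
    day_archetypes = arch,
    archetype_noise_sd = 6,
    pattern_mixtures = mixtures,
    pattern_weights = c(0.361, 0.248, 0.183, 0.208),
    wake_time_distribution = c(mean = 7 * 60 + 22, sd = 35),     # 07:22
    sleep_time_distribution = c(mean = 22 * 60 + 45, sd = 35),   # 22:45
    sleeplog_missing_rate = 0.08,
    full_sleeplog_missing_rate = 0.067,
    nonwear_bout_rate = 0.25,
    nonwear_bout_mean_minutes = 180,   # 90-min floor + Exp(mean 90) tail
    mvpa_minutes_by_pattern = cbind(
      mean = c(28.6, 54.2, 50.7, 82.1),
      sd = c(19.2, 28.8, 28.0, 38.9)
    ),
    mvpa_day_sd = 10,
    mvpa_hour_cap = 20,
    mvpa_split_truth = 43.21,
    pf_model = default_pf_truth(),
    seed = as.integer(seed)
  )
  cfg$target_mean_daily_sb <- implied_daily_sb(cfg)
  class(cfg) <- "sb_generator_config"
  validate_config(cfg)
  cfg
}

#' Analytically implied mean daily sedentary minutes for a configuration
#' @param config an `sb_generator_config`.
#' @return numeric scalar (minutes/day).
#' @keywords internal
implied_daily_sb <- function(config) {
  arch <- config$day_archetypes
  span_min <- config$sleep_time_distribution[["mean"]] -
    config$wake_time_distribution[["mean"]]
  n_hours <- span_min / 60
  per_arch <- apply(arch, 1L, function(cv) {
    full <- sum(cv[seq_len(min(14, floor(n_hours)))])
    extra <- (n_hours - floor(n_hours)) * cv[14]
    if (n_hours > 14) extra <- extra + (floor(n_hours) - 14) * cv[14]
    full + extra
  })
  arch_freq <- as.vector(config$pattern_weights %*% config$pattern_mixtures)
  gross <- sum(arch_freq * per_arch)
  # expected sedentary minutes lost to injected non-wear bouts
  mean_frac_sed <- sum(arch_freq * rowMeans(arch)) / 60
  bout_dur <- 90 + (config$nonwear_bout_mean_minutes - 90)
  loss <- config$nonwear_bout_rate * bout_dur * mean_frac_sed
  gross - loss
}

#' Validate a generator configuration
#' @param config an `sb_generator_config`.
#' @return The config, invisibly; stops with a configuration error otherwise.
#' @export
validate_config <- function(config) {
  stopifnot(is.list(config))
  if (!is.numeric(config$n_participants) || config$n_participants < 1)
    stop("configuration error: n_participants must be a positive integer")
  if (config$epoch_seconds != 15L)
    stop("configuration error: epoch_seconds must be 15")
  arch <- config$day_archetypes
  if (!is.matrix(arch) || ncol(arch) != 14L)
    stop("configuration error: day_archetypes must be an n x 14 matrix")
  if (any(arch < 0 | arch > 60))
    stop("configuration error: archetype curves must lie in [0, 60]")
  mix <- config$pattern_mixtures
  if (!is.matrix(mix) || ncol(mix) != nrow(arch))
    stop("configuration error: each pattern mixture must have one entry per archetype")
  if (any(abs(rowSums(mix) - 1) > 1e-9))
    stop("configuration error: pattern mixtures must sum to 1")
  w <- config$pattern_weights
  if (length(w) != nrow(mix) || abs(sum(w) - 1) > 1e-9)
    stop("configuration error: pattern_weights must sum to 1 with one weight per pattern")
  pf <- config$pf_model
  if (any(pf$baseline_by_stratum < 0 | pf$baseline_by_stratum > 100))
    stop("configuration error: PF baselines must lie in [0, 100]")
  if (pf$random_intercept_sd < 0 || pf$residual_sd < 0 ||
      config$archetype_noise_sd < 0)
    stop("configuration error: SDs must be non-negative")
  if (ncol(pf$baseline_by_stratum) != nrow(mix) ||
      ncol(pf$slope_by_stratum) != nrow(mix))
    stop("configuration error: PF truth must have one column per pattern")
  invisible(config)
}

#' Generate a synthetic cohort
#'
#' Draws, for each participant, a diurnal pattern; for each day, a day
#' archetype from the pattern's mixture plus wake and in-bed clock times;
#' allocates sedentary/light/MVPA minutes per waking hour around the archetype
#' curve; expands to 15-s epochs with counts in the appropriate cutpoint band
#' (sedentary 0–18, light 19–519, MVPA 520–5000; near-zero overnight); injects
#' all-zero non-wear bouts; blanks sleep-log fields at the configured rates;
#' and draws the PF panel from the configured random-intercept model.
#'
#' @param config an `sb_generator_config`, e.g. [default_config()].
#' @param include_epochs generate the epoch-level streams (default TRUE).
#'   With FALSE only the hour-level truth, sleep logs, covariates and PF
#'   panel are produced — sufficient (and much faster) for studying the
#'   outcome-model stage in isolation.
#' @return A list of class `sb_cohort`:
#'   `epochs` (data.table: participant_id, time, vm_counts),
#'   `sleep_log` (participant_id, date, in_bed, out_of_bed; "HH:MM" or NA),
#'   `covariates`, `pf_panel` (participant_id, t_year, pf),
#'   `truth` (day_type_by_day, pattern_by_participant, mvpa_by_participant,
#'   wake/bed truth, pf_params).
#' @export
generate_cohort <- function(config = default_config(), include_epochs = TRUE) {
  validate_config(config)
  set.seed(substream_seed(config$seed, "generator"))
  n <- config$n_participants
  D <- config$n_days
  arch <- config$day_archetypes
  n_arch <- nrow(arch)
  n_pat <- nrow(config$pattern_mixtures)

  ## participant-level draws -------------------------------------------------
  pattern <- sample.int(n_pat, n, replace = TRUE, prob = config$pattern_weights)
  mv <- config$mvpa_minutes_by_pattern
  mvpa_i <- pmax(0, rnorm(n, mv[pattern, "mean"], mv[pattern, "sd"]))

  wk <- config$wake_time_distribution
  sl <- config$sleep_time_distribution
  wake_person <- rnorm(n, wk[["mean"]], wk[["sd"]] * 0.7)
  bed_person <- rnorm(n, sl[["mean"]], sl[["sd"]] * 0.7)

  ## day-level draws ---------------------------------------------------------
  days <- data.table::CJ(participant_id = seq_len(n), day = seq_len(D))
  days[, archetype := {
    p <- pattern[participant_id]
    vapply(p, function(pp) sample.int(n_arch, 1L, prob = config$pattern_mixtures[pp, ]),
           1L)
  }]
  days[, wake_min := round(pmin(600, pmax(300,
    rnorm(.N, wake_person[participant_id], wk[["sd"]] * 0.7))))]
  days[, bed_min := round(pmin(1425, pmax(1230,
    rnorm(.N, bed_person[participant_id], sl[["sd"]] * 0.7))))]

  ## waking-hour allocation --------------------------------------------------
  days[, n_hours := ceiling((bed_min - wake_min) / 60)]
  hours <- days[rep(seq_len(.N), n_hours)]
  hours[, hour_from_wake := seq_len(.N), by = .(participant_id, day)]
  hours[, cap := pmin(60, bed_min - (wake_min + (hour_from_wake - 1L) * 60L))]
  hours[, curve := arch[cbind(archetype, pmin(hour_from_wake, 14L))]]
  hours[, sed := pmin(cap, pmax(0L, as.integer(round(
    rnorm(.N, curve, config$archetype_noise_sd) * cap / 60))))]

  ## MVPA: greedy allocation into early waking hours, capped per hour
  day_mvpa <- pmax(0, round(rnorm(nrow(days), mvpa_i[days$participant_id],
                                  config$mvpa_day_sd)))
  days[, mvpa_target := day_mvpa]
  hours[days, mvpa_target := i.mvpa_target, on = .(participant_id, day)]
  hours[, room := pmin(cap - sed, config$mvpa_hour_cap)]
  hours[, mvpa := {
    r <- pmax(0L, room)
    alloc <- pmin(r, pmax(0, mvpa_target[1L] - data.table::shift(cumsum(r), fill = 0)))
    as.integer(pmax(0L, alloc))
  }, by = .(participant_id, day)]
  hours[, light := cap - sed - mvpa]

  ## expand to 15-s epochs ---------------------------------------------------
  epochs <- NULL
  bouts <- days[0L][, `:=`(start_min = integer(), dur_min = integer())]
  if (include_epochs) {
  n_ep <- with(hours, as.integer(cap) * 4L)
  row_id <- rep(seq_len(nrow(hours)), n_ep)
  cls <- rep(rep(c(0L, 2L, 1L), nrow(hours)),
             as.vector(t(cbind(hours$sed, hours$mvpa, hours$light))) * 4L)
  # shuffle epoch classes within each hour block
  cls <- cls[order(row_id, runif(length(cls)))]
  ep_off <- (sequence(n_ep) - 1L) * 15L
  sec_of_day <- hours$wake_min[row_id] * 60L +
    (hours$hour_from_wake[row_id] - 1L) * 3600L + ep_off
  day_idx <- hours$day[row_id]
  pid_w <- hours$participant_id[row_id]
  u <- runif(length(cls))
  counts_w <- ifelse(cls == 0L, floor(u * 19),
              ifelse(cls == 1L, 19 + floor(u * 501), 520 + floor(u * 4481)))

  ## full epoch grid with near-zero overnight counts -------------------------
  total_ep <- n * D * EPOCHS_PER_DAY
  vm <- integer(total_ep)
  u2 <- runif(total_ep)
  night_spike <- u2 > 0.9
  vm[night_spike] <- as.integer(ceiling((u2[night_spike] - 0.9) * 180)) # 1..18
  gi <- (pid_w - 1L) * D * EPOCHS_PER_DAY + (day_idx - 1L) * EPOCHS_PER_DAY +
    sec_of_day %/% 15L + 1L
  vm[gi] <- as.integer(counts_w)

  ## non-wear bouts: whole-minute all-zero runs >= 90 min in waking hours ----
  nb <- rpois(nrow(days), config$nonwear_bout_rate)
  if (sum(nb)) {
    bouts <- days[rep(seq_len(.N), nb)]
    span <- bouts$bed_min - bouts$wake_min
    dur <- pmin(span - 60L,
                90L + as.integer(round(rexp(nrow(bouts),
                  1 / (config$nonwear_bout_mean_minutes - 90)))))
    dur <- pmax(90L, dur)
    start <- bouts$wake_min + as.integer(floor(runif(nrow(bouts)) * (span - dur)))
    bouts[, `:=`(start_min = start, dur_min = dur)]
    b_ep <- rep(seq_len(nrow(bouts)), bouts$dur_min * 4L)
    off <- (sequence(bouts$dur_min * 4L) - 1L) * 15L
    gi_b <- (bouts$participant_id[b_ep] - 1L) * D * EPOCHS_PER_DAY +
      (bouts$day[b_ep] - 1L) * EPOCHS_PER_DAY +
      (bouts$start_min[b_ep] * 60L + off) %/% 15L + 1L
    vm[gi_b] <- 0L
  }

  epochs <- data.table::data.table(
    participant_id = rep(seq_len(n), each = D * EPOCHS_PER_DAY),
    time = STUDY_ORIGIN + (rep(seq_len(D * EPOCHS_PER_DAY), n) - 1L) * 15,
    vm_counts = vm
  )
  data.table::setattr(epochs$time, "tzone", "UTC")
  }  # include_epochs

  ## sleep logs --------------------------------------------------------------
  log <- days[, .(participant_id, day,
                  date = as.Date("2012-01-02") + day - 1L,
                  in_bed = format_clock(bed_min),
                  out_of_bed = format_clock(wake_min))]
  full_missing <- runif(n) < config$full_sleeplog_missing_rate
  miss_in <- runif(nrow(log)) < config$sleeplog_missing_rate |
    full_missing[log$participant_id]
  miss_out <- runif(nrow(log)) < config$sleeplog_missing_rate |
    full_missing[log$participant_id]
  log[miss_in, in_bed := NA_character_]
  log[miss_out, out_of_bed := NA_character_]
  sleep_log <- log[, .(participant_id, date, in_bed, out_of_bed)]

  ## covariates --------------------------------------------------------------
  covariates <- data.table::data.table(
    participant_id = seq_len(n),
    age = round(pmin(99, pmax(63, rnorm(n, 79, 7))), 1),
    race_ethnicity = sample(c("White", "Black", "Hispanic"), n, TRUE,
                            prob = c(0.496, 0.336, 0.168)),
    bmi = round(pmax(16, rnorm(n, 28.1, 5.7)), 1),
    education = sample(c("hs_or_less", "some_college", "college_grad"), n, TRUE,
                       prob = c(0.204, 0.384, 0.412)),
    smoker = runif(n) < 0.026,
    alcohol = sample(c("none", "lt1_wk", "ge1_wk", "unknown"), n, TRUE,
                     prob = c(0.337, 0.312, 0.258, 0.093)),
    morbidity_count = sample(c("0", "1", "2", "3+"), n, TRUE,
                             prob = c(0.175, 0.340, 0.268, 0.217)),
    self_rated_health = sample(c("excellent_vg", "good", "fair_poor"), n, TRUE,
                               prob = c(0.516, 0.376, 0.108)),
    mvpa_min = round(mvpa_i, 2)
  )
  sed_by_day <- hours[, .(sed_day = sum(sed)), by = .(participant_id, day)]
  covariates[sed_by_day[, .(total_sedentary_min = round(mean(sed_day), 1)),
                        by = participant_id],
             total_sedentary_min := i.total_sedentary_min, on = "participant_id"]

  ## PF panel ----------------------------------------------------------------
  pf <- config$pf_model
  stratum <- ifelse(mvpa_i > config$mvpa_split_truth, "high", "low")
  cov_eff <- pf_covariate_effect(covariates, pf$covariate_effects)
  b_i <- rnorm(n, 0, pf$random_intercept_sd)
  panel <- data.table::CJ(participant_id = seq_len(n),
                          t_year = 0:(pf$n_years - 1L))
  idx <- cbind(match(stratum, rownames(pf$baseline_by_stratum)), pattern)
  base_i <- pf$baseline_by_stratum[idx]
  slope_i <- pf$slope_by_stratum[idx]
  panel[, pf := base_i[participant_id] + slope_i[participant_id] * t_year +
          cov_eff[participant_id] + b_i[participant_id] +
          rnorm(.N, 0, pf$residual_sd)]
  panel[, pf := pmin(100, pmax(0, pf))]

  truth <- list(
    day_type_by_day = days[, .(participant_id, day,
                               date = as.Date("2012-01-02") + day - 1L,
                               archetype, wake_min, bed_min)],
    pattern_by_participant = data.table::data.table(
      participant_id = seq_len(n), pattern = pattern, mvpa_stratum = stratum),
    mvpa_by_participant = data.table::data.table(
      participant_id = seq_len(n), mvpa_min = mvpa_i),
    nonwear_bouts = bouts[, .(participant_id, day, start_min, dur_min)],
    pf_params = pf,
    random_intercepts = b_i,
    covariate_effect = cov_eff
  )
  structure(list(epochs = epochs, sleep_log = sleep_log,
                 covariates = covariates, pf_panel = panel, truth = truth,
                 config = config),
            class = "sb_cohort")
}

#' Deterministic covariate contribution to the PF linear predictor
#' @keywords internal
pf_covariate_effect <- function(covariates, eff) {
  with(covariates,
    eff$age_per_year * (age - 79) +
    eff$bmi_per_unit * (bmi - 28.1) +
    eff$smoker * smoker +
    eff$education[education] +
    eff$alcohol[alcohol] +
    eff$morbidity[morbidity_count] +
    eff$self_rated_health[self_rated_health] +
    eff$race_ethnicity[race_ethnicity])
}

#' Write a synthetic cohort to plain-text files
#'
#' Epochs as long-format CSV (participant_id, ISO-8601 timestamp, vm_counts),
#' sleep log / covariates / PF panel as CSV, ground truth as JSON.
#'
#' @param cohort an `sb_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ep <- data.table::copy(cohort$epochs)
  ep[, time := format(time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")]
  data.table::fwrite(ep, file.path(dir, "epochs.csv"))
  data.table::fwrite(cohort$sleep_log, file.path(dir, "sleep_log.csv"))
  data.table::fwrite(cohort$covariates, file.path(dir, "covariates.csv"))
  data.table::fwrite(cohort$pf_panel, file.path(dir, "pf_panel.csv"))
  tr <- cohort$truth
  jsonlite::write_json(
    list(day_type_by_day = tr$day_type_by_day,
         pattern_by_participant = tr$pattern_by_participant,
         pf_params = tr$pf_params),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read an epoch stream written by [write_cohort()]
#' @param path CSV path.
#' @return data.table (participant_id, time POSIXct UTC, vm_counts).
#' @export
read_epochs <- function(path) {
  ep <- data.table::fread(path)
  ep[, time := as.POSIXct(time, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")]
  ep[]
}
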