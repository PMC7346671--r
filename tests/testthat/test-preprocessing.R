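# Preprocessing: minute aggregation, Choi non-wear, bed-time resolution,
# cutpoint classification and the adherence filter.

test_that("minute aggregation sums epochs and drops partial minutes", {
  ep <- make_epochs(c(10, 10, 10, 10))
  out <- aggregate_minutes(ep)
  expect_equal(nrow(out), 1L)
  expect_equal(out$counts, 40)

  expect_equal(aggregate_minutes(make_epochs(rep(0, 40)))$counts, rep(0, 10))

  # trailing partial minute dropped
  out <- aggregate_minutes(make_epochs(rep(1, 10)))
  expect_equal(nrow(out), 2L)

  expect_error(aggregate_minutes(rbind(ep, ep[1])), "duplicate")
})

test_that("minute aggregation matches a brute-force per-minute groupby", {
  set.seed(11)
  counts <- rpois(5760, 40)
  ep <- make_epochs(counts)
  out <- aggregate_minutes(ep)
  oracle <- tapply(counts, rep(seq_len(1440), each = 4L), sum)
  expect_equal(out$counts, unname(as.vector(oracle)))
})

test_that("Choi detects hand-traced non-wear windows", {
  # 89 zeros bounded by activity: below the 90-min window, all wear
  mm <- make_minutes(c(50, rep(0, 89), 50))
  expect_true(all(choi_nonwear(mm)$wear))

  # 200 zeros with a 1-min spike flanked by >= 30 zeros each side:
  # the whole window including the spike is non-wear
  mm <- make_minutes(c(50, rep(0, 100), 7, rep(0, 100), 50))
  w <- choi_nonwear(mm)$wear
  expect_equal(which(!w), 2:202)

  # 3-min interruption exceeds the 2-min tolerance: run is broken and each
  # side evaluated separately (both >= 90 here -> non-wear; spike is wear)
  mm <- make_minutes(c(50, rep(0, 100), 7, 7, 7, rep(0, 100), 50))
  w <- choi_nonwear(mm)$wear
  expect_false(any(w[2:101]))
  expect_true(all(w[102:104]))
  expect_false(any(w[105:204]))

  # 3-min interruption with one short side: short side is wear
  mm <- make_minutes(c(50, rep(0, 89), 7, 7, 7, rep(0, 100), 50))
  w <- choi_nonwear(mm)$wear
  expect_true(all(w[1:93]))
  expect_false(any(w[94:193]))

  # 1-min spike with a flank below the 30-min stream frame breaks the run
  mm <- make_minutes(c(50, rep(0, 100), 7, rep(0, 20), 50, rep(0, 100), 50))
  w <- choi_nonwear(mm)$wear
  expect_false(any(w[2:101]))   # long side alone still >= 90
  expect_true(all(w[102:123]))  # spike + short zero side are wear

  expect_error(choi_nonwear(make_minutes(numeric(0))), "empty")
})

test_that("Choi is idempotent and invariant to prepending a fully worn day", {
  set.seed(21)
  base <- c(sample(30:100, 300, TRUE), rep(0, 120), sample(30:100, 200, TRUE))
  mm <- make_minutes(base)
  w1 <- choi_nonwear(mm)$wear
  # zeroing already-zero non-wear minutes changes nothing
  base2 <- base; base2[!w1] <- 0
  expect_identical(choi_nonwear(make_minutes(base2))$wear, w1)
  # prepending 1440 active minutes leaves the original segment's mask alone
  w2 <- choi_nonwear(make_minutes(c(sample(30:100, 1440, TRUE), base)))$wear
  expect_identical(w2[-(1:1440)], w1)
})

test_that("injected non-wear bouts are fully recovered on synthetic data", {
  coh <- cached_default_run()$cohort
  run <- cached_default_run()$run
  bouts <- coh$truth$nonwear_bouts
  skip_if(nrow(bouts) == 0L)
  wear <- run$wear
  mins <- run$minutes
  # every injected bout minute is flagged non-wear (recall 1.0)
  bout_minutes <- bouts[, .(
    minute = origin_utc + ((day - 1L) * 1440L + start_min + 0:(dur_min - 1L)) * 60
  ), by = .(participant_id, b = seq_len(nrow(bouts)))]
  hit <- wear[bout_minutes, on = c("participant_id", "minute")]
  expect_true(all(!hit$wear))
  # non-wear is only ever declared on genuinely zero minutes
  nw <- wear[mins, on = c("participant_id", "minute")][wear == FALSE]
  expect_true(all(nw$counts == 0))
})

test_that("bed-time resolution imputes person means, population constants, and handles midnight wrap", {
  lg <- data.table::data.table(
    participant_id = c(1L, 1L, 1L, 2L, 2L, 3L, 3L),
    date = as.Date("2012-01-02") + c(0:2, 0:1, 0:1),
    in_bed = c("22:00", "23:00", NA, NA, NA, "23:30", "00:30"),
    out_of_bed = c("07:00", "07:30", "07:15", NA, NA, "06:00", "08:00")
  )
  out <- resolve_bed_times(lg)
  expect_equal(out[out$participant_id == 1L][3]$in_bed, "22:30")
  # all-missing participant: population constants
  expect_equal(unique(out[out$participant_id == 2L]$in_bed), "22:45")
  expect_equal(unique(out[out$participant_id == 2L]$out_of_bed), "07:22")
  # circular mean across midnight: 23:30 and 00:30 average to 00:00, not noon
  lg2 <- data.table::data.table(participant_id = 3L,
                                date = as.Date("2012-01-02") + 0:2,
                                in_bed = c("23:30", "00:30", NA),
                                out_of_bed = c("07:00", "07:00", "07:00"))
  expect_equal(resolve_bed_times(lg2)[3]$in_bed, "00:00")
  # nothing missing: identity
  lg3 <- lg[1:2]
  out3 <- resolve_bed_times(lg3)
  expect_equal(out3$in_bed, lg3$in_bed)
  expect_equal(out3$out_of_bed, lg3$out_of_bed)
})

test_that("cutpoint classification respects the 18 and 519 count boundaries", {
  # one full day, fully worn, awake from 06:00 to 23:00
  codes <- rep("light", 1440)
  ep <- make_epochs(minutes_to_epochs(codes))
  # place boundary epochs at noon
  i <- 12 * 240 + 1
  ep$vm_counts[i + 0:3] <- c(18L, 19L, 519L, 520L)
  bt <- data.table::data.table(participant_id = 1L, date = as.Date("2012-01-02"),
                               in_bed = "23:00", out_of_bed = "06:00")
  cl <- classify_epochs(ep, choi_nonwear(aggregate_minutes(ep)), bt)
  got <- cl$epochs[i + 0:3]$epoch_class
  expect_equal(got, c("sedentary", "light", "light", "mvpa"))
})

test_that("per-day class minutes partition the calendar day", {
  cl <- cached_default_run()$run$classified
  days <- cl$days
  total <- days$sedentary_min + days$light_min + days$mvpa_min +
    days$nonwear_min + days$inbed_min
  expect_equal(total * 4, as.numeric(days$n_epochs))
  expect_equal(days$awake_wear_min,
               days$sedentary_min + days$light_min + days$mvpa_min)
  expect_equal(days$adherent, days$awake_wear_min >= 600)
})

test_that("the adherence filter keeps >=4 adherent days and summarises exposures", {
  days <- data.table::data.table(
    participant_id = rep(1:3, times = c(5, 3, 4)),
    date = as.Date("2012-01-02") + c(0:4, 0:2, 0:3),
    sedentary_min = 500, light_min = 80, mvpa_min = 20,
    nonwear_min = 0, inbed_min = 840, n_epochs = 5760L,
    awake_wear_min = 600,
    adherent = c(TRUE, TRUE, TRUE, TRUE, FALSE,  # p1: 4 adherent
                 TRUE, TRUE, TRUE,               # p2: 3 adherent -> excluded
                 TRUE, TRUE, TRUE, TRUE)         # p3: exactly 4 -> included
  )
  out <- filter_cohort(days)
  expect_setequal(out$participants$participant_id, c(1L, 3L))
  expect_equal(out$attrition$input_participants, 3L)
  expect_equal(out$attrition$retained_participants, 2L)
  expect_equal(out$participants$total_sedentary_min, c(500, 500))
  # cohort where every participant has >= 4 days, all adherent:
  # participant count unchanged
  days2 <- data.table::copy(days)[participant_id != 2L][, adherent := TRUE]
  expect_equal(filter_cohort(days2)$attrition$retained_participants, 2L)
  expect_equal(filter_cohort(days2)$attrition$input_participants, 2L)
})
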