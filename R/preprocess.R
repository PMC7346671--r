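# Preprocessing: epoch streams + sleep logs -> classified, wear-masked,
# adherence-filtered days.

#' Aggregate 15-s epochs to minute-level counts
#'
#' @param epochs data.table with columns participant_id, time (POSIXct on a
#'   15-s grid), vm_counts. Duplicate timestamps within a participant are an
#'   input error.
#' @return data.table (participant_id, minute POSIXct, counts) where each
#'   minute's count is the sum of its 4 epochs; partial trailing minutes
#'   (fewer than 4 epochs) are dropped.
#' @export
aggregate_minutes <- function(epochs) {
  stopifnot(all(c("participant_id", "time", "vm_counts") %in% names(epochs)))
  ep <- data.table::as.data.table(epochs)
  if (anyDuplicated(ep, by = c("participant_id", "time")))
    stop("input error: duplicate epoch timestamps")
  ep[, minute := as.POSIXct(floor(as.numeric(time) / 60) * 60,
                            origin = "1970-01-01", tz = "UTC")]
  out <- ep[, .(counts = sum(vm_counts), n_ep = .N),
            by = .(participant_id, minute)]
  out <- out[n_ep == 4L][, n_ep := NULL]
  data.table::setkey(out, participant_id, minute)
  out[]
}

#' Choi non-wear detection on minute-level counts
#'
#' Implements the Choi algorithm with a 90-minute window, 30-minute stream
#' frame and 2-minute tolerance: a minute is non-wear iff it belongs to an
#' interval of consecutive zero-count minutes of total length >= 90, inside
#' which interruptions of at most 2 consecutive non-zero minutes are tolerated
#' provided each interruption is flanked on both sides by >= 30 consecutive
#' zero-count minutes. Tolerated interruption minutes are themselves marked
#' non-wear; interruptions at the boundary of a run are not tolerated.
#'
#' @param minutes data.table (participant_id, minute, counts), contiguous per
#'   participant.
#' @return data.table (participant_id, minute, wear logical) of class
#'   `sb_wear_mask`.
#' @export
choi_nonwear <- function(minutes) {
  if (nrow(minutes) == 0L) stop("input error: empty minute series")
  mm <- data.table::as.data.table(minutes)
  mm[, wear := choi_wear_vector(counts), by = participant_id]
  out <- mm[, .(participant_id, minute, wear)]
  data.table::setattr(out, "class", c("sb_wear_mask", class(out)))
  out[]
}

#' Choi rule on a single contiguous minute-count vector
#' @param x numeric minute counts.
#' @return logical vector, TRUE = wear.
#' @keywords internal
choi_wear_vector <- function(x) {
  n <- length(x)
  wear <- rep(TRUE, n)
  r <- rle(x == 0)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  nz <- length(r$lengths)
  i <- 1L
  while (i <= nz) {
    if (!r$values[i]) { i <- i + 1L; next }
    # grow a candidate window from zero-run i, absorbing tolerated
    # interruptions (<= 2 non-zero minutes flanked by >= 30 zeros both sides)
    j <- i
    while (j + 2L <= nz && !r$values[j + 1L] && r$lengths[j + 1L] <= 2L &&
           r$values[j + 2L] &&
           r$lengths[j] >= 30L && r$lengths[j + 2L] >= 30L) {
      j <- j + 2L
    }
    win_len <- ends[j] - starts[i] + 1L
    if (win_len >= 90L) wear[starts[i]:ends[j]] <- FALSE
    i <- j + 1L
  }
  wear
}

#' Resolve missing sleep-log bed times
#'
#' Missing in-bed or out-of-bed entries are filled with the participant's
#' circular mean of that field over available days; participants missing a
#' field on all days receive the population constants 22:45 (in-bed) and
#' 07:22 (out-of-bed).
#'
#' @param sleep_log data.table (participant_id, date, in_bed, out_of_bed;
#'   "HH:MM" strings, NA/blank allowed).
#' @return data.table with completed `in_bed`/`out_of_bed` plus logical
#'   `in_bed_imputed`/`out_of_bed_imputed` columns.
#' @export
resolve_bed_times <- function(sleep_log) {
  lg <- data.table::as.data.table(sleep_log)
  lg[, `:=`(in_bed_min = parse_clock(in_bed),
            out_of_bed_min = parse_clock(out_of_bed))]
  lg[, `:=`(in_bed_imputed = is.na(in_bed_min),
            out_of_bed_imputed = is.na(out_of_bed_min))]
  fill_field <- function(v, fallback) {
    m <- circular_mean_clock(v)
    if (is.na(m)) m <- fallback
    ifelse(is.na(v), round(m), v)
  }
  lg[, in_bed_min := fill_field(in_bed_min, 22 * 60 + 45), by = participant_id]
  lg[, out_of_bed_min := fill_field(out_of_bed_min, 7 * 60 + 22),
     by = participant_id]
  lg[, `:=`(in_bed = format_clock(in_bed_min),
            out_of_bed = format_clock(out_of_bed_min))]
  lg[, .(participant_id, date, in_bed, out_of_bed,
         in_bed_imputed, out_of_bed_imputed)]
}

#' Classify epochs and summarise calendar days
#'
#' Per-epoch class with priority in-bed > non-wear > intensity: an epoch in
#' the in-bed window (from the evening in-bed time to the next morning's
#' out-of-bed time) is `inbed`; otherwise a non-wear minute makes it
#' `nonwear`; otherwise `sedentary` iff vm_counts <= 18, `mvpa` iff
#' vm_counts > 519, else `light`. Days are calendar days (midnight to
#' midnight); an adherent day has >= 600 minutes of awake wear.
#'
#' @param epochs data.table (participant_id, time, vm_counts).
#' @param wear an `sb_wear_mask` from [choi_nonwear()] covering the epochs.
#' @param bedtimes resolved sleep log from [resolve_bed_times()].
#' @return list of class `sb_classified`: `epochs` (adds date, epoch_class)
#'   and `days` (per participant-date totals in minutes plus `adherent`).
#' @export
classify_epochs <- function(epochs, wear, bedtimes) {
  ep <- data.table::as.data.table(epochs)
  ep[, minute := as.POSIXct(floor(as.numeric(time) / 60) * 60,
                            origin = "1970-01-01", tz = "UTC")]
  ep[wear, wear := i.wear, on = c("participant_id", "minute")]
  if (anyNA(ep$wear))
    stop("input error: epochs outside wear-mask coverage")
  ep[, date := as.Date(time, tz = "UTC")]
  ep[, tod_min := (as.numeric(time) %% 86400) / 60]

  bt <- data.table::as.data.table(bedtimes)
  bt[, `:=`(in_bed_min = parse_clock(in_bed),
            out_of_bed_min = parse_clock(out_of_bed))]
  ep[bt, `:=`(in_bed_min = i.in_bed_min, out_of_bed_min = i.out_of_bed_min),
     on = c("participant_id", "date")]
  # days without a sleep-log row: population constants
  ep[is.na(in_bed_min), in_bed_min := 22 * 60 + 45]
  ep[is.na(out_of_bed_min), out_of_bed_min := 7 * 60 + 22]
  # in-bed: before this morning's out-of-bed, or after this evening's in-bed
  # (in-bed times before noon are read as spilling past midnight, i.e. the
  # evening window starts the next calendar day)
  ep[, inbed := tod_min < out_of_bed_min |
       (in_bed_min >= 720 & tod_min >= in_bed_min)]

  ep[, epoch_class := data.table::fifelse(inbed, "inbed",
       data.table::fifelse(!wear, "nonwear",
         data.table::fifelse(vm_counts <= SEDENTARY_CUTPOINT, "sedentary",
           data.table::fifelse(vm_counts > MVPA_CUTPOINT, "mvpa", "light"))))]

  days <- ep[, .(
    sedentary_min = sum(epoch_class == "sedentary") / 4,
    light_min = sum(epoch_class == "light") / 4,
    mvpa_min = sum(epoch_class == "mvpa") / 4,
    nonwear_min = sum(epoch_class == "nonwear") / 4,
    inbed_min = sum(epoch_class == "inbed") / 4,
    n_epochs = .N
  ), by = .(participant_id, date)]
  days[, awake_wear_min := sedentary_min + light_min + mvpa_min]
  days[, adherent := awake_wear_min >= 600]
  ep[, c("minute", "tod_min", "in_bed_min", "out_of_bed_min", "inbed",
         "wear") := NULL]
  structure(list(epochs = ep, days = days[]), class = "sb_classified")
}

#' Apply the adherence filter
#'
#' Retains adherent days (>= 600 min awake wear) and then participants with
#' at least `min_days` adherent days; summarises per-participant mean daily
#' sedentary and MVPA minutes over retained days.
#'
#' @param days the `days` table from [classify_epochs()].
#' @param min_days minimum adherent days for inclusion (default 4).
#' @return list: `days` (retained), `participants` (participant_id,
#'   n_adherent_days, total_sedentary_min, mvpa_min), `attrition` (counts at
#'   each stage).
#' @export
filter_cohort <- function(days, min_days = 4L) {
  dd <- data.table::as.data.table(days)
  n0 <- list(participants = data.table::uniqueN(dd$participant_id),
             days = nrow(dd))
  dd <- dd[adherent == TRUE]
  keep <- dd[, .N, by = participant_id][N >= min_days, participant_id]
  dd <- dd[participant_id %in% keep]
  participants <- dd[, .(
    n_adherent_days = .N,
    total_sedentary_min = mean(sedentary_min),
    mvpa_min = mean(mvpa_min)
  ), by = participant_id]
  list(days = dd[], participants = participants[],
       attrition = list(
         input_participants = n0$participants, input_days = n0$days,
         adherent_days = nrow(dd),
         retained_participants = nrow(participants)))
}
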