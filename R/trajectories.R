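# Wake-aligned 14-hour sedentary-behavior trajectories per adherent day,
# with Copy-Mean imputation of missing hours.

#' Hourly sedentary minutes and awake-wear coverage per clock hour
#'
#' Sedentary minutes are summed per one-hour clock interval (6:00–6:59,
#' 7:00–7:59, ...); coverage is the awake-wear minutes (neither in-bed nor
#' non-wear) in the same interval.
#'
#' @param classified an `sb_classified` from [classify_epochs()], or its
#'   `epochs` table.
#' @return data.table (participant_id, date, hour 0–23, sb_min, coverage_min);
#'   hours with no epochs are present with zeros.
#' @export
hourly_sb <- function(classified) {
  ep <- if (inherits(classified, "sb_classified")) classified$epochs else classified
  ep <- data.table::as.data.table(ep)
  ep[, hour := (as.numeric(time) %% 86400) %/% 3600]
  hb <- ep[, .(
    sb_min = sum(epoch_class == "sedentary") / 4,
    coverage_min = sum(epoch_class %in% c("sedentary", "light", "mvpa")) / 4
  ), by = .(participant_id, date, hour)]
  ep[, hour := NULL]
  grid <- hb[, data.table::CJ(hour = 0:23), by = .(participant_id, date)]
  hb <- hb[grid, on = c("participant_id", "date", "hour")]
  hb[is.na(sb_min), `:=`(sb_min = 0, coverage_min = 0)]
  data.table::setkey(hb, participant_id, date, hour)
  hb[]
}

#' Extract 14-hour day trajectories
#'
#' For wake alignment, element 1 is the first clock-hour bin starting at or
#' after the day's (resolved) out-of-bed time with full 60-minute awake-wear
#' coverage; elements 2–14 are the next 13 clock-hour bins. For clock
#' alignment, the 14 bins start at `fixed_start_hour`. In either case a bin
#' with coverage below 60 minutes is marked missing; bins past midnight are
#' missing. Days with no fully covered bin, or with more than
#' `max_missing_frac` missing bins, are dropped with a logged reason.
#'
#' @param hourly output of [hourly_sb()].
#' @param bedtimes resolved sleep log from [resolve_bed_times()] (wake
#'   alignment only).
#' @param alignment "wake" or "clock".
#' @param fixed_start_hour first bin for clock alignment (default 8, i.e.
#'   8:00–21:59).
#' @param max_missing_frac drop days with more than this fraction of missing
#'   bins (default 0.5).
#' @return list of class `sb_trajectories`: `values` (n x 14 matrix, NA =
#'   missing), `observed` (logical matrix), `meta` (participant_id, date,
#'   start_hour, alignment), `dropped` (participant_id, date, reason).
#' @export
extract_trajectories <- function(hourly, bedtimes = NULL,
                                 alignment = c("wake", "clock"),
                                 fixed_start_hour = 8L,
                                 max_missing_frac = 0.5) {
  alignment <- match.arg(alignment)
  hb <- data.table::as.data.table(hourly)
  if (alignment == "wake") {
    if (is.null(bedtimes)) stop("wake alignment requires resolved bed times")
    bt <- data.table::as.data.table(bedtimes)
    bt[, wake_min := parse_clock(out_of_bed)]
    hb <- bt[, .(participant_id, date, wake_min)][hb,
            on = c("participant_id", "date")]
    hb[is.na(wake_min), wake_min := 7 * 60 + 22]
  }
  data.table::setkey(hb, participant_id, date, hour)

  one_day <- function(sb, cov, wake_min) {
    if (alignment == "wake") {
      start <- ceiling(wake_min[1] / 60)
      cand <- which(seq(0, 23) >= start & cov == 60)
      if (!length(cand))
        return(list(start_hour = NA_integer_,
                    values = rep(NA_real_, 14L)))
      h0 <- cand[1]  # 1-based index of hour h0-1
    } else {
      h0 <- fixed_start_hour + 1L
    }
    idx <- h0:(h0 + 13L)
    vals <- ifelse(idx <= 24L & cov[pmin(idx, 24L)] == 60,
                   sb[pmin(idx, 24L)], NA_real_)
    list(start_hour = h0 - 1L, values = vals)
  }
  res <- hb[, {
    r <- one_day(sb_min, coverage_min, wake_min = if (alignment == "wake")
      wake_min else 0)
    .(start_hour = r$start_hour, slot = 1:14, value = r$values)
  }, by = .(participant_id, date)]

  meta_all <- unique(res[, .(participant_id, date, start_hour)])
  vals <- matrix(res$value, ncol = 14L, byrow = TRUE)
  miss_frac <- rowMeans(is.na(vals))
  no_start <- is.na(meta_all$start_hour)
  drop <- no_start | miss_frac > max_missing_frac
  dropped <- meta_all[drop][, reason := data.table::fifelse(
    no_start[drop], "no fully covered waking hour", "too many missing hours")]
  meta <- meta_all[!drop]
  meta[, alignment := alignment]
  structure(list(values = vals[!drop, , drop = FALSE],
                 observed = !is.na(vals[!drop, , drop = FALSE]),
                 meta = meta[], dropped = dropped[]),
            class = "sb_trajectories")
}

#' Copy-Mean imputation of missing trajectory hours
#'
#' Interior gaps bounded by observed hours a < b are filled with linear
#' interpolation between the observations plus the population mean curve's
#' local deviation from its own chord: `imp(t) = lin_obs(t) + M(t) -
#' lin_M(t)`. Leading/trailing gaps copy the nearest observed value shifted
#' by the mean curve's difference: `imp(t) = x(a) + M(t) - M(a)`. Optional
#' mean-zero Gaussian jitter (default SD 0) can be added to imputed values.
#' Results are clipped to `[0, 60]`; observed values are never changed.
#'
#' @param traj an `sb_trajectories`.
#' @param jitter_sd SD (minutes) of seed-controlled Gaussian jitter added to
#'   imputed entries (default 0: canonical deterministic Copy Mean).
#' @param seed integer seed used when `jitter_sd > 0`.
#' @return The trajectories with `values` completed, plus
#'   `population_curve` (length-14 mean of observed values per slot).
#' @export
copy_mean_impute <- function(traj, jitter_sd = 0, seed = 1L) {
  stopifnot(inherits(traj, "sb_trajectories"))
  x <- traj$values
  if (any(rowSums(!is.na(x)) == 0L))
    stop("all-missing trajectory: should have been dropped upstream")
  M <- colMeans(x, na.rm = TRUE)
  if (anyNA(M))
    stop("population curve not computable at every hour")
  imputed <- t(apply(x, 1L, function(v) copy_mean_row(v, M)))
  if (jitter_sd > 0) {
    set.seed(substream_seed(seed, "copy-mean-jitter"))
    jit <- matrix(rnorm(length(x), 0, jitter_sd), nrow = nrow(x))
    imputed[is.na(x)] <- imputed[is.na(x)] + jit[is.na(x)]
  }
  imputed[imputed < 0] <- 0
  imputed[imputed > 60] <- 60
  imputed[!is.na(x)] <- x[!is.na(x)]
  out <- traj
  out$values <- imputed
  out$population_curve <- M
  out
}

#' Copy-Mean completion of a single row
#' @keywords internal
copy_mean_row <- function(v, M) {
  obs <- which(!is.na(v))
  if (length(obs) == length(v)) return(v)
  out <- v
  gaps <- which(is.na(v))
  for (t in gaps) {
    lo <- suppressWarnings(max(obs[obs < t]))
    hi <- suppressWarnings(min(obs[obs > t]))
    if (is.finite(lo) && is.finite(hi)) {
      w <- (t - lo) / (hi - lo)
      lin_obs <- v[lo] + w * (v[hi] - v[lo])
      lin_M <- M[lo] + w * (M[hi] - M[lo])
      out[t] <- lin_obs + M[t] - lin_M
    } else if (is.finite(lo)) {
      out[t] <- v[lo] + M[t] - M[lo]
    } else {
      out[t] <- v[hi] + M[t] - M[hi]
    }
  }
  out
}
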