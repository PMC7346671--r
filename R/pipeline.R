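# End-to-end orchestration: simulate -> preprocess -> trajectories ->
# cluster days -> cluster participants -> associate -> report.

#' Pipeline configuration
#'
#' @param generator an `sb_generator_config` (default [default_config()]);
#'   alternatively supply `cohort` directly to [run_sb_pipeline()].
#' @param alignments trajectory variants to run: subset of
#'   `c("wake", "clock")`; when both, the concordance analysis is included.
#' @param k_range Phase I candidate day-cluster counts.
#' @param K_range Phase II candidate pattern counts.
#' @param n_restarts k-means restarts per k.
#' @param include_sedentary adjust the association model for total sedentary
#'   time.
#' @param seed root seed; all stage substreams derive from it.
#' @return list of class `sb_pipeline_config`.
#' @export
sb_pipeline_config <- function(generator = default_config(),
                               alignments = "wake",
                               k_range = 2:6, K_range = 2:8,
                               n_restarts = 5L,
                               include_sedentary = FALSE,
                               seed = generator$seed) {
  cfg <- list(generator = generator, alignments = alignments,
              k_range = k_range, K_range = K_range,
              n_restarts = as.integer(n_restarts),
              include_sedentary = include_sedentary,
              seed = as.integer(seed))
  class(cfg) <- "sb_pipeline_config"
  validate_pipeline_config(cfg)
  cfg
}

#' @keywords internal
validate_pipeline_config <- function(cfg) {
  if (is.null(cfg$seed)) stop("validation error: seed is required")
  if (!length(cfg$k_range) || !length(cfg$K_range))
    stop("validation error: k_range and K_range must be non-empty")
  if (!all(cfg$alignments %in% c("wake", "clock")) || !length(cfg$alignments))
    stop("validation error: alignments must be 'wake' and/or 'clock'")
  validate_config(cfg$generator)
  invisible(cfg)
}

#' Run the full diurnal SB pattern pipeline
#'
#' Executes all stages in order on a synthetic (or supplied) cohort and
#' collects a run report: cohort counts at each filter stage, chosen k and K
#' with diagnostics, centroid curves, per-pattern day-cluster proportion
#' quartiles, the stratified estimate table and — when both alignment
#' variants run — day- and participant-level concordance. Identical config
#' and seed give identical reports.
#'
#' @param config an `sb_pipeline_config`.
#' @param cohort optional pre-generated `sb_cohort` (overrides the generator).
#' @return list of class `sb_run_report`.
#' @export
run_sb_pipeline <- function(config = sb_pipeline_config(), cohort = NULL) {
  validate_pipeline_config(config)
  if (is.null(cohort)) {
    gen_cfg <- config$generator
    gen_cfg$seed <- substream_seed(config$seed, "cohort")
    cohort <- generate_cohort(gen_cfg)
  }

  minutes <- aggregate_minutes(cohort$epochs)
  wear <- choi_nonwear(minutes)
  bedtimes <- resolve_bed_times(cohort$sleep_log)
  classified <- classify_epochs(cohort$epochs, wear, bedtimes)
  filtered <- filter_cohort(classified$days)
  hourly <- hourly_sb(classified)
  # restrict trajectory building to retained adherent days
  hourly <- hourly[filtered$days[, .(participant_id, date)],
                   on = c("participant_id", "date")]

  variants <- list()
  for (al in config$alignments) {
    traj <- extract_trajectories(hourly, bedtimes, alignment = al)
    traj <- copy_mean_impute(traj, seed = substream_seed(config$seed, "impute"))
    sel <- select_k_phase1(traj, k_range = config$k_range,
                           n_restarts = config$n_restarts,
                           seed = substream_seed(config$seed, paste0("kml-", al)))
    profiles <- profiles_from_assignments(sel$model)
    pat <- hier_cluster(profiles, K_range = config$K_range)
    variants[[al]] <- list(trajectories = traj, selection = sel,
                           profiles = profiles, patterns = pat)
  }
  primary <- variants[[config$alignments[1L]]]

  pat_dt <- data.table::data.table(
    participant_id = primary$patterns$participant_id,
    pattern = primary$patterns$pattern)
  cv <- data.table::as.data.table(cohort$covariates)
  # accelerometer-derived exposure summaries from the pipeline itself
  cv[filtered$participants, `:=`(total_sedentary_min = i.total_sedentary_min,
                                 mvpa_min = i.mvpa_min), on = "participant_id"]
  fit_full <- fit_pf_model(cohort$pf_panel, pat_dt, cv,
                           include_sedentary = config$include_sedentary,
                           mvpa = "three_way")
  fit_reduced <- fit_pf_model(cohort$pf_panel, pat_dt, cv,
                              include_sedentary = config$include_sedentary,
                              mvpa = "two_way")
  lrt <- lrt_effect_modification(fit_full, fit_reduced)
  strat <- stratified_estimates(fit_full)

  conc <- NULL
  if (all(c("wake", "clock") %in% names(variants))) {
    mk_days <- function(v) data.table::data.table(
      participant_id = v$selection$model$meta$participant_id,
      date = v$selection$model$meta$date,
      cluster = v$selection$model$cluster)
    mk_pat <- function(v) data.table::data.table(
      participant_id = v$patterns$participant_id, pattern = v$patterns$pattern)
    conc <- concordance(mk_days(variants$wake), mk_days(variants$clock),
                        mk_pat(variants$wake), mk_pat(variants$clock))
  }

  prop_summary <- proportion_quartiles(primary$profiles, primary$patterns)

  report <- list(
    attrition = filtered$attrition,
    n_trajectory_days = nrow(primary$trajectories$values),
    chosen_k = primary$selection$k,
    phase1_diagnostics = primary$selection$diagnostics,
    centroids = primary$selection$model$centroids,
    chosen_K = primary$patterns$K,
    silhouette_by_K = primary$patterns$silhouette_by_K,
    pattern_sizes = table(primary$patterns$pattern),
    proportion_summary = prop_summary,
    mvpa_split_value = strat$mvpa_split_value,
    lrt = lrt,
    stratified = strat,
    concordance = conc,
    variants = variants,
    fits = list(full = fit_full, reduced = fit_reduced),
    cohort = cohort,
    config = config
  )
  class(report) <- "sb_run_report"
  report
}

#' Median and quartiles of day-cluster proportions within each pattern
#' @param profiles an `sb_profiles`.
#' @param patterns an `sb_patterns` over the same participants.
#' @return data.table (pattern, day_cluster, q25, median, q75).
#' @export
proportion_quartiles <- function(profiles, patterns) {
  P <- profiles$proportions
  lab <- patterns$pattern
  out <- list()
  for (p in sort(unique(lab))) {
    sub <- P[lab == p, , drop = FALSE]
    for (j in seq_len(ncol(P))) {
      q <- quantile(sub[, j], c(0.25, 0.5, 0.75))
      out[[length(out) + 1L]] <- data.table::data.table(
        pattern = p, day_cluster = LETTERS[j],
        q25 = q[[1L]], median = q[[2L]], q75 = q[[3L]])
    }
  }
  data.table::rbindlist(out)
}

#' Persist a run's intermediate artifacts as plain-text files
#'
#' Writes the classified day summaries and day-cluster assignments as CSV,
#' the wear mask as run-length-encoded intervals (participant_id, start, end,
#' state), the trajectory matrix as wide CSV (h01..h14 values, m01..m14
#' observed mask), cluster model artifacts (centroids, labels, diagnostics,
#' silhouettes) as JSON, and the stratified estimate table as CSV.
#'
#' @param report an `sb_run_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_artifacts <- function(report, dir) {
  stopifnot(inherits(report, "sb_run_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  primary <- report$variants[[1L]]
  traj <- primary$trajectories
  tw <- data.table::as.data.table(traj$values)
  data.table::setnames(tw, sprintf("h%02d", 1:14))
  mw <- data.table::as.data.table(traj$observed)
  data.table::setnames(mw, sprintf("m%02d", 1:14))
  data.table::fwrite(cbind(traj$meta, tw, mw),
                     file.path(dir, "trajectories.csv"))
  model <- primary$selection$model
  data.table::fwrite(
    data.table::data.table(participant_id = model$meta$participant_id,
                           date = model$meta$date,
                           day_cluster = model$labels[model$cluster]),
    file.path(dir, "day_clusters.csv"))
  data.table::fwrite(
    data.table::data.table(participant_id = primary$patterns$participant_id,
                           pattern = primary$patterns$pattern),
    file.path(dir, "patterns.csv"))
  jsonlite::write_json(
    list(k = model$k, labels = model$labels, centroids = model$centroids,
         ch_value = model$ch_value, restart_scores = model$restart_scores,
         phase1_diagnostics = primary$selection$diagnostics,
         K = primary$patterns$K,
         silhouette_by_K = as.list(primary$patterns$silhouette_by_K)),
    file.path(dir, "cluster_model.json"), auto_unbox = TRUE, digits = NA)
  data.table::fwrite(report$stratified$estimates,
                     file.path(dir, "stratified_estimates.csv"))
  invisible(dir)
}

#' Run-length encode a wear mask as intervals
#'
#' @param wear an `sb_wear_mask` from [choi_nonwear()].
#' @return data.table (participant_id, start, end, state) with state
#'   `"wear"`/`"nonwear"`; `end` is exclusive (the first instant after the
#'   interval), so durations are `end - start`.
#' @export
wear_mask_intervals <- function(wear) {
  ww <- data.table::as.data.table(wear)
  ww[, {
    r <- rle(wear)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    .(start = minute[starts], end = minute[ends] + 60,
      state = ifelse(r$values, "wear", "nonwear"))
  }, by = participant_id]
}

#' @export
print.sb_run_report <- function(x, ...) {
  cat("Diurnal SB pattern pipeline run\n")
  at <- x$attrition
  cat(sprintf("  participants: %d -> %d retained (>= 4 adherent days)\n",
              at$input_participants, at$retained_participants))
  cat(sprintf("  days: %d -> %d adherent; %d trajectory days\n",
              at$input_days, at$adherent_days, x$n_trajectory_days))
  cat(sprintf("  Phase I: k = %d day clusters (CH = %.1f)\n",
              x$chosen_k, x$phase1_diagnostics[k == x$chosen_k, ch]))
  cat(sprintf("  Phase II: K = %d patterns (avg silhouette = %.3f)\n",
              x$chosen_K, x$variants[[1L]]$patterns$avg_silhouette))
  cat(sprintf("  MVPA median split at %.2f min/day\n", x$mvpa_split_value))
  cat(sprintf("  LRT for pattern x time x MVPA: chi2 = %.1f, df = %d, p = %.2g\n",
              x$lrt$statistic, x$lrt$df, x$lrt$p_value))
  if (!is.null(x$concordance))
    cat(sprintf("  concordance wake vs clock: %.1f%% days, %.1f%% participants\n",
                x$concordance$day_pct, x$concordance$participant_pct))
  cat("\nStratified baseline/slope estimates:\n")
  print(x$stratified$estimates)
  invisible(x)
}
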