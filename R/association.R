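# Association stage: random-intercept linear mixed models relating diurnal
# SB pattern to longitudinal physical-functioning trajectories, MVPA effect
# modification (median split + likelihood-ratio test), and the stratified
# baseline/slope estimate surface.

#' Median split of MVPA minutes per day
#'
#' @param covariates data.table with `participant_id` and `mvpa_min`.
#' @return list: `stratum` (data.table participant_id, mvpa_high logical),
#'   `split_value` (the sample median, min/day). Participants exactly at the
#'   median are classified low (high iff strictly greater). A warning is
#'   emitted if all values are equal (everyone low).
#' @export
mvpa_split <- function(covariates) {
  cv <- data.table::as.data.table(covariates)
  if (anyNA(cv$mvpa_min)) stop("mvpa_min must be present for all participants")
  med <- median(cv$mvpa_min)
  if (all(cv$mvpa_min == med))
    warning("all MVPA values equal; every participant classified low")
  list(stratum = cv[, .(participant_id, mvpa_high = mvpa_min > med)],
       split_value = med)
}

#' Fit the physical-functioning mixed model
#'
#' Linear mixed model with a person random intercept:
#' `pf ~ pattern * time (+ * mvpa_high) + covariates`, time in years with
#' baseline at t = 0, pattern 1 as reference. With
#' `include_mvpa_interaction`, binary MVPA (median split) enters with all
#' two-way terms and the pattern x time x MVPA three-way term. Complete-case
#' rows only (listwise deletion). REML for reported estimates; ML refits are
#' used for likelihood-ratio testing.
#'
#' @param panel data.table (participant_id, t_year, pf).
#' @param patterns data.table (participant_id, pattern) or an `sb_patterns`.
#' @param covariates baseline covariate table (see [generate_cohort()]).
#' @param include_sedentary also adjust for total sedentary time (default
#'   FALSE).
#' @param mvpa how the MVPA median split enters: `"three_way"` (all two-way
#'   terms plus pattern x time x MVPA; the effect-modification model),
#'   `"two_way"` (main effect and two-way terms only; the null of no effect
#'   modification), or `"none"`.
#' @param mvpa_split_value optional fixed MVPA threshold (min/day); by
#'   default the sample median is used (median split).
#' @param reml fit by REML (default TRUE).
#' @return list of class `sb_pf_fit`: `fit` (lmerMod), `data`, `formula`,
#'   `mvpa_split_value`, `n_obs`, `n_participants`, `mvpa`.
#' @export
fit_pf_model <- function(panel, patterns, covariates,
                         include_sedentary = FALSE,
                         mvpa = c("three_way", "two_way", "none"),
                         mvpa_split_value = NULL,
                         reml = TRUE) {
  mvpa <- match.arg(mvpa)
  if (inherits(patterns, "sb_patterns"))
    patterns <- data.table::data.table(participant_id = patterns$participant_id,
                                       pattern = patterns$pattern)
  dd <- data.table::as.data.table(panel)
  dd <- dd[data.table::as.data.table(patterns), on = "participant_id",
           nomatch = NULL]
  dd <- dd[data.table::as.data.table(covariates), on = "participant_id",
           nomatch = NULL]
  dd[, pattern := factor(pattern)]
  # canonical level orders so the reference level is the natural baseline
  # category (first level), not an alphabetical accident
  canon <- list(
    race_ethnicity = c("White", "Black", "Hispanic"),
    education = c("hs_or_less", "some_college", "college_grad"),
    alcohol = c("none", "lt1_wk", "ge1_wk", "unknown"),
    morbidity_count = c("0", "1", "2", "3+"),
    self_rated_health = c("excellent_vg", "good", "fair_poor")
  )
  for (col in names(canon))
    if (col %in% names(dd)) {
      lev <- intersect(canon[[col]], unique(dd[[col]]))
      lev <- c(lev, setdiff(unique(dd[[col]]), lev))
      dd[, (col) := factor(get(col), levels = lev)]
    }
  split_value <- NA_real_
  if (mvpa != "none") {
    if (is.null(mvpa_split_value)) {
      sp <- mvpa_split(unique(dd[, .(participant_id, mvpa_min)]))
      dd[sp$stratum, mvpa_high := i.mvpa_high, on = "participant_id"]
      split_value <- sp$split_value
    } else {
      split_value <- mvpa_split_value
      dd[, mvpa_high := mvpa_min > split_value]
    }
  }
  covs <- c("age", "race_ethnicity", "bmi", "education", "smoker", "alcohol",
            "morbidity_count", "self_rated_health")
  covs <- intersect(covs, names(dd))
  if (include_sedentary) covs <- c(covs, "total_sedentary_min")
  fix <- switch(mvpa,
    three_way = "pattern * t_year * mvpa_high",
    two_way = "(pattern + t_year + mvpa_high)^2",
    none = "pattern * t_year")
  fml <- as.formula(paste("pf ~", fix,
                          if (length(covs)) paste("+", paste(covs, collapse = " + ")) else "",
                          "+ (1 | participant_id)"))
  use <- complete.cases(dd[, c("pf", "t_year", "pattern", covs,
                               if (mvpa != "none") "mvpa_high"),
                           with = FALSE])
  dd <- dd[use]
  if (mvpa != "none") {
    cells <- dd[, .N, by = .(pattern, mvpa_high)]
    full_cells <- data.table::CJ(pattern = levels(dd$pattern),
                                 mvpa_high = c(FALSE, TRUE))
    miss <- full_cells[!cells, on = c("pattern", "mvpa_high")]
    if (nrow(miss))
      stop("empty pattern x MVPA cell(s): ",
           paste(sprintf("pattern %s/%s MVPA", miss$pattern,
                         ifelse(miss$mvpa_high, "high", "low")),
                 collapse = ", "))
  }
  fit <- lme4::lmer(fml, data = dd, REML = reml)
  structure(list(fit = fit, data = dd, formula = fml,
                 mvpa_split_value = split_value,
                 n_obs = nrow(dd),
                 n_participants = data.table::uniqueN(dd$participant_id),
                 mvpa = mvpa,
                 include_sedentary = include_sedentary),
            class = "sb_pf_fit")
}

#' Likelihood-ratio test for MVPA effect modification
#'
#' Both models are refitted by maximum likelihood on their (identical) rows;
#' the statistic is twice the log-likelihood difference with degrees of
#' freedom equal to the fixed-parameter difference.
#'
#' @param full,reduced `sb_pf_fit` objects, `reduced` nested in `full`.
#' @return list: `statistic`, `df`, `p_value`.
#' @export
lrt_effect_modification <- function(full, reduced) {
  stopifnot(inherits(full, "sb_pf_fit"), inherits(reduced, "sb_pf_fit"))
  if (full$n_obs != reduced$n_obs)
    stop("models were fitted on different rows")
  f_ml <- lme4::refitML(full$fit)
  r_ml <- lme4::refitML(reduced$fit)
  df <- length(lme4::fixef(f_ml)) - length(lme4::fixef(r_ml))
  if (df < 0) stop("reduced model is not nested in full model")
  stat <- max(0, 2 * (as.numeric(logLik(f_ml)) - as.numeric(logLik(r_ml))))
  p <- if (df == 0) 1 else pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p_value = p)
}

#' Stratified baseline and slope estimates per pattern x MVPA stratum
#'
#' For each pattern x MVPA cell, the baseline is the model-predicted PF at
#' t = 0 with continuous covariates at their sample means and categorical
#' covariates at reference levels; the slope is the derivative of the linear
#' predictor in time. Standard errors come from the fixed-effect covariance
#' by the delta method. Pairwise within-stratum contrasts between patterns
#' and within-pattern high-vs-low MVPA contrasts are Wald z tests
#' (unadjusted).
#'
#' @param pf_fit an `sb_pf_fit` including the three-way interaction.
#' @return list of class `sb_stratified`: `estimates` (data.table: pattern,
#'   mvpa, baseline, baseline_se, slope, slope_se), `contrasts_baseline`,
#'   `contrasts_slope` (within-stratum pairwise), `mvpa_contrasts`
#'   (within-pattern), `mvpa_split_value`.
#' @export
stratified_estimates <- function(pf_fit) {
  stopifnot(inherits(pf_fit, "sb_pf_fit"))
  if (pf_fit$mvpa != "three_way")
    stop("fit does not include the pattern x time x MVPA interaction")
  fit <- pf_fit$fit
  beta <- lme4::fixef(fit)
  V <- as.matrix(vcov(fit))
  dd <- pf_fit$data
  pats <- levels(dd$pattern)

  ref_row <- function(pat_val, mvpa_val, t_val) {
    nd <- dd[1L]
    nd[, `:=`(pattern = factor(..pat_val, levels = pats),
              t_year = ..t_val, mvpa_high = ..mvpa_val)]
    for (col in c("age", "bmi", "total_sedentary_min"))
      if (col %in% names(nd)) nd[, (col) := mean(dd[[col]])]
    for (col in c("race_ethnicity", "education", "alcohol",
                  "morbidity_count", "self_rated_health"))
      if (col %in% names(nd))
        nd[, (col) := factor(levels(dd[[col]])[1L],
                             levels = levels(dd[[col]]))]
    if ("smoker" %in% names(nd)) nd[, smoker := FALSE]
    tt <- delete.response(terms(fit))
    model.matrix(tt, data = nd)[1L, names(beta)]
  }

  grid <- data.table::CJ(pattern = pats, mvpa = c("low", "high"))
  Xb <- t(vapply(seq_len(nrow(grid)), function(i)
    ref_row(grid$pattern[i], grid$mvpa[i] == "high", 0), beta))
  X1 <- t(vapply(seq_len(nrow(grid)), function(i)
    ref_row(grid$pattern[i], grid$mvpa[i] == "high", 1), beta))
  Xs <- X1 - Xb   # slope = d/dt of linear predictor
  est <- data.table::data.table(
    pattern = grid$pattern, mvpa = grid$mvpa,
    baseline = as.vector(Xb %*% beta),
    baseline_se = sqrt(rowSums((Xb %*% V) * Xb)),
    slope = as.vector(Xs %*% beta),
    slope_se = sqrt(rowSums((Xs %*% V) * Xs))
  )

  wald <- function(C) {
    se <- sqrt(rowSums((C %*% V) * C))
    diffv <- as.vector(C %*% beta)
    z <- ifelse(se == 0, 0, diffv / se)
    data.table::data.table(diff = diffv, se = se, z = z,
                           p_value = ifelse(se == 0 & diffv == 0, 1,
                                            2 * pnorm(-abs(z))))
  }
  pairs <- t(utils::combn(length(pats), 2L))
  contrast_tab <- function(X) {
    data.table::rbindlist(lapply(c("low", "high"), function(m) {
      rows <- which(grid$mvpa == m)
      C <- X[rows[pairs[, 1L]], , drop = FALSE] -
        X[rows[pairs[, 2L]], , drop = FALSE]
      cbind(data.table::data.table(mvpa = m,
                                   pattern_a = pats[pairs[, 1L]],
                                   pattern_b = pats[pairs[, 2L]]),
            wald(C))
    }))
  }
  mvpa_tab <- function(X) {
    hi <- which(grid$mvpa == "high"); lo <- which(grid$mvpa == "low")
    C <- X[hi, , drop = FALSE] - X[lo, , drop = FALSE]
    cbind(data.table::data.table(pattern = grid$pattern[hi]), wald(C))
  }
  structure(list(estimates = est,
                 contrasts_baseline = contrast_tab(Xb),
                 contrasts_slope = contrast_tab(Xs),
                 mvpa_contrasts = list(baseline = mvpa_tab(Xb),
                                       slope = mvpa_tab(Xs)),
                 mvpa_split_value = pf_fit$mvpa_split_value),
            class = "sb_stratified")
}
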