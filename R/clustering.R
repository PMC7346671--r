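# Two-phase clustering: Phase I longitudinal k-means over day trajectories
# (Calinski-Harabasz selection over restarts), Phase II complete-linkage
# hierarchical clustering over participant day-cluster proportion profiles
# (average silhouette width selection), plus the concordance analysis.

#' Longitudinal k-means over day trajectories
#'
#' Lloyd's k-means with squared Euclidean distance on the 14-dimensional
#' hourly vectors. Each restart draws k distinct data points as initial
#' centroids, iterates until assignments are stable (or `max_iter`), and
#' re-seeds any emptied cluster with the point farthest from its current
#' centroid. The restart with the highest Calinski-Harabasz criterion is
#' returned. Clusters are relabelled A, B, C, ... by descending centroid
#' total sedentary minutes.
#'
#' @param x n x 14 numeric matrix of completed trajectories, or an
#'   `sb_trajectories`.
#' @param k number of clusters (>= 2).
#' @param n_restarts number of random restarts (default 5).
#' @param seed integer seed.
#' @param max_iter maximum Lloyd iterations per restart (default 100).
#' @return list of class `sb_day_clusters`: `k`, `centroids` (k x 14, rows
#'   A..), `cluster` (integer assignments, 1 = A), `labels`, `ch_value`,
#'   `restart_scores`, `sse`, and `meta` when `x` is an `sb_trajectories`.
#' @export
kml_fit <- function(x, k, n_restarts = 5L, seed = 1L, max_iter = 100L) {
  meta <- NULL
  if (inherits(x, "sb_trajectories")) { meta <- x$meta; x <- x$values }
  x <- as.matrix(x)
  if (anyNA(x)) stop("trajectories must be imputed before clustering")
  if (k < 2L) stop("k must be >= 2")
  if (nrow(unique(x)) < k) stop("k exceeds the number of distinct trajectories")
  set.seed(substream_seed(seed, "kml"))
  best <- NULL
  restart_scores <- numeric(n_restarts)
  for (r in seq_len(n_restarts)) {
    fit <- lloyd_once(x, k, max_iter)
    restart_scores[r] <- calinski_harabasz(x, fit$cluster)
    if (is.null(best) || restart_scores[r] > best$ch) {
      best <- fit
      best$ch <- restart_scores[r]
    }
  }
  # relabel by descending centroid total
  ord <- order(-rowSums(best$centroids))
  relabel <- match(seq_len(k), ord)
  out <- list(
    k = k,
    centroids = best$centroids[ord, , drop = FALSE],
    cluster = relabel[best$cluster],
    labels = LETTERS[seq_len(k)],
    ch_value = best$ch,
    restart_scores = restart_scores,
    sse = best$sse,
    meta = meta
  )
  rownames(out$centroids) <- out$labels
  class(out) <- "sb_day_clusters"
  out
}

#' Single Lloyd's k-means run
#' @keywords internal
lloyd_once <- function(x, k, max_iter) {
  n <- nrow(x)
  # initial centroids: k distinct observed trajectories
  repeat {
    centroids <- x[sample.int(n, k), , drop = FALSE]
    if (nrow(unique(centroids)) == k) break
  }
  assign_old <- rep(0L, n)
  for (it in seq_len(max_iter)) {
    d2 <- sq_dist(x, centroids)
    cl <- max.col(-d2, ties.method = "first")
    # re-seed each empty cluster with the point farthest from its centroid
    for (e in setdiff(seq_len(k), unique(cl))) {
      far <- which.max(d2[cbind(seq_len(n), cl)])
      centroids[e, ] <- x[far, ]
      cl[far] <- e
      d2[, e] <- rowSums(sweep(x, 2L, centroids[e, ])^2)
      d2[far, e] <- 0
    }
    if (all(cl == assign_old)) break
    assign_old <- cl
    for (j in seq_len(k))
      centroids[j, ] <- colMeans(x[cl == j, , drop = FALSE])
  }
  sse <- sum((x - centroids[cl, , drop = FALSE])^2)
  list(centroids = centroids, cluster = cl, sse = sse)
}

#' Squared Euclidean distances between rows of x and rows of c
#' @keywords internal
sq_dist <- function(x, cen) {
  xx <- rowSums(x^2)
  cc <- rowSums(cen^2)
  d2 <- outer(xx, cc, "+") - 2 * x %*% t(cen)
  pmax(d2, 0)
}

#' Calinski-Harabasz criterion of a partition
#'
#' `CH = [trace(B)/(k-1)] / [trace(W)/(n-k)]` with B the between-cluster and
#' W the within-cluster scatter about the cluster centroids. If W = 0 with
#' distinct centroids (perfect separation) the value is `Inf`.
#'
#' @param x numeric matrix (rows = observations).
#' @param cluster integer assignments, >= 2 non-empty clusters.
#' @return numeric scalar.
#' @export
calinski_harabasz <- function(x, cluster) {
  x <- as.matrix(x)
  ids <- sort(unique(cluster))
  k <- length(ids)
  n <- nrow(x)
  if (k < 2L) stop("Calinski-Harabasz requires >= 2 non-empty clusters")
  if (n <= k) stop("Calinski-Harabasz requires n > k")
  grand <- colMeans(x)
  W <- 0; B <- 0
  for (j in ids) {
    xi <- x[cluster == j, , drop = FALSE]
    cj <- colMeans(xi)
    W <- W + sum(sweep(xi, 2L, cj)^2)
    B <- B + nrow(xi) * sum((cj - grand)^2)
  }
  if (W == 0) return(Inf)
  (B / (k - 1)) / (W / (n - k))
}

#' Spherical-Gaussian AIC/BIC for a k-means partition (diagnostics only)
#' @keywords internal
kmeans_ic <- function(x, sse, k) {
  n <- nrow(x); p <- ncol(x)
  sigma2 <- sse / (n * p)
  loglik <- -n * p / 2 * (log(2 * pi * sigma2) + 1)
  n_par <- k * p + 1
  c(aic = -2 * loglik + 2 * n_par, bic = -2 * loglik + log(n) * n_par)
}

#' Phase I: choose the number of day clusters
#'
#' Fits [kml_fit()] for each k in `k_range` and selects the k with the
#' highest Calinski-Harabasz criterion. Spherical-Gaussian AIC/BIC are
#' reported as corroborating diagnostics only and never drive the selection.
#'
#' @inheritParams kml_fit
#' @param k_range candidate cluster counts (default 2:6).
#' @return list: `k` (chosen), `model` (the chosen `sb_day_clusters`),
#'   `diagnostics` (data.table: k, ch, aic, bic), `models` (all fits).
#' @export
select_k_phase1 <- function(x, k_range = 2:6, n_restarts = 5L, seed = 1L) {
  if (!length(k_range)) stop("empty k_range")
  xm <- if (inherits(x, "sb_trajectories")) x$values else as.matrix(x)
  models <- lapply(k_range, function(k)
    kml_fit(x, k, n_restarts = n_restarts, seed = substream_seed(seed, paste0("k", k))))
  diag <- data.table::rbindlist(lapply(seq_along(k_range), function(i) {
    ic <- kmeans_ic(xm, models[[i]]$sse, k_range[i])
    data.table::data.table(k = k_range[i], ch = models[[i]]$ch_value,
                           aic = ic[["aic"]], bic = ic[["bic"]])
  }))
  ch <- diag$ch
  best <- which.max(ch)  # ties: smallest k (first index)
  list(k = k_range[best], model = models[[best]], diagnostics = diag,
       models = models)
}

#' Participant profiles: proportion of days per day cluster
#'
#' @param model an `sb_day_clusters` carrying `meta` (participant_id per
#'   day), or a data.table (participant_id, cluster).
#' @param k number of day clusters (taken from the model if available).
#' @return list of class `sb_profiles`: `proportions` (n_participants x k
#'   matrix, rows named by participant), `n_days` (integer vector).
#' @export
profiles_from_assignments <- function(model, k = NULL) {
  if (inherits(model, "sb_day_clusters")) {
    if (is.null(model$meta)) stop("model carries no day metadata")
    dd <- data.table::data.table(participant_id = model$meta$participant_id,
                                 cluster = model$cluster)
    k <- model$k
  } else {
    dd <- data.table::as.data.table(model)
    if (is.null(k)) k <- max(dd$cluster)
  }
  if (nrow(dd) == 0L) stop("no assigned days")
  tab <- dd[, {
    cnt <- tabulate(cluster, nbins = k)
    .(cluster = seq_len(k), n = cnt, n_days = .N)
  }, by = participant_id]
  if (any(tab$n_days == 0L)) stop("participant with 0 days")
  prop <- matrix(tab$n / tab$n_days, ncol = k, byrow = TRUE)
  pid <- unique(tab$participant_id)
  rownames(prop) <- pid
  structure(list(proportions = prop,
                 n_days = tab[cluster == 1L, n_days],
                 participant_id = pid),
            class = "sb_profiles")
}

#' Phase II: hierarchical clustering of participant profiles
#'
#' Agglomerative clustering with complete linkage and Euclidean distance on
#' the day-cluster proportion vectors. The dendrogram is cut at each K in
#' `K_range`; the cut maximising average silhouette width is returned (ties
#' broken toward smaller K). Patterns are relabelled 1..K by the day-cluster
#' letter dominating each pattern's mean profile (pattern 1 <-> cluster A,
#' etc.), falling back to descending pattern size for unresolved ties.
#'
#' @param profiles an `sb_profiles`.
#' @param K_range candidate numbers of patterns (default 2:8).
#' @return list of class `sb_patterns`: `pattern` (integer per participant),
#'   `K`, `avg_silhouette`, `silhouette_by_K`, `hclust`, `participant_id`.
#' @export
hier_cluster <- function(profiles, K_range = 2:8) {
  stopifnot(inherits(profiles, "sb_profiles"))
  P <- profiles$proportions
  if (nrow(P) < max(K_range)) stop("fewer participants than the largest K")
  d <- dist(P, method = "euclidean")
  hc <- hclust(d, method = "complete")
  sil_by_K <- setNames(numeric(length(K_range)), K_range)
  cuts <- list()
  for (i in seq_along(K_range)) {
    K <- K_range[i]
    lab <- cutree(hc, k = K)
    cuts[[i]] <- lab
    sil_by_K[i] <- mean(silhouette_widths(P, lab, d = d))
  }
  best <- which.max(sil_by_K)  # ties: smaller K
  lab <- cuts[[best]]
  K <- K_range[best]
  # relabel: pattern j <-> day cluster whose proportion dominates its mean
  # profile; duplicate winners fall back to descending cluster size order
  means <- vapply(seq_len(K), function(j)
    colMeans(P[lab == j, , drop = FALSE]), numeric(ncol(P)))
  dominant <- apply(means, 2L, which.max)
  relabel <- if (anyDuplicated(dominant))
    rank(-tabulate(lab, K), ties.method = "first")
  else
    rank(dominant, ties.method = "first")
  new_lab <- as.integer(relabel[lab])
  structure(list(pattern = new_lab, K = K,
                 avg_silhouette = unname(sil_by_K[best]),
                 silhouette_by_K = sil_by_K, hclust = hc,
                 participant_id = profiles$participant_id),
            class = "sb_patterns")
}

#' Per-observation silhouette widths
#'
#' `s(i) = (b(i) - a(i)) / max(a(i), b(i))` with a(i) the mean distance to
#' other members of i's cluster and b(i) the smallest mean distance to any
#' other cluster. Members of singleton clusters get s = 0, as do points with
#' a = b = 0.
#'
#' @param x numeric matrix of observations.
#' @param labels integer cluster labels (>= 2 clusters).
#' @param d optional precomputed `dist` object.
#' @return numeric vector of widths.
#' @export
silhouette_widths <- function(x, labels, d = NULL) {
  ids <- sort(unique(labels))
  if (length(ids) < 2L) stop("silhouette requires >= 2 clusters")
  if (is.null(d)) d <- dist(x, method = "euclidean")
  dm <- as.matrix(d)
  n <- nrow(dm)
  s <- numeric(n)
  sizes <- table(factor(labels, levels = ids))
  for (i in seq_len(n)) {
    own <- labels[i]
    if (sizes[as.character(own)] == 1L) { s[i] <- 0; next }
    a <- mean(dm[i, labels == own & seq_len(n) != i])
    b <- min(vapply(ids[ids != own], function(j)
      mean(dm[i, labels == j]), 0))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  s
}

#' Concordance between wake-aligned and clock-aligned cluster variants
#'
#' Day clusters (and patterns) of variant B are matched one-to-one onto
#' variant A's labels by maximal confusion-matrix overlap (exact optimal
#' assignment); concordance is the percentage of common days (participants)
#' whose matched labels agree.
#'
#' @param days_a,days_b data.tables (participant_id, date, cluster) for the
#'   two variants; only common (participant, date) rows are compared.
#' @param patterns_a,patterns_b optional data.tables (participant_id,
#'   pattern); only common participants are compared.
#' @return list: `day_pct`, `participant_pct` (NULL if patterns not given),
#'   `day_mapping`, `pattern_mapping`.
#' @export
concordance <- function(days_a, days_b, patterns_a = NULL, patterns_b = NULL) {
  da <- data.table::as.data.table(days_a)
  db <- data.table::as.data.table(days_b)
  common <- da[db, on = c("participant_id", "date"), nomatch = NULL,
               .(participant_id, date, ca = cluster, cb = i.cluster)]
  if (nrow(common) == 0L) stop("disjoint day sets")
  m_day <- match_labels(common$ca, common$cb)
  out <- list(day_pct = 100 * mean(m_day$mapping[as.character(common$cb)] ==
                                     common$ca),
              day_mapping = m_day$mapping, participant_pct = NULL,
              pattern_mapping = NULL)
  if (!is.null(patterns_a) && !is.null(patterns_b)) {
    pa <- data.table::as.data.table(patterns_a)
    pb <- data.table::as.data.table(patterns_b)
    cp <- pa[pb, on = "participant_id", nomatch = NULL,
             .(participant_id, qa = pattern, qb = i.pattern)]
    if (nrow(cp) == 0L) stop("disjoint participant sets")
    m_pat <- match_labels(cp$qa, cp$qb)
    out$participant_pct <- 100 * mean(m_pat$mapping[as.character(cp$qb)] ==
                                        cp$qa)
    out$pattern_mapping <- m_pat$mapping
  }
  out
}
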