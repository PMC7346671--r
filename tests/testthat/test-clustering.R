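# Phase I/II clustering: k-means vs exhaustive enumeration, CH and silhouette
# vs brute force, complete-linkage merge heights, profiles, concordance.

## Phase I -------------------------------------------------------------------

test_that("k-means on a 6-point fixture matches the exhaustive best-SSE partition", {
  set.seed(1)
  x <- rbind(matrix(rnorm(9, 0, 0.5), 3), matrix(rnorm(9, 6, 0.5), 3))
  fit <- kml_fit(x, k = 2, n_restarts = 5, seed = 4)
  oracle <- best_sse_2part(x)
  expect_equal(fit$sse, oracle$sse, tolerance = 1e-10)
  expect_equal(adjusted_rand_index(fit$cluster, oracle$cl), 1)
})

test_that("k-means recovers noiseless archetype days with ARI 1", {
  arch <- default_archetypes()
  truth <- rep(1:4, times = c(10, 8, 6, 9))
  x <- arch[truth, ]
  fit <- kml_fit(x, k = 4, n_restarts = 5, seed = 2)
  expect_equal(adjusted_rand_index(fit$cluster, truth), 1)
  # centroids equal the archetype curves; cluster A = highest total
  expect_equal(unname(fit$centroids["A", ]), unname(arch["A", ]))
  expect_equal(unname(fit$centroids["D", ]), unname(arch["D", ]))
  expect_true(all(diff(rowSums(fit$centroids)) <= 0))
})

test_that("k-means is deterministic given seed and descends in SSE", {
  set.seed(10)
  x <- matrix(rnorm(200 * 14, 30, 8), ncol = 14)
  f1 <- kml_fit(x, 3, seed = 42)
  f2 <- kml_fit(x, 3, seed = 42)
  expect_identical(f1$cluster, f2$cluster)
  expect_identical(f1$centroids, f2$centroids)
  # SSE after m iterations is non-increasing in m (monotone descent)
  sse <- vapply(1:8, function(m)
    kml_fit(x, 3, n_restarts = 1, seed = 7, max_iter = m)$sse, 0)
  expect_true(all(diff(sse) <= 1e-9))
  expect_error(kml_fit(x[1:2, ], k = 3), "distinct")
})

test_that("Calinski-Harabasz matches hand and brute-force evaluation", {
  # 1-D set {0,1,10,11} split {0,1} vs {10,11}: B = 100, W = 1 -> CH = 200
  x <- matrix(c(0, 1, 10, 11), ncol = 1)
  cl <- c(1, 1, 2, 2)
  expect_equal(calinski_harabasz(x, cl), 200)
  expect_equal(calinski_harabasz(x, cl), brute_ch(x, cl), tolerance = 1e-10)
  # scale invariance: doubling coordinates scales B and W by 4
  expect_equal(calinski_harabasz(2 * x, cl), calinski_harabasz(x, cl))
  # perfect separation: W = 0 -> Inf sentinel
  x0 <- matrix(c(0, 0, 5, 5), ncol = 1)
  expect_identical(calinski_harabasz(x0, cl), Inf)
  expect_error(calinski_harabasz(x, rep(1, 4)), ">= 2")
  # random fixture agreement to 1e-10 relative
  set.seed(6)
  xr <- matrix(rnorm(40 * 3), ncol = 3)
  clr <- sample(1:4, 40, TRUE)
  expect_equal(calinski_harabasz(xr, clr), brute_ch(xr, clr),
               tolerance = 1e-10)
})

test_that("Phase I selection reports one diagnostics row per k and flags the CH argmax", {
  set.seed(12)
  arch <- default_archetypes()
  x <- arch[sample(1:4, 150, TRUE), ] + matrix(rnorm(150 * 14, 0, 4), ncol = 14)
  sel <- select_k_phase1(x, k_range = 2:6, n_restarts = 3, seed = 5)
  expect_equal(sel$diagnostics$k, 2:6)
  expect_equal(sel$k, sel$diagnostics$k[which.max(sel$diagnostics$ch)])
  expect_equal(sel$k, 4L)
  expect_error(select_k_phase1(x, k_range = integer(0)), "empty")
})

## profiles ------------------------------------------------------------------

test_that("participant profiles are day-cluster proportions", {
  dd <- data.table::data.table(
    participant_id = c(rep(1L, 7), rep(2L, 4)),
    cluster = c(rep(1L, 7), 1L, 1L, 2L, 3L))
  pr <- profiles_from_assignments(dd, k = 4L)
  expect_equal(unname(pr$proportions[1, ]), c(1, 0, 0, 0))
  expect_equal(unname(pr$proportions[2, ]), c(0.5, 0.25, 0.25, 0))
  expect_equal(pr$n_days, c(7L, 4L))
  # random fixture vs per-participant tally oracle
  set.seed(9)
  dd2 <- data.table::data.table(participant_id = rep(1:20, each = 6),
                                cluster = sample(1:4, 120, TRUE))
  pr2 <- profiles_from_assignments(dd2, k = 4L)
  tab <- unclass(table(dd2$participant_id, dd2$cluster)) / 6
  expect_equal(unname(pr2$proportions), unname(tab[as.character(1:20), ]))
  expect_true(all(abs(rowSums(pr2$proportions) - 1) < 1e-9))
})

## Phase II ------------------------------------------------------------------

test_that("hierarchical clustering separates simplex-corner profiles and relabels by dominant cluster", {
  set.seed(4)
  corners <- diag(4)
  P <- corners[rep(1:4, each = 6), ] + matrix(runif(96, 0, 0.05), ncol = 4)
  P <- P / rowSums(P)
  pr <- structure(list(proportions = P, n_days = rep(7L, 24),
                       participant_id = 1:24), class = "sb_profiles")
  pat <- hier_cluster(pr, K_range = 2:8)
  expect_equal(pat$K, 4L)
  # relabelling: pattern j is dominated by day cluster j
  expect_equal(pat$pattern, rep(1:4, each = 6))
  expect_gt(pat$avg_silhouette, 0.8)
})

test_that("two participants in two clusters get silhouette 0 by the singleton convention", {
  pr <- structure(list(proportions = rbind(c(1, 0), c(0, 1)),
                       n_days = c(5L, 5L), participant_id = 1:2),
                  class = "sb_profiles")
  pat <- hier_cluster(pr, K_range = 2)
  expect_equal(pat$K, 2L)
  expect_equal(pat$avg_silhouette, 0)
  expect_error(hier_cluster(pr, K_range = 2:3), "fewer participants")
})

test_that("complete-linkage merge heights match the brute-force oracle", {
  set.seed(14)
  x <- matrix(rnorm(8 * 4), ncol = 4)
  hc <- hclust(dist(x), method = "complete")
  expect_equal(hc$height, brute_complete_heights(x), tolerance = 1e-10)
})

test_that("silhouette widths match hand-computed values and conventions", {
  # 6 points on a line, two tight triples
  x <- matrix(c(0, 1, 2, 10, 11, 12), ncol = 1)
  cl <- rep(1:2, each = 3)
  s <- silhouette_widths(x, cl)
  # hand: point 0 -> a = 1.5, b = 11, s = 9.5/11
  expect_equal(s[1], 9.5 / 11)
  expect_equal(s[2], (10 - 1) / 10)       # point 1: a = 1, b = 10
  expect_equal(s, brute_sil(x, cl), tolerance = 1e-10)
  expect_gt(mean(s), 0.85)                # tight, far-apart clusters
  # identical points across 2 labels -> a = b = 0 -> widths 0
  x0 <- matrix(rep(1, 4), ncol = 1)
  expect_equal(silhouette_widths(x0, c(1, 1, 2, 2)), rep(0, 4))
  expect_error(silhouette_widths(x, rep(1, 6)), ">= 2")
  # agreement with the reference implementation on a random fixture
  skip_if_not_installed("cluster")
  set.seed(15)
  xr <- matrix(rnorm(30 * 3), ncol = 3)
  clr <- sample(1:3, 30, TRUE)
  ref <- cluster::silhouette(clr, dist(xr))
  expect_equal(silhouette_widths(xr, clr), unname(ref[, "sil_width"]),
               tolerance = 1e-10)
})

## concordance ---------------------------------------------------------------

test_that("concordance is 100% for identical or label-permuted assignments", {
  set.seed(20)
  days_a <- data.table::data.table(participant_id = rep(1:5, each = 4),
                                   date = rep(as.Date("2012-01-02") + 0:3, 5),
                                   cluster = sample(1:3, 20, TRUE))
  days_b <- data.table::copy(days_a)
  expect_equal(concordance(days_a, days_b)$day_pct, 100)
  perm <- c(3L, 1L, 2L)
  days_b[, cluster := perm[cluster]]
  pa <- data.table::data.table(participant_id = 1:5, pattern = c(1L, 2L, 1L, 2L, 1L))
  pb <- data.table::data.table(participant_id = 1:5, pattern = c(2L, 1L, 2L, 1L, 2L))
  out <- concordance(days_a, days_b, pa, pb)
  expect_equal(out$day_pct, 100)
  expect_equal(out$participant_pct, 100)
})

test_that("a constructed 80%-agreement confusion yields exactly 80%", {
  days_a <- data.table::data.table(participant_id = 1:10,
                                   date = as.Date("2012-01-02"),
                                   cluster = rep(1:2, each = 5))
  days_b <- data.table::copy(days_a)
  # permute labels then flip two days: optimal matching leaves 8/10 agreeing
  days_b[, cluster := 3L - cluster]
  days_b[c(1, 6), cluster := 3L - cluster]
  expect_equal(concordance(days_a, days_b)$day_pct, 80)
  expect_error(concordance(days_a,
    data.table::data.table(participant_id = 99L, date = as.Date("2020-01-01"),
                           cluster = 1L)), "disjoint")
})

test_that("the in-package adjusted Rand index agrees with the reference implementation", {
  skip_if_not_installed("mclust")
  set.seed(18)
  for (i in 1:5) {
    a <- sample(1:4, 60, TRUE)
    b <- ifelse(runif(60) < 0.3, sample(1:4, 60, TRUE), a)
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
  expect_equal(adjusted_rand_index(1:5, c(2L, 3L, 4L, 5L, 1L)), 1)
})
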