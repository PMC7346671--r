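# Independent brute-force oracles used by the clustering and acceptance
# suites. These deliberately re-derive each quantity from its definition and
# share no code with the package implementation.

brute_ch <- function(x, cl) {
  x <- as.matrix(x)
  gm <- colMeans(x)
  ids <- sort(unique(cl)); k <- length(ids); n <- nrow(x)
  W <- 0; B <- 0
  for (j in ids) {
    xi <- x[cl == j, , drop = FALSE]
    cj <- colMeans(xi)
    W <- W + sum(t(t(xi) - cj)^2)
    B <- B + nrow(xi) * sum((cj - gm)^2)
  }
  (B / (k - 1)) / (W / (n - k))
}

brute_sil <- function(x, cl) {
  dm <- as.matrix(dist(x))
  n <- nrow(dm)
  vapply(seq_len(n), function(i) {
    own <- cl[i]
    if (sum(cl == own) == 1L) return(0)
    a <- mean(dm[i, cl == own & seq_len(n) != i])
    b <- min(sapply(setdiff(unique(cl), own), function(j) mean(dm[i, cl == j])))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, 0)
}

# exhaustive enumeration of all 2-cluster partitions, returning the best SSE
best_sse_2part <- function(x) {
  n <- nrow(x)
  best <- Inf; bestcl <- NULL
  for (m in 1:(2^(n - 1) - 1)) {
    cl <- as.integer(intToBits(m))[1:n] + 1L
    if (length(unique(cl)) < 2L) next
    sse <- sum(sapply(unique(cl), function(j) {
      xi <- x[cl == j, , drop = FALSE]
      sum(t(t(xi) - colMeans(xi))^2)
    }))
    if (sse < best) { best <- sse; bestcl <- cl }
  }
  list(sse = best, cl = bestcl)
}

# naive complete-linkage agglomeration returning successive merge heights
brute_complete_heights <- function(x) {
  dm <- as.matrix(dist(x))
  groups <- as.list(seq_len(nrow(dm)))
  heights <- numeric(0)
  while (length(groups) > 1L) {
    best <- Inf; bi <- bj <- 0L
    for (i in seq_along(groups)) for (j in seq_along(groups)) {
      if (i >= j) next
      h <- max(dm[groups[[i]], groups[[j]]])
      if (h < best) { best <- h; bi <- i; bj <- j }
    }
    heights <- c(heights, best)
    groups[[bi]] <- c(groups[[bi]], groups[[bj]])
    groups[[bj]] <- NULL
  }
  heights
}

# minimal trajectory container for imputation tests
make_traj <- function(values_list) {
  v <- do.call(rbind, values_list)
  structure(list(values = v, observed = !is.na(v), meta = NULL,
                 dropped = NULL), class = "sb_trajectories")
}
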