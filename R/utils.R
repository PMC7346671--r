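# Shared small helpers: seed substreams, clock-time arithmetic, label matching.

#' Derive a named substream seed from a root seed
#'
#' All stochastic stages draw their own seed deterministically from one root
#' seed plus a stage name, so that components are reproducible in isolation
#' (re-running only the imputation stage, say, does not depend on how many
#' random numbers the generator consumed).
#'
#' @param seed integer root seed.
#' @param name character stage name.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @keywords internal
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((abs(seed) + 97L * h) %% (.Machine$integer.max - 1L))
}

#' Parse "HH:MM" clock strings to minutes past midnight
#' @param x character vector, `NA` allowed.
#' @return numeric minutes in `[0, 1440)`.
#' @keywords internal
parse_clock <- function(x) {
  out <- rep(NA_real_, length(x))
  ok <- !is.na(x) & nzchar(x)
  if (any(ok)) {
    parts <- strsplit(x[ok], ":", fixed = TRUE)
    out[ok] <- vapply(parts, function(p) as.numeric(p[1]) * 60 + as.numeric(p[2]), 0)
  }
  out
}

#' Format minutes past midnight as "HH:MM"
#' @keywords internal
format_clock <- function(m) {
  ifelse(is.na(m), NA_character_,
         sprintf("%02d:%02d", floor((m %% 1440) / 60), round(m %% 60)))
}

#' Circular mean of clock times
#'
#' Clock times wrap at midnight, so naive averaging of e.g. 23:30 and 00:30
#' gives noon. Times are mapped to angles on the 24-hour circle and averaged
#' as unit vectors.
#'
#' @param minutes numeric vector of minutes past midnight; `NA` dropped.
#' @return Mean clock time in minutes past midnight, or `NA` if no data.
#' @keywords internal
circular_mean_clock <- function(minutes) {
  minutes <- minutes[!is.na(minutes)]
  if (length(minutes) == 0L) return(NA_real_)
  theta <- minutes / 1440 * 2 * pi
  m <- atan2(mean(sin(theta)), mean(cos(theta))) / (2 * pi) * 1440
  m %% 1440
}

#' Best one-to-one matching of cluster labels between two partitions
#'
#' Exhaustive search over permutations of the smaller label set maximising
#' the matched diagonal of the confusion matrix (optimal assignment; the
#' label sets here never exceed 8, so enumeration is exact and cheap).
#'
#' @param a,b integer label vectors over the same items.
#' @return list with `mapping` (named integer: label of `b` -> label of `a`)
#'   and `agreement` (fraction of items matched after relabelling).
#' @keywords internal
match_labels <- function(a, b) {
  stopifnot(length(a) == length(b))
  la <- sort(unique(a)); lb <- sort(unique(b))
  conf <- table(factor(a, levels = la), factor(b, levels = lb))
  if (length(lb) > 8L || length(la) > 8L)
    stop("label matching supports at most 8 clusters per side")
  # permute columns (b labels) onto rows (a labels)
  k <- max(length(la), length(lb))
  perms <- permutations_of(seq_len(k))
  best <- -1L; best_perm <- NULL
  for (i in seq_len(nrow(perms))) {
    p <- perms[i, ]
    s <- 0L
    for (j in seq_along(lb)) {
      r <- p[j]
      if (r <= length(la)) s <- s + conf[r, j]
    }
    if (s > best) { best <- s; best_perm <- p }
  }
  mapping <- setNames(rep(NA_integer_, length(lb)), lb)
  for (j in seq_along(lb)) {
    r <- best_perm[j]
    mapping[j] <- if (r <= length(la)) la[r] else NA_integer_
  }
  list(mapping = mapping, agreement = best / length(a))
}

#' All permutations of a vector (n <= 8)
#' @keywords internal
permutations_of <- function(v) {
  n <- length(v)
  if (n == 1L) return(matrix(v, 1L))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    rest <- permutations_of(v[-i])
    out[[i]] <- cbind(v[i], rest)
  }
  do.call(rbind, out)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items; 1 for
#' identical partitions (up to relabelling), ~0 for independent ones.
#'
#' @param a,b label vectors of equal length.
#' @return numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0L)
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
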