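#' Paired trace set
#'
#' Per-subject pairs of condition traces on a common epoch time grid.
#'
#' @param a,b Numeric matrices, subjects x time, same dimensions.
#' @param time Optional time grid (seconds), length ncol(a).
#' @return List of class `paired_trace_set` with `a`, `b`, `diff`
#'   (a - b), `time`, `n`.
#' @export
paired_trace_set <- function(a, b, time = NULL) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) stop("a and b must have identical dimensions")
  if (nrow(a) < 2) stop("at least 2 subjects required")
  if (is.null(time)) time <- seq_len(ncol(a))
  if (length(time) != ncol(a)) stop("time must match trace length")
  structure(list(a = a, b = b, diff = a - b, time = time, n = nrow(a)),
            class = "paired_trace_set")
}

#' Pointwise paired t statistics
#'
#' t(j) = mean(d_j) / (sd(d_j) / sqrt(n)) over the per-subject difference
#' waveforms, df = n - 1. Points with zero variance get t = 0 with a
#' warning (conservative).
#'
#' @param set A [paired_trace_set()], or a subjects x time difference
#'   matrix.
#' @return Numeric t trace.
#' @export
pointwise_paired_t <- function(set) {
  d <- if (inherits(set, "paired_trace_set")) set$diff else as.matrix(set)
  n <- nrow(d)
  m <- colMeans(d)
  v <- (colSums(d^2) - n * m^2) / (n - 1)
  v[v < 0] <- 0   # numeric guard
  t <- rep(0, length(m))
  nz <- v > 0
  if (any(!nz & m != 0))
    warning("zero variance at some time points; t set to 0 there")
  t[nz] <- m[nz] / sqrt(v[nz] / n)
  t
}

#' Form supra-threshold clusters and T-sums
#'
#' Maximal contiguous runs where |t| exceeds the two-sided critical t at
#' df = n - 1 and the sign is constant; a sign change splits the run.
#' Clusters touching the epoch edges are retained.
#'
#' @param t_trace Pointwise t statistics.
#' @param n Number of subjects (for the critical value).
#' @param cluster_alpha Two-sided cluster-forming alpha (default 0.05).
#' @param time Optional time grid for reporting.
#' @return Data.frame `start`, `end` (1-based sample indices, inclusive),
#'   `start_time`, `end_time`, `t_sum`; zero rows when nothing is
#'   supra-threshold. The critical t is attached as attribute
#'   `threshold_t`.
#' @export
form_clusters <- function(t_trace, n, cluster_alpha = 0.05, time = NULL) {
  thr <- stats::qt(1 - cluster_alpha / 2, n - 1)
  if (is.null(time)) time <- seq_along(t_trace)
  g <- integer(length(t_trace))
  g[t_trace > thr] <- 1L
  g[t_trace < -thr] <- -1L
  r <- rle(g)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0L
  out <- data.frame(start = starts[keep], end = ends[keep])
  out$start_time <- time[out$start]
  out$end_time <- time[out$end]
  out$t_sum <- vapply(seq_len(nrow(out)), function(i)
    sum(t_trace[out$start[i]:out$end[i]]), numeric(1))
  attr(out, "threshold_t") <- thr
  out
}

# max |T-sum| over clusters of one t trace; 0 when none
max_abs_tsum <- function(t_trace, thr) {
  g <- integer(length(t_trace))
  g[t_trace > thr] <- 1L
  g[t_trace < -thr] <- -1L
  if (all(g == 0L)) return(0)
  r <- rle(g)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values != 0L)
  max(vapply(keep, function(k)
    abs(sum(t_trace[starts[k]:ends[k]])), numeric(1)))
}

# all |T-sum|s of one t trace (for the pooled null)
all_abs_tsums <- function(t_trace, thr) {
  g <- integer(length(t_trace))
  g[t_trace > thr] <- 1L
  g[t_trace < -thr] <- -1L
  if (all(g == 0L)) return(numeric(0))
  r <- rle(g)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values != 0L)
  vapply(keep, function(k) abs(sum(t_trace[starts[k]:ends[k]])), numeric(1))
}

# sign matrix for exhaustive enumeration: 2^n x n of +/-1
exhaustive_signs <- function(n) {
  idx <- 0:(2^n - 1)
  m <- matrix(0L, length(idx), n)
  for (b in seq_len(n))
    m[, b] <- bitwAnd(idx, bitwShiftL(1L, b - 1L)) > 0
  1 - 2 * m
}

# t traces for many sign patterns at once: signs is P x n, d is n x T.
# colSums(d^2) is flip-invariant, so only the mean changes per pattern.
signflip_t_matrix <- function(signs, d) {
  n <- ncol(signs)
  ss <- colSums(d^2)
  m <- (signs %*% d) / n
  v <- sweep(-n * m^2, 2, ss, "+") / (n - 1)
  v[v < 1e-300] <- Inf   # zero-variance points contribute t = 0
  m / sqrt(v / n)
}

#' Paired cluster-based sign-flip permutation test
#'
#' Tests condition differences across an entire time course while
#' controlling the family-wise error over time. Observed clusters are
#' formed from the pointwise paired t trace at a two-sided
#' `cluster_alpha` threshold; the null distribution is built by randomly
#' flipping the sign of each subject's whole difference waveform and
#' recording, per permutation, the maximum |T-sum| over that
#' permutation's clusters (or, with `null = "pooled"`, every cluster's
#' |T-sum|). An observed cluster is significant when its |T-sum| exceeds
#' the null's 95th percentile; per-cluster p is the inclusive proportion
#' of null values >= its |T-sum|.
#'
#' For n <= 12 subjects `method = "exhaustive"` (or `"auto"`) enumerates
#' all 2^n sign patterns, making p exact and seed-free.
#'
#' @param set A [paired_trace_set()].
#' @param n_permutations Monte-Carlo permutations (default 10000).
#' @param alpha Family-wise alpha defining the percentile criterion
#'   (default 0.05).
#' @param cluster_alpha Cluster-forming two-sided alpha (default 0.05).
#' @param seed Integer seed for Monte-Carlo sampling.
#' @param method `"auto"` (exhaustive when n <= 12), `"montecarlo"`,
#'   `"exhaustive"`.
#' @param null `"max"` (default; family-wise max-cluster statistic) or
#'   `"pooled"` (all cluster |T-sums| pooled).
#' @return List of class `cluster_result`: `clusters` (data.frame with
#'   `p_value` and `significant` added), `pointwise_t`, `threshold_t`,
#'   `null_distribution`, `n_permutations`, `method`, `seed`.
#' @export
cluster_permutation_test <- function(set, n_permutations = 10000,
                                     alpha = 0.05, cluster_alpha = 0.05,
                                     seed = NULL,
                                     method = c("auto", "montecarlo",
                                                "exhaustive"),
                                     null = c("max", "pooled")) {
  method <- match.arg(method)
  null <- match.arg(null)
  stopifnot(inherits(set, "paired_trace_set"))
  d <- set$diff
  n <- set$n
  if (method == "auto") method <- if (n <= 12) "exhaustive" else "montecarlo"
  if (method == "exhaustive" && n > 20)
    stop("exhaustive enumeration is limited to n <= 20")
  if (method == "montecarlo" && n_permutations < 100)
    warning("fewer than 100 permutations: p-values will be coarse")

  t_obs <- pointwise_paired_t(set)
  thr <- stats::qt(1 - cluster_alpha / 2, n - 1)
  clusters <- form_clusters(t_obs, n, cluster_alpha, time = set$time)

  signs <- if (method == "exhaustive") {
    exhaustive_signs(n)
  } else {
    if (!is.null(seed)) set.seed(seed)
    matrix(sample(c(-1, 1), n_permutations * n, replace = TRUE),
           n_permutations, n)
  }
  tm <- signflip_t_matrix(signs, d)
  null_vals <- if (null == "max") {
    apply(tm, 1, max_abs_tsum, thr = thr)
  } else {
    unlist(apply(tm, 1, all_abs_tsums, thr = thr, simplify = FALSE),
           use.names = FALSE)
  }
  if (length(null_vals) == 0) null_vals <- 0
  crit <- stats::quantile(null_vals, 1 - alpha, names = FALSE)
  if (nrow(clusters) > 0) {
    clusters$p_value <- vapply(abs(clusters$t_sum), function(ts)
      mean(null_vals >= ts), numeric(1))
    clusters$significant <- abs(clusters$t_sum) > crit
  } else {
    clusters$p_value <- numeric(0)
    clusters$significant <- logical(0)
  }
  structure(list(clusters = clusters, pointwise_t = t_obs,
                 threshold_t = thr, null_distribution = null_vals,
                 critical_tsum = crit,
                 n_permutations = nrow(signs), method = method,
                 null = null, seed = seed),
            class = "cluster_result")
}
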