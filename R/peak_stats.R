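#' Peak latency of a phasic trace
#'
#' Time of the maximum value inside the search window; ties (plateaus)
#' break to the earliest occurrence. The default window is the post-cue
#' portion of the epoch.
#'
#' @param trace A `phasic_trace` (from [phasic()]) or a numeric vector.
#' @param time Time grid, seconds (ignored when `trace` carries its own).
#' @param search_window Two-element window, seconds (default c(0, 7)).
#' @return Latency in seconds.
#' @export
peak_latency <- function(trace, time = NULL, search_window = c(0, 7)) {
  if (inherits(trace, "phasic_trace")) {
    time <- trace$time
    trace <- trace$trace
  }
  sel <- which(time >= search_window[1] - 1e-9 &
               time <= search_window[2] + 1e-9)
  if (length(sel) == 0) stop("empty search window")
  time[sel[which.max(trace[sel])]]
}

#' Peak amplitude around a latency
#'
#' Mean of the trace over |t - latency| <= half_width, truncated at the
#' trace edges.
#'
#' @param trace A `phasic_trace` or numeric vector.
#' @param latency Seconds (typically from [peak_latency()]).
#' @param time Time grid (ignored when `trace` carries its own).
#' @param half_width Seconds (default 0.05, i.e. a +/- 50 ms window).
#' @return Mean amplitude over the window.
#' @export
peak_amplitude <- function(trace, latency, time = NULL, half_width = 0.05) {
  if (inherits(trace, "phasic_trace")) {
    time <- trace$time
    trace <- trace$trace
  }
  sel <- abs(time - latency) <= half_width + 1e-9
  if (!any(sel)) stop("window does not intersect the trace")
  mean(trace[sel])
}

#' Shapiro-Wilk normality gate
#'
#' Reports the Shapiro-Wilk W and p for a sample of subject-level scores.
#' The gate is advisory: the pipeline's inferential path is always the
#' sign-flip permutation tests; `use_parametric` only records whether a
#' parametric test would have been defensible (p >= 0.05). Constant
#' samples are flagged degenerate and force the nonparametric path.
#'
#' @param values Numeric sample, 3 <= n <= 5000.
#' @return List `W`, `p`, `use_parametric`, `degenerate`.
#' @export
shapiro_wilk_gate <- function(values) {
  n <- length(values)
  if (n < 3) stop("Shapiro-Wilk requires at least 3 observations")
  if (n > 5000) stop("Shapiro-Wilk is limited to 5000 observations")
  if (stats::sd(values) == 0)
    return(list(W = NA_real_, p = NA_real_, use_parametric = FALSE,
                degenerate = TRUE))
  sw <- stats::shapiro.test(values)
  list(W = unname(sw$statistic), p = sw$p.value,
       use_parametric = sw$p.value >= 0.05, degenerate = FALSE)
}

#' Sign-flip permutation test on a mean difference
#'
#' Tests whether the mean of per-subject difference scores differs from
#' zero under the symmetric null: each subject's score is multiplied by a
#' random +/-1 and the mean recomputed. The two-tailed p is the inclusive
#' proportion of permuted |means| >= the observed |mean| (so p is never
#' 0). For n <= 16 subjects, all 2^n sign patterns are enumerated
#' (`method = "auto"`), making p exact and seed-free.
#'
#' @param differences Per-subject difference scores.
#' @param n_permutations Monte-Carlo permutations (default 10000).
#' @param seed Integer seed for Monte-Carlo sampling.
#' @param method `"auto"` (exhaustive when n <= 16), `"montecarlo"`,
#'   `"exhaustive"`.
#' @return List of class `effect_test`: `observed`, `p`,
#'   `null_distribution`, `n_permutations`, `method`, `seed`.
#' @export
signflip_mean_test <- function(differences, n_permutations = 10000,
                               seed = NULL,
                               method = c("auto", "montecarlo",
                                          "exhaustive")) {
  method <- match.arg(method)
  n <- length(differences)
  if (n < 2) stop("at least 2 difference scores required")
  observed <- mean(differences)
  if (all(differences == 0))
    return(structure(list(observed = 0, p = 1, null_distribution = 0,
                          n_permutations = 0L, method = "degenerate",
                          seed = seed),
                     class = "effect_test"))
  if (method == "auto") method <- if (n <= 16) "exhaustive" else "montecarlo"
  if (method == "exhaustive" && n > 20)
    stop("exhaustive enumeration is limited to n <= 20")
  signs <- if (method == "exhaustive") {
    exhaustive_signs(n)
  } else {
    if (!is.null(seed)) set.seed(seed)
    matrix(sample(c(-1, 1), n_permutations * n, replace = TRUE),
           n_permutations, n)
  }
  null_means <- as.numeric(signs %*% differences) / n
  p <- mean(abs(null_means) >= abs(observed) - 1e-12)
  structure(list(observed = observed, p = p,
                 null_distribution = null_means,
                 n_permutations = nrow(signs), method = method,
                 seed = seed),
            class = "effect_test")
}

#' Sign-flip test on a difference-of-differences (interaction)
#'
#' Identical machinery to [signflip_mean_test()] applied to per-subject
#' interaction scores (A1 - A2) - (B1 - B2).
#'
#' @inheritParams signflip_mean_test
#' @param diff_of_diffs Per-subject difference-of-difference scores.
#' @return An `effect_test`.
#' @export
interaction_signflip_test <- function(diff_of_diffs, n_permutations = 10000,
                                      seed = NULL,
                                      method = c("auto", "montecarlo",
                                                 "exhaustive")) {
  signflip_mean_test(diff_of_diffs, n_permutations = n_permutations,
                     seed = seed, method = method)
}
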