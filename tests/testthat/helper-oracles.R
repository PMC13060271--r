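# Independent oracles and small fixtures used across test files.

# Brute-force within-subject ANOVA from the sums-of-squares definition:
# U(T) = sum over T-cells of (cell total)^2 / cell size, and
# SS(T) = sum_{W subset T} (-1)^{|T|-|W|} U(W) (Yates).  Each within
# effect is tested against its interaction with the subject factor.
oracle_rm_anova <- function(data, dv, within, subject) {
  data[[subject]] <- as.character(data[[subject]])
  for (v in within) data[[v]] <- as.character(data[[v]])
  y <- data[[dv]]
  N <- length(y)
  u_term <- function(facs) {
    if (length(facs) == 0) return(sum(y)^2 / N)
    key <- do.call(paste, c(data[facs], sep = "\r"))
    tot <- tapply(y, key, sum)
    cnt <- tapply(y, key, length)
    sum(tot^2 / cnt)
  }
  subsets <- function(x) {
    out <- list(character(0))
    for (el in x) out <- c(out, lapply(out, function(s) c(s, el)))
    out
  }
  ss_term <- function(facs) {
    s <- 0
    for (w in subsets(facs))
      s <- s + (-1)^(length(facs) - length(w)) * u_term(w)
    s
  }
  df_term <- function(facs) {
    if (length(facs) == 0) return(1)
    prod(vapply(facs, function(f) length(unique(data[[f]])) - 1, numeric(1)))
  }
  effects <- subsets(within)
  effects <- effects[lengths(effects) > 0]
  do.call(rbind, lapply(effects, function(e) {
    ss_e <- ss_term(e)
    ss_err <- ss_term(c(e, subject))
    df_e <- df_term(e)
    df_err <- df_term(c(e, subject))
    f <- (ss_e / df_e) / (ss_err / df_err)
    data.frame(effect = paste(e, collapse = ":"), df1 = df_e, df2 = df_err,
               F = f, p = stats::pf(f, df_e, df_err, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }))
}

# Kolmogorov distance between the ECDFs of two samples
ks_distance <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  max(abs(stats::ecdf(a)(grid) - stats::ecdf(b)(grid)))
}

# tiny deterministic design + schedule fixture
tiny_config <- function(...) design_config(n_trials = 16, n_blocks = 2, ...)

# low-rate pupil params for fast simulation (rate-agnostic generator;
# 50-60 Hz keeps the suite inside the runtime budget, as documented)
fast_pupil_params <- function(...) {
  defaults <- list(sampling_rate = 50, tonic_mean = 4000, tonic_sd = 300,
                   noise_sd = 40, noise_ar1 = 0.9, blink_rate = 0.1,
                   seed = 42L)
  args <- utils::modifyList(defaults, list(...))
  do.call(pupil_gen_params, args)
}

expect_between <- function(x, lo, hi) {
  expect_gte(x, lo)
  expect_lte(x, hi)
}
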