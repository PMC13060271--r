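#' Power-analysis specification
#'
#' Bundle of parameters for a prospective paired-sample t-test power
#' analysis: standardized effect size (Cohen's d on the within-subject
#' difference), significance level and target power.
#'
#' @param effect_size_d Cohen's d of the paired difference (> 0).
#' @param alpha Significance level, in (0, 1).
#' @param power Target power, in (0, 1); must exceed `alpha`.
#' @param tails `"two"` (default) or `"one"`.
#' @return An object of class `power_spec`.
#' @export
#' @examples
#' required_sample_size(power_spec(0.37))
power_spec <- function(effect_size_d, alpha = 0.05, power = 0.8,
                       tails = c("two", "one")) {
  tails <- match.arg(tails)
  if (!is.numeric(effect_size_d) || length(effect_size_d) != 1 ||
      is.na(effect_size_d) || effect_size_d < 0)
    stop("effect_size_d must be a single non-negative number")
  if (effect_size_d == 0)
    stop("undetectable effect: effect_size_d = 0")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (power <= 0 || power >= 1) stop("power must lie in (0, 1)")
  if (power <= alpha) stop("power must exceed alpha")
  structure(list(effect_size_d = effect_size_d, alpha = alpha,
                 power = power, tails = tails),
            class = "power_spec")
}

#' Power of a paired t-test at a given number of pairs
#'
#' Exact power from the noncentral-t distribution with noncentrality
#' d * sqrt(n) and df = n - 1.
#'
#' @param n Number of pairs (may be non-integer; n > 1).
#' @param spec A [power_spec()].
#' @return Power in (0, 1), vectorized over `n`.
#' @export
paired_t_power <- function(n, spec) {
  stopifnot(inherits(spec, "power_spec"))
  df <- n - 1
  ncp <- spec$effect_size_d * sqrt(n)
  if (spec$tails == "two") {
    tcrit <- stats::qt(1 - spec$alpha / 2, df)
    stats::pt(tcrit, df, ncp, lower.tail = FALSE) + stats::pt(-tcrit, df, ncp)
  } else {
    tcrit <- stats::qt(1 - spec$alpha, df)
    stats::pt(tcrit, df, ncp, lower.tail = FALSE)
  }
}

#' Required sample size for a paired t-test
#'
#' Solves the continuous noncentral-t power equation for the number of
#' pairs and rounds to the nearest whole participant.
#'
#' @param spec A [power_spec()].
#' @return Integer sample size.
#' @export
required_sample_size <- function(spec) {
  stopifnot(inherits(spec, "power_spec"))
  f <- function(n) paired_t_power(n, spec) - spec$power
  upper <- 4
  while (f(upper) < 0 && upper < 1e7) upper <- upper * 2
  if (f(upper) < 0) stop("required sample size exceeds search bound")
  n_cont <- stats::uniroot(f, c(1 + 1e-6, upper), tol = 1e-8)$root
  as.integer(round(n_cont))
}

#' Experiment design configuration
#'
#' Trial/block structure and stimulus-timing constants for the interleaved
#' two-stream syllable paradigm. Defaults follow the main experiment:
#' 160 trials in 8 blocks of 20, 450 ms syllables separated by 150 ms of
#' silence (600 ms within-stream onset-to-onset), the leading stream
#' starting 500 ms after the cue ends and the lagging stream 300 ms later,
#' and a 250 ms interrupter starting 125 ms before the onset of the 2nd
#' target syllable on interrupted trials. The cue is a single syllable, so
#' its duration defaults to one syllable duration.
#'
#' @param n_trials Total trial count.
#' @param n_blocks Number of blocks; `n_trials` must divide evenly.
#' @param blocking_mode `"by_room"`: the room is constant within a block and
#'   alternates across blocks, interruption counterbalanced within block;
#'   `"by_interruption"`: interruption is constant within a block (alternating
#'   across blocks) and the two rooms are intermingled and counterbalanced
#'   within each block.
#' @param syllables_per_stream Syllables per stream (>= 2).
#' @param syllable_duration,intersyllable_gap,lead_onset_after_cue,stream_lag
#'   Timing constants, seconds.
#' @param interrupter_duration Interrupter duration, seconds.
#' @param interrupter_lead Seconds before the 2nd target-syllable onset at
#'   which the interrupter starts.
#' @param cue_duration Cue duration, seconds.
#' @param leading_side Side of the leading stream (between-subject factor).
#' @param seed Integer seed controlling trial-order shuffles and syllable
#'   draws.
#' @return An object of class `design_config`.
#' @export
design_config <- function(n_trials = 160, n_blocks = 8,
                          blocking_mode = c("by_room", "by_interruption"),
                          syllables_per_stream = 4,
                          syllable_duration = 0.45,
                          intersyllable_gap = 0.15,
                          lead_onset_after_cue = 0.5,
                          stream_lag = 0.3,
                          interrupter_duration = 0.25,
                          interrupter_lead = 0.125,
                          cue_duration = 0.45,
                          leading_side = c("left", "right"),
                          seed = 1L) {
  blocking_mode <- match.arg(blocking_mode)
  leading_side <- match.arg(leading_side)
  if (n_trials %% n_blocks != 0) stop("n_trials must be divisible by n_blocks")
  if (syllables_per_stream < 2) stop("syllables_per_stream must be >= 2")
  durs <- c(syllable_duration, intersyllable_gap, lead_onset_after_cue,
            stream_lag, interrupter_duration, interrupter_lead, cue_duration)
  if (any(durs <= 0)) stop("all durations must be > 0")
  structure(list(n_trials = as.integer(n_trials),
                 n_blocks = as.integer(n_blocks),
                 blocking_mode = blocking_mode,
                 syllables_per_stream = as.integer(syllables_per_stream),
                 syllable_duration = syllable_duration,
                 intersyllable_gap = intersyllable_gap,
                 lead_onset_after_cue = lead_onset_after_cue,
                 stream_lag = stream_lag,
                 interrupter_duration = interrupter_duration,
                 interrupter_lead = interrupter_lead,
                 cue_duration = cue_duration,
                 leading_side = leading_side,
                 seed = as.integer(seed)),
            class = "design_config")
}

SYLLABLE_SET <- c("ba", "da", "ga")

# balanced factor assignments for one block; crossed when counts allow
block_factors <- function(tpb, f1, f2) {
  if (tpb %% 2 != 0) stop("odd trials-per-block: cannot counterbalance")
  if (tpb %% 4 == 0) {
    g <- expand.grid(a = f1, b = f2, KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)
    idx <- rep(seq_len(4), each = tpb / 4)
    data.frame(a = g$a[idx], b = g$b[idx], stringsAsFactors = FALSE)
  } else {
    # marginal balance only (joint crossing impossible)
    data.frame(a = rep(f1, length.out = tpb),
               b = rep(f2, each = tpb / 2),
               stringsAsFactors = FALSE)
  }
}

#' Build a counterbalanced trial sequence
#'
#' Generates the full trial list for one subject: per-block exact
#' counterbalancing of the within-block factors, alternating block-constant
#' factor across blocks, per-block shuffling, balanced target-leading
#' assignment, and target syllable sequences drawn uniformly with
#' replacement from \{ba, da, ga\}.
#'
#' @param config A [design_config()].
#' @return A data.frame with one row per trial: `trial` (0-based),
#'   `block` (0-based), `room`, `interrupted`, `target_side`,
#'   `target_leading`, `target_syllables` (hyphen-separated labels).
#' @export
build_design <- function(config) {
  stopifnot(inherits(config, "design_config"))
  tpb <- config$n_trials / config$n_blocks
  if (tpb %% 2 != 0) stop("odd trials-per-block: cannot counterbalance")
  set.seed(config$seed)
  rooms <- c("anechoic", "reverberant")
  blocks <- lapply(seq_len(config$n_blocks), function(b) {
    if (config$blocking_mode == "by_room") {
      fac <- block_factors(tpb, c(TRUE, FALSE), c("left", "right"))
      df <- data.frame(room = rooms[(b - 1) %% 2 + 1],
                       interrupted = fac$a, target_side = fac$b,
                       stringsAsFactors = FALSE)
    } else {
      fac <- block_factors(tpb, rooms, c("left", "right"))
      df <- data.frame(room = fac$a,
                       interrupted = c(TRUE, FALSE)[(b - 1) %% 2 + 1],
                       target_side = fac$b, stringsAsFactors = FALSE)
    }
    df$target_leading <- sample(rep(c(TRUE, FALSE), length.out = tpb))
    df <- df[sample.int(tpb), , drop = FALSE]
    df$block <- b - 1L
    df
  })
  out <- do.call(rbind, blocks)
  out$trial <- seq_len(nrow(out)) - 1L
  out$target_syllables <- vapply(seq_len(nrow(out)), function(i)
    paste(sample(SYLLABLE_SET, config$syllables_per_stream, replace = TRUE),
          collapse = "-"), character(1))
  rownames(out) <- NULL
  out[, c("trial", "block", "room", "interrupted", "target_side",
          "target_leading", "target_syllables")]
}

#' Stimulus event schedule for one trial
#'
#' Computes absolute event onsets with t = 0 at cue onset. The leading
#' stream starts `lead_onset_after_cue` seconds after the cue ends; the
#' lagging stream starts `stream_lag` seconds later; within-stream onsets
#' are spaced `syllable_duration + intersyllable_gap`. On interrupted
#' trials the interrupter starts `interrupter_lead` seconds before the 2nd
#' target-syllable onset.
#'
#' @param trial One row of [build_design()] output (data.frame or list).
#' @param config A [design_config()].
#' @return A list of class `stimulus_schedule`: `cue_onset` (0),
#'   `cue_offset_time`, `target_onsets`, `distractor_onsets`,
#'   `interrupter_onset` (NA when uninterrupted).
#' @export
build_schedule <- function(trial, config) {
  stopifnot(inherits(config, "design_config"))
  k <- config$syllables_per_stream
  soa <- config$syllable_duration + config$intersyllable_gap
  cue_end <- config$cue_duration
  lead <- cue_end + config$lead_onset_after_cue + soa * (0:(k - 1))
  lag <- lead + config$stream_lag
  target_leading <- isTRUE(trial$target_leading)
  target <- if (target_leading) lead else lag
  distractor <- if (target_leading) lag else lead
  interrupter <- NA_real_
  if (isTRUE(trial$interrupted)) {
    interrupter <- target[2] - config$interrupter_lead
    if (interrupter <= 0)
      stop("interrupter precedes recording window")
  }
  structure(list(cue_onset = 0, cue_offset_time = cue_end,
                 target_onsets = target, distractor_onsets = distractor,
                 interrupter_onset = interrupter),
            class = "stimulus_schedule")
}

#' Write / read a design table
#'
#' Tabular text representation (CSV, 0-based trial indexing) with per-trial
#' event onsets in seconds appended from [build_schedule()].
#'
#' @param design Output of [build_design()].
#' @param config The matching [design_config()].
#' @param path File path.
#' @return `write_design()` returns `path` invisibly; `read_design()` the
#'   data.frame.
#' @export
write_design <- function(design, config, path) {
  sched <- lapply(seq_len(nrow(design)), function(i)
    build_schedule(design[i, ], config))
  design$target_onsets <- vapply(sched, function(s)
    paste(s$target_onsets, collapse = ";"), character(1))
  design$distractor_onsets <- vapply(sched, function(s)
    paste(s$distractor_onsets, collapse = ";"), character(1))
  design$interrupter_onset <- vapply(sched, function(s)
    s$interrupter_onset, numeric(1))
  utils::write.csv(design, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
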