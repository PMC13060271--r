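#' Pipeline run configuration
#'
#' Collects every tunable of the end-to-end workflow with the package
#' defaults (which mirror the experiment's stated parameters), validates
#' them against the owning modules' constraints, and returns a plain
#' list. Any subset of fields can be overridden.
#'
#' @param ... Named overrides; see Details for the field list.
#' @details Fields: `n_subjects`, `out_dir`, `design` (a
#'   [design_config()]), `pupil` (a [pupil_gen_params()]), `behavior` (a
#'   [behavior_gen_params()]), `pre_pad`, `post_pad`, `filter_order`,
#'   `filter_cutoff`, `epoch_window`, `baseline_window`,
#'   `exclusion_threshold`, `baseline_mode`, `n_permutations`, `alpha`,
#'   `cluster_alpha`, `cluster_null`, `peak_window`, `peak_half_width`,
#'   `seed`.
#' @return List of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(n_subjects = 5L, out_dir = ".",
              design = design_config(), pupil = pupil_gen_params(),
              behavior = behavior_gen_params(),
              pre_pad = 0.05, post_pad = 0.15,
              filter_order = 4, filter_cutoff = 10,
              epoch_window = c(-1, 7), baseline_window = c(-0.5, 0),
              exclusion_threshold = 0.5, baseline_mode = "zscore",
              n_permutations = 10000, alpha = 0.05, cluster_alpha = 0.05,
              cluster_null = "max", peak_window = c(0, 7),
              peak_half_width = 0.05, seed = 1L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0)
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  stopifnot(cfg$exclusion_threshold > 0, cfg$alpha > 0, cfg$alpha < 1,
            cfg$cluster_alpha > 0, cfg$cluster_alpha < 1,
            cfg$filter_cutoff < cfg$pupil$sampling_rate / 2,
            diff(cfg$epoch_window) > 0,
            cfg$baseline_window[1] >= cfg$epoch_window[1],
            cfg$baseline_window[2] <= cfg$epoch_window[2])
  class(cfg) <- "run_config"
  cfg
}

# stable md5 of the serializable part of a config (no digest dependency)
config_hash <- function(cfg) {
  ser <- jsonlite::toJSON(lapply(unclass(cfg), function(x)
    if (is.list(x)) unclass(x) else x), auto_unbox = TRUE, digits = 12)
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(ser, tf)
  unname(tools::md5sum(tf))
}

#' Preprocess one subject's recording
#'
#' Whole-recording missing fraction (pre-interpolation), blink
#' interpolation, zero-phase lowpass, epoching around cue onsets, baseline
#' statistics, and condition-averaged phasic traces for the four
#' room-by-interruption cells.
#'
#' @param series A [sample_series()].
#' @param events Data.frame `trial`, `cue_onset_s`, `room`, `interrupted`.
#' @param config A [run_config()].
#' @return List: `missing_fraction`, `baseline`, `phasic` (named list of
#'   `phasic_trace`s keyed "room.interrupted"), `tonic_by_room`,
#'   `epoch_time`.
#' @export
preprocess_subject <- function(series, events, config = run_config()) {
  missing_fraction <- mean(!series$valid)
  clean <- interpolate_blinks(series, config$pre_pad, config$post_pad)
  filt <- lowpass(clean, config$filter_order, config$filter_cutoff)
  labels <- events[, c("room", "interrupted")]
  ep <- epoch_series(filt, events$cue_onset_s, config$epoch_window, labels)
  bl <- baseline_stats(ep, config$baseline_window)
  cond <- interaction(events$room, events$interrupted, drop = TRUE)
  ph <- phasic(ep, bl, mode = config$baseline_mode, condition = cond)
  tonic_by_room <- tapply(bl$per_trial_baseline, events$room, mean)
  list(missing_fraction = missing_fraction, baseline = bl, phasic = ph,
       tonic_by_room = tonic_by_room, epoch_time = ep$epoch_time)
}

# subjects x time matrix of one condition's phasic traces
phasic_matrix <- function(pre_list, condition) {
  do.call(rbind, lapply(pre_list, function(p) p$phasic[[condition]]$trace))
}

#' Run the full statistical analysis on preprocessed subjects
#'
#' Applies the exclusion rule, then runs the cluster-based permutation
#' tests (interrupted vs uninterrupted within each room), extracts peak
#' latency and amplitude per subject and condition, runs the sign-flip
#' permutation tests (interruption and room main effects and their
#' interaction, on both peak measures), and, when behavioral responses
#' are supplied, scores recall and runs the accuracy ANOVA, interruption
#' effect and Bonferroni post-hocs.
#'
#' @param pre_list Named list of [preprocess_subject()] results.
#' @param behavior Optional data.frame `subject`, `trial`, `position`,
#'   `target`, `response`.
#' @param designs Optional data.frame `subject`, `trial`, `room`,
#'   `interrupted` (required when `behavior` is given).
#' @param config A [run_config()].
#' @return List with `qc`, `clusters`, `peaks`, `effect_tests`,
#'   `tonic_test`, `behavior` (NULL unless responses supplied), `config`.
#' @export
analyze_cohort <- function(pre_list, behavior = NULL, designs = NULL,
                           config = run_config()) {
  qc <- exclude_high_missing(
    vapply(pre_list, function(p) p$missing_fraction, numeric(1)),
    config$exclusion_threshold)
  keep <- qc$subject[!qc$excluded]
  if (length(keep) < 2) stop("fewer than 2 subjects survive exclusion")
  pre <- pre_list[keep]
  tt <- pre[[1]]$epoch_time

  conds <- c(anechoic_un = "anechoic.FALSE", anechoic_int = "anechoic.TRUE",
             reverberant_un = "reverberant.FALSE",
             reverberant_int = "reverberant.TRUE")
  mats <- lapply(conds, phasic_matrix, pre_list = pre)

  seed <- config$seed
  clusters <- list(
    anechoic = cluster_permutation_test(
      paired_trace_set(mats$anechoic_int, mats$anechoic_un, tt),
      n_permutations = config$n_permutations, alpha = config$alpha,
      cluster_alpha = config$cluster_alpha, seed = seed + 11L,
      null = config$cluster_null),
    reverberant = cluster_permutation_test(
      paired_trace_set(mats$reverberant_int, mats$reverberant_un, tt),
      n_permutations = config$n_permutations, alpha = config$alpha,
      cluster_alpha = config$cluster_alpha, seed = seed + 12L,
      null = config$cluster_null))

  peaks <- do.call(rbind, lapply(names(conds), function(nm) {
    m <- mats[[nm]]
    lat <- apply(m, 1, function(tr)
      peak_latency(tr, tt, config$peak_window))
    amp <- vapply(seq_len(nrow(m)), function(i)
      peak_amplitude(m[i, ], lat[i], tt, config$peak_half_width),
      numeric(1))
    data.frame(subject = keep, condition = nm, latency_s = lat,
               amplitude = amp, stringsAsFactors = FALSE)
  }))

  wide <- function(measure) {
    sapply(names(conds), function(nm)
      peaks[peaks$condition == nm, measure])
  }
  effect_tests <- list()
  for (measure in c("amplitude", "latency_s")) {
    w <- wide(measure)
    d_int <- (w[, "anechoic_int"] + w[, "reverberant_int"]) / 2 -
             (w[, "anechoic_un"] + w[, "reverberant_un"]) / 2
    d_room <- (w[, "anechoic_int"] + w[, "anechoic_un"]) / 2 -
              (w[, "reverberant_int"] + w[, "reverberant_un"]) / 2
    d_inter <- (w[, "anechoic_int"] - w[, "anechoic_un"]) -
               (w[, "reverberant_int"] - w[, "reverberant_un"])
    effect_tests[[measure]] <- list(
      normality = shapiro_wilk_gate(d_int),
      interruption = signflip_mean_test(
        d_int, config$n_permutations, seed = seed + 21L),
      room = signflip_mean_test(
        d_room, config$n_permutations, seed = seed + 22L),
      interaction = interaction_signflip_test(
        d_inter, config$n_permutations, seed = seed + 23L))
  }

  tonic <- t(vapply(pre, function(p) p$tonic_by_room, numeric(2)))
  tonic_test <- if (ncol(tonic) == 2 && nrow(tonic) >= 2 &&
                    stats::sd(tonic[, 1] - tonic[, 2]) > 0)
    stats::t.test(tonic[, 1], tonic[, 2], paired = TRUE) else NULL

  beh <- NULL
  if (!is.null(behavior)) {
    if (is.null(designs)) stop("behavior requires per-subject designs")
    behavior <- behavior[behavior$subject %in% keep, ]
    designs <- designs[designs$subject %in% keep, ]
    acc <- accuracy_table(behavior, designs)
    anova <- rm_anova(acc)
    eff <- interruption_effect(acc)
    eff_by_pos <- sapply(sort(unique(eff$position)), function(p)
      tapply(eff$effect[eff$position == p], eff$subject[eff$position == p],
             mean)[keep])
    combs <- utils::combn(ncol(eff_by_pos), 2)
    pairs <- stats::setNames(
      lapply(seq_len(ncol(combs)), function(k)
        list(x = eff_by_pos[, combs[1, k]], y = eff_by_pos[, combs[2, k]])),
      apply(combs, 2, function(ij)
        paste0("pos", ij[1], "_vs_pos", ij[2])))
    beh <- list(accuracy = acc, anova = anova,
                interruption_effect = eff,
                effect_by_position = colMeans(eff_by_pos),
                posthoc = posthoc_paired(pairs, config$alpha))
  }

  list(qc = qc, clusters = clusters, peaks = peaks,
       effect_tests = effect_tests, tonic_test = tonic_test,
       behavior = beh, config = config)
}

#' Simulate a cohort and write it to disk
#'
#' Writes one design CSV (all subjects stacked), per-subject sample and
#' event CSVs, a pooled behavioral response CSV, and a `manifest.json`
#' recording the file list, root seed and config hash. Deterministic
#' given the config seed.
#'
#' @param config A [run_config()].
#' @return The manifest, invisibly.
#' @export
run_simulate <- function(config = run_config()) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(config$out_dir, 2) != 0)
    stop("output directory is not writable: ", config$out_dir)
  if (config$n_subjects == 0) {
    warning("n_subjects = 0: writing an empty manifest")
    manifest <- list(files = character(0), seed = config$seed,
                     config_hash = config_hash(config))
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    return(invisible(manifest))
  }
  cohort <- simulate_cohort(config$n_subjects, config$design,
                            config$pupil, config$behavior,
                            seed = config$seed)
  files <- character(0)
  designs <- list(); responses <- list()
  for (s in names(cohort)) {
    f_samp <- file.path(config$out_dir, paste0("samples_", s, ".csv"))
    f_ev <- file.path(config$out_dir, paste0("events_", s, ".csv"))
    write_sample_series(cohort[[s]]$series, f_samp)
    utils::write.csv(cohort[[s]]$events, f_ev, row.names = FALSE)
    files <- c(files, f_samp, f_ev)
    d <- cohort[[s]]$design; d$subject <- s
    designs[[s]] <- d
    if (!is.null(cohort[[s]]$behavior)) {
      b <- cohort[[s]]$behavior; b$subject <- s
      responses[[s]] <- b
    }
  }
  f_design <- file.path(config$out_dir, "design.csv")
  utils::write.csv(do.call(rbind, designs), f_design, row.names = FALSE)
  files <- c(files, f_design)
  if (length(responses) > 0) {
    f_resp <- file.path(config$out_dir, "responses.csv")
    utils::write.csv(do.call(rbind, responses), f_resp, row.names = FALSE)
    files <- c(files, f_resp)
  }
  manifest <- list(files = basename(files), seed = config$seed,
                   n_subjects = config$n_subjects,
                   config_hash = config_hash(config))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Analyze a simulated (or recorded) cohort from disk
#'
#' Reads the files written by [run_simulate()] (or equivalently formatted
#' recordings), preprocesses every subject, runs [analyze_cohort()], and
#' writes the result tables: `qc.json`, `clusters.csv`, `peaks.csv`,
#' `effect_tests.json`, `accuracy.csv`, `anova.csv`, `posthoc.csv`, plus
#' `analysis_manifest.json` with the seed and config hash.
#'
#' @param config A [run_config()] whose `out_dir` holds the input files.
#' @return The [analyze_cohort()] result, invisibly.
#' @export
run_analyze <- function(config = run_config()) {
  dirp <- config$out_dir
  manifest <- jsonlite::read_json(file.path(dirp, "manifest.json"))
  subjects <- sort(unique(sub("^samples_(.*)\\.csv$", "\\1",
                              grep("^samples_", unlist(manifest$files),
                                   value = TRUE))))
  if (length(subjects) == 0) stop("no subject sample files in manifest")
  fs <- config$pupil$sampling_rate
  pre_list <- lapply(stats::setNames(subjects, subjects), function(s) {
    series <- read_sample_series(
      file.path(dirp, paste0("samples_", s, ".csv")), sampling_rate = fs)
    events <- utils::read.csv(file.path(dirp, paste0("events_", s, ".csv")))
    tryCatch(preprocess_subject(series, events, config),
             error = function(e)
               stop("preprocess failed for subject ", s, ": ",
                    conditionMessage(e)))
  })
  behavior <- NULL; designs <- NULL
  f_resp <- file.path(dirp, "responses.csv")
  if (file.exists(f_resp)) {
    behavior <- utils::read.csv(f_resp, stringsAsFactors = FALSE)
    designs <- utils::read.csv(file.path(dirp, "design.csv"),
                               stringsAsFactors = FALSE)
  }
  res <- analyze_cohort(pre_list, behavior, designs, config)

  jsonlite::write_json(res$qc, file.path(dirp, "qc.json"),
                       auto_unbox = TRUE, pretty = TRUE, dataframe = "rows")
  cl <- do.call(rbind, lapply(names(res$clusters), function(room) {
    cc <- res$clusters[[room]]$clusters
    if (nrow(cc) == 0) return(NULL)
    cbind(room = room, cc[, c("start_time", "end_time", "t_sum",
                              "p_value", "significant")])
  }))
  if (is.null(cl))
    cl <- data.frame(room = character(0), start_time = numeric(0),
                     end_time = numeric(0), t_sum = numeric(0),
                     p_value = numeric(0), significant = logical(0))
  utils::write.csv(cl, file.path(dirp, "clusters.csv"), row.names = FALSE)
  utils::write.csv(res$peaks, file.path(dirp, "peaks.csv"),
                   row.names = FALSE)
  et <- lapply(res$effect_tests, function(msr)
    lapply(msr[c("interruption", "room", "interaction")], function(e)
      list(observed = e$observed, p = e$p,
           n_permutations = e$n_permutations)))
  jsonlite::write_json(et, file.path(dirp, "effect_tests.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(res$behavior)) {
    utils::write.csv(res$behavior$accuracy,
                     file.path(dirp, "accuracy.csv"), row.names = FALSE)
    utils::write.csv(res$behavior$anova, file.path(dirp, "anova.csv"),
                     row.names = FALSE)
    utils::write.csv(res$behavior$posthoc, file.path(dirp, "posthoc.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(list(seed = config$seed,
                            config_hash = config_hash(config),
                            excluded = res$qc$subject[res$qc$excluded]),
                       file.path(dirp, "analysis_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(res)
}
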