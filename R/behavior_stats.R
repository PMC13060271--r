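#' Score one trial of serial recall
#'
#' Strict positional matching: position i is correct iff the response at
#' position i equals the target at position i.
#'
#' @param targets,response Character vectors of syllable labels, equal
#'   length.
#' @return Logical vector per position.
#' @export
score_recall <- function(targets, response) {
  if (length(targets) != length(response))
    stop("targets and response must have equal length")
  targets == response
}

#' Subject x room x interruption x position accuracy table
#'
#' Joins scored responses with the trial design and averages correctness
#' over trials within each cell.
#'
#' @param responses Data.frame with columns `subject`, `trial`, `position`
#'   and either `correct` (0/1) or both `target` and `response`.
#' @param design Data.frame with columns `trial`, `room`, `interrupted`
#'   (a shared design), or `subject`, `trial`, `room`, `interrupted` for
#'   per-subject designs.
#' @return Data.frame `subject`, `room`, `interrupted`, `position`,
#'   `n_trials`, `accuracy`, one row per populated cell; errors if a cell
#'   of the full crossing is empty.
#' @export
accuracy_table <- function(responses, design) {
  if (!"correct" %in% names(responses))
    responses$correct <- as.integer(score_recall(responses$target,
                                                 responses$response))
  by_subject_design <- "subject" %in% names(design)
  keys <- if (by_subject_design) c("subject", "trial") else "trial"
  merged <- merge(responses,
                  design[, c(keys, "room", "interrupted"), drop = FALSE],
                  by = keys)
  if (nrow(merged) != nrow(responses))
    stop("some responses have no matching design trial")
  agg <- stats::aggregate(correct ~ subject + room + interrupted + position,
                          data = merged,
                          FUN = function(x) c(n = length(x), acc = mean(x)))
  out <- data.frame(subject = agg$subject, room = agg$room,
                    interrupted = agg$interrupted, position = agg$position,
                    n_trials = agg$correct[, "n"],
                    accuracy = agg$correct[, "acc"],
                    stringsAsFactors = FALSE)
  full <- expand.grid(subject = unique(responses$subject),
                      room = unique(design$room),
                      interrupted = unique(design$interrupted),
                      position = unique(responses$position),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  miss <- merge(full, out, all.x = TRUE)
  if (any(is.na(miss$accuracy))) {
    bad <- miss[is.na(miss$accuracy), c("subject", "room", "interrupted",
                                        "position")]
    stop("empty design cells: ",
         paste(apply(bad, 1, paste, collapse = "/"), collapse = "; "))
  }
  out <- out[order(out$subject, out$room, out$interrupted, out$position), ]
  rownames(out) <- NULL
  out
}

#' Interruption effect (uninterrupted minus interrupted accuracy)
#'
#' @param table An [accuracy_table()] result containing both interruption
#'   levels.
#' @return Data.frame `subject`, `room`, `position`, `effect` with
#'   effect = accuracy(uninterrupted) - accuracy(interrupted).
#' @export
interruption_effect <- function(table) {
  if (length(unique(table$interrupted)) != 2)
    stop("both interruption levels are required")
  un <- table[!table$interrupted, ]
  it <- table[table$interrupted, ]
  m <- merge(un, it, by = c("subject", "room", "position"),
             suffixes = c("_un", "_int"))
  out <- data.frame(subject = m$subject, room = m$room,
                    position = m$position,
                    effect = m$accuracy_un - m$accuracy_int,
                    stringsAsFactors = FALSE)
  out[order(out$subject, out$room, out$position), ]
}

#' Repeated-measures ANOVA on a fully-within design
#'
#' Classical univariate within-subject ANOVA (subject as random blocking
#' factor): each effect is tested against its effect-by-subject
#' interaction mean square. No sphericity correction is applied and
#' uncorrected degrees of freedom are reported.
#'
#' @param data Long-format data.frame.
#' @param dv Name of the dependent-variable column.
#' @param within Character vector of within-subject factor column names.
#' @param subject Name of the subject column.
#' @return Data.frame `effect`, `df1`, `df2`, `F`, `p`.
#' @export
rm_anova <- function(data, dv = "accuracy",
                     within = c("interrupted", "room", "position"),
                     subject = "subject") {
  for (v in c(within, subject)) data[[v]] <- factor(data[[v]])
  counts <- table(data[, c(subject, within)])
  if (any(counts != 1))
    stop("incomplete within-subject design: every subject needs exactly ",
         "one value per factor-level combination")
  if (nlevels(data[[subject]]) < 2) stop("at least 2 subjects required")
  rhs <- paste(within, collapse = " * ")
  fml <- stats::as.formula(paste0(dv, " ~ ", rhs, " + Error(", subject,
                                  "/(", rhs, "))"))
  fit <- stats::aov(fml, data = data)
  smry <- summary(fit)
  rows <- list()
  for (stratum in smry) {
    tab <- stratum[[1]]
    terms <- trimws(rownames(tab))
    resid <- terms == "Residuals"
    for (i in which(!resid)) {
      rows[[length(rows) + 1]] <- data.frame(
        effect = terms[i],
        df1 = tab$Df[i],
        df2 = tab$Df[resid],
        F = tab$`F value`[i],
        p = tab$`Pr(>F)`[i],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bonferroni-corrected paired t-test post-hocs
#'
#' @param pairs Named list; each element a list/data.frame with numeric
#'   vectors `x` and `y` of paired observations.
#' @param alpha Family-wise alpha (default 0.05).
#' @return Data.frame `comparison`, `mean_diff`, `t`, `df`, `p`, `p_adj`
#'   (Bonferroni: min(1, m * p)), `significant`.
#' @export
posthoc_paired <- function(pairs, alpha = 0.05) {
  m <- length(pairs)
  rows <- lapply(names(pairs), function(nm) {
    x <- pairs[[nm]]$x; y <- pairs[[nm]]$y
    if (length(x) != length(y) || length(x) < 2)
      stop("comparison '", nm, "' needs >= 2 complete pairs")
    d <- x - y
    if (stats::sd(d) == 0) {
      tstat <- 0; p <- 1
    } else {
      tt <- stats::t.test(x, y, paired = TRUE)
      tstat <- unname(tt$statistic); p <- tt$p.value
    }
    data.frame(comparison = nm, mean_diff = mean(d), t = tstat,
               df = length(x) - 1, p = p,
               p_adj = min(1, m * p), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$significant <- out$p_adj < alpha
  rownames(out) <- NULL
  out
}
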