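# Performance metrics: selection timing, Wolpaw ITR, Wilson intervals,
# bootstrap group intervals, signed-r2, AUC, and the session-level report.

#' Trial duration (selection time)
#'
#' `T = (Ns - 1) * SOA + Tmax`: the onset-to-onset span of the `Ns` stimuli
#' plus the epoch length needed to classify the last one. The standard
#' online setting (450 stimuli, SOA 0.2 s, Tmax 1.0 s) gives 90.8 s.
#'
#' @param nStimuli number of presented stimuli `Ns`.
#' @param soaS stimulus-onset asynchrony (s).
#' @param epochLenS classifier epoch length `Tmax` (s).
#' @return duration in seconds.
#' @examples
#' trialDuration(450, 0.2, 1.0)  # 90.8
#' @export
trialDuration <- function(nStimuli, soaS, epochLenS) {
  .check(all(nStimuli >= 1), "nStimuli must be >= 1")
  (nStimuli - 1) * soaS + epochLenS
}

#' Information per selection (bits/trial, Wolpaw)
#'
#' `R = log2 N + P log2 P + (1 - P) log2((1 - P)/(N - 1))`, with the
#' `x log2 x -> 0` limits at P = 0 and P = 1. At chance (P = 1/N) this is 0;
#' at P = 1 it is `log2 N`.
#'
#' @param nClasses number of classes N (>= 2).
#' @param pCorrect selection accuracy P in `[0, 1]` (vectorised).
#' @return bits per trial.
#' @examples
#' itrBitsPerTrial(30, 1)        # log2(30) ~ 4.907
#' itrBitsPerTrial(30, 13 / 15)  # ~ 3.692
#' @export
itrBitsPerTrial <- function(nClasses, pCorrect) {
  .check(nClasses >= 2, "need at least 2 classes")
  .check(all(pCorrect >= 0 & pCorrect <= 1), "P must be in [0, 1]")
  xlog2 <- function(x) ifelse(x > 0, x * log2(x), 0)
  log2(nClasses) + xlog2(pCorrect) +
    ifelse(pCorrect < 1,
           (1 - pCorrect) * log2((1 - pCorrect) / (nClasses - 1)),
           0)
}

#' Information transfer rate (bits/min)
#'
#' `B = R * 60 / T` for a selection time of `T` seconds.
#'
#' @param bitsPerTrial R from [itrBitsPerTrial()].
#' @param durationS selection time T (s).
#' @return bits per minute.
#' @examples
#' itrBitsPerMin(itrBitsPerTrial(30, 1), 90.8)  # ~ 3.24
#' @export
itrBitsPerMin <- function(bitsPerTrial, durationS) {
  .check(all(durationS > 0), "duration must be positive")
  bitsPerTrial * 60 / durationS
}

#' Wilson score interval for a binomial proportion
#'
#' @param k number of successes.
#' @param n number of trials (>= 1).
#' @param level confidence level (default 0.95).
#' @return named numeric `c(lower, upper)`.
#' @examples
#' wilsonInterval(15, 15)  # lower ~ 0.796
#' @export
wilsonInterval <- function(k, n, level = 0.95) {
  .check(n >= 1 && k >= 0 && k <= n, "need 0 <= k <= n, n >= 1")
  z <- qnorm((1 + level) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

#' Convert an accuracy confidence interval to an ITR interval
#'
#' Applies the Wolpaw formulas to the (full-precision) Wilson bounds of
#' `k/n`, giving the ITR confidence interval.
#'
#' @param k,n successes and trials.
#' @param nClasses number of classes N.
#' @param durationS selection time T (s).
#' @param level confidence level (default 0.95).
#' @return named numeric `c(lower, upper)` in bits/min.
#' @examples
#' accuracyCiToItrCi(15, 15, 30, 90.8)  # ~ (2.11, 3.24)
#' @export
accuracyCiToItrCi <- function(k, n, nClasses, durationS, level = 0.95) {
  ci <- wilsonInterval(k, n, level)
  out <- itrBitsPerMin(itrBitsPerTrial(nClasses, ci), durationS)
  names(out) <- c("lower", "upper")
  out
}

#' Percentile bootstrap CI for a mean
#'
#' Participant-level percentile bootstrap: resamples the values with
#' replacement `nBoot` times and returns the percentile bounds of the
#' resampled means. Deterministic under `seed`.
#'
#' @param values numeric vector (>= 1 value).
#' @param nBoot bootstrap iterations (default 10000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed.
#' @return named numeric `c(lower, upper)`.
#' @export
bootstrapMeanCi <- function(values, nBoot = 10000L, level = 0.95,
                            seed = NULL) {
  .check(length(values) >= 1, "empty input")
  means <- withSeed(seed, {
    n <- length(values)
    vapply(seq_len(nBoot), function(i)
      mean(values[sample.int(n, n, replace = TRUE)]), 0)
  })
  q <- quantile(means, c((1 - level) / 2, (1 + level) / 2), names = FALSE)
  c(lower = q[1], upper = q[2])
}

#' Signed r-squared separability index
#'
#' Signed squared point-biserial correlation between a feature and the
#' binary target/non-target label: `sign(r) * r^2` with `r` the Pearson
#' correlation between `x` and the 0/1 indicator.
#'
#' @param x numeric feature values.
#' @param y binary labels (logical or 0/1); the positive class is
#'   `TRUE`/1.
#' @return value in `[-1, 1]`.
#' @examples
#' signedR2(c(1, 2, 3, 4), c(0, 1, 0, 1))  # 0.2
#' @export
signedR2 <- function(x, y) {
  y <- as.numeric(as.logical(y))
  .check(any(y == 1) && any(y == 0), "both labels must be present")
  .check(sd(x) > 0, "zero variance in x")
  r <- cor(x, y)
  sign(r) * r^2
}

#' Area under the ROC curve (rank formulation)
#'
#' Probability that a random target score exceeds a random non-target score,
#' ties counting one half — the normalised Mann-Whitney U statistic.
#'
#' @param scores numeric classifier outputs.
#' @param labels binary labels (TRUE/1 = target).
#' @return AUC in `[0, 1]`.
#' @examples
#' aucScore(c(0.8, 0.4, 0.6, 0.2), c(1, 1, 0, 0))  # 0.75
#' @export
aucScore <- function(scores, labels) {
  y <- as.logical(labels)
  .check(any(y) && any(!y), "both classes required")
  n1 <- sum(y)
  n0 <- sum(!y)
  r <- rank(scores)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Session performance report
#'
#' Aggregates trial decisions into the standard speller report: per
#' participant, accuracy `k/n` with Wilson CI, ITR with its CI (selection
#' time = mean elapsed time across that participant's trials, which under
#' full-length or static stopping is the fixed `T`); group mean accuracy and
#' ITR with participant-level percentile-bootstrap CIs; and the 30 x 30
#' confusion matrix aggregated across participants.
#'
#' @param decisionTables list (one element per participant) of decision
#'   data.frames with columns `target`, `chosen`, `elapsed_s` (as written by
#'   [writeDecisionsTsv()], or assembled directly).
#' @param nClasses number of classes (default 30).
#' @param level confidence level (default 0.95).
#' @param nBoot bootstrap iterations for the group CIs (default 10000).
#' @param seed seed for the bootstrap.
#' @param excludeParticipants optional indices excluded from the secondary
#'   group summary (e.g. a participant without BCI control).
#' @return list of class `PerformanceReport` with `perParticipant`
#'   (data.frame), `group`, `groupExcluding`, and `confusion`.
#' @export
summarizePerformance <- function(decisionTables, nClasses = 30L,
                                 level = 0.95, nBoot = 10000L, seed = 1L,
                                 excludeParticipants = integer()) {
  .check(length(decisionTables) >= 1, "no decision tables")
  per <- do.call(rbind, lapply(seq_along(decisionTables), function(i) {
    d <- decisionTables[[i]]
    n <- nrow(d)
    k <- sum(d$target == d$chosen)
    tMean <- mean(d$elapsed_s)
    ci <- wilsonInterval(k, n, level)
    itr <- itrBitsPerMin(itrBitsPerTrial(nClasses, k / n), tMean)
    itrCi <- itrBitsPerMin(itrBitsPerTrial(nClasses, ci), tMean)
    data.frame(participant = i, n = n, k = k, accuracy = k / n,
               accLower = ci[1], accUpper = ci[2],
               meanSelectionTimeS = tMean, itr = itr,
               itrLower = itrCi[1], itrUpper = itrCi[2])
  }))
  rownames(per) <- NULL
  groupStats <- function(rows) {
    list(
      meanAccuracy = mean(rows$accuracy),
      sdAccuracy = sd(rows$accuracy),
      meanItr = mean(rows$itr),
      sdItr = sd(rows$itr),
      accuracyCi = bootstrapMeanCi(rows$accuracy, nBoot, level,
                                   seed = childSeed(seed, 1L)),
      itrCi = bootstrapMeanCi(rows$itr, nBoot, level,
                              seed = childSeed(seed, 2L)))
  }
  confusion <- matrix(0L, nClasses, nClasses,
                      dimnames = list(target = 0:(nClasses - 1),
                                      chosen = 0:(nClasses - 1)))
  for (d in decisionTables) {
    for (j in seq_len(nrow(d))) {
      confusion[d$target[j] + 1L, d$chosen[j] + 1L] <-
        confusion[d$target[j] + 1L, d$chosen[j] + 1L] + 1L
    }
  }
  keep <- setdiff(seq_along(decisionTables), excludeParticipants)
  structure(list(
    perParticipant = per,
    group = groupStats(per),
    groupExcluding = if (length(excludeParticipants))
      groupStats(per[keep, , drop = FALSE]) else NULL,
    excluded = excludeParticipants,
    confusion = confusion
  ), class = "PerformanceReport")
}

#' @export
print.PerformanceReport <- function(x, ...) {
  cat(sprintf("PerformanceReport: %d participants\n",
              nrow(x$perParticipant)))
  cat(sprintf("  group mean accuracy %.2f, mean ITR %.2f bits/min\n",
              x$group$meanAccuracy, x$group$meanItr))
  if (!is.null(x$groupExcluding))
    cat(sprintf("  excluding {%s}: accuracy %.2f, ITR %.2f\n",
                paste(x$excluded, collapse = ","),
                x$groupExcluding$meanAccuracy, x$groupExcluding$meanItr))
  invisible(x)
}

#' Write a performance report
#'
#' JSON for the scalar summaries plus TSVs for the per-participant table and
#' the labelled confusion matrix.
#'
#' @param report a `PerformanceReport`.
#' @param dir output directory (created if needed).
#' @param layout optional layout data.frame to label the confusion matrix.
#' @return `dir`, invisibly.
#' @export
writePerformanceReport <- function(report, dir, layout = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(report$perParticipant,
              file.path(dir, "per_participant.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  conf <- report$confusion
  if (!is.null(layout)) {
    dimnames(conf) <- list(target = layout$label, chosen = layout$label)
  }
  write.table(conf, file.path(dir, "confusion.tsv"), sep = "\t",
              quote = FALSE, col.names = NA)
  jsonlite::write_json(
    list(group = report$group, groupExcluding = report$groupExcluding),
    file.path(dir, "group_summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
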