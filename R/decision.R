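# Trial decisions: per-class mean scores, argmax letter choice, and the
# full-length / static / dynamic stopping protocols.

#' Bundle per-stimulus scores of one trial
#'
#' @param scores numeric classifier output per stimulus, in presentation
#'   order.
#' @param classId class_id per stimulus.
#' @param sequence sequence index per stimulus (1-based).
#' @param soaS stimulus-onset asynchrony (s).
#' @param tmaxS epoch length used by the classifier (s); enters the elapsed
#'   selection time as `(n - 1) * soaS + tmaxS`.
#' @param target optional true target class_id (bookkeeping only).
#' @return list of class `TrialScores`.
#' @export
trialScores <- function(scores, classId, sequence, soaS = 0.2, tmaxS = 1.0,
                        target = NA_integer_) {
  .check(length(scores) == length(classId) &&
           length(scores) == length(sequence),
         "scores, classId and sequence must have equal length")
  structure(list(scores = as.numeric(scores), classId = as.integer(classId),
                 sequence = as.integer(sequence), soaS = soaS,
                 tmaxS = tmaxS, target = target),
            class = "TrialScores")
}

#' Letter decision from cumulative scores
#'
#' Averages the scores of each class among the first `uptoStimulus` stimuli
#' and selects the class with the highest mean (ties broken toward the
#' lowest class_id). The elapsed selection time is
#' `(uptoStimulus - 1) * soaS + tmaxS`.
#'
#' @param trial a [trialScores()] object.
#' @param uptoStimulus number of leading stimuli to use (default: all).
#' @return list of class `Decision`: `chosenClass`, `perClassMeans` (named
#'   by class_id), `nStimuliUsed`, `elapsedS`, `stoppedEarly` (FALSE here).
#' @examples
#' tr <- trialScores(c(1, 0.3, -0.2, 0.1), c(0, 1, 0, 1), c(1, 1, 2, 2))
#' decideTrial(tr)$chosenClass  # 0 (means 0.4 vs 0.2)
#' @export
decideTrial <- function(trial, uptoStimulus = length(trial$scores)) {
  n <- length(trial$scores)
  .check(uptoStimulus >= 1 && uptoStimulus <= n,
         "uptoStimulus out of range")
  idx <- seq_len(uptoStimulus)
  cls <- trial$classId[idx]
  means <- tapply(trial$scores[idx], cls, mean)
  ids <- as.integer(names(means))
  o <- order(ids)
  means <- means[o]
  ids <- ids[o]
  best <- ids[which.max(means)]  # which.max: lowest index on ties
  structure(list(chosenClass = best,
                 perClassMeans = stats::setNames(as.numeric(means), ids),
                 nStimuliUsed = as.integer(uptoStimulus),
                 elapsedS = (uptoStimulus - 1) * trial$soaS + trial$tmaxS,
                 stoppedEarly = FALSE,
                 target = trial$target),
            class = "Decision")
}

#' One-sided Welch's t-test (mean(a) > mean(b))
#'
#' Closed-form Welch statistic with Welch-Satterthwaite degrees of freedom
#' and upper-tail Student-t p-value. When both samples are degenerate
#' (zero variance) with equal means the p-value is 0.5 by convention and the
#' result is flagged with attribute `degenerate`.
#'
#' @param a,b numeric samples, each of length >= 2.
#' @return list with `t`, `df`, `p`.
#' @examples
#' welchTOneSided(c(2, 4, 6), c(1, 2, 3))  # t ~ 1.549, df ~ 2.94
#' @export
welchTOneSided <- function(a, b) {
  .check(length(a) >= 2 && length(b) >= 2,
         "both samples need at least 2 values")
  na <- length(a)
  nb <- length(b)
  va <- var(a)
  vb <- var(b)
  se2 <- va / na + vb / nb
  dm <- mean(a) - mean(b)
  if (se2 == 0) {
    out <- list(t = if (dm == 0) 0 else sign(dm) * Inf,
                df = na + nb - 2,
                p = if (dm == 0) 0.5 else if (dm > 0) 0 else 1)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  tstat <- dm / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = tstat, df = df, p = pt(tstat, df, lower.tail = FALSE))
}

#' Static-stopping decision
#'
#' Decision from the cumulative data of the first `nSequences` sequences,
#' equivalent to `decideTrial(trial, nSequences * 30)` on a full 30-class
#' schedule.
#'
#' @param trial a [trialScores()] object.
#' @param nSequences number of sequences to use.
#' @return a `Decision`.
#' @export
staticStop <- function(trial, nSequences) {
  .check(nSequences >= 1 && nSequences <= max(trial$sequence),
         "nSequences out of range")
  upto <- sum(trial$sequence <= nSequences)
  decideTrial(trial, upto)
}

#' Dynamic-stopping decision (one-sided Welch rule)
#'
#' Waits until `minSequences` complete sequences have been presented, then
#' after EVERY subsequent stimulus: identifies the class with the highest
#' running mean score, tests its scores against the pooled scores of all
#' other classes with a one-sided Welch t-test, and terminates at the first
#' stimulus where `p < alpha`. If no test is significant the trial runs to
#' completion. The best class is re-identified at every evaluation; the
#' decision uses only data up to the stopping stimulus.
#'
#' @param trial a [trialScores()] object.
#' @param minSequences minimum sequences before testing starts (2-14 in the
#'   standard sweep).
#' @param alpha significance level (default 0.05).
#' @return a `Decision` with `stoppedEarly` set accordingly.
#' @export
dynamicStop <- function(trial, minSequences, alpha = 0.05) {
  nSeqTotal <- max(trial$sequence)
  .check(minSequences >= 1 && minSequences < nSeqTotal,
         "minSequences must be below the total sequence count")
  n <- length(trial$scores)
  startAt <- sum(trial$sequence <= minSequences) + 1L
  cls <- trial$classId
  scores <- trial$scores
  ids <- sort(unique(cls))
  # running sums and counts per class for O(1) mean updates
  sums <- stats::setNames(numeric(length(ids)), ids)
  cnts <- stats::setNames(integer(length(ids)), ids)
  for (u in seq_len(n)) {
    key <- as.character(cls[u])
    sums[key] <- sums[key] + scores[u]
    cnts[key] <- cnts[key] + 1L
    if (u < startAt) next
    means <- sums / pmax(cnts, 1L)
    means[cnts == 0L] <- -Inf
    best <- which.max(means)  # lowest index on ties
    bestId <- ids[best]
    aIdx <- cls[seq_len(u)] == bestId
    a <- scores[seq_len(u)][aIdx]
    b <- scores[seq_len(u)][!aIdx]
    if (length(a) >= 2 && length(b) >= 2) {
      w <- welchTOneSided(a, b)
      if (w$p < alpha) {
        dec <- decideTrial(trial, u)
        dec$stoppedEarly <- TRUE
        return(dec)
      }
    }
  }
  dec <- decideTrial(trial, n)
  dec$stoppedEarly <- FALSE
  dec
}

#' Apply a stopping rule to one trial
#'
#' @param trial a [trialScores()] object.
#' @param mode `"full"`, `"static"` or `"dynamic"`.
#' @param nSequences sequences used in static mode.
#' @param minSequences minimum sequences in dynamic mode.
#' @param alpha dynamic-mode significance level (default 0.05).
#' @return a `Decision`.
#' @export
applyStoppingRule <- function(trial,
                              mode = c("full", "static", "dynamic"),
                              nSequences = NULL, minSequences = NULL,
                              alpha = 0.05) {
  mode <- match.arg(mode)
  switch(mode,
    full = decideTrial(trial),
    static = staticStop(trial, nSequences),
    dynamic = dynamicStop(trial, minSequences, alpha))
}

#' Export decisions as TSV
#'
#' One row per trial: run, trial, target, chosen, correct, n_stimuli_used,
#' elapsed_s, stopped_early.
#'
#' @param decisions list of `Decision` objects.
#' @param run,trial parallel integer vectors (recycled if length 1).
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writeDecisionsTsv <- function(decisions, run, trial, path) {
  df <- data.frame(
    run = rep_len(run, length(decisions)),
    trial = rep_len(trial, length(decisions)),
    target = vapply(decisions, function(d) as.integer(d$target), 0L),
    chosen = vapply(decisions, function(d) as.integer(d$chosenClass), 0L),
    correct = vapply(decisions, function(d)
      isTRUE(d$chosenClass == d$target), FALSE),
    n_stimuli_used = vapply(decisions, `[[`, 0L, "nStimuliUsed"),
    elapsed_s = vapply(decisions, `[[`, 0, "elapsedS"),
    stopped_early = vapply(decisions, `[[`, FALSE, "stoppedEarly"))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
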