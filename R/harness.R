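# Experiment harness: online-protocol replica, stopping sweeps, the class
# imbalance experiment, and the preprocessing parameter grid.

#' Concatenate epoch containers
#'
#' @param epochsList list of [EEGEpochs-class] objects with identical
#'   channels, rates and windows.
#' @return one [EEGEpochs-class].
#' @export
bindEpochs <- function(epochsList) {
  .check(length(epochsList) >= 1, "empty epoch list")
  e1 <- epochsList[[1]]
  if (length(epochsList) == 1L) return(e1)
  datas <- lapply(epochsList, eegData)
  d <- dim(datas[[1]])
  total <- sum(vapply(datas, function(x) dim(x)[1], 0))
  out <- array(0, dim = c(total, d[2], d[3]))
  at <- 0L
  for (x in datas) {
    n <- dim(x)[1]
    if (n > 0) out[(at + 1):(at + n), , ] <- x
    at <- at + n
  }
  meta <- do.call(rbind, lapply(epochsList, epochMetadata))
  EEGEpochs(out, samplingRate(e1), e1@tminS, e1@tmaxS,
            channelLabels(e1), meta)
}

#' Experiment configuration
#'
#' Bundles every knob of a simulated session: paradigm geometry, generator
#' settings, preprocessing, pipeline and stopping rule.
#'
#' @param seed master seed; drives the plan, the schedules, the generator
#'   and every stochastic analysis step.
#' @param nSequences sequences per trial (default 15).
#' @param soaS stimulus-onset asynchrony (default 0.2 s).
#' @param synth a [synthConfig()]; defaults to `synthConfig(seed = seed)`.
#' @param filter a [filterSpec()] (default 1-40 Hz).
#' @param tminS,tmaxS epoch window (defaults -0.1, 1.0 s).
#' @param pipeline `"lda"`, `"xdw_lda"` or `"xdwcov_ts_lda"`.
#' @param offlineRuns,onlineRuns,trialsPerRun session geometry (6/3/5).
#' @param binS interval-mean bin width (default 0.1 s).
#' @param onlineTargets optional explicit online target classes.
#' @return list of class `ExperimentConfig`.
#' @export
experimentConfig <- function(seed = 1L, nSequences = 15L, soaS = 0.2,
                             synth = NULL, filter = filterSpec(1, 40),
                             tminS = -0.1, tmaxS = 1.0,
                             pipeline = "lda",
                             offlineRuns = 6L, onlineRuns = 3L,
                             trialsPerRun = 5L, binS = 0.1,
                             onlineTargets = NULL) {
  if (is.null(synth)) synth <- synthConfig(seed = seed)
  structure(list(seed = as.integer(seed), nSequences = nSequences,
                 soaS = soaS, synth = synth, filter = filter,
                 tminS = tminS, tmaxS = tmaxS, pipeline = pipeline,
                 offlineRuns = offlineRuns, onlineRuns = onlineRuns,
                 trialsPerRun = trialsPerRun, binS = binS,
                 onlineTargets = onlineTargets),
            class = "ExperimentConfig")
}

# Synthesize, filter and epoch a whole session; returns the pieces every
# experiment needs.
.prepareSession <- function(config) {
  layout <- defaultLayout()
  plan <- makeSessionPlan(layout, config$seed,
                          offlineRuns = config$offlineRuns,
                          onlineRuns = config$onlineRuns,
                          trialsPerRun = config$trialsPerRun,
                          onlineTargets = config$onlineTargets)
  schedules <- makeSessionSchedules(plan, layout,
                                    nSequences = config$nSequences,
                                    soaS = config$soaS)
  recs <- synthesizeSession(plan, schedules, config$synth)
  phase <- vapply(plan$runs, `[[`, "", "phase")
  epochRun <- function(r) {
    rec <- bandpassRecording(recs[[r]], config$filter)
    extractEpochs(rec, tminS = config$tminS, tmaxS = config$tmaxS)
  }
  offline <- bindEpochs(lapply(which(phase == "offline"), epochRun))
  online <- bindEpochs(lapply(which(phase == "online"), epochRun))
  list(layout = layout, plan = plan, schedules = schedules,
       offline = offline, online = online, phase = phase)
}

# Split scored online epochs into per-trial TrialScores objects.
.trialScoreList <- function(scores, meta, config) {
  key <- interaction(meta$run, meta$trial, drop = TRUE)
  lapply(split(seq_along(scores), key), function(idx) {
    trialScores(scores[idx], meta$class_id[idx], meta$sequence[idx],
                soaS = config$soaS, tmaxS = config$tmaxS,
                target = meta$class_id[idx][meta$is_target[idx]][1])
  })
}

#' Run the online protocol end to end
#'
#' Synthesizes a full session, trains the configured pipeline on the offline
#' runs (no artifact removal), scores every online stimulus, makes
#' full-length letter decisions and reports performance.
#'
#' @param config an [experimentConfig()].
#' @return list of class `OnlineResult`: `model`, `trials` (per-trial
#'   [trialScores()] objects), `decisions` (data.frame), `report`
#'   (single-participant [summarizePerformance()] output), and
#'   `nFeatures`.
#' @export
runOnlineProtocol <- function(config) {
  ses <- .prepareSession(config)
  model <- trainPipeline(ses$offline, pipeline = config$pipeline,
                         binS = config$binS)
  scores <- scorePipeline(model, ses$online)
  trials <- .trialScoreList(scores, epochMetadata(ses$online), config)
  decisions <- do.call(rbind, lapply(trials, function(tr) {
    d <- decideTrial(tr)
    data.frame(target = tr$target, chosen = d$chosenClass,
               n_stimuli_used = d$nStimuliUsed, elapsed_s = d$elapsedS,
               stopped_early = d$stoppedEarly)
  }))
  rownames(decisions) <- NULL
  nFeatures <- if (!is.null(model$lda)) length(model$lda$w) else NA_integer_
  structure(list(model = model, trials = trials, decisions = decisions,
                 report = summarizePerformance(list(decisions),
                                               seed = config$seed),
                 nFeatures = nFeatures,
                 config = config),
            class = "OnlineResult")
}

#' Static/dynamic stopping sweep
#'
#' Re-decides each scored online trial under every static cut (1..total
#' sequences) and every dynamic minimum (2..total-1 by default), and tabulates
#' accuracy, mean selection time and ITR per setting; also returns the three
#' maximiser rows (max accuracy; max ITR; max ITR subject to accuracy >=
#' `accuracyFloor`).
#'
#' @param trials list of [trialScores()] objects (e.g. from
#'   [runOnlineProtocol()]).
#' @param nClasses number of classes (default 30).
#' @param staticSequences static cuts to evaluate (default 1..total).
#' @param dynamicMinSequences dynamic minimums (default 2..total-1).
#' @param alpha dynamic-stopping significance level (default 0.05).
#' @param accuracyFloor constraint for the third criterion (default 0.7).
#' @return list of class `StoppingSweep` with `table` (one row per mode x
#'   setting) and `optima`.
#' @export
runStoppingSweep <- function(trials, nClasses = 30L,
                             staticSequences = NULL,
                             dynamicMinSequences = NULL, alpha = 0.05,
                             accuracyFloor = 0.7) {
  total <- max(trials[[1]]$sequence)
  if (is.null(staticSequences)) staticSequences <- seq_len(total)
  if (is.null(dynamicMinSequences))
    dynamicMinSequences <- seq(2L, max(2L, total - 1L))
  evalRule <- function(mode, setting) {
    decs <- lapply(trials, function(tr) {
      if (mode == "static") staticStop(tr, setting)
      else dynamicStop(tr, setting, alpha)
    })
    correct <- vapply(seq_along(trials), function(i)
      isTRUE(decs[[i]]$chosenClass == trials[[i]]$target), FALSE)
    acc <- mean(correct)
    st <- mean(vapply(decs, `[[`, 0, "elapsedS"))
    data.frame(mode = mode, setting = setting, accuracy = acc,
               meanSelectionTimeS = st,
               itr = itrBitsPerMin(itrBitsPerTrial(nClasses, acc), st))
  }
  tab <- rbind(
    do.call(rbind, lapply(staticSequences, function(s)
      evalRule("static", s))),
    do.call(rbind, lapply(dynamicMinSequences, function(s)
      evalRule("dynamic", s))))
  rownames(tab) <- NULL
  pickOptima <- function(rows) {
    ok <- rows[rows$accuracy >= accuracyFloor, , drop = FALSE]
    list(
      maxAccuracy = rows[which.max(rows$accuracy), ],
      maxItr = rows[which.max(rows$itr), ],
      maxItrAboveFloor = if (nrow(ok)) ok[which.max(ok$itr), ] else NULL)
  }
  structure(list(
    table = tab,
    optima = list(
      static = pickOptima(tab[tab$mode == "static", , drop = FALSE]),
      dynamic = pickOptima(tab[tab$mode == "dynamic", , drop = FALSE]))
  ), class = "StoppingSweep")
}

#' Class-imbalance sub-sampling experiment
#'
#' Keeps all offline target epochs, sub-samples the non-targets to
#' `ratio x` the target count, trains shrinkage LDA on interval-mean
#' features, decodes the online trials full-length and averages accuracy
#' over seeded repeats. At the maximal ratio all non-targets are used and a
#' single repeat suffices.
#'
#' @param config an [experimentConfig()] (pipeline forced to `"lda"`).
#' @param ratios non-target : target ratios (default 1, 5, 10, 20, 29).
#' @param nRepeats sub-sampling repeats per ratio (default 10).
#' @return data.frame with one row per ratio: `ratio`, `nNonTarget`,
#'   `meanAccuracy`, `sdAccuracy`, `nRepeats`.
#' @export
runImbalanceExperiment <- function(config, ratios = c(1, 5, 10, 20, 29),
                                   nRepeats = 10L) {
  ses <- .prepareSession(config)
  feats <- intervalMeans(ses$offline, 0, config$tmaxS, config$binS)
  labels <- epochMetadata(ses$offline)$is_target
  onlineFeats <- intervalMeans(ses$online, 0, config$tmaxS, config$binS)
  onlineMeta <- epochMetadata(ses$online)
  tgIdx <- which(labels)
  ntIdx <- which(!labels)
  decodeWith <- function(model) {
    scores <- ldaScore(model, onlineFeats)
    trials <- .trialScoreList(scores, onlineMeta, config)
    mean(vapply(trials, function(tr)
      isTRUE(decideTrial(tr)$chosenClass == tr$target), FALSE))
  }
  do.call(rbind, lapply(ratios, function(rt) {
    nNt <- rt * length(tgIdx)
    .check(nNt <= length(ntIdx), "ratio exceeds available non-targets")
    reps <- if (nNt == length(ntIdx)) 1L else nRepeats
    accs <- vapply(seq_len(reps), function(rep) {
      sub <- if (nNt == length(ntIdx)) ntIdx else
        withSeed(childSeed(config$seed, 300L, rt, rep),
                 sample(ntIdx, nNt))
      keep <- sort(c(tgIdx, sub))
      model <- fitShrinkageLda(feats$values[keep, , drop = FALSE],
                               labels[keep])
      decodeWith(model)
    }, 0)
    data.frame(ratio = rt, nNonTarget = nNt, meanAccuracy = mean(accs),
               sdAccuracy = if (length(accs) > 1) sd(accs) else 0,
               nRepeats = reps)
  }))
}

#' Preprocessing parameter grid with run-bounded cross-validation
#'
#' For every (high-pass, low-pass, epoch length, pipeline) cell: band-pass
#' the raw offline runs, epoch, and run 3-fold cross-validation whose folds
#' are whole-run pairs (runs 1-2 / 3-4 / 5-6 by default), scoring held-out
#' stimuli and averaging the stimulus-level AUC over folds. Returns the full
#' table and the best row per pipeline.
#'
#' @param config an [experimentConfig()] (its `pipeline` field is ignored).
#' @param hpGrid,lpGrid,tmaxGrid explored values (defaults: the standard
#'   grid 0.1/0.5/1.0 Hz, 8/15/20/40 Hz, 0.5/1.0/1.5/2.0 s).
#' @param pipelines pipelines to evaluate (default all three).
#' @param folds list of integer run-index vectors partitioning the offline
#'   runs (default pairs 1-2 / 3-4 / 5-6).
#' @return list of class `ParameterGrid` with `table` and `best` (one row
#'   per pipeline).
#' @export
runParameterGrid <- function(config,
                             hpGrid = c(0.1, 0.5, 1.0),
                             lpGrid = c(8, 15, 20, 40),
                             tmaxGrid = c(0.5, 1.0, 1.5, 2.0),
                             pipelines = c("lda", "xdw_lda",
                                           "xdwcov_ts_lda"),
                             folds = NULL) {
  layout <- defaultLayout()
  plan <- makeSessionPlan(layout, config$seed,
                          offlineRuns = config$offlineRuns,
                          onlineRuns = config$onlineRuns,
                          trialsPerRun = config$trialsPerRun,
                          onlineTargets = config$onlineTargets)
  schedules <- makeSessionSchedules(plan, layout,
                                    nSequences = config$nSequences,
                                    soaS = config$soaS)
  recs <- synthesizeSession(plan, schedules, config$synth)
  phase <- vapply(plan$runs, `[[`, "", "phase")
  offRuns <- which(phase == "offline")
  if (is.null(folds)) {
    .check(length(offRuns) %% 3L == 0L,
           "default folds need a multiple of 3 offline runs")
    folds <- split(seq_along(offRuns),
                   rep(1:3, each = length(offRuns) / 3))
  }
  rows <- list()
  for (hp in hpGrid) for (lp in lpGrid) {
    if (hp >= lp) next
    spec <- filterSpec(hp, lp)
    filtered <- lapply(offRuns, function(r)
      bandpassRecording(recs[[r]], spec))
    for (tmax in tmaxGrid) {
      eps <- lapply(filtered, function(rec)
        extractEpochs(rec, tminS = config$tminS, tmaxS = tmax))
      for (pl in pipelines) {
        aucs <- vapply(seq_along(folds), function(f) {
          testIdx <- folds[[f]]
          trainEp <- bindEpochs(eps[-testIdx])
          testEp <- bindEpochs(eps[testIdx])
          model <- trainPipeline(trainEp, pipeline = pl,
                                 binS = config$binS)
          aucScore(scorePipeline(model, testEp),
                   epochMetadata(testEp)$is_target)
        }, 0)
        rows[[length(rows) + 1L]] <-
          data.frame(hpHz = hp, lpHz = lp, tmaxS = tmax, pipeline = pl,
                     meanAuc = mean(aucs))
      }
    }
  }
  tab <- do.call(rbind, rows)
  if (is.null(tab)) {
    return(structure(list(table = NULL, best = NULL),
                     class = "ParameterGrid"))
  }
  rownames(tab) <- NULL
  best <- do.call(rbind, lapply(split(tab, tab$pipeline), function(g)
    g[which.max(g$meanAuc), ]))
  rownames(best) <- NULL
  structure(list(table = tab, best = best), class = "ParameterGrid")
}
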