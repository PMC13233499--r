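# Shared fixtures, built in code and cached for the duration of the run.

# Full default-SNR session decoded with the LDA pipeline (the workhorse
# end-to-end fixture); computed once on first use.
getOnlineResult <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- experimentConfig(seed = 20240001L)
      cache <<- runOnlineProtocol(cfg)
    }
    cache
  }
})

# Small noiseless session for exact-recovery checks.
quietConfig <- function(seed = 5L, nSequences = 2L, pipeline = "lda",
                        ssrAmplitudeUv = 0) {
  experimentConfig(
    seed = seed, nSequences = nSequences, pipeline = pipeline,
    synth = synthConfig(noiseSigmaUv = 0, latencyJitterSdS = 0,
                        ssrAmplitudeUv = ssrAmplitudeUv, seed = seed))
}

# Epochs object built directly from an array (bypasses synthesis).
makeEpochs <- function(data, fs = 100, tmin = -0.1, tmax = 1.0,
                       meta = NULL) {
  d <- dim(data)
  if (is.null(meta))
    meta <- data.frame(class_id = rep(0L, d[1]),
                       is_target = rep(FALSE, d[1]))
  EEGEpochs(data, fs, tmin, tmax, paste0("ch", seq_len(d[2])), meta)
}

# Random TrialScores stream over the 30-class schedule.
randomTrial <- function(seed, nSequences = 15, soaS = 0.2, tmaxS = 1.0,
                        target = 0L, targetBoost = 0) {
  set.seed(seed)
  sched <- makeTrialSchedule(defaultLayout(), target,
                             nSequences = nSequences, seed = seed)
  sc <- rnorm(nrow(sched$events)) +
    targetBoost * (sched$events$class_id == target)
  trialScores(sc, sched$events$class_id, sched$events$sequence,
              soaS = soaS, tmaxS = tmaxS, target = target)
}
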