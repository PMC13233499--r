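# Synthetic EEG generator.
#
# Emulates the reported structure of the speller EEG: target-locked ERP
# components (frontal N2, centro-parietal P300, late N700), a steady-state
# response phase-locked to the 0.2 s SOA, spatially mixed 1/f background
# noise, and optional blink artifacts with matching EOG channels.  Every
# stimulus adds the steady-state template; only target stimuli additionally
# receive the ERP components.  Overlapping templates superpose additively,
# so neighbours of a target carry shifted target-like waveforms, as on real
# recordings with a 0.2 s SOA.

.DEFAULT_CHANNELS <- c("Fz", "FCz", "Cz", "CPz", "Pz", "Oz", "C3", "C4")

# named topography helpers on the default 8-channel montage
.topoFrontal <- c(Fz = 1, FCz = 0.8, Cz = 0.5, CPz = 0.3, Pz = 0.2,
                  Oz = 0.1, C3 = 0.4, C4 = 0.4)
.topoCentroParietal <- c(Fz = 0.2, FCz = 0.4, Cz = 0.7, CPz = 0.9, Pz = 1,
                         Oz = 0.5, C3 = 0.5, C4 = 0.5)
.topoCentral <- c(Fz = 0.5, FCz = 0.8, Cz = 1, CPz = 0.8, Pz = 0.5,
                  Oz = 0.2, C3 = 0.6, C4 = 0.6)

.matchTopo <- function(weights, channels) {
  if (is.null(names(weights))) {
    .check(length(weights) == length(channels),
           "unnamed topography must have one weight per channel")
    return(as.numeric(weights))
  }
  w <- weights[channels]
  w[is.na(w)] <- 0
  as.numeric(w)
}

#' Describe one ERP component
#'
#' A component is a raised-cosine bump of a given centre, width and signed
#' amplitude, projected onto the channels through a fixed topography (named
#' channel-weight map with max |weight| = 1; no head model).
#'
#' @param name component name ("N2", "P300", ...).
#' @param centerS centre latency relative to stimulus onset (s).
#' @param widthS full width of the bump (s), > 0.
#' @param amplitudeUv signed peak amplitude in microvolts.
#' @param topography named numeric vector of per-channel weights, or an
#'   unnamed vector matching the channel count.
#' @return list of class `ErpComponent`.
#' @export
erpComponent <- function(name, centerS, widthS, amplitudeUv, topography) {
  .check(widthS > 0, "widthS must be positive")
  structure(list(name = name, centerS = centerS, widthS = widthS,
                 amplitudeUv = amplitudeUv, topography = topography),
            class = "ErpComponent")
}

#' Default ERP components of the generator
#'
#' N2: -2 uV, centre 0.40 s, width 0.20 s, frontal. P300: +4 uV, centre
#' 0.65 s, width 0.30 s, centro-parietal. N700: -1.5 uV, centre 0.95 s,
#' width 0.15 s, central. Latencies and polarities follow the component
#' windows reported for this paradigm; amplitudes are configurable and never
#' used as ground truth.
#'
#' @return list of `ErpComponent` objects.
#' @export
defaultErpComponents <- function() {
  list(
    erpComponent("N2", 0.40, 0.20, -2, .topoFrontal),
    erpComponent("P300", 0.65, 0.30, +4, .topoCentroParietal),
    erpComponent("N700", 0.95, 0.15, -1.5, .topoCentral)
  )
}

#' Generator configuration
#'
#' @param fsHz sampling rate (default 250 Hz; 1000 Hz supported).
#' @param channels ordered channel labels (default 8-channel 10-20 subset).
#' @param components list of [erpComponent()] objects added at target onsets.
#' @param ssrAmplitudeUv amplitude of the steady-state response: one sinusoid
#'   cycle at 1/SOA Hz added at every stimulus onset (default 1 uV).
#' @param noiseSigmaUv standard deviation of the 1/f background noise per
#'   channel (default 15 uV).
#' @param oneOverFExponent spectral slope of the background noise
#'   (power ~ 1/f^exponent, default 1).
#' @param latencyJitterSdS SD of the Gaussian latency jitter applied to each
#'   target's ERP components (default 0.02 s).
#' @param eogBlinkRateHz mean blink rate; 0 disables blinks (default).
#' @param eogAmplitudeUv blink amplitude on the EOG channel (default 100 uV).
#' @param interTrialGapS silent gap inserted before each trial within a run
#'   (default 2 s); also provides the pre-stimulus baseline of the first
#'   epoch.
#' @param seed integer seed; the session synthesiser derives per-run child
#'   seeds from it.
#' @return list of class `SynthConfig`.
#' @export
synthConfig <- function(fsHz = 250, channels = .DEFAULT_CHANNELS,
                        components = defaultErpComponents(),
                        ssrAmplitudeUv = 1, noiseSigmaUv = 15,
                        oneOverFExponent = 1, latencyJitterSdS = 0.02,
                        eogBlinkRateHz = 0, eogAmplitudeUv = 100,
                        interTrialGapS = 2, seed = 1L) {
  .check(fsHz > 0, "fsHz must be positive")
  .check(ssrAmplitudeUv >= 0 && noiseSigmaUv >= 0 && latencyJitterSdS >= 0,
         "all scales must be >= 0")
  structure(list(
    fsHz = fsHz, channels = channels, components = components,
    ssrAmplitudeUv = ssrAmplitudeUv, noiseSigmaUv = noiseSigmaUv,
    oneOverFExponent = oneOverFExponent,
    latencyJitterSdS = latencyJitterSdS,
    eogBlinkRateHz = eogBlinkRateHz, eogAmplitudeUv = eogAmplitudeUv,
    interTrialGapS = interTrialGapS, seed = as.integer(seed)
  ), class = "SynthConfig")
}

#' Raised-cosine ERP template
#'
#' Evaluates `a * 0.5 * (1 + cos(2*pi*(t - c)/w))` for `|t - c| <= w/2` and 0
#' elsewhere, where `a`, `c`, `w` are the component's amplitude, centre and
#' width. The time integral of the bump is `a * w / 2`.
#'
#' @param component an [erpComponent()].
#' @param t monotone increasing time grid (s).
#' @return numeric amplitude series (microvolts).
#' @examples
#' cmp <- erpComponent("P300", 0.65, 0.3, 4, c(Pz = 1))
#' t <- seq(0, 1.2, by = 0.004)
#' max(erpWaveform(cmp, t))  # 4 at t = centre
#' @export
erpWaveform <- function(component, t) {
  .check(all(diff(t) > 0), "t must be monotone increasing")
  .check(component$widthS > 0, "width must be positive")
  a <- component$amplitudeUv
  c0 <- component$centerS
  w <- component$widthS
  out <- numeric(length(t))
  inb <- abs(t - c0) <= w / 2
  out[inb] <- a * 0.5 * (1 + cos(2 * pi * (t[inb] - c0) / w))
  out
}

# 1/f noise: shape white Gaussian noise in the frequency domain so that
# amplitude ~ f^(-exponent/2), then scale each channel to sigma and mix
# across channels for spatial correlation.
.oneOverFNoise <- function(nChannels, nSamples, fs, sigma, exponent) {
  if (sigma == 0) return(matrix(0, nChannels, nSamples))
  # two-sided frequency axis matching R's fft bin order
  k <- seq_len(nSamples) - 1L
  k[k > nSamples / 2] <- k[k > nSamples / 2] - nSamples
  f <- abs(k) * fs / nSamples
  mult <- c(0, f[-1]^(-exponent / 2))
  out <- matrix(0, nChannels, nSamples)
  for (ch in seq_len(nChannels)) {
    W <- fft(rnorm(nSamples))
    x <- Re(fft(W * mult, inverse = TRUE)) / nSamples
    out[ch, ] <- x / sd(x) * sigma
  }
  # mild spatial mixing: neighbouring channels share background activity
  if (nChannels > 1) {
    A <- diag(nChannels)
    A <- A + 0.25 * matrix(runif(nChannels^2, -1, 1), nChannels)
    A <- A / sqrt(rowSums(A^2))
    out <- A %*% out
    out <- out / apply(out, 1, sd) * sigma
  }
  out
}

#' Synthesize the continuous EEG of one run
#'
#' Lays the run's trials end to end (each preceded by `interTrialGapS` of
#' stimulus-free recording), then adds, per stimulus onset: one cycle of a
#' 1/SOA-Hz sinusoid on all channels (the steady-state response, fixed
#' topography), and, for target onsets only, every configured ERP component
#' with optional Gaussian latency jitter. Finally adds spatially mixed 1/f
#' noise and, if enabled, blink bumps mirrored on an appended EOG channel.
#' Deterministic given `seed`.
#'
#' @param schedules list of `TrialSchedule` objects (the run's trials).
#' @param config a [synthConfig()].
#' @param runIndex integer tag stored in the event table.
#' @param seed integer seed for this run (default derives from the config
#'   seed and `runIndex`).
#' @return an [EEGRecording-class]; its events table carries the schedule
#'   columns plus `run`, `trial` and onsets in recording time.
#' @export
synthesizeRun <- function(schedules, config, runIndex = 1L, seed = NULL) {
  if (is.null(seed)) seed <- childSeed(config$seed, 100L, runIndex)
  fs <- config$fsHz
  nCh <- length(config$channels)
  soaS <- schedules[[1]]$soaS
  gap <- config$interTrialGapS
  # trial span: last onset + 1.5 s tail so late components fit
  trialSpan <- vapply(schedules, function(s)
    max(s$events$onset_s) + 1.5, 0)
  starts <- gap + cumsum(c(0, head(trialSpan + gap, -1)))
  nSamples <- ceiling((starts[length(starts)] +
                         trialSpan[length(trialSpan)] + gap) * fs)

  events <- do.call(rbind, lapply(seq_along(schedules), function(tr) {
    ev <- schedules[[tr]]$events
    ev$run <- runIndex
    ev$trial <- tr
    ev$onset_s <- ev$onset_s + starts[tr]
    ev
  }))

  withSeed(seed, {
    data <- matrix(0, nCh, nSamples)

    # steady-state response: one sinusoid cycle per stimulus onset
    ssrLen <- round(soaS * fs)
    if (config$ssrAmplitudeUv > 0 && ssrLen >= 2) {
      tt <- (seq_len(ssrLen) - 1) / fs
      ssrTemplate <- config$ssrAmplitudeUv * sin(2 * pi * tt / soaS)
      ssrTopo <- .matchTopo(.topoCentroParietal, config$channels)
      onIdx <- round(events$onset_s * fs) + 1L
      for (i in onIdx) {
        j <- i:(i + ssrLen - 1L)
        data[, j] <- data[, j] + ssrTopo %o% ssrTemplate
      }
    }

    # target-locked ERP components, evaluated on the absolute sample grid
    # so templates stay exact under arbitrary onsets and jitter
    tgIdx <- which(events$is_target)
    if (length(tgIdx) && length(config$components)) {
      comps <- lapply(config$components, function(cmp)
        list(cmp = cmp,
             topo = .matchTopo(cmp$topography, config$channels)))
      for (i in tgIdx) {
        jit <- if (config$latencyJitterSdS > 0)
          rnorm(1, 0, config$latencyJitterSdS) else 0
        for (cc in comps) {
          cmp <- cc$cmp
          c0 <- events$onset_s[i] + cmp$centerS + jit
          half <- cmp$widthS / 2
          j <- max(1L, floor((c0 - half) * fs) + 1L):
            min(nSamples, ceiling((c0 + half) * fs) + 1L)
          tj <- (j - 1) / fs - events$onset_s[i] - jit
          data[, j] <- data[, j] + cc$topo %o% erpWaveform(cmp, tj)
        }
      }
    }

    # background noise
    data <- data + .oneOverFNoise(nCh, nSamples, fs,
                                  config$noiseSigmaUv,
                                  config$oneOverFExponent)

    labels <- config$channels
    # optional blinks + EOG channel
    if (config$eogBlinkRateHz > 0) {
      nBlinks <- max(0L, round(config$eogBlinkRateHz * nSamples / fs))
      blinkLen <- round(0.4 * fs)
      tt <- (seq_len(blinkLen) - 1) / fs
      blink <- config$eogAmplitudeUv * 0.5 *
        (1 - cos(2 * pi * tt / 0.4))  # slow positive bump
      eog <- numeric(nSamples)
      frontTopo <- .matchTopo(c(Fz = 0.4, FCz = 0.25, Cz = 0.1),
                              config$channels)
      if (nBlinks > 0) {
        at <- sort(sample.int(nSamples - blinkLen, nBlinks))
        for (i in at) {
          j <- i:(i + blinkLen - 1L)
          eog[j] <- eog[j] + blink
          data[, j] <- data[, j] + frontTopo %o% blink
        }
      }
      data <- rbind(data, eog + rnorm(nSamples, 0, 1))
      labels <- c(labels, "EOG")
    }

    EEGRecording(data, fs, labels, events)
  })
}

#' Synthesize all runs of a session plan
#'
#' @param plan a `SessionPlan` from [makeSessionPlan()].
#' @param schedules nested schedule list from [makeSessionSchedules()].
#' @param config a [synthConfig()].
#' @return list of [EEGRecording-class] objects, one per run, in plan order.
#' @examples
#' layout <- defaultLayout()
#' plan <- makeSessionPlan(layout, seed = 3)
#' sch <- makeSessionSchedules(plan, layout, nSequences = 2)
#' cfg <- synthConfig(seed = 3)
#' rec <- synthesizeRun(sch[[1]], cfg, runIndex = 1L)
#' @export
synthesizeSession <- function(plan, schedules, config) {
  .check(length(schedules) == length(plan$runs),
         "schedules inconsistent with plan")
  lapply(seq_along(schedules), function(r)
    synthesizeRun(schedules[[r]], config, runIndex = r,
                  seed = childSeed(config$seed, 100L, r)))
}
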