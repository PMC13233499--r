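# Preprocessing: causal Butterworth band-pass, epoching with end-of-run
# zero-padding, FFT-domain resampling, interval-mean features, and the
# EOG component selection / removal rules.

#' Filter specification
#'
#' An order-2 Butterworth band-pass (order-2 prototype through the standard
#' low/high band transformation) applied causally, i.e. in a single forward
#' pass; no zero-phase filtering.
#'
#' @param hpHz high-pass cutoff (Hz).
#' @param lpHz low-pass cutoff (Hz); must satisfy `0 < hpHz < lpHz < fs/2`.
#' @param order filter order of the prototype (fixed at 2).
#' @param causal logical; the pipeline only uses causal filtering.
#' @return list of class `FilterSpec`.
#' @export
filterSpec <- function(hpHz = 1, lpHz = 40, order = 2L, causal = TRUE) {
  .check(hpHz > 0 && lpHz > hpHz, "need 0 < hpHz < lpHz")
  structure(list(hpHz = hpHz, lpHz = lpHz, order = as.integer(order),
                 causal = isTRUE(causal)),
            class = "FilterSpec")
}

#' Causal band-pass filtering of a recording
#'
#' Applies the band-pass of `spec` channel-wise in the forward direction
#' only. The filter state starts at zero, so a DC offset decays over the
#' initial transient rather than being removed instantaneously.
#'
#' @param recording an [EEGRecording-class].
#' @param spec a [filterSpec()].
#' @return a filtered [EEGRecording-class] (events unchanged).
#' @export
bandpassRecording <- function(recording, spec) {
  fs <- samplingRate(recording)
  .check(spec$lpHz < fs / 2, "low-pass cutoff must be below Nyquist")
  bf <- signal::butter(spec$order, c(spec$hpHz, spec$lpHz) / (fs / 2),
                       type = "pass")
  x <- eegData(recording)
  out <- t(apply(x, 1, function(ch) as.numeric(signal::filter(bf, ch))))
  EEGRecording(out, fs, channelLabels(recording),
               stimulusEvents(recording))
}

#' Extract per-stimulus epochs from a recording
#'
#' Windows are half-open `[tminS, tmaxS)` relative to each stimulus onset,
#' with the onset sample at t = 0 and `round((tmaxS - tminS) * fs)` samples
#' per epoch. The recording is zero-padded (5 s at the end, and at the start
#' as needed) so that windows exceeding the run boundaries draw exact zeros,
#' mirroring the post-hoc convention for runs that stop early. Epoch order
#' preserves event order.
#'
#' @param recording an [EEGRecording-class].
#' @param events events data.frame with `onset_s` (defaults to the
#'   recording's own events).
#' @param tminS,tmaxS window bounds in seconds (defaults -0.1 and 1.0).
#' @return an [EEGEpochs-class]; metadata is the events table.
#' @export
extractEpochs <- function(recording, events = NULL, tminS = -0.1,
                          tmaxS = 1.0) {
  .check(tminS < tmaxS, "tminS must be < tmaxS")
  if (is.null(events)) events <- stimulusEvents(recording)
  fs <- samplingRate(recording)
  x <- eegData(recording)
  nCh <- nrow(x)
  nWin <- round((tmaxS - tminS) * fs)
  nEv <- nrow(events)
  if (nEv == 0) {
    return(EEGEpochs(array(0, dim = c(0, nCh, nWin)), fs, tminS, tmaxS,
                     channelLabels(recording), events))
  }
  .check(all(events$onset_s >= 0) &&
           all(events$onset_s <= ncol(x) / fs),
         "events must lie within the recording")
  padEnd <- round(5 * fs)
  padStart <- max(0L, -(round(min(events$onset_s) * fs) + round(tminS * fs)))
  xp <- cbind(matrix(0, nCh, padStart), x, matrix(0, nCh, padEnd))
  out <- array(0, dim = c(nEv, nCh, nWin))
  startIdx <- round(events$onset_s * fs) + round(tminS * fs) + padStart + 1L
  .check(max(startIdx) + nWin - 1L <= ncol(xp),
         "epoch window extends past the zero-padded run end")
  for (e in seq_len(nEv)) {
    out[e, , ] <- xp[, startIdx[e]:(startIdx[e] + nWin - 1L)]
  }
  EEGEpochs(out, fs, tminS, tmaxS, channelLabels(recording), events)
}

# FFT-domain resampling of one series to n_out samples (truncate or zero-pad
# the spectrum; Nyquist bin split symmetrically when downsampling from an
# even length).
.fftResample1 <- function(x, nOut) {
  nIn <- length(x)
  if (nOut == nIn) return(x)
  X <- fft(x)
  Y <- complex(length.out = nOut)
  nMin <- min(nIn, nOut)
  h <- floor(nMin / 2)
  Y[seq_len(h + 1)] <- X[seq_len(h + 1)]
  if (h >= 1) Y[(nOut - h + 1):nOut] <- X[(nIn - h + 1):nIn]
  if (nMin %% 2 == 0) {
    Y[h + 1] <- Y[h + 1] / 2
    Y[nOut - h + 1] <- Y[nOut - h + 1] + Y[h + 1]
  }
  Re(fft(Y, inverse = TRUE)) / nIn
}

#' Resample epochs to a lower sampling rate
#'
#' FFT-domain (spectrum truncation) resampling, an inherently anti-aliased
#' scheme; the new sample count is `round(duration * targetFs)` per epoch and
#' metadata is unchanged.
#'
#' @param epochs an [EEGEpochs-class].
#' @param targetFs target sampling rate (Hz), `0 < targetFs <= fs`.
#' @return an [EEGEpochs-class] at `targetFs`.
#' @export
resampleEpochs <- function(epochs, targetFs = 128) {
  .check(targetFs > 0, "targetFs must be positive")
  fs <- samplingRate(epochs)
  .check(targetFs <= fs, "targetFs must not exceed the current rate")
  if (targetFs == fs) return(epochs)
  d <- dim(eegData(epochs))
  nOut <- round((epochs@tmaxS - epochs@tminS) * targetFs)
  x <- eegData(epochs)
  out <- array(0, dim = c(d[1], d[2], nOut))
  for (e in seq_len(d[1])) {
    for (ch in seq_len(d[2])) {
      out[e, ch, ] <- .fftResample1(x[e, ch, ], nOut)
    }
  }
  EEGEpochs(out, targetFs, epochs@tminS, epochs@tmaxS,
            channelLabels(epochs), epochMetadata(epochs))
}

#' Interval-mean features
#'
#' Averages each channel in consecutive non-overlapping bins of `binS`
#' seconds covering `[startS, endS)` of the epoch window (sample t belongs to
#' bin k iff `startS + k*binS <= t < startS + (k+1)*binS`). Features are
#' ordered channel-major: all bins of channel 1, then channel 2, ... With 64
#' channels and ten 0.1-s bins this is the standard 640-dimensional feature
#' vector.
#'
#' @param epochs an [EEGEpochs-class].
#' @param startS,endS feature window (defaults 0 and the epoch's `tmaxS`);
#'   `(endS - startS) / binS` must be integral.
#' @param binS bin width in seconds (default 0.1).
#' @return list of class `FeatureMatrix`: `values` (events x features
#'   matrix), `featureNames`, and the epoch metadata as `metadata`.
#' @export
intervalMeans <- function(epochs, startS = 0, endS = NULL, binS = 0.1) {
  if (is.null(endS)) endS <- epochs@tmaxS
  .check(startS >= epochs@tminS && endS <= epochs@tmaxS + 1e-9,
         "[startS, endS) must lie inside the epoch window")
  nBins <- (endS - startS) / binS
  .check(abs(nBins - round(nBins)) < 1e-9,
         "(endS - startS) / binS must be integral")
  nBins <- as.integer(round(nBins))
  tt <- epochTimes(epochs)
  x <- eegData(epochs)
  d <- dim(x)
  # assign each sample to a bin (or NA outside the window)
  binOf <- floor((tt - startS) / binS + 1e-9)
  binOf[tt < startS - 1e-9 | binOf >= nBins | binOf < 0] <- NA
  vals <- matrix(0, d[1], d[2] * nBins)
  for (b in seq_len(nBins) - 1L) {
    sel <- which(!is.na(binOf) & binOf == b)
    m <- rowMeans(x[, , sel, drop = FALSE], dims = 2)
    vals[, (seq_len(d[2]) - 1L) * nBins + b + 1L] <- m
  }
  featureNames <- as.vector(t(outer(channelLabels(epochs),
                                    seq_len(nBins) - 1L,
                                    function(ch, b)
                                      sprintf("%s_bin%02d", ch, b))))
  structure(list(values = vals, featureNames = featureNames,
                 metadata = epochMetadata(epochs)),
            class = "FeatureMatrix")
}

#' Select EOG-related source components
#'
#' Given the source time courses of an externally supplied linear
#' decomposition (e.g. PCA+ICA) and the recorded EOG channels, returns for
#' each EOG channel the source with the largest |Pearson correlation|; the
#' union is returned de-duplicated and sorted. Ties are broken toward the
#' lowest source index.
#'
#' @param sourceTimecourses sources x samples matrix.
#' @param eogSignals EOG channels x samples matrix (or one vector).
#' @return integer vector of selected source indices (1-based).
#' @export
pickEogComponents <- function(sourceTimecourses, eogSignals) {
  if (is.vector(eogSignals)) eogSignals <- matrix(eogSignals, nrow = 1)
  .check(ncol(sourceTimecourses) == ncol(eogSignals),
         "sources and EOG signals must have equal sample counts")
  sv <- apply(sourceTimecourses, 1, sd)
  ev <- apply(eogSignals, 1, sd)
  .check(all(sv > 0) && all(ev > 0),
         "zero-variance input: correlation undefined")
  picked <- vapply(seq_len(nrow(eogSignals)), function(k) {
    r <- abs(as.numeric(cor(t(sourceTimecourses), eogSignals[k, ])))
    which.max(r)  # which.max takes the lowest index on ties
  }, 0L)
  sort(unique(picked))
}

#' Remove source components from a recording
#'
#' Projects the recording into source space with `unmixing`, zeroes the
#' listed source indices, and reconstructs with `mixing`. With a complete
#' decomposition and an empty index set this is the identity (up to the
#' subspace retained by the decomposition).
#'
#' @param recording an [EEGRecording-class].
#' @param unmixing sources x channels matrix.
#' @param mixing channels x sources matrix.
#' @param indices integer indices of sources to remove (1-based).
#' @return reconstructed [EEGRecording-class].
#' @export
removeComponents <- function(recording, unmixing, mixing, indices) {
  nSrc <- nrow(unmixing)
  .check(all(indices >= 1 & indices <= nSrc), "component index out of range")
  src <- unmixing %*% eegData(recording)
  if (length(indices)) src[indices, ] <- 0
  EEGRecording(mixing %*% src, samplingRate(recording),
               channelLabels(recording), stimulusEvents(recording))
}
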