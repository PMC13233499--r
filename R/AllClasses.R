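#' EEGRecording: continuous multichannel EEG with stimulus events
#'
#' S4 container for one run of continuous EEG. The signal is stored as a
#' channels x samples matrix in microvolts; stimulus events carry onsets in
#' recording time (seconds) together with the paradigm bookkeeping columns of
#' the events table (run, trial, sequence, slot, class_id, label, stream,
#' is_target).
#'
#' @slot data numeric matrix, channels x samples, microvolts.
#' @slot fsHz sampling rate in Hz.
#' @slot channelLabels character vector of unique channel names.
#' @slot events data.frame of stimulus events with at least `onset_s`.
#'
#' @seealso [synthesizeSession()], [bandpassRecording()], [extractEpochs()]
#' @export
setClass("EEGRecording",
  representation(
    data = "matrix",
    fsHz = "numeric",
    channelLabels = "character",
    events = "data.frame"
  )
)

setValidity("EEGRecording", function(object) {
  msg <- character()
  if (nrow(object@data) != length(object@channelLabels))
    msg <- c(msg, "number of data rows must equal number of channel labels")
  if (anyDuplicated(object@channelLabels))
    msg <- c(msg, "channel labels must be unique")
  if (length(object@fsHz) != 1L || object@fsHz <= 0)
    msg <- c(msg, "fsHz must be a single positive number")
  if (nrow(object@events) > 0) {
    dur <- ncol(object@data) / object@fsHz
    on <- object@events$onset_s
    if (is.null(on))
      msg <- c(msg, "events must have an onset_s column")
    else if (any(on < 0) || any(on > dur))
      msg <- c(msg, "event onsets must lie within [0, duration]")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an EEGRecording
#'
#' @param data channels x samples numeric matrix (microvolts).
#' @param fsHz sampling rate (Hz).
#' @param channelLabels character channel names; defaults to `ch1..chN`.
#' @param events data.frame of stimulus events (may be empty).
#' @return an [EEGRecording-class] object.
#' @export
EEGRecording <- function(data, fsHz, channelLabels = NULL,
                         events = data.frame()) {
  data <- as.matrix(data)
  if (is.null(channelLabels))
    channelLabels <- paste0("ch", seq_len(nrow(data)))
  new("EEGRecording", data = data, fsHz = as.numeric(fsHz),
      channelLabels = as.character(channelLabels), events = events)
}

#' EEGEpochs: per-stimulus EEG windows
#'
#' S4 container for epoched EEG. Data are stored as a 3-D array with
#' dimensions events x channels x samples; the time axis runs from `tminS`
#' (inclusive) to `tmaxS` (exclusive) with `round((tmaxS - tminS) * fsHz)`
#' samples, the stimulus onset sitting at t = 0.
#'
#' @slot data numeric array, events x channels x samples.
#' @slot fsHz sampling rate in Hz.
#' @slot tminS window start relative to stimulus onset (s).
#' @slot tmaxS window end relative to stimulus onset (s, exclusive).
#' @slot channelLabels character channel names.
#' @slot metadata data.frame, one row per epoch (run, trial, sequence,
#'   class_id, is_target, ...).
#' @export
setClass("EEGEpochs",
  representation(
    data = "array",
    fsHz = "numeric",
    tminS = "numeric",
    tmaxS = "numeric",
    channelLabels = "character",
    metadata = "data.frame"
  )
)

setValidity("EEGEpochs", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 3L)
    msg <- c(msg, "data must be a 3-D array (events x channels x samples)")
  else {
    if (d[2] != length(object@channelLabels))
      msg <- c(msg, "dim 2 must equal number of channel labels")
    nexp <- round((object@tmaxS - object@tminS) * object@fsHz)
    if (d[3] != nexp)
      msg <- c(msg, sprintf("dim 3 is %d but round((tmax-tmin)*fs) = %d",
                            d[3], nexp))
    if (nrow(object@metadata) != d[1])
      msg <- c(msg, "metadata rows must equal number of epochs")
  }
  if (object@tminS >= object@tmaxS)
    msg <- c(msg, "tminS must be < tmaxS")
  if (length(msg)) msg else TRUE
})

#' Construct an EEGEpochs object
#'
#' @param data events x channels x samples array.
#' @param fsHz sampling rate (Hz).
#' @param tminS,tmaxS window bounds relative to onset; half-open
#'   `[tminS, tmaxS)`.
#' @param channelLabels channel names.
#' @param metadata per-epoch data.frame.
#' @return an [EEGEpochs-class] object.
#' @export
EEGEpochs <- function(data, fsHz, tminS, tmaxS, channelLabels,
                      metadata) {
  new("EEGEpochs", data = data, fsHz = as.numeric(fsHz),
      tminS = as.numeric(tminS), tmaxS = as.numeric(tmaxS),
      channelLabels = as.character(channelLabels), metadata = metadata)
}
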