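# Accessor generics for the EEG containers.

#' Access the signal array of an EEG container
#' @param x an [EEGRecording-class] or [EEGEpochs-class] object.
#' @return for a recording, a channels x samples matrix; for epochs, an
#'   events x channels x samples array (microvolts).
#' @export
setGeneric("eegData", function(x) standardGeneric("eegData"))

#' Sampling rate accessor
#' @param x an EEG container.
#' @return sampling rate in Hz.
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' Channel label accessor
#' @param x an EEG container.
#' @return character vector of channel names.
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))

#' Stimulus events of a recording
#' @param x an [EEGRecording-class].
#' @return data.frame of events.
#' @export
setGeneric("stimulusEvents", function(x) standardGeneric("stimulusEvents"))

#' Per-epoch metadata
#' @param x an [EEGEpochs-class].
#' @return data.frame with one row per epoch.
#' @export
setGeneric("epochMetadata", function(x) standardGeneric("epochMetadata"))

#' Number of epochs
#' @param x an [EEGEpochs-class].
#' @return integer count.
#' @export
setGeneric("nEpochs", function(x) standardGeneric("nEpochs"))

#' Epoch time axis
#' @param x an [EEGEpochs-class].
#' @return numeric vector of sample times relative to stimulus onset (s).
#' @export
setGeneric("epochTimes", function(x) standardGeneric("epochTimes"))

#' @rdname eegData
#' @export
setMethod("eegData", "EEGRecording", function(x) x@data)
#' @rdname eegData
#' @export
setMethod("eegData", "EEGEpochs", function(x) x@data)

#' @rdname samplingRate
#' @export
setMethod("samplingRate", "EEGRecording", function(x) x@fsHz)
#' @rdname samplingRate
#' @export
setMethod("samplingRate", "EEGEpochs", function(x) x@fsHz)

#' @rdname channelLabels
#' @export
setMethod("channelLabels", "EEGRecording", function(x) x@channelLabels)
#' @rdname channelLabels
#' @export
setMethod("channelLabels", "EEGEpochs", function(x) x@channelLabels)

#' @rdname stimulusEvents
#' @export
setMethod("stimulusEvents", "EEGRecording", function(x) x@events)

#' @rdname epochMetadata
#' @export
setMethod("epochMetadata", "EEGEpochs", function(x) x@metadata)

#' @rdname nEpochs
#' @export
setMethod("nEpochs", "EEGEpochs", function(x) dim(x@data)[1])

#' @rdname epochTimes
#' @export
setMethod("epochTimes", "EEGEpochs", function(x) {
  n <- dim(x@data)[3]
  x@tminS + (seq_len(n) - 1) / x@fsHz
})

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf(
    "EEGRecording: %d channels x %d samples @ %g Hz (%.1f s), %d events\n",
    nrow(object@data), ncol(object@data), object@fsHz,
    ncol(object@data) / object@fsHz, nrow(object@events)))
  cat("  channels:", paste(head(object@channelLabels, 8), collapse = ", "),
      if (length(object@channelLabels) > 8) "..." else "", "\n")
})

setMethod("show", "EEGEpochs", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "EEGEpochs: %d epochs x %d channels x %d samples @ %g Hz, [%g, %g) s\n",
    d[1], d[2], d[3], object@fsHz, object@tminS, object@tmaxS))
  if (!is.null(object@metadata$is_target))
    cat(sprintf("  targets: %d / %d\n",
                sum(object@metadata$is_target), d[1]))
})
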