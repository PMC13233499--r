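# Pipeline registry: the three per-stimulus scorers behind one train/score
# contract.  Custom scorers can be registered by supplying a list with
# `train(epochs, labels)` returning an object with a `score(epochs)` closure.

.PIPELINES <- c("lda", "xdw_lda", "xdwcov_ts_lda")

#' Train a per-stimulus decoding pipeline
#'
#' Pipelines: `"lda"` (interval-mean features, shrinkage LDA),
#' `"xdw_lda"` (xDAWN to `nComponents` virtual channels, then interval
#' means and shrinkage LDA), and `"xdwcov_ts_lda"` (xDAWN, prototype-
#' augmented ERP covariances, tangent-space embedding at the Riemannian
#' geometric mean, shrinkage LDA).
#'
#' @param epochs training [EEGEpochs-class] (sensor space, window
#'   `[-0.1, tmax)`).
#' @param labels logical target indicator (defaults to metadata
#'   `is_target`).
#' @param pipeline one of `"lda"`, `"xdw_lda"`, `"xdwcov_ts_lda"`.
#' @param nComponents xDAWN components (default 2).
#' @param binS interval-mean bin width (default 0.1 s).
#' @return list of class `SpellerPipeline` holding the fitted stages.
#' @export
trainPipeline <- function(epochs, labels = NULL,
                          pipeline = c("lda", "xdw_lda", "xdwcov_ts_lda"),
                          nComponents = 2L, binS = 0.1) {
  pipeline <- match.arg(pipeline)
  if (is.null(labels)) labels <- epochMetadata(epochs)$is_target
  labels <- as.logical(labels)
  obj <- list(pipeline = pipeline, binS = binS,
              tmaxS = epochs@tmaxS)
  if (pipeline == "lda") {
    fm <- intervalMeans(epochs, 0, epochs@tmaxS, binS)
    obj$lda <- fitShrinkageLda(fm, labels)
  } else {
    xdw <- fitXdawn(epochs, labels, nComponents = nComponents)
    obj$xdawn <- xdw
    if (pipeline == "xdw_lda") {
      fm <- intervalMeans(applyXdawn(xdw, epochs), 0, epochs@tmaxS, binS)
      obj$lda <- fitShrinkageLda(fm, labels)
    } else {
      covs <- erpCovariances(epochs, xdw)
      obj$referenceMean <- spdGeometricMean(covs)
      fm <- tangentEmbed(covs, obj$referenceMean)
      obj$lda <- fitShrinkageLda(fm, labels)
    }
  }
  structure(obj, class = "SpellerPipeline")
}

#' Score epochs with a trained pipeline
#'
#' @param model a `SpellerPipeline` from [trainPipeline()].
#' @param epochs [EEGEpochs-class] to score (same channels and window as
#'   training).
#' @return numeric score per epoch (positive = target-like).
#' @export
scorePipeline <- function(model, epochs) {
  if (model$pipeline == "lda") {
    fm <- intervalMeans(epochs, 0, model$tmaxS, model$binS)
    return(ldaScore(model$lda, fm))
  }
  if (model$pipeline == "xdw_lda") {
    fm <- intervalMeans(applyXdawn(model$xdawn, epochs), 0, model$tmaxS,
                        model$binS)
    return(ldaScore(model$lda, fm))
  }
  covs <- erpCovariances(epochs, model$xdawn)
  fm <- tangentEmbed(covs, model$referenceMean)
  ldaScore(model$lda, fm)
}

#' @export
print.SpellerPipeline <- function(x, ...) {
  cat(sprintf("SpellerPipeline '%s' (tmax %g s, bin %g s)\n",
              x$pipeline, x$tmaxS, x$binS))
  if (!is.null(x$lda))
    cat(sprintf("  LDA: %d features, shrinkage %.4f\n",
                length(x$lda$w), x$lda$shrinkageLambda))
  invisible(x)
}
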