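# Per-stimulus binary decoders: Ledoit-Wolf shrinkage LDA, xDAWN spatial
# filtering, and the xDAWN-covariance / Riemannian tangent-space embedding.

#' Fisher LDA with Ledoit-Wolf covariance shrinkage
#'
#' Binary target vs non-target discriminant. The pooled within-class
#' covariance `Sw` of the class-centred data is shrunk toward the scaled
#' identity `nu * I` (`nu = tr(S)/p`) with the Ledoit-Wolf intensity, then
#' `w = Sw^-1 (m1 - m0)` and the bias places the projected midpoint of the
#' class means at score zero, so targets train to positive scores.
#'
#' @param features a `FeatureMatrix` from [intervalMeans()], or a plain
#'   events x features matrix.
#' @param labels logical (or 0/1) vector, TRUE/1 = target.
#' @param shrinkage optional fixed shrinkage intensity in `[0, 1]`;
#'   default NULL estimates it by the Ledoit-Wolf formula.
#' @return list of class `LdaModel`: `w`, `b`, `shrinkageLambda`,
#'   `classMeans` (m0, m1 columns), `nu`.
#' @examples
#' x <- matrix(c(0, 2, 4, 6), ncol = 1)
#' fitShrinkageLda(x, c(FALSE, FALSE, TRUE, TRUE))$w > 0
#' @export
fitShrinkageLda <- function(features, labels, shrinkage = NULL) {
  x <- if (inherits(features, "FeatureMatrix")) features$values else
    as.matrix(features)
  y <- as.logical(labels)
  .check(length(y) == nrow(x), "labels must match feature rows")
  .check(any(y) && any(!y), "both classes must be present")
  m1 <- colMeans(x[y, , drop = FALSE])
  m0 <- colMeans(x[!y, , drop = FALSE])
  n <- nrow(x)
  p <- ncol(x)
  # class-centre
  xc <- x
  xc[y, ] <- sweep(x[y, , drop = FALSE], 2, m1)
  xc[!y, ] <- sweep(x[!y, , drop = FALSE], 2, m0)
  # pooled within-class covariance (unbiased, N - 2 classes)
  S <- crossprod(xc) / (n - 2)
  nu <- sum(diag(S)) / p
  if (is.null(shrinkage)) {
    # Ledoit-Wolf intensity on the centred data (biased normalisation)
    Sb <- crossprod(xc) / n
    nub <- sum(diag(Sb)) / p
    x2 <- xc^2
    beta2 <- sum(crossprod(x2)) / n^2 - sum(Sb^2) / n
    delta2 <- sum((Sb - diag(nub, p))^2)
    lambda <- if (delta2 > 0) max(0, min(1, beta2 / delta2)) else 0
  } else {
    lambda <- shrinkage
  }
  Sw <- (1 - lambda) * S
  diag(Sw) <- diag(Sw) + lambda * nu
  w <- solve(Sw, m1 - m0)
  b <- -sum(w * (m1 + m0)) / 2
  structure(list(w = as.numeric(w), b = b, shrinkageLambda = lambda,
                 classMeans = cbind(m0 = m0, m1 = m1), nu = nu),
            class = "LdaModel")
}

#' Score events with an LDA model
#'
#' `d_i = w' x_i + b`, the signed distance proxy from the classification
#' hyperplane; positive scores indicate target-like responses.
#'
#' @param model an `LdaModel`.
#' @param features `FeatureMatrix` or events x features matrix.
#' @return numeric score per event.
#' @export
ldaScore <- function(model, features) {
  x <- if (inherits(features, "FeatureMatrix")) features$values else
    as.matrix(features)
  .check(ncol(x) == length(model$w), "feature dimension mismatch")
  as.numeric(x %*% model$w + model$b)
}

# symmetric eigen helpers
.symSqrtInv <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  v <- pmax(e$values, .Machine$double.eps)
  list(half = e$vectors %*% (sqrt(v) * t(e$vectors)),
       invhalf = e$vectors %*% ((1 / sqrt(v)) * t(e$vectors)))
}
.logm <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  e$vectors %*% (log(pmax(e$values, .Machine$double.eps)) * t(e$vectors))
}
.expm <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  e$vectors %*% (exp(e$values) * t(e$vectors))
}

#' Fit an xDAWN spatial filter
#'
#' Solves the generalized eigenproblem between the evoked (average target)
#' response covariance and the total signal covariance, maximising the
#' signal-to-signal-plus-noise ratio; filters are returned in decreasing
#' eigenvalue-ratio order, with each filter's sign fixed so its
#' largest-magnitude pattern coefficient is positive. Fitted on the
#' `[0, tmax)` portion of the epochs.
#'
#' @param epochs an [EEGEpochs-class].
#' @param labels logical target indicator per epoch (defaults to the
#'   metadata's `is_target`).
#' @param nComponents number of spatial filters to keep (default 2).
#' @param jitter relative diagonal regularisation applied to the total
#'   covariance if it is rank-deficient (default 1e-9).
#' @return list of class `SpatialFilter`: `projection`
#'   (nComponents x channels), `patterns` (channels x nComponents),
#'   `eigenvalues` (non-increasing), `evokedPrototype`
#'   (nComponents x samples, the filtered average target response), plus the
#'   window bookkeeping needed to apply it.
#' @export
fitXdawn <- function(epochs, labels = NULL, nComponents = 2L,
                     jitter = 1e-9) {
  x <- eegData(epochs)
  d <- dim(x)
  if (is.null(labels)) labels <- epochMetadata(epochs)$is_target
  labels <- as.logical(labels)
  .check(any(labels), "no target epochs")
  .check(d[2] >= nComponents, "need at least nComponents channels")
  # feature window [0, tmax)
  tt <- epochTimes(epochs)
  sel <- which(tt >= -1e-9)
  # evoked response: average target epoch
  P <- colMeans(x[labels, , sel, drop = FALSE], dims = 1)   # ch x samp
  Ce <- tcrossprod(P) / ncol(P)
  # total covariance over all epochs
  Ct <- matrix(0, d[2], d[2])
  for (e in seq_len(d[1])) {
    xe <- x[e, , sel]
    Ct <- Ct + tcrossprod(xe)
  }
  Ct <- Ct / (d[1] * length(sel))
  diag(Ct) <- diag(Ct) + jitter * mean(diag(Ct))
  si <- .symSqrtInv(Ct)
  M <- si$invhalf %*% Ce %*% si$invhalf
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  W <- t(si$invhalf %*% e$vectors[, seq_len(nComponents), drop = FALSE])
  patterns <- Ct %*% t(W)  # forward model up to scale
  for (k in seq_len(nComponents)) {
    j <- which.max(abs(patterns[, k]))
    if (patterns[j, k] < 0) {
      W[k, ] <- -W[k, ]
      patterns[, k] <- -patterns[, k]
    }
    patterns[, k] <- patterns[, k] / sqrt(sum(patterns[, k]^2))
  }
  structure(list(projection = W, patterns = patterns,
                 eigenvalues = e$values[seq_len(nComponents)],
                 evokedPrototype = W %*% P,
                 windowSel = sel),
            class = "SpatialFilter")
}

#' Apply an xDAWN filter to epochs
#'
#' @param filter a `SpatialFilter`.
#' @param epochs an [EEGEpochs-class] with the channel set the filter was
#'   fitted on.
#' @return an [EEGEpochs-class] whose channels are the virtual xDAWN
#'   components.
#' @export
applyXdawn <- function(filter, epochs) {
  x <- eegData(epochs)
  d <- dim(x)
  W <- filter$projection
  out <- array(0, dim = c(d[1], nrow(W), d[3]))
  for (e in seq_len(d[1])) out[e, , ] <- W %*% x[e, , ]
  EEGEpochs(out, samplingRate(epochs), epochs@tminS, epochs@tmaxS,
            paste0("xdw", seq_len(nrow(W))), epochMetadata(epochs))
}

#' Prototype-augmented ERP covariance matrices
#'
#' For each epoch, the xDAWN-filtered epoch (restricted to the filter's
#' `[0, tmax)` window) is stacked under the filtered evoked prototype and the
#' sample covariance of the stack is computed (no mean removal), giving
#' `2n x 2n` matrices for `n` components; this keeps the evoked mean that a
#' plain per-epoch covariance would discard. Matrices are jitter-regularised
#' to SPD.
#'
#' @param epochs an [EEGEpochs-class] (sensor space).
#' @param filter a `SpatialFilter` from [fitXdawn()].
#' @param jitter relative diagonal loading (default 1e-10).
#' @return list of class `SpdSet`: `matrices` (list of SPD matrices) and
#'   `n` (matrix dimension).
#' @export
erpCovariances <- function(epochs, filter, jitter = 1e-10) {
  x <- eegData(epochs)
  .check(all(is.finite(x)), "non-finite epoch data")
  d <- dim(x)
  W <- filter$projection
  P <- filter$evokedPrototype
  sel <- filter$windowSel
  mats <- vector("list", d[1])
  for (e in seq_len(d[1])) {
    Z <- W %*% x[e, , sel]
    S <- rbind(P, Z)
    C <- tcrossprod(S) / ncol(S)
    diag(C) <- diag(C) + jitter * mean(diag(C)) + 1e-12
    mats[[e]] <- C
  }
  structure(list(matrices = mats, n = 2L * nrow(W)), class = "SpdSet")
}

#' Riemannian (affine-invariant) geometric mean of SPD matrices
#'
#' Fixed-point iteration `G <- G^{1/2} exp(mean_i log(G^{-1/2} C_i
#' G^{-1/2})) G^{1/2}` starting from the arithmetic mean; converged when the
#' Frobenius norm of the mean log falls below `tol`.
#'
#' @param spdSet an `SpdSet` or plain list of SPD matrices.
#' @param tol convergence tolerance (default 1e-8).
#' @param maxIter maximum iterations (default 50).
#' @return the SPD geometric mean matrix; attribute `converged` reports
#'   convergence and a warning is raised otherwise.
#' @export
spdGeometricMean <- function(spdSet, tol = 1e-8, maxIter = 50L) {
  mats <- if (inherits(spdSet, "SpdSet")) spdSet$matrices else spdSet
  .check(length(mats) > 0, "empty SPD set")
  if (length(mats) == 1L) {
    G <- mats[[1]]
    attr(G, "converged") <- TRUE
    return(G)
  }
  G <- Reduce(`+`, mats) / length(mats)
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    si <- .symSqrtInv(G)
    L <- matrix(0, nrow(G), ncol(G))
    for (C in mats) {
      L <- L + .logm(si$invhalf %*% C %*% si$invhalf)
    }
    L <- L / length(mats)
    G <- si$half %*% .expm(L) %*% si$half
    G <- (G + t(G)) / 2
    if (sqrt(sum(L^2)) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) warning("geometric mean did not converge in ",
                          maxIter, " iterations")
  attr(G, "converged") <- converged
  G
}

#' Tangent-space embedding of SPD matrices
#'
#' Maps each matrix to `log(G^{-1/2} C G^{-1/2})` at the reference `G` and
#' vectorises the upper triangle row-wise with off-diagonal entries scaled by
#' sqrt(2), so the Euclidean norm of the vector equals the affine-invariant
#' Riemannian distance between `C` and `G`. A `d x d` matrix yields
#' `d(d+1)/2` features.
#'
#' @param spdSet an `SpdSet` or list of SPD matrices.
#' @param reference SPD reference matrix (typically [spdGeometricMean()]).
#' @return list of class `FeatureMatrix` (`values`: matrices x features).
#' @export
tangentEmbed <- function(spdSet, reference) {
  mats <- if (inherits(spdSet, "SpdSet")) spdSet$matrices else spdSet
  d <- nrow(reference)
  si <- .symSqrtInv(reference)
  ut <- upper.tri(reference, diag = TRUE)
  # row-wise upper-triangle order: (1,1), (1,2), ..., (1,d), (2,2), ...
  ord <- order(row(reference)[ut], col(reference)[ut])
  scale <- ifelse(row(reference)[ut] == col(reference)[ut], 1, sqrt(2))
  vals <- t(vapply(mats, function(C) {
    L <- .logm(si$invhalf %*% C %*% si$invhalf)
    (L[ut] * scale)[ord]
  }, numeric(d * (d + 1) / 2)))
  nm <- outer(seq_len(d), seq_len(d), function(i, j)
    sprintf("ts_%d_%d", i, j))
  structure(list(values = vals,
                 featureNames = (nm[ut])[ord],
                 metadata = NULL),
            class = "FeatureMatrix")
}
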