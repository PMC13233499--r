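test_that("shrinkage LDA matches hand arithmetic on the 1-D toy problem", {
  x <- matrix(c(0, 2, 4, 6), ncol = 1)
  y <- c(FALSE, FALSE, TRUE, TRUE)
  # hand: m0 = 1, m1 = 5; centred {-1,1,-1,1}; pooled S = 4/2 = 2 = nu,
  # so any shrinkage leaves Sw = 2: w = 4/2 = 2, b = -w * 3 = -6
  m <- fitShrinkageLda(x, y, shrinkage = 0)
  expect_equal(m$w, 2)
  expect_equal(m$b, -6)
  expect_gt(m$w, 0)
  expect_gt(ldaScore(m, matrix(5)), ldaScore(m, matrix(1)))
  expect_equal(ldaScore(m, matrix(6)), 2 * 6 - 6)
  # shrinkage toward nu*I is a no-op when S is already nu*I
  mLw <- fitShrinkageLda(x, y)
  expect_equal(mLw$w, m$w)
  # midpoint of projected class means scores zero
  expect_equal(ldaScore(m, matrix(3)), 0)
})

test_that("LDA scores negate under label swap and are affine in x", {
  set.seed(10)
  x <- matrix(rnorm(200 * 5), 200)
  y <- rep(c(TRUE, FALSE), 100)
  x[y, 1] <- x[y, 1] + 2
  a <- fitShrinkageLda(x, y)
  b <- fitShrinkageLda(x, !y)
  expect_equal(a$w, -b$w, tolerance = 1e-10)
  expect_equal(a$b, -b$b, tolerance = 1e-10)
  expect_equal(ldaScore(a, x), -ldaScore(b, x), tolerance = 1e-9)
  # affine: score(x + d) - score(x) = w'd
  d <- rnorm(5)
  expect_equal(ldaScore(a, sweep(x, 2, -d)) - ldaScore(a, x),
               rep(sum(a$w * d), 200), tolerance = 1e-9)
  expect_error(fitShrinkageLda(x, rep(TRUE, 200)), "both classes")
  expect_error(ldaScore(a, x[, 1:3]), "dimension")
})

test_that("LDA separates distant Gaussian clouds perfectly", {
  set.seed(11)
  n <- 200
  x <- rbind(matrix(rnorm(n * 4), n), matrix(rnorm(n * 4, mean = 10), n))
  y <- rep(c(FALSE, TRUE), each = n)
  m <- fitShrinkageLda(x, y)
  expect_equal(aucScore(ldaScore(m, x), y), 1.0)
})

test_that("LDA direction is invariant to common translation", {
  set.seed(12)
  x <- matrix(rnorm(100 * 6), 100)
  y <- rep(c(TRUE, FALSE), 50)
  x[y, 2] <- x[y, 2] + 1
  shift <- sweep(x, 2, rnorm(6, 5))
  expect_equal(fitShrinkageLda(x, y)$w, fitShrinkageLda(shift, y)$w,
               tolerance = 1e-9)
})

test_that("the Ledoit-Wolf intensity matches its reference implementation", {
  # oracle: direct transcription of the scaled-identity Ledoit-Wolf formula
  # computed independently of the package internals
  lwOracle <- function(xc) {
    n <- nrow(xc)
    S <- crossprod(xc) / n
    nu <- mean(diag(S))
    b2 <- 0
    for (i in seq_len(n)) {
      dev <- tcrossprod(xc[i, ]) - S
      b2 <- b2 + sum(dev^2)
    }
    b2 <- b2 / n^2
    d2 <- sum((S - diag(nu, ncol(S)))^2)
    min(1, b2 / d2)
  }
  set.seed(13)
  x <- matrix(rnorm(60 * 8), 60)
  y <- rep(c(TRUE, FALSE), 30)
  x[y, 1] <- x[y, 1] + 1
  m <- fitShrinkageLda(x, y)
  xc <- x
  xc[y, ] <- sweep(x[y, , drop = FALSE], 2, colMeans(x[y, , drop = FALSE]))
  xc[!y, ] <- sweep(x[!y, , drop = FALSE], 2,
                    colMeans(x[!y, , drop = FALSE]))
  expect_equal(m$shrinkageLambda, lwOracle(xc), tolerance = 1e-10)
  expect_gt(m$shrinkageLambda, 0)
  expect_lt(m$shrinkageLambda, 1)
})

test_that("xDAWN recovers a planted single-channel evoked pattern", {
  set.seed(14)
  nEv <- 400
  nCh <- 6
  nS <- 50
  lab <- rep(c(TRUE, FALSE, FALSE, FALSE), nEv / 4)
  bump <- sin(pi * (1:nS) / nS)
  arr <- array(rnorm(nEv * nCh * nS, sd = 0.2), dim = c(nEv, nCh, nS))
  for (e in which(lab)) arr[e, 1, ] <- arr[e, 1, ] + 5 * bump
  ep <- makeEpochs(arr, fs = 100, tmin = 0, tmax = 0.5,
                   meta = data.frame(class_id = 0L, is_target = lab))
  xdw <- fitXdawn(ep, nComponents = 2L)
  cosine <- abs(sum(xdw$patterns[, 1] * c(1, rep(0, nCh - 1))))
  expect_gt(cosine, 0.95)
  # ordering and shape contracts
  expect_true(all(diff(xdw$eigenvalues) <= 1e-12))
  proj <- applyXdawn(xdw, ep)
  expect_equal(dim(eegData(proj))[2], 2L)
  # deterministic sign: largest-magnitude pattern coefficient positive
  expect_gt(max(xdw$patterns[, 1]), 0)
  expect_equal(max(abs(xdw$patterns[, 1])), max(xdw$patterns[, 1]))
})

test_that("ERP covariances are prototype-augmented and scale quadratically", {
  set.seed(15)
  nS <- 40
  P <- rbind(sin(2 * pi * (1:nS) / nS), cos(2 * pi * (1:nS) / nS))
  fakeFilter <- structure(list(projection = diag(2), evokedPrototype = P,
                               windowSel = seq_len(nS)),
                          class = "SpatialFilter")
  # epoch identical to the prototype: equal diagonal blocks
  arr <- array(0, dim = c(1, 2, nS))
  arr[1, , ] <- P
  ep <- makeEpochs(arr, fs = 100, tmin = 0, tmax = 0.4)
  covs <- erpCovariances(ep, fakeFilter, jitter = 0)
  C <- covs$matrices[[1]]
  expect_equal(dim(C), c(4L, 4L))     # 2n x 2n for n = 2 components
  expect_equal(C[1:2, 1:2], C[3:4, 3:4], tolerance = 1e-9)
  # scaling epochs by c scales matrices by c^2 (prototype fixed)
  arr2 <- arr
  arr2[1, , ] <- 3 * P
  covs2 <- erpCovariances(makeEpochs(arr2, fs = 100, tmin = 0, tmax = 0.4),
                          fakeFilter, jitter = 0)
  expect_equal(covs2$matrices[[1]][3:4, 3:4], 9 * C[3:4, 3:4],
               tolerance = 1e-9)
})

test_that("the Riemannian mean satisfies its closed-form identities", {
  A <- matrix(c(2, 0.3, 0.3, 1), 2)
  # singleton and idempotence
  expect_equal(spdGeometricMean(list(A)), A, ignore_attr = TRUE)
  expect_equal(spdGeometricMean(list(A, A)), A, tolerance = 1e-8,
               ignore_attr = TRUE)
  # commuting matrices: element-wise geometric mean of eigenvalues
  G <- spdGeometricMean(list(diag(c(1, 4)), diag(c(4, 1))))
  expect_equal(G, diag(c(2, 2)), tolerance = 1e-7, ignore_attr = TRUE)
})

test_that("the Riemannian mean is congruence invariant", {
  set.seed(16)
  mats <- lapply(1:5, function(i) {
    M <- matrix(rnorm(9), 3)
    crossprod(M) + diag(3)
  })
  W <- matrix(rnorm(9), 3)
  G <- spdGeometricMean(mats)
  GW <- spdGeometricMean(lapply(mats, function(C) W %*% C %*% t(W)))
  expect_equal(GW, W %*% G %*% t(W), tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("tangent embedding matches closed forms and the distance norm", {
  # reference itself maps to zero
  A <- matrix(c(3, 1, 1, 2), 2)
  expect_equal(as.numeric(tangentEmbed(list(A), A)$values), rep(0, 3),
               tolerance = 1e-10)
  # diagonal closed form at the identity
  v <- as.numeric(tangentEmbed(list(diag(c(exp(1), exp(-1)))),
                               diag(2))$values)
  expect_equal(v, c(1, 0, -1), tolerance = 1e-10)
  # d = 4 -> d(d+1)/2 = 10 features
  set.seed(17)
  M <- matrix(rnorm(16), 4)
  C4 <- crossprod(M) + diag(4)
  expect_equal(ncol(tangentEmbed(list(C4), diag(4))$values), 10L)
  # singleton norm equals the affine-invariant Riemannian distance
  B <- matrix(c(2, 0.5, 0.5, 1.5), 2)
  ref <- matrix(c(1, 0.2, 0.2, 1), 2)
  v2 <- as.numeric(tangentEmbed(list(B), ref)$values)
  ev <- eigen(solve(ref, B), only.values = TRUE)$values
  expect_equal(sqrt(sum(v2^2)), sqrt(sum(log(Re(ev))^2)), tolerance = 1e-8)
})

test_that("all pipelines sit at chance when epochs carry no signal", {
  set.seed(18)
  nEv <- 600
  arr <- array(rnorm(nEv * 4 * 55), dim = c(nEv, 4, 55))
  lab <- rep(c(TRUE, rep(FALSE, 5)), 100)
  ep <- makeEpochs(arr, fs = 50, tmin = -0.1, tmax = 1.0,
                   meta = data.frame(class_id = 0L, is_target = lab))
  holdArr <- array(rnorm(nEv * 4 * 55), dim = c(nEv, 4, 55))
  hold <- makeEpochs(holdArr, fs = 50, tmin = -0.1, tmax = 1.0,
                     meta = data.frame(class_id = 0L, is_target = lab))
  for (pl in c("lda", "xdw_lda", "xdwcov_ts_lda")) {
    model <- trainPipeline(ep, pipeline = pl)
    auc <- aucScore(scorePipeline(model, hold), lab)
    expect_lt(abs(auc - 0.5), 0.06)
  }
})
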