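toyRecording <- function(x, fs, events = data.frame()) {
  EEGRecording(matrix(x, nrow = 1), fs, "ch1", events)
}

test_that("the causal band-pass matches its frequency-response oracle", {
  fs <- 250
  spec <- filterSpec(1, 40)
  tt <- (0:(10 * fs - 1)) / fs
  # oracle: gain of the designed filter evaluated at the probe frequencies
  bf <- signal::butter(2, c(1, 40) / (fs / 2), type = "pass")
  gainAt <- function(f) {
    h <- signal::freqz(bf, Fs = fs)
    approx(h$f, Mod(h$h), f)$y
  }
  steadyAmp <- function(f) {
    rec <- toyRecording(sin(2 * pi * f * tt), fs)
    y <- eegData(bandpassRecording(rec, spec))[1, ]
    max(abs(y[(5 * fs):(10 * fs - 1)]))  # past the transient
  }
  expect_equal(steadyAmp(5), gainAt(5), tolerance = 0.01)
  expect_gt(steadyAmp(5), 0.95)            # within 5% of unity at 5 Hz
  expect_lt(steadyAmp(80), 0.3)            # strong stop-band attenuation
  expect_equal(steadyAmp(80), gainAt(80), tolerance = 0.05)
  # DC rejection: constant input decays below 1% after 2 s
  recDc <- toyRecording(rep(1, 10 * fs), fs)
  yDc <- eegData(bandpassRecording(recDc, spec))[1, ]
  expect_lt(max(abs(yDc[(2 * fs):(10 * fs - 1)])), 0.01)
})

test_that("filtering is linear and rejects cutoffs at or above Nyquist", {
  fs <- 100
  spec <- filterSpec(1, 30)
  set.seed(1)
  x <- rnorm(500)
  y <- rnorm(500)
  f <- function(v) eegData(bandpassRecording(toyRecording(v, fs), spec))[1, ]
  expect_equal(f(2 * x + 3 * y), 2 * f(x) + 3 * f(y), tolerance = 1e-10)
  expect_error(bandpassRecording(toyRecording(x, fs), filterSpec(1, 60)),
               "Nyquist")
  expect_error(filterSpec(40, 8), "hpHz < lpHz")
})

test_that("epoch extraction follows the half-open window convention", {
  fs <- 1000
  n <- 95 * fs
  rec <- EEGRecording(matrix(rnorm(2 * n), nrow = 2), fs, c("a", "b"),
                      data.frame(onset_s = (0:449) * 0.2 + 1))
  ep <- extractEpochs(rec, tminS = -0.1, tmaxS = 1.0)
  expect_equal(dim(eegData(ep)), c(450L, 2L, 1100L))
  expect_equal(nEpochs(ep), 450L)
  # onset sample at t = 0
  tt <- epochTimes(ep)
  expect_equal(tt[1], -0.1)
  expect_true(any(abs(tt) < 1e-12))
  idx0 <- which.min(abs(tt))
  on1 <- round((1.0) * fs) + 1L
  expect_equal(eegData(ep)[1, , idx0], eegData(rec)[, on1])
})

test_that("windows past the run end draw zeros from the padding region", {
  fs <- 100
  n <- 10 * fs
  rec <- EEGRecording(matrix(rnorm(n), nrow = 1), fs, "a",
                      data.frame(onset_s = 9.5))
  ep <- extractEpochs(rec, tminS = -0.1, tmaxS = 2.1)
  x <- eegData(ep)[1, 1, ]
  tt <- epochTimes(ep)
  expect_true(all(x[tt >= 0.5] == 0))          # beyond the recording: zeros
  expect_true(any(x[tt < 0.5] != 0))
})

test_that("epoching no events yields an empty container", {
  rec <- EEGRecording(matrix(0, 1, 100), 100, "a", data.frame())
  ep <- extractEpochs(rec, tminS = -0.1, tmaxS = 0.5)
  expect_equal(nEpochs(ep), 0L)
  expect_error(extractEpochs(rec, tminS = 1, tmaxS = 1), "tminS")
})

test_that("FFT resampling keeps counts, identity and amplitudes", {
  fs <- 1000
  set.seed(2)
  nEv <- 3
  arr <- array(rnorm(nEv * 2 * 2200), dim = c(nEv, 2, 2200))
  ep <- makeEpochs(arr, fs = fs, tmin = -0.1, tmax = 2.1)
  down <- resampleEpochs(ep, 128)
  expect_equal(dim(eegData(down))[3], 282L)  # round(2.2 * 128)
  expect_equal(samplingRate(down), 128)
  expect_identical(epochMetadata(down), epochMetadata(ep))
  # identity at the same rate
  expect_identical(resampleEpochs(ep, fs), ep)
  # spectral oracle: a pure 5 Hz tone keeps its amplitude within 2%
  tt <- (-0.1) + (0:2199) / fs
  tone <- aperm(array(sin(2 * pi * 5 * tt), dim = c(2200, nEv, 2)),
                c(2, 3, 1))
  epT <- makeEpochs(tone, fs = fs, tmin = -0.1, tmax = 2.1)
  dn <- resampleEpochs(epT, 128)
  mid <- 60:220
  t2 <- (-0.1) + (0:281) / 128
  expect_equal(max(abs(eegData(dn)[1, 1, mid])), 1, tolerance = 0.02)
  expect_error(resampleEpochs(ep, 2000), "exceed")
})

test_that("interval means reproduce block averages channel-major", {
  # single channel equal to the sample index at fs 100
  fs <- 100
  arr <- array(0, dim = c(1, 1, round(1.1 * fs)))
  arr[1, 1, ] <- seq_len(round(1.1 * fs)) - 1
  ep <- makeEpochs(arr, fs = fs, tmin = -0.1, tmax = 1.0)
  fm <- intervalMeans(ep, 0, 0.1, binS = 0.1)
  tt <- epochTimes(ep)
  oracle <- mean((seq_len(110) - 1)[tt >= 0 & tt < 0.1])
  expect_equal(as.numeric(fm$values), oracle)

  # constant signal: every feature equals the constant
  arr2 <- array(7, dim = c(2, 3, 110))
  fm2 <- intervalMeans(makeEpochs(arr2, fs = fs), 0, 1.0, binS = 0.1)
  expect_true(all(fm2$values == 7))
  expect_equal(ncol(fm2$values), 30L)  # 3 channels x 10 bins

  # 64 channels x ten 0.1-s bins -> the 640-dimensional feature vector
  arr3 <- array(rnorm(64 * 110), dim = c(1, 64, 110))
  fm3 <- intervalMeans(makeEpochs(arr3, fs = fs), 0, 1.0, binS = 0.1)
  expect_equal(ncol(fm3$values), 640L)
  expect_error(intervalMeans(makeEpochs(arr3, fs = fs), 0, 1.0,
                             binS = 0.13), "integral")
})

test_that("interval means commute with channel permutation", {
  set.seed(3)
  arr <- array(rnorm(5 * 4 * 110), dim = c(5, 4, 110))
  ep <- makeEpochs(arr, fs = 100)
  fm <- intervalMeans(ep, 0, 1.0)
  perm <- c(3, 1, 4, 2)
  epP <- EEGEpochs(arr[, perm, , drop = FALSE], 100, -0.1, 1.0,
                   paste0("ch", perm), epochMetadata(ep))
  fmP <- intervalMeans(epP, 0, 1.0)
  blocks <- function(v, ch) v[, ((ch - 1) * 10 + 1):(ch * 10), drop = FALSE]
  for (k in seq_along(perm))
    expect_equal(blocks(fmP$values, k), blocks(fm$values, perm[k]))
})

test_that("noiseless pipeline recovers template bin means end to end", {
  cfg <- quietConfig(seed = 8L)
  layout <- defaultLayout()
  sched <- list(makeTrialSchedule(layout, 0L, nSequences = 1L, soaS = 1.5,
                                  seed = 2L))
  rec <- synthesizeRun(sched, cfg$synth, runIndex = 1L)
  ep <- extractEpochs(rec, tminS = -0.1, tmaxS = 1.0)
  fm <- intervalMeans(ep, 0, 1.0)
  tt <- epochTimes(ep)
  # oracle: bin means of the summed component templates per channel
  lab <- epochMetadata(ep)$is_target
  topoOf <- function(cmp) {
    w <- cmp$topography[channelLabels(ep)]
    w[is.na(w)] <- 0
    as.numeric(w)
  }
  for (ch in c(1, 5)) {
    tot <- rowSums(vapply(cfg$synth$components, function(cmp)
      topoOf(cmp)[ch] * erpWaveform(cmp, tt), numeric(length(tt))))
    oracle <- vapply(0:9, function(b)
      mean(tot[tt >= b / 10 & tt < (b + 1) / 10 - 1e-12]), 0)
    got <- fm$values[which(lab), ((ch - 1) * 10 + 1):(ch * 10),
                     drop = FALSE][1, ]
    expect_equal(got, oracle, tolerance = 1e-9)
  }
})

test_that("EOG component selection picks the best-correlated source", {
  set.seed(4)
  n <- 2000
  src <- matrix(rnorm(5 * n), 5)
  eog <- src[3, ] + rnorm(n, 0, 0.1)   # planted: source 3 is the artifact
  expect_equal(pickEogComponents(src, eog), 3L)
  # two EOG channels matching the same source de-duplicate
  expect_equal(pickEogComponents(src, rbind(eog, src[3, ] + rnorm(n, 0, 0.2))),
               3L)
  # tie in |r|: identical sources -> lowest index
  srcTie <- rbind(src[3, ], src[3, ], rnorm(n))
  expect_equal(pickEogComponents(srcTie, eog), 1L)
  expect_error(pickEogComponents(matrix(0, 2, n), eog), "zero-variance")
})

test_that("component removal zeroes planted artifact subspaces", {
  set.seed(5)
  n <- 3000
  q <- qr.Q(qr(matrix(rnorm(16), 4)))   # orthogonal mixing
  sources <- rbind(rnorm(n), rnorm(n), rnorm(n), 40 * sin(2 * pi * (1:n) / 250))
  rec <- EEGRecording(q %*% sources, 250, paste0("ch", 1:4))
  # empty index set: identity for a complete decomposition
  same <- removeComponents(rec, t(q), q, integer())
  expect_equal(eegData(same), eegData(rec), tolerance = 1e-10)
  # all removed: all-zero output
  none <- removeComponents(rec, t(q), q, 1:4)
  expect_true(all(none@data == 0))
  # removing the planted artifact source cuts its power by > 95%
  clean <- removeComponents(rec, t(q), q, 4L)
  resid <- t(q) %*% eegData(clean)
  expect_lt(sum(resid[4, ]^2), 0.05 * sum(sources[4, ]^2))
  expect_equal(resid[1:3, ], sources[1:3, ], tolerance = 1e-10)
  expect_error(removeComponents(rec, t(q), q, 9L), "out of range")
})
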