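test_that("trial decisions take the per-class mean argmax with tie rules", {
  tr <- trialScores(c(1.0, 0.3, -0.2, 0.1), c(0L, 1L, 0L, 1L),
                    c(1L, 1L, 2L, 2L), soaS = 0.2, tmaxS = 1.0)
  d <- decideTrial(tr)
  expect_equal(d$chosenClass, 0L)  # means 0.4 vs 0.2
  expect_equal(unname(d$perClassMeans), c(0.4, 0.2))
  expect_equal(d$elapsedS, 3 * 0.2 + 1.0)
  # shift invariance
  tr2 <- trialScores(tr$scores + 5, tr$classId, tr$sequence)
  expect_equal(decideTrial(tr2)$chosenClass, 0L)
  # all equal: lowest class_id wins
  trEq <- trialScores(rep(1, 6), c(2L, 1L, 0L, 2L, 1L, 0L), rep(1L, 6))
  expect_equal(decideTrial(trEq)$chosenClass, 0L)
  expect_error(decideTrial(tr, 9), "out of range")
})

test_that("cumulative decisions use only the leading stimuli", {
  tr <- randomTrial(21, targetBoost = 0.8, target = 3L)
  d5 <- decideTrial(tr, 150)
  expect_equal(d5$nStimuliUsed, 150L)
  expect_equal(d5$elapsedS, 149 * 0.2 + 1.0)
  # oracle: recompute means by hand on the first 150 scores
  means <- tapply(tr$scores[1:150], tr$classId[1:150], mean)
  expect_equal(d5$chosenClass,
               as.integer(names(means)[which.max(means)]))
})

test_that("the one-sided Welch test matches stats::t.test", {
  a <- c(2, 4, 6)
  b <- c(1, 2, 3)
  w <- welchTOneSided(a, b)
  expect_equal(w$t, 1.549193, tolerance = 1e-6)
  expect_equal(w$df, 2.941176, tolerance = 1e-6)
  ref <- t.test(a, b, alternative = "greater", var.equal = FALSE)
  expect_equal(w$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(w$df, unname(ref$parameter), tolerance = 1e-12)
  expect_equal(w$p, ref$p.value, tolerance = 1e-12)
  # randomised cross-check over many draws
  set.seed(22)
  for (i in 1:50) {
    x <- rnorm(sample(3:20, 1))
    y <- rnorm(sample(3:20, 1), mean = runif(1, -1, 1))
    got <- welchTOneSided(x, y)
    ref <- t.test(x, y, alternative = "greater")
    expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("Welch edge cases follow the documented conventions", {
  # equal means, equal spread: symmetric null
  w <- welchTOneSided(c(1, 2, 3), c(3, 2, 1))
  expect_equal(w$t, 0)
  expect_equal(w$p, 0.5)
  # degenerate: both variances zero
  wd <- welchTOneSided(c(1, 1), c(1, 1))
  expect_equal(wd$p, 0.5)
  expect_true(isTRUE(attr(wd, "degenerate")))
  expect_equal(welchTOneSided(c(2, 2), c(1, 1))$p, 0)
  # monotone in the mean difference
  a <- c(0.1, 0.5, 0.3)
  b <- c(0, 0.2, -0.1)
  p1 <- welchTOneSided(a, b)$p
  p2 <- welchTOneSided(a + 0.5, b)$p
  expect_lt(p2, p1)
  expect_error(welchTOneSided(1, c(1, 2)), "at least 2")
})

test_that("static stopping equals the cumulative decision at the cut", {
  tr <- randomTrial(23, targetBoost = 0.6, target = 7L)
  expect_equal(staticStop(tr, 15), decideTrial(tr))
  d1 <- staticStop(tr, 1)
  expect_equal(d1$nStimuliUsed, 30L)
  expect_equal(staticStop(tr, 5), decideTrial(tr, 150))
  expect_error(staticStop(tr, 16), "out of range")
})

test_that("static decisions stabilise on a monotone score stream", {
  # constructed stream: target carries a constant offset; per-class means
  # stabilise, so decisions at sequences 5 and 15 agree
  tr <- randomTrial(24, targetBoost = 3, target = 12L)
  expect_equal(staticStop(tr, 5)$chosenClass,
               staticStop(tr, 15)$chosenClass)
})

test_that("dynamic stopping stops and selects per the Welch rule", {
  # planted stream: target scores exactly 1, others ~0 with tiny spread
  sched <- makeTrialSchedule(defaultLayout(), 9L, nSequences = 15L,
                             seed = 30L)
  set.seed(30)
  sc <- ifelse(sched$events$class_id == 9L, 1.0,
               rnorm(450, 0, 0.01))
  tr <- trialScores(sc, sched$events$class_id, sched$events$sequence,
                    target = 9L)
  d <- dynamicStop(tr, minSequences = 2L, alpha = 0.05)
  expect_true(d$stoppedEarly)
  expect_equal(d$chosenClass, 9L)
  expect_lte(d$nStimuliUsed, 3 * 30)   # stops within the first tested seq
  expect_gte(d$nStimuliUsed, 2 * 30 + 1)
  expect_equal(d$elapsedS, (d$nStimuliUsed - 1) * 0.2 + 1.0)

  # near-certain rejection stops at the first evaluated stimulus
  trR <- randomTrial(31, target = 0L)
  dR <- dynamicStop(trR, minSequences = 2L, alpha = 0.999)
  expect_equal(dR$nStimuliUsed, 2L * 30L + 1L)
  expect_true(dR$stoppedEarly)

  # identically constant scores never reach significance
  trC <- trialScores(rep(1, 450), sched$events$class_id,
                     sched$events$sequence, target = 9L)
  dC <- dynamicStop(trC, minSequences = 2L, alpha = 0.05)
  expect_false(dC$stoppedEarly)
  expect_equal(dC$nStimuliUsed, 450L)
  expect_error(dynamicStop(tr, minSequences = 15L), "below the total")
})

test_that("dynamic stopping with vanishing alpha equals the full decision", {
  for (seed in 41:45) {
    tr <- randomTrial(seed, targetBoost = runif(1, 0, 1),
                      target = sample(0:29, 1))
    dyn <- dynamicStop(tr, minSequences = 2L, alpha = 1e-300)
    full <- decideTrial(tr)
    expect_false(dyn$stoppedEarly)
    expect_equal(dyn$chosenClass, full$chosenClass)
    expect_equal(dyn$nStimuliUsed, full$nStimuliUsed)
  }
})

test_that("decisions are invariant to increasing affine score transforms", {
  tr <- randomTrial(50, targetBoost = 0.5, target = 5L)
  tr2 <- trialScores(3.7 * tr$scores + 11, tr$classId, tr$sequence,
                     target = 5L)
  expect_equal(decideTrial(tr)$chosenClass, decideTrial(tr2)$chosenClass)
  d1 <- dynamicStop(tr, 3L)
  d2 <- dynamicStop(tr2, 3L)
  expect_equal(d1$chosenClass, d2$chosenClass)
  expect_equal(d1$nStimuliUsed, d2$nStimuliUsed)  # Welch p is scale-free
})

test_that("early stops use between min*30+1 stimuli and the trial total", {
  for (seed in 51:54) {
    tr <- randomTrial(seed, targetBoost = 1.5, target = 2L)
    d <- dynamicStop(tr, minSequences = 2L)
    if (d$stoppedEarly) {
      expect_gte(d$nStimuliUsed, 61L)
      expect_lte(d$nStimuliUsed, 450L)
    } else {
      expect_equal(d$nStimuliUsed, 450L)
    }
  }
})

test_that("applyStoppingRule dispatches to the three protocols", {
  tr <- randomTrial(55, targetBoost = 2, target = 1L)
  expect_equal(applyStoppingRule(tr, "full"), decideTrial(tr))
  expect_equal(applyStoppingRule(tr, "static", nSequences = 4),
               staticStop(tr, 4))
  expect_equal(applyStoppingRule(tr, "dynamic", minSequences = 3),
               dynamicStop(tr, 3))
})
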