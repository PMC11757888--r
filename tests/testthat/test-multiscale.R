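test_that("a thresholds-at-zero cascade is lossless with zero residual", {
  set.seed(21)
  y <- 30 * rnorm(1024) +
    makeImpulse(1024, 400, 0.5, c(300, 100, -50, 25))$window
  d <- decomposeSignal(Signal(y, 500))
  expect_lt(restorationError(d, maxAbs = TRUE), 1e-9 * max(abs(y)))
  # the complete 4-point bottom level absorbs everything that is left
  expect_lt(max(abs(residualSignal(d))), 1e-9 * max(abs(y)))
  # the events carry their own energy identity
  e <- events(d)
  expect_equal(e$energy, unname(rowSums(e$coefficients^2)),
               tolerance = 1e-9)
  expect_true(all(e$isReaction))
})

test_that("decomposing the residual again finds nothing", {
  set.seed(22)
  y <- rnorm(512 * 2) * 10
  d <- decomposeSignal(Signal(y, 500), decompositionConfig(nMax = 9))
  r2 <- decomposeSignal(Signal(residualSignal(d) + 1e-300, 500),
                        decompositionConfig(nMax = 9))
  for (key in names(r2@components))
    expect_lt(max(abs(r2@components[[key]])), 1e-9 * max(abs(y)))
})

test_that("short tails are zero-padded and spawn no events past the end", {
  set.seed(23)
  y <- rnorm(1500) * 5
  d <- decomposeSignal(Signal(y, 500))
  expect_equal(length(d@input), 2048L)
  expect_equal(d@input[1501:2048], rep(0, 548))
  expect_true(all(events(d)$globalSample <= 1500))
  expect_lt(restorationError(d, maxAbs = TRUE), 1e-9 * max(abs(y)))
})

test_that("non-finite samples are rejected with their index", {
  y <- rnorm(16)
  y[7] <- NA
  expect_error(decomposeSignal(y), "index 7")
})

test_that("level-band labels follow rate / 2^n", {
  expect_equal(levelToFrequency(5, 500), 15.625)
  expect_equal(levelToFrequency(10, 500), 0.48828125)
  expect_equal(levelToFrequency(2, 500), 125)
  d <- decomposeSignal(Signal(rnorm(64), 500),
                       decompositionConfig(nMax = 6, nMin = 4))
  e <- events(d)
  expect_equal(e$bandHz, 500 / 2^e$level)
})

test_that("thresholds gate subtraction and recording monotonically", {
  set.seed(24)
  sim <- makeComposite(2.048, 500,
                       events = data.frame(type = "blink", time = 1.0,
                                           amplitude = 80),
                       noise = list(model = "white", sigma = 10),
                       seed = 91)
  cfg0 <- decompositionConfig(nMin = 8)
  d0 <- decomposeSignal(sim$signal, cfg0)
  wTop <- max(events(d0)$energy[events(d0)$level == 10])
  # a threshold above the observed maximum suppresses the reaction and
  # leaves the level's component untouched
  cfgHi <- decompositionConfig(nMin = 8,
                               thresholds = c(n10 = wTop * 1.01),
                               keepSubthreshold = TRUE)
  dHi <- decomposeSignal(sim$signal, cfgHi)
  eHi <- events(dHi)
  expect_false(any(eHi$isReaction[eHi$level == 10]))
  expect_true(all(abs(dHi@components[["n10"]]) == 0))
  # raising a threshold never increases the number of reactions
  nReact <- function(t) {
    cfg <- decompositionConfig(nMin = 8, thresholds = c(n10 = t))
    sum(events(decomposeSignal(sim$signal, cfg))$isReaction)
  }
  counts <- vapply(c(0, wTop / 2, wTop * 1.01), nReact, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("trained thresholds are minima of per-signal maxima", {
  set.seed(25)
  mk <- function(amp, seed)
    makeComposite(2.048, 500,
                  events = data.frame(type = "blink", time = 1.0,
                                      amplitude = amp),
                  noise = list(model = "white", sigma = 5),
                  seed = seed)$signal
  sigs <- list(mk(60, 1), mk(90, 2), mk(120, 3))
  cfg <- decompositionConfig(nMin = 9)
  tt <- trainThresholds(sigs, config = cfg)
  perSignal <- vapply(sigs, function(s) {
    e <- events(decomposeSignal(s, cfg))
    max(e$energy[e$level == 10])
  }, numeric(1))
  expect_equal(unname(thresholds(tt)["n10"]), min(perSignal))
  # singleton training set: threshold equals that signal's maximum
  t1 <- trainThresholds(sigs[1], config = cfg)
  expect_equal(unname(thresholds(t1)["n10"]), perSignal[1])
  # a held-out signal below threshold is not subtracted
  weak <- mk(20, 4)
  cfgT <- decompositionConfig(nMin = 9, thresholds = thresholds(tt),
                              keepSubthreshold = TRUE)
  dw <- decomposeSignal(weak, cfgT)
  ew <- events(dw)
  top <- ew[ew$level == 10, ]
  expect_true(all(!top$isReaction))
  expect_error(trainThresholds(list()), "at least one")
  expect_error(trainThresholds(sigs, marked = c(FALSE, FALSE, FALSE)),
               "marked")
})

test_that("band energy equals the direct sum over the energy map", {
  set.seed(26)
  y <- rnorm(32) * 4
  cfg <- decompositionConfig(nMax = 5, nMin = 5)
  d <- decomposeSignal(Signal(y, 500), cfg)
  z <- zeroLevel(y)$centered
  bf <- bruteForceLocate(z)
  V <- basisValues(getBasis(32, bf$p0, 4))
  direct <- sum(directShiftSpectra(z, V)^2)
  expect_equal(bandEnergy(d, 5), direct, tolerance = 1e-9)
  expect_error(bandEnergy(d, 9), "not computed")
  # zero signal has zero band energy
  dz <- decomposeSignal(Signal(rep(3, 32), 500), cfg)  # constant = DC only
  expect_lt(bandEnergy(dz, 5), 1e-18)
})

test_that("signal/noise ratio behaves on constructed spectra", {
  set.seed(27)
  sim <- makeComposite(2.048, 500,
                       events = data.frame(type = "blink", time = 1.0,
                                           amplitude = 150),
                       noise = list(model = "white", sigma = 5),
                       seed = 13)
  d <- decomposeSignal(sim$signal, decompositionConfig(nMin = 2))
  # a large slow impulse against weak fast noise: top band dominates
  expect_gt(signalNoiseRatio(d, 10, 9:2), 1)
  # identical level sets on both sides give exactly 1
  expect_equal(signalNoiseRatio(d, 10, 9:2) /
                 (bandEnergy(d, 10) / sum(vapply(9:2, function(n)
                   bandEnergy(d, n), numeric(1)))), 1)
  expect_error(signalNoiseRatio(d, 10, 10:9), "disjoint")
})

test_that("event power and span aggregate selected events", {
  e <- S4Vectors::DataFrame(level = c(9L, 7L), segment = c(1L, 1L),
                            window = c(2L, 5L), a0 = c(75L, 99L),
                            p0 = c(0.5, 0.3),
                            shiftSample = c(587, 736),
                            globalSample = c(587, 736),
                            timeS = c(587, 736) / 500,
                            timeMs = c(587, 736) * 2,
                            bandHz = 500 / 2^c(9, 7),
                            energy = c(3, 4),
                            bandEnergy = c(30, 40),
                            isReaction = c(TRUE, TRUE),
                            coefficients = I(matrix(0, 2, 4)))
  expect_equal(eventPower(e), 7)
  expect_equal(eventPower(e, levels = 9), 3)
  expect_warning(p0 <- eventPower(e, levels = 3), "no events")
  expect_equal(p0, 0)
  sp <- eventSpan(e, rate = 500)
  expect_equal(unname(sp["startMs"]), 1174)
  expect_equal(unname(sp["endMs"]), 1472)
  expect_equal(unname(sp["durationMs"]), 298)
  # single event: zero duration
  expect_equal(unname(eventSpan(e[1, ], rate = 500)["durationMs"]), 0)
  expect_equal(unname(eventSpan(S4Vectors::DataFrame(
    level = 2L, globalSample = c(100, 300)), rate = 1000)["durationMs"]),
    200)
})

test_that("reconstruction subsets behave additively", {
  set.seed(28)
  y <- rnorm(1024) * 8
  d <- decomposeSignal(Signal(y, 500))
  full <- reconstructSignal(d)
  noTop <- reconstructSignal(d, levels = 9:2)
  expect_equal(full - noTop, d@components[["n10"]], tolerance = 1e-12)
  expect_equal(restorationError(d), sqrt(sum((full - y)^2)),
               tolerance = 1e-12)
})
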