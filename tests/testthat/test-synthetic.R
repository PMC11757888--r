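test_that("basis-built impulses carry their truth", {
  amp <- c(2, -1, 0.5, 0.25)
  imp <- makeImpulse(64, 40, 0.6, amp)
  expect_equal(imp$truth$Wmax, sum(amp^2))
  r <- locateImpulse(imp$window)
  expect_equal(r@a0, 40L)
  expect_equal(r@p0, 0.6)
  zero <- makeImpulse(32, 10, 0.4, rep(0, 4))
  expect_equal(zero$window, rep(0, 32))
  expect_identical(makeImpulse(64, 5, 0.2, amp)$window,
                   makeImpulse(64, 5, 0.2, amp)$window)
  expect_error(makeImpulse(64, 0, 0.5, amp), "'a0'")
  expect_error(makeImpulse(64, 5, 1.5, amp), "'p0'")
})

test_that("composite traces are deterministic and respect their spec", {
  sim0 <- makeComposite(1, 500, events = NULL,
                        noise = list(model = "white", sigma = 0), seed = 5)
  expect_equal(samples(sim0$signal), rep(0, 500))
  a <- makeComposite(2, 500,
                     events = data.frame(type = "blink", time = 1,
                                         amplitude = 100),
                     noise = list(model = "pink", sigma = 15), seed = 9)
  b <- makeComposite(2, 500,
                     events = data.frame(type = "blink", time = 1,
                                         amplitude = 100),
                     noise = list(model = "pink", sigma = 15), seed = 9)
  expect_identical(samples(a$signal), samples(b$signal))
  c2 <- makeComposite(2, 500,
                      events = data.frame(type = "blink", time = 1,
                                          amplitude = 100),
                      noise = list(model = "pink", sigma = 15), seed = 10)
  expect_false(identical(samples(a$signal), samples(c2$signal)))
  # generation does not disturb the caller's RNG stream
  set.seed(77); before <- rnorm(3)
  set.seed(77); invisible(makeComposite(1, 500, seed = 3)); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("a noiseless blink is localized on the top scale within 8 samples", {
  sim <- makeComposite(2.048, 500,
                       events = data.frame(type = "blink", time = 2.0,
                                           amplitude = 100),
                       noise = list(model = "white", sigma = 0), seed = 3)
  d <- decomposeSignal(sim$signal, decompositionConfig(nMin = 9))
  e <- events(d)
  top <- e[e$level == 10, ]
  expect_equal(nrow(top), 1L)
  expect_lte(abs(top$globalSample - truthEvents(sim$truth)$extremumSample),
             8)
  expect_equal(top$bandHz, 500 / 1024)
})

test_that("bursts land in the 16 Hz band", {
  sim <- makeComposite(2.048, 500,
                       events = data.frame(type = "burst", time = 1.0,
                                           amplitude = 40),
                       noise = list(model = "white", sigma = 0), seed = 4)
  expect_equal(truthEvents(sim$truth)$level, 5)
  expect_equal(truthEvents(sim$truth)$freq, 500 / 32)
  d <- decomposeSignal(sim$signal, decompositionConfig(nMin = 2))
  e <- events(d)
  # the strongest reaction in the 32-point band sits on the burst
  lvl5 <- e[e$level == 5, ]
  hit <- lvl5[which.max(lvl5$energy), ]
  expect_lt(abs(hit$globalSample - 500), 32)
})

test_that("localization error statistics are order statistics", {
  sim <- makeComposite(4.096, 500,
                       events = data.frame(type = "blink",
                                           time = c(0.7, 1.8, 3.2),
                                           amplitude = 100),
                       noise = list(model = "white", sigma = 0), seed = 6)
  ext <- truthEvents(sim$truth)$extremumSample
  fake <- S4Vectors::DataFrame(
    level = rep(10L, 3), segment = 1:3, window = rep(1L, 3),
    a0 = rep(1L, 3), p0 = rep(0.5, 3),
    shiftSample = ext + c(1, 8, 20),
    globalSample = ext + c(1, 8, 20),
    timeS = 0, timeMs = 0, bandHz = 0.5,
    energy = rep(10, 3), bandEnergy = rep(10, 3),
    isReaction = rep(TRUE, 3), coefficients = I(matrix(0, 3, 4)))
  st <- evaluateLocalization(sim$truth, fake)
  expect_equal(st$errors, c(1, 8, 20))
  expect_equal(st$median, 8)
  expect_equal(st$misses, 0L)
  expect_equal(st$falseAlarms, 0L)
  # perfect detection: all-zero errors and degenerate quartiles
  perfect <- fake
  perfect$globalSample <- ext
  stp <- evaluateLocalization(sim$truth, perfect)
  expect_equal(stp$median, 0)
  expect_equal(c(stp$lowerQuartile, stp$upperQuartile), c(0, 0))
  # an event far from every truth is a false alarm and the truths misses
  far <- fake[1, ]
  far$globalSample <- 5000
  stf <- evaluateLocalization(sim$truth, far)
  expect_equal(stf$misses, 3L)
  expect_equal(stf$falseAlarms, 1L)
})

test_that("full-pipeline recovery is exact over the design grid", {
  shifts <- c(1, 9, 17, 25, 33, 41, 49, 57)
  amp <- c(1.3, 0.9, -0.7, 0.4)
  for (p in seq(0.1, 0.9, by = 0.1)) {
    for (a0 in shifts) {
      r <- locateImpulse(makeImpulse(64, a0, p, amp)$window)
      expect_equal(r@a0, as.integer(a0))
      expect_equal(r@p0, p)
    }
  }
})
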