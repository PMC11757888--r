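test_that("zeroLevel centers a window and reports the removed mean", {
  z <- zeroLevel(c(1, 2, 3, 6))
  expect_equal(z$centered, c(-2, -1, 0, 3))
  expect_equal(z$mean, 3)
  zc <- zeroLevel(rep(7.5, 10))
  expect_equal(zc$centered, rep(0, 10))
  expect_equal(zc$mean, 7.5)
  set.seed(1)
  expect_lt(abs(mean(zeroLevel(rnorm(100, 5))$centered)), 1e-12)
  expect_error(zeroLevel(numeric(0)), "non-empty")
})

test_that("shift spectra recover a planted basis row exactly", {
  b <- getBasis(64, 0.3, 4)
  for (s in c(1, 17, 64)) {
    y <- basisValues(b)[2, ((seq_len(64) - s) %% 64) + 1]
    C <- shiftSpectra(y, b)@coefficients
    expect_equal(C[2, s], 1, tolerance = 1e-10)
    expect_lt(max(abs(C[c(1, 3, 4), s])), 1e-10)
  }
})

test_that("FFT shift spectra equal direct summation", {
  set.seed(7)
  for (N in c(4, 8, 32, 128, 256)) {
    y <- rnorm(N)
    for (p in c(0.2, 0.5, 0.7)) {
      b <- getBasis(N, p, 4)
      C <- shiftSpectra(y, b)@coefficients
      expect_lt(max(abs(C - directShiftSpectra(y, basisValues(b)))),
                1e-9 * sqrt(sum(y^2)))
    }
  }
  expect_error(shiftSpectra(rnorm(16), getBasis(32, 0.5, 4)),
               "does not match")
})

test_that("shifting the input shifts every spectral row", {
  set.seed(8)
  y <- rnorm(64)
  b <- getBasis(64, 0.4, 4)
  C0 <- shiftSpectra(y, b)@coefficients
  for (d in c(1, 13, 40)) {
    Cd <- shiftSpectra(circShift(y, d), b)@coefficients
    for (k in 1:4)
      expect_equal(Cd[k, ], circShift(C0[k, ], d), tolerance = 1e-10)
  }
})

test_that("the energy map obeys the Bessel bound everywhere", {
  set.seed(9)
  for (rep in 1:5) {
    N <- sample(c(16, 64, 256), 1)
    y <- rnorm(N) * 10
    normSq <- sum(y^2)
    for (p in c(0.1, 0.5, 0.9)) {
      W <- energyMap(shiftSpectra(y, getBasis(N, p, 4)))@W
      expect_true(all(W >= 0))
      expect_lte(max(W), normSq * (1 + 1e-12))
    }
  }
  Wz <- energyMap(shiftSpectra(numeric(32), getBasis(32, 0.5, 4)))@W
  expect_equal(Wz, rep(0, 32))
})

test_that("locateImpulse recovers planted parameters exactly", {
  amp <- c(1, 0.8, -0.5, 0.3)
  imp <- makeImpulse(64, a0 = 17, p0 = 0.3, amplitudes = amp)
  r <- locateImpulse(imp$window)
  expect_equal(r@a0, 17L)
  expect_equal(r@p0, 0.3)
  expect_equal(r@Wmax, sum(amp^2), tolerance = 1e-10)
  expect_equal(r@coefficients, amp, tolerance = 1e-8)
  # matches the exhaustive brute-force oracle
  bf <- bruteForceLocate(imp$window)
  expect_equal(r@a0, bf$a0)
  expect_equal(r@p0, bf$p0)
  expect_equal(r@Wmax, bf$Wmax, tolerance = 1e-12)
})

test_that("localization is equivariant under circular shifts", {
  set.seed(10)
  y <- makeImpulse(128, 40, 0.6, c(2, -1, 0.5, 0.25))$window + rnorm(128)
  r0 <- locateImpulse(y)
  for (d in c(5, 64, 100)) {
    rd <- locateImpulse(circShift(y, d))
    expect_equal(rd@p0, r0@p0)
    expect_equal(rd@Wmax, r0@Wmax, tolerance = 1e-9)
    expect_equal(rd@a0, as.integer(((r0@a0 - 1 + d) %% 128) + 1))
  }
})

test_that("re-zeroing makes localization invariant to additive constants", {
  set.seed(11)
  y <- rnorm(64) * 5
  r1 <- locateImpulse(zeroLevel(y)$centered)
  r2 <- locateImpulse(zeroLevel(y + 123.4)$centered)
  expect_equal(r1@a0, r2@a0)
  expect_equal(r1@p0, r2@p0)
  expect_equal(r1@Wmax, r2@Wmax, tolerance = 1e-9)
})

test_that("adding an impulse raises the noise-only energy maximum", {
  set.seed(12)
  for (rep in 1:5) {
    noise <- rnorm(64)
    imp <- makeImpulse(64, sample(64, 1), 0.4,
                       c(6, 3, -2, 1))$window
    expect_gt(locateImpulse(noise + imp)@Wmax, locateImpulse(noise)@Wmax)
  }
})

test_that("restoration splits energy orthogonally", {
  set.seed(13)
  y <- rnorm(64) * 3
  r <- locateImpulse(y)
  comp <- restoreComponent(r)
  resid <- y - comp
  # Pythagoras under orthonormal projection
  expect_equal(sum(y^2), sum(comp^2) + sum(resid^2),
               tolerance = 1e-9)
  expect_equal(sum(resid^2), sum(y^2) - r@Wmax,
               tolerance = 1e-9 * sum(y^2))
  # a window inside the shifted span is restored exactly
  imp <- makeImpulse(64, 21, 0.7, c(1.5, -0.4, 0.2, 0.9))
  expect_lt(max(abs(restoreComponent(locateImpulse(imp$window)) -
                    imp$window)), 1e-10)
})

test_that("a complete basis restores any window", {
  set.seed(14)
  y <- rnorm(16)
  r <- locateImpulse(y, pGrid = 0.5, K = 16L)
  expect_lt(max(abs(restoreComponent(r) - y)), 1e-9)
})
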