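# Classical Krawtchouk mother-wavelet transform (the shift-variant
# baseline) and the shift-invariance comparison.

#' Classical Krawtchouk mother-wavelet transform
#'
#' The baseline transform against which the localization method is
#' compared: at every dyadic level \code{n} the first K Krawtchouk
#' functions with the symmetric asymmetry p = 0.5 are translated over
#' aligned, non-overlapping positions \code{b = 2^n * s},
#' \code{s = 0 .. 2^(nMax-n) - 1}, and coefficients are plain inner
#' products of the signal window with the (un-shifted) basis rows.  The
#' aligned translation grid is exactly what makes this transform variant
#' under impulse shifts that are not multiples of the window size.
#'
#' Levels are processed from the smallest windows upwards within each
#' top-level segment; the trailing segment is zero-padded.
#'
#' @param signal a [Signal-class] or numeric vector.
#' @param nMax,nMin dyadic level range (defaults 10 and 2).
#' @param K functions per window (default 4).
#' @param rate sampling rate in Hz (defaults to the signal's).
#' @return a [ClassicalSpectrum-class].
#' @export
classicalTransform <- function(signal, nMax = 10L, nMin = 2L, K = 4L,
                               rate = NULL) {
  if (is.numeric(signal)) signal <- Signal(signal, rate = 500)
  stopifnot(is(signal, "Signal"))
  if (is.null(rate)) rate <- signal@rate
  y <- signal@samples
  if (!all(is.finite(y)))
    stop(sprintf("non-finite sample at index %d",
                 which(!is.finite(y))[1L]), call. = FALSE)
  nMax <- as.integer(nMax); nMin <- as.integer(nMin); K <- as.integer(K)
  M <- length(y)
  W0 <- 2L^nMax
  nSeg <- max(1L, ceiling(M / W0))
  L <- nSeg * W0
  padded <- c(y, numeric(L - M))
  lev <- nMin:nMax                      # smallest windows first
  coefficients <- list()
  energ <- list()
  for (n in lev) {
    N <- 2L^n
    V <- getBasis(N, 0.5, K)@values
    S <- L %/% N
    C <- matrix(0, K, S)
    for (s in seq_len(S)) {
      w <- padded[((s - 1L) * N + 1L):(s * N)]
      C[, s] <- as.numeric(V %*% w)
    }
    coefficients[[.levelKey(n)]] <- C
    energ[[.levelKey(n)]] <- colSums(C^2)
  }
  new("ClassicalSpectrum", coefficients = coefficients, energies = energ,
      nMax = nMax, nMin = nMin, K = K, rate = as.numeric(rate),
      M = as.integer(M), L = as.integer(L))
}

# Per-level maximal localization energies of a raw (centered) segment:
# locate in every aligned window of each level, no cascade subtraction.
# Used by the shift-invariance comparison, where subtraction across levels
# would mix window geometries into the quantity being compared.
.levelMaxima <- function(segment, nMax, nMin, pGrid, K) {
  out <- list()
  for (n in nMax:nMin) {
    N <- 2L^n
    S <- length(segment) %/% N
    best <- NULL
    for (l in seq_len(S)) {
      w <- segment[((l - 1L) * N + 1L):(l * N)]
      loc <- locateImpulse(w, pGrid = pGrid, K = K)
      if (is.null(best) || loc@Wmax > best$Wmax)
        best <- list(Wmax = loc@Wmax, p0 = loc@p0,
                     position = (l - 1L) * N + loc@a0,
                     peak = (l - 1L) * N +
                       which.max(abs(restoreComponent(loc))))
    }
    out[[.levelKey(n)]] <- best
  }
  out
}

#' Compare shift invariance of the two transforms
#'
#' Analyzes the first top-level segment of a signal and the same segment
#' circularly shifted by \code{d} samples, with both methods, and reports
#' per level: the maximal localization energy of each version (equal to
#' rounding error whenever the impulse stays within one window of that
#' level in both versions), the winning asymmetries, the shift of the
#' located position, and the Euclidean distance between the classical
#' energy vectors (generally nonzero — the baseline is shift-variant —
#' except when \code{d} is a multiple of the level's window size, in which
#' case the shifted energy vector is only rotated and the aligned distance
#' vanishes).
#'
#' @param signal a [Signal-class] or numeric vector (at least one
#'   top-level window long; only the first segment is compared).
#' @param d circular shift in samples.
#' @param nMax,nMin dyadic level range.
#' @param pGrid,K localization parameters.
#' @return a data.frame with one row per level: \code{level}, \code{bandHz},
#'   \code{WmaxOriginal}, \code{WmaxShifted}, \code{WmaxRelDiff},
#'   \code{p0Original}, \code{p0Shifted}, \code{locShift} (located position
#'   difference, circular), \code{classicalDist}.
#' @export
compareShiftInvariance <- function(signal, d, nMax = 10L, nMin = 2L,
                                   pGrid = seq(0.1, 0.9, by = 0.1),
                                   K = 4L) {
  if (is.numeric(signal)) signal <- Signal(signal, rate = 500)
  stopifnot(is(signal, "Signal"))
  W0 <- 2L^nMax
  y <- signal@samples
  if (length(y) < W0) y <- c(y, numeric(W0 - length(y)))
  seg <- zeroLevel(y[seq_len(W0)])$centered
  d <- as.integer(d) %% W0
  segShift <- if (d == 0L) seg else c(seg[(W0 - d + 1L):W0],
                                      seg[seq_len(W0 - d)])
  lmO <- .levelMaxima(seg, nMax, nMin, pGrid, K)
  lmS <- .levelMaxima(segShift, nMax, nMin, pGrid, K)
  clO <- classicalTransform(seg, nMax = nMax, nMin = nMin, K = K,
                            rate = signal@rate)
  clS <- classicalTransform(segShift, nMax = nMax, nMin = nMin, K = K,
                            rate = signal@rate)
  lev <- nMax:nMin
  rows <- lapply(lev, function(n) {
    key <- .levelKey(n)
    o <- lmO[[key]]; sft <- lmS[[key]]
    eO <- clO@energies[[key]]; eS <- clS@energies[[key]]
    N <- 2L^n
    if (d %% N == 0L && d > 0L) {
      # whole-window translation: undo the rotation before comparing
      k <- d %/% N
      S <- length(eS)
      eS <- eS[((seq_len(S) - 1L - k) %% S) + 1L]
    }
    data.frame(level = n, bandHz = signal@rate / 2^n,
               WmaxOriginal = o$Wmax, WmaxShifted = sft$Wmax,
               WmaxRelDiff = abs(sft$Wmax - o$Wmax) /
                 max(o$Wmax, .Machine$double.xmin),
               p0Original = o$p0, p0Shifted = sft$p0,
               locShift = (sft$position - o$position) %% W0,
               classicalDist = sqrt(sum((eS - eO)^2)))
  })
  do.call(rbind, rows)
}
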