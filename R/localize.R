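# Within-window shift/asymmetry localization.
#
# Shift convention ("mod*"): the basis shifted by a is
# F_k((i - a) mod* N) with (i - a) mod* N = ((i - a) mod N) + 1 in
# {1..N}; a = N reproduces the unshifted basis.  The coefficient
#   c_k(a) = sum_i y(i) F_k((i - a) mod* N)
# is a circular cross-correlation, evaluated in the frequency domain with
# the conjugated basis spectrum.  (The source formulation writes this as a
# "convolution"; the cross-correlation is the reading under which the
# energy maximum is a matched-filter peak at the impulse shift.)

#' Construct a Signal
#'
#' @param samples numeric vector of finite sample values (µV for EEG/ECG).
#' @param rate sampling rate in Hz.
#' @param label lead / channel name.
#' @param origin global 1-based index of the first sample.
#' @return a [Signal-class].
#' @examples
#' s <- Signal(sin(seq(0, 2 * pi, length.out = 500)), rate = 500,
#'             label = "Fp1")
#' @export
Signal <- function(samples, rate = 500, label = "signal", origin = 1) {
  new("Signal", samples = as.numeric(samples), rate = as.numeric(rate),
      label = as.character(label), origin = as.numeric(origin))
}

#' Re-zero a window
#'
#' Subtracts the arithmetic mean of a segment ("new zero level"), returning
#' both the centered segment and the removed mean so that DC bookkeeping in
#' the cascade stays exact.
#'
#' @param window numeric vector (non-empty).
#' @return list with elements \code{centered} (mean-zero vector) and
#'   \code{mean}.
#' @examples
#' zeroLevel(c(1, 2, 3, 6))   # centered -2 -1 0 3, mean 3
#' @export
zeroLevel <- function(window) {
  if (is(window, "Signal")) window <- window@samples
  if (!length(window))
    stop("'window' must be a non-empty numeric vector", call. = FALSE)
  m <- mean(window)
  list(centered = window - m, mean = m)
}

#' Shift spectra of a window
#'
#' Coefficients of the window relative to all N circular shifts of the
#' basis, computed via the convolution theorem: for each retained function
#' the full shift profile is one forward FFT of the window, a pointwise
#' product with the conjugated cached basis spectrum, and one inverse FFT.
#' Matches direct summation to rounding error.
#'
#' @param window numeric vector of length equal to the basis window N.
#' @param basis a [KrawtchoukBasis-class] (spectra cached on demand).
#' @return a [ShiftSpectra-class]; entry \code{(k, a)} is
#'   \eqn{\sum_i y(i) F_k((i-a) mod^* N)}.
#' @export
shiftSpectra <- function(window, basis) {
  stopifnot(is(basis, "KrawtchoukBasis"))
  if (length(window) != basis@N)
    stop(sprintf("window length %d does not match basis N = %d",
                 length(window), basis@N), call. = FALSE)
  basis <- cacheSpectra(basis)
  Fy <- fft(window)
  C <- matrix(0, basis@K, basis@N)
  for (k in seq_len(basis@K))
    C[k, ] <- Re(fft(Fy * Conj(basis@spectra[k, ]), inverse = TRUE)) / basis@N
  new("ShiftSpectra", p = basis@p, coefficients = C, N = basis@N)
}

#' Energy functional over shifts
#'
#' \eqn{W(a) = \sum_k |c_k(a)|^2}: the energy captured by the K-dimensional
#' basis at every circular shift.  Bounded above by the squared norm of the
#' window (Bessel).
#'
#' @param spectra a [ShiftSpectra-class].
#' @return an [EnergyMap-class].
#' @export
energyMap <- function(spectra) {
  stopifnot(is(spectra, "ShiftSpectra"))
  new("EnergyMap", p = spectra@p,
      W = colSums(spectra@coefficients^2))
}

#' Locate the impulse in one window
#'
#' Scans the asymmetry grid, computes the energy functional over all
#' circular shifts for each p, and returns the global maximum together
#' with the K coefficients there.  Tie-breaking is deterministic: the first
#' maximum in scan order (shift ascending within asymmetry ascending),
#' compared with exact double ordering — no epsilon fuzzing.
#'
#' @param window numeric vector (a centered analysis window).
#' @param pGrid asymmetry grid (default 0.1..0.9 step 0.1).
#' @param K number of Krawtchouk functions (default 4).
#' @return a [LocalizationResult-class].
#' @examples
#' imp <- makeImpulse(64, a0 = 17, p0 = 0.3, amplitudes = c(1, .8, -.5, .3))
#' locateImpulse(imp$window)   # recovers a0 = 17, p0 = 0.3
#' @export
locateImpulse <- function(window, pGrid = seq(0.1, 0.9, by = 0.1), K = 4L) {
  if (!length(pGrid) || any(pGrid <= 0 | pGrid >= 1))
    stop("'pGrid' must be non-empty with all values in (0, 1)",
         call. = FALSE)
  N <- length(window)
  best <- NULL
  for (p in sort(pGrid)) {
    sp <- shiftSpectra(window, getBasis(N, p, K))
    W <- colSums(sp@coefficients^2)
    a <- which.max(W)                       # first maximum, a ascending
    if (is.null(best) || W[a] > best$Wmax)  # strict: first p wins ties
      best <- list(a0 = a, p0 = p, Wmax = W[[a]],
                   coefficients = sp@coefficients[, a])
  }
  new("LocalizationResult", a0 = as.integer(best$a0), p0 = best$p0,
      Wmax = best$Wmax, coefficients = best$coefficients, N = as.integer(N))
}

#' Restore the localized component
#'
#' Reconstructs the impulse component from a localization result:
#' \eqn{\tilde y(i) = \sum_k c_k F_k^{(p_0)}((i-a_0) mod^* N)}.  Because
#' the basis is orthonormal, \eqn{\|y\|^2 = \|\tilde y\|^2 + \|y-\tilde
#' y\|^2} holds to rounding error.
#'
#' @param result a [LocalizationResult-class].
#' @return numeric vector of length N, the restored component.
#' @export
restoreComponent <- function(result) {
  stopifnot(is(result, "LocalizationResult"))
  V <- getBasis(result@N, result@p0, length(result@coefficients))@values
  idx <- ((seq_len(result@N) - result@a0) %% result@N) + 1L
  as.numeric(result@coefficients %*% V[, idx, drop = FALSE])
}
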