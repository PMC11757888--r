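#' @import methods
#' @importFrom stats fft median quantile rnorm runif
#' @importFrom S4Vectors DataFrame
NULL

#' Sampled biosignal trace
#'
#' A single-channel real-valued time series with its sampling rate, a lead
#' label and the global index of its first sample.  Amplitudes are carried in
#' input units (microvolts for EEG/ECG).
#'
#' @slot samples numeric vector of finite sample values.
#' @slot rate sampling rate in Hz (> 0).
#' @slot label lead / channel name.
#' @slot origin global 1-based index of the first sample, used to convert
#'   window-local positions of detected events into global sample indices.
#'
#' @seealso [Signal()] for the constructor, [readSignal()] to load recordings.
#' @exportClass Signal
setClass("Signal",
  representation(samples = "numeric", rate = "numeric",
                 label = "character", origin = "numeric"),
  prototype(samples = numeric(0), rate = 500, label = "signal", origin = 1))

setValidity("Signal", function(object) {
  msg <- NULL
  if (length(object@samples) < 1L)
    msg <- c(msg, "'samples' must contain at least one value")
  if (length(object@samples) && !all(is.finite(object@samples)))
    msg <- c(msg, sprintf("non-finite sample at index %d",
                          which(!is.finite(object@samples))[1L]))
  if (length(object@rate) != 1L || !is.finite(object@rate) || object@rate <= 0)
    msg <- c(msg, "'rate' must be a single positive number")
  if (length(object@origin) != 1L || object@origin < 1)
    msg <- c(msg, "'origin' must be a single index >= 1")
  if (is.null(msg)) TRUE else msg
})

#' Orthonormal Krawtchouk function basis
#'
#' The first \code{K} orthonormal Krawtchouk functions on an \code{N}-point
#' lattice for asymmetry \code{p}, stored as a \code{K x N} matrix (row
#' \code{k} has polynomial degree \code{k - 1}), together with an optional
#' cache of the discrete Fourier transforms of the rows used by the FFT path
#' of [shiftSpectra()].
#'
#' @slot N window length.
#' @slot p asymmetry coefficient in (0, 1).
#' @slot K number of retained functions.
#' @slot values \code{K x N} numeric matrix of function values.
#' @slot spectra \code{K x N} complex matrix of row DFTs (possibly empty
#'   until [cacheSpectra()] is called).
#'
#' @seealso [krawtchoukBasis()], [mirrorBasis()], [verifyOrthonormality()]
#' @exportClass KrawtchoukBasis
setClass("KrawtchoukBasis",
  representation(N = "integer", p = "numeric", K = "integer",
                 values = "matrix", spectra = "matrix"))

setValidity("KrawtchoukBasis", function(object) {
  msg <- NULL
  if (object@N < 2L) msg <- c(msg, "'N' must be >= 2")
  if (object@p <= 0 || object@p >= 1)
    msg <- c(msg, "'p' must lie strictly between 0 and 1")
  if (object@K < 1L || object@K > object@N)
    msg <- c(msg, "'K' must satisfy 1 <= K <= N")
  if (!identical(dim(object@values), c(object@K, object@N)))
    msg <- c(msg, "'values' must be a K x N matrix")
  if (nrow(object@spectra) &&
      !identical(dim(object@spectra), c(object@K, object@N)))
    msg <- c(msg, "'spectra' must be empty or a K x N matrix")
  if (is.null(msg)) TRUE else msg
})

#' Shift spectra of a window
#'
#' Generalized spectral coefficients of one analysis window relative to the
#' set of all circular shifts of a Krawtchouk basis: entry \code{(k, a)} is
#' \eqn{c_k(a) = \sum_i y(i)\,F_k((i-a) \bmod^* N)}.
#'
#' @slot p asymmetry of the basis used.
#' @slot coefficients \code{K x N} numeric matrix of coefficients.
#' @slot N window length.
#' @exportClass ShiftSpectra
setClass("ShiftSpectra",
  representation(p = "numeric", coefficients = "matrix", N = "integer"))

#' Energy functional over shifts
#'
#' \eqn{W(a) = \sum_k |c_k(a)|^2} for one window and one asymmetry; by
#' Bessel's inequality every entry is bounded by the squared Euclidean norm
#' of the window.
#'
#' @slot p asymmetry.
#' @slot W nonnegative numeric vector of length \code{N}.
#' @exportClass EnergyMap
setClass("EnergyMap", representation(p = "numeric", W = "numeric"))

#' Result of impulse localization in one window
#'
#' The winning shift \code{a0}, asymmetry \code{p0}, the energy at the
#' maximum and the K projection coefficients there.
#'
#' @slot a0 winning circular shift (1-based window index).
#' @slot p0 winning asymmetry.
#' @slot Wmax energy functional at the maximum.
#' @slot coefficients numeric vector of K coefficients at the maximum.
#' @slot N window length.
#' @exportClass LocalizationResult
setClass("LocalizationResult",
  representation(a0 = "integer", p0 = "numeric", Wmax = "numeric",
                 coefficients = "numeric", N = "integer"))

setValidity("LocalizationResult", function(object) {
  msg <- NULL
  if (object@a0 < 1L || object@a0 > object@N)
    msg <- c(msg, "'a0' must lie in 1..N")
  if (abs(object@Wmax - sum(object@coefficients^2)) >
      1e-9 * max(1, object@Wmax))
    msg <- c(msg, "'Wmax' must equal the sum of squared coefficients")
  if (is.null(msg)) TRUE else msg
})

#' Configuration of the multiscale decomposition
#'
#' @slot nMax top dyadic level (window length \code{2^nMax}; default 10,
#'   i.e. 1024-point windows).
#' @slot nMin bottom dyadic level (default 2, i.e. 4-point windows, where
#'   the first four Krawtchouk functions are a complete basis).
#' @slot pGrid asymmetry grid searched at every window (default 0.1..0.9).
#' @slot K number of Krawtchouk functions per window (default 4).
#' @slot thresholds named numeric of per-level energy thresholds
#'   \code{T_n}; a window's maximum is a "reaction" (and is subtracted)
#'   only when \code{Wmax >= T_n}.  Default all 0: full decomposition.
#' @slot rate sampling rate in Hz used for time and band annotation.
#' @slot iteratePerWindow if TRUE, repeat locate-and-subtract within a
#'   window while the maximum stays above threshold (capped).
#' @slot maxIter iteration cap for \code{iteratePerWindow}.
#' @slot keepSubthreshold if TRUE, sub-threshold maxima are recorded in the
#'   event table (flagged \code{isReaction = FALSE}) for diagnostics; they
#'   are never subtracted.
#' @exportClass DecompositionConfig
setClass("DecompositionConfig",
  representation(nMax = "integer", nMin = "integer", pGrid = "numeric",
                 K = "integer", thresholds = "numeric", rate = "numeric",
                 iteratePerWindow = "logical", maxIter = "integer",
                 keepSubthreshold = "logical"))

setValidity("DecompositionConfig", function(object) {
  msg <- NULL
  if (object@nMin < 2L) msg <- c(msg, "'nMin' must be >= 2")
  if (object@nMax < object@nMin) msg <- c(msg, "'nMax' must be >= nMin")
  if (!length(object@pGrid) || any(object@pGrid <= 0 | object@pGrid >= 1))
    msg <- c(msg, "'pGrid' values must lie strictly between 0 and 1")
  if (any(object@thresholds < 0))
    msg <- c(msg, "'thresholds' must be nonnegative")
  if (object@rate <= 0) msg <- c(msg, "'rate' must be positive")
  if (is.null(msg)) TRUE else msg
})

#' Result of the dyadic multiscale decomposition
#'
#' Everything the cascade produces for one trace: the event table, per-level
#' restored components and winning-asymmetry energy maps laid out over the
#' (zero-padded) sample axis, per-segment DC terms and the final residual.
#' With all thresholds at zero the identity
#' \code{input = DC + sum(components) + residual} holds to double precision
#' and the bottom-level residual vanishes (complete 4-point basis).
#'
#' @slot events [S4Vectors::DataFrame] with one row per detected event;
#'   columns include level, segment, window, a0, p0, shiftSample,
#'   globalSample, timeS, timeMs, bandHz, energy, bandEnergy, isReaction
#'   and a K-column \code{coefficients} matrix column.
#' @slot components named list (\code{"n10"} .. \code{"n2"}) of full-length
#'   numeric vectors: the sum of restored components subtracted at that level.
#' @slot energyMaps named list of full-length numeric vectors: per level,
#'   the winning-asymmetry energy functional of every window, concatenated.
#' @slot dcTerms numeric, mean removed from each top-level segment.
#' @slot residual numeric, final residual over the padded axis.
#' @slot input numeric, the zero-padded input trace.
#' @slot M original (unpadded) signal length.
#' @slot rate sampling rate in Hz.
#' @slot config the [DecompositionConfig-class] used.
#' @exportClass DecompositionResult
setClass("DecompositionResult",
  representation(events = "DataFrame", components = "list",
                 energyMaps = "list", dcTerms = "numeric",
                 residual = "numeric", input = "numeric", M = "integer",
                 rate = "numeric", config = "DecompositionConfig"))

#' Per-level energy thresholds trained from labeled examples
#'
#' @slot thresholds named numeric of per-level thresholds \code{T_n}, the
#'   minimum over expert-marked training signals of each signal's maximal
#'   window energy at that level.
#' @slot provenance [S4Vectors::DataFrame] of the per-signal, per-level
#'   maximal energies that entered the minimum.
#' @exportClass ThresholdTable
setClass("ThresholdTable",
  representation(thresholds = "numeric", provenance = "DataFrame"))

#' Classical Krawtchouk mother-wavelet spectrum
#'
#' Coefficients and energies of the shift-variant baseline transform:
#' aligned, non-overlapping translations \code{b = 2^n * s} at every dyadic
#' level, symmetric mother wavelet (p = 0.5).
#'
#' @slot coefficients named list per level of \code{K x S} coefficient
#'   matrices (S translations, concatenated over top-level segments).
#' @slot energies named list per level of numeric energy vectors
#'   \code{W^{n,b}}.
#' @slot nMax,nMin dyadic level range.
#' @slot K functions per window.
#' @slot rate sampling rate in Hz.
#' @slot M original signal length; \code{L} padded length.
#' @slot L padded length.
#' @exportClass ClassicalSpectrum
setClass("ClassicalSpectrum",
  representation(coefficients = "list", energies = "list",
                 nMax = "integer", nMin = "integer", K = "integer",
                 rate = "numeric", M = "integer", L = "integer"))

#' Ground truth attached to a synthetic trace
#'
#' @slot events data.frame with one row per planted event: type ("blink" or
#'   "burst"), time (s), centerSample, extremumSample (argmax of |waveform|,
#'   the location a localization method is expected to report), amplitude
#'   (peak, µV), width (s), skew, freq (Hz, bursts) and level (the dyadic
#'   level whose band contains the event).
#' @slot noise list with elements \code{model} ("white" or "pink") and
#'   \code{sigma}.
#' @slot rate sampling rate in Hz.
#' @slot seed integer seed that fully determines the trace.
#' @exportClass SyntheticTruth
setClass("SyntheticTruth",
  representation(events = "data.frame", noise = "list",
                 rate = "numeric", seed = "integer"))
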