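#' Accessors for krawlet classes
#'
#' Small generic accessors so that slots never need to be touched directly:
#' `samples()` and `sampleRate()` for [Signal-class], `basisValues()`,
#' `basisAsymmetry()`, `basisSize()` and `basisOrder()` for
#' [KrawtchoukBasis-class], `events()`, `residualSignal()` and `dcTerms()`
#' for [DecompositionResult-class], `thresholds()` for
#' [ThresholdTable-class], `energies()` for [ClassicalSpectrum-class] and
#' `truthEvents()` for [SyntheticTruth-class].
#'
#' @param object an object of the documented class.
#' @return the corresponding slot value.
#' @name accessors
#' @aliases samples sampleRate basisValues basisAsymmetry basisSize
#'   basisOrder events residualSignal dcTerms thresholds energies
#'   truthEvents
NULL

#' @rdname accessors
#' @export
setGeneric("samples", function(object) standardGeneric("samples"))
#' @rdname accessors
#' @export
setGeneric("sampleRate", function(object) standardGeneric("sampleRate"))
#' @rdname accessors
#' @export
setGeneric("basisValues", function(object) standardGeneric("basisValues"))
#' @rdname accessors
#' @export
setGeneric("basisAsymmetry", function(object) standardGeneric("basisAsymmetry"))
#' @rdname accessors
#' @export
setGeneric("basisSize", function(object) standardGeneric("basisSize"))
#' @rdname accessors
#' @export
setGeneric("basisOrder", function(object) standardGeneric("basisOrder"))
#' @rdname accessors
#' @export
setGeneric("events", function(object) standardGeneric("events"))
#' @rdname accessors
#' @export
setGeneric("residualSignal", function(object) standardGeneric("residualSignal"))
#' @rdname accessors
#' @export
setGeneric("dcTerms", function(object) standardGeneric("dcTerms"))
#' @rdname accessors
#' @export
setGeneric("thresholds", function(object) standardGeneric("thresholds"))
#' @rdname accessors
#' @export
setGeneric("energies", function(object) standardGeneric("energies"))
#' @rdname accessors
#' @export
setGeneric("truthEvents", function(object) standardGeneric("truthEvents"))

#' @describeIn accessors sample vector of a Signal.
setMethod("samples", "Signal", function(object) object@samples)
#' @describeIn accessors sampling rate of a Signal.
setMethod("sampleRate", "Signal", function(object) object@rate)
#' @describeIn accessors K x N matrix of basis function values.
setMethod("basisValues", "KrawtchoukBasis", function(object) object@values)
#' @describeIn accessors asymmetry p of a basis.
setMethod("basisAsymmetry", "KrawtchoukBasis", function(object) object@p)
#' @describeIn accessors window length N of a basis.
setMethod("basisSize", "KrawtchoukBasis", function(object) object@N)
#' @describeIn accessors number of retained functions K.
setMethod("basisOrder", "KrawtchoukBasis", function(object) object@K)
#' @describeIn accessors event table of a decomposition.
setMethod("events", "DecompositionResult", function(object) object@events)
#' @describeIn accessors final residual (padded axis).
setMethod("residualSignal", "DecompositionResult",
          function(object) object@residual)
#' @describeIn accessors per-segment DC terms.
setMethod("dcTerms", "DecompositionResult", function(object) object@dcTerms)
#' @describeIn accessors per-level thresholds T_n.
setMethod("thresholds", "ThresholdTable", function(object) object@thresholds)
#' @describeIn accessors per-level classical energy vectors.
setMethod("energies", "ClassicalSpectrum", function(object) object@energies)
#' @describeIn accessors planted-event table of a synthetic truth.
setMethod("truthEvents", "SyntheticTruth", function(object) object@events)

#' Length of a Signal
#'
#' @param x a [Signal-class].
#' @return number of samples.
#' @export
setMethod("length", "Signal", function(x) length(x@samples))

#' Write a spectrogram matrix to CSV
#'
#' Exports a level-by-position energy matrix (rows = dyadic levels from
#' coarse to fine, columns = sample positions on the padded axis).  For a
#' [DecompositionResult-class] each row is the concatenated winning-asymmetry
#' energy functional of the level's windows; for a
#' [ClassicalSpectrum-class] each window's energy \eqn{W^{n,b}} is held
#' constant across the window, which is what makes the baseline's
#' time-resolution limit visible.
#'
#' @param object a [DecompositionResult-class] or [ClassicalSpectrum-class].
#' @param path output CSV path.
#' @return (invisibly) the matrix written.
#' @export
setGeneric("writeSpectrogram",
           function(object, path) standardGeneric("writeSpectrogram"))

#' Spectrogram matrix of a result
#'
#' The level-by-position energy matrix underlying [writeSpectrogram()].
#'
#' @param object a [DecompositionResult-class] or [ClassicalSpectrum-class].
#' @return numeric matrix, rows named \code{"n<level>"} coarse to fine.
#' @export
setGeneric("spectrogramMatrix",
           function(object) standardGeneric("spectrogramMatrix"))
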