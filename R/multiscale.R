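# Dyadic multiscale decomposition.
#
# Processing order: the trace is cut into consecutive top-level segments of
# 2^nMax samples (tail zero-padded).  Within a segment the mean is removed
# once (kept as the DC term) and levels are processed in descending order on
# the running residual, windows left to right within a level.  A window's
# located component is subtracted only when its energy reaches the level
# threshold T_n; with all thresholds at zero the cascade is a lossless
# decomposition and the 4-point bottom level leaves an exactly zero residual
# (complete basis).

.levelKey <- function(n) paste0("n", n)

#' Configure a multiscale decomposition
#'
#' @param nMax top dyadic level; windows of \code{2^nMax} samples
#'   (default 10: 1024-point windows, the scale used for 500 Hz EEG).
#' @param nMin bottom dyadic level (default 2: 4-point windows).
#' @param pGrid asymmetry grid (default \code{seq(0.1, 0.9, 0.1)}).
#' @param K Krawtchouk functions per window (default 4).
#' @param thresholds per-level energy thresholds \eqn{T_n}: a single number
#'   recycled to all levels, or a vector named \code{"n10"..."n2"}.
#'   Default 0 everywhere, i.e. full decomposition.
#' @param rate sampling rate in Hz.
#' @param iteratePerWindow repeat locate-and-subtract within a window while
#'   the maximum stays at or above threshold (only meaningful with positive
#'   thresholds; capped at \code{maxIter}).
#' @param maxIter iteration cap per window (default 8).
#' @param keepSubthreshold record sub-threshold maxima (not subtracted) in
#'   the event table for diagnostics.
#' @return a [DecompositionConfig-class].
#' @export
decompositionConfig <- function(nMax = 10L, nMin = 2L,
                                pGrid = seq(0.1, 0.9, by = 0.1), K = 4L,
                                thresholds = 0, rate = 500,
                                iteratePerWindow = FALSE, maxIter = 8L,
                                keepSubthreshold = FALSE) {
  nMax <- as.integer(nMax); nMin <- as.integer(nMin)
  lev <- nMax:nMin
  th <- if (length(thresholds) == 1L && is.null(names(thresholds))) {
    structure(rep(as.numeric(thresholds), length(lev)),
              names = .levelKey(lev))
  } else {
    full <- structure(numeric(length(lev)), names = .levelKey(lev))
    miss <- setdiff(names(thresholds), names(full))
    if (length(miss))
      stop("unknown threshold level(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    full[names(thresholds)] <- as.numeric(thresholds)
    full
  }
  new("DecompositionConfig", nMax = nMax, nMin = nMin,
      pGrid = as.numeric(pGrid), K = as.integer(K), thresholds = th,
      rate = as.numeric(rate), iteratePerWindow = isTRUE(iteratePerWindow),
      maxIter = as.integer(maxIter),
      keepSubthreshold = isTRUE(keepSubthreshold))
}

.emptyEvents <- function(K) {
  DataFrame(level = integer(0), segment = integer(0), window = integer(0),
            a0 = integer(0), p0 = numeric(0), shiftSample = numeric(0),
            globalSample = numeric(0), timeS = numeric(0),
            timeMs = numeric(0), bandHz = numeric(0), energy = numeric(0),
            bandEnergy = numeric(0), isReaction = logical(0),
            coefficients = I(matrix(numeric(0), 0L, K)))
}

#' Multiscale localization of impulse components
#'
#' Runs the full cascade: per top-level segment, re-zeroing (DC kept), then
#' per level from coarse to fine, per window, shift/asymmetry localization,
#' threshold-gated reaction detection and component subtraction from the
#' running residual.  Every detected event is annotated with its global
#' sample index, time and nominal frequency band \code{rate / 2^n}.
#'
#' Two location columns are reported per event: \code{shiftSample}, the raw
#' winning shift \code{a0} mapped to global coordinates
#' (\code{origin + segment/window offset + a0}), and \code{globalSample},
#' the extremum (argmax of absolute value) of the restored component in
#' global coordinates — the estimate comparable to the visible extremum of
#' the impulse, since the raw shift is offset from the impulse body by the
#' mass center of the basis (about \code{p0 * (N-1)} lattice points).
#' Events whose \code{globalSample} falls in the zero-padded tail beyond
#' the end of the signal are not reported.
#'
#' @param signal a [Signal-class] or numeric vector.
#' @param config a [DecompositionConfig-class]; by default constructed with
#'   the signal's sampling rate.
#' @return a [DecompositionResult-class].
#' @examples
#' sim <- makeComposite(3, events = data.frame(type = "blink", time = 1.5,
#'                                             amplitude = 120), seed = 7)
#' d <- decomposeSignal(sim$signal, decompositionConfig(nMin = 5))
#' head(events(d))
#' @export
decomposeSignal <- function(signal, config = NULL) {
  if (is.numeric(signal)) signal <- Signal(signal, rate = 500)
  stopifnot(is(signal, "Signal"))
  if (is.null(config)) config <- decompositionConfig(rate = signal@rate)
  stopifnot(is(config, "DecompositionConfig"))
  y <- signal@samples
  if (!all(is.finite(y)))
    stop(sprintf("non-finite sample at index %d",
                 which(!is.finite(y))[1L]), call. = FALSE)
  M <- length(y)
  W0 <- 2L^config@nMax
  nSeg <- max(1L, ceiling(M / W0))
  L <- nSeg * W0
  padded <- c(y, numeric(L - M))
  origin0 <- signal@origin - 1          # global offset of sample 1
  lev <- config@nMax:config@nMin

  components <- lapply(lev, function(n) numeric(L))
  energyMaps <- lapply(lev, function(n) numeric(L))
  names(components) <- names(energyMaps) <- .levelKey(lev)
  dc <- numeric(nSeg)
  residual <- numeric(L)
  ev <- list()

  for (s in seq_len(nSeg)) {
    segIdx <- ((s - 1L) * W0 + 1L):(s * W0)
    z <- zeroLevel(padded[segIdx])
    dc[s] <- z$mean
    r <- z$centered
    for (n in lev) {
      N <- 2L^n
      Tn <- config@thresholds[[.levelKey(n)]]
      Sn <- W0 %/% N
      for (l in seq_len(Sn)) {
        wIdx <- ((l - 1L) * N + 1L):(l * N)
        offset <- origin0 + (s - 1L) * W0 + (l - 1L) * N
        iter <- 0L
        repeat {
          iter <- iter + 1L
          loc <- locateImpulse(r[wIdx], pGrid = config@pGrid, K = config@K)
          spW <- energyMap(shiftSpectra(r[wIdx],
                                        getBasis(N, loc@p0, config@K)))@W
          if (iter == 1L)
            energyMaps[[.levelKey(n)]][segIdx[wIdx]] <- spW
          reaction <- loc@Wmax >= Tn
          record <- reaction || config@keepSubthreshold
          if (record) {
            comp <- restoreComponent(loc)
            peak <- which.max(abs(comp))
            gs <- offset + peak
            if (gs <= origin0 + M) {
              ev[[length(ev) + 1L]] <- list(
                level = n, segment = s, window = l, a0 = loc@a0,
                p0 = loc@p0, shiftSample = offset + loc@a0,
                globalSample = gs, energy = loc@Wmax,
                bandEnergy = sum(spW), isReaction = reaction,
                coefficients = loc@coefficients)
            }
          }
          if (reaction) {
            comp <- restoreComponent(loc)
            r[wIdx] <- r[wIdx] - comp
            components[[.levelKey(n)]][segIdx[wIdx]] <-
              components[[.levelKey(n)]][segIdx[wIdx]] + comp
          }
          if (!reaction || !config@iteratePerWindow ||
              iter >= config@maxIter) break
        }
      }
    }
    residual[segIdx] <- r
  }

  events <- if (length(ev)) {
    DataFrame(level = vapply(ev, `[[`, integer(1), "level"),
              segment = vapply(ev, `[[`, integer(1), "segment"),
              window = vapply(ev, `[[`, integer(1), "window"),
              a0 = vapply(ev, `[[`, integer(1), "a0"),
              p0 = vapply(ev, `[[`, numeric(1), "p0"),
              shiftSample = vapply(ev, `[[`, numeric(1), "shiftSample"),
              globalSample = vapply(ev, `[[`, numeric(1), "globalSample"),
              timeS = vapply(ev, `[[`, numeric(1), "globalSample") /
                config@rate,
              timeMs = vapply(ev, `[[`, numeric(1), "globalSample") *
                1000 / config@rate,
              bandHz = config@rate / 2^vapply(ev, `[[`, integer(1), "level"),
              energy = vapply(ev, `[[`, numeric(1), "energy"),
              bandEnergy = vapply(ev, `[[`, numeric(1), "bandEnergy"),
              isReaction = vapply(ev, `[[`, logical(1), "isReaction"),
              coefficients = I(do.call(rbind,
                                       lapply(ev, `[[`, "coefficients"))))
  } else .emptyEvents(config@K)

  new("DecompositionResult", events = events, components = components,
      energyMaps = energyMaps, dcTerms = dc, residual = residual,
      input = padded, M = as.integer(M), rate = config@rate,
      config = config)
}

#' Reconstruct a trace from decomposition pieces
#'
#' Sums the per-segment DC terms, the restored components of selected
#' levels, and (optionally) the final residual over the padded sample axis.
#' With all levels, DC and residual included, the reconstruction equals the
#' (zero-padded) input to double precision when the decomposition was run
#' with zero thresholds.
#'
#' @param result a [DecompositionResult-class].
#' @param levels integer levels to include (default all).
#' @param dc include the per-segment DC terms (default TRUE).
#' @param residual include the final residual (default TRUE).
#' @return numeric vector on the padded axis.
#' @export
reconstructSignal <- function(result, levels = NULL, dc = TRUE,
                              residual = TRUE) {
  stopifnot(is(result, "DecompositionResult"))
  cfg <- result@config
  if (is.null(levels)) levels <- cfg@nMax:cfg@nMin
  out <- numeric(length(result@input))
  if (dc) {
    W0 <- 2L^cfg@nMax
    out <- out + rep(result@dcTerms, each = W0)
  }
  for (n in levels) {
    key <- .levelKey(n)
    if (is.null(result@components[[key]]))
      stop("level ", n, " was not computed", call. = FALSE)
    out <- out + result@components[[key]]
  }
  if (residual) out <- out + result@residual
  out
}

#' Restoration error of a component subset
#'
#' Euclidean distance \eqn{\varepsilon = \|y' - y\|} between the input
#' trace and a reconstruction from the selected pieces.
#'
#' @inheritParams reconstructSignal
#' @param maxAbs if TRUE return the maximum absolute ordinate difference
#'   instead of the Euclidean norm.
#' @return a single nonnegative number.
#' @export
restorationError <- function(result, levels = NULL, dc = TRUE,
                             residual = TRUE, maxAbs = FALSE) {
  d <- reconstructSignal(result, levels = levels, dc = dc,
                         residual = residual) - result@input
  if (maxAbs) max(abs(d)) else sqrt(sum(d^2))
}

#' Train per-level reaction thresholds
#'
#' For every training signal that experts marked as containing a reaction,
#' the cascade is run with zero thresholds and the maximal window energy at
#' each level is recorded; the trained threshold \eqn{T_n} is the minimum
#' of these maxima over the marked signals, so that every expert-marked
#' reaction would have passed it.
#'
#' @param signals list of [Signal-class] (or numeric vectors).
#' @param marked logical vector: which signals contain an expert-confirmed
#'   reaction.  Default: all of them.
#' @param config a [DecompositionConfig-class] (thresholds ignored).
#' @return a [ThresholdTable-class].
#' @export
trainThresholds <- function(signals, marked = rep(TRUE, length(signals)),
                            config = decompositionConfig()) {
  if (!length(signals))
    stop("'signals' must contain at least one training signal",
         call. = FALSE)
  if (length(marked) != length(signals))
    stop("'marked' must match 'signals' in length", call. = FALSE)
  if (!any(marked))
    stop("at least one training signal must be marked as a reaction",
         call. = FALSE)
  cfg0 <- decompositionConfig(nMax = config@nMax, nMin = config@nMin,
                              pGrid = config@pGrid, K = config@K,
                              thresholds = 0, rate = config@rate)
  lev <- config@nMax:config@nMin
  rows <- list()
  for (i in which(marked)) {
    d <- decomposeSignal(signals[[i]], cfg0)
    e <- d@events
    for (n in lev) {
      wmax <- if (any(e$level == n)) max(e$energy[e$level == n]) else NA_real_
      rows[[length(rows) + 1L]] <- list(signal = i, level = n, Wmax = wmax)
    }
  }
  prov <- DataFrame(signal = vapply(rows, `[[`, numeric(1), "signal"),
                    level = vapply(rows, `[[`, numeric(1), "level"),
                    Wmax = vapply(rows, `[[`, numeric(1), "Wmax"))
  th <- vapply(lev, function(n) {
    v <- prov$Wmax[prov$level == n]
    v <- v[is.finite(v)]
    if (length(v)) min(v) else 0
  }, numeric(1))
  names(th) <- .levelKey(lev)
  new("ThresholdTable", thresholds = th, provenance = prov)
}

#' Nominal frequency band of a dyadic level
#'
#' The band label attached to level \code{n} windows of \code{2^n} samples:
#' \code{rate / 2^n} Hz.  At 500 Hz this reproduces the usual
#' correspondences (level 10 ~ 0.49 Hz blink band, level 5 ~ 15.6 Hz
#' muscle band, level 2 ~ 125 Hz).
#'
#' @param n dyadic level (>= 1).
#' @param rate sampling rate in Hz.
#' @return band in Hz.
#' @export
levelToFrequency <- function(n, rate) {
  stopifnot(all(n >= 1), rate > 0)
  rate / 2^n
}

#' Total shift-spectrum energy of one level
#'
#' Sums the winning-asymmetry energy functional over all shift positions
#' and all windows of a level — the level's share of decomposition energy
#' measured over the full shift spectrum (not only at the located maxima;
#' for the latter see [eventPower()]).
#'
#' @param result a [DecompositionResult-class].
#' @param level dyadic level.
#' @return a single nonnegative number (units: squared input units).
#' @export
bandEnergy <- function(result, level) {
  stopifnot(is(result, "DecompositionResult"))
  key <- .levelKey(level)
  if (is.null(result@energyMaps[[key]]))
    stop("level ", level, " was not computed in this decomposition",
         call. = FALSE)
  sum(result@energyMaps[[key]])
}

#' Signal-to-noise ratio between level sets
#'
#' Ratio of the summed [bandEnergy()] of the signal levels to that of the
#' noise levels (e.g. signal = the 1024-point blink scale, noise = the
#' 512- down to 4-point scales).
#'
#' @param result a [DecompositionResult-class].
#' @param signalLevels,noiseLevels disjoint sets of dyadic levels.
#' @return a single positive number.
#' @export
signalNoiseRatio <- function(result, signalLevels, noiseLevels) {
  if (length(intersect(signalLevels, noiseLevels)))
    stop("'signalLevels' and 'noiseLevels' must be disjoint", call. = FALSE)
  es <- sum(vapply(signalLevels, function(n) bandEnergy(result, n),
                   numeric(1)))
  en <- sum(vapply(noiseLevels, function(n) bandEnergy(result, n),
                   numeric(1)))
  if (en == 0)
    stop("noise energy is zero; the ratio is undefined", call. = FALSE)
  es / en
}

.eventTable <- function(events) {
  if (is(events, "DecompositionResult")) events@events else events
}

#' Summed power of selected events
#'
#' Sum of the located maxima \eqn{W^{(p)}(a, a)} over the selected events —
#' the power of a reaction spread over several scales and windows.
#'
#' @param events a [DecompositionResult-class] or its event table.
#' @param levels dyadic levels to include (default all).
#' @param sampleRange optional length-2 numeric: keep events whose
#'   \code{globalSample} lies inside the closed range.
#' @return total power in squared input units; 0 (with a warning) when the
#'   selection is empty.
#' @export
eventPower <- function(events, levels = NULL, sampleRange = NULL) {
  e <- .eventTable(events)
  keep <- rep(TRUE, nrow(e))
  if (!is.null(levels)) keep <- keep & e$level %in% levels
  if (!is.null(sampleRange))
    keep <- keep & e$globalSample >= sampleRange[1L] &
      e$globalSample <= sampleRange[2L]
  if (!any(keep)) {
    warning("no events in the selection; returning zero power")
    return(0)
  }
  sum(e$energy[keep])
}

#' Temporal span of selected events
#'
#' Earliest and latest global samples among the events, converted to
#' milliseconds, plus the duration between them.
#'
#' @param events a [DecompositionResult-class] or its event table.
#' @param rate sampling rate in Hz.
#' @param levels optional subset of dyadic levels.
#' @return named numeric: \code{startSample}, \code{endSample},
#'   \code{startMs}, \code{endMs}, \code{durationMs}.
#' @export
eventSpan <- function(events, rate, levels = NULL) {
  e <- .eventTable(events)
  if (!is.null(levels)) e <- e[e$level %in% levels, , drop = FALSE]
  if (!nrow(e)) stop("no events in the selection", call. = FALSE)
  s0 <- min(e$globalSample); s1 <- max(e$globalSample)
  c(startSample = s0, endSample = s1,
    startMs = s0 * 1000 / rate, endMs = s1 * 1000 / rate,
    durationMs = (s1 - s0) * 1000 / rate)
}
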