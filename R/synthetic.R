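# Seeded generator of EEG-like traces with ground truth, and
# localization-accuracy evaluation.

# Run code with a private, fully seeded RNG stream; the caller's RNG state
# is untouched.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

#' Basis-built impulse window
#'
#' An exact member of the shifted Krawtchouk family:
#' \eqn{\sum_k \alpha_k F_k^{(p_0)}((i-a_0) mod^* N)}.  [locateImpulse()]
#' recovers \code{(a0, p0)} exactly on such windows with
#' \code{Wmax = sum(amplitudes^2)}, which makes them the reference fixture
#' for parameter-recovery checks.
#'
#' @param N window length.
#' @param a0 true shift, \code{1 <= a0 <= N}.
#' @param p0 true asymmetry (a value of the analysis grid).
#' @param amplitudes numeric vector of K coefficients (µV).
#' @return list with \code{window} (numeric length N) and \code{truth}
#'   (list with a0, p0, amplitudes, Wmax).
#' @export
makeImpulse <- function(N, a0, p0, amplitudes) {
  if (length(a0) != 1L || a0 < 1 || a0 > N || a0 != round(a0))
    stop("'a0' must be a single integer in 1..N", call. = FALSE)
  if (length(p0) != 1L || p0 <= 0 || p0 >= 1)
    stop("'p0' must lie strictly between 0 and 1", call. = FALSE)
  K <- length(amplitudes)
  V <- getBasis(N, p0, K)@values
  idx <- ((seq_len(N) - a0) %% N) + 1L
  window <- as.numeric(amplitudes %*% V[, idx, drop = FALSE])
  list(window = window,
       truth = list(a0 = as.integer(a0), p0 = p0, amplitudes = amplitudes,
                    Wmax = sum(amplitudes^2)))
}

# Blink surrogate: skewed derivative-of-Gaussian (biphasic, smooth).  Each
# side has width width*(1 +/- skew) and amplitude scaled inversely with its
# width, as for the derivative of a genuinely skewed Gaussian: the narrow
# lobe is the taller one, giving the dominant-deflection-plus-rebound shape
# of real blink artifacts.  A is the peak amplitude of the symmetric
# (skew = 0) bump.
.blinkWave <- function(t, tc, A, width, skew) {
  u <- t - tc
  s <- width * (1 + skew * sign(u))
  x <- u / s
  A * (width / s) * x * exp((1 - x^2) / 2)
}

.burstWave <- function(t, tc, A, width, freq, phase = 0) {
  u <- t - tc
  A * exp(-0.5 * (u / width)^2) * sin(2 * pi * freq * u + phase)
}

.pinkNoise <- function(n, sigma) {
  w <- rnorm(n)
  sp <- fft(w)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)                # two-sided frequency index
  sp <- sp / sqrt(f)
  x <- Re(fft(sp, inverse = TRUE)) / n
  x * sigma / stats::sd(x)
}

#' Composite EEG-like trace with ground truth
#'
#' Generates a deterministic (seeded) surrogate EEG trace: slow blink-like
#' biphasic bumps (skewed Gaussian derivatives, default width 0.08 s, i.e. a
#' ~0.4 s physiological blink footprint detected in the 0.5-1 Hz band of
#' a 500 Hz recording),
#' EMG-like bursts (Gaussian-enveloped oscillations, default frequency
#' \code{rate/32}, the 32-point band), and additive white or pink noise.
#'
#' @param duration trace duration in seconds.
#' @param rate sampling rate in Hz (default 500).
#' @param events data.frame with columns \code{type} ("blink" or "burst"),
#'   \code{time} (center, s), \code{amplitude} (peak, µV) and optionally
#'   \code{width} (s), \code{skew} (blinks, in (-1, 1)), \code{freq} (Hz,
#'   bursts).  NULL for a pure-noise trace.
#' @param noise list with \code{model} ("white" or "pink") and \code{sigma}
#'   (µV); \code{sigma = 0} for a noiseless trace.
#' @param seed integer seed; together with the arguments it fully
#'   determines the trace.
#' @param label lead label for the generated [Signal-class].
#' @return list with \code{signal} (a [Signal-class]) and \code{truth}
#'   (a [SyntheticTruth-class]; its event table records, per event, the
#'   center sample and the extremum sample of the clean waveform plus the
#'   dyadic level whose nominal band contains the event).
#' @examples
#' sim <- makeComposite(3, events = data.frame(type = "blink", time = 1.5,
#'                                             amplitude = 100), seed = 1)
#' truthEvents(sim$truth)
#' @export
makeComposite <- function(duration, rate = 500,
                          events = NULL,
                          noise = list(model = "white", sigma = 0),
                          seed = 1L, label = "synthetic") {
  n <- round(duration * rate)
  if (n < 4) stop("'duration' * 'rate' must be at least 4", call. = FALSE)
  t <- (seq_len(n) - 1) / rate
  clean <- numeric(n)
  truthRows <- list()
  if (!is.null(events) && nrow(events)) {
    for (j in seq_len(nrow(events))) {
      ev <- events[j, , drop = FALSE]
      type <- as.character(ev$type)
      width <- if (!is.null(ev$width) && is.finite(ev$width)) ev$width
               else if (type == "blink") 0.08 else 0.05
      A <- ev$amplitude
      wave <- switch(type,
        blink = {
          skew <- if (!is.null(ev$skew) && is.finite(ev$skew)) ev$skew
                  else 0.2
          .blinkWave(t, ev$time, A, width, skew)
        },
        burst = {
          freq <- if (!is.null(ev$freq) && is.finite(ev$freq)) ev$freq
                  else rate / 32
          .burstWave(t, ev$time, A, width, freq)
        },
        stop("unknown event type '", type, "'", call. = FALSE))
      center <- round(ev$time * rate)
      if (center < 1 || center > n)
        stop("event ", j, " lies outside the trace", call. = FALSE)
      if (length(truthRows)) {
        prev <- vapply(truthRows, `[[`, numeric(1), "centerSample")
        if (any(abs(prev - center) < width * rate))
          warning("events ", j, " and an earlier event overlap")
      }
      level <- if (type == "blink") round(log2(rate * 2)) else
        round(log2(rate / (if (!is.null(ev$freq) && is.finite(ev$freq))
                             ev$freq else rate / 32)))
      truthRows[[j]] <- list(
        type = type, time = ev$time, centerSample = center,
        extremumSample = which.max(abs(wave)), amplitude = A,
        width = width,
        skew = if (type == "blink" && !is.null(ev$skew) &&
                   is.finite(ev$skew)) ev$skew
               else if (type == "blink") 0.2 else NA_real_,
        freq = if (type == "burst")
          (if (!is.null(ev$freq) && is.finite(ev$freq)) ev$freq
           else rate / 32) else NA_real_,
        level = level)
      clean <- clean + wave
    }
  }
  noiseVec <- .withSeed(seed, {
    if (noise$sigma > 0) {
      switch(match.arg(noise$model, c("white", "pink")),
             white = rnorm(n, 0, noise$sigma),
             pink = .pinkNoise(n, noise$sigma))
    } else numeric(n)
  })
  truthDf <- if (length(truthRows)) {
    do.call(rbind, lapply(truthRows, function(r)
      data.frame(r, stringsAsFactors = FALSE)))
  } else {
    data.frame(type = character(0), time = numeric(0),
               centerSample = numeric(0), extremumSample = numeric(0),
               amplitude = numeric(0), width = numeric(0),
               skew = numeric(0), freq = numeric(0), level = numeric(0))
  }
  list(signal = Signal(clean + noiseVec, rate = rate, label = label),
       truth = new("SyntheticTruth", events = truthDf,
                   noise = noise[c("model", "sigma")], rate = rate,
                   seed = as.integer(seed)))
}

#' Localization-error statistics against ground truth
#'
#' Matches detected events to planted events by proximity (greedy nearest
#' neighbour on the global sample axis; a match must fall within half the
#' event's window length) and summarizes the absolute sample errors by
#' their median and quartiles — the robust statistics appropriate for the
#' strongly non-normal error distributions these comparisons produce.
#'
#' @param truth a [SyntheticTruth-class].
#' @param result a [DecompositionResult-class] or an event table
#'   (the \code{globalSample}, \code{level} and \code{isReaction} columns
#'   are used).
#' @param levels optional dyadic levels to which candidate events are
#'   restricted (default: the truth events' own levels, ±1).
#' @return list with \code{errors} (per matched truth event, in samples),
#'   \code{median}, \code{lowerQuartile}, \code{upperQuartile},
#'   \code{misses}, \code{falseAlarms}.
#' @export
evaluateLocalization <- function(truth, result, levels = NULL) {
  stopifnot(is(truth, "SyntheticTruth"))
  te <- truth@events
  if (!nrow(te)) stop("truth contains no events", call. = FALSE)
  e <- .eventTable(result)
  e <- e[e$isReaction, , drop = FALSE]
  if (is.null(levels))
    levels <- unique(unlist(lapply(te$level, function(l) (l - 1):(l + 1))))
  e <- e[e$level %in% levels, , drop = FALSE]
  used <- logical(nrow(e))
  errors <- numeric(0)
  misses <- 0L
  for (j in seq_len(nrow(te))) {
    tol <- 2^te$level[j] / 2
    if (nrow(e)) {
      dist <- abs(e$globalSample - te$extremumSample[j])
      dist[used] <- Inf
      i <- which.min(dist)
      if (is.finite(dist[i]) && dist[i] <= tol) {
        errors <- c(errors, dist[i])
        used[i] <- TRUE
        next
      }
    }
    misses <- misses + 1L
  }
  list(errors = errors,
       median = if (length(errors)) median(errors) else NA_real_,
       lowerQuartile = if (length(errors))
         unname(quantile(errors, 0.25)) else NA_real_,
       upperQuartile = if (length(errors))
         unname(quantile(errors, 0.75)) else NA_real_,
       misses = misses,
       falseAlarms = sum(!used))
}
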