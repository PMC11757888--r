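# Readers and writers: EDF (European Data Format, read-only), delimited
# text, JSON event tables, CSV spectrograms, YAML run configuration.

.edfNum <- function(raw, from, len) as.numeric(.edfStr(raw, from, len))
.edfStr <- function(raw, from, len)
  trimws(rawToChar(raw[from:(from + len - 1L)]))

# Minimal EDF header parser: 256-byte fixed ASCII header followed by
# ns * 256 bytes of per-signal ASCII fields; data records are consecutive
# little-endian int16 blocks per signal.
.readEdfHeader <- function(con) {
  h <- readBin(con, "raw", 256L)
  if (length(h) < 256L) stop("truncated EDF header", call. = FALSE)
  ndr <- .edfNum(h, 237L, 8L)
  recDur <- .edfNum(h, 245L, 8L)
  ns <- as.integer(.edfNum(h, 253L, 4L))
  sh <- readBin(con, "raw", 256L * ns)
  fld <- function(width, offset) {
    start <- offset * ns
    vapply(seq_len(ns), function(i)
      .edfStr(sh, start + (i - 1L) * width + 1L, width), character(1))
  }
  # per-signal blocks: labels at 0, transducer 16, physdim 96, physmin 104,
  # physmax 112, digmin 120, digmax 128, prefilter 136, nsamples 216
  # (byte offsets per signal, each block ns entries wide)
  labels <- fld(16L, 0L)
  physdim <- fld(8L, 96L)
  physmin <- as.numeric(fld(8L, 104L))
  physmax <- as.numeric(fld(8L, 112L))
  digmin <- as.numeric(fld(8L, 120L))
  digmax <- as.numeric(fld(8L, 128L))
  nsamp <- as.integer(fld(8L, 216L))
  list(nRecords = ndr, recordDuration = recDur, nSignals = ns,
       labels = labels, physdim = physdim, physmin = physmin,
       physmax = physmax, digmin = digmin, digmax = digmax,
       samplesPerRecord = nsamp)
}

.readEdf <- function(path, channel) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- .readEdfHeader(con)
  if (is.null(channel))
    stop("EDF file has channels: ",
         paste(hdr$labels, collapse = ", "),
         "; select one with 'channel'", call. = FALSE)
  ci <- if (is.numeric(channel)) as.integer(channel)
        else match(channel, hdr$labels)
  if (is.na(ci) || ci < 1L || ci > hdr$nSignals)
    stop("channel '", channel, "' not found; available: ",
         paste(hdr$labels, collapse = ", "), call. = FALSE)
  perRec <- hdr$samplesPerRecord
  out <- numeric(hdr$nRecords * perRec[ci])
  pos <- 0L
  for (r in seq_len(hdr$nRecords)) {
    for (s in seq_len(hdr$nSignals)) {
      v <- readBin(con, "integer", perRec[s], size = 2L, signed = TRUE,
                   endian = "little")
      if (s == ci) {
        out[pos + seq_len(perRec[s])] <- v
        pos <- pos + perRec[s]
      }
    }
  }
  scale <- (hdr$physmax[ci] - hdr$physmin[ci]) /
    (hdr$digmax[ci] - hdr$digmin[ci])
  phys <- (out - hdr$digmin[ci]) * scale + hdr$physmin[ci]
  list(samples = phys, rate = perRec[ci] / hdr$recordDuration,
       label = hdr$labels[ci])
}

#' Read a single-channel signal
#'
#' Loads a recording from EDF (European Data Format), CSV or plain text.
#' For EDF the sampling rate and lead label come from the header (a
#' conflicting \code{rate} override is an error); for text formats
#' \code{rate} must be supplied.  CSV files may carry a time column named
#' \code{t} or \code{time}, which is skipped.
#'
#' @param path file path.
#' @param format "edf", "csv" or "txt"; "auto" (default) decides from the
#'   file extension.
#' @param channel EDF channel label or index; for CSV, the value column
#'   name or index (default: the single non-time column).
#' @param rate sampling rate in Hz for text formats.
#' @param label lead label override for text formats.
#' @return a [Signal-class].
#' @export
readSignal <- function(path, format = c("auto", "edf", "csv", "txt"),
                       channel = NULL, rate = NULL, label = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, edf = "edf", csv = "csv", tsv = "csv", "txt")
  }
  if (format == "edf") {
    r <- .readEdf(path, channel)
    if (!is.null(rate) && abs(rate - r$rate) > 1e-9)
      stop(sprintf("rate override %g Hz conflicts with EDF header (%g Hz)",
                   rate, r$rate), call. = FALSE)
    return(Signal(r$samples, rate = r$rate, label = r$label))
  }
  if (is.null(rate))
    stop("'rate' must be given for text formats", call. = FALSE)
  if (format == "csv") {
    df <- utils::read.csv(path)
    timeCols <- tolower(names(df)) %in% c("t", "time", "sec", "seconds")
    value <- if (!is.null(channel)) {
      if (is.numeric(channel)) df[[channel]] else {
        if (!channel %in% names(df))
          stop("channel '", channel, "' not found; available: ",
               paste(names(df), collapse = ", "), call. = FALSE)
        df[[channel]]
      }
    } else {
      cand <- which(!timeCols)
      if (!length(cand)) stop("no value column found", call. = FALSE)
      df[[cand[1L]]]
    }
    lab <- if (!is.null(label)) label
           else if (!is.null(channel) && is.character(channel)) channel
           else names(df)[which(!timeCols)[1L]]
    return(Signal(as.numeric(value), rate = rate, label = lab))
  }
  Signal(scan(path, quiet = TRUE), rate = rate,
         label = if (is.null(label)) "signal" else label)
}

#' Write a signal as CSV
#'
#' Two columns: time in seconds and amplitude (column named after the
#' lead label).  Values round-trip through [readSignal()] to full double
#' precision.
#'
#' @param signal a [Signal-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSignal <- function(signal, path) {
  stopifnot(is(signal, "Signal"))
  df <- data.frame(t = (seq_along(signal@samples) - 1) / signal@rate,
                   value = signal@samples)
  names(df)[2L] <- make.names(signal@label)
  utils::write.csv(format(df, digits = 17, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export the event table as JSON
#'
#' One JSON object per event with level, window, shift, global sample,
#' times, nominal band, asymmetry, coefficients, energy and the reaction
#' flag; an empty event list produces a valid empty array.
#'
#' @param result a [DecompositionResult-class] or its event table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeEvents <- function(result, path) {
  e <- .eventTable(result)
  lst <- lapply(seq_len(nrow(e)), function(i) list(
    level = e$level[i], segment = e$segment[i], window = e$window[i],
    a0 = e$a0[i], p0 = e$p0[i], shiftSample = e$shiftSample[i],
    globalSample = e$globalSample[i], timeS = e$timeS[i],
    timeMs = e$timeMs[i], bandHz = e$bandHz[i], energy = e$energy[i],
    bandEnergy = e$bandEnergy[i], isReaction = e$isReaction[i],
    coefficients = as.numeric(e$coefficients[i, ])))
  jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read back a JSON event table
#'
#' @param path a file written by [writeEvents()].
#' @return an [S4Vectors::DataFrame] with the same columns as the event
#'   table of a [DecompositionResult-class].
#' @export
readEvents <- function(path) {
  lst <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!length(lst)) return(.emptyEvents(4L))
  num <- function(f) vapply(lst, function(x) as.numeric(x[[f]]), numeric(1))
  DataFrame(level = as.integer(num("level")),
            segment = as.integer(num("segment")),
            window = as.integer(num("window")),
            a0 = as.integer(num("a0")), p0 = num("p0"),
            shiftSample = num("shiftSample"),
            globalSample = num("globalSample"), timeS = num("timeS"),
            timeMs = num("timeMs"), bandHz = num("bandHz"),
            energy = num("energy"), bandEnergy = num("bandEnergy"),
            isReaction = vapply(lst, function(x)
              isTRUE(x$isReaction), logical(1)),
            coefficients = I(do.call(rbind, lapply(lst, function(x)
              as.numeric(unlist(x$coefficients))))))
}

#' @describeIn writeSpectrogram energy maps of the localization method.
setMethod("spectrogramMatrix", "DecompositionResult", function(object) {
  do.call(rbind, object@energyMaps)
})

#' @describeIn writeSpectrogram classical energies held constant per window.
setMethod("spectrogramMatrix", "ClassicalSpectrum", function(object) {
  lev <- object@nMax:object@nMin
  m <- do.call(rbind, lapply(lev, function(n)
    rep(object@energies[[.levelKey(n)]], each = 2L^n)))
  rownames(m) <- .levelKey(lev)
  m
})

.writeSpectrogramMatrix <- function(m, path) {
  utils::write.csv(data.frame(level = rownames(m), m, check.names = FALSE),
                   path, row.names = FALSE)
  invisible(m)
}

setMethod("writeSpectrogram", "DecompositionResult",
          function(object, path)
            .writeSpectrogramMatrix(spectrogramMatrix(object), path))

setMethod("writeSpectrogram", "ClassicalSpectrum",
          function(object, path)
            .writeSpectrogramMatrix(spectrogramMatrix(object), path))

#' Read a YAML run configuration
#'
#' Loads analysis settings (nMax, nMin, pGrid, K, thresholds, rate,
#' channel, ...) from a YAML file and merges them over the package
#' defaults; unknown keys are an error, so typos do not silently fall back
#' to defaults.  Numbers written with a decimal comma (a convention in
#' some lab exports) are accepted.
#'
#' @param path YAML file.
#' @return list with a [DecompositionConfig-class] under \code{$config}
#'   and any I/O keys (\code{input}, \code{channel}, \code{output})
#'   alongside.
#' @export
readRunConfig <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read run configurations",
         call. = FALSE)
  raw <- yaml::read_yaml(path)
  deComma <- function(x)
    if (is.character(x) && all(grepl("^-?[0-9]+,[0-9]+$", x)))
      as.numeric(sub(",", ".", x, fixed = TRUE)) else x
  raw <- lapply(raw, deComma)
  known <- c("nMax", "nMin", "pGrid", "K", "thresholds", "rate",
             "iteratePerWindow", "maxIter", "keepSubthreshold",
             "input", "channel", "output", "seed", "verbose")
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  cfgKeys <- intersect(names(raw),
                       c("nMax", "nMin", "pGrid", "K", "thresholds",
                         "rate", "iteratePerWindow", "maxIter",
                         "keepSubthreshold"))
  cfg <- do.call(decompositionConfig, raw[cfgKeys])
  c(list(config = cfg),
    raw[intersect(names(raw), c("input", "channel", "output", "seed",
                                "verbose"))])
}

#' Event-metric pipeline for one recording
#'
#' The standard post-decomposition report for a single-channel recording:
#' top-scale reaction locations, the temporal span and summed power of the
#' reactions in a chosen level range, per-level band energies, and the
#' ratio of signal-band to noise-band energy.  This is the pipeline behind
#' the blink/muscle-artifact analyses this method is used for.
#'
#' @param signal a [Signal-class] (e.g. from [readSignal()]).
#' @param config a [DecompositionConfig-class].
#' @param signalLevels levels counted as signal band (default: the top
#'   level).
#' @param noiseLevels levels counted as noise band (default: all others).
#' @param spanLevels level range over which the reaction span/power is
#'   measured (default: signalLevels).
#' @return list with \code{result} (the [DecompositionResult-class]),
#'   \code{reactionSamples}, \code{span}, \code{power},
#'   \code{bandEnergies}, \code{signalNoiseRatio}.
#' @export
reproduceRecording <- function(signal, config = NULL,
                               signalLevels = NULL, noiseLevels = NULL,
                               spanLevels = NULL) {
  stopifnot(is(signal, "Signal"))
  if (is.null(config)) config <- decompositionConfig(rate = signal@rate)
  if (is.null(signalLevels)) signalLevels <- config@nMax
  if (is.null(noiseLevels))
    noiseLevels <- setdiff(config@nMax:config@nMin, signalLevels)
  if (is.null(spanLevels)) spanLevels <- signalLevels
  res <- decomposeSignal(signal, config)
  e <- events(res)
  top <- e[e$isReaction & e$level %in% signalLevels, , drop = FALSE]
  lev <- config@nMax:config@nMin
  be <- vapply(lev, function(n) bandEnergy(res, n), numeric(1))
  names(be) <- .levelKey(lev)
  spanEv <- e[e$isReaction & e$level %in% spanLevels, , drop = FALSE]
  list(result = res,
       reactionSamples = top$globalSample,
       span = if (nrow(spanEv)) eventSpan(spanEv, signal@rate) else NULL,
       power = if (nrow(spanEv)) eventPower(spanEv) else 0,
       bandEnergies = be,
       signalNoiseRatio = signalNoiseRatio(res, signalLevels, noiseLevels))
}
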