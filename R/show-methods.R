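setMethod("show", "Signal", function(object) {
  n <- length(object@samples)
  cat(sprintf("Signal '%s': %d samples at %g Hz (%.3f s), origin %g\n",
              object@label, n, object@rate, n / object@rate,
              object@origin))
  cat(sprintf("  range [%.4g, %.4g]\n",
              min(object@samples), max(object@samples)))
})

setMethod("show", "KrawtchoukBasis", function(object) {
  cat(sprintf("KrawtchoukBasis: N = %d, p = %g, K = %d%s\n",
              object@N, object@p, object@K,
              if (nrow(object@spectra)) " (spectra cached)" else ""))
  cat(sprintf("  Gram deviation %.3e\n", verifyOrthonormality(object)))
})

setMethod("show", "ShiftSpectra", function(object) {
  cat(sprintf("ShiftSpectra: %d functions x %d shifts, p = %g\n",
              nrow(object@coefficients), object@N, object@p))
})

setMethod("show", "EnergyMap", function(object) {
  cat(sprintf("EnergyMap: p = %g, max W = %.4g at a = %d\n",
              object@p, max(object@W), which.max(object@W)))
})

setMethod("show", "LocalizationResult", function(object) {
  cat(sprintf("LocalizationResult: a0 = %d, p0 = %g, Wmax = %.4g (N = %d)\n",
              object@a0, object@p0, object@Wmax, object@N))
})

setMethod("show", "DecompositionConfig", function(object) {
  cat(sprintf(paste0("DecompositionConfig: levels %d..%d ",
                     "(windows %d..%d), K = %d, rate = %g Hz\n"),
              object@nMax, object@nMin, 2L^object@nMax, 2L^object@nMin,
              object@K, object@rate))
  cat(sprintf("  p grid: %s\n", paste(object@pGrid, collapse = " ")))
  if (any(object@thresholds > 0)) {
    cat("  thresholds:\n")
    print(object@thresholds)
  } else cat("  thresholds: all 0 (full decomposition)\n")
})

setMethod("show", "DecompositionResult", function(object) {
  e <- object@events
  cat(sprintf(paste0("DecompositionResult: %d samples (%d padded), ",
                     "%g Hz, levels %d..%d\n"),
              object@M, length(object@input), object@rate,
              object@config@nMax, object@config@nMin))
  cat(sprintf("  %d events (%d reactions); residual max |.| = %.3e\n",
              nrow(e), sum(e$isReaction), max(abs(object@residual))))
  if (nrow(e)) {
    byLevel <- table(e$level[e$isReaction])
    cat("  reactions per level:",
        paste(sprintf("n%s:%d", names(byLevel), byLevel), collapse = " "),
        "\n")
  }
})

setMethod("show", "ThresholdTable", function(object) {
  cat("ThresholdTable:\n")
  print(object@thresholds)
  cat(sprintf("  trained on %d signal(s)\n",
              length(unique(object@provenance$signal))))
})

setMethod("show", "ClassicalSpectrum", function(object) {
  cat(sprintf(paste0("ClassicalSpectrum: levels %d..%d, K = %d, ",
                     "%d samples (%d padded)\n"),
              object@nMax, object@nMin, object@K, object@M, object@L))
})

setMethod("show", "SyntheticTruth", function(object) {
  cat(sprintf("SyntheticTruth: %d event(s), %s noise (sigma = %g), %g Hz, seed %d\n",
              nrow(object@events), object@noise$model, object@noise$sigma,
              object@rate, object@seed))
})
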