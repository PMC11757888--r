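# Independent oracles used across the suite.  These deliberately avoid the
# package's own computational paths (recurrences, FFTs) so that agreement
# is evidence, not tautology.

# Orthonormalize the monomials 1, x, x^2, ... under the binomial weight by
# (twice-iterated) Gram-Schmidt: the result spans the same flag as the
# Krawtchouk functions and equals them up to row signs.
gramSchmidtBasis <- function(N, p, K) {
  M <- N - 1
  x <- 0:M
  rho <- choose(M, x) * p^x * (1 - p)^(M - x)
  G <- t(vapply(seq_len(K), function(k) x^(k - 1) * sqrt(rho),
                numeric(N)))
  for (pass in 1:2) {
    for (k in seq_len(K)) {
      if (k > 1) {
        for (j in seq_len(k - 1))
          G[k, ] <- G[k, ] - sum(G[k, ] * G[j, ]) * G[j, ]
      }
      G[k, ] <- G[k, ] / sqrt(sum(G[k, ]^2))
    }
  }
  G
}

# Align oracle row signs to a reference matrix before comparison.
alignSigns <- function(A, ref) {
  for (k in seq_len(nrow(A))) {
    i <- which.max(abs(ref[k, ]))
    if (sign(A[k, i]) != sign(ref[k, i])) A[k, ] <- -A[k, ]
  }
  A
}

# Direct double-loop evaluation of the shift spectra (no FFT).
directShiftSpectra <- function(y, V) {
  N <- length(y)
  K <- nrow(V)
  C <- matrix(0, K, N)
  for (a in seq_len(N)) {
    idx <- ((seq_len(N) - a) %% N) + 1L
    for (k in seq_len(K)) C[k, a] <- sum(y * V[k, idx])
  }
  C
}

# Exhaustive brute-force localization over (p, a), direct sums only.
bruteForceLocate <- function(y, pGrid = seq(0.1, 0.9, 0.1), K = 4) {
  N <- length(y)
  best <- NULL
  for (p in pGrid) {
    V <- krawlet::basisValues(krawlet::getBasis(N, p, K))
    C <- directShiftSpectra(y, V)
    W <- colSums(C^2)
    a <- which.max(W)
    if (is.null(best) || W[a] > best$Wmax)
      best <- list(a0 = a, p0 = p, Wmax = W[[a]], coefficients = C[, a])
  }
  best
}

circShift <- function(x, d) {
  n <- length(x)
  d <- d %% n
  if (d == 0) x else c(x[(n - d + 1):n], x[1:(n - d)])
}

# Minimal EDF writer for fixtures: one data-record per second, int16
# little-endian, standard 256 + ns*256 byte ASCII header.
writeMiniEdf <- function(path, channels, rate, seconds) {
  ns <- length(channels)
  pad <- function(s, w) formatC(as.character(s), width = -w)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(pad("0", 8), pad("patient X", 80), pad("test rec", 80),
                pad("01.01.26", 8), pad("00.00.00", 8),
                pad(256 * (ns + 1), 8), pad("", 44), pad(seconds, 8),
                pad(1, 8), pad(ns, 4))
  sigfld <- function(vals, w)
    paste(vapply(vals, pad, character(1), w = w), collapse = "")
  physmin <- vapply(channels, function(ch) ch$physmin, numeric(1))
  physmax <- vapply(channels, function(ch) ch$physmax, numeric(1))
  hdr <- paste0(hdr,
    sigfld(names(channels), 16),
    sigfld(rep("AgAgCl electrode", ns), 80),
    sigfld(rep("uV", ns), 8),
    sigfld(physmin, 8), sigfld(physmax, 8),
    sigfld(rep(-32768, ns), 8), sigfld(rep(32767, ns), 8),
    sigfld(rep("none", ns), 80),
    sigfld(rep(rate, ns), 8), sigfld(rep("", ns), 32))
  writeBin(charToRaw(hdr), con)
  for (r in seq_len(seconds)) {
    for (ch in channels) {
      seg <- ch$digital[((r - 1) * rate + 1):(r * rate)]
      writeBin(as.integer(seg), con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}
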