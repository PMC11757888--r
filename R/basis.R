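# Krawtchouk function bases.
#
# Lattice convention: the N window points sit at x = 0..N-1 and the binomial
# weight uses parameter M = N-1, rho(x) = C(M,x) p^x (1-p)^(M-x).  This is
# the unique convention under which the discrete orthogonality relation is
# exact and the four functions on the smallest (4-point) window form a
# complete basis.  Reported indices are 1-based (i = x + 1).

#' Binomial weight lattice
#'
#' The N-point binomial probability weights \eqn{\rho(x) = \binom{N-1}{x}
#' p^x (1-p)^{N-1-x}}, \eqn{x = 0..N-1}, computed in the log domain
#' (via `lchoose`) so that windows up to 1024 points neither underflow the
#' combinatorial factor nor overflow.
#'
#' @param N window length (>= 2).
#' @param p asymmetry coefficient, strictly between 0 and 1.
#' @return numeric vector of N nonnegative weights summing to 1; the mirror
#'   identity \eqn{\rho_p(x) = \rho_{1-p}(N-1-x)} holds to rounding error.
#' @examples
#' binomialWeights(4, 0.5)   # 0.125 0.375 0.375 0.125
#' @export
binomialWeights <- function(N, p) {
  if (length(N) != 1L || !is.finite(N) || N < 2 || N != round(N))
    stop("'N' must be a single integer >= 2", call. = FALSE)
  if (length(p) != 1L || !is.finite(p) || p <= 0 || p >= 1)
    stop("'p' must be a single number strictly between 0 and 1",
         call. = FALSE)
  M <- as.integer(N) - 1L
  x <- 0:M
  exp(lchoose(M, x) + x * log(p) + (M - x) * log1p(-p))
}

# Orthonormal three-term recurrence, pointwise in x.  With M = N-1 and
# phi_0 = sqrt(rho), the orthonormal Krawtchouk functions satisfy
#   x phi_n = a_n phi_{n+1} + b_n phi_n + a_{n-1} phi_{n-1},
#   a_n = sqrt(p q (n+1)(M-n)),  b_n = pM + n(1-2p)
# (Jacobi matrix of the binomial distribution).  `cols` restricts the
# evaluation to a subset of lattice points (used by the p = 0.5 half-lattice
# shortcut); the recurrence acts independently on every x.
.krawtchoukRows <- function(N, p, K, cols = NULL) {
  M <- N - 1L
  x <- if (is.null(cols)) 0:M else cols
  q <- 1 - p
  f0 <- exp(0.5 * (lchoose(M, x) + x * log(p) + (M - x) * log1p(-p)))
  V <- matrix(0, K, length(x))
  V[1L, ] <- f0
  if (K >= 2L)
    V[2L, ] <- (x - p * M) / sqrt(p * q * M) * f0
  if (K >= 3L) {
    for (n in seq_len(K - 2L)) {
      an  <- sqrt(p * q * (n + 1) * (M - n))
      bn  <- p * M + n * (1 - 2 * p)
      anm <- sqrt(p * q * n * (M - n + 1))
      V[n + 2L, ] <- ((x - bn) * V[n + 1L, ] - anm * V[n, ]) / an
    }
  }
  V
}

# The forward recurrence in the order is numerically reliable only while
# the order does not exceed the lattice point (the function value there is
# non-decaying relative to the dominant solution); beyond that the exact
# self-duality phi_n(x) = phi_x(n) of the orthonormal functions supplies
# the value from a reliable entry.  .applyDuality rewrites every entry with
# n > x accordingly (such entries always have x < K, so the needed row
# exists).
.applyDuality <- function(V, K) {
  for (x in 0:(K - 2L)) {
    n <- (x + 1L):(K - 1L)
    V[n + 1L, x + 1L] <- (-1)^(n - x) * V[x + 1L, n + 1L]
  }
  V
}

# Stable high-order evaluation.  The N x N matrix [phi_n(x)] is the
# orthogonal eigenvector matrix of the symmetric tridiagonal Jacobi matrix
# of the binomial weight (eigenvalue x), so a symmetric eigendecomposition
# yields the same functions with machine-precision orthonormality where
# plain forward recurrence would degrade.  Column signs are inherently
# ambiguous in an eigendecomposition; they are fixed against the
# recurrence-plus-duality evaluation, which is accurate wherever the
# entries are non-negligible.
.krawtchoukHighOrder <- function(N, p, K) {
  ref <- if (p > 0.5) {
    # the recurrence-plus-duality scheme is reliable on the side where the
    # weight mass sits; for p > 1/2 build the mirror image at 1-p and
    # reflect (index reversal with degree-parity signs, an exact identity)
    V <- .applyDuality(.krawtchoukRows(N, 1 - p, K), K)
    (-1)^(seq_len(K) - 1L) * V[, N:1L, drop = FALSE]
  } else {
    .applyDuality(.krawtchoukRows(N, p, K), K)
  }
  M <- N - 1L
  q <- 1 - p
  J <- diag(p * M + (0:M) * (1 - 2 * p))
  off <- sqrt(p * q * seq_len(M) * (M - seq_len(M) + 1))
  J[cbind(1:M, 2:N)] <- off
  J[cbind(2:N, 1:M)] <- off
  E <- eigen(J, symmetric = TRUE)
  U <- E$vectors[seq_len(K), order(E$values), drop = FALSE]
  s <- sign(colSums(U * ref))
  s[s == 0] <- 1
  sweep(U, 2L, s, "*")
}

.basisMatrix <- function(N, p, K) {
  if (K > 4L) {
    .krawtchoukHighOrder(N, p, K)
  } else if (abs(p - 0.5) < .Machine$double.eps && N %% 2L == 0L) {
    # Symmetric case: compute the left half only and mirror with the
    # degree-parity sign, halving recurrence error accumulation.
    h <- N %/% 2L
    left <- .krawtchoukRows(N, 0.5, K, cols = 0:(h - 1L))
    V <- matrix(0, K, N)
    V[, seq_len(h)] <- left
    sgn <- (-1)^(seq_len(K) - 1L)
    V[, N:(h + 1L)] <- sgn * left
    V
  } else {
    .krawtchoukRows(N, p, K)
  }
}

#' Construct an orthonormal Krawtchouk basis
#'
#' Builds the first \code{K} orthonormal Krawtchouk functions on an
#' \code{N}-point lattice for asymmetry \code{p} via the orthonormal
#' three-term recurrence (row 1 is the square root of the binomial weight).
#' At \code{p = 0.5} only the left half of the lattice is computed and the
#' right half is mirrored with degree-parity signs, which reduces error
#' accumulation.  Construction fails if the measured Gram deviation exceeds
#' \code{checkTol}; no silent re-orthonormalization is performed.
#'
#' @param N window length (>= 2).
#' @param p asymmetry, strictly between 0 and 1.
#' @param K number of functions, \code{1 <= K <= N} (default 4).
#' @param checkTol orthonormality tolerance enforced at construction
#'   (default \code{1e-8}); set to \code{Inf} to disable.
#' @param spectra if TRUE (default) the row DFTs are cached immediately
#'   (see [cacheSpectra()]).
#' @return a [KrawtchoukBasis-class].
#' @examples
#' b <- krawtchoukBasis(64, 0.3)
#' verifyOrthonormality(b)
#' @export
krawtchoukBasis <- function(N, p, K = 4L, checkTol = 1e-8, spectra = TRUE) {
  if (length(N) != 1L || !is.finite(N) || N < 2 || N != round(N))
    stop("'N' must be a single integer >= 2", call. = FALSE)
  if (length(p) != 1L || !is.finite(p) || p <= 0 || p >= 1)
    stop("'p' must be a single number strictly between 0 and 1",
         call. = FALSE)
  N <- as.integer(N); K <- as.integer(K)
  if (K < 1L || K > N)
    stop("'K' must satisfy 1 <= K <= N", call. = FALSE)
  V <- .basisMatrix(N, p, K)
  b <- new("KrawtchoukBasis", N = N, p = p, K = K, values = V,
           spectra = matrix(complex(0), 0L, 0L))
  dev <- verifyOrthonormality(b)
  if (dev > checkTol)
    stop(sprintf(paste0("Krawtchouk basis (N=%d, p=%g, K=%d) failed the ",
                        "orthonormality check: deviation %.3e > %.3e"),
                 N, p, K, dev, checkTol), call. = FALSE)
  if (spectra) b <- cacheSpectra(b)
  b
}

#' Maximum Gram deviation of a basis
#'
#' Returns \eqn{\max |G - I|} where \eqn{G} is the \code{K x K} Gram matrix
#' of the basis rows — the numerical distance from exact orthonormality.
#'
#' @param basis a [KrawtchoukBasis-class].
#' @return a single nonnegative number.
#' @export
verifyOrthonormality <- function(basis) {
  stopifnot(is(basis, "KrawtchoukBasis"))
  G <- tcrossprod(basis@values)
  max(abs(G - diag(nrow(G))))
}

#' Mirror a basis to asymmetry 1 - p
#'
#' The symmetry of Krawtchouk functions under \eqn{p \mapsto 1-p} is an
#' index reversal with a degree-parity sign:
#' \eqn{F_k^{(p)}(x) = (-1)^{k-1} F_k^{(1-p)}(N-1-x)}.  The mirrored basis
#' equals a direct construction at \eqn{1-p} to rounding error, at the cost
#' of a reversal instead of a recurrence.
#'
#' @param basis a [KrawtchoukBasis-class].
#' @return the [KrawtchoukBasis-class] for asymmetry \code{1 - p} (spectra
#'   cache recomputed if the input had one).
#' @export
mirrorBasis <- function(basis) {
  stopifnot(is(basis, "KrawtchoukBasis"))
  sgn <- (-1)^(seq_len(basis@K) - 1L)
  V <- sgn * basis@values[, basis@N:1L, drop = FALSE]
  b <- new("KrawtchoukBasis", N = basis@N, p = 1 - basis@p, K = basis@K,
           values = V, spectra = matrix(complex(0), 0L, 0L))
  if (nrow(basis@spectra)) b <- cacheSpectra(b) else b
}

#' Cache the frequency-domain transforms of the basis rows
#'
#' Precomputes the DFT of every basis row once per \code{(N, p, K)} so that
#' [shiftSpectra()] can evaluate all N circular shifts with O(N log N) work
#' per function (convolution theorem).  Idempotent.
#'
#' @param basis a [KrawtchoukBasis-class].
#' @return the basis with its \code{spectra} slot filled.
#' @export
cacheSpectra <- function(basis) {
  stopifnot(is(basis, "KrawtchoukBasis"))
  if (nrow(basis@spectra)) return(basis)
  S <- t(apply(basis@values, 1L, fft))
  if (basis@K == 1L) S <- matrix(S, 1L, basis@N)
  basis@spectra <- S
  basis
}

# Session-level memo of constructed bases, keyed by (N, p, K).  The cascade
# revisits the same (N, p) pairs for every window, so construction cost is
# paid once.
.basisMemo <- new.env(parent = emptyenv())

#' Memoized basis lookup
#'
#' Returns the cached [KrawtchoukBasis-class] for \code{(N, p, K)}, building
#' and storing it (with spectra) on first use.
#'
#' @inheritParams krawtchoukBasis
#' @return a [KrawtchoukBasis-class] with cached spectra.
#' @export
getBasis <- function(N, p, K = 4L) {
  key <- sprintf("N%d_p%.10g_K%d", as.integer(N), p, as.integer(K))
  b <- .basisMemo[[key]]
  if (is.null(b)) {
    b <- krawtchoukBasis(N, p, K)
    assign(key, b, envir = .basisMemo)
  }
  b
}

#' Save / load a basis cache on disk
#'
#' Round-trips a [KrawtchoukBasis-class] (values and spectra) bit-exactly
#' through R's native serialization, so large bases can be precomputed once
#' and reused across sessions.
#'
#' @param basis a [KrawtchoukBasis-class].
#' @param path file path.
#' @return `saveBasisCache` returns `path` invisibly; `readBasisCache`
#'   returns the basis.
#' @export
saveBasisCache <- function(basis, path) {
  stopifnot(is(basis, "KrawtchoukBasis"))
  saveRDS(basis, path)
  invisible(path)
}

#' @rdname saveBasisCache
#' @export
readBasisCache <- function(path) {
  b <- readRDS(path)
  if (!is(b, "KrawtchoukBasis"))
    stop("'", path, "' does not contain a KrawtchoukBasis", call. = FALSE)
  b
}
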