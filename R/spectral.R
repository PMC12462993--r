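#' Multitaper cross-spectral density of an ensemble of binned spike trains
#'
#' @slot freq frequency grid (Hz), 0 to Nyquist.
#' @slot S complex array `[channel, channel, frequency]`; Hermitian
#'   positive semidefinite per frequency.
#' @slot nTapers,nTrials estimation metadata.
#' @slot fs sampling rate (Hz).
#' @slot nfft FFT length used (determines the factorization circle).
#' @slot channels channel/unit identifiers.
#' @slot degenerate TRUE when the window carried no spikes at all.
#' @export
setClass("CrossSpectrum", representation(
  freq = "numeric", S = "array", nTapers = "integer", nTrials = "integer",
  fs = "numeric", nfft = "integer", channels = "character",
  degenerate = "logical"
))

setMethod("show", "CrossSpectrum", function(object) {
  cat(sprintf(
    "CrossSpectrum: %d channels, %d frequencies (0-%g Hz), %d trials x %d tapers%s\n",
    dim(object@S)[1], length(object@freq), max(object@freq),
    object@nTrials, object@nTapers,
    if (object@degenerate) " [degenerate]" else ""))
})

## Discrete prolate spheroidal (Slepian) tapers via the symmetric
## tridiagonal eigenproblem; cached per (N, nw, k).
.dpssCache <- new.env(parent = emptyenv())
dpssTapers <- function(N, nw = 2, k = 3) {
  key <- sprintf("%d-%g-%d", N, nw, k)
  if (!is.null(.dpssCache[[key]])) return(.dpssCache[[key]])
  W <- nw / N
  t <- 0:(N - 1)
  md <- ((N - 1 - 2 * t) / 2)^2 * cos(2 * pi * W)
  od <- (1:(N - 1)) * (N - 1:(N - 1)) / 2
  A <- matrix(0, N, N)
  diag(A) <- md
  A[cbind(1:(N - 1), 2:N)] <- od
  A[cbind(2:N, 1:(N - 1))] <- od
  ev <- eigen(A, symmetric = TRUE)
  tap <- ev$vectors[, seq_len(k), drop = FALSE]
  for (i in seq_len(k)) {
    tap[, i] <- tap[, i] / sqrt(sum(tap[, i]^2))
    if (sum(tap[, i]) < 0) tap[, i] <- -tap[, i]
  }
  .dpssCache[[key]] <- tap
  tap
}

#' Multitaper cross-spectral density of binned spike trains
#'
#' Estimates the channel x channel cross-spectral density of 1 ms binned
#' spike counts, mean-subtracted per trial and channel, tapered with
#' `nTapers` Slepian tapers (time-bandwidth `nw`) and averaged over trials
#' and tapers. Trials are treated as independent realizations. The
#' frequency grid runs from 0 to the Nyquist frequency (500 Hz at 1 ms
#' bins).
#'
#' @param ens numeric array `[time, trial, channel]` of binned counts (see
#'   [binSpikes()]), or a list of time x trial matrices (one per channel).
#' @param fs sampling rate of the bins (Hz).
#' @param nTapers number of Slepian tapers.
#' @param nw time-bandwidth product.
#' @param nfft FFT length (default: next power of two >= window length,
#'   at least 256).
#' @param channels channel identifiers.
#' @return a [CrossSpectrum].
#' @export
multitaperCSD <- function(ens, fs = 1000, nTapers = 3, nw = 2, nfft = NULL,
                          channels = NULL) {
  if (is.list(ens))
    ens <- array(unlist(ens), dim = c(dim(ens[[1]]), length(ens)))
  stopifnot(length(dim(ens)) == 3)
  N <- dim(ens)[1]; ntr <- dim(ens)[2]; nch <- dim(ens)[3]
  if (ntr < 2) stop("need at least 2 trials")
  if (is.null(nfft)) nfft <- max(256L, 2^ceiling(log2(2 * N)))
  if (is.null(channels)) channels <- as.character(seq_len(nch))
  degenerate <- sum(ens) == 0
  tap <- dpssTapers(N, nw, nTapers)
  nf <- nfft / 2 + 1
  ## mean-subtract per trial and channel
  mu <- colMeans(ens)                      # trial x channel
  ens <- ens - rep(mu, each = N)
  S <- csd_cpp(ens, tap, as.integer(nfft), fs)
  dimnames(S) <- list(channels, channels, NULL)
  new("CrossSpectrum", freq = seq(0, fs / 2, length.out = nf), S = S,
      nTapers = as.integer(nTapers), nTrials = as.integer(ntr),
      fs = fs, nfft = as.integer(nfft), channels = channels,
      degenerate = degenerate)
}

#' Wilson spectral matrix factorization
#'
#' Factorizes a cross-spectral density into a causal minimum-phase transfer
#' function and an innovation covariance, `S(f) = H(f) Sigma H*(f)`, by
#' Wilson's iteration. This is the step that lets Granger causality be
#' computed from a spectrum directly, without fitting an autoregressive
#' model.
#'
#' @param csd a [CrossSpectrum], or a complex array `[n, n, nf]` (then
#'   `nfft` must be `2 * (nf - 1)`).
#' @param tol convergence tolerance on the relative update of the spectral
#'   factor.
#' @param maxIter maximum iterations.
#' @param ridge diagonal loading added as `ridge * mean(Re(diag))` before
#'   factorizing (stabilizes spike spectra; 0 disables).
#' @return list with `H` (complex array, one-sided), `Sigma` (n x n),
#'   `iterations`, `residual` (worst relative reconstruction error) and
#'   `freq`.
#' @export
wilsonFactorize <- function(csd, tol = 1e-9, maxIter = 100, ridge = 1e-8) {
  if (is(csd, "CrossSpectrum")) {
    S <- csd@S; nfft <- csd@nfft; freq <- csd@freq
  } else {
    S <- csd; nfft <- 2L * (dim(S)[3] - 1L); freq <- NULL
  }
  n <- dim(S)[1]
  if (ridge > 0) {
    lam <- ridge * mean(vapply(seq_len(n), function(i)
      mean(Re(S[i, i, ])), numeric(1)))
    for (i in seq_len(n)) S[i, i, ] <- S[i, i, ] + lam
  }
  out <- wilson_cpp(S, nfft, tol, maxIter)
  if (out$relchange > sqrt(tol) && out$iterations >= maxIter)
    stop(sprintf(
      "Wilson factorization did not converge: rel. change %.3g after %d iterations",
      out$relchange, out$iterations))
  list(H = out$H, Sigma = out$Sigma, iterations = out$iterations,
       residual = out$residual, relchange = out$relchange, freq = freq)
}
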