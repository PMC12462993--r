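## Independent oracles and handmade fixtures used across the suite.

## ---- VAR fixtures with analytic spectra ----

## one-sided CSD of a VAR(1) X_t = A X_{t-1} + e, cov(e) = Sig
varSpectrum <- function(A, Sig, nfft = 256, fs = 1000) {
  n <- nrow(A)
  nf <- nfft / 2 + 1
  S <- array(0i, c(n, n, nf))
  H <- array(0i, c(n, n, nf))
  for (k in seq_len(nf)) {
    z <- exp(-2i * pi * (k - 1) / nfft)
    Hk <- solve(diag(n) - A * z)
    H[, , k] <- Hk
    S[, , k] <- Hk %*% Sig %*% Conj(t(Hk))
  }
  csd <- new("CrossSpectrum", freq = seq(0, fs / 2, length.out = nf),
             S = S, nTapers = 1L, nTrials = 2L, fs = fs,
             nfft = as.integer(nfft), channels = paste0("x", seq_len(n)),
             degenerate = FALSE)
  list(csd = csd, H = H)
}

## parametric time-domain Geweke GC j -> i for a bivariate VAR, via the
## Kolmogorov formula for the reduced univariate innovation variance
gewekeBivariateOracle <- function(A, Sig, i = 2, j = 1, nfft = 4096) {
  sp <- varSpectrum(A, Sig, nfft = nfft)
  Sii <- Re(sp$csd@S[i, i, ])
  nf <- length(Sii)
  Sfull <- c(Sii, rev(Sii[2:(nf - 1)]))     # two-sided circle
  sig2red <- exp(mean(log(Sfull)))
  log(sig2red / Sig[i, i])
}

## simulate trials of a VAR(1) for non-parametric estimation
simulateVAR <- function(A, Sig, N, trials, seed = 1) {
  n <- nrow(A)
  L <- chol(Sig)
  set.seed(seed)
  ens <- array(0, c(N, trials, n))
  for (r in seq_len(trials)) {
    x <- matrix(0, n, N + 50)
    e <- t(matrix(rnorm((N + 50) * n), ncol = n) %*% L)
    for (t in 2:(N + 50)) x[, t] <- A %*% x[, t - 1] + e[, t]
    ens[, r, ] <- t(x[, 51:(N + 50), drop = FALSE])
  }
  ens
}

## ---- brute-force balanced two-way SS decomposition (eta^2 oracle) ----
bruteForceEta <- function(y, f1, f2) {
  f1 <- factor(f1); f2 <- factor(f2)
  mu <- mean(y)
  m1 <- tapply(y, f1, mean)
  m2 <- tapply(y, f2, mean)
  m12 <- tapply(y, interaction(f1, f2), mean)
  n1 <- table(f1); n2 <- table(f2); n12 <- table(interaction(f1, f2))
  ssA <- sum(n1 * (m1 - mu)^2)
  ssB <- sum(n2 * (m2 - mu)^2)
  cell <- interaction(f1, f2)
  ssCells <- sum(n12 * (m12 - mu)^2)
  ssAB <- ssCells - ssA - ssB
  ssE <- sum((y - m12[cell])^2)
  tot <- ssA + ssB + ssAB + ssE
  c(texture = ssA, load = ssB, interaction = ssAB) / tot
}

## ---- handmade session bundles ----

## minimal valid trial table
toyTrials <- function(n = 1, spacing = 3) {
  touch <- 2 + (seq_len(n) - 1) * spacing
  data.frame(index = seq_len(n), block = 1L,
             texture = rep("A", n), load = rep(500, n),
             t_cue = touch - 0.5, t_touch = touch,
             t_hold_end = touch + 1.2)
}

toyBundle <- function(spikes = c(2.1), n = 1) {
  tr <- toyTrials(n)
  SessionBundle(
    sessionId = "toy", animalId = "t",
    regions = data.frame(channel = 1L, region = "M1"),
    trials = tr,
    units = list(SpikeTrain("u1", 1L, "M1", spikes)),
    conditionLevels = list(texture = "A", load = 500))
}

## session of independent homogeneous Poisson units (null fixture for
## connectivity calibration); regions alternate M1 / S1A
poissonBundle <- function(nUnits = 4, rate = 15, nTrials = 40, seed = 1,
                          span = c(-0.8, 1.2)) {
  set.seed(seed)
  tr <- toyTrials(nTrials)
  regions <- rep(c("M1", "S1A"), length.out = nUnits)
  units <- lapply(seq_len(nUnits), function(u) {
    times <- sort(unlist(lapply(tr$t_touch, function(t0) {
      k <- rpois(1, rate * diff(span))
      t0 + sort(runif(k, span[1], span[2]))
    })))
    SpikeTrain(sprintf("%s_u%02d", regions[u], u), u, regions[u], times)
  })
  SessionBundle(
    sessionId = sprintf("null-%d", seed), animalId = "t",
    regions = data.frame(channel = seq_len(nUnits), region = regions),
    trials = tr, units = units,
    conditionLevels = list(texture = "A", load = 500))
}

## unidirectional source -> target fixture: the target emits an extra
## spike 4 ms after each source spike with probability pHit
coupledPairBundle <- function(pHit = 0.35, latency = 0.004, rate = 15,
                              nTrials = 40, seed = 1,
                              span = c(-0.8, 1.2)) {
  set.seed(seed)
  tr <- toyTrials(nTrials)
  gen <- function(t0) {
    k <- rpois(1, rate * diff(span))
    t0 + sort(runif(k, span[1], span[2]))
  }
  src <- lapply(tr$t_touch, gen)
  tgt <- lapply(seq_along(src), function(i) {
    base <- gen(tr$t_touch[i])
    hit <- src[[i]][runif(length(src[[i]])) < pHit]
    sort(c(base, hit + latency + rnorm(length(hit), 0, 3e-4)))
  })
  units <- list(
    SpikeTrain("S1A_src", 1L, "S1A", sort(unlist(src))),
    SpikeTrain("M1_tgt", 2L, "M1", sort(unlist(tgt))),
    SpikeTrain("M1_other", 3L, "M1",
               sort(unlist(lapply(tr$t_touch, gen)))))
  SessionBundle(
    sessionId = sprintf("edge-%d", seed), animalId = "t",
    regions = data.frame(channel = 1:3, region = c("S1A", "M1", "M1")),
    trials = tr, units = units,
    conditionLevels = list(texture = "A", load = 500))
}

## synthetic EffectSeries with prescribed p-values (for inclusion-rule
## boundary tests)
fakeEffectSeries <- function(pTex, pLoad, etaTex = NULL, etaLoad = NULL) {
  grid <- tuningGrid()
  n <- length(windowStarts(grid))
  stopifnot(length(pTex) == n, length(pLoad) == n)
  if (is.null(etaTex)) etaTex <- 1 - pTex
  if (is.null(etaLoad)) etaLoad <- 1 - pLoad
  new("EffectSeries", unitId = "fake", grid = grid,
      table = data.frame(start = windowStarts(grid),
                         eta_texture = etaTex, eta_load = etaLoad,
                         eta_interaction = 0,
                         p_texture = pTex, p_load = pLoad,
                         p_interaction = 1, degenerate = FALSE))
}
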