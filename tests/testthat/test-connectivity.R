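test_that("top-unit selection ranks by rate with deterministic ties", {
  tr <- toyTrials(2)
  mk <- function(id, ch, region, n)
    SpikeTrain(id, ch, region, sort(runif(n, 0, 8)))
  set.seed(1)
  units <- c(lapply(1:12, function(i)
    mk(sprintf("M1_%02d", i), i, "M1", 10 * i)),
    list(mk("S1A_a", 13L, "S1A", 40), mk("S1A_b", 14L, "S1B", 40)))
  b <- SessionBundle("s", "t",
                     data.frame(channel = 1:14,
                                region = c(rep("M1", 12), "S1A", "S1B")),
                     tr, units,
                     conditionLevels = list(texture = "A", load = 500),
                     duration = 10)
  top <- selectTopUnits(b, "M1", 10)
  expect_length(top, 10)
  expect_equal(top[1], "M1_12")
  expect_false(any(c("M1_01", "M1_02") %in% top))
  ## fewer units than requested: all returned
  expect_length(selectTopUnits(b, "S1", 10), 2)
  ## equal rates: lexicographically smaller id first
  expect_equal(selectTopUnits(b, "S1", 1), "S1A_a")
  expect_error(selectTopUnits(toyBundle(), "S1"), "no units")
})

test_that("coherence of independent units is near zero, self-coherence one", {
  b <- poissonBundle(nUnits = 2, rate = 25, nTrials = 60, seed = 3)
  ens <- graspflow:::cgcEnsemble(b, c("M1_u01", "S1A_u02"), c(0, 300))
  csd <- multitaperCSD(ens)
  S <- csd@S
  coh <- Mod(S[1, 2, ])^2 / (Re(S[1, 1, ]) * Re(S[2, 2, ]))
  expect_lt(mean(coh, na.rm = TRUE), 0.05)
  ensSelf <- ens[, , c(1, 1)]
  Ss <- multitaperCSD(ensSelf)@S
  cohSelf <- Mod(Ss[1, 2, ])^2 / (Re(Ss[1, 1, ]) * Re(Ss[2, 2, ]))
  expect_equal(mean(cohSelf[-1]), 1, tolerance = 1e-8)
})

test_that("a cosine-modulated rate shows a spectral peak at its frequency", {
  set.seed(11)
  N <- 300; ntr <- 150
  tt <- seq_len(N) / 1000
  rate <- 40 * (1 + 0.9 * cos(2 * pi * 40 * tt))
  ens <- array(rbinom(N * ntr, 1, rep(rate, ntr) / 1000),
               c(N, ntr, 1))
  csd <- multitaperCSD(ens)
  pow <- Re(csd@S[1, 1, ])
  sel <- csd@freq > 5 & csd@freq < 200
  peak <- csd@freq[sel][which.max(pow[sel])]
  expect_lt(abs(peak - 40), 5)
})

test_that("a flat white spectrum factorizes to identity transfer", {
  n <- 2; nfft <- 128; nf <- nfft / 2 + 1
  Sig <- matrix(c(2, 0.5, 0.5, 1), 2)
  S <- array(0i, c(n, n, nf))
  for (k in 1:nf) S[, , k] <- Sig
  fac <- wilsonFactorize(S, ridge = 0)
  expect_equal(fac$Sigma, Sig, tolerance = 1e-8)
  for (k in c(1, 30, nf))
    expect_equal(Mod(fac$H[, , k]), diag(2), tolerance = 1e-6)
})

test_that("factorization reconstructs a VAR spectrum to oracle precision", {
  A <- matrix(c(0.5, 0, 0.4, 0.3), 2, 2, byrow = TRUE)
  Sig <- diag(c(1, 0.7))
  sp <- varSpectrum(A, Sig)
  fac <- wilsonFactorize(sp$csd, ridge = 0)
  expect_lt(fac$residual, 1e-6)
  expect_lt(max(Mod(fac$H - sp$H)), 1e-6)
  expect_equal(fac$Sigma, Sig, tolerance = 1e-6)
})

test_that("a rank-deficient spectrum is rejected", {
  n <- 2; nfft <- 128; nf <- nfft / 2 + 1
  S <- array(0i, c(n, n, nf))
  for (k in 1:nf) S[, , k] <- matrix(c(1, 1, 1, 1), 2)  # rank 1
  expect_error(wilsonFactorize(S, ridge = 0), "rank-deficient")
})

test_that("conditional GC matches the parametric Geweke oracle on a VAR", {
  A <- matrix(c(0.5, 0, 0.4, 0.3), 2, 2, byrow = TRUE)
  Sig <- diag(c(1, 0.7))
  oracle <- gewekeBivariateOracle(A, Sig)
  ## analytic-spectrum route: should agree closely
  sp <- varSpectrum(A, Sig)
  g <- conditionalGC(sp$csd, "x2", "x1", ridge = 0)
  expect_lt(abs(g$scalar - oracle) / oracle, 0.02)
  ## null direction is numerically zero
  g0 <- conditionalGC(sp$csd, "x1", "x2", ridge = 0)
  expect_lt(g0$scalar, 1e-10)
  ## non-parametric route from simulated trials: within 15%
  ens <- simulateVAR(A, Sig, N = 300, trials = 200, seed = 5)
  csd <- multitaperCSD(ens, nTapers = 3, channels = c("x1", "x2"))
  gHat <- conditionalGC(csd, "x2", "x1")
  expect_lt(abs(gHat$scalar - oracle) / oracle, 0.15)
})

test_that("conditioning removes an indirect chain influence", {
  A <- matrix(0, 3, 3)
  A[1, 1] <- 0.5; A[2, 2] <- 0.3; A[2, 1] <- 0.5
  A[3, 3] <- 0.3; A[3, 2] <- 0.5
  sp <- varSpectrum(A, diag(3))
  biv <- conditionalGC(sp$csd, "x3", "x1", ridge = 0)$scalar
  cond <- conditionalGC(sp$csd, "x3", "x1", "x2", ridge = 0)$scalar
  expect_gt(biv, 0.05)
  expect_lt(cond, 0.2 * biv)
})

test_that("time-domain CGC is nonnegative across random spike windows", {
  b <- poissonBundle(nUnits = 3, rate = 18, nTrials = 40, seed = 17)
  for (s in c(-100, 100, 300)) {
    ens <- graspflow:::cgcEnsemble(b, c("M1_u01", "S1A_u02", "M1_u03"),
                                   c(s, s + 300))
    g <- conditionalGC(multitaperCSD(ens), 1, 2, 3)
    expect_gte(g$scalar, -1e-10)
    fac <- wilsonFactorize(multitaperCSD(ens), tol = 1e-12,
                           maxIter = 300)
    expect_lt(fac$residual, 1e-6)
  }
})

test_that("zero-width jitter cannot reach significance by the strict rule", {
  b <- poissonBundle(nUnits = 2, rate = 20, nTrials = 30, seed = 23)
  js <- jitterSignificance(b, "S1A_u02", "M1_u01", "GH", n = 10,
                           halfwidth = 0, seed = 1)
  expect_false(js$significant)
  expect_equal(max(abs(js$surrogates - js$observed)), 0)
})

test_that("a strong coupled pair is forward- but not reverse-significant", {
  b <- coupledPairBundle(pHit = 0.35, nTrials = 40, seed = 29)
  fw <- jitterSignificance(b, "S1A_src", "M1_tgt", "GH",
                           condUnits = "M1_other", seed = 4)
  rv <- jitterSignificance(b, "M1_tgt", "S1A_src", "GH", seed = 4)
  expect_true(fw$significant)
  expect_false(rv$significant)
})

test_that("resampling draws round(frac * n) trials and detects gain scaling", {
  expect_equal(round(0.2 * 30), 6)
  sess <- makeGraspSession(
    graspConfig(nUnits = c(M1 = 2, S1A = 2, S1B = 0), nEdges = 1,
                edgeGain = 2.5, edgeTextureScale = 0.8,
                tunedFraction = 0, trialsPerCondition = 30), seed = 41)
  e <- sess$truth$edges
  src <- sess$truth$units$unitId[e$source[1]]
  tgt <- sess$truth$units$unitId[e$target[1]]
  ra <- resampleConditionAnova(sess$bundle, src, tgt, seed = 3)
  expect_equal(nrow(ra$GH$values), 9 * 20)
  ## texture-scaled coupling should surface as a texture effect on CGC
  expect_lt(ra$GH$anova$p[["texture"]], 0.05)
})

test_that("PCA of CGC trajectories reports ordered variance and rank", {
  set.seed(6)
  ## rank-1 synthetic table: every pair's series is a scalar multiple of
  ## one template over 2 conditions x 5 windows
  template <- sin(seq(0, 3, length.out = 10))
  tab <- do.call(rbind, lapply(1:6, function(p) {
    data.frame(source = sprintf("s%d", p), target = "t",
               texture = rep(c("a", "b"), each = 5), load = 500,
               start = rep(1:5, 2), cgc = p * template)
  }))
  pc <- cgcPCA(tab, components = c(1, 2))
  expect_gt(pc$explained[1], 0.999)
  expect_true(all(diff(pc$explained) <= 1e-12))
  expect_lte(sum(pc$explained), 1 + 1e-8)
  expect_error(cgcPCA(tab[tab$source == "s1", ], components = c(3, 4)),
               "fewer pairs")
})
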