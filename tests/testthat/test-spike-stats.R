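test_that("noiseless one-factor structure yields eta^2 of exactly one", {
  a <- anovaEta(c(0, 0, 2, 2, 0, 0, 2, 2),
                texture = rep(c("a", "a", "b", "b"), 2),
                load = rep(c(1, 2), 4))
  expect_equal(unname(a$eta["texture"]), 1)
  expect_equal(unname(a$eta["load"]), 0)
  expect_equal(unname(a$eta["interaction"]), 0)
  expect_false(a$degenerate)
})

test_that("constant responses are flagged degenerate with zero effects", {
  a <- anovaEta(rep(3, 12), texture = rep(c("a", "b"), 6),
                load = rep(c(1, 2), each = 6))
  expect_true(a$degenerate)
  expect_equal(unname(a$eta), c(0, 0, 0))
  expect_equal(unname(a$p), c(1, 1, 1))
})

test_that("eta^2 matches an independent sums-of-squares decomposition", {
  set.seed(42)
  for (i in 1:100) {
    tex <- rep(c("a", "b", "c"), each = 12)
    load <- rep(rep(c(400, 550, 700), each = 4), 3)
    y <- rnorm(36, mean = as.numeric(factor(tex)) * runif(1, 0, 2) +
                 as.numeric(factor(load)) * runif(1, 0, 2))
    a <- anovaEta(y, tex, load)
    expect_equal(unname(a$eta), unname(bruteForceEta(y, tex, load)),
                 tolerance = 1e-10)
  }
})

test_that("eta^2 is invariant to trial order and response scaling", {
  set.seed(1)
  tex <- rep(c("a", "b"), each = 10)
  load <- rep(rep(c(1, 2), each = 5), 2)
  y <- rnorm(20)
  a0 <- anovaEta(y, tex, load)
  perm <- sample(20)
  expect_equal(anovaEta(y[perm], tex[perm], load[perm])$eta, a0$eta)
  expect_equal(anovaEta(3.7 * y, tex, load)$eta, a0$eta)
})

test_that("empty design cells are reported by name", {
  expect_error(anovaEta(rnorm(6), c("a", "a", "a", "b", "b", "b"),
                        c(1, 1, 2, 1, 1, 1)), "empty design cell")
})

test_that("the corrected threshold reproduces the printed value", {
  expect_equal(correctedThreshold(0.05, 3, 23, 5), 0.0036)
  expect_equal(correctedThreshold(0.05, 1, 1, 1), 0.05)
  expect_equal(correctedThreshold(0.05, 2, 10, 5), 0.0125)
})

test_that("the inclusion rule keys on either factor reaching 5 windows", {
  thr <- correctedThreshold()
  n <- length(windowStarts(tuningGrid()))
  pSig <- rep(1, n); pSig[1:5] <- thr / 2
  pAlmost <- rep(1, n); pAlmost[1:4] <- thr / 2
  expect_true(includeUnit(fakeEffectSeries(pSig, rep(1, n)), thr)$included)
  expect_true(includeUnit(fakeEffectSeries(rep(1, n), pSig), thr)$included)
  expect_false(includeUnit(fakeEffectSeries(pAlmost, pAlmost),
                           thr)$included)
})

test_that("peak latencies break ties toward the earlier window", {
  n <- length(windowStarts(tuningGrid()))
  eta <- rep(0.2, n)   # all tied
  s <- fakeEffectSeries(rep(1, n), rep(1, n), etaTex = eta, etaLoad = eta)
  inc <- includeUnit(s, 0.05)
  expect_equal(unname(inc$peakLatency["texture"]), -200)
})

test_that("a tuned generator unit peaks in its designed stage windows", {
  sess <- makeGraspSession(graspConfig(nUnits = c(M1 = 1, S1A = 2,
                                                  S1B = 0),
                                       nEdges = 0, texAmp = 0.8,
                                       loadAmp = 0.8,
                                       trialsPerCondition = 30),
                           seed = 21)
  tu <- sess$truth$units
  uid <- tu$unitId[which.max(abs(tu$alphaTex) + abs(tu$alphaLoad))]
  es <- effectSeries(units2(sess$bundle)[[uid]], trials(sess$bundle))
  tab <- effectTable(es)
  peakTex <- tab$start[which.max(tab$eta_texture)]
  peakLoad <- tab$start[which.max(tab$eta_load)]
  ## texture kernel peaks in the touching stage, load in grasp-and-hold
  expect_true(peakTex >= -150 & peakTex <= 150)
  expect_true(peakLoad >= 250 & peakLoad <= 550)
})

test_that("under the global null the significant fraction matches alpha", {
  set.seed(99)
  tex <- rep(c("a", "b", "c"), each = 12)
  load <- rep(rep(c(1, 2, 3), each = 4), 3)
  p <- replicate(2000, anovaEta(rnorm(36), tex, load)$p[["texture"]])
  frac <- mean(p < 0.05)
  ## 3 binomial SDs around 0.05 at n = 2000
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 2000))
})

test_that("stage comparison is symmetric, directional and null-safe", {
  n <- length(windowStarts(tuningGrid()))
  mk <- function(seed) {
    set.seed(seed)
    eta <- runif(n, 0, 0.3)
    fakeEffectSeries(rep(1, n), rep(1, n), etaTex = eta, etaLoad = eta)
  }
  same <- lapply(1:8, mk)
  res <- stageCompare(same, "T", "T", "texture")
  expect_equal(res$p.value, 1)
  ## early-texture construction: eta_texture concentrated in stage T
  early <- lapply(1:20, function(s) {
    set.seed(s)
    eta <- rep(0.02, n)
    eta[graspflow:::stageWindows(tuningGrid(), stageSpan("T"))] <- runif(5, 0.2, 0.4)
    fakeEffectSeries(rep(1, n), rep(1, n), etaTex = eta)
  })
  res2 <- stageCompare(early, "T", "GH", "texture")
  expect_lt(res2$p.value, 0.01)
  expect_equal(res2$direction, 1)
  res3 <- stageCompare(early, "GH", "T", "texture")
  expect_equal(res3$direction, -1)
  expect_equal(res3$p.value, res2$p.value)
})
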