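test_that("the default grasp session realizes the mirrored 3x3 design", {
  sess <- makeGraspSession(graspConfig(nUnits = c(M1 = 3, S1A = 3,
                                                  S1B = 0), nEdges = 0),
                           seed = 1)
  tr <- trials(sess$bundle)
  expect_equal(nrow(tr), 270)
  cells <- table(tr$texture, tr$load)
  expect_true(all(cells == 30))
  expect_equal(length(unique(tr$block)), 18)
  ## blocks 10..18 mirror blocks 9..1 in condition
  firstHalf <- unique(tr[tr$block <= 9, c("block", "texture", "load")])
  secondHalf <- unique(tr[tr$block > 9, c("block", "texture", "load")])
  expect_equal(firstHalf[order(firstHalf$block), -1],
               secondHalf[order(-secondHalf$block), -1],
               ignore_attr = TRUE)
  expect_error(graspConfig(trialsPerCondition = 20), ">= 25")
})

test_that("the same configuration and seed give bit-identical sessions", {
  cfg <- graspConfig(nUnits = c(M1 = 2, S1A = 2, S1B = 0),
                     trialsPerCondition = 26)
  a <- makeGraspSession(cfg, seed = 5)
  b <- makeGraspSession(cfg, seed = 5)
  expect_identical(trials(a$bundle), trials(b$bundle))
  expect_identical(lapply(units2(a$bundle), spikeTimes),
                   lapply(units2(b$bundle), spikeTimes))
  expect_identical(a$truth, b$truth)
  c <- makeGraspSession(cfg, seed = 6)
  expect_false(identical(spikeTimes(units2(a$bundle)[[1]]),
                         spikeTimes(units2(c$bundle)[[1]])))
})

test_that("zeroed effects produce homogeneous Poisson units", {
  cfg <- graspConfig(nUnits = c(M1 = 3, S1A = 3, S1B = 0), nEdges = 0,
                     tunedFraction = 0, trialsPerCondition = 30)
  sess <- makeGraspSession(cfg, seed = 3)
  expect_true(all(sess$truth$units$alphaTex == 0))
  u <- units2(sess$bundle)[[1]]
  es <- effectSeries(u, trials(sess$bundle))
  ## eta^2 stays at its small-sample noise floor everywhere
  expect_lt(max(effectTable(es)$eta_texture), 0.12)
  ## windowed rates are time-invariant up to sampling error
  wc <- windowCounts(alignSpikes(u, trials(sess$bundle), "touch",
                                 c(-200, 1100)), tuningGrid())
  profile <- colMeans(wc)
  expect_lt(diff(range(profile)) / mean(profile), 0.35)
})

test_that("a single strong edge leaves a cross-correlogram peak at its lag", {
  cfg <- graspConfig(nUnits = c(M1 = 1, S1A = 1, S1B = 0), nEdges = 1,
                     edgeGain = 3, edgeLatency = c(4, 4),
                     tunedFraction = 0, trialsPerCondition = 30)
  sess <- makeGraspSession(cfg, seed = 7)
  e <- sess$truth$edges
  expect_equal(e$latency, 4)
  src <- alignSpikes(units2(sess$bundle)[[e$source[1]]],
                     trials(sess$bundle), "touch", c(0, 1000))
  tgt <- alignSpikes(units2(sess$bundle)[[e$target[1]]],
                     trials(sess$bundle), "touch", c(0, 1000))
  ## correlogram oracle: histogram of pairwise delays, 1 ms bins
  lags <- -10:14
  cc <- numeric(length(lags) - 1)
  for (i in seq_along(src)) {
    if (!length(src[[i]]) || !length(tgt[[i]])) next
    d <- as.vector(outer(tgt[[i]], src[[i]], "-"))
    cc <- cc + hist(d[d > -10 & d < 14], breaks = lags,
                    plot = FALSE)$counts
  }
  peakLag <- lags[which.max(cc)] + 0.5
  expect_true(peakLag >= 4 & peakLag <= 6)  # kernel rises just after 4 ms
  expect_gt(max(cc), 2 * median(cc))
})

test_that("phase-locked response probability follows the configured gain", {
  g <- 0.25
  cfg <- restIcmsConfig(nSites = 1, nChannels = 12, amplitudes = 80,
                        frequencies = 100, plGain = g,
                        categoryProbs = c(pl = 1, npl = 0, inh = 0,
                                          none = 0))
  r <- makeRestIcmsSession(cfg, seed = 4)
  stim <- Filter(function(s) !s@sham, stimTrains(r$bundle))
  pulses <- unlist(lapply(stim, function(s) s@pulseTimes))
  ## per-pulse extra-spike probability = plGain * gainMult, on top of the
  ## baseline probability in 3-9 ms
  shams <- Filter(function(s) s@sham, stimTrains(r$bundle))
  shamPulses <- unlist(lapply(shams, function(s) s@pulseTimes))
  for (row in sample(nrow(r$truth), 4)) {
    ch <- r$truth$channel[row]
    u <- Filter(function(u) u@channel == ch, r$bundle@units)[[1]]
    expected <- min(0.9, r$truth$gainMult[row] * g * 1.5)  # >25 Hz boost
    pStim <- sum(computePTA(u, pulses)$prob)
    pSham <- sum(computePTA(u, shamPulses)$prob)
    expect_lt(abs((pStim - pSham) - expected) / expected, 0.35)
  }
})

test_that("sham trains leave the force and rates unperturbed by design", {
  cfg <- stimConfig(forceCoupling = 0)
  pairs <- list(list(type = "W",
                     assignment = setNames(c(11L, 12L),
                                           cfg$textures)))
  ## zero out all response gains: stimulated and control trials are
  ## statistically exchangeable
  cfg$rest$plGain <- 0
  cfg$rest$nplFactor <- 1
  cfg$rest$inhFactor <- 1
  d2 <- makeGraspIcmsSession(cfg, pairs, seed = 6)
  tr <- trials(d2$bundle)
  f <- graspflow:::forceWindowMeans(d2$bundle, tr, 300, width = 400)
  pv <- wilcox.test(f[!tr$is_control, 1], f[tr$is_control, 1])$p.value
  expect_gt(pv, 0.01)
})

test_that("day-2 blocks hold 60 trials, half stimulated", {
  cfg <- stimConfig()
  pairs <- list(list(type = "C", assignment = setNames(c(11L, 12L),
                                                       cfg$textures)),
                list(type = "D", assignment = setNames(c(12L, 11L),
                                                       cfg$textures)))
  d2 <- makeGraspIcmsSession(cfg, pairs, seed = 2)
  tr <- trials(d2$bundle)
  expect_equal(length(unique(tr$block)), 4)
  counts <- table(tr$block, tr$is_control)
  expect_true(all(counts == 30))
  ## ICMS onset 210 ms (median) after touch, 1 s trains
  stim <- stimTrains(d2$bundle)
  delays <- vapply(which(!tr$is_control), function(i)
    tr$t_stim_on[i] - tr$t_touch[i], numeric(1))
  expect_lt(abs(median(delays) - 0.21), 0.02)
  expect_true(all(vapply(stim, function(s) s@duration, numeric(1)) == 1))
  expect_error(
    makeGraspIcmsSession(cfg, list(list(type = "X",
                                        assignment = setNames(c(1L, 2L),
                                                              cfg$textures))),
                         seed = 1),
    "outside the S1 array")
})

test_that("forward CGC grows with the coupling gain", {
  gains <- c(0.5, 1.5, 3)
  means <- vapply(gains, function(g) {
    vals <- c()
    for (seed in 1:4) {
      cfg <- graspConfig(nUnits = c(M1 = 2, S1A = 2, S1B = 0),
                         nEdges = 1, edgeGain = g, tunedFraction = 0,
                         trialsPerCondition = 26)
      sess <- makeGraspSession(cfg, seed = seed)
      e <- sess$truth$edges
      src <- sess$truth$units$unitId[e$source[1]]
      tgt <- sess$truth$units$unitId[e$target[1]]
      rast <- graspflow:::cgcRasters(sess$bundle, c(tgt, src),
                                     c(-500, 1000))
      for (s in seq(-500, 700, by = 50)) {
        ens <- graspflow:::rastersToEnsemble(rast, c(s, s + 300))
        vals <- c(vals,
                  conditionalGC(multitaperCSD(ens), 1, 2)$scalar)
      }
    }
    mean(vals)   # 4 seeds x 25 windows = 100 estimates per rung
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})
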