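test_that("pulse-aligned rates count only the 3-9 ms window", {
  pulses <- seq(10, 11, by = 0.01)            # 100 Hz train
  spikes <- pulses + 0.005                    # one spike at +5 ms each
  r <- pulseAlignedRates(spikes, pulses)
  expect_equal(r, rep(1 / 0.006, length(pulses)))   # 166.7 Hz
  ## spikes inside the artifact blank are never counted
  rBlank <- pulseAlignedRates(pulses + 0.001, pulses)
  expect_equal(rBlank, rep(0, length(pulses)))
  ## blanking conservation: counted time is span - 3 - 1 ms
  expect_equal(diff(graspflow:::PULSE_WIN_MS), 10 - 3 - 1)
  expect_error(pulseAlignedRates(spikes, seq(10, 11, by = 0.005)),
               "overlap")
})

test_that("pulse-aligned rates of a Poisson unit recover its rate", {
  set.seed(12)
  pulses <- seq(0, 120, by = 0.1)[-1]         # 1200 pulses
  spikes <- sort(runif(20 * 125, 0, 125))     # 20 Hz homogeneous
  r <- pulseAlignedRates(spikes, pulses)
  expect_lt(abs(mean(r) - 20), 3 * sqrt(20 / (length(pulses) * 0.006)))
})

test_that("the phase-locking index is the peak triplet above the median", {
  expect_equal(phaseLockIndex(list(prob = rep(0.02, 12))), 0)
  prob <- rep(0.01, 12); prob[5] <- 0.3
  expect_equal(phaseLockIndex(list(prob = prob)),
               (0.3 + 0.01 + 0.01) / 3 - 0.01, tolerance = 1e-12)
  ## edge peaks use the available neighbors only
  probEdge <- rep(0.01, 12); probEdge[1] <- 0.3
  expect_equal(phaseLockIndex(list(prob = probEdge)),
               (0.3 + 0.01) / 2 - 0.01, tolerance = 1e-12)
  ## invariance under a uniform probability offset
  expect_equal(phaseLockIndex(list(prob = prob + 0.1)),
               phaseLockIndex(list(prob = prob)), tolerance = 1e-12)
})

test_that("the shuffle null flags locked channels and spares silent ones", {
  pulses <- seq(10, 24, by = 0.01)
  ## deterministic spike at +4 ms after every pulse
  locked <- phaseLockNull(pulses + 0.004, pulses, n = 300, seed = 2)
  expect_true(locked$significant)
  ## zero spikes: index 0, not flagged
  none <- phaseLockNull(numeric(), pulses, n = 100, seed = 2)
  expect_equal(none$index, 0)
  expect_false(none$significant)
})

test_that("the phase-lock null holds its false-positive rate", {
  set.seed(77)
  pulses <- seq(0, 14, by = 0.01)[-1]
  flags <- vapply(1:200, function(i) {
    spikes <- sort(runif(rpois(1, 15 * 15), 0, 15))
    phaseLockNull(spikes, pulses, n = 400, seed = i)$significant
  }, logical(1))
  expect_lte(mean(flags), 0.04)               # nominal 1%
})

test_that("channel response classification applies threshold and guard", {
  set.seed(31)
  sham <- rpois(500, 5) / 0.006 / 1000 * 6    # per-pulse rates around 5 Hz
  expect_equal(classifyChannelResponse(sham, sham)$category, "none")
  post <- rpois(500, 15) / 0.006 / 1000 * 6
  expect_equal(classifyChannelResponse(post, sham)$category, "elicited")
  expect_equal(classifyChannelResponse(sham, post)$category, "inhibited")
  ## significantly elevated but below the 2 Hz guard: none
  lowSham <- rbinom(500, 1, 0.002) / 0.006
  lowPost <- rbinom(500, 1, 0.008) / 0.006
  cls <- classifyChannelResponse(lowPost, lowSham)
  expect_equal(cls$category, "none")
})

test_that("rest sessions deliver the designed pulse counts and shams", {
  cfg <- restIcmsConfig(nSites = 2, nChannels = 3, amplitudes = 80,
                        frequencies = 100)
  r <- makeRestIcmsSession(cfg, seed = 3)
  st <- stimTrains(r$bundle)
  stim <- Filter(function(s) !s@sham, st)
  sham <- Filter(function(s) s@sham, st)
  ## 14 repetitions x 1 s at 100 Hz = 1400 pulses per site
  perSite <- table(vapply(stim, function(s) s@channel, integer(1)))
  expect_true(all(perSite == 14))
  expect_equal(sum(lengths(lapply(stim, function(s) s@pulseTimes))),
               2 * 14 * 100)
  expect_true(all(vapply(sham, function(s) s@amplitude, numeric(1)) == 0))
})

test_that("the response map recovers the generated taxonomy", {
  r <- makeRestIcmsSession(restIcmsConfig(nSites = 3, nChannels = 6,
                                          amplitudes = 80,
                                          frequencies = 100), seed = 2)
  rmap <- responseMap(r$bundle, amplitude = 80, frequency = 100,
                      nShuffles = 300)
  m <- merge(rmap, r$truth, by = c("site", "channel"),
             suffixes = c("", ".truth"))
  agree <- mean(m$category == m$category.truth)
  expect_gte(agree, 0.8)
  ## sham-only comparison cannot produce elicitation calls in quantity
  expect_lt(mean(m$category[m$category.truth == "none"] != "none"), 0.3)
})

test_that("response proportions grow with stimulation amplitude", {
  r <- makeRestIcmsSession(restIcmsConfig(nSites = 3, nChannels = 8,
                                          amplitudes = c(20, 50, 80),
                                          frequencies = 100), seed = 8)
  ps <- parameterEffectSummary(r$bundle, "amplitude", nShuffles = 100)
  responding <- aggregate(proportion ~ level, ps$proportions, sum)
  responding <- responding[order(responding$level), ]
  expect_true(responding$proportion[3] >= responding$proportion[1])
  ## elicited magnitudes increase with amplitude for responsive pairs
  magMean <- tapply(ps$magnitudes$magnitude, ps$magnitudes$level, mean)
  expect_true(magMean[length(magMean)] > magMean[1])
})

test_that("phase-locked generator channels are detected with high power", {
  r <- makeRestIcmsSession(restIcmsConfig(nSites = 2, nChannels = 8,
                                          amplitudes = 80,
                                          frequencies = 100,
                                          plGain = 0.3), seed = 13)
  stim <- Filter(function(s) !s@sham, stimTrains(r$bundle))
  hits <- 0; total <- 0
  for (row in which(r$truth$category == "pl")) {
    site <- r$truth$site[row]; ch <- r$truth$channel[row]
    pulses <- unlist(lapply(Filter(function(s) s@channel == site, stim),
                            function(s) s@pulseTimes))
    u <- Filter(function(u) u@channel == ch, r$bundle@units)[[1]]
    pl <- phaseLockNull(u, pulses, n = 300, seed = row)
    total <- total + 1
    hits <- hits + pl$significant
  }
  expect_gte(hits / total, 0.9)
})
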