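## handmade day-2 bundle with prescribed force levels for exact index
## arithmetic: force is `fCtrl` on control trials and `fStim` on
## stimulated trials throughout the post-touch second
toyDay2 <- function(fStim, fCtrl, nEach = 6, rate = 15, seed = 1) {
  set.seed(seed)
  n <- 2 * nEach
  touch <- 2 + (seq_len(n) - 1) * 4
  tr <- data.frame(index = seq_len(n), block = 1L,
                   texture = rep("A", n), load = 500,
                   t_cue = touch - 0.5, t_touch = touch,
                   t_hold_end = touch + 1.5,
                   t_stim_on = touch + 0.21,
                   pair_type = "C",
                   stim_id = NA_integer_,
                   is_control = rep(c(TRUE, FALSE), nEach))
  stimRows <- which(!tr$is_control)
  trains <- lapply(seq_along(stimRows), function(k)
    StimTrain(k, tr$t_stim_on[stimRows[k]], 2L, 80, 100, 1))
  tr$stim_id[stimRows] <- seq_along(stimRows)
  fs <- 100
  dur <- max(tr$t_hold_end) + 2
  fvals <- numeric(round(dur * fs))
  tt <- (seq_along(fvals) - 1) / fs
  for (i in seq_len(n)) {
    lvl <- if (tr$is_control[i]) fCtrl else fStim
    fvals[tt >= tr$t_touch[i] & tt <= tr$t_touch[i] + 1.5] <- lvl
  }
  units <- list(SpikeTrain("M1_c01", 1L, "M1",
                           sort(runif(rpois(1, rate * dur), 0, dur)),
                           sorted = FALSE))
  SessionBundle("toy2", "t",
                data.frame(channel = 1:2, region = c("M1", "S1A")),
                tr, units, force = ForceTrace(fvals, fs, 0),
                stimTrains = trains,
                conditionLevels = list(texture = "A", load = 500))
}

test_that("I_F reproduces exact force ratios and handles equality", {
  b <- toyDay2(fStim = 1.1, fCtrl = 1.0)
  grid <- windowGrid(300, 500, width = 200, step = 100)
  res <- iFSeries(b, 1, grid)
  expect_equal(res$series$iF, rep(0.1, 3), tolerance = 1e-9)
  expect_equal(res$blockMean, 0.1, tolerance = 1e-9)
  bEq <- toyDay2(fStim = 1, fCtrl = 1)
  expect_equal(iFSeries(bEq, 1, grid)$series$iF, rep(0, 3),
               tolerance = 1e-9)
  expect_error(iFSeries(toyBundle(), 1, grid), "stimulated and control")
})

test_that("I_N sits at chance without a stimulation effect", {
  cfg <- stimConfig(forceCoupling = 0)
  cfg$rest$plGain <- 0; cfg$rest$nplFactor <- 1; cfg$rest$inhFactor <- 1
  pairs <- list(list(type = "W",
                     assignment = setNames(c(11L, 12L), cfg$textures)))
  d2 <- makeGraspIcmsSession(cfg, pairs, seed = 61)
  grid <- windowGrid(100, 500, width = 200, step = 200)
  res <- iNSeries(d2$bundle, 1, grid, seed = 1)
  n <- sum(trials(d2$bundle)$block == 1)
  expect_lt(abs(res$blockMean - 0.5), 3 * sqrt(0.25 / n))
})

test_that("I_N detects a strong pair during, but not before, the train", {
  cfg <- stimConfig(taskGainScale = 0.5)   # strong neural intervention
  pairs <- list(list(type = "C",
                     assignment = setNames(c(11L, 12L), cfg$textures)))
  d2 <- makeGraspIcmsSession(cfg, pairs, seed = 62)
  grid <- windowGrid(-400, 600, width = 200, step = 200)
  res <- iNSeries(d2$bundle, 1, grid, seed = 1)
  pre <- res$series$iN[res$series$start <= -300]
  during <- res$series$iN[res$series$start >= 200]
  n <- sum(trials(d2$bundle)$block == 1)
  expect_lt(abs(mean(pre) - 0.5), 3 * sqrt(0.25 / n))
  expect_gt(max(during), 0.5 + 3 * sqrt(0.25 / n))
})

test_that("feature blanking keys on the stimulation schedule only", {
  b <- toyDay2(1, 1)
  tr <- trials(b)
  X1 <- graspflow:::blankedFeatures(b, tr, 0, 200)
  trFlip <- tr
  trFlip$is_control <- !trFlip$is_control     # amplitude labels flipped
  X2 <- graspflow:::blankedFeatures(b, trFlip, 0, 200)
  expect_identical(X1, X2)
  ## counted time inside the train is 60% of each fully covered bin
  expect_equal(graspflow:::countedTime(0, 40), 24)
  expect_equal(graspflow:::countedTime(-240, -200), 40)  # pre-train
})

test_that("I_ACC and bias columns satisfy their defining identities", {
  cfg <- stimConfig()
  exp1 <- makeStimExperiment(cfg, seed = 63)
  pairs <- list(list(type = "C",
                     assignment = setNames(c(11L, 12L), cfg$textures)))
  d2 <- makeGraspIcmsSession(cfg, pairs, seed = 63)
  grid <- windowGrid(0, 200, width = 200, step = 100)
  ia <- iaccSeries(exp1$day1, d2$bundle, grid = grid)
  ok <- !is.na(ia$iacc)
  expect_equal(ia$iacc[ok],
               (ia$accICMS[ok] - ia$accNONE[ok]) / ia$accNONE[ok])
  fb <- forceDecodeBias(exp1$day1, d2$bundle, grid = grid)
  ok <- complete.cases(fb[, c("biasICMS", "biasNONE")])
  expect_equal(fb$biasIndex[ok], fb$biasICMS[ok] - fb$biasNONE[ok])
})

test_that("block-level neural and force indices correlate when coupled", {
  mkBlock <- function(x, noise, seed) {
    set.seed(seed)
    starts <- seq(0, 600, by = 40)
    list(series = data.frame(start = starts,
                             iN = 0.5 + x + rnorm(length(starts), 0,
                                                  noise),
                             iF = 2 * x + rnorm(length(starts), 0,
                                                noise)))
  }
  blocks <- lapply(1:10, function(i) mkBlock((i %% 5) / 20, 0.01, i))
  iNList <- lapply(blocks, function(b)
    list(series = b$series[, c("start", "iN")]))
  iFList <- lapply(blocks, function(b) {
    s <- b$series[, c("start", "iF")]
    names(s) <- c("start", "iF")
    list(series = s)
  })
  res <- inIfCorrelation(iNList, iFList)
  expect_gt(res$r, 0.8)
  expect_lt(res$p, 0.01)
  expect_equal(dim(res$matrix),
               c(length(blocks[[1]]$series$start),
                 length(blocks[[1]]$series$start)))
  ## duplicated blocks have zero variance: error
  dup <- lapply(1:6, function(i) iNList[[1]])
  dupF <- lapply(1:6, function(i) iFList[[1]])
  expect_error(inIfCorrelation(dup, dupF), "zero variance")
  expect_error(inIfCorrelation(iNList[1:3], iFList[1:3]), "at least 5")
})

test_that("the adaptation check is flat without decay and falls with it", {
  cfg <- stimConfig()
  pairs <- list(list(type = "C",
                     assignment = setNames(c(11L, 12L), cfg$textures)),
                list(type = "D",
                     assignment = setNames(c(12L, 11L), cfg$textures)))
  d2 <- makeGraspIcmsSession(cfg, pairs, seed = 64)
  flat <- adaptationCheck(d2$bundle, "force")
  expect_gt(flat$p, 0.05)
  cfgA <- stimConfig(adaptationRate = 0.12)
  d2a <- makeGraspIcmsSession(cfgA, pairs, seed = 64)
  dec <- adaptationCheck(d2a$bundle, "force")
  expect_lt(dec$rho, 0)
  expect_lt(dec$p, 0.05)
  ## single-trial blocks are rejected
  small <- d2$bundle
  small@trials <- small@trials[c(1, which(!small@trials$is_control)[1]), ]
  expect_error(adaptationCheck(small, "force"), "at least 2")
})

test_that("tactile-gated stimulation yields context-dependent responses", {
  contrasts <- list()
  for (seed in 1:6) {
    cfg <- stimConfig(tactileGateSd = 1.2)
    pairs <- list(list(type = "C",
                       assignment = setNames(c(11L, 12L), cfg$textures)),
                  list(type = "D",
                       assignment = setNames(c(12L, 11L), cfg$textures)))
    d2 <- makeGraspIcmsSession(cfg, pairs, seed = seed)
    ix <- interactionTest(d2$bundle)
    contrasts[[seed]] <- ix$contrast
  }
  ct <- do.call(rbind, contrasts)
  expect_gte(nrow(ct), 20)
  expect_lt(wilcox.test(ct$consistent, ct$inconsistent, paired = TRUE,
                        alternative = "greater")$p.value, 0.05)
  ## ungated, gain-stable generator: interaction flags near the nominal
  ## level
  flags <- c()
  for (seed in 1:3) {
    cfg0 <- stimConfig(tactileGateSd = 0, blockGainSd = 0)
    pairs <- list(list(type = "C",
                       assignment = setNames(c(11L, 12L), cfg0$textures)),
                  list(type = "D",
                       assignment = setNames(c(12L, 11L), cfg0$textures)))
    d20 <- makeGraspIcmsSession(cfg0, pairs, seed = seed)
    flags <- c(flags, interactionTest(d20$bundle)$table$flagged)
  }
  expect_lte(mean(flags), 0.05 + 3 * sqrt(0.05 * 0.95 / length(flags)))
})
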