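## ICMS session generators: rest-state parameter mapping and the two-day
## grasping + ICMS experiment. M1 "units" here are threshold-crossing
## multi-unit channels (sorted = FALSE), as in ICMS recordings.

ampScale <- function(amp, cfg) amp / max(cfg$amplitudes, cfg$ampAtFreq)
freqFactor <- function(freq, cfg) ifelse(freq > 25, cfg$freqBoost, 1)

## per-(site,channel) effective effect at given parameters
effectAt <- function(truthRow, amp, freq, cfg) {
  a <- ampScale(amp, cfg) * freqFactor(freq, cfg)
  switch(truthRow$category,
    pl = list(plProb = min(0.9, cfg$plGain * truthRow$gainMult * a),
              mult = 1),
    npl = list(plProb = 0,
               mult = 1 + (cfg$nplFactor - 1) * truthRow$gainMult *
                 ampScale(amp, cfg) * freqFactor(freq, cfg)),
    inh = list(plProb = 0,
               mult = max(0.05, 1 - (1 - cfg$inhFactor) *
                            truthRow$gainMult * ampScale(amp, cfg))),
    list(plProb = 0, mult = 1))
}

## draw the (site, channel) response taxonomy; sites are identified by
## their S1 channel numbers (M1 channels come first in the channel map)
drawResponseTruth <- function(cfg) {
  sites <- cfg$nChannels + seq_len(cfg$nSites)
  grid <- expand.grid(site = sites, channel = seq_len(cfg$nChannels))
  cats <- sample(names(cfg$categoryProbs), nrow(grid), replace = TRUE,
                 prob = cfg$categoryProbs)
  data.frame(site = grid$site, channel = grid$channel, category = cats,
             gainMult = runif(nrow(grid), 0.6, 1.4),
             latency = runif(nrow(grid), 3, 6), stringsAsFactors = FALSE)
}

## Remove spikes falling into the artifact blanks of a pulse train:
## [pulse, pulse + 3 ms) and the last 1 ms before the next pulse.
## `times` must be sorted; pulses form a regular grid.
blankArtifacts <- function(times, pulses, freq) {
  if (!length(times) || !length(pulses)) return(times)
  ipi <- 1 / freq
  lo <- findInterval(min(pulses) - 1e-9, times)
  hi <- findInterval(max(pulses) + ipi + 1e-9, times)
  if (hi <= lo) return(times)
  seg <- times[(lo + 1):hi]
  pi <- findInterval(seg, pulses)
  rel <- seg - pulses[pmax(pi, 1)]
  bad <- pi >= 1 & rel < ipi &
    ((rel >= 0 & rel < 0.003) | (rel >= ipi - 0.001))
  c(times[seq_len(lo)], seg[!bad],
    if (hi < length(times)) times[(hi + 1):length(times)])
}

#' Generate a synthetic rest-state ICMS session
#'
#' Stimulation trains (1 s on, `interTrain` s onset spacing, `reps`
#' repetitions per site x parameter set, plus matched sham trains) are
#' delivered to S1 sites while M1 channels fire as baseline Poisson
#' processes perturbed per the ground-truth response taxonomy. Spikes inside
#' the artifact blanks (first 3 ms after each pulse, last 1 ms before the
#' next) of non-sham trains are removed, as threshold crossing cannot
#' recover them.
#'
#' @param config a [restIcmsConfig()].
#' @param seed integer seed.
#' @return list with `bundle` ([SessionBundle]) and `truth` (response
#'   data.frame: site, channel, category, gainMult, latency).
#' @export
makeRestIcmsSession <- function(config = restIcmsConfig(), seed = 1) {
  withSeed(deriveSeed(seed, "rest-icms"), {
    truth <- drawResponseTruth(config)
    bundle <- makeRestIcmsImpl(config, truth, sprintf("rest-%d", seed))
    list(bundle = bundle, truth = truth)
  })
}

makeRestIcmsImpl <- function(cfg, truth, sessionId) {
  params <- unique(rbind(
    data.frame(amplitude = cfg$amplitudes, frequency = cfg$freqAtAmp),
    data.frame(amplitude = cfg$ampAtFreq, frequency = cfg$frequencies)))
  siteCh <- cfg$nChannels + seq_len(cfg$nSites)  # S1 site channel numbers
  mCh <- seq_len(cfg$nChannels)

  ## train schedule: per site x param set, `reps` stim trains; per param
  ## set, `reps` sham trains for the baseline
  sched <- do.call(rbind, c(
    lapply(siteCh, function(s) do.call(rbind, lapply(seq_len(nrow(params)),
      function(p) data.frame(site = s, amplitude = params$amplitude[p],
                             frequency = params$frequency[p], sham = FALSE,
                             rep = seq_len(cfg$reps))))),
    lapply(seq_len(nrow(params)), function(p)
      data.frame(site = siteCh[1], amplitude = 0,
                 frequency = params$frequency[p], sham = TRUE,
                 rep = seq_len(cfg$reps)))))
  sched <- sched[sample(nrow(sched)), ]
  sched$onset <- 5 + (seq_len(nrow(sched)) - 1) * cfg$interTrain
  dur <- max(sched$onset) + cfg$trainDur + 5

  trains <- lapply(seq_len(nrow(sched)), function(i) {
    StimTrain(i, sched$onset[i], sched$site[i], sched$amplitude[i],
              sched$frequency[i], cfg$trainDur, sham = sched$sham[i])
  })

  base <- exp(runif(cfg$nChannels, log(cfg$baselineRange[1]),
                    log(cfg$baselineRange[2])))
  units <- vector("list", cfg$nChannels)
  stimIdx <- which(!sched$sham)
  for (c in mCh) {
    nb <- rpois(1, base[c] * dur)
    times <- sort(runif(nb, 0, dur))
    drop <- logical(length(times))
    extra <- vector("list", length(stimIdx))
    for (w in seq_along(stimIdx)) {
      i <- stimIdx[w]
      tt <- truth[truth$site == sched$site[i] & truth$channel == c, ]
      eff <- effectAt(tt, sched$amplitude[i], sched$frequency[i], cfg)
      on <- sched$onset[i]; off <- on + cfg$trainDur
      i0 <- findInterval(on, times); i1 <- findInterval(off, times)
      if (eff$mult < 1 && i1 > i0) {            # inhibition: thinning
        idx <- (i0 + 1):i1
        drop[idx] <- drop[idx] | runif(length(idx)) >= eff$mult
      } else if (eff$mult > 1) {                # sustained elevation
        nx <- rpois(1, base[c] * (eff$mult - 1) * cfg$trainDur)
        extra[[w]] <- runif(nx, on, off)
      }
      if (eff$plProb > 0) {                     # phase-locked elicitation
        pulses <- trains[[i]]@pulseTimes
        hit <- runif(length(pulses)) < eff$plProb
        lat <- (tt$latency + rnorm(sum(hit), 0, 0.25)) / 1000
        lat <- pmin(pmax(lat, 0.0032), 0.0088)
        extra[[w]] <- c(extra[[w]], pulses[hit] + lat)
      }
    }
    times <- sort(c(times[!drop], unlist(extra)))
    for (i in stimIdx)                          # artifact blanks
      times <- blankArtifacts(times, trains[[i]]@pulseTimes,
                              sched$frequency[i])
    units[[c]] <- SpikeTrain(sprintf("M1_c%02d", c), c, "M1", times,
                             sorted = FALSE)
  }

  emptyTrials <- data.frame(index = integer(), block = integer(),
                            texture = character(), load = numeric(),
                            t_cue = numeric(), t_touch = numeric(),
                            t_hold_end = numeric())
  SessionBundle(
    sessionId = sessionId, animalId = "synthA",
    regions = data.frame(channel = c(mCh, siteCh),
                         region = c(rep("M1", length(mCh)),
                                    rep("S1A", length(siteCh)))),
    trials = emptyTrials, units = units,
    stimTrains = trains,
    conditionLevels = list(texture = character(), load = numeric()),
    duration = dur)
}

## ---- two-day stimulation experiment ----

## deterministic population shared by day-1, rest and day-2 sessions
drawStimPopulation <- function(config, seed) {
  withSeed(deriveSeed(seed, "stim-pop"), {
    rest <- config$rest
    nCh <- rest$nChannels
    baseM1 <- exp(runif(nCh, log(rest$baselineRange[1]),
                        log(rest$baselineRange[2])))
    tuned <- runif(nCh) < config$tunedFraction
    aTex <- ifelse(tuned, config$texAmp * runif(nCh, 0.6, 1.4) *
                     sample(c(-1, 1), nCh, replace = TRUE), 0)
    baseS1 <- exp(runif(config$nS1, log(rest$baselineRange[1]),
                        log(rest$baselineRange[2])))
    aTexS1 <- config$texAmp * runif(config$nS1, 0.6, 1.4) *
      sample(c(-1, 1), config$nS1, replace = TRUE)
    ## Response truth with spatially structured projections: sites
    ## preferentially excite M1 channels sharing one tactile preference
    ## (and may inhibit the opposite group), so that gap contributions
    ## are sign-consistent; two quiet sites support the weak (W) pair.
    sites <- rest$nChannels + seq_len(rest$nSites)
    pref <- sign(-aTex)            # expected sign of FR(T1) - FR(T2)
    pref[pref == 0] <- sample(c(-1, 1), sum(pref == 0), replace = TRUE)
    nQuiet <- max(1L, rest$nSites %/% 3)
    siteAlign <- c(rep(c(1, -1), length.out = rest$nSites - nQuiet),
                   rep(0, nQuiet))
    rows <- list()
    for (k in seq_len(rest$nSites)) {
      for (c in seq_len(rest$nChannels)) {
        al <- siteAlign[k]
        category <- "none"
        if (al != 0) {
          if (pref[c] == al && runif(1) < 0.75)
            category <- sample(c("pl", "npl"), 1)
          else if (pref[c] == -al && runif(1) < 0.4)
            category <- "inh"
        }
        rows[[length(rows) + 1L]] <- data.frame(
          site = sites[k], channel = c, category = category,
          gainMult = runif(1, 0.8, 1.4), latency = runif(1, 3, 6),
          gate = rnorm(1, 0, config$tactileGateSd),
          stringsAsFactors = FALSE)
      }
    }
    response <- do.call(rbind, rows)
    list(m1 = data.frame(channel = seq_len(nCh), baseline = baseM1,
                         alphaTex = aTex, tuned = tuned),
         s1 = data.frame(channel = nCh + rest$nSites + seq_len(config$nS1),
                         baseline = baseS1, alphaTex = aTexS1),
         response = response)
  })
}

## rest-state effect attenuated by the task-gain scale
taskEffectAt <- function(truthRow, config) {
  eff <- effectAt(truthRow, config$stimAmp, config$stimFreq, config$rest)
  g <- config$taskGainScale
  list(plProb = eff$plProb * g, mult = 1 + (eff$mult - 1) * g)
}

## net signed relative M1 rate modulation of stimulating `site`
netModulation <- function(pop, site, config) {
  rows <- pop$response[pop$response$site == site, ]
  rows <- rows[order(rows$channel), ]
  b <- pop$m1$baseline
  d <- numeric(nrow(rows))
  for (i in seq_len(nrow(rows))) {
    eff <- taskEffectAt(rows[i, ], config)
    d[i] <- b[rows$channel[i]] * (eff$mult - 1) + eff$plProb * config$stimFreq
  }
  sum(d) / sum(b)
}

## sustained task tuning kernel: differences persist from touch through hold
taskKernel <- function(tMs) {
  1 / (1 + exp(-(tMs - 50) / 40)) / (1 + exp((tMs - 1100) / 80))
}

## core task-session generator shared by day 1 (no stim) and day 2
genTaskSession <- function(pop, config, trialsDf, stimPlan, sessionId,
                           blockGain = NULL) {
  rest <- config$rest
  spanMs <- c(-700, 1800)
  nbins <- diff(spanMs)
  tMs <- spanMs[1] + seq_len(nbins) - 0.5
  gTask <- taskKernel(tMs)
  sTex <- levelScore(trialsDf$texture, config$textures)
  n <- nrow(trialsDf)
  hasStim <- !is.null(stimPlan)
  if (is.null(blockGain))
    blockGain <- setNames(rep(1, length(unique(trialsDf$block))),
                          unique(trialsDf$block))

  trains <- list(); stimId <- rep(NA_integer_, n)
  if (hasStim) {
    k <- 0L
    for (j in seq_len(n)) {
      if (is.na(stimPlan$site[j])) next
      k <- k + 1L
      trains[[k]] <- StimTrain(
        k, trialsDf$t_stim_on[j], stimPlan$site[j], config$stimAmp,
        config$stimFreq, 1)
      stimId[j] <- k
    }
  }

  sampleUnit <- function(baseline, alphaTex, channel, region, unitId,
                         sorted) {
    logL <- matrix(log(baseline), nbins, n) +
      outer(gTask, sTex) * alphaTex
    plSpikes <- vector("list", n)
    if (hasStim && region == "M1") {
      for (j in which(!is.na(stimPlan$site[seq_len(n)]))) {
        tt <- pop$response[pop$response$site == stimPlan$site[j] &
                             pop$response$channel == channel, ]
        if (!nrow(tt)) next
        eff <- taskEffectAt(tt, config)
        g <- blockGain[[as.character(trialsDf$block[j])]]
        gate <- if (!is.null(tt$gate)) max(0, 1 + tt$gate * sTex[j]) else 1
        g <- g * gate * stimPlan$decay[j]
        onMs <- (trialsDf$t_stim_on[j] - trialsDf$t_touch[j]) * 1000
        sel <- tMs >= onMs & tMs < onMs + 1000
        mult <- 1 + (eff$mult - 1) * g
        if (mult != 1) logL[sel, j] <- logL[sel, j] + log(max(mult, 0.05))
        if (eff$plProb > 0) {
          pulses <- trains[[stimId[j]]]@pulseTimes
          hit <- runif(length(pulses)) < min(0.9, eff$plProb * g)
          lat <- pmin(pmax((tt$latency +
                              rnorm(sum(hit), 0, 0.25)) / 1000,
                           0.0032), 0.0088)
          plSpikes[[j]] <- pulses[hit] + lat
        }
      }
    }
    bins <- sampleSpikeBins(logL)
    times <- unlist(lapply(seq_len(n), function(j) {
      b <- bins[[j]]
      tj <- if (length(b))
        trialsDf$t_touch[j] + (spanMs[1] + b - 1 + runif(length(b))) / 1000
      else numeric()
      tj <- c(tj, plSpikes[[j]])
      if (hasStim && !is.na(stimId[j]))
        tj <- blankArtifacts(sort(tj), trains[[stimId[j]]]@pulseTimes,
                             config$stimFreq)
      tj
    }))
    SpikeTrain(unitId, channel, region, sort(times), sorted = sorted)
  }

  units <- c(
    lapply(seq_len(nrow(pop$m1)), function(i)
      sampleUnit(pop$m1$baseline[i], pop$m1$alphaTex[i], pop$m1$channel[i],
                 "M1", sprintf("M1_c%02d", pop$m1$channel[i]), FALSE)),
    lapply(seq_len(nrow(pop$s1)), function(i)
      sampleUnit(pop$s1$baseline[i], pop$s1$alphaTex[i], pop$s1$channel[i],
                 "S1A", sprintf("S1_c%02d", pop$s1$channel[i]), FALSE)))

  ## force: plateau lower for the rougher texture (less grip demand)
  fs <- 100
  dur <- max(trialsDf$t_hold_end) + 2
  fvals <- rnorm(round(dur * fs), 0, 0.02)
  tf <- (seq_along(fvals) - 1) / fs
  rough01 <- (sTex + 1) / 2
  plateau <- 1 + 0.3 * (1 - rough01)
  for (j in seq_len(n)) {
    sel <- which(tf >= trialsDf$t_touch[j] - 0.3 &
                   tf <= trialsDf$t_hold_end[j] + 0.3)
    f <- forceProfile(tf[sel] - trialsDf$t_touch[j], plateau[j], 0.04)
    if (hasStim && !is.na(stimId[j]) && config$forceCoupling != 0) {
      nm <- netModulation(pop, stimPlan$site[j], config) *
        blockGain[[as.character(trialsDf$block[j])]] * stimPlan$decay[j]
      tRelOn <- tf[sel] - trialsDf$t_stim_on[j]
      ramp <- 1 / (1 + exp(-(tRelOn - config$forceLag / 1000) / 0.05)) /
        (1 + exp((tRelOn - 1.3) / 0.1))
      f <- f * (1 + config$forceCoupling * nm * ramp)
    }
    fvals[sel] <- f
  }

  trialsDf$stim_id <- stimId
  trialsDf$is_control <- is.na(stimId)
  rest <- config$rest
  SessionBundle(
    sessionId = sessionId, animalId = "synthA",
    regions = data.frame(
      channel = c(pop$m1$channel, rest$nChannels + seq_len(rest$nSites),
                  pop$s1$channel),
      region = c(rep("M1", nrow(pop$m1)), rep("S1A", rest$nSites),
                 rep("S1A", nrow(pop$s1)))),
    trials = trialsDf, units = units,
    force = ForceTrace(fvals, fs, 0), stimTrains = trains,
    conditionLevels = list(texture = config$textures,
                           load = as.numeric(config$load)),
    duration = dur)
}

stimTrialTable <- function(config, blocks, trialsPerBlock, withStim) {
  n <- length(blocks) * trialsPerBlock
  touch <- 2 + (seq_len(n) - 1) * 3.8
  df <- data.frame(
    index = seq_len(n), block = rep(blocks, each = trialsPerBlock),
    texture = NA_character_, load = config$load,
    t_cue = touch - 0.5, t_touch = touch, t_hold_end = touch + 1.5,
    stringsAsFactors = FALSE)
  df$t_stim_on <- df$t_touch + config$stimDelay +
    runif(n, -config$stimDelayJitter, config$stimDelayJitter)
  df
}

#' Generate the day-1 sessions of a stimulation experiment
#'
#' Returns the day-1 grasping session (two tactile levels, no stimulation),
#' the matching rest-state ICMS mapping session, and the shared population
#' ground truth. [makeGraspIcmsSession()] called with the same `config` and
#' `seed` generates day-2 sessions for the same population, so the response
#' map estimated from the rest session applies to day 2.
#'
#' @param config a [stimConfig()].
#' @param seed integer seed.
#' @return list with `day1` ([SessionBundle]), `rest` ([SessionBundle]) and
#'   `truth` (population + response ground truth).
#' @export
makeStimExperiment <- function(config = stimConfig(), seed = 1) {
  pop <- drawStimPopulation(config, seed)
  rest <- withSeed(deriveSeed(seed, "stim-rest"),
                   makeRestIcmsImpl(config$rest, pop$response,
                                    sprintf("rest-%d", seed)))
  day1 <- withSeed(deriveSeed(seed, "stim-day1"), {
    tpl <- config$day1TrialsPerLevel
    perBlock <- ceiling(tpl / 2)
    df <- stimTrialTable(config, blocks = 1:4, trialsPerBlock = perBlock,
                         withStim = FALSE)
    lv <- c(config$textures, rev(config$textures))  # mirrored blocks
    df$texture <- lv[df$block]
    genTaskSession(pop, config, df, stimPlan = NULL,
                   sessionId = sprintf("day1-%d", seed))
  })
  list(day1 = day1, rest = rest, truth = pop)
}

#' Generate a day-2 grasping + ICMS session
#'
#' Four blocks cross the two tactile levels with the two stimulation pairs;
#' each block holds `blockTrials` trials, half stimulated (ICMS triggered
#' ~210 ms after touch, 1 s train) in pseudo-random order. Stimulated S1
#' sites act on M1 channels per the rest-state ground truth, and the grip
#' force deviates from `forceLag` ms after onset in proportion to the net
#' signed M1 modulation.
#'
#' @param config a [stimConfig()].
#' @param pairs list of stimulation-pair designs; each element needs fields
#'   `type` (label) and `assignment` (named integer: tactile level ->
#'   S1 site index), as produced by [selectPairs()] / [selectWeakPair()].
#' @param seed integer seed (same seed as the matching
#'   [makeStimExperiment()] call).
#' @return list with `bundle` ([SessionBundle]; trial table gains columns
#'   `pair_type`, `stim_id`, `is_control`, `t_stim_on`) and `truth`.
#' @export
makeGraspIcmsSession <- function(config = stimConfig(), pairs, seed = 1) {
  pop <- drawStimPopulation(config, seed)
  sites <- unlist(lapply(pairs, function(p) p$assignment))
  siteCh <- config$rest$nChannels + seq_len(config$rest$nSites)
  if (any(!sites %in% siteCh))
    stop("pair assignment references a site outside the S1 array")
  withSeed(deriveSeed(seed, "stim-day2",
                      paste(vapply(pairs, function(p) p$type, ""),
                            collapse = "")), {
    plan <- expand.grid(level = config$textures,
                        pair = seq_along(pairs), stringsAsFactors = FALSE)
    half <- config$blockTrials / 2
    df <- stimTrialTable(config, blocks = seq_len(nrow(plan)),
                         trialsPerBlock = config$blockTrials,
                         withStim = TRUE)
    df$texture <- plan$level[df$block]
    df$pair_type <- vapply(pairs[plan$pair[df$block]],
                           function(p) p$type, "")
    site <- rep(NA_integer_, nrow(df))
    decay <- rep(1, nrow(df))
    for (b in seq_len(nrow(plan))) {
      rows <- which(df$block == b)
      stimRows <- sort(sample(rows, half))
      site[stimRows] <-
        pairs[[plan$pair[b]]]$assignment[[plan$level[b]]]
      decay[stimRows] <- exp(-config$adaptationRate *
                               (seq_along(stimRows) - 1))
    }
    blockGain <- setNames(exp(rnorm(nrow(plan), 0, config$blockGainSd)),
                          as.character(seq_len(nrow(plan))))
    bundle <- genTaskSession(pop, config, df,
                             stimPlan = data.frame(site = site,
                                                   decay = decay),
                             sessionId = sprintf("day2-%d", seed),
                             blockGain = blockGain)
    list(bundle = bundle, truth = pop, blockGain = blockGain)
  })
}
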