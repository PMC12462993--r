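## Grasp-session generator. One RNG stream per session is derived from the
## master seed via deriveSeed(seed, "grasp", ...).

## Temporal tuning kernels (unit peak), t in ms relative to touch.
gaussKernel <- function(t, center, width) exp(-0.5 * ((t - center) / width)^2)

## Alpha-function coupling kernel on the 1 ms grid: zero before `latency`,
## peak 1 at latency + tau.
alphaKernel <- function(latency, tau = 1.5, span = 15) {
  t <- seq_len(span)  # ms after source spike
  u <- (t - latency) / tau
  k <- ifelse(u > 0, u * exp(1 - u), 0)
  k / max(k)
}

## Condition scores centered at 0: levels -> -1..1 (ordinal).
levelScore <- function(x, levels) {
  i <- match(x, levels)
  if (length(levels) == 1L) return(rep(0, length(x)))
  2 * (i - 1) / (length(levels) - 1) - 1
}

## Bernoulli sampling of a discretized conditional-Poisson unit.
## logLambda: nbins x ntrials matrix of log-rates (Hz). Returns a list of
## per-trial spike bin indices.
sampleSpikeBins <- function(logLambda, ceiling = log(200), dt = 0.001) {
  logLambda[logLambda > ceiling] <- ceiling
  p <- 1 - exp(-exp(logLambda) * dt)
  u <- matrix(runif(length(p)), nrow(p), ncol(p))
  hits <- u < p
  lapply(seq_len(ncol(p)), function(j) which(hits[, j]))
}

## Build the mirrored block structure: first nCond blocks are the condition
## cells in a seeded order, the remaining nCond blocks repeat them in
## reverse order; each block carries trialsPerCondition / 2 trials.
blockPlan <- function(textures, loads, trialsPerCondition) {
  cells <- expand.grid(texture = textures, load = loads,
                       stringsAsFactors = FALSE)
  ord <- sample(nrow(cells))
  seqBlocks <- c(ord, rev(ord))
  nFirst <- ceiling(trialsPerCondition / 2)
  nSecond <- trialsPerCondition - nFirst
  counts <- c(rep(nFirst, nrow(cells)), rep(nSecond, nrow(cells)))
  data.frame(block = seq_along(seqBlocks),
             texture = cells$texture[seqBlocks],
             load = cells$load[seqBlocks],
             nTrials = counts)
}

## Synthesize the condition-dependent force profile on the force sampling
## grid of one trial (relative seconds to touch).
forceProfile <- function(tRel, plateau, noiseSd) {
  rise <- 1 / (1 + exp(-(tRel - 0.15) / 0.06))
  release <- 1 / (1 + exp((tRel - 1.35) / 0.08))
  f <- plateau * rise * release
  f + rnorm(length(f), 0, noiseSd)
}

#' Generate a synthetic grasp session
#'
#' Produces a [SessionBundle] with the mirrored-block 3x3 texture x load
#' design (2 x nine-condition blocks, about `trialsPerCondition` trials per
#' cell), tactile-tuned conditionally-Poisson spike trains with early
#' texture and late load latencies, directed S1 -> M1 coupling through
#' short-latency alpha kernels, and a grip-force trace with load-ordered
#' plateaus. The returned ground truth registers every tuning amplitude and
#' coupling edge for parameter-recovery tests.
#'
#' @param config a [graspConfig()].
#' @param seed integer seed; the same `(config, seed)` yields a
#'   bit-identical session.
#' @return list with elements `bundle` ([SessionBundle]) and `truth` (list
#'   with `units` and `edges` data frames).
#' @examples
#' sess <- makeGraspSession(graspConfig(nUnits = c(M1 = 3, S1A = 3, S1B = 0),
#'                                      trialsPerCondition = 26), seed = 1)
#' sess$bundle
#' @export
makeGraspSession <- function(config = graspConfig(), seed = 1) {
  validateGraspConfig(config)
  withSeed(deriveSeed(seed, "grasp"), {
    makeGraspSessionImpl(config, sprintf("grasp-%d", seed))
  })
}

makeGraspSessionImpl <- function(config, sessionId,
                                 spanMs = c(-700, 1600)) {
  plan <- blockPlan(config$textures, config$loads,
                    config$trialsPerCondition)
  trialsPerSlot <- 3.5  # seconds between consecutive touches
  n <- sum(plan$nTrials)
  touch <- 2 + (seq_len(n) - 1) * trialsPerSlot
  tr <- data.frame(
    index = seq_len(n),
    block = rep(plan$block, plan$nTrials),
    texture = rep(plan$texture, plan$nTrials),
    load = rep(plan$load, plan$nTrials),
    t_cue = touch - 0.5, t_touch = touch, t_hold_end = touch + 1.5,
    stringsAsFactors = FALSE)

  regions <- rep(names(config$nUnits), config$nUnits)
  nu <- length(regions)
  channels <- seq_len(nu)
  unitIds <- sprintf("%s_u%02d", regions, channels)

  base <- exp(runif(nu, log(config$baselineRange[1]),
                    log(config$baselineRange[2])))
  tuned <- runif(nu) < config$tunedFraction
  sgn <- function(k) sample(c(-1, 1), k, replace = TRUE)
  aTex <- ifelse(tuned, config$texAmp * runif(nu, 0.6, 1.4) * sgn(nu), 0)
  aLoad <- ifelse(tuned, config$loadAmp * runif(nu, 0.6, 1.4) * sgn(nu), 0)
  aInt <- ifelse(tuned & regions == "M1",
                 config$intAmp * runif(nu, 0.5, 1.5) * sgn(nu), 0)

  ## directed edges: forward S1 -> M1, optional reverse M1 -> S1
  edges <- data.frame(source = integer(), target = integer(),
                      latency = numeric(), gain = numeric(),
                      direction = character())
  s1 <- which(regions %in% c("S1A", "S1B"))
  m1 <- which(regions == "M1")
  if (config$nEdges > 0 && length(s1) && length(m1)) {
    src <- sample(s1, config$nEdges, replace = config$nEdges > length(s1))
    tgt <- sample(m1, config$nEdges, replace = config$nEdges > length(m1))
    edges <- rbind(edges, data.frame(
      source = src, target = tgt,
      latency = runif(config$nEdges, config$edgeLatency[1],
                      config$edgeLatency[2]),
      gain = config$edgeGain * runif(config$nEdges, 0.8, 1.2),
      direction = "S1->M1"))
  }
  if (config$reverseEdges > 0 && length(s1) && length(m1)) {
    edges <- rbind(edges, data.frame(
      source = sample(m1, config$reverseEdges, replace = TRUE),
      target = sample(s1, config$reverseEdges, replace = TRUE),
      latency = runif(config$reverseEdges, config$edgeLatency[1],
                      config$edgeLatency[2]),
      gain = config$edgeGain * runif(config$reverseEdges, 0.8, 1.2),
      direction = "M1->S1"))
  }

  nbins <- diff(spanMs)
  tMs <- spanMs[1] + seq_len(nbins) - 0.5
  gTex <- gaussKernel(tMs, 50, 60)    # peaks inside -50..150 ms
  gLoad <- gaussKernel(tMs, 450, 80)  # peaks inside 350..550 ms
  gInt <- gaussKernel(tMs, 300, 80)
  sTex <- levelScore(tr$texture, config$textures)
  sLoad <- levelScore(tr$load, config$loads)

  ## generation order: units without incoming edges first
  order <- c(setdiff(seq_len(nu), edges$target), unique(edges$target))
  spikeBins <- vector("list", nu)
  for (u in order) {
    logL <- matrix(log(base[u]), nbins, n)
    if (aTex[u] != 0)
      logL <- logL + outer(gTex, sTex) * aTex[u]
    if (aLoad[u] != 0)
      logL <- logL + outer(gLoad, sLoad) * aLoad[u]
    if (aInt[u] != 0)
      logL <- logL + outer(gInt, sTex * sLoad) * aInt[u]
    ein <- edges[edges$target == u, , drop = FALSE]
    if (nrow(ein)) {
      for (e in seq_len(nrow(ein))) {
        ker <- alphaKernel(ein$latency[e])
        gainTrial <- ein$gain[e] *
          (1 + config$edgeTextureScale * sTex)
        src <- spikeBins[[ein$source[e]]]
        for (j in seq_len(n)) {
          sb <- src[[j]]
          if (!length(sb)) next
          contrib <- numeric(nbins)
          for (b in sb) {
            hi <- min(nbins, b + length(ker))
            if (hi > b)
              contrib[(b + 1):hi] <- contrib[(b + 1):hi] +
                ker[seq_len(hi - b)]
          }
          logL[, j] <- logL[, j] + gainTrial[j] * contrib
        }
      }
    }
    spikeBins[[u]] <- sampleSpikeBins(logL, config$logRateCeiling)
  }

  units <- vector("list", nu)
  for (u in seq_len(nu)) {
    times <- unlist(lapply(seq_len(n), function(j) {
      b <- spikeBins[[u]][[j]]
      if (!length(b)) return(numeric())
      tr$t_touch[j] + (spanMs[1] + b - 1 + runif(length(b))) / 1000
    }))
    units[[u]] <- SpikeTrain(unitIds[u], channels[u], regions[u],
                             sort(times), sorted = TRUE)
  }

  ## force trace: one continuous session trace
  fs <- config$forceSampleRate
  dur <- max(tr$t_hold_end) + 2
  fvals <- rnorm(round(dur * fs), 0, config$forceNoiseSd / 2)
  tf <- (seq_along(fvals) - 1) / fs
  plateau <- config$forcePlateau +
    config$forceLoadGain * (levelScore(tr$load, config$loads) + 1) / 2
  for (j in seq_len(n)) {
    sel <- which(tf >= tr$t_touch[j] - 0.3 & tf <= tr$t_hold_end[j] + 0.3)
    fvals[sel] <- forceProfile(tf[sel] - tr$t_touch[j], plateau[j],
                               config$forceNoiseSd)
  }

  bundle <- SessionBundle(
    sessionId = sessionId, animalId = "synthA",
    regions = data.frame(channel = channels, region = regions),
    trials = tr, units = units,
    force = ForceTrace(fvals, fs, 0),
    conditionLevels = list(texture = config$textures,
                           load = as.numeric(config$loads)),
    duration = dur)
  truth <- list(
    units = data.frame(unitId = unitIds, region = regions, channel = channels,
                       baseline = base, alphaTex = aTex, alphaLoad = aLoad,
                       alphaInt = aInt, tuned = tuned,
                       stringsAsFactors = FALSE),
    edges = edges)
  list(bundle = bundle, truth = truth)
}
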