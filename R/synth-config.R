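## Generator configurations. Defaults encode the study conditions: a 3x3
## texture x load design with ~30 trials per cell in 18 mirrored blocks,
## rest-state ICMS trains of 1 s on / 3 s off with 14 repetitions per
## parameter set, and day-2 blocks of 60 trials evenly split between
## stimulated and control trials with ICMS triggered 210 ms after touch.

#' Configuration of the grasp-session generator
#'
#' Units are discretized conditionally-Poisson processes on a 1 ms grid:
#' per-bin spike probability `1 - exp(-lambda * dt)` with
#' `log lambda = log(baseline) + aTex * sTex * gTex(t) + aLoad * sLoad *
#' gLoad(t) + aInt * sTex * sLoad * gInt(t) + sum(edges) gain *
#' (kernel %*% source spikes)`, where `sTex`, `sLoad` are centered condition
#' scores and `gTex`/`gLoad` are Gaussian temporal kernels peaking in the
#' touching (-50..150 ms) and grasping-and-holding (350..550 ms) stages.
#' Directed coupling uses alpha-function kernels with 3-6 ms latency,
#' mirroring phase-locked cortico-cortical latencies.
#'
#' @param trialsPerCondition trials per condition cell (>= 25).
#' @param textures texture labels ordered by increasing roughness.
#' @param loads load levels in grams.
#' @param nUnits named vector: units per region.
#' @param baselineRange range (Hz) of per-unit baseline rates (log-uniform).
#' @param tunedFraction fraction of units carrying tactile tuning.
#' @param texAmp,loadAmp,intAmp log-rate tuning amplitudes (texture, load,
#'   interaction; interaction applies to M1 units only).
#' @param nEdges number of directed S1 -> M1 coupling edges.
#' @param edgeGain log-rate gain of each coupling kernel at its peak.
#' @param edgeLatency range (ms) of coupling latencies.
#' @param edgeTextureScale if nonzero, edge gains scale multiplicatively
#'   with the texture score (`gain * (1 + scale * sTex)`), making coupling
#'   condition-dependent.
#' @param reverseEdges number of reverse M1 -> S1 edges (default 0).
#' @param logRateCeiling clip on log-rate (Hz scale) to avoid pathological
#'   bins.
#' @param forcePlateau base force plateau (arbitrary units).
#' @param forceLoadGain plateau increment per load score unit (heavier load
#'   means higher plateau).
#' @param forceNoiseSd force noise SD (a.u.).
#' @param forceSampleRate force sampling rate (Hz).
#' @return a list of class `graspConfig`.
#' @export
graspConfig <- function(trialsPerCondition = 30,
                        textures = c("P7000", "P400", "P36"),
                        loads = c(400, 550, 700),
                        nUnits = c(M1 = 10, S1A = 10, S1B = 4),
                        baselineRange = c(5, 25),
                        tunedFraction = 0.7,
                        texAmp = 0.55, loadAmp = 0.55, intAmp = 0.18,
                        nEdges = 6, edgeGain = 1.6,
                        edgeLatency = c(3, 6), edgeTextureScale = 0,
                        reverseEdges = 0,
                        logRateCeiling = log(200),
                        forcePlateau = 1, forceLoadGain = 0.3,
                        forceNoiseSd = 0.04, forceSampleRate = 100) {
  cfg <- list(trialsPerCondition = trialsPerCondition, textures = textures,
              loads = loads, nUnits = nUnits, baselineRange = baselineRange,
              tunedFraction = tunedFraction, texAmp = texAmp,
              loadAmp = loadAmp, intAmp = intAmp, nEdges = nEdges,
              edgeGain = edgeGain, edgeLatency = edgeLatency,
              edgeTextureScale = edgeTextureScale,
              reverseEdges = reverseEdges,
              logRateCeiling = logRateCeiling,
              forcePlateau = forcePlateau, forceLoadGain = forceLoadGain,
              forceNoiseSd = forceNoiseSd,
              forceSampleRate = forceSampleRate)
  class(cfg) <- "graspConfig"
  validateGraspConfig(cfg)
  cfg
}

validateGraspConfig <- function(cfg) {
  if (cfg$trialsPerCondition < 25)
    stop("trialsPerCondition must be >= 25")
  if (any(cfg$baselineRange <= 0)) stop("baseline rates must be positive")
  if (cfg$edgeGain < 0 || cfg$nEdges < 0) stop("coupling spec invalid")
  invisible(TRUE)
}

#' Configuration of the rest-state ICMS generator
#'
#' Trains last `trainDur` seconds with `interTrain` seconds between onsets
#' of consecutive trains; every site x parameter set is repeated `reps`
#' times, and matched sham trains (amplitude 0) provide the baseline.
#' Per (site, channel) responses follow the ground-truth taxonomy:
#' phase-locked excitation adds a transient spike 3-6 ms after each pulse
#' with probability scaling with amplitude (and, above 25 Hz, frequency);
#' non-phase-locked excitation elevates the rate throughout the train;
#' inhibition multiplicatively suppresses it.
#'
#' @param nSites number of stimulated S1 sites.
#' @param nChannels number of recorded M1 channels.
#' @param amplitudes amplitude ladder (uA), tested at `freqAtAmp` Hz.
#' @param freqAtAmp frequency used for the amplitude ladder (Hz).
#' @param frequencies frequency ladder (Hz), tested at `ampAtFreq` uA.
#' @param ampAtFreq amplitude used for the frequency ladder (uA).
#' @param reps repetitions per site x parameter set.
#' @param trainDur,interTrain train duration and onset-to-onset spacing (s).
#' @param baselineRange M1 baseline rate range (Hz).
#' @param categoryProbs probabilities of the response taxonomy per
#'   (site, channel): phase-locked, non-phase-locked, inhibition, none.
#' @param plGain per-pulse extra-spike probability of a phase-locked link at
#'   the maximum amplitude.
#' @param nplFactor rate multiplier of a non-phase-locked link at maximum
#'   amplitude.
#' @param inhFactor rate multiplier of an inhibited channel at maximum
#'   amplitude (< 1).
#' @param freqBoost gain multiplier applied above 25 Hz.
#' @return a list of class `restIcmsConfig`.
#' @export
restIcmsConfig <- function(nSites = 6, nChannels = 10,
                           amplitudes = c(20, 50, 80), freqAtAmp = 100,
                           frequencies = c(10, 25, 50, 100), ampAtFreq = 80,
                           reps = 14, trainDur = 1, interTrain = 4,
                           baselineRange = c(6, 20),
                           categoryProbs = c(pl = 0.2, npl = 0.25,
                                             inh = 0.25, none = 0.3),
                           plGain = 0.3, nplFactor = 1.9, inhFactor = 0.4,
                           freqBoost = 1.5) {
  cfg <- list(nSites = nSites, nChannels = nChannels,
              amplitudes = amplitudes, freqAtAmp = freqAtAmp,
              frequencies = frequencies, ampAtFreq = ampAtFreq, reps = reps,
              trainDur = trainDur, interTrain = interTrain,
              baselineRange = baselineRange, categoryProbs = categoryProbs,
              plGain = plGain, nplFactor = nplFactor, inhFactor = inhFactor,
              freqBoost = freqBoost)
  class(cfg) <- "restIcmsConfig"
  if (!length(cfg$amplitudes) || !length(cfg$frequencies))
    stop("amplitude/frequency level lists must be nonempty")
  cfg
}

#' Configuration of the two-day stimulation experiment generator
#'
#' Day 1: grasping under two tactile levels without stimulation (for
#' decoder training and channel ranking) plus a rest-state ICMS session at
#' the day-2 stimulation parameters (for the response map). Day 2: four
#' blocks crossing the two tactile levels with a stimulation pair; each
#' block holds `blockTrials` trials, evenly split between stimulated and
#' control trials in pseudo-random order; ICMS is triggered by touch with a
#' median `stimDelay` delay and lasts 1 s. The ICMS effect on each M1
#' channel equals its rest-state response gain superposed on task activity,
#' and the force trace deviates from `forceLag` ms after train onset with
#' magnitude proportional to the net signed M1 rate modulation, which ties
#' the neural index to the force index by construction.
#'
#' @param textures the two tactile levels (texture labels).
#' @param load the single load used (grams).
#' @param day1TrialsPerLevel day-1 trials per tactile level.
#' @param blockTrials day-2 trials per block (half stimulated).
#' @param stimDelay median stimulation delay after touch (s).
#' @param stimDelayJitter half-range of the (uniform) delay jitter (s).
#' @param stimFreq,stimAmp day-2 train frequency (Hz) and amplitude (uA).
#' @param tunedFraction fraction of tactile-tuned M1 channels.
#' @param texAmp log-rate texture tuning amplitude of tuned channels.
#' @param taskGainScale scaling of the rest-state response gains when
#'   superposed on task activity (stimulation effects during active
#'   behavior are perturbative, not dominant).
#' @param tactileGateSd SD of the per-(site, channel) tactile gate: the
#'   stimulation effect is scaled by `1 + gate * sTex` for the trial's
#'   tactile score, making pulse-evoked responses depend on the tactile
#'   context (0 disables gating).
#' @param adaptationRate per-trial exponential decay rate of the
#'   stimulation gain across a block's stimulated trials (0 = no
#'   short-term adaptation).
#' @param forceCoupling proportionality constant between net signed M1 rate
#'   modulation and relative force deviation (0 disables behavioral
#'   coupling).
#' @param forceLag latency of the force deviation after train onset (ms).
#' @param blockGainSd SD of the per-block log-normal gain jitter shared by
#'   neural and force effects (drives block-level neural-behavioral
#'   correlation).
#' @param rest a [restIcmsConfig()] for the day-1 rest-state mapping
#'   session (single amplitude/frequency by default).
#' @param nS1 number of S1 units recorded on the neighboring array.
#' @return a list of class `stimConfig`.
#' @export
stimConfig <- function(textures = c("P7000", "P400"), load = 550,
                       day1TrialsPerLevel = 50, blockTrials = 60,
                       stimDelay = 0.21, stimDelayJitter = 0.03,
                       stimFreq = 100, stimAmp = 80,
                       tunedFraction = 0.75, texAmp = 0.4,
                       taskGainScale = 0.1, tactileGateSd = 0.4,
                       adaptationRate = 0,
                       forceCoupling = 0.6, forceLag = 300,
                       blockGainSd = 0.25,
                       rest = restIcmsConfig(amplitudes = 80,
                                             frequencies = 100,
                                             nSites = 6, nChannels = 10),
                       nS1 = 6) {
  cfg <- list(textures = textures, load = load,
              day1TrialsPerLevel = day1TrialsPerLevel,
              blockTrials = blockTrials, stimDelay = stimDelay,
              stimDelayJitter = stimDelayJitter, stimFreq = stimFreq,
              stimAmp = stimAmp, tunedFraction = tunedFraction,
              texAmp = texAmp, taskGainScale = taskGainScale,
              tactileGateSd = tactileGateSd,
              adaptationRate = adaptationRate,
              forceCoupling = forceCoupling,
              forceLag = forceLag, blockGainSd = blockGainSd,
              rest = rest, nS1 = nS1)
  class(cfg) <- "stimConfig"
  if (length(textures) != 2L) stop("stimConfig requires two tactile levels")
  if (blockTrials %% 2L) stop("blockTrials must be even")
  cfg
}
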