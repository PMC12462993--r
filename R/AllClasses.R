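## S4 classes for session data. Times are stored in seconds on the session
## clock; analysis interfaces (window grids, spans) use milliseconds.

REGION_LEVELS <- c("M1", "S1A", "S1B")

#' Spike train of one sorted unit or multi-unit channel
#'
#' @slot unitId character identifier, unique within a session.
#' @slot channel integer recording channel.
#' @slot region region label, one of `"M1"`, `"S1A"`, `"S1B"`.
#' @slot sorted logical; `TRUE` for a manually sorted unit, `FALSE` for
#'   threshold-crossing multi-unit activity (the ICMS recording mode).
#' @slot times nondecreasing numeric vector of spike times (seconds).
#' @export
setClass("SpikeTrain", representation(
  unitId = "character", channel = "integer", region = "character",
  sorted = "logical", times = "numeric"
))

setValidity("SpikeTrain", function(object) {
  msg <- character()
  if (length(object@unitId) != 1L) msg <- c(msg, "unitId must be length 1")
  if (!object@region %in% REGION_LEVELS)
    msg <- c(msg, sprintf("region '%s' not one of %s", object@region,
                          paste(REGION_LEVELS, collapse = "/")))
  if (length(object@times) && any(diff(object@times) < 0))
    msg <- c(msg, "times: spike times must be nondecreasing")
  if (length(object@times) && any(!is.finite(object@times)))
    msg <- c(msg, "times: spike times must be finite")
  if (length(msg)) msg else TRUE
})

#' Continuous grip-force trace
#'
#' @slot sampleRate sampling rate in Hz.
#' @slot values force samples (arbitrary units).
#' @slot t0 session-clock time of the first sample (seconds).
#' @export
setClass("ForceTrace", representation(
  sampleRate = "numeric", values = "numeric", t0 = "numeric"
))

setValidity("ForceTrace", function(object) {
  msg <- character()
  if (length(object@sampleRate) != 1L || !is.finite(object@sampleRate) ||
      object@sampleRate <= 0)
    msg <- c(msg, "sampleRate must be a single positive number")
  if (length(object@values) && any(!is.finite(object@values)))
    msg <- c(msg, "values must be finite")
  if (length(msg)) msg else TRUE
})

#' ICMS pulse train
#'
#' One stimulation train: charge-balanced biphasic pulses delivered through a
#' single S1 electrode. Sham trains carry zero amplitude and mark the
#' baseline condition.
#'
#' @slot id integer train identifier, unique within a session.
#' @slot onset train onset (seconds, session clock).
#' @slot channel stimulated S1 channel.
#' @slot amplitude pulse amplitude in microamperes; 0 for sham.
#' @slot frequency pulse rate in Hz.
#' @slot duration train duration in seconds.
#' @slot pulseTimes per-pulse times (seconds), within
#'   `[onset, onset + duration]`.
#' @slot sham logical sham flag; implies `amplitude == 0`.
#' @export
setClass("StimTrain", representation(
  id = "integer", onset = "numeric", channel = "integer",
  amplitude = "numeric", frequency = "numeric", duration = "numeric",
  pulseTimes = "numeric", sham = "logical"
))

setValidity("StimTrain", function(object) {
  msg <- character()
  eps <- 1e-9
  if (length(object@pulseTimes) &&
      (min(object@pulseTimes) < object@onset - eps ||
       max(object@pulseTimes) > object@onset + object@duration + eps))
    msg <- c(msg, "pulseTimes must lie within [onset, onset + duration]")
  if (object@sham && object@amplitude != 0)
    msg <- c(msg, "sham train must have amplitude 0")
  if (object@frequency <= 0) msg <- c(msg, "frequency must be positive")
  if (length(msg)) msg else TRUE
})

#' Sliding analysis window grid
#'
#' Windows are half-open `[start, start + width)` in milliseconds relative to
#' an alignment event, so a spike on a boundary belongs to exactly one
#' window.
#'
#' @slot width window width (ms).
#' @slot step step between window starts (ms).
#' @slot starts strictly increasing window starts (ms).
#' @export
setClass("WindowGrid", representation(
  width = "numeric", step = "numeric", starts = "numeric"
))

setValidity("WindowGrid", function(object) {
  msg <- character()
  if (object@width <= 0) msg <- c(msg, "width must be positive")
  if (length(object@starts) > 1L && any(diff(object@starts) <= 0))
    msg <- c(msg, "starts must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' One experimental session
#'
#' Container for a complete session: the trial table, spike trains of all
#' units/channels, the grip-force trace, ICMS trains (possibly none) and the
#' channel-to-region map.
#'
#' The trial table has columns `index`, `block`, `texture` (character level),
#' `load` (grams), `t_cue`, `t_touch`, `t_hold_end` (seconds) and, for
#' sessions with stimulation, `stim_id` (integer id of the associated
#' [StimTrain] or `NA`), `is_control` (logical) and `t_stim_on` (actual or
#' scheduled stimulation onset, also defined for control trials so that
#' control and stimulated trials can be aligned identically).
#'
#' @slot sessionId session identifier.
#' @slot animalId animal identifier.
#' @slot regions data.frame with columns `channel`, `region`.
#' @slot trials trial table (see Details).
#' @slot units list of [SpikeTrain] objects.
#' @slot force a [ForceTrace].
#' @slot stimTrains list of [StimTrain] objects.
#' @slot conditionLevels list with `texture` (character, ordered by
#'   increasing roughness) and `load` (numeric grams).
#' @slot duration session duration (seconds).
#' @export
setClass("SessionBundle", representation(
  sessionId = "character", animalId = "character", regions = "data.frame",
  trials = "data.frame", units = "list", force = "ForceTrace",
  stimTrains = "list", conditionLevels = "list", duration = "numeric"
))

setValidity("SessionBundle", function(object) {
  msg <- character()
  tr <- object@trials
  need <- c("index", "block", "texture", "load", "t_cue", "t_touch",
            "t_hold_end")
  miss <- setdiff(need, names(tr))
  if (length(miss))
    return(sprintf("trials: missing column(s) %s", paste(miss, collapse = ", ")))
  if (nrow(tr)) {
    bad <- !(tr$t_cue < tr$t_touch & tr$t_touch < tr$t_hold_end)
    if (any(bad))
      msg <- c(msg, sprintf(
        "trials: event times must satisfy t_cue < t_touch < t_hold_end (trial %d)",
        tr$index[which(bad)[1]]))
    if (!all(tr$texture %in% object@conditionLevels$texture))
      msg <- c(msg, "trials: texture outside declared levels")
    if (!all(tr$load %in% object@conditionLevels$load))
      msg <- c(msg, "trials: load outside declared levels")
  }
  for (u in object@units) {
    if (length(u@times) &&
        (min(u@times) < 0 || max(u@times) > object@duration)) {
      msg <- c(msg, sprintf(
        "units: spikes of '%s' outside session duration [0, %g]",
        u@unitId, object@duration))
      break
    }
  }
  if (length(object@stimTrains)) {
    ch <- vapply(object@stimTrains, function(s) s@channel, integer(1))
    if (!all(ch %in% object@regions$channel))
      msg <- c(msg, "stimTrains: train references unknown channel")
  }
  if (length(msg)) msg else TRUE
})

## ---- constructors ----

#' @describeIn SpikeTrain-class Construct a spike train.
#' @param unitId,channel,region,sorted,times see slots.
#' @export
SpikeTrain <- function(unitId, channel, region, times, sorted = TRUE) {
  new("SpikeTrain", unitId = as.character(unitId),
      channel = as.integer(channel), region = as.character(region),
      sorted = isTRUE(sorted), times = as.numeric(times))
}

#' @describeIn ForceTrace-class Construct a force trace.
#' @param sampleRate,values,t0 see slots.
#' @export
ForceTrace <- function(values = numeric(), sampleRate = 100, t0 = 0) {
  new("ForceTrace", sampleRate = as.numeric(sampleRate),
      values = as.numeric(values), t0 = as.numeric(t0))
}

#' @describeIn StimTrain-class Construct a stimulation train.
#' @param id,onset,channel,amplitude,frequency,duration,pulseTimes,sham see
#'   slots. `pulseTimes` defaults to a regular grid at `frequency`.
#' @export
StimTrain <- function(id, onset, channel, amplitude, frequency,
                      duration = 1, pulseTimes = NULL, sham = amplitude == 0) {
  if (is.null(pulseTimes))
    pulseTimes <- onset + seq(0, duration - 1e-9, by = 1 / frequency)
  new("StimTrain", id = as.integer(id), onset = as.numeric(onset),
      channel = as.integer(channel), amplitude = as.numeric(amplitude),
      frequency = as.numeric(frequency), duration = as.numeric(duration),
      pulseTimes = as.numeric(pulseTimes), sham = isTRUE(sham))
}

#' @describeIn SessionBundle-class Construct and validate a session bundle.
#' @param sessionId,animalId,regions,trials,units,force,stimTrains,conditionLevels,duration
#'   see slots; `duration` defaults to just past the last event.
#' @export
SessionBundle <- function(sessionId, animalId, regions, trials, units,
                          force = ForceTrace(), stimTrains = list(),
                          conditionLevels, duration = NULL) {
  if (is.null(duration)) {
    ends <- c(trials$t_hold_end, 0,
              unlist(lapply(units, function(u) u@times)),
              unlist(lapply(stimTrains, function(s) s@onset + s@duration)))
    duration <- max(ends) + 1
  }
  new("SessionBundle", sessionId = as.character(sessionId),
      animalId = as.character(animalId), regions = regions,
      trials = trials, units = units, force = force,
      stimTrains = stimTrains, conditionLevels = conditionLevels,
      duration = as.numeric(duration))
}

## ---- show methods ----

setMethod("show", "SpikeTrain", function(object) {
  cat(sprintf("SpikeTrain '%s' (%s ch %d, %s): %d spikes\n",
              object@unitId, object@region, object@channel,
              if (object@sorted) "sorted" else "multi-unit",
              length(object@times)))
})

setMethod("show", "StimTrain", function(object) {
  cat(sprintf("StimTrain %d: ch %d, %g uA @ %g Hz, %g s, %d pulses%s\n",
              object@id, object@channel, object@amplitude, object@frequency,
              object@duration, length(object@pulseTimes),
              if (object@sham) " (sham)" else ""))
})

setMethod("show", "WindowGrid", function(object) {
  cat(sprintf("WindowGrid: %d windows of %g ms (step %g ms), starts %g..%g ms\n",
              length(object@starts), object@width, object@step,
              min(object@starts), max(object@starts)))
})

setMethod("show", "SessionBundle", function(object) {
  reg <- table(vapply(object@units, function(u) u@region, character(1)))
  cat(sprintf("SessionBundle '%s' (animal %s)\n", object@sessionId,
              object@animalId))
  cat(sprintf("  %d trials in %d blocks; conditions: %d textures x %d loads\n",
              nrow(object@trials), length(unique(object@trials$block)),
              length(object@conditionLevels$texture),
              length(object@conditionLevels$load)))
  cat(sprintf("  units: %s\n",
              paste(sprintf("%s=%d", names(reg), as.integer(reg)),
                    collapse = ", ")))
  cat(sprintf("  stim trains: %d; force samples: %d @ %g Hz; duration %.1f s\n",
              length(object@stimTrains), length(object@force@values),
              object@force@sampleRate, object@duration))
})
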