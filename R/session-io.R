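#' Write a session bundle to a directory
#'
#' Serializes a [SessionBundle] as a plain-text directory: `manifest.json`
#' plus column-oriented CSV tables (`trials.csv`, `spikes.csv`,
#' `regions.csv`, `force.csv`, `stim.csv`). The format round-trips
#' losslessly through [readBundle()].
#'
#' @param bundle a validated [SessionBundle].
#' @param path directory to create/write into.
#' @return the manifest path, invisibly.
#' @export
writeBundle <- function(bundle, path) {
  validObject(bundle)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, file) {
    ## format doubles at full precision so the round trip is lossless
    for (col in names(df))
      if (is.double(df[[col]]))
        df[[col]] <- sprintf("%.17g", df[[col]])
    write.csv(df, file.path(path, file), row.names = FALSE, quote = TRUE)
    file
  }
  files <- list(trials = wr(bundle@trials, "trials.csv"))
  sp <- do.call(rbind, lapply(bundle@units, function(u) {
    data.frame(unit_id = rep(u@unitId, max(1L, length(u@times))),
               channel = u@channel, region = u@region, sorted = u@sorted,
               time_s = if (length(u@times)) u@times else NA_real_)
  }))
  if (is.null(sp))
    sp <- data.frame(unit_id = character(), channel = integer(),
                     region = character(), sorted = logical(),
                     time_s = numeric())
  files$spikes <- wr(sp, "spikes.csv")
  files$regions <- wr(bundle@regions, "regions.csv")
  fr <- bundle@force
  files$force <- wr(data.frame(
    time_s = if (length(fr@values))
      fr@t0 + (seq_along(fr@values) - 1) / fr@sampleRate else numeric(),
    value = fr@values), "force.csv")
  st <- do.call(rbind, lapply(bundle@stimTrains, function(s) {
    data.frame(train_id = rep(s@id, max(1L, length(s@pulseTimes))),
               onset = s@onset, channel = s@channel, amplitude = s@amplitude,
               frequency = s@frequency, duration = s@duration, sham = s@sham,
               pulse_time = if (length(s@pulseTimes)) s@pulseTimes
                            else NA_real_)
  }))
  if (is.null(st))
    st <- data.frame(train_id = integer(), onset = numeric(),
                     channel = integer(), amplitude = numeric(),
                     frequency = numeric(), duration = numeric(),
                     sham = logical(), pulse_time = numeric())
  files$stim <- wr(st, "stim.csv")
  ncond <- length(bundle@conditionLevels$texture) *
    length(bundle@conditionLevels$load)
  manifest <- list(
    format = "graspflow-bundle", version = 1L,
    session_id = bundle@sessionId, animal_id = bundle@animalId,
    duration_s = bundle@duration,
    condition_levels = list(texture = bundle@conditionLevels$texture,
                            load = bundle@conditionLevels$load),
    n_condition_cells = ncond,
    force_sample_rate = fr@sampleRate, force_t0 = fr@t0,
    files = files)
  mpath <- file.path(path, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(mpath)
}

#' Read a session bundle from a directory
#'
#' @param path directory written by [writeBundle()].
#' @return a validated [SessionBundle].
#' @export
readBundle <- function(path) {
  mpath <- file.path(path, "manifest.json")
  if (!file.exists(mpath))
    stop(sprintf("no manifest.json in '%s'", path))
  man <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  rd <- function(key) {
    f <- file.path(path, man$files[[key]])
    if (!file.exists(f))
      stop(sprintf("manifest references missing table '%s'", man$files[[key]]))
    read.csv(f, stringsAsFactors = FALSE)
  }
  trialsDf <- rd("trials")
  for (col in intersect(c("load", "t_cue", "t_touch", "t_hold_end",
                          "t_stim_on"), names(trialsDf)))
    trialsDf[[col]] <- as.numeric(trialsDf[[col]])
  if ("stim_id" %in% names(trialsDf))
    trialsDf$stim_id <- as.integer(trialsDf$stim_id)
  spikes <- rd("spikes")
  regions <- rd("regions")
  forceDf <- rd("force")
  stim <- rd("stim")
  units <- list()
  if (nrow(spikes)) {
    for (uid in unique(spikes$unit_id)) {
      rows <- spikes[spikes$unit_id == uid, ]
      tt <- rows$time_s[!is.na(rows$time_s)]
      units[[length(units) + 1L]] <- SpikeTrain(
        uid, rows$channel[1], rows$region[1], sort(tt),
        sorted = rows$sorted[1])
    }
  }
  stimTrains <- list()
  if (nrow(stim)) {
    for (id in unique(stim$train_id)) {
      rows <- stim[stim$train_id == id, ]
      pt <- rows$pulse_time[!is.na(rows$pulse_time)]
      stimTrains[[length(stimTrains) + 1L]] <- StimTrain(
        id, rows$onset[1], rows$channel[1], rows$amplitude[1],
        rows$frequency[1], rows$duration[1], pulseTimes = sort(pt),
        sham = rows$sham[1])
    }
  }
  force <- ForceTrace(values = forceDf$value,
                      sampleRate = man$force_sample_rate,
                      t0 = man$force_t0)
  bundle <- SessionBundle(
    sessionId = man$session_id, animalId = man$animal_id,
    regions = regions, trials = trialsDf, units = units, force = force,
    stimTrains = stimTrains,
    conditionLevels = list(texture = as.character(man$condition_levels$texture),
                           load = as.numeric(man$condition_levels$load)),
    duration = man$duration_s)
  validObject(bundle)
  bundle
}
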