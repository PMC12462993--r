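#' Construct a sliding window grid
#'
#' Windows are half-open `[start, start + width)` milliseconds relative to an
#' alignment event.
#'
#' @param start first window start (ms).
#' @param end last window start (ms).
#' @param width window width (ms).
#' @param step step between starts (ms).
#' @return a [WindowGrid].
#' @examples
#' windowGrid(-200, 900, width = 200, step = 50)  # the tuning grid
#' @export
windowGrid <- function(start, end, width = 200, step = 50) {
  new("WindowGrid", width = as.numeric(width), step = as.numeric(step),
      starts = seq(as.numeric(start), as.numeric(end), by = as.numeric(step)))
}

#' Default analysis grids and behavioral stage spans
#'
#' `tuningGrid()` is the tactile-tuning grid: 23 window starts from -200 to
#' +900 ms (200 ms windows, 50 ms step) relative to target touch, covering
#' spikes up to +1100 ms. `cgcGrid()` is the Granger-causality grid: 300 ms
#' windows stepping 50 ms over -500 to 1000 ms (starts -500..700).
#' `indexGrid()` is the stimulation-onset-aligned modulation grid: 200 ms
#' windows, 40 ms step, starts spanning `span`.
#'
#' @return a [WindowGrid].
#' @export
tuningGrid <- function() windowGrid(-200, 900, width = 200, step = 50)

#' @rdname tuningGrid
#' @export
cgcGrid <- function() windowGrid(-500, 700, width = 300, step = 50)

#' @rdname tuningGrid
#' @param span start of first and last window (ms relative to stimulation
#'   onset).
#' @export
indexGrid <- function(span = c(-500, 1300)) {
  windowGrid(span[1], span[2], width = 200, step = 40)
}

#' Behavioral stage definitions
#'
#' Named spans in ms. Touch-aligned: `T` (touching, -50..150 ms) and `GH`
#' (grasping & holding, 350..550 ms); their 300 ms Granger-causality
#' counterparts `T.cgc` (-100..200) and `GH.cgc` (300..600); and
#' stimulation-onset-aligned `GRASP` (0..280) and `HOLD` (400..680).
#'
#' @param label stage label.
#' @return numeric span `c(start, end)` in ms.
#' @export
stageSpan <- function(label = c("T", "GH", "T.cgc", "GH.cgc",
                                "GRASP", "HOLD")) {
  label <- match.arg(label)
  switch(label,
         "T"      = c(-50, 150),
         "GH"     = c(350, 550),
         "T.cgc"  = c(-100, 200),
         "GH.cgc" = c(300, 600),
         "GRASP"  = c(0, 280),
         "HOLD"   = c(400, 680))
}

## per-trial alignment event times (seconds)
eventTimes <- function(trials, event) {
  col <- switch(event,
                cue = "t_cue", touch = "t_touch", hold_end = "t_hold_end",
                stim_on = "t_stim_on",
                stop(sprintf("unknown event label '%s'", event)))
  if (!col %in% names(trials))
    stop(sprintf("trials table has no '%s' column for event '%s'", col, event))
  trials[[col]]
}

#' Align spikes to a trial event
#'
#' For each trial, returns spike times in milliseconds relative to the named
#' event (0 ms = event time), restricted to `span` (half-open
#' `[span[1], span[2])`).
#'
#' @param train a [SpikeTrain] or a numeric vector of spike times (seconds).
#' @param trials trial table of a [SessionBundle].
#' @param event one of `"cue"`, `"touch"`, `"hold_end"`, `"stim_on"`.
#' @param span window around the event in ms.
#' @return list (one numeric vector of relative times, ms, per trial).
#' @export
alignSpikes <- function(train, trials, event = "touch",
                        span = c(-200, 1100)) {
  times <- if (is(train, "SpikeTrain")) train@times else as.numeric(train)
  ev <- eventTimes(trials, event)
  ## binary-search the sorted spike vector, then apply the exact
  ## half-open filter on the small slice
  lapply(ev, function(t0) {
    a <- t0 + span[1] / 1000
    b <- t0 + span[2] / 1000
    i0 <- findInterval(a - 1e-9, times)
    i1 <- findInterval(b + 1e-9, times)
    if (i1 <= i0) return(numeric())
    rel <- (times[seq.int(i0 + 1L, i1)] - t0) * 1000
    rel[rel >= span[1] & rel < span[2]]
  })
}

#' Windowed firing rates
#'
#' Converts a per-trial raster of relative spike times into a trials x
#' windows matrix of firing rates: spike count in the half-open window
#' `[start, start + width)` divided by the window width.
#'
#' @param raster list of per-trial relative spike times (ms), as returned by
#'   [alignSpikes()].
#' @param grid a [WindowGrid].
#' @return numeric matrix, `length(raster)` rows x `length(starts)` columns
#'   (Hz), with window starts as column names.
#' @export
windowCounts <- function(raster, grid) {
  validObject(grid)
  starts <- grid@starts
  w <- grid@width
  out <- matrix(0, nrow = length(raster), ncol = length(starts),
                dimnames = list(NULL, as.character(starts)))
  for (i in seq_along(raster)) {
    sp <- raster[[i]]
    if (!length(sp)) next
    out[i, ] <- vapply(starts, function(s)
      sum(sp >= s & sp < s + w), numeric(1))
  }
  out / (w / 1000)
}

#' Bin spikes on a 1 ms grid
#'
#' Returns a time x trial matrix of spike counts on `binWidth` ms bins over
#' `span` (relative ms), the input format of the spectral estimator.
#'
#' @inheritParams windowCounts
#' @param span analysis span in ms (half-open).
#' @param binWidth bin width in ms.
#' @return integer matrix, `diff(span)/binWidth` rows x trials columns.
#' @export
binSpikes <- function(raster, span, binWidth = 1) {
  edges <- seq(span[1], span[2], by = binWidth)
  nb <- length(edges) - 1L
  out <- matrix(0L, nrow = nb, ncol = length(raster))
  for (i in seq_along(raster)) {
    sp <- raster[[i]]
    sp <- sp[sp >= span[1] & sp < span[2]]
    if (!length(sp)) next
    idx <- floor((sp - span[1]) / binWidth) + 1L
    tab <- tabulate(idx, nbins = nb)
    out[, i] <- tab
  }
  out
}
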