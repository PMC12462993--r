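## Characterization of M1 responses to S1 microstimulation: pulse-aligned
## rates against the sham baseline, the pulse-triggered-average (PTA)
## phase-locking statistic with its shuffle null, and the response
## taxonomy (phase-locked elicitation / non-phase-locked elicitation /
## inhibition / none).

## Analysis span per pulse: only the first 10 ms are used (the highest
## train frequency is 100 Hz); the first 3 ms after the pulse and the last
## 1 ms before the next are artifact blanks, leaving [3, 9) ms.
PULSE_SPAN_MS <- 10
PULSE_WIN_MS <- c(3, 9)

#' Per-pulse firing rates in the 3-9 ms post-pulse window
#'
#' Counts spikes in the half-open `[3, 9)` ms window after each pulse and
#' converts to Hz (artifact blanks are never counted: the counted time per
#' pulse epoch is exactly `span - 3 - 1` ms).
#'
#' @param train a [SpikeTrain] or numeric spike-time vector (seconds).
#' @param pulses pulse times (seconds).
#' @param span pulse epoch length (ms); pulse windows must not overlap.
#' @return numeric vector, one rate (Hz) per pulse.
#' @export
pulseAlignedRates <- function(train, pulses, span = PULSE_SPAN_MS) {
  times <- if (is(train, "SpikeTrain")) train@times else as.numeric(train)
  if (!length(pulses)) stop("pulses must be nonempty")
  if (length(pulses) > 1 && min(diff(sort(pulses))) < span / 1000 - 1e-9)
    stop("pulse windows overlap: inter-pulse interval shorter than span")
  w <- PULSE_WIN_MS / 1000
  times <- sort(times)
  counts <- findInterval(pulses + w[2] - 1e-9, times) -
    findInterval(pulses + w[1] - 1e-9, times)
  counts / diff(w)
}

#' Pulse-triggered average (PTA)
#'
#' Spike probability per 0.5 ms bin across the non-blanked part of the
#' inter-pulse interval (3-9 ms post-pulse by default).
#'
#' @inheritParams pulseAlignedRates
#' @param binWidth bin width (ms).
#' @param window analysis window (ms post-pulse).
#' @return list with `edges` (ms), `prob` (spike probability per bin) and
#'   `nPulses`.
#' @export
computePTA <- function(train, pulses, binWidth = 0.5,
                       window = PULSE_WIN_MS) {
  times <- sort(if (is(train, "SpikeTrain")) train@times
                else as.numeric(train))
  edges <- seq(window[1], window[2], by = binWidth)
  cum <- vapply(edges, function(e)
    sum(findInterval(pulses + e / 1000 - 1e-9, times)), numeric(1))
  counts <- diff(cum)
  list(edges = edges, prob = counts / length(pulses),
       nPulses = length(pulses))
}

#' Phase-locking index of a PTA
#'
#' Mean of the highest-probability bin and its adjacent bins (available
#' neighbors at the edges, no wraparound) minus the median probability of
#' all bins; a large value marks a response locked to individual pulses.
#'
#' @param pta output of [computePTA()].
#' @return the index (probability units).
#' @export
phaseLockIndex <- function(pta) {
  p <- pta$prob
  if (length(p) < 3) stop("PTA needs at least 3 bins")
  top <- which.max(p)
  nb <- intersect((top - 1):(top + 1), seq_along(p))
  mean(p[nb]) - median(p)
}

#' Shuffle null for the phase-locking index
#'
#' Per surrogate, 20% of pulse epochs are sampled, their spikes
#' redistributed uniformly over the non-blanked bins (preserving the spike
#' count), and the index recomputed on the shuffled PTA. The observed index
#' is significant when it strictly exceeds the `pct` percentile of `n`
#' surrogates.
#'
#' @inheritParams computePTA
#' @param sampleFrac fraction of pulse epochs per surrogate.
#' @param n surrogate count.
#' @param pct percentile of the null.
#' @param seed RNG seed.
#' @return list with `index`, `threshold`, `significant`, `surrogates`.
#' @export
phaseLockNull <- function(train, pulses, sampleFrac = 0.2, n = 1000,
                          pct = 99, seed = 1, binWidth = 0.5,
                          window = PULSE_WIN_MS) {
  if (length(pulses) < 10) stop("need at least 10 pulses")
  times <- sort(if (is(train, "SpikeTrain")) train@times
                else as.numeric(train))
  nb <- as.integer(diff(window) / binWidth)
  perPulse <- findInterval(pulses + window[2] / 1000 - 1e-9, times) -
    findInterval(pulses + window[1] / 1000 - 1e-9, times)
  obs <- phaseLockIndex(computePTA(times, pulses, binWidth, window))
  nSamp <- max(1L, round(sampleFrac * length(pulses)))
  surr <- withSeed(deriveSeed(seed, "pl-null"), {
    vapply(seq_len(n), function(b) {
      idx <- sample(length(pulses), nSamp)
      m <- sum(perPulse[idx])
      prob <- tabulate(sample.int(nb, m, replace = TRUE), nb) / nSamp
      phaseLockIndex(list(prob = prob))
    }, numeric(1))
  })
  thr <- as.numeric(quantile(surr, pct / 100, type = 1))
  list(index = obs, threshold = thr, significant = obs > thr,
       surrogates = surr)
}

#' Classify one channel's response to stimulation at one site
#'
#' Two-sided rank-sum comparison of per-pulse post rates against sham
#' baseline rates. Elicited requires a significant increase AND a mean
#' post rate of at least `minRate` Hz (the low-rate guard against
#' incidental activity); a significant decrease marks inhibition.
#'
#' @param post,sham per-pulse rates (Hz) after stimulation and sham pulses.
#' @param alpha significance level.
#' @param minRate elicitation rate guard (Hz).
#' @return list with `category` (`"elicited"`, `"inhibited"`, `"none"`),
#'   `p`, and `magnitude` (mean post minus sham spike probability in the
#'   3-9 ms window).
#' @export
classifyChannelResponse <- function(post, sham, alpha = 0.01,
                                    minRate = 2) {
  stopifnot(length(post) > 0, length(sham) > 0)
  ht <- suppressWarnings(wilcox.test(post, sham, exact = FALSE))
  p <- ht$p.value
  if (is.na(p)) p <- 1
  dm <- mean(post) - mean(sham)
  winS <- diff(PULSE_WIN_MS) / 1000
  category <- "none"
  if (p < alpha && dm > 0 && mean(post) >= minRate) category <- "elicited"
  if (p < alpha && dm < 0) category <- "inhibited"
  list(category = category, p = p, magnitude = dm * winS)
}

shamPulses <- function(bundle, frequency = NULL) {
  st <- Filter(function(s) s@sham, stimTrains(bundle))
  if (!is.null(frequency))
    st <- Filter(function(s) s@frequency == frequency, st)
  unlist(lapply(st, function(s) s@pulseTimes))
}

#' Map M1 responses over stimulation sites
#'
#' For every (S1 site, M1 channel) pair at the requested stimulation
#' parameters, classifies the response against sham baseline and, for
#' elicited channels, tests pulse phase locking, yielding the response
#' taxonomy that drives stimulation-pair design.
#'
#' @param bundle a rest-state ICMS [SessionBundle].
#' @param amplitude,frequency restrict to trains at these parameters
#'   (NULL = any non-sham train).
#' @param alpha elicitation/inhibition level.
#' @param minRate elicitation rate guard (Hz).
#' @param nShuffles phase-locking surrogate count.
#' @param seed RNG seed for the shuffle null.
#' @return data.frame: `site` (S1 channel), `channel` (M1), `category`
#'   (`"pl"`, `"npl"`, `"inh"`, `"none"`), `magnitude` (firing-probability
#'   difference), `p`.
#' @export
responseMap <- function(bundle, amplitude = NULL, frequency = NULL,
                        alpha = 0.01, minRate = 2, nShuffles = 1000,
                        seed = 1) {
  st <- Filter(function(s) !s@sham, stimTrains(bundle))
  if (!is.null(amplitude))
    st <- Filter(function(s) s@amplitude == amplitude, st)
  if (!is.null(frequency))
    st <- Filter(function(s) s@frequency == frequency, st)
  if (!length(st)) stop("no matching stimulation trains")
  sites <- sort(unique(vapply(st, function(s) s@channel, integer(1))))
  m1 <- Filter(function(u) u@region == "M1", bundle@units)
  rows <- list()
  for (site in sites) {
    pulses <- unlist(lapply(Filter(function(s) s@channel == site, st),
                            function(s) s@pulseTimes))
    freqs <- unique(vapply(Filter(function(s) s@channel == site, st),
                           function(s) s@frequency, numeric(1)))
    sham <- shamPulses(bundle)
    if (!length(sham)) stop("no sham trains for baseline")
    for (u in m1) {
      post <- pulseAlignedRates(u, pulses)
      base <- pulseAlignedRates(u, sham)
      cls <- classifyChannelResponse(post, base, alpha, minRate)
      category <- cls$category
      if (category == "elicited") {
        pl <- phaseLockNull(u, pulses, n = nShuffles,
                            seed = deriveSeed(seed, "map", site,
                                              u@channel))
        category <- if (pl$significant) "pl" else "npl"
      } else if (category == "inhibited") category <- "inh"
      rows[[length(rows) + 1L]] <- data.frame(
        site = site, channel = u@channel, category = category,
        magnitude = cls$magnitude, p = cls$p)
    }
  }
  do.call(rbind, rows)
}

#' Response proportions and magnitudes across stimulation parameters
#'
#' Per amplitude (at the frequency common to the amplitude ladder) or per
#' frequency (at the common amplitude), computes the proportion of
#' (site, channel) pairs in each response category and the elicitation
#' magnitudes of pairs responsive at one level or more.
#'
#' @param bundle a rest-state ICMS [SessionBundle].
#' @param vary `"amplitude"` or `"frequency"`.
#' @param nShuffles,seed phase-locking controls (shuffles reduced by
#'   default: category proportions do not depend on the pl/npl split).
#' @return list with `proportions` (level x category data.frame) and
#'   `magnitudes` (per level and pair, elicited pairs only).
#' @export
parameterEffectSummary <- function(bundle, vary = c("amplitude",
                                                    "frequency"),
                                   nShuffles = 200, seed = 1) {
  vary <- match.arg(vary)
  st <- Filter(function(s) !s@sham, stimTrains(bundle))
  params <- unique(data.frame(
    amplitude = vapply(st, function(s) s@amplitude, numeric(1)),
    frequency = vapply(st, function(s) s@frequency, numeric(1))))
  if (vary == "amplitude") {
    at <- as.numeric(names(sort(-table(params$frequency)))[1])
    levels <- sort(params$amplitude[params$frequency == at])
  } else {
    at <- as.numeric(names(sort(-table(params$amplitude)))[1])
    levels <- sort(params$frequency[params$amplitude == at])
  }
  maps <- lapply(levels, function(lv) {
    if (vary == "amplitude")
      responseMap(bundle, amplitude = lv, frequency = at,
                  nShuffles = nShuffles, seed = seed)
    else
      responseMap(bundle, amplitude = at, frequency = lv,
                  nShuffles = nShuffles, seed = seed)
  })
  prop <- do.call(rbind, lapply(seq_along(levels), function(i) {
    m <- maps[[i]]
    data.frame(level = levels[i],
               category = c("pl", "npl", "inh"),
               proportion = c(mean(m$category == "pl"),
                              mean(m$category == "npl"),
                              mean(m$category == "inh")))
  }))
  responsive <- unique(do.call(rbind, lapply(maps, function(m)
    m[m$category %in% c("pl", "npl"), c("site", "channel")])))
  mag <- do.call(rbind, lapply(seq_along(levels), function(i) {
    m <- merge(maps[[i]], responsive)
    if (!nrow(m)) return(NULL)
    data.frame(level = levels[i], site = m$site, channel = m$channel,
               magnitude = m$magnitude)
  }))
  list(proportions = prop, magnitudes = mag)
}
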