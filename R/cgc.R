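## Non-parametric conditional Granger causality between spike trains.
## Direction S1 -> M1 is computed conditioning on the other selected M1
## units (S1->M1|M1) and vice versa.

regionUnits <- function(bundle, region) {
  reg <- vapply(bundle@units, function(u) u@region, character(1))
  hit <- if (region == "S1") reg %in% c("S1A", "S1B") else reg == region
  bundle@units[hit]
}

#' Select the highest-firing units of a region
#'
#' Units are ranked by session-mean firing rate; ties are broken by unit id
#' so the selection is deterministic. Used to restrict Granger-causality
#' analysis to units whose rates can support spectral estimation.
#'
#' @param bundle a [SessionBundle].
#' @param region `"M1"` or `"S1"` (covering both S1 arrays).
#' @param n number of units to keep (all if fewer are available).
#' @return character vector of unit ids, highest rate first.
#' @export
selectTopUnits <- function(bundle, region = c("M1", "S1"), n = 10) {
  region <- match.arg(region)
  ul <- regionUnits(bundle, region)
  if (!length(ul)) stop(sprintf("no units in region %s", region))
  ids <- vapply(ul, function(u) u@unitId, character(1))
  rate <- vapply(ul, function(u) length(u@times), numeric(1)) /
    bundle@duration
  ord <- order(-rate, ids)
  ids[ord][seq_len(min(n, length(ids)))]
}

#' Conditional Granger causality from a cross-spectral density
#'
#' Computes the frequency-domain conditional Granger causality from channel
#' `j` to channel `i` given conditioning channels `k`, by Wilson-factorizing
#' the full `(i, j, k)` and reduced `(i, k)` spectral systems and applying
#' the partition (normalization) transform that removes instantaneous
#' correlation between the target innovation and the remaining channels.
#' The time-domain scalar is the arithmetic mean of the spectral measure
#' over the frequency grid (the discrete Geweke integral), floored at 0.
#'
#' @param csd a [CrossSpectrum] covering all involved channels.
#' @param i,j,k target, source and conditioning channels (indices or
#'   channel names; `k` may be empty for pairwise GC).
#' @param tol,maxIter,ridge factorization controls (see
#'   [wilsonFactorize()]).
#' @return list with `freq`, `spectral` (per-frequency CGC, nats),
#'   `scalar`, and the two factorization residuals.
#' @export
conditionalGC <- function(csd, i, j, k = integer(), tol = 1e-8,
                          maxIter = 100, ridge = 1e-6) {
  chn <- csd@channels
  ix <- function(z) if (is.character(z)) match(z, chn) else as.integer(z)
  i <- ix(i); j <- ix(j); k <- ix(k)
  if (anyNA(c(i, j, k))) stop("unknown channel")
  if (anyDuplicated(c(i, j, k))) stop("i, j, k must be distinct")
  if (csd@degenerate)
    return(list(freq = csd@freq, spectral = rep(NA_real_, length(csd@freq)),
                scalar = NA_real_, degenerate = TRUE))
  full <- c(i, j, k)
  red <- c(i, k)
  Sf <- csd@S[full, full, , drop = FALSE]
  Sr <- csd@S[red, red, , drop = FALSE]
  nfft <- csd@nfft
  facF <- wilsonFactorize(structure2csd(Sf, csd), tol, maxIter, ridge)
  facR <- wilsonFactorize(structure2csd(Sr, csd), tol, maxIter, ridge)
  ## embed the reduced transfer function into the full variable space
  ## (identity row/column for the source j, which sits at position 2) and
  ## apply the partition normalization of the full innovation covariance
  spec <- as.numeric(cgc_spectral_cpp(facF$H, facF$Sigma, facR$H,
                                      facR$Sigma[1, 1]))
  list(freq = csd@freq, spectral = spec,
       scalar = mean(pmax(spec, 0)),
       residualFull = facF$residual, residualReduced = facR$residual,
       degenerate = FALSE)
}

## wrap a plain sub-array in a minimal CrossSpectrum for factorization
structure2csd <- function(S, parent) {
  new("CrossSpectrum", freq = parent@freq, S = S,
      nTapers = parent@nTapers, nTrials = parent@nTrials, fs = parent@fs,
      nfft = parent@nfft, channels = as.character(seq_len(dim(S)[1])),
      degenerate = FALSE)
}

## per-unit, per-trial rasters over a span (cached by callers that need
## many re-binnings, e.g. jitter surrogates)
cgcRasters <- function(bundle, unitIds, span, event = "touch") {
  ul <- units2(bundle)[unitIds]
  if (any(vapply(ul, is.null, logical(1))))
    stop(sprintf("unknown unit id(s): %s",
                 paste(unitIds[vapply(ul, is.null, logical(1))],
                       collapse = ", ")))
  lapply(ul, function(u) alignSpikes(u, trials(bundle), event, span))
}

## binned ensemble [time, trial, channel] from cached rasters
rastersToEnsemble <- function(rasters, windowMs, trialsSel = NULL,
                              jitterMs = 0) {
  mats <- lapply(rasters, function(r) {
    if (!is.null(trialsSel)) r <- r[trialsSel]
    if (jitterMs > 0)
      r <- lapply(r, function(sp) sp + runif(length(sp), -jitterMs,
                                             jitterMs))
    binSpikes(r, windowMs, 1)
  })
  out <- array(0, dim = c(dim(mats[[1]]), length(mats)))
  for (j in seq_along(mats)) out[, , j] <- mats[[j]]
  out
}

## binned ensemble [time, trial, channel] for a set of units over one
## window (ms relative to event)
cgcEnsemble <- function(bundle, unitIds, windowMs, trialsSel = NULL,
                        event = "touch", jitterMs = 0) {
  r <- cgcRasters(bundle, unitIds,
                  c(windowMs[1] - jitterMs, windowMs[2] + jitterMs), event)
  rastersToEnsemble(r, windowMs, trialsSel, jitterMs)
}

## conditioning set: remaining selected units of the target's region,
## excluding source and target, capped for tractability
conditioningSet <- function(selTarget, source, target, cap = 8) {
  k <- setdiff(selTarget, c(source, target))
  head(k, cap)
}

#' Sliding-window conditional Granger causality
#'
#' Computes the time-resolved CGC for directed unit pairs over the analysis
#' grid (default 300 ms windows stepping 50 ms across -500..1000 ms around
#' touch), separately per tactile condition. The conditioning set of each
#' pair holds the remaining selected units of the target's region
#' (S1->M1|M1 and M1->S1|S1), capped at `condCap` units.
#'
#' @param bundle a [SessionBundle].
#' @param pairs data.frame with columns `source`, `target` (unit ids).
#' @param grid a [WindowGrid] (300 ms windows).
#' @param byCondition if TRUE, one series per texture x load cell;
#'   otherwise all trials pooled.
#' @param topM1,topS1 unit selections (default [selectTopUnits()]).
#' @param condCap conditioning-set cap.
#' @param nTapers multitaper count.
#' @return long data.frame: source, target, direction, texture, load,
#'   start, cgc (NA for degenerate windows).
#' @export
slidingCGC <- function(bundle, pairs, grid = cgcGrid(), byCondition = TRUE,
                       topM1 = selectTopUnits(bundle, "M1"),
                       topS1 = selectTopUnits(bundle, "S1"),
                       condCap = 8, nTapers = 3) {
  tr <- trials(bundle)
  reg <- setNames(vapply(bundle@units, function(u) u@region, character(1)),
                  unitIds(bundle))
  conds <- if (byCondition)
    unique(tr[, c("texture", "load")])
  else data.frame(texture = NA, load = NA)
  out <- list()
  for (p in seq_len(nrow(pairs))) {
    src <- pairs$source[p]; tgt <- pairs$target[p]
    tgtRegion <- if (reg[[tgt]] == "M1") "M1" else "S1"
    selT <- if (tgtRegion == "M1") topM1 else topS1
    k <- conditioningSet(selT, src, tgt, condCap)
    ids <- c(tgt, src, k)
    rasters <- cgcRasters(bundle, ids,
                          c(min(grid@starts), max(grid@starts) + grid@width))
    for (cc in seq_len(nrow(conds))) {
      sel <- if (byCondition)
        which(tr$texture == conds$texture[cc] & tr$load == conds$load[cc])
      else seq_len(nrow(tr))
      for (s in grid@starts) {
        ens <- rastersToEnsemble(rasters, c(s, s + grid@width), sel)
        csd <- multitaperCSD(ens, nTapers = nTapers, channels = ids)
        val <- if (csd@degenerate) NA_real_ else
          conditionalGC(csd, 1, 2, seq_along(k) + 2)$scalar
        out[[length(out) + 1L]] <- data.frame(
          source = src, target = tgt,
          direction = if (tgtRegion == "M1") "S1->M1|M1" else "M1->S1|S1",
          texture = conds$texture[cc], load = conds$load[cc],
          start = s, cgc = val)
      }
    }
  }
  do.call(rbind, out)
}

#' Spike-jitter significance test of a stage CGC
#'
#' The observed stage CGC (one 300 ms window, all trials pooled) is
#' compared with surrogates in which every spike of the involved units is
#' independently displaced by a uniform offset within `+/- halfwidth` ms
#' (within trial, then re-windowed), which destroys fine-timescale
#' dependencies while preserving slow rate structure. Significant when the
#' observed value strictly exceeds the `pct` percentile of the surrogate
#' distribution.
#'
#' @param bundle a [SessionBundle].
#' @param source,target unit ids.
#' @param stage `"T"` (window -100..200 ms) or `"GH"` (300..600 ms).
#' @param n number of surrogates.
#' @param halfwidth jitter half-width (ms).
#' @param pct surrogate percentile.
#' @param seed RNG seed; surrogate streams are derived per (pair, stage,
#'   surrogate index).
#' @param condUnits conditioning unit ids (default: none).
#' @param nTapers multitaper count.
#' @return list with `observed`, `surrogates`, `threshold`, `significant`.
#' @export
jitterSignificance <- function(bundle, source, target,
                               stage = c("GH", "T"), n = 30,
                               halfwidth = 10, pct = 95, seed = 1,
                               condUnits = character(), nTapers = 3) {
  stage <- match.arg(stage)
  win <- stageSpan(paste0(stage, ".cgc"))
  ids <- c(target, source, condUnits)
  kIdx <- if (length(condUnits)) seq_along(condUnits) + 2 else integer()
  rasters <- cgcRasters(bundle, ids, c(win[1] - halfwidth - 1,
                                       win[2] + halfwidth + 1))
  obs <- conditionalGC(
    multitaperCSD(rastersToEnsemble(rasters, win), nTapers = nTapers,
                  channels = ids), 1, 2, kIdx)$scalar
  surr <- vapply(seq_len(n), function(b) {
    withSeed(deriveSeed(seed, "jitter", source, target, stage, b), {
      ens <- rastersToEnsemble(rasters, win, jitterMs = halfwidth)
      conditionalGC(multitaperCSD(ens, nTapers = nTapers, channels = ids),
                    1, 2, kIdx)$scalar
    })
  }, numeric(1))
  ## empirical percentile as the ceiling order statistic (standard for
  ## surrogate tests; interpolation would be anticonservative)
  thr <- as.numeric(quantile(surr, pct / 100, type = 1))
  list(observed = obs, surrogates = surr, threshold = thr,
       significant = obs > thr)
}

#' Trial-resampling condition ANOVA of stage CGC
#'
#' Draws `frac` of each condition cell's trials with replacement
#' `nResamples` times, computes the stage-T (-100..200 ms) and stage-GH
#' (300..600 ms) CGC per draw, and runs a two-way texture x load ANOVA
#' across the resample values per cell. The resampling scheme treats
#' resamples as replicates, exactly as designed.
#'
#' @inheritParams jitterSignificance
#' @param frac fraction of trials per draw (count = `round(frac * n)`).
#' @param nResamples draws per condition cell.
#' @return list per stage: `values` (long data.frame) and `anova`
#'   ([anovaEta()] output).
#' @export
resampleConditionAnova <- function(bundle, source, target, frac = 0.2,
                                   nResamples = 20, seed = 1,
                                   condUnits = character(), nTapers = 3) {
  tr <- trials(bundle)
  cells <- unique(tr[, c("texture", "load")])
  ids <- c(target, source, condUnits)
  kIdx <- if (length(condUnits)) seq_along(condUnits) + 2 else integer()
  stages <- c("T", "GH")
  res <- list()
  for (st in stages) {
    win <- stageSpan(paste0(st, ".cgc"))
    rasters <- cgcRasters(bundle, ids, win)
    rows <- list()
    for (cc in seq_len(nrow(cells))) {
      sel <- which(tr$texture == cells$texture[cc] &
                     tr$load == cells$load[cc])
      ndraw <- round(frac * length(sel))
      for (r in seq_len(nResamples)) {
        take <- withSeed(deriveSeed(seed, "resample", st, cc, r),
                         sample(sel, ndraw, replace = TRUE))
        ens <- rastersToEnsemble(rasters, win, trialsSel = take)
        csd <- multitaperCSD(ens, nTapers = nTapers, channels = ids)
        val <- if (csd@degenerate) NA_real_ else
          conditionalGC(csd, 1, 2, kIdx)$scalar
        rows[[length(rows) + 1L]] <- data.frame(
          texture = cells$texture[cc], load = cells$load[cc],
          resample = r, cgc = val)
      }
    }
    vals <- do.call(rbind, rows)
    ok <- !is.na(vals$cgc)
    res[[st]] <- list(values = vals,
                      anova = anovaEta(vals$cgc[ok], vals$texture[ok],
                                       vals$load[ok]))
  }
  res
}

#' PCA of condition-concatenated CGC trajectories
#'
#' Each pair contributes one feature vector formed by concatenating its CGC
#' time courses under all conditions; PCA is centered and unscaled, with
#' each component's sign fixed so its largest-magnitude loading is
#' positive. Optional resampled CGC vectors are projected onto the
#' requested components.
#'
#' @param cgcTable long data.frame from [slidingCGC()] (columns source,
#'   target, texture, load, start, cgc).
#' @param components components to report projections for.
#' @param resampled optional matrix (rows = resampled observations,
#'   columns matching the concatenated feature order).
#' @return list with `loadings`, `explained` (variance fractions),
#'   `scores` (per pair) and `projections` (resampled, or NULL).
#' @export
cgcPCA <- function(cgcTable, components = c(3, 4), resampled = NULL) {
  key <- interaction(cgcTable$source, cgcTable$target, drop = TRUE)
  split_ <- split(cgcTable, key)
  feat <- t(vapply(split_, function(d) {
    d <- d[order(d$texture, d$load, d$start), ]
    d$cgc
  }, numeric(nrow(split_[[1]]))))
  feat[is.na(feat)] <- 0
  if (nrow(feat) < max(components))
    stop("fewer pairs than requested components")
  pc <- prcomp(feat, center = TRUE, scale. = FALSE)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  rot <- sweep(pc$rotation, 2, flip, "*")
  scores <- sweep(pc$x, 2, flip, "*")
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  proj <- NULL
  if (!is.null(resampled)) {
    ctr <- sweep(resampled, 2, pc$center)
    proj <- ctr %*% rot[, components, drop = FALSE]
  }
  list(loadings = rot, explained = expl, scores = scores,
       projections = proj)
}
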