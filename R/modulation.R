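## Day-2 analyses: artifact-blanked windowed decoding and the normalized
## indices of ICMS effect on tactile classification (I_ACC), force-decoding
## bias, actual grip force (I_F) and neural discriminability (I_N).
## All features are aligned to stimulation onset; the blanking pattern
## (first 3 ms and last 1 ms of every 10 ms cycle during the 1 s train,
## keyed on the stimulation schedule, not amplitude) is applied identically
## to stimulated and control trials and to training and testing data.

TRAIN_SPAN_MS <- c(0, 1000)
BLANK_CYCLE_MS <- 10
BLANK_WIN_MS <- c(3, 9)  # counted part of each cycle

inBlank <- function(relMs) {
  inTrain <- relMs >= TRAIN_SPAN_MS[1] & relMs < TRAIN_SPAN_MS[2]
  phase <- (relMs - TRAIN_SPAN_MS[1]) %% BLANK_CYCLE_MS
  inTrain & (phase < BLANK_WIN_MS[1] | phase >= BLANK_WIN_MS[2])
}

## exact counted time (ms) of [a, b): total minus blanked overlap; blank
## boundaries are integer ms, so 1 ms quadrature is exact for integer edges
countedTime <- function(a, b) {
  ms <- seq(a, b - 1)
  (b - a) - sum(inBlank(ms + 0.5))
}

## trials x bins matrix of blanking-corrected rates for one unit
blankedBinnedRates <- function(unit, tr, start, width, binWidth,
                               event = "stim_on") {
  raster <- alignSpikes(unit, tr, event, c(start, start + width))
  raster <- lapply(raster, function(sp) sp[!inBlank(sp)])
  counts <- t(binSpikes(raster, c(start, start + width), binWidth))
  edges <- seq(start, start + width, by = binWidth)
  ct <- vapply(seq_len(length(edges) - 1L), function(i)
    countedTime(edges[i], edges[i + 1]), numeric(1))
  sweep(counts, 2, pmax(ct, 1e-6) / 1000, "/")
}

## trials x (units * bins) blanked feature matrix for one window
blankedFeatures <- function(bundle, tr, start, width = 200, binWidth = 40,
                            units = NULL, event = "stim_on") {
  ul <- Filter(function(u) u@region == "M1", bundle@units)
  if (!is.null(units))
    ul <- Filter(function(u) u@channel %in% units, ul)
  do.call(cbind, lapply(ul, function(u)
    blankedBinnedRates(u, tr, start, width, binWidth, event)))
}

## ensure a scheduled stimulation-onset column exists (virtual onset for
## sessions recorded without stimulation)
withStimOnset <- function(tr, delay = 0.21) {
  if (!"t_stim_on" %in% names(tr)) tr$t_stim_on <- tr$t_touch + delay
  tr
}

## per-trial mean force in each window (ms relative to event)
forceWindowMeans <- function(bundle, tr, starts, width = 200,
                             event = "stim_on") {
  fr <- gripForce(bundle)
  ev <- eventTimes(tr, event)
  fs <- fr@sampleRate
  nS <- length(fr@values)
  out <- matrix(NA_real_, nrow(tr), length(starts),
                dimnames = list(NULL, as.character(starts)))
  for (i in seq_len(nrow(tr))) {
    for (w in seq_along(starts)) {
      a <- ev[i] + starts[w] / 1000 - fr@t0
      i0 <- max(1L, ceiling(a * fs) + 1L)
      i1 <- min(nS, ceiling((a + width / 1000) * fs))
      if (i1 >= i0) out[i, w] <- mean(fr@values[i0:i1])
    }
  }
  out
}

## day-1 channels with a significant tactile main effect (one-way F test
## on 0-500 ms mean rates)
tactileMainEffectChannels <- function(day1, alpha = 0.05) {
  tr <- trials(day1)
  m1 <- Filter(function(u) u@region == "M1", day1@units)
  keep <- vapply(m1, function(u) {
    raster <- alignSpikes(u, tr, "touch", c(0, 500))
    y <- vapply(raster, length, numeric(1)) / 0.5
    fit <- lm(y ~ factor(tr$texture))
    pv <- anova(fit)[["Pr(>F)"]][1]
    !is.na(pv) && pv < alpha
  }, logical(1))
  vapply(m1[keep], function(u) u@channel, integer(1))
}

meanOverSpan <- function(starts, values, span, width = 200) {
  centers <- starts + width / 2
  mean(values[centers >= span[1] & centers <= span[2]], na.rm = TRUE)
}

#' ICMS effect on tactile classification accuracy (I_ACC)
#'
#' A Gaussian-kernel SVM is trained per 200 ms window (40 ms bins, 40 ms
#' step) on day-1 (no-ICMS) trials of channels with significant tactile
#' main effects and tested on day-2 stimulated and control trials;
#' `I_ACC(t) = (ACC_ICMS(t) - ACC_NONE(t)) / ACC_NONE(t)` per stimulus
#' pair. Windows with `ACC_NONE = 0` are emitted as missing.
#'
#' @param day1,day2 the day-1 and day-2 [SessionBundle]s.
#' @param scope `"population"` (one classifier on all selected channels)
#'   or `"single"` (per-channel classifiers, accuracies averaged).
#' @param grid a [WindowGrid] relative to stimulation onset.
#' @param channels channel subset (default: day-1 tactile-significant).
#' @param alpha channel-filter level.
#' @return data.frame: `pair_type`, `start`, `accICMS`, `accNONE`, `iacc`;
#'   attribute `"stageMeans"` holds GRASP (0-280 ms) and HOLD (400-680 ms)
#'   means per pair.
#' @export
iaccSeries <- function(day1, day2, scope = c("population", "single"),
                       grid = indexGrid(c(-200, 800)), channels = NULL,
                       alpha = 0.05) {
  scope <- match.arg(scope)
  if (is.null(channels)) channels <- tactileMainEffectChannels(day1, alpha)
  if (!length(channels)) stop("no tactile-significant channels")
  tr1 <- withStimOnset(trials(day1))
  tr2 <- trials(day2)
  y1 <- factor(tr1$texture)
  y2 <- factor(tr2$texture, levels = levels(y1))
  pairTypes <- unique(tr2$pair_type)
  chSets <- if (scope == "population") list(channels) else
    as.list(channels)
  out <- list()
  for (s in grid@starts) {
    acc <- matrix(0, length(chSets), 2 * length(pairTypes))
    for (ci in seq_along(chSets)) {
      X1 <- blankedFeatures(day1, tr1, s, grid@width, units = chSets[[ci]])
      X2 <- blankedFeatures(day2, tr2, s, grid@width, units = chSets[[ci]])
      pred <- svmTrainTest(X1, y1, X2)
      k <- 0
      for (pt in pairTypes) {
        stim <- tr2$pair_type == pt & !tr2$is_control
        ctrl <- tr2$pair_type == pt & tr2$is_control
        acc[ci, k + 1] <- mean(pred[stim] == y2[stim])
        acc[ci, k + 2] <- mean(pred[ctrl] == y2[ctrl])
        k <- k + 2
      }
    }
    k <- 0
    for (pt in pairTypes) {
      aI <- mean(acc[, k + 1]); aN <- mean(acc[, k + 2])
      out[[length(out) + 1L]] <- data.frame(
        pair_type = pt, start = s, accICMS = aI, accNONE = aN,
        iacc = if (aN > 0) (aI - aN) / aN else NA_real_)
      k <- k + 2
    }
  }
  res <- do.call(rbind, out)
  sm <- do.call(rbind, lapply(split(res, res$pair_type), function(d)
    data.frame(pair_type = d$pair_type[1],
               GRASP = meanOverSpan(d$start, d$iacc, stageSpan("GRASP")),
               HOLD = meanOverSpan(d$start, d$iacc, stageSpan("HOLD")))))
  attr(res, "stageMeans") <- sm
  res
}

#' ICMS effect on grip-force decoding (bias index)
#'
#' A linear-kernel support-vector regression is trained per window on
#' day-1 population features against the window-mean grip force, then
#' applied to day-2 trials. `Bias(t) = (F_decoded - F_real) / F_real` on
#' trial-averaged forces; the bias index is `Bias_ICMS - Bias_NONE` per
#' stimulus pair and tactile level. Windows whose real force falls below
#' `floorFrac` of the peak condition-mean force are emitted as missing.
#'
#' @inheritParams iaccSeries
#' @param floorFrac denominator floor as a fraction of peak force.
#' @return data.frame: `pair_type`, `texture`, `start`, `biasICMS`,
#'   `biasNONE`, `biasIndex`; attribute `"stageMeans"` as in
#'   [iaccSeries()].
#' @export
forceDecodeBias <- function(day1, day2, grid = indexGrid(c(-200, 800)),
                            channels = NULL, floorFrac = 0.05) {
  tr1 <- withStimOnset(trials(day1))
  tr2 <- trials(day2)
  F1 <- forceWindowMeans(day1, tr1, grid@starts, grid@width)
  F2 <- forceWindowMeans(day2, tr2, grid@starts, grid@width)
  floorV <- floorFrac * max(colMeans(F2, na.rm = TRUE))
  pairTypes <- unique(tr2$pair_type)
  levelsTex <- unique(tr2$texture)
  out <- list()
  for (w in seq_along(grid@starts)) {
    s <- grid@starts[w]
    X1 <- blankedFeatures(day1, tr1, s, grid@width, units = channels)
    X2 <- blankedFeatures(day2, tr2, s, grid@width, units = channels)
    pred <- svrTrainPredict(X1, F1[, w], X2)
    for (pt in pairTypes) for (tx in levelsTex) {
      bias <- vapply(c(FALSE, TRUE), function(isCtrl) {
        sel <- tr2$pair_type == pt & tr2$texture == tx &
          tr2$is_control == isCtrl
        fr <- mean(F2[sel, w])
        if (!is.finite(fr) || abs(fr) < floorV) return(NA_real_)
        (mean(pred[sel]) - fr) / fr
      }, numeric(1))
      out[[length(out) + 1L]] <- data.frame(
        pair_type = pt, texture = tx, start = s,
        biasICMS = bias[1], biasNONE = bias[2],
        biasIndex = bias[1] - bias[2])
    }
  }
  res <- do.call(rbind, out)
  sm <- do.call(rbind, lapply(
    split(res, list(res$pair_type, res$texture)), function(d)
      data.frame(pair_type = d$pair_type[1], texture = d$texture[1],
                 GRASP = meanOverSpan(d$start, d$biasIndex,
                                      stageSpan("GRASP")),
                 HOLD = meanOverSpan(d$start, d$biasIndex,
                                     stageSpan("HOLD")))))
  attr(res, "stageMeans") <- sm
  res
}

#' ICMS effect on actual grip force (I_F)
#'
#' Per 200 ms window (40 ms step) within one block,
#' `I_F(t) = (F_ICMS(t) - F_NONE(t)) / F_NONE(t)` on trial-averaged force;
#' the block summary is the mean over the 300-700 ms post-stimulation
#' comparison window.
#'
#' @param day2 a day-2 [SessionBundle].
#' @param block block id.
#' @param grid a [WindowGrid] relative to stimulation onset.
#' @param floorFrac denominator floor as fraction of peak mean force.
#' @return list with `series` (data.frame `start`, `iF`) and `blockMean`
#'   (mean I_F over 300-700 ms).
#' @export
iFSeries <- function(day2, block, grid = indexGrid(), floorFrac = 0.05) {
  tr <- trials(day2)
  sel <- tr$block == block
  if (!"is_control" %in% names(tr) ||
      !any(sel & !tr$is_control) || !any(sel & tr$is_control))
    stop("block needs stimulated and control trials")
  Fw <- forceWindowMeans(day2, tr[sel, ], grid@starts, grid@width)
  isCtrl <- tr$is_control[sel]
  fI <- colMeans(Fw[!isCtrl, , drop = FALSE], na.rm = TRUE)
  fN <- colMeans(Fw[isCtrl, , drop = FALSE], na.rm = TRUE)
  floorV <- floorFrac * max(abs(fN), na.rm = TRUE)
  iF <- ifelse(abs(fN) < floorV, NA_real_, fI / fN - 1)
  series <- data.frame(start = grid@starts, iF = iF)
  list(series = series,
       blockMean = meanOverSpan(grid@starts, iF, c(300, 700)))
}

#' ICMS effect on neural discriminability (I_N)
#'
#' Per window, the stratified cross-validated accuracy of a
#' Gaussian-kernel SVM classifying stimulated vs control trials on blanked
#' M1 features; accuracy near 0.5 means no detectable neural intervention.
#'
#' @inheritParams iFSeries
#' @param folds cross-validation folds.
#' @param seed fold seed.
#' @param channels channel subset (default all M1).
#' @return list with `series` (data.frame `start`, `iN`), `blockMean`
#'   (300-700 ms) and `headlineMean` (140-500 ms, the window used for the
#'   neural-behavioral correlation).
#' @export
iNSeries <- function(day2, block, grid = indexGrid(), folds = 5, seed = 1,
                     channels = NULL) {
  tr <- trials(day2)
  sel <- which(tr$block == block)
  trb <- tr[sel, ]
  y <- factor(ifelse(trb$is_control, "none", "icms"))
  if (nlevels(y) < 2) stop("block needs stimulated and control trials")
  fold <- stratifiedFolds(y, folds, deriveSeed(seed, "iN", block))
  iN <- vapply(grid@starts, function(s) {
    X <- blankedFeatures(day2, trb, s, grid@width, units = channels)
    svmCvAccuracy(X, y, fold = fold)
  }, numeric(1))
  series <- data.frame(start = grid@starts, iN = iN)
  list(series = series,
       blockMean = meanOverSpan(grid@starts, iN, c(300, 700)),
       headlineMean = meanOverSpan(grid@starts, iN, c(140, 500)))
}

#' Correlation between neural and behavioral modulation
#'
#' Pearson correlation, across blocks, of the mean I_N (140-500 ms) and
#' mean I_F (200-700 ms), plus the full window x window correlation matrix
#' over the supplied grids (block-level series must share grids).
#'
#' @param iNList,iFList per-block outputs of [iNSeries()] and
#'   [iFSeries()].
#' @param inWindow,ifWindow headline averaging windows (ms).
#' @return list with `r`, `p`, `n`, the per-block means, and `matrix`
#'   (I_N windows x I_F windows correlation).
#' @export
inIfCorrelation <- function(iNList, iFList, inWindow = c(140, 500),
                            ifWindow = c(200, 700)) {
  if (length(iNList) < 5) stop("need at least 5 blocks")
  starts <- iNList[[1]]$series$start
  mIN <- vapply(iNList, function(b)
    meanOverSpan(b$series$start, b$series$iN, inWindow), numeric(1))
  mIF <- vapply(iFList, function(b)
    meanOverSpan(b$series$start, b$series$iF, ifWindow), numeric(1))
  if (sd(mIN) < 1e-12 || sd(mIF) < 1e-12)
    stop("zero variance across blocks")
  ht <- cor.test(mIN, mIF)
  matIN <- t(vapply(iNList, function(b) b$series$iN,
                    numeric(length(starts))))
  matIF <- t(vapply(iFList, function(b) b$series$iF,
                    numeric(length(iFList[[1]]$series$start))))
  cm <- suppressWarnings(cor(matIN, matIF, use = "pairwise.complete.obs"))
  list(r = unname(ht$estimate), p = ht$p.value, n = length(mIN),
       meanIN = mIN, meanIF = mIF, matrix = cm)
}

#' Stability of the ICMS effect across trial positions
#'
#' Recomputes a per-trial modulation index by trial position within block
#' (averaged across blocks) and tests for a monotone trend (Spearman); a
#' flat curve indicates no short-term neural adaptation to the
#' stimulation.
#'
#' @param day2 a day-2 [SessionBundle].
#' @param kind `"force"` (relative force deviation, 300-700 ms) or
#'   `"neural"` (relative net M1 rate modulation, 0-1000 ms).
#' @return list with `curve` (data.frame `position`, `value`), `rho`, `p`.
#' @export
adaptationCheck <- function(day2, kind = c("force", "neural")) {
  kind <- match.arg(kind)
  tr <- trials(day2)
  blocks <- unique(tr$block)
  span <- if (kind == "force") c(300, 700) else c(0, 1000)
  vals <- list()
  for (b in blocks) {
    stim <- tr[tr$block == b & !tr$is_control, ]
    ctrl <- tr[tr$block == b & tr$is_control, ]
    if (nrow(stim) < 2) stop("need at least 2 stimulated trials per block")
    stim <- stim[order(stim$index), ]
    if (kind == "force") {
      fS <- forceWindowMeans(day2, stim, span[1], width = diff(span))[, 1]
      fC <- mean(forceWindowMeans(day2, ctrl, span[1],
                                  width = diff(span))[, 1])
      vals[[length(vals) + 1L]] <- (fS - fC) / fC
    } else {
      rS <- rowMeans(blankedFeatures(day2, stim, span[1],
                                     width = diff(span),
                                     binWidth = diff(span)))
      rC <- mean(rowMeans(blankedFeatures(day2, ctrl, span[1],
                                          width = diff(span),
                                          binWidth = diff(span))))
      vals[[length(vals) + 1L]] <- (rS - rC) / rC
    }
  }
  npos <- min(lengths(vals))
  mat <- vapply(vals, function(v) v[seq_len(npos)], numeric(npos))
  curve <- data.frame(position = seq_len(npos), value = rowMeans(mat))
  ht <- suppressWarnings(cor.test(curve$position, curve$value,
                                  method = "spearman"))
  list(curve = curve, rho = unname(ht$estimate), p = ht$p.value)
}

#' Stimulation x tactile interaction on M1 rates
#'
#' Two-way ANOVA (stimulation site x tactile level) on blanked 0-400 ms
#' mean rates of stimulated trials flags channels with significant
#' interaction; for those, a per-channel SVM classifying the two sites is
#' trained within one tactile level and tested on both, and the
#' consistent-vs-inconsistent accuracy contrast quantifies whether
#' pulse-evoked responses depend on the tactile context.
#'
#' @param day2 a day-2 [SessionBundle] with two stimulation sites.
#' @param window interaction analysis window (ms after onset).
#' @param alpha interaction flag level.
#' @param folds cross-validation folds.
#' @param seed fold seed.
#' @return list with `table` (per channel: p values, flag), `contrast`
#'   (per flagged channel: consistent/inconsistent accuracy), and `test`
#'   (paired Wilcoxon p, one-sided consistent > inconsistent).
#' @export
interactionTest <- function(day2, window = c(0, 400), alpha = 0.05,
                            folds = 5, seed = 1) {
  tr <- trials(day2)
  stim <- tr[!tr$is_control, ]
  sites <- vapply(stim$stim_id, function(id)
    day2@stimTrains[[id]]@channel, integer(1))
  if (length(unique(sites)) != 2 || length(unique(stim$texture)) != 2)
    stop("interaction test needs 2 stimulation sites x 2 tactile levels")
  m1 <- Filter(function(u) u@region == "M1", day2@units)
  rows <- lapply(m1, function(u) {
    y <- blankedBinnedRates(u, stim, window[1], diff(window),
                            diff(window))[, 1]
    a <- anovaEta(y, texture = sites, load = stim$texture)
    data.frame(channel = u@channel, p_site = a$p[["texture"]],
               p_tactile = a$p[["load"]],
               p_interaction = a$p[["interaction"]],
               flagged = a$p[["interaction"]] < alpha)
  })
  tab <- do.call(rbind, rows)
  flagged <- tab$channel[tab$flagged]
  starts <- seq(window[1], window[2] - 200, by = 40)
  if (!length(starts)) starts <- window[1]
  contrast <- NULL
  if (length(flagged)) {
    tex <- sort(unique(stim$texture))
    contrast <- do.call(rbind, lapply(flagged, function(ch) {
      accC <- accI <- numeric(0)
      for (s in starts) {
        X <- blankedFeatures(day2, stim, s, 200, units = ch)
        t1 <- stim$texture == tex[1]
        ySite <- factor(sites)
        fold <- stratifiedFolds(ySite[t1], folds,
                                deriveSeed(seed, "ixn", ch, s))
        for (f in sort(unique(fold))) {
          trIdx <- which(t1)[fold != f]
          teC <- which(t1)[fold == f]
          teI <- which(!t1)
          if (length(unique(ySite[trIdx])) < 2) next
          pred <- svmTrainTest(X[trIdx, , drop = FALSE], ySite[trIdx],
                               X[c(teC, teI), , drop = FALSE])
          accC <- c(accC, mean(pred[seq_along(teC)] == ySite[teC]))
          accI <- c(accI, mean(pred[-seq_along(teC)] == ySite[teI]))
        }
      }
      data.frame(channel = ch, consistent = mean(accC),
                 inconsistent = mean(accI))
    }))
  }
  pv <- if (!is.null(contrast) && nrow(contrast) >= 2)
    suppressWarnings(wilcox.test(contrast$consistent,
                                 contrast$inconsistent, paired = TRUE,
                                 alternative = "greater"))$p.value
  else NA_real_
  list(table = tab, contrast = contrast, test = pv)
}
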