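#' Per-unit time series of ANOVA effect sizes
#'
#' One row per analysis window: eta-squared and p-values for the texture
#' and load main effects and their interaction.
#'
#' @slot unitId unit identifier.
#' @slot grid the [WindowGrid] the series was computed on.
#' @slot table data.frame with columns `start`, `eta_texture`, `eta_load`,
#'   `eta_interaction`, `p_texture`, `p_load`, `p_interaction`,
#'   `degenerate`.
#' @export
setClass("EffectSeries", representation(
  unitId = "character", grid = "WindowGrid", table = "data.frame"
))

setMethod("show", "EffectSeries", function(object) {
  cat(sprintf("EffectSeries '%s': %d windows; peak eta2 tex %.3f, load %.3f\n",
              object@unitId, nrow(object@table),
              max(object@table$eta_texture), max(object@table$eta_load)))
})

#' @rdname accessors
#' @export
setMethod("windowStarts", "EffectSeries", function(x) x@table$start)
#' @rdname accessors
#' @export
setMethod("effectTable", "EffectSeries", function(x) x@table)

#' Two-way ANOVA effect decomposition of one response window
#'
#' Computes the effect size of texture, load and their interaction on a
#' single response value per trial as the fraction of summed squares:
#' `eta_i^2 = SS_i / (SS_texture + SS_load + SS_interaction + SS_error)`,
#' with Type-II sums of squares (equal to Type-I on balanced designs) and
#' p-values from the F distribution.
#'
#' @param y numeric response, one value per trial (e.g. a window firing
#'   rate).
#' @param texture,load factor levels per trial.
#' @return list with `eta` and `p` (named: texture, load, interaction) and
#'   `degenerate` (TRUE when total SS is zero; eta and p are then all zero
#'   and all one).
#' @examples
#' anovaEta(c(0, 0, 2, 2), texture = c("a", "a", "b", "b"),
#'          load = c(1, 2, 1, 2))$eta
#' @export
anovaEta <- function(y, texture, load) {
  texture <- factor(texture)
  load <- factor(load)
  if (nlevels(texture) < 2L || nlevels(load) < 2L)
    stop("need >= 2 levels per factor")
  cells <- table(texture, load)
  if (any(cells == 0)) {
    bad <- which(cells == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("empty design cell: texture '%s' x load '%s'",
                 rownames(cells)[bad[1]], colnames(cells)[bad[2]]))
  }
  nm <- c(texture = "texture", load = "load", interaction = "interaction")
  if (var(y) < .Machine$double.eps) {
    z <- setNames(numeric(3), names(nm))
    return(list(eta = z, p = setNames(rep(1, 3), names(nm)),
                degenerate = TRUE))
  }
  fit <- lm(y ~ texture * load)
  tab <- tryCatch(suppressWarnings(car::Anova(fit, type = 2)),
                  error = function(e) NULL)
  if (is.null(tab)) {
    ## perfect fit (zero residual): the Type-I table is exact here and
    ## p-values degenerate to 0 for any factor carrying variance
    tab <- suppressWarnings(anova(fit))
    rownames(tab)[rownames(tab) == "texture:load"] <- "texture:load"
    ssn <- tab[["Sum Sq"]]
    pr <- ifelse(ssn > 1e-12 * sum(ssn), 0, 1)
    pr[rownames(tab) == "Residuals"] <- NA
    tab[["Pr(>F)"]] <- pr
  }
  ss <- tab[["Sum Sq"]]
  rows <- rownames(tab)
  iTex <- match("texture", rows); iLoad <- match("load", rows)
  iInt <- match("texture:load", rows); iRes <- match("Residuals", rows)
  tot <- ss[iTex] + ss[iLoad] + ss[iInt] + ss[iRes]
  eta <- c(ss[iTex], ss[iLoad], ss[iInt]) / tot
  p <- tab[["Pr(>F)"]][c(iTex, iLoad, iInt)]
  p[is.na(p)] <- 1
  list(eta = setNames(eta, names(nm)), p = setNames(p, names(nm)),
       degenerate = FALSE)
}

#' Sliding-window effect series for one unit
#'
#' Applies [anovaEta()] to the windowed firing rates of one unit across the
#' analysis grid (default: the tuning grid, 200 ms windows stepping 50 ms
#' over -200..1100 ms around touch).
#'
#' @param raster per-trial relative spike times (ms; from [alignSpikes()])
#'   or a [SpikeTrain] (then aligned to touch using `trials`).
#' @param trials the trial table (texture/load labels per trial).
#' @param grid a [WindowGrid].
#' @param unitId identifier stored in the result.
#' @return an [EffectSeries].
#' @export
effectSeries <- function(raster, trials, grid = tuningGrid(),
                         unitId = "unit") {
  if (is(raster, "SpikeTrain")) {
    unitId <- raster@unitId
    span <- c(min(grid@starts), max(grid@starts) + grid@width)
    raster <- alignSpikes(raster, trials, "touch", span)
  }
  rates <- windowCounts(raster, grid)
  rows <- lapply(seq_along(grid@starts), function(w) {
    a <- anovaEta(rates[, w], trials$texture, trials$load)
    data.frame(start = grid@starts[w],
               eta_texture = a$eta[["texture"]],
               eta_load = a$eta[["load"]],
               eta_interaction = a$eta[["interaction"]],
               p_texture = a$p[["texture"]], p_load = a$p[["load"]],
               p_interaction = a$p[["interaction"]],
               degenerate = a$degenerate)
  })
  new("EffectSeries", unitId = unitId, grid = grid,
      table = do.call(rbind, rows))
}

#' Bonferroni-style corrected significance threshold
#'
#' `alpha / (nFactors * nWindows / nInclusion)`, reported to 4 decimals.
#' With the defaults (3 factors, 23 windows, 5 inclusion windows) this
#' yields 0.0036.
#'
#' @param alpha nominal level.
#' @param nFactors number of tested factors.
#' @param nWindows number of analysis windows.
#' @param nInclusion the minimum-significant-window inclusion count.
#' @return the corrected p threshold.
#' @export
correctedThreshold <- function(alpha = 0.05, nFactors = 3, nWindows = 23,
                               nInclusion = 5) {
  stopifnot(alpha > 0, nFactors > 0, nWindows > 0, nInclusion > 0)
  round(alpha / (nFactors * nWindows / nInclusion), 4)
}

#' Tactile-sensitivity inclusion rule and tuning summary
#'
#' A unit is tactilely sensitive (included) when at least `minWindows`
#' windows are significant for texture OR at least `minWindows` for load at
#' the corrected threshold; units failing both are dropped. Peak latency per
#' factor is the start of the argmax-eta window (ties broken toward the
#' earlier window).
#'
#' @param series an [EffectSeries] on the tuning grid.
#' @param threshold corrected p threshold (see [correctedThreshold()]).
#' @param minWindows minimum significant windows per factor.
#' @return list with `included`, `nSig` (per factor), `peakLatency` (ms,
#'   per factor), and `stageMeanEta` (stage x factor matrix for stages T
#'   and GH).
#' @export
includeUnit <- function(series, threshold = correctedThreshold(),
                        minWindows = 5) {
  tab <- series@table
  nSig <- c(texture = sum(tab$p_texture < threshold),
            load = sum(tab$p_load < threshold))
  peak <- c(texture = tab$start[which.max(tab$eta_texture)],
            load = tab$start[which.max(tab$eta_load)])
  sm <- sapply(c("T", "GH"), function(st) {
    w <- stageWindows(series@grid, stageSpan(st))
    c(texture = mean(tab$eta_texture[w]), load = mean(tab$eta_load[w]))
  })
  list(included = any(nSig >= minWindows), nSig = nSig,
       peakLatency = peak, stageMeanEta = t(sm))
}

## windows belonging to a stage: window center inside the stage span
stageWindows <- function(grid, span) {
  centers <- grid@starts + grid@width / 2
  which(centers >= span[1] & centers <= span[2])
}

#' Paired stage comparison of effect sizes across units
#'
#' Wilcoxon signed-rank test on per-unit stage-mean eta-squared between two
#' stages (exact distribution below 25 units, normal approximation with
#' continuity correction above).
#'
#' @param seriesList list of [EffectSeries] (one per unit).
#' @param stageA,stageB stage labels (see [stageSpan()]).
#' @param factor `"texture"` or `"load"`.
#' @param alternative passed to [wilcox.test()].
#' @return list with `p.value`, `statistic`, `direction` (+1 when stage A
#'   exceeds stage B on median), `nUnits` and the per-stage means.
#' @export
stageCompare <- function(seriesList, stageA = "T", stageB = "GH",
                         factor = c("texture", "load"),
                         alternative = "two.sided") {
  factor <- match.arg(factor)
  if (length(seriesList) < 2L) stop("need at least 2 units")
  col <- paste0("eta_", factor)
  stageMean <- function(s, stage) {
    w <- stageWindows(s@grid, stageSpan(stage))
    mean(s@table[[col]][w])
  }
  a <- vapply(seriesList, stageMean, numeric(1), stage = stageA)
  b <- vapply(seriesList, stageMean, numeric(1), stage = stageB)
  d <- a - b
  if (all(d == 0)) {
    return(list(p.value = 1, statistic = NA_real_, direction = 0,
                nUnits = length(a), meanA = mean(a), meanB = mean(b)))
  }
  ht <- suppressWarnings(
    wilcox.test(a, b, paired = TRUE, alternative = alternative,
                exact = length(a) < 25, correct = TRUE))
  list(p.value = ht$p.value, statistic = unname(ht$statistic),
       direction = sign(median(d[d != 0])), nUnits = length(a),
       meanA = mean(a), meanB = mean(b))
}
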