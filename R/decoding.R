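## Population decoding of tactile conditions: windowed rate features, a
## fixed Gaussian-kernel SVM contract (cost 1, gamma 1/d on fold-wise
## standardized features), and unit-dropping curves.

#' Per-trial binned-rate feature array
#'
#' For a single analysis window starting at `start` (ms relative to
#' `event`), builds the trials x units x bins array of firing rates (Hz)
#' with `width / binWidth` bins per unit.
#'
#' @param bundle a [SessionBundle].
#' @param start window start (ms).
#' @param width window width (ms).
#' @param binWidth bin width (ms).
#' @param units optional character vector of unit ids to include.
#' @param event alignment event.
#' @return numeric array `[trial, unit, bin]` with unit ids as dimnames.
#' @export
featureArray <- function(bundle, start, width = 200, binWidth = 50,
                         units = NULL, event = "touch") {
  ul <- units2(bundle)
  if (!is.null(units)) ul <- ul[units]
  tr <- trials(bundle)
  arr <- array(0, dim = c(nrow(tr), length(ul), width / binWidth),
               dimnames = list(NULL, names(ul), NULL))
  for (u in seq_along(ul)) {
    raster <- alignSpikes(ul[[u]], tr, event, c(start, start + width))
    b <- binSpikes(raster, c(start, start + width), binWidth)
    arr[, u, ] <- t(b) / (binWidth / 1000)
  }
  arr
}

flattenFeatures <- function(arr) {
  matrix(arr, nrow = dim(arr)[1])
}

#' Windowed population classification of tactile conditions
#'
#' Decodes texture or load labels from population firing-rate features
#' (50 ms bins within each 200 ms window by default) with a Gaussian-kernel
#' SVM under stratified k-fold cross-validation. The same fold split is
#' reused across windows so the accuracy time course is comparable.
#'
#' @param bundle a [SessionBundle].
#' @param target `"texture"` or `"load"`.
#' @param grid a [WindowGrid].
#' @param binWidth feature bin width (ms).
#' @param folds cross-validation folds.
#' @param seed fold-split seed.
#' @param units optional subset of unit ids.
#' @param event alignment event.
#' @return data.frame with `start` (ms) and `accuracy`.
#' @export
classifyTactile <- function(bundle, target = c("texture", "load"),
                            grid = tuningGrid(), binWidth = 50, folds = 10,
                            seed = 1, units = NULL, event = "touch") {
  target <- match.arg(target)
  labels <- factor(trials(bundle)[[target]])
  if (any(table(labels) < folds))
    stop(sprintf("each %s class needs at least %d trials", target, folds))
  fold <- stratifiedFolds(labels, folds, seed)
  acc <- vapply(grid@starts, function(s) {
    X <- flattenFeatures(featureArray(bundle, s, grid@width, binWidth,
                                      units, event))
    svmCvAccuracy(X, labels, fold = fold)
  }, numeric(1))
  data.frame(start = grid@starts, accuracy = acc)
}

#' Unit-dropping curves and minimal-fraction summary
#'
#' Classification accuracy as a function of retained unit count when units
#' are dropped in ascending order of a sensitivity score (so the
#' highest-scoring units are retained longest) or in random order (averaged
#' over `nRandom` seeded repeats). Also reports, per ordering, the smallest
#' retained fraction reaching at least 95% of that ordering's top accuracy.
#'
#' @param arr feature array `[trial, unit, bin]` (see [featureArray()]).
#' @param labels class labels, one per trial.
#' @param orderings named list of per-unit score vectors (e.g. stage-mean
#'   eta-squared for texture/load); units are dropped lowest-score-first.
#' @param counts retained-unit counts to evaluate (default: up to 12
#'   log-spaced counts).
#' @param nRandom random-ordering repeats.
#' @param folds,seed cross-validation controls.
#' @return list with `curve` (data.frame: ordering, nUnits, accuracy) and
#'   `minimalFraction` (named vector).
#' @export
droppingCurve <- function(arr, labels, orderings, counts = NULL,
                          nRandom = 10, folds = 10, seed = 1) {
  nu <- dim(arr)[2]
  labels <- factor(labels)
  if (is.null(counts))
    counts <- sort(unique(round(exp(seq(log(1), log(nu),
                                        length.out = min(nu, 12))))))
  fold <- stratifiedFolds(labels, folds, seed)
  accAt <- function(keep) {
    X <- flattenFeatures(arr[, keep, , drop = FALSE])
    svmCvAccuracy(X, labels, fold = fold)
  }
  rows <- list()
  for (nm in names(orderings)) {
    ord <- order(orderings[[nm]], decreasing = TRUE)  # best first
    for (k in counts)
      rows[[length(rows) + 1L]] <- data.frame(
        ordering = nm, nUnits = k, accuracy = accAt(ord[seq_len(k)]))
  }
  for (r in seq_len(nRandom)) {
    ord <- withSeed(deriveSeed(seed, "drop-random", r), sample(nu))
    for (k in counts)
      rows[[length(rows) + 1L]] <- data.frame(
        ordering = "random", nUnits = k, accuracy = accAt(ord[seq_len(k)]))
  }
  curve <- do.call(rbind, rows)
  curve <- aggregate(accuracy ~ ordering + nUnits, curve, mean)
  minFrac <- vapply(split(curve, curve$ordering), function(d) {
    d <- d[order(d$nUnits), ]
    top <- max(d$accuracy)
    min(d$nUnits[d$accuracy >= 0.95 * top]) / nu
  }, numeric(1))
  list(curve = curve, minimalFraction = minFrac)
}
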