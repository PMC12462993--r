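## Day-1 stimulation-site selection: rank tactile-sensitive M1 channels,
## score site-to-level assignments by their expected effect on the
## firing-rate gap, and pick Distinguishable (D) / Confusable (C) /
## Weak (W) pairs. D and C use the same two sites with swapped level
## assignment; W minimizes M1 modulation.

#' Rank M1 channels by tactile classification accuracy
#'
#' Per M1 channel, a Gaussian-kernel SVM on 50 ms binned rates over
#' 0-500 ms after touch classifies the two tactile levels under
#' stratified cross-validation; channels are ranked by accuracy. The
#' signed rate difference (level 1 minus level 2 mean rate) records each
#' channel's preference. Sensitivity is decided by a label-permutation
#' test on the accuracy, the quantitative counterpart of visual PSTH
#' inspection.
#'
#' @param bundle the day-1 [SessionBundle] (two tactile levels).
#' @param folds cross-validation folds.
#' @param nPerm label permutations for the sensitivity test.
#' @param alpha permutation significance level.
#' @param seed RNG seed.
#' @return data.frame: `channel`, `unitId`, `accuracy`, `rateDiff` (Hz),
#'   `pPerm`, `sensitive`, sorted by decreasing accuracy.
#' @export
rankTactileChannels <- function(bundle, folds = 10, nPerm = 200,
                                alpha = 0.05, seed = 1) {
  tr <- trials(bundle)
  lv <- conditionLevels(bundle)$texture
  if (length(lv) != 2) stop("day-1 ranking requires two tactile levels")
  if (any(table(tr$texture) < 20))
    stop("need >= 20 trials per tactile level")
  labels <- factor(tr$texture, levels = lv)
  m1 <- Filter(function(u) u@region == "M1", bundle@units)
  fold <- stratifiedFolds(labels, folds, seed)
  rows <- lapply(m1, function(u) {
    raster <- alignSpikes(u, tr, "touch", c(0, 500))
    X <- t(binSpikes(raster, c(0, 500), 50)) / 0.05
    acc <- svmCvAccuracy(X, labels, fold = fold)
    meanRate <- rowMeans(X)
    rateDiff <- mean(meanRate[labels == lv[1]]) -
      mean(meanRate[labels == lv[2]])
    nullAcc <- withSeed(deriveSeed(seed, "rank-perm", u@unitId), {
      vapply(seq_len(nPerm), function(b)
        svmCvAccuracy(X, sample(labels), fold = fold), numeric(1))
    })
    pPerm <- (1 + sum(nullAcc >= acc)) / (nPerm + 1)
    data.frame(channel = u@channel, unitId = u@unitId, accuracy = acc,
               rateDiff = rateDiff, pPerm = pPerm,
               sensitive = pPerm < alpha)
  })
  out <- do.call(rbind, rows)
  out[order(-out$accuracy), ]
}

## per-channel gap contribution of a site: sign(preference) x effect
gapContributions <- function(ranking, rmap, site) {
  sens <- ranking[ranking$sensitive, ]
  m <- merge(sens, rmap[rmap$site == site, ], by = "channel")
  eff <- ifelse(m$category == "none", 0, m$magnitude)
  data.frame(channel = m$channel, contrib = sign(m$rateDiff) * eff)
}

#' Score a site-to-level assignment
#'
#' The signed score sums, over tactile-sensitive channels, the preferred
#' direction of the channel times the difference between the effect of the
#' site assigned to level 1 and the site assigned to level 2. Positive
#' scores increase the firing-rate gap between levels (D-like), negative
#' scores reduce it (C-like); swapping the assignment negates the score
#' exactly.
#'
#' @param ranking output of [rankTactileChannels()].
#' @param rmap output of [responseMap()].
#' @param assignment named integer vector, tactile level -> S1 site; the
#'   first element is taken as level 1.
#' @return the signed score (firing-probability units).
#' @export
scorePair <- function(ranking, rmap, assignment) {
  if (!all(assignment %in% rmap$site)) stop("site missing from response map")
  c1 <- gapContributions(ranking, rmap, assignment[[1]])
  c2 <- gapContributions(ranking, rmap, assignment[[2]])
  sum(c1$contrib) - sum(c2$contrib)
}

admissibleSites <- function(ranking, rmap) {
  sites <- sort(unique(rmap$site))
  ok <- vapply(sites, function(s) {
    contrib <- gapContributions(ranking, rmap, s)$contrib
    nz <- contrib[contrib != 0]
    length(unique(sign(nz))) <= 1   # no mixed-sign gap effects
  }, logical(1))
  sites[ok]
}

#' Select the Distinguishable and Confusable stimulation pairs
#'
#' Excludes sites whose significant effects on sensitive channels have
#' mixed signs of gap contribution, then chooses the admissible site pair
#' and assignment maximizing the [scorePair()] score as pair D; pair C is
#' the same two sites with the swapped assignment. Ties break toward the
#' lower site indices.
#'
#' @inheritParams scorePair
#' @param levels the two tactile levels (default: order of appearance in
#'   the ranking's session is unknown, so pass the session's texture
#'   levels).
#' @return list with `D` and `C`, each a list with `type`, `assignment`
#'   (named level -> site) and `score`.
#' @export
selectPairs <- function(ranking, rmap, levels) {
  sites <- admissibleSites(ranking, rmap)
  if (length(sites) < 2) stop("no admissible site pair")
  best <- NULL
  for (a in sites) for (b in sites) {
    if (a == b) next
    sc <- scorePair(ranking, rmap, setNames(c(a, b), levels))
    if (is.null(best) || sc > best$score + 1e-12)
      best <- list(a = a, b = b, score = sc)
  }
  D <- list(type = "D", assignment = setNames(c(best$a, best$b), levels),
            score = best$score)
  C <- list(type = "C", assignment = setNames(c(best$b, best$a), levels),
            score = -best$score)
  list(D = D, C = C)
}

#' Select the weak (W) stimulation pair
#'
#' Chooses the two sites with the fewest significantly modulated M1
#' channels (ties broken by the summed response magnitude, then site
#' index); the W pair serves as the minimal-response control.
#'
#' @inheritParams scorePair
#' @param levels the two tactile levels.
#' @return list with `type = "W"`, `assignment`, and the per-site
#'   modulation counts; a warning is issued when every site modulates at
#'   least one channel.
#' @export
selectWeakPair <- function(rmap, levels) {
  sites <- sort(unique(rmap$site))
  if (length(sites) < 2) stop("need at least 2 sites")
  stats <- t(vapply(sites, function(s) {
    m <- rmap[rmap$site == s, ]
    c(nMod = sum(m$category != "none"),
      mag = sum(abs(m$magnitude[m$category != "none"])))
  }, numeric(2)))
  ord <- order(stats[, "nMod"], stats[, "mag"], sites)
  if (all(stats[, "nMod"] > 0))
    warning("every site significantly modulates at least one M1 channel")
  list(type = "W", assignment = setNames(sites[ord[1:2]], levels),
       nModulated = setNames(stats[, "nMod"], sites))
}
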