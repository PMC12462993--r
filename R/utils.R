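## Internal utilities: reproducible seed derivation, stratified folds, SVM
## helpers shared by the decoding and modulation stages.

## Deterministic child seed from a master seed and a string key. Keeps all
## derived seeds below 2^31 - 1.
deriveSeed <- function(seed, ...) {
  key <- paste(c(...), collapse = "|")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483629
  as.integer((((seed %% 65521) + 1) * 2654435 + h) %% 2147483647L)
}

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

## Stratified fold assignment: shuffles within class, then deals folds round
## robin so every class is spread over folds as evenly as possible.
stratifiedFolds <- function(labels, folds, seed) {
  labels <- as.factor(labels)
  fold <- integer(length(labels))
  withSeed(seed, {
    for (lv in levels(labels)) {
      idx <- sample(which(labels == lv))
      fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  fold
}

## Standardize columns by train-set statistics (no leakage). Constant
## columns are left centered at zero.
standardizeBy <- function(train, test) {
  mu <- colMeans(train)
  sdv <- apply(train, 2, sd)
  sdv[!is.finite(sdv) | sdv < 1e-12] <- 1
  list(train = sweep(sweep(train, 2, mu), 2, sdv, "/"),
       test = sweep(sweep(test, 2, mu), 2, sdv, "/"))
}

## Cross-validated classification accuracy with a Gaussian-kernel SVM.
## Fixed contract: cost 1, gamma 1/d on fold-standardized features.
svmCvAccuracy <- function(X, y, folds = 10, seed = 1, fold = NULL) {
  y <- as.factor(y)
  X <- as.matrix(X)
  if (is.null(fold)) fold <- stratifiedFolds(y, folds, seed)
  correct <- 0L
  for (f in sort(unique(fold))) {
    tr <- fold != f
    st <- standardizeBy(X[tr, , drop = FALSE], X[!tr, , drop = FALSE])
    if (length(unique(y[tr])) < 2L) next
    fit <- e1071::svm(st$train, y[tr], kernel = "radial",
                      cost = 1, gamma = 1 / ncol(X), scale = FALSE)
    correct <- correct + sum(predict(fit, st$test) == y[!tr])
  }
  correct / length(y)
}

## Train on one set, test on another (no CV), same SVM contract.
svmTrainTest <- function(Xtr, ytr, Xte) {
  st <- standardizeBy(as.matrix(Xtr), as.matrix(Xte))
  fit <- e1071::svm(st$train, as.factor(ytr), kernel = "radial",
                    cost = 1, gamma = 1 / ncol(st$train), scale = FALSE)
  predict(fit, st$test)
}

## Linear support-vector regression contract for force decoding.
svrTrainPredict <- function(Xtr, ytr, Xte) {
  st <- standardizeBy(as.matrix(Xtr), as.matrix(Xte))
  fit <- e1071::svm(st$train, as.numeric(ytr), type = "eps-regression",
                    kernel = "linear", cost = 1, scale = FALSE)
  as.numeric(predict(fit, st$test))
}
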