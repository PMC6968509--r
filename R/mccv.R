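#' Monte Carlo cross-validation of the OPLS classifier
#'
#' Repeats, for \code{nCycles} cycles (100 by default): draw a random
#' training set of \code{trainFraction} (90 percent) of the samples
#' (stratified by class by default, preserving small classes in the
#' held-out 10 percent), compute centring/scaling statistics on the
#' training split only, select the number of orthogonal components by
#' inner cross-validation on the training split, fit the OPLS model and
#' predict the held-out samples. Returns the per-cycle accuracies, their
#' mean (the averaged discrimination accuracy), the pooled confusion
#' matrix aggregated over all test sets and its pooled accuracy.
#' Reproducible from the seed.
#'
#' In non-stratified mode a drawn training split can lack a class; such
#' splits are redrawn and the event is logged via \code{message()}.
#'
#' @param X samples x bins matrix (included, normalized bins).
#' @param y two-class labels.
#' @param nCycles number of Monte Carlo cycles.
#' @param trainFraction fraction of samples used for training per cycle.
#' @param seed integer seed for the splits (and inner fold assignment).
#' @param stratified draw the training split per class (default TRUE).
#' @param mode scaling mode (see \code{\link{centerScale}}).
#' @param kMax largest number of orthogonal components considered by the
#'   per-cycle inner selection (0 forces plain single-component models).
#' @param innerFolds folds of the inner selection.
#' @return An \linkS4class{MCCVResult}.
#' @examples
#' set.seed(1)
#' X <- rbind(matrix(rnorm(60, 0), 10), matrix(rnorm(60, 3), 10))
#' y <- rep(c("a", "b"), each = 10)
#' mccv(X, y, nCycles = 10, seed = 1, kMax = 0)
#' @export
mccv <- function(X, y, nCycles = 100, trainFraction = 0.9, seed = 1L,
                 stratified = TRUE, mode = "center", kMax = 3,
                 innerFolds = 7) {
  y <- as.character(y)
  cls <- .codeClasses(y)
  if (min(table(y)) < 2) stopf("each class needs at least 2 members")
  n <- length(y)
  lev <- cls$levels

  acc <- numeric(nCycles)
  conf <- matrix(0L, 2, 2, dimnames = list(truth = lev, predicted = lev))
  cycles <- vector("list", nCycles)

  withLocalSeed(seed, {
    for (cy in seq_len(nCycles)) {
      train <- .drawTrainingSplit(y, trainFraction, stratified)
      test <- setdiff(seq_len(n), train)
      sc <- centerScale(X[train, , drop = FALSE], mode)
      k <- if (kMax > 0)
        selectNOrth(X[train, , drop = FALSE], y[train], kMax = kMax,
                    innerFolds = innerFolds, seed = NULL, mode = mode)
      else 0L
      fit <- oplsFit(sc$X, y[train], nOrth = k)
      pred <- oplsPredict(fit, applyScaling(sc$record,
                                            X[test, , drop = FALSE]))
      hits <- pred$class == y[test]
      acc[cy] <- mean(hits)
      for (i in seq_along(test))
        conf[y[test[i]], pred$class[i]] <- conf[y[test[i]], pred$class[i]] + 1L
      cycles[[cy]] <- list(test = test, response = pred$response,
                           class = pred$class, nOrth = k)
    }
  })

  new("MCCVResult", cycleAccuracies = acc, meanAccuracy = mean(acc),
      pooledAccuracy = sum(diag(conf)) / sum(conf),
      confusionMatrix = conf, nCycles = as.integer(nCycles),
      trainFraction = trainFraction,
      seed = as.integer(seed %||% NA_integer_),
      classLevels = lev, cycles = cycles)
}

## draw training indices; stratified mode samples within each class and
## guarantees at least one held-out sample per class
.drawTrainingSplit <- function(y, trainFraction, stratified) {
  n <- length(y)
  idx <- seq_len(n)
  if (stratified) {
    unlist(lapply(unique(y), function(cl) {
      members <- idx[y == cl]
      nTrain <- min(round(trainFraction * length(members)),
                    length(members) - 1L)
      nTrain <- max(nTrain, 2L)
      sample(members, nTrain)
    }), use.names = FALSE)
  } else {
    repeat {
      train <- sample(idx, round(trainFraction * n))
      if (length(unique(y[train])) == 2L &&
          length(train) < n)
        return(train)
      message("redrawing split: a class was missing from the training set")
    }
  }
}
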