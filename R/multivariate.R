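#' Column centring and scaling with a replayable record
#'
#' Applies the chosen column operation to a samples x bins matrix and
#' returns both the transformed matrix and a record sufficient to apply
#' the identical transform to new samples (the cross-validation
#' contract: statistics are computed on training data only and replayed
#' on test data).
#'
#' @param X numeric matrix, samples in rows (>= 2).
#' @param mode "center" (mean-centring only, the default for
#'   already-normalized bucket tables), "unit_variance" (autoscaling) or
#'   "pareto" (divide by the square root of the column standard
#'   deviation).
#' @return list with \code{X} (transformed matrix) and \code{record}
#'   (list of mode, centres, scales). Zero-variance columns under
#'   variance-based scaling are flagged and left centred only.
#' @export
centerScale <- function(X, mode = c("center", "unit_variance", "pareto")) {
  mode <- match.arg(mode)
  if (nrow(X) < 2) stopf("centerScale needs at least 2 samples")
  ctr <- colMeans(X)
  scl <- rep(1, ncol(X))
  zeroVar <- logical(ncol(X))
  if (mode != "center") {
    s <- apply(X, 2, stats::sd)
    zeroVar <- s < .Machine$double.eps^0.5
    s[zeroVar] <- 1
    scl <- if (mode == "unit_variance") s else sqrt(s)
  }
  record <- list(mode = mode, center = ctr, scale = scl, zeroVar = zeroVar)
  list(X = applyScaling(record, X), record = record)
}

#' Replay a stored scaling record on new data
#'
#' @param record record from \code{\link{centerScale}}.
#' @param X samples x bins matrix with the same bin dimension.
#' @return The transformed matrix.
#' @export
applyScaling <- function(record, X) {
  if (ncol(X) != length(record$center))
    stopf("dimension mismatch: record has %d bins, data has %d",
          length(record$center), ncol(X))
  sweep(sweep(X, 2, record$center, "-"), 2, record$scale, "/")
}

#' Principal component analysis by singular value decomposition
#'
#' Mean-centres the samples x bins matrix and decomposes it. Scores are
#' the centred data projected on the orthonormal loadings; explained
#' variance fractions are the squared singular values over their total.
#'
#' @param X numeric matrix, samples in rows.
#' @param nComponents number of components to keep
#'   (<= min(samples - 1, bins)).
#' @return A \linkS4class{PCAModel}.
#' @export
pcaFit <- function(X, nComponents = 2) {
  if (nrow(X) < 2) stopf("PCA needs at least 2 samples")
  rmax <- min(nrow(X) - 1, ncol(X))
  if (nComponents > rmax)
    stopf("nComponents must be <= min(samples - 1, bins) = %d", rmax)
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr, "-")
  sv <- svd(Xc)
  ev <- sv$d^2 / sum(sv$d^2)
  keep <- seq_len(nComponents)
  new("PCAModel", mean = ctr,
      loadings = sv$v[, keep, drop = FALSE],
      scores = sv$u[, keep, drop = FALSE] %*% diag(sv$d[keep], nComponents),
      explainedVariance = ev[keep])
}

## coded response: first level -> -1, second level -> +1
.codeClasses <- function(y) {
  lev <- if (is.factor(y)) levels(droplevels(y)) else unique(as.character(y))
  if (length(lev) != 2L)
    stopf("exactly two classes required (got: %s)",
          paste(lev, collapse = ", "))
  coding <- structure(c(-1, 1), names = lev)
  list(coded = coding[as.character(y)], coding = coding, levels = lev)
}

#' Fit a two-class OPLS model
#'
#' Orthogonal projections to latent structures for a single binary
#' response: the response-orthogonal variation is removed from the
#' centred predictor matrix by \code{nOrth} successive orthogonal
#' components, then a single predictive component is fitted on the
#' filtered matrix. Classes are coded -1/+1; the decision threshold
#' follows \code{thresholdRule} (ties at the threshold go to the
#' +1-coded class).
#'
#' For a single response, the fitted responses of OPLS with one
#' predictive plus k orthogonal components coincide with those of PLS1
#' with k + 1 components; the orthogonal decomposition changes the
#' interpretation (response-related vs response-unrelated variation),
#' not the fit.
#'
#' @param X samples x bins matrix (included bins only).
#' @param y two-class labels (factor or character).
#' @param nOrth number of orthogonal components to remove (>= 0; must
#'   leave the problem over-determined, nOrth <= min(n - 2, bins - 1)).
#' @param thresholdRule "prior" (default): fixed cutoff at
#'   \code{-mean(coded y)} on the centred response scale, the exact
#'   equivalent of the conventional 0.5 cutoff on a 0/1 dummy-coded
#'   response; when the response carries no class information the
#'   classifier then falls back to the majority class, so a
#'   label-permutation baseline sits at the majority-class proportion.
#'   "midpoint": midpoint of the two class means of the training fitted
#'   response, symmetric to class imbalance.
#' @return An \linkS4class{OPLSModel}.
#' @export
oplsFit <- function(X, y, nOrth = 0,
                    thresholdRule = c("prior", "midpoint")) {
  thresholdRule <- match.arg(thresholdRule)
  cls <- .codeClasses(y)
  if (min(table(y)) < 1) stopf("both classes must be present")
  nOrth <- as.integer(nOrth)
  if (nOrth < 0) stopf("nOrth must be >= 0")
  if (nOrth > min(nrow(X) - 2, ncol(X) - 1))
    stopf("nOrth = %d too large for a %d x %d matrix", nOrth, nrow(X),
          ncol(X))
  ctr <- colMeans(X)
  E <- sweep(X, 2, ctr, "-")
  yc <- cls$coded - mean(cls$coded)
  ## predictive weight from the original centred matrix
  w <- drop(crossprod(E, yc))
  nw <- sqrt(sum(w^2))
  if (nw < .Machine$double.eps^0.5)
    stopf("response carries no covariance with the predictors")
  w <- w / nw
  Wo <- matrix(0, ncol(X), nOrth)
  Po <- matrix(0, ncol(X), nOrth)
  To <- matrix(0, nrow(X), nOrth)
  for (k in seq_len(nOrth)) {
    t <- drop(E %*% w)
    p <- drop(crossprod(E, t)) / sum(t^2)
    wo <- p - drop(crossprod(w, p)) * w
    nwo <- sqrt(sum(wo^2))
    if (nwo < 1e-12 * sqrt(sum(p^2)) || nwo == 0) {
      ## no response-orthogonal structure left: keep a zero component
      next
    }
    wo <- wo / nwo
    to <- drop(E %*% wo)
    po <- drop(crossprod(E, to)) / sum(to^2)
    Wo[, k] <- wo
    Po[, k] <- po
    To[, k] <- to
    E <- E - tcrossprod(to, po)
  }
  t <- drop(E %*% w)
  if (sum(t^2) < .Machine$double.eps)
    stopf("predictive score collapsed; nOrth too large for the data rank")
  p <- drop(crossprod(E, t)) / sum(t^2)
  q <- sum(yc * t) / sum(t^2)
  fitted <- t * q
  thr <- if (thresholdRule == "prior") {
    -mean(cls$coded)
  } else {
    (mean(fitted[cls$coded == -1]) + mean(fitted[cls$coded == 1])) / 2
  }
  new("OPLSModel", center = ctr, yMean = mean(cls$coded),
      predictiveWeights = w, predictiveLoadings = p,
      predictiveScores = t,
      orthogonalWeights = Wo, orthogonalLoadings = Po,
      orthogonalScores = To,
      yLoading = q, nOrth = nOrth, classCoding = cls$coding,
      decisionThreshold = thr)
}

#' Predict with a fitted OPLS model
#'
#' Centres new samples with the training centres, removes the stored
#' orthogonal components, projects on the predictive weights and
#' classifies by the side of the decision threshold (ties at the
#' threshold go to the +1-coded class). Predicting the training matrix
#' reproduces the training fitted responses.
#'
#' @param model an \linkS4class{OPLSModel}.
#' @param X samples x bins matrix on the model's bin dimension, with the
#'   same preprocessing as the training data.
#' @return list with \code{response} (numeric fitted response, centred
#'   scale) and \code{class} (predicted group labels).
#' @export
oplsPredict <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (ncol(X) != length(model@center))
    stopf("dimension mismatch: model has %d bins, data has %d",
          length(model@center), ncol(X))
  E <- sweep(X, 2, model@center, "-")
  for (k in seq_len(model@nOrth)) {
    wo <- model@orthogonalWeights[, k]
    if (all(wo == 0)) next
    to <- drop(E %*% wo)
    E <- E - tcrossprod(to, model@orthogonalLoadings[, k])
  }
  resp <- drop(E %*% model@predictiveWeights) * model@yLoading
  side <- ifelse(resp >= model@decisionThreshold, 1, -1)
  lev <- names(model@classCoding)
  list(response = resp, class = lev[match(side, model@classCoding)])
}

#' Select the number of orthogonal components by inner cross-validation
#'
#' Evaluates k = 0 .. kMax orthogonal components by stratified k-fold
#' cross-validation within the supplied (training) data and returns the
#' k with the highest cross-validated accuracy; ties break toward the
#' smaller, simpler model.
#'
#' @param X samples x bins matrix.
#' @param y two-class labels.
#' @param kMax largest number of orthogonal components to consider.
#' @param innerFolds number of cross-validation folds.
#' @param seed seed for the fold assignment.
#' @param mode scaling mode replayed inside each fold.
#' @return integer in [0, kMax].
#' @export
selectNOrth <- function(X, y, kMax = 3, innerFolds = 7, seed = NULL,
                        mode = "center") {
  if (kMax < 0) stopf("kMax must be >= 0")
  if (kMax == 0) return(0L)
  y <- as.character(y)
  folds <- withLocalSeed(seed, .stratifiedFolds(y, innerFolds))
  acc <- numeric(kMax + 1)
  for (k in 0:kMax) {
    hits <- 0L; tot <- 0L
    for (f in seq_along(folds)) {
      test <- folds[[f]]
      if (length(test) == 0) next
      ytr <- y[-test]
      if (length(unique(ytr)) < 2) next
      kAdm <- min(k, length(ytr) - 2, ncol(X) - 1)
      sc <- centerScale(X[-test, , drop = FALSE], mode)
      fit <- oplsFit(sc$X, ytr, nOrth = kAdm)
      pred <- oplsPredict(fit,
                          applyScaling(sc$record, X[test, , drop = FALSE]))
      hits <- hits + sum(pred$class == y[test])
      tot <- tot + length(test)
    }
    acc[k + 1] <- if (tot > 0) hits / tot else 0
  }
  as.integer(which.max(acc) - 1L)  # which.max takes the first (smallest k) tie
}

## stratified fold assignment: shuffle within class, deal round-robin
.stratifiedFolds <- function(y, nFolds) {
  idx <- seq_along(y)
  folds <- vector("list", nFolds)
  for (cl in unique(y)) {
    members <- sample(idx[y == cl])
    f <- rep(seq_len(nFolds), length.out = length(members))
    for (j in seq_len(nFolds))
      folds[[j]] <- c(folds[[j]], members[f == j])
  }
  folds
}
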