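#' Fit a weighted least-squares regression stump on one feature
#'
#' Exhaustively minimizes \eqn{\sum_i w_i (z_i - f(x_i))^2} over stumps
#' \eqn{f} with thresholds midway between consecutive distinct sorted feature
#' values, the left/right values being the weighted means of \eqn{z} on each
#' side. Ties in the loss are broken toward the smallest threshold. A
#' constant response gives the degenerate stump (left = right = that
#' constant) with its canonical threshold below the feature minimum.
#'
#' @param x numeric feature values.
#' @param z numeric working responses, same length.
#' @param w non-negative weights, same length, with positive total.
#' @return list with \code{threshold}, \code{left}, \code{right} and the
#'   achieved weighted squared-error \code{loss}.
#' @examples
#' fitStumpWeighted(1:4, c(-1, -1, 1, 1), rep(1, 4))  # threshold 2.5
#' @export
fitStumpWeighted <- function(x, z, w) {
  n <- length(x)
  if (length(z) != n || length(w) != n)
    stop("x, z and w must have the same length")
  if (any(w < 0) || sum(w) <= 0)
    stop("weights must be non-negative with positive total")
  W <- sum(w)
  WZ <- sum(w * z)
  WZ2 <- sum(w * z * z)
  if (diff(range(z)) == 0 || diff(range(x)) == 0) {
    m <- WZ / W
    return(list(threshold = min(x) - 1, left = m, right = m,
                loss = WZ2 - W * m^2))
  }
  o <- order(x)
  xs <- x[o]
  cw <- cumsum(w[o])
  cwz <- cumsum((w * z)[o])
  cand <- which(xs[-n] < xs[-1])          # split after position i
  if (length(cand) == 0) {                # unreachable given range check
    m <- WZ / W
    return(list(threshold = min(x) - 1, left = m, right = m,
                loss = WZ2 - W * m^2))
  }
  lw <- cw[cand]
  rw <- W - lw
  lz <- cwz[cand]
  rz <- WZ - lz
  score <- ifelse(lw > 0, lz^2 / lw, 0) + ifelse(rw > 0, rz^2 / rw, 0)
  best <- which.max(score)                # first max = smallest threshold
  i <- cand[best]
  list(
    threshold = (xs[i] + xs[i + 1]) / 2,
    left = if (lw[best] > 0) lz[best] / lw[best] else 0,
    right = if (rw[best] > 0) rz[best] / rw[best] else 0,
    loss = WZ2 - score[best]
  )
}

# One boosting round: scan all features with presorted orders and return the
# best stump. ord/cand are precomputed per feature by fitLogitBoost.
bestStump <- function(X, z, w, ord, cand, xsorted) {
  W <- sum(w)
  wz <- w * z
  WZ <- sum(wz)
  bestScore <- -Inf
  best <- NULL
  for (j in seq_len(ncol(X))) {
    cj <- cand[[j]]
    if (length(cj) == 0) next
    o <- ord[[j]]
    cw <- cumsum(w[o])[cj]
    cwz <- cumsum(wz[o])[cj]
    rw <- W - cw
    rz <- WZ - cwz
    score <- ifelse(cw > 0, cwz^2 / cw, 0) + ifelse(rw > 0, rz^2 / rw, 0)
    k <- which.max(score)
    if (score[k] > bestScore + 1e-12) {
      bestScore <- score[k]
      i <- cj[k]
      xs <- xsorted[[j]]
      best <- list(feature = j, threshold = (xs[i] + xs[i + 1]) / 2,
                   left = if (cw[k] > 0) cwz[k] / cw[k] else 0,
                   right = if (rw[k] > 0) rz[k] / rw[k] else 0)
    }
  }
  if (is.null(best)) {                    # all features constant
    m <- WZ / W
    best <- list(feature = 1L, threshold = min(X[, 1]) - 1, left = m,
                 right = m)
  }
  best
}

#' Fit a binary LogitBoost classifier over decision stumps
#'
#' Stagewise additive logistic regression by Newton steps on the binomial
#' log-likelihood: starting from \eqn{F = 0}, \eqn{p = 1/2}, each iteration
#' computes weights \eqn{w_i = p_i (1 - p_i)} and working responses
#' \eqn{z_i = (y^*_i - p_i) / w_i} (with \eqn{y^* \in \{0, 1\}}, \eqn{z}
#' clamped to \eqn{\pm z_{max}} and \eqn{w} floored at twice machine
#' epsilon), fits the best weighted stump over all features, and updates
#' \eqn{F \leftarrow F + \frac{1}{2} f_m}. Fitting is fully deterministic.
#'
#' Boosting stops early once the training negative log-likelihood improves
#' by less than \code{tol}; on a small marker panel the fit typically
#' saturates well before the default 50 iterations.
#'
#' @param X samples-by-markers numeric matrix (or a
#'   \linkS4class{SummarizedExperiment}, markers in rows, whose assay is
#'   transposed internally).
#' @param y two-class labels (factor, character or 0/1); the second factor
#'   level is the positive class.
#' @param M maximum boosting iterations (default 50).
#' @param zMax working-response clamp (default 4).
#' @param tol early-stopping tolerance on the training negative
#'   log-likelihood (default 1e-6).
#' @return a [LogitBoostModel-class].
#' @examples
#' X <- matrix(c(rnorm(20, 0), rnorm(20, 3)), ncol = 2)
#' y <- rep(c("a", "b"), each = 10)
#' fitLogitBoost(X, y, M = 10)
#' @export
fitLogitBoost <- function(X, y, M = 50, zMax = 4, tol = 1e-6) {
  if (methods::is(X, "SummarizedExperiment")) {
    if (missing(y)) y <- X$cohort
    X <- t(SummarizedExperiment::assay(X))
  }
  X <- as.matrix(X)
  if (anyNA(X)) stop("X must not contain missing values")
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2)
    stop("y must contain exactly two classes")
  if (nrow(X) != length(y))
    stop("nrow(X) must equal length(y)")
  if (M < 0 || M != round(M)) stop("M must be a non-negative integer")
  if (zMax <= 0) stop("zMax must be positive")
  n <- nrow(X)
  ystar <- as.numeric(y == levels(y)[2])
  ord <- lapply(seq_len(ncol(X)), function(j) order(X[, j]))
  xsorted <- lapply(seq_len(ncol(X)), function(j) X[ord[[j]], j])
  cand <- lapply(xsorted, function(xs) which(xs[-n] < xs[-1]))
  Fs <- numeric(n)
  p <- rep(0.5, n)
  nll <- function(p) -sum(ystar * log(p) + (1 - ystar) * log1p(-p))
  nllTrace <- nll(p)
  stumps <- vector("list", M)
  m <- 0L
  wfloor <- 2 * .Machine$double.eps
  while (m < M) {
    w <- pmax(p * (1 - p), wfloor)
    z <- pmin(pmax((ystar - p) / w, -zMax), zMax)
    st <- bestStump(X, z, w, ord, cand, xsorted)
    m <- m + 1L
    stumps[[m]] <- st
    fx <- ifelse(X[, st$feature] <= st$threshold, st$left, st$right)
    Fs <- Fs + 0.5 * fx
    p <- 1 / (1 + exp(-2 * Fs))
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    nllTrace <- c(nllTrace, nll(p))
    if (nllTrace[m] - nllTrace[m + 1] < tol) break
  }
  stumps <- stumps[seq_len(m)]
  sdf <- if (m > 0)
    data.frame(feature = vapply(stumps, `[[`, 0, "feature"),
               threshold = vapply(stumps, `[[`, 0, "threshold"),
               left = vapply(stumps, `[[`, 0, "left"),
               right = vapply(stumps, `[[`, 0, "right"))
  else
    data.frame(feature = integer(), threshold = numeric(),
               left = numeric(), right = numeric())
  fn <- colnames(X)
  if (is.null(fn)) fn <- as.character(seq_len(ncol(X)))
  new("LogitBoostModel", stumps = sdf, featureNames = fn,
      classLabels = levels(y), M = m, zMax = zMax, negLogLik = nllTrace)
}

additiveScore <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(model@featureNames))
    stop("feature count does not match the model")
  Fs <- numeric(nrow(X))
  st <- model@stumps
  for (m in seq_len(nrow(st)))
    Fs <- Fs + 0.5 * ifelse(X[, st$feature[m]] <= st$threshold[m],
                            st$left[m], st$right[m])
  setNames(Fs, rownames(X))
}

#' @describeIn predictPosterior posterior from a samples-by-markers matrix
#' @export
setMethod("predictPosterior", signature("LogitBoostModel", "matrix"),
  function(model, X, ...) {
    Fs <- additiveScore(model, X)
    1 / (1 + exp(-2 * Fs))
  })

#' @describeIn predictPosterior posterior from a SummarizedExperiment
#'   (markers in rows)
#' @export
setMethod("predictPosterior",
  signature("LogitBoostModel", "SummarizedExperiment"),
  function(model, X, ...) {
    predictPosterior(model, t(SummarizedExperiment::assay(X)))
  })

#' @describeIn predictPosterior the additive score F(x) itself
#' @export
setMethod("diagnosticScore", signature("LogitBoostModel", "matrix"),
  function(model, X, ...) additiveScore(model, X))

#' Leave-one-out cross-validated posterior probabilities
#'
#' For each sample, the whole procedure — including the optional marker
#' pre-selection — is refit on the other n - 1 samples and the held-out
#' sample's posterior recorded, so no information about the left-out label
#' leaks into its prediction. Folds whose training set loses a class
#' entirely are flagged (posterior NA, recorded in the \code{flagged}
#' attribute) rather than silently skipped.
#'
#' @param X samples-by-markers matrix (or SummarizedExperiment, markers in
#'   rows).
#' @param y two-class labels.
#' @param M,zMax passed to [fitLogitBoost()].
#' @param preselect optional number of markers to keep per fold, chosen by
#'   smallest moderated-t p-value on the training fold only; NULL (default)
#'   uses the full panel.
#' @return named numeric vector of held-out posteriors (positive class),
#'   with attribute \code{flagged} naming any undecidable folds.
#' @export
loocvPosteriors <- function(X, y, M = 50, zMax = 4, preselect = NULL) {
  if (methods::is(X, "SummarizedExperiment")) {
    if (missing(y)) y <- X$cohort
    X <- t(SummarizedExperiment::assay(X))
  }
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  n <- nrow(X)
  if (n < 4) stop("need at least 4 samples for LOOCV")
  if (any(table(y) < 2)) stop("each class needs at least 2 members")
  post <- setNames(rep(NA_real_, n),
                   rownames(X) %||% as.character(seq_len(n)))
  flagged <- character()
  for (i in seq_len(n)) {
    ytr <- droplevels(y[-i])
    if (nlevels(ytr) < 2) {
      flagged <- c(flagged, names(post)[i])
      next
    }
    Xtr <- X[-i, , drop = FALSE]
    keep <- seq_len(ncol(X))
    if (!is.null(preselect) && preselect < ncol(X)) {
      scr <- moderatedT(t(Xtr), ytr)
      keep <- order(scr$p)[seq_len(preselect)]
    }
    fit <- fitLogitBoost(Xtr[, keep, drop = FALSE], ytr, M = M, zMax = zMax)
    post[i] <- predictPosterior(fit, X[i, keep, drop = FALSE])
  }
  attr(post, "flagged") <- flagged
  post
}

`%||%` <- function(a, b) if (is.null(a)) b else a
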