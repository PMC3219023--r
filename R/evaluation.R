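# Coerce (X, y) from either a samples-by-markers matrix + labels or a
# SummarizedExperiment (markers in rows, cohort in colData).
coerceXy <- function(X, y) {
  if (methods::is(X, "SummarizedExperiment")) {
    if (is.null(y)) y <- X$cohort
    X <- t(SummarizedExperiment::assay(X))
  }
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2) stop("labels must define exactly two classes")
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)")
  list(X = X, y = y)
}

# Rank/Mann-Whitney AUC; ties contribute 1/2. pos is logical.
aucValue <- function(scores, pos) {
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve and AUC for a diagnostic index
#'
#' Computes the receiver operating characteristic curve of continuous scores
#' against two-class labels (second factor level = positive class) and its
#' area by the rank (Mann-Whitney) method, in which a tied positive-negative
#' pair contributes 1/2: AUC is exactly the probability that a random
#' positive outscores a random negative, ties half-counted.
#'
#' @param scores numeric diagnostic scores (higher = more positive).
#' @param labels two-class labels.
#' @return a [ROCCurve-class].
#' @examples
#' auc(rocAuc(c(.9, .8, .3, .2), c("pos", "pos", "neg", "neg")))
#' @export
rocAuc <- function(scores, labels) {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2)
    stop("labels must contain exactly two classes")
  if (length(scores) != length(labels))
    stop("scores and labels must have the same length")
  pos <- labels == levels(labels)[2]
  a <- aucValue(scores, pos)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  p <- pos[o]
  last <- c(s[-1] != s[-length(s)], TRUE)   # end of each tie group
  tp <- cumsum(p)[last]
  fp <- cumsum(!p)[last]
  new("ROCCurve",
      fpr = c(0, fp / sum(!pos)), tpr = c(0, tp / sum(pos)),
      auc = a, nPositive = sum(pos), nNegative = sum(!pos))
}

#' Random train/validation partitioning scheme
#'
#' @param B number of random partitions (default 500, the protocol used for
#'   the reported AUC distributions).
#' @param trainFraction fraction of samples used for training, in (0, 1)
#'   (default 2/3).
#' @param stratified draw the split within each class (default TRUE);
#'   required for small cohorts so both halves keep both classes.
#' @param seed integer root seed for the partition stream.
#' @return validated list of the four settings.
#' @export
partitionScheme <- function(B = 500, trainFraction = 2 / 3,
                            stratified = TRUE, seed = 1) {
  if (B < 1 || B != round(B)) stop("B must be a positive integer")
  if (trainFraction <= 0 || trainFraction >= 1)
    stop("trainFraction must lie strictly in (0, 1)")
  list(B = as.integer(B), trainFraction = trainFraction,
       stratified = isTRUE(stratified), seed = as.integer(seed))
}

# One train/validation split as a logical "in training set" vector. Every
# split must leave >= 2 members of each class on both sides; non-stratified
# draws are redrawn until they do.
drawPartition <- function(y, scheme) {
  n <- length(y)
  if (scheme$stratified) {
    train <- logical(n)
    for (lev in levels(y)) {
      idx <- which(y == lev)
      k <- round(scheme$trainFraction * length(idx))
      k <- min(max(k, 2L), length(idx) - 2L)
      if (k < 2 || length(idx) - k < 2)
        stop("infeasible stratification: class ", lev, " has only ",
             length(idx), " members")
      train[sample(idx, k)] <- TRUE
    }
    return(train)
  }
  for (attempt in 1:1000) {
    train <- logical(n)
    train[sample(n, round(scheme$trainFraction * n))] <- TRUE
    if (all(table(y[train]) >= 2) && all(table(y[!train]) >= 2) &&
        nlevels(droplevels(y[train])) == 2 &&
        nlevels(droplevels(y[!train])) == 2)
      return(train)
  }
  stop("could not draw a partition keeping 2 of each class in both halves")
}

#' Repeated random-partition evaluation of the LogitBoost diagnostic
#'
#' For each of B random train/validation partitions: fit LogitBoost on the
#' training half, compute validation posteriors, and record the validation
#' AUC. The mean and SD of the resulting AUC sample are the headline
#' diagnostic-performance summaries. Deterministic given the scheme's seed.
#'
#' @param X samples-by-markers matrix or \linkS4class{SummarizedExperiment}
#'   (markers in rows).
#' @param y two-class labels (taken from \code{colData(X)$cohort} when X is a
#'   SummarizedExperiment and y is NULL).
#' @param scheme a [partitionScheme()].
#' @param M,zMax classifier settings, passed to [fitLogitBoost()].
#' @param comparison label stored in the result, e.g. "Sepsis Vs PS".
#' @return an [EvaluationResult-class] with the observed AUC sample.
#' @export
repeatedPartitionEval <- function(X, y = NULL, scheme = partitionScheme(),
                                  M = 50, zMax = 4,
                                  comparison = "group1 Vs group2") {
  d <- coerceXy(X, y)
  aucs <- withSeed(scheme$seed, vapply(seq_len(scheme$B), function(b) {
    train <- drawPartition(d$y, scheme)
    fit <- fitLogitBoost(d$X[train, , drop = FALSE], d$y[train],
                         M = M, zMax = zMax)
    post <- predictPosterior(fit, d$X[!train, , drop = FALSE])
    aucValue(post, d$y[!train] == levels(d$y)[2])
  }, numeric(1)))
  new("EvaluationResult", comparison = comparison,
      panelSize = ncol(d$X), auc = aucs, seed = scheme$seed)
}

#' Label-permutation null distribution and empirical p-value
#'
#' Repeats the partition-fit-score cycle B times with the cohort labels
#' freshly and uniformly permuted before each split, destroying any true
#' association while preserving class sizes. The null AUC distribution
#' centres at 0.5 for an unbiased procedure. When an observed result is
#' supplied, the one-sided add-one empirical p-value
#' \eqn{p = (1 + \#\{AUC_{null} \ge \bar{AUC}_{obs}\}) / (B + 1)} is
#' attached; its floor 1/(B + 1) (about 0.002 at B = 500) is the smallest
#' attainable p. The null stream is seeded independently of the observed
#' stream (a fixed offset of the scheme seed), so the two runs are
#' separately reproducible.
#'
#' @inheritParams repeatedPartitionEval
#' @param observed an [EvaluationResult-class] from
#'   [repeatedPartitionEval()] on the same data (its observed sample and
#'   comparison label are carried over), or a single numeric observed mean
#'   AUC, or NULL for a null-only run.
#' @return an [EvaluationResult-class] holding the null AUC sample (and the
#'   observed sample plus empirical p when \code{observed} was given).
#' @export
permutationNull <- function(X, y = NULL, scheme = partitionScheme(),
                            M = 50, zMax = 4, observed = NULL,
                            comparison = "group1 Vs group2") {
  d <- coerceXy(X, y)
  nulls <- withSeed((scheme$seed + 999983L) %% .Machine$integer.max,
    vapply(seq_len(scheme$B), function(b) {
      yp <- sample(d$y)
      train <- drawPartition(yp, scheme)
      fit <- fitLogitBoost(d$X[train, , drop = FALSE], yp[train],
                           M = M, zMax = zMax)
      post <- predictPosterior(fit, d$X[!train, , drop = FALSE])
      aucValue(post, yp[!train] == levels(d$y)[2])
    }, numeric(1)))
  obsAuc <- numeric()
  pval <- NA_real_
  if (methods::is(observed, "EvaluationResult")) {
    obsAuc <- aucSample(observed)
    comparison <- observed@comparison
    pval <- (1 + sum(nulls >= mean(obsAuc))) / (scheme$B + 1)
  } else if (is.numeric(observed) && length(observed) == 1) {
    pval <- (1 + sum(nulls >= observed)) / (scheme$B + 1)
  }
  new("EvaluationResult", comparison = comparison,
      panelSize = ncol(d$X), auc = obsAuc, nullAuc = nulls,
      pValue = pval, seed = scheme$seed)
}

#' Evaluate a restricted marker sub-panel
#'
#' Runs the identical repeated-partition pipeline on a subset of markers,
#' enabling full-panel versus sub-panel (e.g. 42 vs 7) comparisons.
#'
#' @inheritParams repeatedPartitionEval
#' @param markers character marker ids (matched against column names) or
#'   integer column indices; must be non-empty and present.
#' @return an [EvaluationResult-class] with \code{panelSize} equal to the
#'   subset size.
#' @export
subsetPanelEval <- function(X, y = NULL, markers, scheme = partitionScheme(),
                            M = 50, zMax = 4,
                            comparison = "group1 Vs group2") {
  d <- coerceXy(X, y)
  if (length(markers) == 0) stop("marker subset must be non-empty")
  if (is.character(markers)) {
    missing <- setdiff(markers, colnames(d$X))
    if (length(missing))
      stop("unknown marker id(s): ", paste(missing, collapse = ", "))
  } else if (any(markers < 1 | markers > ncol(d$X))) {
    stop("marker indices out of range")
  }
  repeatedPartitionEval(d$X[, markers, drop = FALSE], d$y, scheme,
                        M = M, zMax = zMax, comparison = comparison)
}

#' Principal-component score projection of an expression matrix
#'
#' Column-centred singular-value projection of the samples-by-markers
#' matrix: component variances are non-increasing and directions mutually
#' orthogonal; using all components reconstructs the centred matrix exactly.
#' Used to visualize cohort separation.
#'
#' @param X samples-by-markers matrix or SummarizedExperiment (markers in
#'   rows).
#' @param nComponents number of components to return; at most
#'   \code{min(n samples, n markers)}.
#' @return list with \code{scores} (samples x nComponents), \code{sdev}
#'   (all singular values / sqrt(n - 1)), \code{rotation} and \code{center}.
#' @export
pcaScores <- function(X, nComponents = 2) {
  if (methods::is(X, "SummarizedExperiment"))
    X <- t(SummarizedExperiment::assay(X))
  X <- as.matrix(X)
  if (nComponents < 1 || nComponents > min(dim(X)))
    stop("nComponents must lie in [1, min(n samples, n markers)]")
  pr <- prcomp(X, center = TRUE, scale. = FALSE)
  list(scores = pr$x[, seq_len(nComponents), drop = FALSE],
       sdev = pr$sdev, rotation = pr$rotation, center = pr$center)
}

formatPValue <- function(p, B) {
  if (is.na(p)) return(NA_character_)
  floorP <- 1 / (B + 1)
  if (p <= floorP + 1e-12) sprintf("< %.3g", signif(floorP, 1))
  else sprintf("%.4g", p)
}

#' Summarize evaluation results as a report table
#'
#' One row per comparison/panel combination with columns Comparison,
#' Biomarker Set, Mean, SD and P-value. The p-value is printed as
#' "< 1/(B + 1)" (e.g. "< 0.002" at B = 500) when no permutation-null AUC
#' reached the observed mean.
#'
#' @param results list of [EvaluationResult-class] objects.
#' @return data.frame with the five report columns (header only when the
#'   input is empty).
#' @export
summarizeTable <- function(results) {
  if (methods::is(results, "EvaluationResult")) results <- list(results)
  rows <- lapply(results, function(r) {
    data.frame(
      Comparison = r@comparison,
      `Biomarker Set` = r@panelSize,
      Mean = mean(r@auc),
      SD = sd(r@auc),
      `P-value` = formatPValue(r@pValue, length(r@nullAuc)),
      check.names = FALSE, stringsAsFactors = FALSE
    )
  })
  if (length(rows) == 0)
    return(data.frame(Comparison = character(), `Biomarker Set` = integer(),
                      Mean = numeric(), SD = numeric(),
                      `P-value` = character(), check.names = FALSE))
  do.call(rbind, rows)
}
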