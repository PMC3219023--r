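#' @import methods
#' @importFrom stats rnorm runif sd var median quantile pt setNames prcomp
#'   p.adjust
NULL

#' LogitBoostModel: an additive ensemble of weighted regression stumps
#'
#' Binary LogitBoost fits an additive score \eqn{F(x) = \sum_m \frac{1}{2}
#' f_m(x)} by Newton steps on the binomial log-likelihood, each step fitting a
#' weighted least-squares decision stump \eqn{f_m}. The posterior probability
#' of the positive class, \eqn{p(x) = 1/(1 + e^{-2F(x)})}, is the diagnostic
#' index. With zero iterations every posterior is 1/2.
#'
#' @slot stumps data.frame with one row per boosting iteration and columns
#'   \code{feature} (column index into the training matrix), \code{threshold},
#'   \code{left}, \code{right}: the stump predicts \code{left} when the
#'   feature value is \code{<= threshold}, else \code{right}.
#' @slot featureNames character, the training feature (marker) names, used to
#'   check prediction inputs.
#' @slot classLabels character of length 2: negative then positive class.
#' @slot M integer, number of boosting iterations actually performed.
#' @slot zMax numeric, clamp applied to the working response during fitting.
#' @slot negLogLik numeric, training negative log-likelihood after each
#'   iteration (element 1 is the value at initialization, F = 0).
#'
#' @seealso [fitLogitBoost()], [predictPosterior()]
#' @export
setClass("LogitBoostModel",
  representation(
    stumps = "data.frame",
    featureNames = "character",
    classLabels = "character",
    M = "integer",
    zMax = "numeric",
    negLogLik = "numeric"
  )
)

setValidity("LogitBoostModel", function(object) {
  msg <- character()
  need <- c("feature", "threshold", "left", "right")
  if (!all(need %in% names(object@stumps)))
    msg <- c(msg, "stumps must have columns feature, threshold, left, right")
  if (nrow(object@stumps) != object@M)
    msg <- c(msg, "M must equal the number of stumps")
  if (length(object@classLabels) != 2L)
    msg <- c(msg, "classLabels must have length 2")
  if (length(object@zMax) != 1L || object@zMax <= 0)
    msg <- c(msg, "zMax must be a single positive number")
  if (nrow(object@stumps) > 0 &&
      (any(object@stumps$feature < 1) ||
       any(object@stumps$feature > length(object@featureNames))))
    msg <- c(msg, "stump feature indices out of range")
  if (length(msg)) msg else TRUE
})

#' ROCCurve: a receiver operating characteristic curve with its AUC
#'
#' The curve starts at (0, 0), ends at (1, 1), and both coordinate sequences
#' are non-decreasing. The AUC is computed by the rank (Mann-Whitney) method,
#' so tied score pairs contribute 1/2.
#'
#' @slot fpr,tpr numeric, false/true positive rates at each score threshold
#'   (thresholds descending).
#' @slot auc numeric in \[0, 1\].
#' @slot nPositive,nNegative integer class counts.
#'
#' @seealso [rocAuc()]
#' @export
setClass("ROCCurve",
  representation(
    fpr = "numeric", tpr = "numeric", auc = "numeric",
    nPositive = "integer", nNegative = "integer"
  )
)

setValidity("ROCCurve", function(object) {
  msg <- character()
  if (length(object@fpr) != length(object@tpr))
    msg <- c(msg, "fpr and tpr must have the same length")
  if (is.unsorted(object@fpr) || is.unsorted(object@tpr))
    msg <- c(msg, "fpr and tpr must be non-decreasing")
  if (object@auc < 0 || object@auc > 1)
    msg <- c(msg, "auc must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' EvaluationResult: AUC distributions from repeated random partitioning
#'
#' Holds the observed validation-AUC sample over B random train/validation
#' partitions and, when a permutation null has been run, the B-element null
#' AUC sample together with the add-one empirical p-value
#' \eqn{p = (1 + \#\{AUC_{null} \ge \bar{AUC}_{obs}\})/(B + 1)}.
#'
#' @slot comparison character label, e.g. "Sepsis Vs PS".
#' @slot panelSize integer, number of markers used.
#' @slot auc numeric, observed validation AUCs (length B; may be empty for a
#'   null-only result).
#' @slot nullAuc numeric, permutation-null AUCs (length 0 if not run).
#' @slot pValue numeric, empirical p (NA until the null is attached).
#' @slot seed integer, root seed of the run.
#'
#' @seealso [repeatedPartitionEval()], [permutationNull()], [summarizeTable()]
#' @export
setClass("EvaluationResult",
  representation(
    comparison = "character",
    panelSize = "integer",
    auc = "numeric",
    nullAuc = "numeric",
    pValue = "numeric",
    seed = "integer"
  ),
  prototype(nullAuc = numeric(), pValue = NA_real_, seed = NA_integer_)
)

setValidity("EvaluationResult", function(object) {
  msg <- character()
  if (any(object@auc < 0 | object@auc > 1, na.rm = TRUE))
    msg <- c(msg, "observed AUCs must lie in [0, 1]")
  if (any(object@nullAuc < 0 | object@nullAuc > 1, na.rm = TRUE))
    msg <- c(msg, "null AUCs must lie in [0, 1]")
  if (!is.na(object@pValue) && length(object@nullAuc) > 0 &&
      object@pValue < 1 / (length(object@nullAuc) + 1) - 1e-12)
    msg <- c(msg, "empirical p cannot be below 1/(B + 1)")
  if (length(msg)) msg else TRUE
})

#' PlateQC: positive/negative control check for one PCR plate
#'
#' A plate passes when every negative-control well fails to amplify (no
#' take-off detected) and every positive-control well amplifies, and the
#' expected numbers of control wells are present (five of each by default).
#'
#' @slot negativePass,positivePass logical flags.
#' @slot nNegative,nPositive integer, control wells found.
#' @slot reasons character, human-readable failure reasons (empty on pass).
#'
#' @seealso [plateQC()]
#' @export
setClass("PlateQC",
  representation(
    negativePass = "logical", positivePass = "logical",
    nNegative = "integer", nPositive = "integer",
    reasons = "character"
  )
)
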