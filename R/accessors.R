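#' @describeIn EvaluationResult-accessors observed AUC sample
#' @export
setMethod("aucSample", "EvaluationResult", function(object) object@auc)

#' @describeIn EvaluationResult-accessors permutation-null AUC sample
#' @export
setMethod("nullSample", "EvaluationResult", function(object) object@nullAuc)

#' @describeIn EvaluationResult-accessors mean observed AUC
#' @export
setMethod("meanAuc", "EvaluationResult", function(object) mean(object@auc))

#' @describeIn EvaluationResult-accessors SD of the observed AUC sample
#' @export
setMethod("sdAuc", "EvaluationResult", function(object) sd(object@auc))

#' @describeIn EvaluationResult-accessors empirical p-value
#' @export
setMethod("pValue", "EvaluationResult", function(object) object@pValue)

#' @rdname auc
#' @export
setMethod("auc", "ROCCurve", function(object) object@auc)

#' @rdname qcPassed
#' @export
setMethod("qcPassed", "PlateQC", function(object)
  isTRUE(object@negativePass) && isTRUE(object@positivePass))

#' @rdname nIterations
#' @export
setMethod("nIterations", "LogitBoostModel", function(object) object@M)

setMethod("show", "LogitBoostModel", function(object) {
  cat("LogitBoostModel with", object@M, "stump(s) over",
      length(object@featureNames), "feature(s)\n")
  cat("  classes:", object@classLabels[1], "(negative) vs",
      object@classLabels[2], "(positive)\n")
  if (object@M > 0) {
    used <- sort(unique(object@featureNames[object@stumps$feature]))
    cat("  features used:", length(used), "\n")
    cat("  final training neg. log-likelihood:",
        format(utils::tail(object@negLogLik, 1), digits = 6), "\n")
  }
  invisible(object)
})

setMethod("show", "ROCCurve", function(object) {
  cat("ROCCurve:", object@nPositive, "positive vs", object@nNegative,
      "negative samples\n")
  cat("  AUC =", format(object@auc, digits = 4), "\n")
  invisible(object)
})

setMethod("show", "EvaluationResult", function(object) {
  cat("EvaluationResult:", object@comparison,
      sprintf("(panel of %d markers)\n", object@panelSize))
  if (length(object@auc))
    cat(sprintf("  observed AUC over %d partitions: mean %.3f, SD %.4f\n",
                length(object@auc), mean(object@auc), sd(object@auc)))
  if (length(object@nullAuc))
    cat(sprintf("  permutation null over %d iterations: mean %.3f; p %s\n",
                length(object@nullAuc), mean(object@nullAuc),
                formatPValue(object@pValue, length(object@nullAuc))))
  invisible(object)
})

setMethod("show", "PlateQC", function(object) {
  cat("PlateQC:", if (qcPassed(object)) "PASS" else "FAIL", "\n")
  cat(sprintf("  negative controls (%d found): %s\n", object@nNegative,
              if (object@negativePass) "all silent" else "FAILED"))
  cat(sprintf("  positive controls (%d found): %s\n", object@nPositive,
              if (object@positivePass) "all amplified" else "FAILED"))
  for (r in object@reasons) cat("  -", r, "\n")
  invisible(object)
})
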