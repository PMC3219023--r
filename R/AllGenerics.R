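#' Posterior probabilities from a fitted LogitBoost model
#'
#' @param model a [LogitBoostModel-class].
#' @param X samples-by-markers numeric matrix, or a
#'   \linkS4class{SummarizedExperiment} (markers in rows) whose assay is used.
#' @param ... passed to methods.
#' @return named numeric vector of posterior probabilities of the positive
#'   class, one per sample, each strictly inside (0, 1).
#' @export
setGeneric("predictPosterior", function(model, X, ...)
  standardGeneric("predictPosterior"))

#' @rdname predictPosterior
#' @export
setGeneric("diagnosticScore", function(model, X, ...)
  standardGeneric("diagnosticScore"))

#' Accessors for evaluation results
#'
#' `aucSample()` / `nullSample()` return the stored observed / permutation-null
#' validation AUC samples; `meanAuc()` and `sdAuc()` summarize the observed
#' sample; `pValue()` returns the add-one empirical p-value (NA when no null
#' has been attached).
#'
#' @param object an [EvaluationResult-class].
#' @return numeric.
#' @name EvaluationResult-accessors
#' @export
setGeneric("aucSample", function(object) standardGeneric("aucSample"))

#' @rdname EvaluationResult-accessors
#' @export
setGeneric("nullSample", function(object) standardGeneric("nullSample"))

#' @rdname EvaluationResult-accessors
#' @export
setGeneric("meanAuc", function(object) standardGeneric("meanAuc"))

#' @rdname EvaluationResult-accessors
#' @export
setGeneric("sdAuc", function(object) standardGeneric("sdAuc"))

#' @rdname EvaluationResult-accessors
#' @export
setGeneric("pValue", function(object) standardGeneric("pValue"))

#' Area under an ROC curve
#'
#' @param object a [ROCCurve-class].
#' @return numeric scalar in \[0, 1\].
#' @export
setGeneric("auc", function(object) standardGeneric("auc"))

#' Did a plate pass quality control?
#'
#' @param object a [PlateQC-class].
#' @return logical scalar: TRUE iff both the negative- and positive-control
#'   checks passed.
#' @export
setGeneric("qcPassed", function(object) standardGeneric("qcPassed"))

#' Number of boosting iterations in a model
#'
#' @param object a [LogitBoostModel-class].
#' @return integer scalar.
#' @export
setGeneric("nIterations", function(object) standardGeneric("nIterations"))
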