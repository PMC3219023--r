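#' Microarray-style inclusion filter
#'
#' Keeps a marker when its signal exceeds \code{signalThreshold} AND its fold
#' change exceeds \code{foldChangeThreshold}, both strictly. By default fold
#' change is treated symmetrically — \code{max(fc, 1/fc)} — so two-fold
#' down-regulation also passes; set \code{symmetric = FALSE} to require
#' up-regulation.
#'
#' @param signal non-negative expression signal (vectorized).
#' @param foldChange positive fold-change ratio (vectorized).
#' @param signalThreshold default 100.
#' @param foldChangeThreshold default 2.
#' @param symmetric treat down-regulation like up-regulation (default TRUE).
#' @return logical vector: TRUE = keep.
#' @examples
#' expressionFilter(150, 2.5)   # TRUE
#' expressionFilter(100, 3.0)   # FALSE: boundaries are strict
#' @export
expressionFilter <- function(signal, foldChange, signalThreshold = 100,
                             foldChangeThreshold = 2, symmetric = TRUE) {
  if (signalThreshold <= 0 || foldChangeThreshold <= 0)
    stop("thresholds must be strictly positive")
  if (any(signal < 0)) stop("signal must be non-negative")
  if (any(foldChange <= 0)) stop("foldChange must be positive")
  fc <- if (symmetric) pmax(foldChange, 1 / foldChange) else foldChange
  signal > signalThreshold & fc > foldChangeThreshold
}

#' Moderated two-sample t statistics with empirical-Bayes variance shrinkage
#'
#' For each marker the pooled two-group variance \eqn{s^2} (residual df
#' \eqn{d = n_1 + n_2 - 2}) is shrunk toward a prior:
#' \deqn{\tilde s^2 = (d_0 s_0^2 + d s^2) / (d_0 + d)}
#' and the moderated statistic
#' \eqn{\tilde t = (\bar x_1 - \bar x_2) / (\tilde s \sqrt{1/n_1 + 1/n_2})}
#' is referred to a t distribution on \eqn{d_0 + d} degrees of freedom. With
#' \eqn{d_0 = 0} this is exactly the ordinary pooled-variance t test.
#'
#' When \code{d0} and \code{s02} are not supplied they are estimated by the
#' method of moments from the marker-wise \eqn{s^2} values, using the mean
#' and variance of the scaled-F marginal distribution of \eqn{s^2} (see the
#' package vignette); over/under-dispersion degenerate cases fall back to a
#' very large \eqn{d_0} (complete shrinkage to the mean variance).
#'
#' @param x markers-by-samples numeric matrix of (log2) expression, or a
#'   \linkS4class{SummarizedExperiment} whose first assay is used.
#' @param labels two-level factor (or coercible) over the samples.
#' @param d0 prior degrees of freedom (>= 0), or NULL to estimate.
#' @param s02 prior variance (> 0), or NULL to estimate.
#' @return data.frame with one row per marker: \code{marker_id},
#'   \code{mean1}, \code{mean2} (group means, first level = group 1),
#'   \code{s} (pooled SD), \code{sTilde} (moderated SD), \code{t} (moderated
#'   statistic, mean1 - mean2 orientation), \code{df}, \code{p} (two-sided)
#'   and \code{p_holm}.
#' @export
moderatedT <- function(x, labels, d0 = NULL, s02 = NULL) {
  if (methods::is(x, "SummarizedExperiment")) {
    labels <- if (missing(labels)) x$cohort else labels
    x <- SummarizedExperiment::assay(x)
  }
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2)
    stop("labels must define exactly two groups")
  g1 <- labels == levels(labels)[1]
  n1 <- sum(g1); n2 <- sum(!g1)
  if (n1 < 2 || n2 < 2)
    stop("each group needs at least 2 samples")
  m1 <- rowMeans(x[, g1, drop = FALSE])
  m2 <- rowMeans(x[, !g1, drop = FALSE])
  ss1 <- rowSums((x[, g1, drop = FALSE] - m1)^2)
  ss2 <- rowSums((x[, !g1, drop = FALSE] - m2)^2)
  d <- n1 + n2 - 2
  s2 <- (ss1 + ss2) / d
  if (is.null(d0) || is.null(s02)) {
    est <- estimatePriorMoments(s2, d)
    if (is.null(d0)) d0 <- est$d0
    if (is.null(s02)) s02 <- est$s02
  }
  if (d0 < 0) stop("d0 must be >= 0")
  if (s02 <= 0) stop("s02 must be > 0")
  s2tilde <- (d0 * s02 + d * s2) / (d0 + d)
  tstat <- (m1 - m2) / sqrt(s2tilde * (1 / n1 + 1 / n2))
  df <- d0 + d
  p <- 2 * pt(-abs(tstat), df = df)
  data.frame(
    marker_id = if (is.null(rownames(x))) as.character(seq_len(nrow(x)))
                else rownames(x),
    mean1 = m1, mean2 = m2, s = sqrt(s2), sTilde = sqrt(s2tilde),
    t = tstat, df = df, p = p, p_holm = holmAdjust(p),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

# Method-of-moments hyperparameters for the scaled-F marginal of s^2:
# s^2 / s0^2 ~ F(d, d0), so E[s^2] = s0^2 d0/(d0-2) and
# Var/E^2 = 2 (d + d0 - 2) / (d (d0 - 4)). Solving the second for d0 and
# back-substituting gives the estimates; r d <= 2 (under-dispersion) means
# effectively infinite prior df.
estimatePriorMoments <- function(s2, d) {
  m <- mean(s2)
  v <- var(s2)
  if (length(s2) < 3 || !is.finite(v) || v <= 0 || m <= 0)
    return(list(d0 = 1e6, s02 = max(m, .Machine$double.eps)))
  r <- v / m^2
  if (r * d <= 2) return(list(d0 = 1e6, s02 = m))
  d0 <- (4 * r * d + 2 * d - 4) / (r * d - 2)
  if (!is.finite(d0) || d0 <= 4) d0 <- 4.001  # moment solution needs d0 > 4
  list(d0 = d0, s02 = m * (d0 - 2) / d0)
}

#' Holm step-down multiple-testing adjustment
#'
#' Step-down family-wise-error control: with raw p-values sorted ascending,
#' the i-th adjusted value is \eqn{\max_{j \le i} \min(1, (m - j + 1)
#' p_{(j)})}, returned in the original order. Uniformly dominates Bonferroni.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same length and order.
#' @examples
#' holmAdjust(c(0.01, 0.04))  # 0.02, 0.04
#' @export
holmAdjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "holm")
}
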