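#' Take-off cycle by the second-derivative-maximum method
#'
#' Locates the point of peak cycling acceleration of an amplification curve:
#' the maximum of the discrete second difference of the (optionally smoothed)
#' fluorescence series, refined to sub-cycle resolution by a quadratic fit
#' through the peak and its two neighbours. This is the standard
#' second-derivative-maximum Cq and serves as the Ct-equivalent entering the
#' relative-quantification ratio.
#'
#' A well is called NOT_DETECTED (returned as \code{NA}) when the peak second
#' difference does not exceed 5 times the median absolute second difference
#' over the first 10 cycles — a baseline-relative rule that keeps flat
#' negative-control traces undetected even under noise.
#'
#' @param fluorescence numeric fluorescence series.
#' @param cycles strictly increasing integer cycle numbers (default
#'   \code{seq_along(fluorescence)}); at least 10 are required.
#' @param smoothingWindow odd width of a centered moving-average smoother
#'   applied before differencing; 1 (default) disables smoothing.
#' @return take-off cycle as a single numeric, or \code{NA_real_} when no
#'   amplification is detected.
#' @examples
#' cyc <- 1:40
#' f <- 0.5 + 10 / (1 + exp(-0.8 * (cyc - 25)))
#' takeoffCycle(f, cyc)  # close to 25 - log(2 + sqrt(3)) / 0.8
#' @export
takeoffCycle <- function(fluorescence, cycles = seq_along(fluorescence),
                         smoothingWindow = 1) {
  if (length(fluorescence) != length(cycles))
    stop("fluorescence and cycles must have the same length")
  if (length(cycles) < 10)
    stop("a curve needs at least 10 cycles")
  if (any(diff(cycles) <= 0))
    stop("cycles must be strictly increasing")
  y <- as.numeric(fluorescence)
  if (smoothingWindow > 1) {
    if (smoothingWindow %% 2 == 0) stop("smoothingWindow must be odd")
    sm <- stats::filter(y, rep(1 / smoothingWindow, smoothingWindow),
                        sides = 2)
    keep <- !is.na(sm)
    y <- as.numeric(sm[keep])
    cycles <- cycles[keep]
  }
  n <- length(y)
  d2 <- y[3:n] - 2 * y[2:(n - 1)] + y[1:(n - 2)]   # at cycles[2..n-1]
  baseIdx <- which(cycles[2:(n - 1)] <= cycles[1] + 9)
  if (length(baseIdx) == 0) baseIdx <- seq_len(min(8L, length(d2)))
  noiseScale <- median(abs(d2[baseIdx]))
  j <- which.max(d2)
  if (!(d2[j] > 5 * noiseScale)) return(NA_real_)
  peakCycle <- cycles[j + 1]
  if (j > 1 && j < length(d2)) {
    denom <- d2[j - 1] - 2 * d2[j] + d2[j + 1]
    if (denom < 0) {
      offset <- 0.5 * (d2[j - 1] - d2[j + 1]) / denom
      step <- (cycles[j + 2] - cycles[j]) / 2
      peakCycle <- peakCycle + offset * step
    }
  }
  peakCycle
}

#' Efficiency-corrected relative fold change (Pfaffl ratio)
#'
#' \deqn{FC = E_{target}^{\Delta Ct_{target}} / E_{norm}^{\Delta Ct_{norm}}}
#' with \eqn{\Delta Ct} oriented as (reference take-off − sample take-off),
#' so that higher expression in the sample (earlier take-off) gives a fold
#' change above 1. With both efficiencies equal to 2 this reduces exactly to
#' the classic \eqn{2^{-\Delta\Delta Ct}}.
#'
#' @param dctTarget,dctNorm \eqn{\Delta Ct} of the target and of the
#'   (combined) normalizer, in cycles.
#' @param eTarget,eNorm amplification efficiencies, each in (1, 2]; 2 means
#'   perfect per-cycle doubling (default).
#' @return positive numeric fold change (vectorized over its arguments).
#' @examples
#' pfafflFoldChange(1, 0)                 # one extra doubling: 2
#' pfafflFoldChange(2.5, 0.5, 1.9, 2.0)   # 1.9^2.5 / 2^0.5
#' @export
pfafflFoldChange <- function(dctTarget, dctNorm, eTarget = 2, eNorm = 2) {
  if (any(eTarget <= 1 | eTarget > 2) || any(eNorm <= 1 | eNorm > 2))
    stop("efficiencies must lie in (1, 2]")
  eTarget^dctTarget / eNorm^dctNorm
}

#' Combine reference-gene ratios by their geometric mean
#'
#' The accepted convention for multi-reference-gene normalization: the
#' combined normalization factor is the geometric mean of the individual
#' reference-gene fold changes, which is invariant to input order and
#' scale-consistent (scaling every input by a constant scales the result by
#' the same constant).
#'
#' @param x non-empty numeric vector of positive fold changes.
#' @return positive numeric scalar, \code{exp(mean(log(x)))}.
#' @examples
#' combineNormalizers(c(1, 1, 8))  # 2
#' @export
combineNormalizers <- function(x) {
  if (length(x) == 0) stop("need at least one normalizer fold change")
  if (any(!is.finite(x)) || any(x <= 0))
    stop("normalizer fold changes must be positive and finite")
  exp(mean(log(x)))
}

#' Plate-level quality control on control wells
#'
#' A plate passes when its negative controls (water template) show no
#' amplification, its positive controls (universal RNA template) all take
#' off, and the expected numbers of control wells are present (five of each
#' by default). Shortfalls are reported as QC failures with reasons, never as
#' exceptions.
#'
#' @param curves long curve data.frame with columns \code{well_id},
#'   \code{role}, \code{cycle}, \code{fluorescence} (as produced by
#'   [simulateAmplificationCurves()]).
#' @param nNegativeExpected,nPositiveExpected expected control-well counts
#'   (defaults 5 and 5).
#' @param smoothingWindow passed to [takeoffCycle()].
#' @return a [PlateQC-class] object.
#' @export
plateQC <- function(curves, nNegativeExpected = 5, nPositiveExpected = 5,
                    smoothingWindow = 1) {
  toff <- function(df) takeoffCycle(df$fluorescence[order(df$cycle)],
                                    sort(df$cycle), smoothingWindow)
  negWells <- split(curves[curves$role == "NEGATIVE_CONTROL", ],
                    curves$well_id[curves$role == "NEGATIVE_CONTROL"])
  posWells <- split(curves[curves$role == "POSITIVE_CONTROL", ],
                    curves$well_id[curves$role == "POSITIVE_CONTROL"])
  reasons <- character()
  negPass <- TRUE
  posPass <- TRUE
  if (length(negWells) != nNegativeExpected) {
    negPass <- FALSE
    reasons <- c(reasons, sprintf("expected %d negative controls, found %d",
                                  nNegativeExpected, length(negWells)))
  }
  if (length(posWells) != nPositiveExpected) {
    posPass <- FALSE
    reasons <- c(reasons, sprintf("expected %d positive controls, found %d",
                                  nPositiveExpected, length(posWells)))
  }
  negT <- vapply(negWells, toff, numeric(1))
  if (any(!is.na(negT))) {
    negPass <- FALSE
    reasons <- c(reasons, paste("amplifying negative control(s):",
                                paste(names(negT)[!is.na(negT)],
                                      collapse = ", ")))
  }
  posT <- vapply(posWells, toff, numeric(1))
  if (any(is.na(posT))) {
    posPass <- FALSE
    reasons <- c(reasons, paste("silent positive control(s):",
                                paste(names(posT)[is.na(posT)],
                                      collapse = ", ")))
  }
  new("PlateQC", negativePass = negPass, positivePass = posPass,
      nNegative = length(negWells), nPositive = length(posWells),
      reasons = reasons)
}

#' Quantify one sample's plate into normalized relative fold changes
#'
#' Runs the full relative-quantification workflow for a single sample: plate
#' QC, take-off estimation for every well, per-marker \eqn{\Delta Ct}
#' against the supplied reference take-offs, the Pfaffl ratio with the
#' geometric-mean-combined normalizer factor, and the log2 fold change.
#'
#' The plate must pass QC and all normalizers must be detected; otherwise the
#' sample is unquantifiable and an error is signalled. A diagnostic target
#' that fails detection yields an \code{NA} row rather than an error.
#'
#' @param curves long curve data.frame for one sample (targets, normalizers
#'   and control wells).
#' @param referenceTakeoffs named numeric vector of reference (calibrator)
#'   take-off cycles covering every diagnostic and normalizer marker.
#' @param panel a [panelSpec()].
#' @param efficiencies amplification efficiency per marker: scalar (applied
#'   to all markers, default 2) or named vector.
#' @param sampleId sample identifier copied into the result.
#' @param smoothingWindow passed to [takeoffCycle()].
#' @return data.frame with one row per diagnostic marker and columns
#'   \code{marker_id}, \code{sample_id}, \code{takeoff_cycle},
#'   \code{delta_ct}, \code{efficiency}, \code{fold_change},
#'   \code{log2_fold_change}.
#' @export
quantifySample <- function(curves, referenceTakeoffs, panel,
                           efficiencies = 2, sampleId = "sample",
                           smoothingWindow = 1) {
  qc <- plateQC(curves, smoothingWindow = smoothingWindow)
  if (!qcPassed(qc))
    stop("plate failed QC: ", paste(qc@reasons, collapse = "; "))
  allMarkers <- c(panel$markerIds, panel$normalizerIds)
  if (!all(allMarkers %in% names(referenceTakeoffs)))
    stop("referenceTakeoffs must cover every panel marker and normalizer")
  eff <- if (length(efficiencies) == 1 && is.null(names(efficiencies)))
    setNames(rep(efficiencies, length(allMarkers)), allMarkers)
  else efficiencies
  if (!all(allMarkers %in% names(eff)))
    stop("efficiencies must cover every panel marker and normalizer")
  wellTakeoff <- function(marker, role) {
    df <- curves[curves$marker_id == marker & curves$role == role, ]
    if (nrow(df) == 0) return(NA_real_)
    takeoffCycle(df$fluorescence[order(df$cycle)], sort(df$cycle),
                 smoothingWindow)
  }
  normT <- vapply(panel$normalizerIds, wellTakeoff, numeric(1),
                  role = "NORMALIZER")
  if (any(is.na(normT)))
    stop("sample unquantifiable: normalizer(s) not detected: ",
         paste(panel$normalizerIds[is.na(normT)], collapse = ", "))
  normRatio <- eff[panel$normalizerIds] ^
    (referenceTakeoffs[panel$normalizerIds] - normT)
  combined <- combineNormalizers(normRatio)
  targT <- vapply(panel$markerIds, wellTakeoff, numeric(1), role = "TARGET")
  dct <- referenceTakeoffs[panel$markerIds] - targT
  fc <- eff[panel$markerIds] ^ dct / combined
  data.frame(
    marker_id = panel$markerIds,
    sample_id = sampleId,
    takeoff_cycle = unname(targT),
    delta_ct = unname(dct),
    efficiency = unname(eff[panel$markerIds]),
    fold_change = unname(fc),
    log2_fold_change = unname(log2(fc)),
    stringsAsFactors = FALSE
  )
}
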