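#' Build a three-cohort study design
#'
#' Creates the sample sheet for a healthy-control (HC) / post-surgical (PS) /
#' sepsis (SEPSIS) cohort study. The default sizes, 20 + 38 + 27 = 85, match
#' the clinical study the pipeline emulates. Samples are ordered HC, then PS,
#' then SEPSIS, with unique opaque identifiers.
#'
#' @param nHC,nPS,nSepsis non-negative cohort sizes.
#' @return data.frame with columns \code{sample_id} (character, unique) and
#'   \code{cohort} (factor with levels HC, PS, SEPSIS).
#' @examples
#' design <- cohortDesign()
#' table(design$cohort)
#' @export
cohortDesign <- function(nHC = 20, nPS = 38, nSepsis = 27) {
  for (n in c(nHC, nPS, nSepsis))
    if (length(n) != 1L || is.na(n) || n < 0 || n != round(n))
      stop("cohort sizes must be single non-negative integers")
  cohort <- factor(rep(c("HC", "PS", "SEPSIS"), times = c(nHC, nPS, nSepsis)),
                   levels = c("HC", "PS", "SEPSIS"))
  ids <- character(length(cohort))
  for (lev in levels(cohort)) {
    idx <- which(cohort == lev)
    ids[idx] <- sprintf("%s%02d", lev, seq_along(idx))
  }
  data.frame(sample_id = ids, cohort = cohort, stringsAsFactors = FALSE)
}

#' Mixed-inflammation (MI) grouping of a cohort design
#'
#' MI is the union of the PS and SEPSIS cohorts: the "systemically inflamed"
#' class used against healthy controls.
#'
#' @param design a data.frame from [cohortDesign()].
#' @return factor of length \code{nrow(design)} with levels HC, MI.
#' @export
miGroup <- function(design) {
  stopifnot(is.factor(design$cohort))
  factor(ifelse(design$cohort == "HC", "HC", "MI"), levels = c("HC", "MI"))
}

#' Describe a marker panel
#'
#' Anonymous marker identifiers stand in for the study's 42 patented
#' diagnostic markers and its three normalization genes.
#'
#' @param nMarkers number of diagnostic markers (default 42).
#' @param nNormalizers number of reference/normalization markers (default 3).
#' @return list with character vectors \code{markerIds} (M01, M02, ...) and
#'   \code{normalizerIds} (NORM1, ...), guaranteed disjoint.
#' @export
panelSpec <- function(nMarkers = 42, nNormalizers = 3) {
  if (nMarkers < 1) stop("nMarkers must be >= 1")
  if (nNormalizers < 1) stop("nNormalizers must be >= 1")
  list(
    markerIds = sprintf("M%02d", seq_len(nMarkers)),
    normalizerIds = sprintf("NORM%d", seq_len(nNormalizers))
  )
}

#' Cohort effect model for synthetic expression data
#'
#' Defines per-marker, per-cohort mean log2 fold changes and per-marker noise
#' SDs. Signal is spread across the first \code{nInformative} markers (the
#' rest are pure noise), emulating the redundancy of a multi-marker panel:
#' with signal on 20 of 42 markers, small random sub-panels retain most of
#' the discriminative power. Informative markers are shifted by
#' \code{miVsHc - sepsisVsPs/2} in PS and \code{miVsHc + sepsisVsPs/2} in
#' SEPSIS relative to HC, so the stated contrasts hold exactly.
#'
#' @param panel a [panelSpec()].
#' @param nInformative number of markers carrying cohort signal (default 20).
#' @param sepsisVsPs mean log2 shift of SEPSIS relative to PS on informative
#'   markers (default 0.75).
#' @param miVsHc mean log2 shift of the MI midpoint relative to HC (default
#'   1.5).
#' @param sigma per-marker noise SD in log2 units; scalar or one value per
#'   marker (default 1).
#' @return list with \code{mu} (markers x cohorts matrix of means, cohorts
#'   HC/PS/SEPSIS) and \code{sigma} (named per-marker SD vector).
#' @export
effectModel <- function(panel, nInformative = 20, sepsisVsPs = 0.75,
                        miVsHc = 1.5, sigma = 1) {
  m <- length(panel$markerIds)
  if (nInformative < 0 || nInformative > m)
    stop("nInformative must lie in [0, number of markers]")
  sigma <- rep_len(sigma, m)
  if (any(sigma <= 0)) stop("sigma must be positive for every marker")
  mu <- matrix(0, nrow = m, ncol = 3,
               dimnames = list(panel$markerIds, c("HC", "PS", "SEPSIS")))
  if (nInformative > 0) {
    inf <- seq_len(nInformative)
    mu[inf, "PS"] <- miVsHc - sepsisVsPs / 2
    mu[inf, "SEPSIS"] <- miVsHc + sepsisVsPs / 2
  }
  list(mu = mu, sigma = setNames(sigma, panel$markerIds))
}

#' Simulate a cohort expression matrix
#'
#' Draws each log2 relative fold change independently as
#' \eqn{N(\mu(g, c), \sigma(g))} for marker g in the cohort c of the sample.
#' The same seed reproduces the matrix bit-for-bit.
#'
#' @param design a [cohortDesign()].
#' @param panel a [panelSpec()].
#' @param effects an [effectModel()]; must cover every (marker, cohort) pair.
#' @param seed integer seed.
#' @return \linkS4class{SummarizedExperiment} with assay \code{log2fc}
#'   (markers in rows, samples in columns) and \code{cohort} in colData.
#' @examples
#' panel <- panelSpec()
#' se <- simulateExpression(cohortDesign(), panel, effectModel(panel), seed = 1)
#' dim(se)
#' @export
simulateExpression <- function(design, panel, effects, seed) {
  if (!all(panel$markerIds %in% rownames(effects$mu)))
    stop("effect model is missing entries for some markers")
  if (!all(levels(design$cohort) %in% colnames(effects$mu)))
    stop("effect model is missing entries for some cohorts")
  mu <- effects$mu[panel$markerIds, , drop = FALSE]
  sigma <- effects$sigma[panel$markerIds]
  if (anyNA(mu) || anyNA(sigma))
    stop("effect model contains missing values")
  n <- nrow(design)
  m <- length(panel$markerIds)
  means <- mu[, as.character(design$cohort), drop = FALSE]
  x <- withSeed(seed,
    matrix(rnorm(m * n, mean = means, sd = sigma), nrow = m, ncol = n,
           dimnames = list(panel$markerIds, design$sample_id)))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(log2fc = x),
    colData = S4Vectors::DataFrame(cohort = design$cohort,
                                   row.names = design$sample_id),
    rowData = S4Vectors::DataFrame(
      informative = apply(mu, 1, function(r) any(r != r[1])),
      row.names = panel$markerIds
    )
  )
}

#' Parameters of a synthetic amplification curve
#'
#' Noiseless traces are 4-parameter logistics,
#' \eqn{b + F_{max} / (1 + e^{-k (c - c_0)})}, whose second derivative peaks
#' at \eqn{c_0 - \ln(2 + \sqrt 3)/k}; the generator positions \eqn{c_0} so
#' that this analytic take-off sits at the requested cycle, giving an exact
#' oracle for take-off estimation.
#'
#' @param fMax plateau fluorescence above baseline (default 10).
#' @param k logistic slope per cycle, > 0 (default 0.8).
#' @param baseline baseline fluorescence (default 0.5).
#' @param noiseSd additive Gaussian noise SD on fluorescence (default 0).
#' @param nCycles number of cycles recorded, >= 10 (default 40).
#' @param efficiency per-cycle amplification factor in (1, 2] (default 2).
#' @return list of the validated parameters.
#' @export
curveModel <- function(fMax = 10, k = 0.8, baseline = 0.5, noiseSd = 0,
                       nCycles = 40, efficiency = 2) {
  if (k <= 0) stop("slope k must be > 0")
  if (nCycles < 10) stop("nCycles must be >= 10")
  if (fMax < 0) stop("fMax must be non-negative")
  if (noiseSd < 0) stop("noiseSd must be non-negative")
  if (efficiency <= 1 || efficiency > 2)
    stop("efficiency must lie in (1, 2]")
  list(fMax = fMax, k = k, baseline = baseline, noiseSd = noiseSd,
       nCycles = nCycles, efficiency = efficiency)
}

# Offset between the logistic midpoint c0 and the point of peak acceleration
# (second-derivative maximum): c_takeoff = c0 - log(2 + sqrt(3)) / k.
takeoffOffset <- function(k) log(2 + sqrt(3)) / k

#' Simulate per-well amplification curves
#'
#' Each well gets a logistic fluorescence trace whose analytic point of peak
#' cycling acceleration equals the requested take-off cycle. Negative-control
#' wells are generated with a flat plateau (\code{fMax = 0}), i.e. baseline
#' plus noise only.
#'
#' @param wells data.frame with columns \code{well_id}, \code{marker_id},
#'   \code{role} (TARGET, NORMALIZER, POSITIVE_CONTROL or NEGATIVE_CONTROL)
#'   and \code{takeoff} (true take-off cycle; ignored for negative controls).
#' @param model a [curveModel()].
#' @param seed integer seed for the additive noise.
#' @return long data.frame with columns \code{well_id}, \code{marker_id},
#'   \code{role}, \code{cycle}, \code{fluorescence}.
#' @examples
#' wells <- data.frame(well_id = "w1", marker_id = "M01", role = "TARGET",
#'                     takeoff = 20)
#' curves <- simulateAmplificationCurves(wells, curveModel(), seed = 1)
#' head(curves)
#' @export
simulateAmplificationCurves <- function(wells, model = curveModel(),
                                        seed = 1) {
  roles <- c("TARGET", "NORMALIZER", "POSITIVE_CONTROL", "NEGATIVE_CONTROL")
  need <- c("well_id", "marker_id", "role", "takeoff")
  if (!all(need %in% names(wells)))
    stop("wells must have columns well_id, marker_id, role, takeoff")
  if (!all(wells$role %in% roles))
    stop("unknown well role; expected one of ", paste(roles, collapse = ", "))
  cycles <- seq_len(model$nCycles)
  out <- withSeed(seed, lapply(seq_len(nrow(wells)), function(i) {
    w <- wells[i, ]
    fmax <- if (w$role == "NEGATIVE_CONTROL") 0 else model$fMax
    c0 <- w$takeoff + takeoffOffset(model$k)
    f <- model$baseline + fmax / (1 + exp(-model$k * (cycles - c0)))
    if (model$noiseSd > 0)
      f <- f + rnorm(length(cycles), sd = model$noiseSd)
    data.frame(well_id = w$well_id, marker_id = w$marker_id, role = w$role,
               cycle = cycles, fluorescence = f, stringsAsFactors = FALSE)
  }))
  do.call(rbind, out)
}

#' Build one sample's plate from known log2 fold changes
#'
#' Converts known marker-level truth into well take-off cycles: relative to a
#' reference take-off, a sample with log2 fold change \eqn{L} on a marker
#' takes off \eqn{L / \log_2 E} cycles earlier. Normalizer wells sit at the
#' reference take-off, and five positive and five negative control wells are
#' added.
#'
#' @param log2fc named numeric vector of true log2 fold changes, one per
#'   diagnostic marker in \code{panel}.
#' @param panel a [panelSpec()].
#' @param model a [curveModel()]; its \code{efficiency} sets the cycle shift
#'   per log2 unit.
#' @param referenceTakeoff take-off cycle of the reference for every marker
#'   (default 20).
#' @param seed integer seed passed to [simulateAmplificationCurves()].
#' @return long curve data.frame as from [simulateAmplificationCurves()].
#' @export
simulateSamplePlate <- function(log2fc, panel, model = curveModel(),
                                referenceTakeoff = 20, seed = 1) {
  if (!all(panel$markerIds %in% names(log2fc)))
    stop("log2fc must be named and cover every diagnostic marker")
  shift <- log2fc[panel$markerIds] / log2(model$efficiency)
  wells <- rbind(
    data.frame(well_id = paste0("T_", panel$markerIds),
               marker_id = panel$markerIds, role = "TARGET",
               takeoff = referenceTakeoff - unname(shift)),
    data.frame(well_id = paste0("N_", panel$normalizerIds),
               marker_id = panel$normalizerIds, role = "NORMALIZER",
               takeoff = referenceTakeoff),
    data.frame(well_id = sprintf("POS%d", 1:5), marker_id = "POS",
               role = "POSITIVE_CONTROL", takeoff = referenceTakeoff),
    data.frame(well_id = sprintf("NEG%d", 1:5), marker_id = "NEG",
               role = "NEGATIVE_CONTROL", takeoff = referenceTakeoff)
  )
  simulateAmplificationCurves(wells, model, seed = seed)
}
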