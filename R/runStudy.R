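studyConfigDefaults <- function() {
  list(
    cohort = list(nHC = 20, nPS = 38, nSepsis = 27),
    panel = list(nMarkers = 42, nNormalizers = 3),
    effects = list(nInformative = 20, sepsisVsPs = 0.75, miVsHc = 1.5,
                   sigma = 1),
    quantify = list(enabled = FALSE, referenceTakeoff = 20, noiseSd = 0,
                    efficiency = 2),
    classifier = list(M = 50, zMax = 4),
    scheme = list(B = 500, trainFraction = 2 / 3, stratified = TRUE),
    subPanelSize = 7,
    seed = 1
  )
}

mergeConfig <- function(defaults, override, path = "config") {
  if (length(override) == 0) return(defaults)
  unknown <- setdiff(names(override), names(defaults))
  if (length(unknown))
    stop("unknown ", path, " key(s): ", paste(unknown, collapse = ", "))
  for (k in names(override)) {
    defaults[[k]] <- if (is.list(defaults[[k]]))
      mergeConfig(defaults[[k]], override[[k]], paste0(path, "$", k))
    else override[[k]]
  }
  defaults
}

#' Build (or load) a full study configuration
#'
#' Returns the default end-to-end study configuration — the three-cohort
#' 20/38/27 design, the 42 + 3 marker panel, the default effect model,
#' classifier settings (M = 50, zMax = 4) and partition scheme (B = 500,
#' training fraction 2/3, stratified) — with any supplied overrides merged
#' in. Unknown keys at any level are rejected.
#'
#' @param ... named overrides, e.g. \code{scheme = list(B = 10)},
#'   \code{seed = 42}.
#' @param file optionally, a JSON file of overrides (applied before
#'   \code{...}).
#' @return nested configuration list.
#' @examples
#' cfg <- studyConfig(scheme = list(B = 10), seed = 7)
#' cfg$scheme$B
#' @export
studyConfig <- function(..., file = NULL) {
  cfg <- studyConfigDefaults()
  if (!is.null(file))
    cfg <- mergeConfig(cfg, jsonlite::read_json(file, simplifyVector = TRUE))
  mergeConfig(cfg, list(...))
}

#' Run the end-to-end synthetic study replica
#'
#' Executes the whole pipeline under one root seed: simulate the cohort
#' expression matrix; optionally push every sample through synthetic
#' amplification curves and relative quantification; screen markers
#' (moderated t, MI vs HC, Holm-adjusted); then evaluate the LogitBoost
#' diagnostic for the four pairwise comparisons (MI vs HC, Sepsis vs HC,
#' PS vs HC, Sepsis vs PS) at the full panel and at a random sub-panel
#' (default 7 markers), each with its permutation null — eight result rows
#' in the report table. All intermediate artifacts (TSV/JSON) plus a run
#' log are written to \code{outDir}; a rerun with the same config is
#' byte-identical.
#'
#' @param config a [studyConfig()].
#' @param outDir output directory (created if needed).
#' @return (invisibly) list with the \code{results} (named list of
#'   [EvaluationResult-class]), the report \code{table}, the simulated
#'   SummarizedExperiment \code{se}, and \code{outDir}.
#' @export
runStudy <- function(config = studyConfig(), outDir = tempfile("study")) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logPath <- file.path(outDir, "run.log")
  logLines <- character()
  note <- function(...) {
    logLines <<- c(logLines, paste0(...))
    writeLines(logLines, logPath)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      note("ABORT at stage '", name, "': ", conditionMessage(e))
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  note("root seed: ", config$seed)

  se <- stage("simulate", {
    design <- cohortDesign(config$cohort$nHC, config$cohort$nPS,
                           config$cohort$nSepsis)
    panel <- panelSpec(config$panel$nMarkers, config$panel$nNormalizers)
    effects <- effectModel(panel, config$effects$nInformative,
                           config$effects$sepsisVsPs, config$effects$miVsHc,
                           config$effects$sigma)
    se <- simulateExpression(design, panel, effects, seed = config$seed)
    writeExpressionTSV(se, file.path(outDir, "expression.tsv"))
    writeMetadataTSV(design, file.path(outDir, "metadata.tsv"))
    note("simulate: ", nrow(design), " samples x ", nrow(se), " markers")
    se
  })

  if (isTRUE(config$quantify$enabled)) {
    se <- stage("quantify", {
      panel <- panelSpec(config$panel$nMarkers, config$panel$nNormalizers)
      model <- curveModel(noiseSd = config$quantify$noiseSd,
                          efficiency = config$quantify$efficiency)
      refs <- setNames(rep(config$quantify$referenceTakeoff,
                           length(c(panel$markerIds, panel$normalizerIds))),
                       c(panel$markerIds, panel$normalizerIds))
      truth <- SummarizedExperiment::assay(se)
      rec <- vapply(seq_len(ncol(truth)), function(i) {
        curves <- simulateSamplePlate(truth[, i], panel, model,
                                      config$quantify$referenceTakeoff,
                                      seed = config$seed + i)
        quantifySample(curves, refs, panel,
                       efficiencies = config$quantify$efficiency,
                       sampleId = colnames(truth)[i])$log2_fold_change
      }, numeric(nrow(truth)))
      dimnames(rec) <- dimnames(truth)
      writeCurveTSV(
        data.frame(marker_id = rownames(rec)[row(rec)],
                   sample_id = colnames(rec)[col(rec)],
                   log2_fold_change = as.vector(rec)),
        file.path(outDir, "quantified.tsv"))
      note("quantify: recovered ", nrow(rec), " markers x ", ncol(rec),
           " samples from synthetic curves")
      SummarizedExperiment::SummarizedExperiment(
        assays = list(log2fc = rec),
        colData = SummarizedExperiment::colData(se))
    })
  }

  stage("screen", {
    scr <- moderatedT(SummarizedExperiment::assay(se),
                      miGroup(data.frame(
                        sample_id = colnames(se),
                        cohort = se$cohort)))
    utils::write.table(scr, file.path(outDir, "screening.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    note("screen: ", sum(scr$p_holm < 0.05), "/", nrow(scr),
         " markers significant (Holm < 0.05), MI vs HC")
  })

  results <- stage("evaluate", {
    x <- t(SummarizedExperiment::assay(se))
    cohort <- se$cohort
    mi <- factor(ifelse(cohort == "HC", "HC", "MI"), c("HC", "MI"))
    comparisons <- list(
      "MI Vs HC" = list(keep = rep(TRUE, length(cohort)),
                        y = factor(mi, c("HC", "MI"))),
      "Sepsis Vs HC" = list(keep = cohort %in% c("HC", "SEPSIS"),
                            y = factor(cohort, c("HC", "SEPSIS"))),
      "PS Vs HC" = list(keep = cohort %in% c("HC", "PS"),
                        y = factor(cohort, c("HC", "PS"))),
      "Sepsis Vs PS" = list(keep = cohort %in% c("PS", "SEPSIS"),
                            y = factor(cohort, c("PS", "SEPSIS")))
    )
    sub <- withSeed(config$seed,
                    sort(sample(colnames(x), min(config$subPanelSize,
                                                 ncol(x)))))
    note("evaluate: sub-panel = ", paste(sub, collapse = ", "))
    results <- list()
    idx <- 0L
    for (cmpName in names(comparisons)) {
      cmp <- comparisons[[cmpName]]
      xk <- x[cmp$keep, , drop = FALSE]
      yk <- droplevels(cmp$y[cmp$keep])
      for (panelCols in list(colnames(x), sub)) {
        idx <- idx + 1L
        scheme <- partitionScheme(config$scheme$B,
                                  config$scheme$trainFraction,
                                  config$scheme$stratified,
                                  seed = config$seed + idx)
        obs <- subsetPanelEval(xk, yk, panelCols, scheme,
                               M = config$classifier$M,
                               zMax = config$classifier$zMax,
                               comparison = cmpName)
        res <- permutationNull(xk[, panelCols, drop = FALSE], yk, scheme,
                               M = config$classifier$M,
                               zMax = config$classifier$zMax,
                               observed = obs)
        key <- sprintf("%s_%d", gsub(" ", "_", cmpName), length(panelCols))
        results[[key]] <- res
        writeResultJSON(res, file.path(outDir, paste0(key, ".json")))
        note("evaluate: ", cmpName, " panel ", length(panelCols),
             sprintf(": mean AUC %.3f (SD %.4f), p %s", meanAuc(res),
                     sdAuc(res), formatPValue(pValue(res), scheme$B)))
      }
    }
    results
  })

  tab <- summarizeTable(results)
  utils::write.table(tab, file.path(outDir, "report_table.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(config, file.path(outDir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  note("done: ", length(results), " evaluation results")
  invisible(list(results = results, table = tab, se = se, outDir = outDir))
}
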