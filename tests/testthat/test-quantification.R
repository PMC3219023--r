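test_that("take-off estimation tracks the analytic second-derivative maximum", {
  tr <- logisticTrace(c0 = 25, k = 0.8)
  expect_lt(abs(takeoffCycle(tr$f, tr$cycles) - tr$takeoff), 0.25)

  # translation equivariance: +3 cycles in, +3 cycles out
  tr2 <- logisticTrace(c0 = 22, k = 0.8)
  expect_equal(takeoffCycle(tr$f, tr$cycles) -
                 takeoffCycle(tr2$f, tr2$cycles), 3, tolerance = 0.05)

  # flat negative-control trace: NOT_DETECTED
  expect_true(is.na(takeoffCycle(rep(0.5, 40))))
  set.seed(1)
  expect_true(is.na(takeoffCycle(rep(0.5, 40) + rnorm(40, sd = 0.01))))

  expect_error(takeoffCycle(1:9), "at least 10 cycles")
  expect_error(takeoffCycle(1:20, cycles = 20:1), "strictly increasing")
})

test_that("Pfaffl ratio matches direct arithmetic and the 2^-ddCt special case", {
  expect_equal(pfafflFoldChange(0, 0, 1.8, 1.95), 1.0)
  expect_equal(pfafflFoldChange(1, 0, 2, 2), 2.0)
  expect_equal(pfafflFoldChange(2.5, 0.5, 1.9, 2.0), 1.9^2.5 / 2^0.5)

  # with both efficiencies 2 the ratio is exactly 2^-(ddCt) on a grid
  grid <- expand.grid(a = seq(-3, 3, by = 0.75), b = seq(-2, 2, by = 0.5))
  expect_equal(pfafflFoldChange(grid$a, grid$b),
               2^(-(grid$b - grid$a)))

  expect_error(pfafflFoldChange(1, 0, eTarget = 1), "\\(1, 2\\]")
  expect_error(pfafflFoldChange(1, 0, eNorm = 2.1), "\\(1, 2\\]")
})

test_that("normalizer combination is the geometric mean", {
  expect_equal(combineNormalizers(c(1, 1, 8)), 2)
  expect_equal(combineNormalizers(c(3.7, 3.7, 3.7)), 3.7)
  expect_equal(combineNormalizers(c(1.2, 0.9, 1.5)),
               exp(mean(log(c(1.2, 0.9, 1.5)))))
  expect_equal(combineNormalizers(c(0.9, 1.5, 1.2)),
               combineNormalizers(c(1.2, 0.9, 1.5)))
  expect_error(combineNormalizers(numeric()), "at least one")
  expect_error(combineNormalizers(c(1, -2)), "positive")
})

test_that("plate QC demands silent negatives and amplifying positives", {
  ok <- rbind(
    data.frame(well_id = sprintf("P%d", 1:5), marker_id = "POS",
               role = "POSITIVE_CONTROL", takeoff = 20),
    data.frame(well_id = sprintf("N%d", 1:5), marker_id = "NEG",
               role = "NEGATIVE_CONTROL", takeoff = 20))
  curves <- simulateAmplificationCurves(ok, curveModel(), seed = 1)
  expect_true(qcPassed(plateQC(curves)))

  # contamination signature: one amplifying negative control
  bad <- ok
  bad$role[bad$well_id == "N1"] <- "TARGET"
  badCurves <- simulateAmplificationCurves(bad, curveModel(), seed = 1)
  badCurves$role[badCurves$well_id == "N1"] <- "NEGATIVE_CONTROL"
  qc <- plateQC(badCurves)
  expect_false(qc@negativePass)
  expect_true(qc@positivePass)
  expect_false(qcPassed(qc))

  # reaction-failure signature: one silent positive control
  silent <- simulateAmplificationCurves(ok, curveModel(), seed = 1)
  silent$fluorescence[silent$well_id == "P2"] <- 0.5
  qc2 <- plateQC(silent)
  expect_false(qc2@positivePass)
  expect_true(qc2@negativePass)

  # missing control wells fail with a reason, not an exception
  qc3 <- plateQC(curves[curves$well_id != "N5", ])
  expect_false(qcPassed(qc3))
  expect_match(paste(qc3@reasons, collapse = " "), "expected 5 negative")
})

test_that("sample quantification recovers known truth end-to-end", {
  panel <- panelSpec(nMarkers = 4)
  model <- curveModel()
  refs <- setNames(rep(20, 7), c(panel$markerIds, panel$normalizerIds))

  # identical to reference everywhere -> all fold changes 1
  q0 <- quantifySample(
    simulateSamplePlate(setNames(rep(0, 4), panel$markerIds), panel, model),
    refs, panel)
  expect_equal(q0$fold_change, rep(1, 4), tolerance = 1e-6)
  expect_equal(q0$log2_fold_change, log2(q0$fold_change))

  # grid recovery: true log2 fold changes in [-4, 4] within 0.05
  for (L in seq(-4, 4, by = 1)) {
    q <- quantifySample(
      simulateSamplePlate(setNames(c(L, 0, 2, -2), panel$markerIds),
                          panel, model),
      refs, panel)
    expect_lt(abs(q$log2_fold_change[1] - L), 0.05)
    expect_lt(abs(q$log2_fold_change[3] - 2), 0.05)
  }

  # scale consistency: normalizers amplified kappa-fold divide every marker
  fcTrue <- setNames(c(1, 0, 2, -2), panel$markerIds)
  plate <- simulateSamplePlate(fcTrue, panel, model)
  q1 <- quantifySample(plate, refs, panel)
  refsShift <- refs
  refsShift[panel$normalizerIds] <- refsShift[panel$normalizerIds] + 1
  q2 <- quantifySample(plate, refsShift, panel)  # normalizer ratios x2
  expect_equal(q2$fold_change, q1$fold_change / 2, tolerance = 1e-6)

  # failed plate QC aborts quantification explicitly
  noNeg <- plate[plate$role != "NEGATIVE_CONTROL", ]
  expect_error(quantifySample(noNeg, refs, panel), "failed QC")

  # silent normalizer flags the sample unquantifiable
  broken <- plate
  broken$fluorescence[broken$well_id == "N_NORM1"] <- 0.5
  expect_error(quantifySample(broken, refs, panel), "unquantifiable")
})
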