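test_that("ROC AUC equals pairwise concordance with ties half-counted", {
  expect_equal(auc(rocAuc(c(.9, .8, .3, .2), c("p", "p", "n", "n"))), 1.0)
  expect_equal(auc(rocAuc(rep(0.5, 6), rep(c("n", "p"), 3))), 0.5)
  # 6 positive-negative pairs: 0.9 beats all three negatives, 0.4 loses to
  # 0.6, beats 0.2 and ties 0.4 -> (1+1+1+0+1+0.5)/6
  expect_equal(auc(rocAuc(c(.9, .4, .6, .2, .4),
                          factor(c("p", "p", "n", "n", "n"),
                                 levels = c("n", "p")))), 4.5 / 6)

  set.seed(37)
  for (rep in 1:200) {
    n <- sample(4:30, 1)
    pos <- c(TRUE, FALSE, runif(n - 2) > 0.5)
    s <- round(runif(n), 2)
    lab <- factor(ifelse(pos, "p", "n"), levels = c("n", "p"))
    expect_equal(auc(rocAuc(s, lab)), bruteForceAuc(s, pos))
  }

  # complement symmetry for tie-free scores
  s <- c(0.11, 0.52, 0.37, 0.93, 0.78, 0.05)
  lab <- factor(c("n", "p", "n", "p", "p", "n"), levels = c("n", "p"))
  expect_equal(auc(rocAuc(s, lab)) + auc(rocAuc(-s, lab)), 1)

  # curve geometry
  r <- rocAuc(s, lab)
  expect_equal(c(r@fpr[1], r@tpr[1]), c(0, 0))
  expect_equal(c(r@fpr[length(r@fpr)], r@tpr[length(r@tpr)]), c(1, 1))
  expect_true(!is.unsorted(r@fpr) && !is.unsorted(r@tpr))

  expect_error(rocAuc(1:4, rep("p", 4)), "two classes")
})

test_that("ROC AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(41)
  s <- rnorm(40)
  lab <- factor(sample(c("n", "p"), 40, replace = TRUE), c("n", "p"))
  expect_equal(auc(rocAuc(s, lab)),
               as.numeric(pROC::auc(pROC::roc(lab, s, levels = c("n", "p"),
                                              direction = "<", quiet = TRUE))))
})

test_that("repeated partition evaluation is stratified, seeded and reproducible", {
  fx <- twoClassFixture(n1 = 14, n2 = 18, m = 5, delta = 1.5, seed = 43)
  sch <- partitionScheme(B = 12, seed = 5)
  a <- repeatedPartitionEval(fx$X, fx$y, sch, M = 10, comparison = "b Vs a")
  b <- repeatedPartitionEval(fx$X, fx$y, sch, M = 10, comparison = "b Vs a")
  expect_identical(aucSample(a), aucSample(b))
  expect_length(aucSample(a), 12)
  expect_equal(meanAuc(a), mean(aucSample(a)))
  expect_equal(sdAuc(a), sd(aucSample(a)))

  # seeded entry points must not disturb the caller's RNG stream
  set.seed(99); r1 <- runif(1)
  set.seed(99)
  invisible(repeatedPartitionEval(fx$X, fx$y, partitionScheme(B = 2,
                                                              seed = 5)))
  expect_identical(runif(1), r1)

  # a different seed gives a different AUC sample
  c2 <- repeatedPartitionEval(fx$X, fx$y, partitionScheme(B = 12, seed = 6),
                              M = 10)
  expect_false(identical(aucSample(a), aucSample(c2)))

  # every stratified split keeps >= 2 of each class on both sides
  set.seed(1)
  y <- factor(rep(c("n", "p"), c(6, 9)))
  for (i in 1:50) {
    tr <- septiclass:::drawPartition(y, partitionScheme(B = 1))
    expect_true(all(table(y[tr]) >= 2) && all(table(y[!tr]) >= 2))
  }
  expect_error(
    repeatedPartitionEval(fx$X[c(1, 2, 15, 16, 17), ],
                          fx$y[c(1, 2, 15, 16, 17)], sch),
    "infeasible stratification")
})

test_that("the permutation machinery attains its p-value floor and centre", {
  fx <- twoClassFixture(n1 = 18, n2 = 18, m = 5, delta = 4, seed = 47)
  sch <- partitionScheme(B = 19, seed = 7)
  obs <- repeatedPartitionEval(fx$X, fx$y, sch, M = 10, comparison = "b Vs a")
  res <- permutationNull(fx$X, fx$y, sch, M = 10, observed = obs)
  expect_length(nullSample(res), 19)
  # add-one estimator, recomputable from the stored samples, never below
  # its floor 1/(B + 1); an overwhelming effect sits at (or near) the floor
  expect_equal(pValue(res),
               (1 + sum(nullSample(res) >= meanAuc(obs))) / 20)
  expect_gte(pValue(res), 1 / 20)
  expect_lte(pValue(res), 2 / 20)
  expect_identical(aucSample(res), aucSample(obs))

  # observed mean at the null median -> central p
  resMid <- permutationNull(fx$X, fx$y, sch, M = 10,
                            observed = median(nullSample(res)))
  expect_gt(pValue(resMid), 0.3)
  expect_lt(pValue(resMid), 0.8)
})

test_that("panel subsetting reproduces the full pipeline on chosen markers", {
  fx <- twoClassFixture(n1 = 12, n2 = 12, m = 6, delta = 1.5, seed = 53)
  sch <- partitionScheme(B = 8, seed = 9)
  full <- repeatedPartitionEval(fx$X, fx$y, sch, M = 10)
  ident <- subsetPanelEval(fx$X, fx$y, colnames(fx$X), sch, M = 10)
  expect_identical(aucSample(full), aucSample(ident))

  sub <- subsetPanelEval(fx$X, fx$y, c("M01", "M02"), sch, M = 10)
  expect_equal(sub@panelSize, 2L)

  expect_error(subsetPanelEval(fx$X, fx$y, character(), sch), "non-empty")
  expect_error(subsetPanelEval(fx$X, fx$y, "M99", sch), "unknown marker")
})

test_that("PCA scores are an orthogonal variance-ordered projection", {
  set.seed(59)
  X <- matrix(rnorm(30 * 6), 30, 6) %*% diag(c(4, 3, 2, 1, 0.5, 0.2))
  p <- pcaScores(X, nComponents = 6)

  # completeness: all components reconstruct the centred matrix
  centred <- sweep(X, 2, colMeans(X))
  expect_equal(unname(p$scores %*% t(p$rotation)), unname(centred),
               tolerance = 1e-10)
  # orthogonal directions, non-increasing variances
  expect_equal(unname(crossprod(p$rotation)), diag(6), tolerance = 1e-10)
  expect_true(all(diff(p$sdev) <= 1e-12))
  # variances match the covariance eigenvalues (independent decomposition)
  expect_equal(p$sdev^2, sort(eigen(cov(X))$values, decreasing = TRUE),
               tolerance = 1e-10)

  # rank-1 data: first component captures essentially all variance
  line <- outer(rnorm(20), c(1, 2, 3))
  pl <- pcaScores(line, 2)
  expect_gt(pl$sdev[1]^2 / sum(pl$sdev^2), 0.999)

  expect_error(pcaScores(X, 7), "nComponents")
})

test_that("the report table mirrors the stored AUC samples", {
  atFloor <- new("EvaluationResult", comparison = "b Vs a", panelSize = 4L,
                 auc = c(0.9, 0.95, 1.0),
                 nullAuc = seq(0.3, 0.7, length.out = 9),
                 pValue = 1 / 10, seed = 1L)
  fx <- twoClassFixture(n1 = 10, n2 = 10, m = 4, delta = 3, seed = 61)
  obs <- repeatedPartitionEval(fx$X, fx$y, partitionScheme(B = 9, seed = 11),
                               M = 8, comparison = "b Vs a")
  tab <- summarizeTable(list(atFloor, obs))
  expect_equal(names(tab),
               c("Comparison", "Biomarker Set", "Mean", "SD", "P-value"))
  expect_equal(nrow(tab), 2)
  expect_equal(tab$Mean[1], mean(aucSample(atFloor)))
  expect_equal(tab$SD[1], sd(aucSample(atFloor)))
  expect_equal(tab$Mean[2], meanAuc(obs))
  # p at the floor (no null reached the observed mean) prints as a bound
  expect_equal(tab$`P-value`[1], "< 0.1")
  expect_true(is.na(tab$`P-value`[2]))

  empty <- summarizeTable(list())
  expect_equal(nrow(empty), 0)
  expect_equal(names(empty),
               c("Comparison", "Biomarker Set", "Mean", "SD", "P-value"))
})
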