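test_that("weighted stump fitting matches exhaustive split search", {
  # hand-checkable case: clean split at 2.5 with zero loss
  st <- fitStumpWeighted(1:4, c(-1, -1, 1, 1), rep(1, 4))
  expect_equal(st$threshold, 2.5)
  expect_equal(st$left, -1)
  expect_equal(st$right, 1)
  expect_equal(st$loss, 0)

  # constant response: degenerate stump below the feature minimum
  stc <- fitStumpWeighted(c(3, 1, 2), c(0.4, 0.4, 0.4), c(1, 2, 1))
  expect_equal(stc$left, 0.4)
  expect_equal(stc$right, 0.4)
  expect_lt(stc$threshold, 1)

  # random small instances: achieved loss equals the brute-force minimum
  set.seed(21)
  for (rep in 1:150) {
    n <- sample(2:12, 1)
    x <- round(rnorm(n), 1)          # induce ties
    z <- rnorm(n)
    w <- runif(n, 0.05, 2)
    st <- fitStumpWeighted(x, z, w)
    expect_equal(st$loss, bruteForceStumpLoss(x, z, w), tolerance = 1e-9)
  }

  expect_error(fitStumpWeighted(1:3, 1:3, c(0, 0, 0)), "positive total")
  expect_error(fitStumpWeighted(1:3, 1:2, 1:3), "same length")
})

test_that("LogitBoost honours its initialization, descent and determinism contracts", {
  fx <- twoClassFixture(delta = 3, seed = 9)

  # M = 0: every posterior is exactly 1/2
  m0 <- fitLogitBoost(fx$X, fx$y, M = 0)
  expect_equal(unname(predictPosterior(m0, fx$X)), rep(0.5, nrow(fx$X)))

  # separable 1-D data: perfect training AUC after a single stump
  x1 <- matrix(c(1:5, 11:15), ncol = 1)
  y1 <- rep(c("n", "p"), each = 5)
  m1 <- fitLogitBoost(x1, y1, M = 1)
  expect_equal(auc(rocAuc(predictPosterior(m1, x1), y1)), 1.0)

  # Newton-step descent: training NLL is non-increasing across iterations
  fit <- fitLogitBoost(fx$X, fx$y, M = 30)
  expect_true(all(diff(fit@negLogLik) <= 1e-10))

  # determinism: no randomness inside the learner
  fit2 <- fitLogitBoost(fx$X, fx$y, M = 30)
  expect_identical(fit@stumps, fit2@stumps)

  expect_error(fitLogitBoost(fx$X, rep("a", nrow(fx$X))), "two classes")
  expect_error(fitLogitBoost(fx$X[1:10, ], fx$y), "nrow")
})

test_that("posterior probabilities follow the additive-logistic link", {
  fx <- twoClassFixture(seed = 13)
  fit <- fitLogitBoost(fx$X, fx$y, M = 12)
  Fs <- diagnosticScore(fit, fx$X)
  p <- predictPosterior(fit, fx$X)
  expect_equal(unname(p), unname(1 / (1 + exp(-2 * Fs))))
  # F = 3 corresponds to 1/(1 + e^-6)
  expect_equal(1 / (1 + exp(-2 * 3)), 0.99752738, tolerance = 1e-7)
  expect_true(all(p > 0 & p < 1))

  # swapping the class labels complements the posterior
  ySwap <- factor(fx$y, levels = rev(levels(fx$y)))
  fitSwap <- fitLogitBoost(fx$X, ySwap, M = 12)
  expect_equal(unname(predictPosterior(fitSwap, fx$X)), unname(1 - p),
               tolerance = 1e-8)

  expect_error(predictPosterior(fit, fx$X[, 1:3]), "feature count")
})

test_that("posteriors agree with an independent LogitBoost implementation", {
  # literal reference implementation on a shared fixture
  fx <- twoClassFixture(n1 = 12, n2 = 12, m = 4, delta = 1.2, seed = 17)
  ours <- predictPosterior(fitLogitBoost(fx$X, fx$y, M = 8, tol = 0),
                           fx$X)
  ref <- naiveLogitBoost(fx$X, as.numeric(fx$y == "b"), M = 8)
  expect_lt(mean(abs(ours - ref)), 1e-6)

  # established library implementation (different tie-breaking/clamping
  # conventions, hence the loose tolerance on shared fixtures)
  skip_if_not_installed("caTools")
  big <- twoClassFixture(n1 = 30, n2 = 30, m = 6, delta = 2, seed = 19)
  ourP <- predictPosterior(fitLogitBoost(big$X, big$y, M = 20, tol = 0),
                           big$X)
  ct <- caTools::LogitBoost(big$X, big$y, nIter = 20)
  ctP <- predict(ct, big$X, type = "raw")[, "b"]
  expect_lt(mean(abs(ourP - ctP)), 0.05)
})

test_that("LOOCV predicts each held-out sample without label leakage", {
  # signal spread over several markers so the ensemble cannot rely on a
  # single feature (a one-feature-separable training set makes stumps
  # degenerate and held-out outliers fall on the wrong side)
  fx <- twoClassFixture(n1 = 15, n2 = 15, m = 6, delta = 2, seed = 23)
  post <- loocvPosteriors(fx$X, fx$y, M = 15)
  expect_length(post, 30)
  expect_true(all(is.finite(post)))
  expect_identical(attr(post, "flagged"), character(0))

  # flipping the held-out sample's own label cannot change its prediction
  yFlip <- fx$y
  yFlip[7] <- "b"
  postFlip <- loocvPosteriors(fx$X, yFlip, M = 15)
  expect_equal(post[[7]], postFlip[[7]])

  # strongly separable data: near-perfect held-out ranking
  expect_gt(auc(rocAuc(post, fx$y)), 0.95)

  # per-fold marker pre-selection stays inside the training fold
  postSel <- loocvPosteriors(fx$X, fx$y, M = 15, preselect = 3)
  expect_length(postSel, 30)
  # half the panel per fold: still clearly above chance
  expect_gt(auc(rocAuc(postSel, fx$y)), 0.8)

  expect_error(loocvPosteriors(fx$X[1:3, ], fx$y[1:3]), "at least 4")
  expect_error(loocvPosteriors(fx$X[c(1, 2, 3, 16), ], fx$y[c(1, 2, 3, 16)]),
               "at least 2")
})

test_that("permuted training labels yield chance-level held-out performance", {
  fx <- twoClassFixture(n1 = 20, n2 = 20, m = 8, delta = 2, seed = 29)
  set.seed(31)
  aucs <- replicate(30, {
    yp <- sample(fx$y)
    tr <- sample(40, 26)
    fit <- fitLogitBoost(fx$X[tr, ], yp[tr], M = 15)
    auc(rocAuc(predictPosterior(fit, fx$X[-tr, ]), yp[-tr]))
  })
  expect_gt(mean(aucs), 0.4)
  expect_lt(mean(aucs), 0.6)
})
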