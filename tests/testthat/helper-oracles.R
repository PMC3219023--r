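# Independent reference implementations used as oracles. These deliberately
# use the slowest, most literal formulation of each quantity and share no
# code with the package internals.

# AUC as the fraction of positive-negative pairs in which the positive
# outscores the negative, ties counted 1/2.
bruteForceAuc <- function(scores, pos) {
  sp <- scores[pos]
  sn <- scores[!pos]
  tot <- 0
  for (a in sp) for (b in sn)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(sp) * length(sn))
}

# Exhaustive weighted stump search: every midpoint between consecutive
# distinct sorted values, plus the constant fit.
bruteForceStumpLoss <- function(x, z, w) {
  wmean <- function(v, wt) if (sum(wt) > 0) sum(wt * v) / sum(wt) else 0
  best <- sum(w * (z - wmean(z, w))^2)
  xs <- sort(unique(x))
  if (length(xs) > 1) {
    for (i in seq_len(length(xs) - 1)) {
      thr <- (xs[i] + xs[i + 1]) / 2
      l <- x <= thr
      fit <- ifelse(l, wmean(z[l], w[l]), wmean(z[!l], w[!l]))
      best <- min(best, sum(w * (z - fit)^2))
    }
  }
  best
}

# Straightforward literal LogitBoost (loops everywhere), for cross-checking
# the optimized learner on shared fixtures.
naiveLogitBoost <- function(X, ystar, M, zMax = 4) {
  n <- nrow(X)
  Fs <- numeric(n)
  p <- rep(0.5, n)
  stumps <- list()
  for (m in seq_len(M)) {
    w <- pmax(p * (1 - p), 2 * .Machine$double.eps)
    z <- pmin(pmax((ystar - p) / w, -zMax), zMax)
    best <- NULL
    bestLoss <- Inf
    for (j in seq_len(ncol(X))) {
      xs <- sort(unique(X[, j]))
      cands <- if (length(xs) > 1) (xs[-length(xs)] + xs[-1]) / 2
               else xs[1] - 1
      for (thr in cands) {
        l <- X[, j] <= thr
        lv <- if (sum(w[l]) > 0) sum(w[l] * z[l]) / sum(w[l]) else 0
        rv <- if (sum(w[!l]) > 0) sum(w[!l] * z[!l]) / sum(w[!l]) else 0
        fit <- ifelse(l, lv, rv)
        loss <- sum(w * (z - fit)^2)
        if (loss < bestLoss - 1e-12) {
          bestLoss <- loss
          best <- list(j = j, thr = thr, lv = lv, rv = rv)
        }
      }
    }
    stumps[[m]] <- best
    Fs <- Fs + 0.5 * ifelse(X[, best$j] <= best$thr, best$lv, best$rv)
    p <- 1 / (1 + exp(-2 * Fs))
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  }
  1 / (1 + exp(-2 * Fs))
}

# Noiseless logistic trace and the analytic location of its point of peak
# acceleration (second-derivative maximum).
logisticTrace <- function(c0, k = 0.8, fMax = 10, b = 0.5, nCycles = 40) {
  cyc <- seq_len(nCycles)
  list(cycles = cyc, f = b + fMax / (1 + exp(-k * (cyc - c0))),
       takeoff = c0 - log(2 + sqrt(3)) / k)
}

# Small two-class expression fixture (samples x markers).
twoClassFixture <- function(n1 = 15, n2 = 15, m = 6, delta = 1.5, sd = 1,
                            seed = 42) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n1 * m, 0, sd), n1),
             matrix(rnorm(n2 * m, delta, sd), n2))
  colnames(X) <- sprintf("M%02d", seq_len(m))
  rownames(X) <- sprintf("s%02d", seq_len(n1 + n2))
  list(X = X, y = factor(rep(c("a", "b"), c(n1, n2))))
}
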