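test_that("correlation PCA handles collinearity and satisfies its identities", {
  set.seed(83)
  x1 <- rnorm(20)
  m <- cbind(a = x1, b = 2 * x1 + 3, c = rnorm(20))
  r <- pcaOrdination(m[, 1:2])
  expect_equal(r@proportion[1], 1, tolerance = 1e-12)
  r3 <- pcaOrdination(m)
  expect_equal(sum(r3@proportion), 1, tolerance = 1e-12)
  # score covariance is diagonal with the eigenvalues on the diagonal
  cv <- crossprod(ordScores(r3)) / (nrow(m) - 1)
  expect_equal(unname(cv), diag(eigenValues(r3)), tolerance = 1e-10)
  mz <- cbind(a = x1, flat = rep(1, 20))
  expect_error(pcaOrdination(mz), "flat")
  expect_equal(unname(explainedVariation(pcaOrdination(mz,
    useCorrelation = FALSE))["r2"]), NA_real_)
})

test_that("NMDS recovers a planar configuration and is rank-invariant", {
  set.seed(89)
  n <- 30
  truth <- matrix(runif(2 * n), n, 2)
  d0 <- as.matrix(dist(truth))
  dimnames(d0) <- list(paste0("p", 1:n), paste0("p", 1:n))
  dm <- new("DissimilarityMatrix", values = d0, metricTag = "geographic_km")
  r <- nmdsOrdination(dm, k = 2, nStarts = 10, seed = 97)
  expect_lt(r@stress, 0.01)
  expect_lt(procrustesError(ordScores(r), truth), 1e-2)
  # any strictly monotone transform of the distances gives the same fit
  dmono <- new("DissimilarityMatrix", values = sqrt(d0) + d0^2,
               metricTag = "geographic_km")
  r2 <- nmdsOrdination(dmono, k = 2, nStarts = 10, seed = 97)
  expect_lt(r2@stress, 0.01)
  expect_lt(procrustesError(ordScores(r2), truth), 5e-2)
  expect_error(nmdsOrdination(matrix(0, 3, 3)), "zero")
})

test_that("RDA matches the per-column regression oracle", {
  set.seed(101)
  n <- 25
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("x1", "x2", "x3")))
  Y <- cbind(X %*% c(1, -1, 0) + rnorm(n), X %*% c(0, 1, 2) + rnorm(n))
  r <- rdaFit(Y, X)
  # oracle: independent lm per response column
  rss <- sum(vapply(1:2, function(j) sum(resid(lm(Y[, j] ~ X))^2), numeric(1)))
  tss <- sum(scale(Y, scale = FALSE)^2)
  expect_equal(r@r2, 1 - rss / tss, tolerance = 1e-10)
  expect_equal(r@adjR2, 1 - (1 - r@r2) * (n - 1) / (n - 3 - 1), tolerance = 1e-12)
  expect_lte(r@adjR2, r@r2)

  # exact linear dependence and constructed orthogonality
  expect_equal(rdaFit(X %*% matrix(rnorm(6), 3, 2), X)@r2, 1, tolerance = 1e-10)
  Yc <- scale(Y, scale = FALSE)
  Xc <- scale(X, scale = FALSE)
  Yorth <- Yc - Xc %*% solve(crossprod(Xc), crossprod(Xc, Yc))
  expect_lt(rdaFit(Yorth, X)@r2, 1e-10)

  Xbad <- cbind(X, x4 = X[, 1] + X[, 2])
  expect_error(rdaFit(Y, Xbad), "x4")
  # vegan cross-check of the constrained eigenvalues
  vr <- vegan::rda(Y ~ X)
  expect_equal(unname(r@eigenvalues),
               unname(vr$CCA$eig)[seq_along(r@eigenvalues)], tolerance = 1e-8)
})

test_that("db-RDA on Euclidean distances equals RDA on the raw data", {
  set.seed(103)
  for (rep in 1:5) {
    n <- 20
    X <- matrix(rnorm(n * 2), n, 2)
    Y <- matrix(rnorm(n * 4), n, 4) + X %*% matrix(rnorm(8), 2, 4)
    D <- as.matrix(dist(Y))
    dimnames(D) <- list(paste0("p", 1:n), paste0("p", 1:n))
    dr <- dbRDA(D, X)
    rr <- rdaFit(Y, X)
    expect_equal(dr@r2, rr@r2, tolerance = 1e-8)
    expect_equal(dr@adjR2, rr@adjR2, tolerance = 1e-8)
    k <- min(length(dr@proportion), length(rr@proportion))
    expect_equal(dr@proportion[1:k], rr@proportion[1:k], tolerance = 1e-8)
  }
})

test_that("db-RDA trivial geometries behave as constructed", {
  set.seed(107)
  n <- 12
  Y <- matrix(rnorm(n * 3), n, 3)
  D <- as.matrix(dist(Y))
  dimnames(D) <- list(paste0("p", 1:n), paste0("p", 1:n))
  pc <- dbRDA(D, matrix(rnorm(n), n, 1))@details$pcoaAxes
  # predictors = the PCoA axes themselves: everything explained
  expect_equal(dbRDA(D, pc)@r2, 1, tolerance = 1e-10)
  # two groups, zero within-group dissimilarity: one binary predictor
  # carries all the variance on the first constrained axis
  g <- rep(c(0, 1), each = 3)
  D2 <- outer(g, g, function(a, b) abs(a - b))
  dimnames(D2) <- list(paste0("p", 1:6), paste0("p", 1:6))
  r2g <- dbRDA(D2, cbind(g = g))
  expect_equal(r2g@r2, 1, tolerance = 1e-10)
  expect_equal(r2g@proportion[1], 1, tolerance = 1e-10)
  expect_error(dbRDA(D, NULL), "predictors")
})

test_that("permutation pseudo-F attains its minimum p under perfect signal", {
  set.seed(109)
  n <- 20
  X <- matrix(rnorm(n * 2), n, 2)
  Y <- X %*% matrix(c(1, 0, 0, 1), 2, 2)
  tst <- permutationPseudoF(Y, X, nPerm = 99)
  expect_equal(tst$p, 1 / 100)
  expect_error(permutationPseudoF(Y, X, nPerm = 9), ">= 19")
  # invariance to predictor column order (same seed)
  Yn <- Y + matrix(rnorm(n * 2), n, 2)
  a <- permutationPseudoF(Yn, X, nPerm = 99, seed = 11)
  b <- permutationPseudoF(Yn, X[, 2:1], nPerm = 99, seed = 11)
  expect_equal(a$F, b$F, tolerance = 1e-12)
  expect_equal(a$p, b$p)
  # permutation p from the same seed is reproducible
  expect_equal(permutationPseudoF(Yn, X, nPerm = 99, seed = 11)$p, a$p)
})

test_that("partial permutation test is calibrated under the Freedman-Lane scheme", {
  set.seed(113)
  n <- 30
  rejections <- 0
  nSim <- 100
  for (s in seq_len(nSim)) {
    Z <- matrix(rnorm(n), n, 1)
    Y <- Z %*% matrix(c(1, 0.5), 1, 2) + matrix(rnorm(n * 2), n, 2)
    X <- matrix(rnorm(n), n, 1)  # independent of Y given anything
    p <- permutationPseudoF(Y, X, nPerm = 99, condition = Z)$p
    rejections <- rejections + (p <= 0.05)
  }
  expect_lt(abs(rejections / nSim - 0.05), 3 * sqrt(0.05 * 0.95 / nSim) + 0.01)
})

test_that("forward selection selects signal first and respects its constraints", {
  set.seed(127)
  n <- 40
  signal <- rnorm(n)
  cand <- cbind(sig = signal, matrix(rnorm(n * 9), n, 9,
                dimnames = list(NULL, paste0("noise", 1:9))))
  nonEmpty <- 0
  sigFirst <- 0
  for (rep in 1:30) {
    Y <- cbind(signal + rnorm(n, 0, 1))  # marginal R2 of the signal ~ 0.5
    tr <- suppressMessages(forwardSelect(Y, cand, nPerm = 99))
    if (length(tr@selected)) {
      nonEmpty <- nonEmpty + 1
      if (tr@selected[1] == "sig") sigFirst <- sigFirst + 1
    }
    # trace constraints hold by construction
    expect_true(all(tr@stepP <= tr@alpha))
    if (length(tr@cumAdjR2)) {
      expect_true(all(diff(tr@cumAdjR2) >= -1e-10))
      expect_lte(max(tr@cumAdjR2), tr@cap + 1e-10)
    }
  }
  # the adjusted-R2 cap rejects the first entry in roughly half the runs
  # (pure-noise candidates add ~0 expected adjusted R2 to the global model,
  # the behavior of the canonical double stopping rule); whenever anything
  # is selected, the true predictor enters first
  expect_gte(nonEmpty, 5)
  expect_identical(sigFirst, nonEmpty)

  # a candidate identical to the response is picked first with minimum p
  Y1 <- matrix(rnorm(n), n, 1)
  cand2 <- cbind(self = Y1[, 1], matrix(rnorm(n * 3), n, 3,
                 dimnames = list(NULL, paste0("v", 1:3))))
  tr2 <- suppressMessages(forwardSelect(Y1, cand2, nPerm = 99))
  expect_identical(tr2@selected[1], "self")
  expect_equal(tr2@stepP[1], 1 / 100)
})
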