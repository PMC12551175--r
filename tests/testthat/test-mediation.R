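test_that("noiseless mediator model recovers Theta exactly", {
  set.seed(61)
  n <- 60; p <- 5; q <- 4
  X <- matrix(rnorm(n * p), n, p)
  Theta <- matrix(0, p, q)
  Theta[1, 1] <- 2; Theta[3, 2] <- -1; Theta[5, 4] <- 0.5
  M <- X %*% Theta                      # zero noise
  md <- MediationData(X, M + 1e-8 * matrix(rnorm(n * q), n, q),
                      rnorm(n))
  fit <- fitMediatorModels(md, s = 0, lambda = 0, nodewiseLambda = 0,
                           seed = 1)
  # compare on the original scale
  eff <- sweep(sweep(fit@thetaHat, 2, fit@scaleM, "*"), 1, fit@scaleX, "/")
  expect_equal(unname(eff), Theta, tolerance = 1e-6)
})

test_that("two-predictor outcome model equals bivariate OLS", {
  set.seed(62)
  n <- 100
  X <- matrix(rnorm(n), n, 1)
  M <- matrix(0.5 * X + rnorm(n), n, 1)
  y <- drop(2 * X - M) + rnorm(n)
  md <- MediationData(X, M, y)
  fit <- fitOutcomeModel(md, s = 0, lambda = 0, nodewiseLambda = 0)
  Xs <- scale(X); Ms <- scale(M); yc <- y - mean(y)
  ols <- qr.coef(qr(cbind(Xs, Ms)), yc)
  expect_equal(fit@gamma@estimate, ols[1], tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(fit@beta@estimate, ols[2], tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("jointly permuting sample order leaves estimates unchanged", {
  sim <- quietSim(simulationConfig(n = 80, p = 6, q = 5, seed = 63))
  md <- sim$data
  set.seed(63)
  perm <- sample(80)
  md2 <- MediationData(exposures(md)[perm, ], mediators(md)[perm, ],
                       outcome(md)[perm], covariates(md)[perm, ],
                       sampleIds = sampleIds(md)[perm])
  # penalties fixed so the fit does not depend on CV fold assignment
  f1 <- fitOutcomeModel(md, s = 1, lambda = 0.05, nodewiseLambda = 0.05)
  f2 <- fitOutcomeModel(md2, s = 1, lambda = 0.05, nodewiseLambda = 0.05)
  expect_equal(f1@gamma@estimate, f2@gamma@estimate, tolerance = 1e-10)
  expect_equal(f1@beta@pValue, f2@beta@pValue, tolerance = 1e-10)
})

test_that("outcome split reproduces the joint debiased fit exactly", {
  sim <- quietSim(simulationConfig(n = 90, p = 7, q = 5, seed = 64))
  md <- sim$data
  fit <- fitOutcomeModel(md, s = 2, seed = 64)
  blk <- hilama:::prepareBlocks(md)
  dd <- decorrelate(cbind(blk$X, blk$M), 2)
  ci <- debiasFit(dd, applyDecorrelation(dd, blk$Y), seed = 64)
  expect_identical(c(fit@gamma@estimate, fit@beta@estimate), ci@estimate)
  expect_identical(c(fit@gamma@pValue, fit@beta@pValue), ci@pValue)
  expect_identical(fit@gamma@label, colnames(exposures(md)))
})

test_that("parallel mediator fits match the serial result exactly", {
  sim <- quietSim(simulationConfig(n = 80, p = 6, q = 6, seed = 65))
  f1 <- fitMediatorModels(sim$data, s = 1, workers = 1, seed = 65)
  f2 <- fitMediatorModels(sim$data, s = 1, workers = 4, seed = 65)
  expect_identical(f1@pValues, f2@pValues)
  expect_identical(f1@thetaHat, f2@thetaHat)
})

test_that("shared directions equal per-column independent fits", {
  sim <- quietSim(simulationConfig(n = 70, p = 5, q = 4, seed = 66))
  md <- sim$data
  fit <- fitMediatorModels(md, s = 1, lambda = 0.05, nodewiseLambda = 0.05)
  blk <- hilama:::prepareBlocks(md)
  dd <- decorrelate(blk$X, 1)
  for (l in c(1, 3)) {
    ci <- debiasFit(trimmed(dd), applyDecorrelation(dd, blk$M[, l]),
                    s = 1, lambda = 0.05, nodewiseLambda = 0.05)
    expect_equal(fit@thetaHat[, l], ci@estimate, tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("effect assembly multiplies theta and beta with shape checks", {
  sim <- quietSim(simulationConfig(n = 80, p = 5, q = 4, seed = 67))
  out <- fitOutcomeModel(sim$data, s = 0, seed = 67)
  med <- fitMediatorModels(sim$data, s = 0, seed = 67)
  eff <- assembleEffects(out, med)
  expect_identical(dim(eff$nie), c(5L, 4L))
  expect_equal(eff$nie[2, 3], med@thetaHat[2, 3] * out@beta@estimate[3])
  expect_identical(unname(eff$nde), out@gamma@estimate)

  # beta = 0 implies a zero NIE matrix
  outZero <- out
  outZero@beta@estimate[] <- 0
  effZero <- assembleEffects(outZero, med)
  expect_true(all(effZero$nie == 0))

  medBad <- med
  medBad@thetaHat <- med@thetaHat[, 1:3]
  medBad@se <- med@se[, 1:3]
  medBad@pValues <- med@pValues[, 1:3]
  expect_error(assembleEffects(out, medBad), "disagree")
})

test_that("rescaled effects undo the column standardization", {
  set.seed(68)
  n <- 500
  X <- matrix(rnorm(2 * n, sd = 4), n, 2)   # wildly different scale
  M <- matrix(0.8 * X[, 1] + rnorm(n, sd = 0.5), n, 1)
  y <- drop(3 * M) + rnorm(n, sd = 0.2)
  md <- MediationData(X, M, y)
  out <- fitOutcomeModel(md, s = 0, lambda = 0, nodewiseLambda = 0)
  med <- fitMediatorModels(md, s = 0, lambda = 0, nodewiseLambda = 0)
  eff <- assembleEffects(out, med, rescale = TRUE)
  expect_equal(unname(eff$thetaHat[1, 1]), 0.8, tolerance = 0.1)
  expect_equal(unname(eff$betaHat[1]), 3, tolerance = 0.1)
  expect_equal(unname(eff$nie[1, 1]), 2.4, tolerance = 0.25)
})
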