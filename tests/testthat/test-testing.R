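test_that("minScreen ranks pairs by the min-p statistic", {
  # hand-enumerated 2x2 example
  pTheta <- matrix(c(0.5, 0.03, 0.2, 0.8), 2, 2)   # [[0.5,0.2],[0.03,0.8]]
  pBeta <- c(0.01, 0.9)
  scr <- minScreen(pTheta, pBeta, K = 2)
  expect_equal(scr$pMin, c(0.01, 0.01))
  expect_equal(scr[, c("k", "l")], data.frame(k = c(1L, 2L), l = c(1L, 1L)))

  # K = p*q returns every pair
  expect_identical(nrow(minScreen(pTheta, pBeta, K = 4)), 4L)
  expect_error(minScreen(pTheta, pBeta, K = 0), "K must")
  expect_error(minScreen(pTheta, pBeta, K = 5), "K must")
})

test_that("minScreen breaks total ties deterministically and exactly at K", {
  pTheta <- matrix(0.5, 4, 5)
  pBeta <- rep(0.5, 5)
  scr <- minScreen(pTheta, pBeta, K = 7)
  expect_identical(nrow(scr), 7L)
  # lexicographic (k, l) order among ties
  expect_equal(scr$k, c(1L, 1L, 1L, 1L, 1L, 2L, 2L))
  expect_equal(scr$l, c(1L, 2L, 3L, 4L, 5L, 1L, 2L))
  expect_identical(scr, minScreen(pTheta, pBeta, K = 7))
})

test_that("joint-significance p-value is the componentwise maximum", {
  pTheta <- matrix(c(0.3, 0, 0.2), 3, 1)
  pBeta <- 0.05
  pairs <- data.frame(k = 1:3, l = c(1L, 1L, 1L))
  expect_equal(jstPvalues(pairs, pTheta, pBeta), c(0.3, 0.05, 0.2))
  expect_equal(jstPvalues(data.frame(k = 2L, l = 1L), matrix(0, 2, 1), 0), 0)
  expect_error(jstPvalues(data.frame(k = 4L, l = 1L), pTheta, pBeta),
               "out of range")
})

test_that("BH threshold matches the hand-derived step-up example", {
  # 4*0.01/1 <= .1 ok; 4*0.02/2 ok; 4*0.2/3 no; 4*0.9/4 no
  bh <- bhSelect(c(0.01, 0.02, 0.2, 0.9), alpha = 0.1)
  expect_equal(bh$threshold, 0.02)
  expect_identical(sort(bh$selected), 1:2)

  none <- bhSelect(rep(1, 5), alpha = 0.1)
  expect_true(is.na(none$threshold))
  expect_length(none$selected, 0)

  all0 <- bhSelect(rep(0, 5), alpha = 0.1)
  expect_identical(sort(all0$selected), 1:5)

  expect_error(bhSelect(c(0.5, 1.2), 0.1), "0, 1")
  expect_error(bhSelect(c(0.5), 1.5), "alpha")
})

test_that("BH selection agrees with brute force on 1000 random vectors", {
  set.seed(71)
  for (i in 1:1000) {
    K <- sample(1:40, 1)
    p <- round(runif(K)^sample(1:3, 1), 3)   # encourage ties and small values
    alpha <- runif(1, 0.01, 0.3)
    bh <- bhSelect(p, alpha)
    expect_identical(bh$threshold, bruteForceBH(p, alpha))
    ref <- if (is.na(bh$threshold)) integer(0) else which(p <= bh$threshold)
    expect_identical(bh$selected, ref)
  }
})

test_that("q-values match the standard BH adjustment", {
  set.seed(72)
  p <- runif(25)
  expect_equal(bhSelect(p, 0.1)$qValue, p.adjust(p, "BH"), tolerance = 1e-12)
})

test_that("decreasing one p-value never shrinks the BH selection", {
  set.seed(73)
  for (i in 1:200) {
    p <- runif(sample(3:20, 1))
    alpha <- 0.1
    sel0 <- bhSelect(p, alpha)$selected
    j <- sample(seq_along(p), 1)
    p2 <- p
    p2[j] <- p[j] * runif(1)
    sel1 <- bhSelect(p2, alpha)$selected
    expect_true(all(setdiff(sel0, j) %in% sel1))
    expect_gte(length(sel1), length(sel0))
  }
})

test_that("testPaths composes screening, maxP and BH with auto K", {
  sim <- quietSim(simulationConfig(n = 80, p = 3, q = 3, seed = 74))
  out <- fitOutcomeModel(sim$data, s = 0, seed = 74)
  med <- fitMediatorModels(sim$data, s = 0, seed = 74)
  res <- testPaths(out, med, K = 5, alpha = 0.2)

  scr <- minScreen(med@pValues, out@beta@pValue, K = 5)
  pm <- jstPvalues(scr, med@pValues, out@beta@pValue)
  bh <- bhSelect(pm, 0.2)
  expect_equal(screenedPaths(res)$pMax, pm)
  expect_equal(screenedPaths(res)[, c("k", "l")], scr[, c("k", "l")])
  expect_identical(bhThreshold(res), bh$threshold)
  expect_identical(selectedPaths(res)[, c("k", "l")],
                   scr[bh$selected, c("k", "l")],
                   ignore_attr = TRUE)

  # NIE attached to selected pairs equals theta_hat * beta_hat
  sel <- selectedPaths(res)
  if (nrow(sel) > 0) {
    expect_equal(sel$nie,
                 med@thetaHat[cbind(sel$k, sel$l)] *
                   out@beta@estimate[sel$l],
                 ignore_attr = TRUE)
  }

  # auto K is a tenth of all pairs, clipped to at least one
  resAuto <- testPaths(out, med, K = "auto", alpha = 0.2)
  expect_identical(resAuto@K, 1L)   # round(0.1 * 9) clipped up to 1
})

test_that("all-null p-value matrices select nothing", {
  sim <- quietSim(simulationConfig(n = 80, p = 3, q = 3, seed = 75))
  out <- fitOutcomeModel(sim$data, s = 0, seed = 75)
  med <- fitMediatorModels(sim$data, s = 0, seed = 75)
  med@pValues[] <- 1
  out@beta@pValue[] <- 1
  res <- testPaths(out, med, K = 9, alpha = 0.1)
  expect_identical(nrow(selectedPaths(res)), 0L)
  expect_true(is.na(bhThreshold(res)))
})
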