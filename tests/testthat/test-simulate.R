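test_that("config validation catches out-of-range parameters", {
  expect_error(simulationConfig(n = 100, p = 10, q = 10, rho = 1), "rho")
  expect_error(simulationConfig(n = 100, p = 10, q = 10, rP = 1.2),
               "fractions")
  expect_error(simulationConfig(n = 2, p = 10, q = 10), "dimensions")
  cfg <- simulationConfig(n = 100, p = 10, q = 10)
  expect_s3_class(cfg, "SimulationConfig")
  expect_identical(cfg$r, 3L)
  expect_identical(cfg$s, 2L)
  expect_equal(cfg$signalSd, sqrt(0.1))
})

test_that("no-signal and no-confounding regimes produce the stated structure", {
  # rP = 0: no exposure effects anywhere
  sim0 <- suppressWarnings(
    simulateDataset(simulationConfig(n = 50, p = 10, q = 8, rP = 0,
                                     seed = 81)))
  expect_true(all(sim0$truth$Theta == 0))
  expect_true(all(sim0$truth$gamma == 0))
  expect_identical(nrow(sim0$truth$activeSet), 0L)
  expect_length(sim0$truth$A, 0)

  # rH = 0: latent loadings vanish entirely
  simNc <- suppressWarnings(
    simulateDataset(simulationConfig(n = 50, p = 10, q = 8, rH = 0,
                                     seed = 82)))
  expect_true(all(simNc$truth$Psi1 == 0))
  expect_true(all(simNc$truth$Psi2 == 0))

  # intermediate density: each loading row carries the stated fraction
  simHalf <- suppressWarnings(
    simulateDataset(simulationConfig(n = 50, p = 20, q = 10, rH = 0.5,
                                     seed = 83)))
  expect_equal(rowSums(simHalf$truth$Psi1 != 0), rep(10, 2))
  expect_equal(rowSums(simHalf$truth$Psi2 != 0), rep(5, 2))
})

test_that("exposure noise has the specified AR(1) covariance", {
  sim <- simulateDataset(simulationConfig(n = 5000, p = 4, q = 2, r = 0,
                                          s = 0, rho = 0.6, rP = 0,
                                          seed = 84))
  EX <- exposures(sim$data)   # with r = s = 0 and rP = 0, X is pure E_X
  emp <- cov(EX)
  expect_equal(unname(emp), outer(1:4, 1:4, function(i, j) 0.6^abs(i - j)),
               tolerance = 0.05)
})

test_that("truth bookkeeping is exact and support sizes follow the design", {
  for (sd in 1:5) {
    cfg <- simulationConfig(n = 60, p = 40, q = 30, seed = sd)
    sim <- simulateDataset(cfg)
    tr <- sim$truth
    # active set recomputed from Theta and beta
    S <- which((tr$Theta != 0) &
                 matrix(tr$beta != 0, 40, 30, byrow = TRUE), arr.ind = TRUE)
    expect_identical(nrow(tr$activeSet), nrow(S))
    expect_setequal(paste(tr$activeSet$k, tr$activeSet$l),
                    paste(S[, 1], S[, 2]))
    # row/column sparsity
    expect_identical(sum(rowSums(tr$Theta != 0) > 0), 4L)   # round(40*0.1)
    expect_true(all(rowSums(tr$Theta != 0)[rowSums(tr$Theta != 0) > 0]
                    %in% 5:20))
    expect_identical(sum(tr$beta != 0), 3L)                 # round(30*0.1)
    expect_identical(tr$s01 + tr$s11, 3L)
    expect_identical(sum(tr$gamma != 0), 4L)
    # s01 placed on inactive columns, s11 on active ones
    bSupp <- which(tr$beta != 0)
    expect_identical(sum(bSupp %in% tr$Ac), tr$s01)
    expect_identical(sum(bSupp %in% tr$A), tr$s11)
  }
})

test_that("row support is truncated with a warning when q < 5", {
  expect_warning(
    sim <- simulateDataset(simulationConfig(n = 50, p = 10, q = 3, seed = 85)),
    "truncated")
  expect_true(all(rowSums(sim$truth$Theta != 0) <= 3))
})

test_that("identical seeds reproduce identical datasets", {
  cfg <- simulationConfig(n = 40, p = 8, q = 6, rho = 0.3, seed = 86)
  s1 <- suppressWarnings(simulateDataset(cfg))
  s2 <- suppressWarnings(simulateDataset(cfg))
  expect_identical(exposures(s1$data), exposures(s2$data))
  expect_identical(outcome(s1$data), outcome(s2$data))
  expect_identical(s1$truth$Theta, s2$truth$Theta)
})

test_that("selection metrics follow the set-arithmetic definitions", {
  truth <- list(activeSet = data.frame(k = rep(1:2, each = 5),
                                       l = rep(1:5, 2)))
  # oracle selection
  ev <- evaluateSelection(truth$activeSet, truth)
  expect_equal(ev$fdp, 0)
  expect_equal(ev$tpp, 1)
  # empty selection: 0/max convention
  ev0 <- evaluateSelection(data.frame(k = integer(0), l = integer(0)), truth)
  expect_equal(ev0$fdp, 0)
  expect_equal(ev0$tpp, 0)
  # 8 true + 2 false of |S| = 10
  sel <- rbind(truth$activeSet[1:8, ], data.frame(k = 9:10, l = 1:2))
  ev2 <- evaluateSelection(sel, truth)
  expect_equal(ev2$fdp, 0.2)
  expect_equal(ev2$tpp, 0.8)
})

test_that("mean bias averages |true - estimated| NIE over the active set", {
  sim <- suppressWarnings(
    simulateDataset(simulationConfig(n = 50, p = 10, q = 8, seed = 87)))
  tr <- sim$truth
  nieTrue <- sweep(tr$Theta, 2, tr$beta, "*")
  ev <- evaluateSelection(tr$activeSet, tr, nieHat = nieTrue)
  expect_equal(ev$meanBias, 0)
  ev2 <- evaluateSelection(tr$activeSet, tr, nieHat = nieTrue + 0.3)
  expect_equal(ev2$meanBias, 0.3, tolerance = 1e-12)
  # empty active set: bias 0 by convention
  sim0 <- suppressWarnings(
    simulateDataset(simulationConfig(n = 50, p = 10, q = 8, rP = 0,
                                     seed = 88)))
  ev3 <- evaluateSelection(data.frame(k = 1L, l = 1L), sim0$truth,
                           nieHat = matrix(1, 10, 8))
  expect_equal(ev3$meanBias, 0)
})

test_that("the simulation harness is deterministic and aggregates per cell", {
  grid <- list(simulationConfig(n = 80, p = 8, q = 6, seed = 1),
               simulationConfig(n = 80, p = 8, q = 6, rho = 0.4, seed = 1))
  t1 <- suppressWarnings(
    runSimulationStudy(grid, reps = 2, alpha = 0.2, seeds = c(4, 5)))
  t2 <- suppressWarnings(
    runSimulationStudy(grid, reps = 2, alpha = 0.2, seeds = c(4, 5)))
  expect_identical(t1, t2)
  expect_identical(nrow(t1), 2L)
  expect_true(all(c("fdp", "tpp", "meanBias", "nFail") %in% names(t1)))

  one <- suppressWarnings(runSimulationStudy(grid[1], reps = 1, alpha = 0.2))
  expect_true(is.na(one$fdpSd))
  expect_identical(one$reps, 1L)
})

test_that("failing replicates are excluded and counted", {
  # n below the minimum the initial fit accepts: every replicate fails
  grid <- simulationConfig(n = 6, p = 3, q = 21, seed = 1)
  tab <- suppressMessages(
    suppressWarnings(runSimulationStudy(grid, reps = 2, alpha = 0.1)))
  expect_identical(tab$nFail, 2L)
  expect_identical(tab$reps, 0L)
})
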