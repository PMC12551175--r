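#' Configuration for the synthetic mediation-data generator
#'
#' Collects and validates the parameters of the factor-model generative
#' design used throughout the simulation studies: exposures confounded by
#' observed covariates Z and latent factors H with AR(1) idiosyncratic
#' noise, mediators driven by the sparse exposure-effect matrix
#' \eqn{\Theta} plus confounding, and an outcome combining sparse direct
#' effects, mediator effects, covariate and latent effects, and unit
#' Gaussian noise.
#'
#' @param n,p,q sample size, exposure dimension, mediator dimension.
#' @param r dimension of observed baseline covariates (default 3).
#' @param s number of latent confounders (default 2).
#' @param rho AR(1) correlation of the exposure noise,
#'   \eqn{\Sigma_{E,kl} = \rho^{|k-l|}}, in [0, 1).
#' @param eta latent/covariate confounding-effect magnitude: entries of
#'   \eqn{\Phi_2, \Psi_2, \phi, \psi} are Rademacher-signed N(eta, 1).
#' @param rP,rQ sparsity fractions: round(p*rP) active exposure rows in
#'   \eqn{\Theta} (and nonzeros in \eqn{\gamma}); round(q*rQ) nonzeros in
#'   \eqn{\beta} (default 0.1 each).
#' @param rH confounding density: fraction of entries kept (nonzero) per
#'   row of the latent loading matrices \eqn{\Psi_1, \Psi_2}; `rH = 0`
#'   means no latent confounding (default 1, fully dense).
#' @param kappa signal-magnitude mean: nonzero effects are
#'   Rademacher-signed N(kappa, signalSd^2) (default 0.8).
#' @param signalSd standard deviation of the signal magnitudes; default
#'   `sqrt(0.1)`, reading the conventional N(mean, variance) notation.
#' @param seed integer seed driving all randomness of one draw.
#' @return a validated list of class `"SimulationConfig"`.
#' @export
simulationConfig <- function(n, p, q, r = 3L, s = 2L, rho = 0, eta = 1,
                             rP = 0.1, rQ = 0.1, rH = 1, kappa = 0.8,
                             signalSd = sqrt(0.1), seed = 1L) {
  cfg <- list(n = as.integer(n), p = as.integer(p), q = as.integer(q),
              r = as.integer(r), s = as.integer(s), rho = rho, eta = eta,
              rP = rP, rQ = rQ, rH = rH, kappa = kappa,
              signalSd = signalSd, seed = as.integer(seed))
  with(cfg, {
    if (n < 4L || p < 1L || q < 1L || r < 0L || s < 0L)
      stop("invalid dimensions in simulation config")
    if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
    if (any(c(rP, rQ, rH) < 0) || any(c(rP, rQ, rH) > 1))
      stop("sparsity fractions rP, rQ, rH must lie in [0, 1]")
    if (signalSd < 0) stop("signalSd must be non-negative")
  })
  structure(cfg, class = "SimulationConfig")
}

roundHalfUp <- function(x) floor(x + 0.5)

## Rademacher-signed normal draws: xi * N(mean, sd^2), xi = +/-1 w.p. 1/2.
rSignedNormal <- function(m, mean, sd = 1) {
  sample(c(-1, 1), m, replace = TRUE) * stats::rnorm(m, mean, sd)
}

## Zero a fraction (1 - rH) of entries in each row, uniformly at random.
sparsifyRows <- function(A, rH) {
  if (rH >= 1 || nrow(A) == 0L) return(A)
  d <- ncol(A)
  nZero <- roundHalfUp((1 - rH) * d)
  for (i in seq_len(nrow(A))) A[i, sample.int(d, nZero)] <- 0
  A
}

sampleSafe <- function(x, size, prob = NULL) {
  if (length(x) == 1L) return(rep(x, min(size, 1L)))
  sample(x, size, prob = prob)
}

#' Generate a synthetic mediation dataset with ground truth
#'
#' Draws one dataset from the factor-model generative design described in
#' [simulationConfig()]:
#' \deqn{X = Z \Phi_1 + H \Psi_1 + E_X, \quad
#'       M = X \Theta + Z \Phi_2 + H \Psi_2 + E_M, \quad
#'       Y = X \gamma + M \beta + Z \phi + H \psi + \epsilon,}
#' with Z, H, \eqn{\Phi_1, \Psi_1} standard normal, \eqn{E_X} Gaussian with
#' AR(1) covariance \eqn{\rho^{|k-l|}}, \eqn{E_M} and \eqn{\epsilon}
#' standard normal, confounding loadings \eqn{\Phi_2, \Psi_2, \phi, \psi}
#' Rademacher-signed N(eta, 1), and sparse Rademacher-signed
#' N(kappa, signalSd^2) effects. Each active row of \eqn{\Theta} carries
#' \eqn{\delta \sim} Unif\{5, ..., 20\} nonzeros (truncated at q); the
#' support of \eqn{\beta} places \eqn{s_{01} = \min(0.2 q r_Q, |A^c|)}
#' entries on mediator columns with no upstream exposure effect and the
#' remaining \eqn{s_{11}} on active columns with probability proportional
#' to the column's share of nonzeros in \eqn{\Theta}. A fraction
#' \eqn{1 - r_H} of each row of \eqn{\Psi_1, \Psi_2} is zeroed after the
#' magnitudes are drawn.
#'
#' @param config a [simulationConfig()] object.
#' @return list with elements `data` (a [MediationData-class]) and `truth`
#'   (list with Theta, beta, gamma, phi, psi, Phi1, Phi2, Psi1, Psi2, H,
#'   activeSet, A, Ac, s01, s11).
#' @export
simulateDataset <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  cf <- config
  set.seed(cf$seed)
  n <- cf$n; p <- cf$p; q <- cf$q; r <- cf$r; s <- cf$s

  Z <- matrix(stats::rnorm(n * r), n, r)
  H <- matrix(stats::rnorm(n * s), n, s)
  Phi1 <- matrix(stats::rnorm(r * p), r, p)
  Psi1 <- sparsifyRows(matrix(stats::rnorm(s * p), s, p), cf$rH)

  if (cf$rho > 0) {
    R <- chol(stats::toeplitz(cf$rho^(0:(p - 1))))
    EX <- matrix(stats::rnorm(n * p), n, p) %*% R
  } else EX <- matrix(stats::rnorm(n * p), n, p)
  X <- Z %*% Phi1 + H %*% Psi1 + EX

  Theta <- matrix(0, p, q)
  nActive <- roundHalfUp(p * cf$rP)
  activeRows <- integer(0)
  if (nActive > 0L) {
    activeRows <- sort(sample.int(p, nActive))
    for (k in activeRows) {
      delta <- sample(5:20, 1L)
      if (delta > q) {
        warning("row support size truncated to q = ", q)
        delta <- q
      }
      cols <- sample.int(q, delta)
      Theta[k, cols] <- rSignedNormal(delta, cf$kappa, cf$signalSd)
    }
  }

  Phi2 <- matrix(rSignedNormal(r * q, cf$eta, 1), r, q)
  Psi2 <- sparsifyRows(matrix(rSignedNormal(s * q, cf$eta, 1), s, q), cf$rH)
  EM <- matrix(stats::rnorm(n * q), n, q)
  M <- X %*% Theta + Z %*% Phi2 + H %*% Psi2 + EM

  gamma <- numeric(p)
  if (nActive > 0L) {
    gIdx <- sample.int(p, nActive)
    gamma[gIdx] <- rSignedNormal(nActive, cf$kappa, cf$signalSd)
  }

  colNnz <- colSums(Theta != 0)
  A <- which(colNnz > 0)
  Ac <- which(colNnz == 0)
  nBeta <- as.integer(roundHalfUp(q * cf$rQ))
  s01 <- as.integer(min(roundHalfUp(0.2 * q * cf$rQ), length(Ac)))
  s11 <- nBeta - s01
  if (s11 > length(A)) {
    extra <- s11 - length(A)
    s11 <- length(A)
    s01 <- as.integer(min(s01 + extra, length(Ac)))
    warning("beta support adjusted: not enough active mediator columns")
  }
  beta <- numeric(q)
  supp <- integer(0)
  if (s01 > 0L) supp <- c(supp, sampleSafe(Ac, s01))
  if (s11 > 0L)
    supp <- c(supp, sampleSafe(A, s11, prob = colNnz[A] / sum(colNnz)))
  beta[supp] <- rSignedNormal(length(supp), cf$kappa, cf$signalSd)

  phi <- rSignedNormal(r, cf$eta, 1)
  psi <- rSignedNormal(s, cf$eta, 1)
  Y <- as.numeric(X %*% gamma + M %*% beta + Z %*% phi + H %*% psi +
                    stats::rnorm(n))

  active <- which((Theta != 0) &
                    matrix(beta != 0, p, q, byrow = TRUE), arr.ind = TRUE)
  activeSet <- data.frame(k = as.integer(active[, 1L]),
                          l = as.integer(active[, 2L]))
  activeSet <- activeSet[order(activeSet$k, activeSet$l), , drop = FALSE]
  rownames(activeSet) <- NULL

  rownames(X) <- rownames(M) <- paste0("sample", seq_len(n))
  colnames(X) <- paste0("X", seq_len(p))
  colnames(M) <- paste0("M", seq_len(q))
  data <- MediationData(X, M, Y, Z = if (r > 0L) Z else NULL,
                        sampleIds = rownames(X))
  truth <- list(Theta = Theta, beta = beta, gamma = gamma, phi = phi,
                psi = psi, Phi1 = Phi1, Phi2 = Phi2, Psi1 = Psi1,
                Psi2 = Psi2, H = H, activeSet = activeSet, A = A, Ac = Ac,
                s01 = s01, s11 = s11)
  list(data = data, truth = truth)
}

#' Evaluate a selected path set against the simulation truth
#'
#' Computes the false discovery proportion, true positive proportion and
#' mean indirect-effect bias of a selected path set:
#' \deqn{FDP = |\hat S \cap S^c| / \max(|\hat S|, 1), \quad
#'       TPP = |\hat S \cap S| / \max(|S|, 1),}
#' and, when estimates are supplied, the mean absolute bias
#' \eqn{\sum_{(k,l) \in S} |\theta_{kl}\beta_l -
#' \hat\theta_{kl}\hat\beta_l| / |S|} over the true active set.
#'
#' @param selected a [PathTestResult-class] or a data.frame with integer
#'   columns `k`, `l`.
#' @param truth the `truth` element of [simulateDataset()].
#' @param nieHat optional p x q matrix of estimated indirect effects
#'   \eqn{\hat\theta_{kl}\hat\beta_l} (for the bias metric).
#' @return list with `fdp`, `tpp` and `meanBias` (NA when `nieHat` is
#'   missing, 0 when the true active set is empty).
#' @export
evaluateSelection <- function(selected, truth, nieHat = NULL) {
  if (is(selected, "PathTestResult")) selected <- selectedPaths(selected)
  key <- function(df) paste(df$k, df$l)
  S <- truth$activeSet
  hatKeys <- key(selected)
  trueKeys <- key(S)
  nSel <- length(hatKeys)
  fdp <- sum(!(hatKeys %in% trueKeys)) / max(nSel, 1L)
  tpp <- sum(hatKeys %in% trueKeys) / max(nrow(S), 1L)
  meanBias <- NA_real_
  if (!is.null(nieHat)) {
    if (nrow(S) == 0L) meanBias <- 0 else {
      idx <- cbind(S$k, S$l)
      trueNie <- truth$Theta[idx] * truth$beta[S$l]
      meanBias <- mean(abs(trueNie - nieHat[idx]))
    }
  }
  list(fdp = fdp, tpp = tpp, meanBias = meanBias)
}

#' Run a grid of simulation replicates through the full pipeline
#'
#' For each configuration cell and each replicate seed: simulate a dataset,
#' fit the outcome and mediator models, select paths at level `alpha`, and
#' score the selection against the truth. Replicate failures are counted
#' and excluded from the aggregates.
#'
#' @param grid a single [simulationConfig()] or a list of them.
#' @param reps number of Monte Carlo replicates per cell.
#' @param alpha nominal FDR level (default 0.1).
#' @param workers parallel workers for the mediator-model fits.
#' @param K screening size passed to [testPaths()].
#' @param s factor count (`"auto"` or integer) for both models.
#' @param seeds optional integer vector of replicate seeds (default
#'   `seq_len(reps)`); the cell config's own seed is ignored.
#' @return data.frame with one row per cell: the cell parameters, means
#'   and standard deviations of fdp/tpp/meanBias over successful
#'   replicates, and the failure count.
#' @export
runSimulationStudy <- function(grid, reps, alpha = 0.1, workers = 1L,
                               K = "auto", s = "auto", seeds = NULL) {
  if (inherits(grid, "SimulationConfig")) grid <- list(grid)
  if (reps < 1L) stop("reps must be at least 1")
  if (is.null(seeds)) seeds <- seq_len(reps)
  stopifnot(length(seeds) == reps)
  rows <- lapply(grid, function(cfg) {
    mets <- vector("list", reps)
    nFail <- 0L
    for (i in seq_len(reps)) {
      cfgI <- do.call(simulationConfig,
                      utils::modifyList(unclass(cfg), list(seed = seeds[i])))
      val <- tryCatch({
        sim <- simulateDataset(cfgI)
        out <- fitOutcomeModel(sim$data, s = s, seed = seeds[i])
        med <- fitMediatorModels(sim$data, s = s, workers = workers,
                                 seed = seeds[i])
        res <- testPaths(out, med, K = K, alpha = alpha)
        eff <- assembleEffects(out, med, rescale = TRUE)
        evaluateSelection(res, sim$truth, nieHat = eff$nie)
      }, error = function(e) {
        message("replicate ", i, " failed: ", conditionMessage(e))
        NULL
      })
      if (is.null(val)) nFail <- nFail + 1L else mets[[i]] <- val
    }
    mets <- mets[!vapply(mets, is.null, logical(1L))]
    pull <- function(f) vapply(mets, `[[`, numeric(1L), f)
    agg <- function(x) c(mean = mean(x), sd = if (length(x) > 1L) stats::sd(x) else NA_real_)
    fd <- agg(pull("fdp")); tp <- agg(pull("tpp")); mb <- agg(pull("meanBias"))
    data.frame(n = cfg$n, p = cfg$p, q = cfg$q, rho = cfg$rho,
               eta = cfg$eta, rH = cfg$rH, kappa = cfg$kappa,
               reps = length(mets), nFail = nFail,
               fdp = fd[["mean"]], fdpSd = fd[["sd"]],
               tpp = tp[["mean"]], tppSd = tp[["sd"]],
               meanBias = mb[["mean"]], meanBiasSd = mb[["sd"]])
  })
  do.call(rbind, rows)
}
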