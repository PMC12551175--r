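## Shared preprocessing: standardize X and M columns (mean 0, sd 1), center
## Y, and project every block onto the orthogonal complement of Z.
prepareBlocks <- function(data) {
  stopifnot(is(data, "MediationData"))
  sx <- standardizeColumns(exposures(data))
  sm <- standardizeColumns(mediators(data))
  y <- outcome(data) - mean(outcome(data))
  Z <- covariates(data)
  X <- sx$mat
  M <- sm$mat
  if (ncol(Z) > 0L) {
    X <- projectOutCovariates(X, Z)
    M <- projectOutCovariates(M, Z)
    y <- projectOutCovariates(y, Z)
  }
  list(X = X, M = M, Y = y, dropped = c(sx$dropped, sm$dropped),
       rz = ncol(Z),
       scaleX = stats::setNames(sx$scale, colnames(X)),
       scaleM = stats::setNames(sm$scale, colnames(M)))
}

resolveS <- function(s, O, maxS = NULL, ratioThreshold = 1.5) {
  if (identical(s, "auto")) return(estimateTrimCount(O))
  if (identical(s, "ratio"))
    return(estimateNumFactors(O, maxS = maxS, ratioThreshold = ratioThreshold))
  s <- as.integer(s)
  if (is.na(s) || s < 0L)
    stop("s must be \"auto\", \"ratio\" or a non-negative integer")
  s
}

#' Fit the outcome model with decorrelated debiased inference
#'
#' Regresses the (centered, covariate-adjusted) outcome on the concatenated
#' design \eqn{O = [X, M]} of standardized exposures and mediators. The
#' latent factor count is estimated from the spectrum of O (or supplied),
#' the top-s singular directions are trimmed from both O and Y, and every
#' coefficient receives a debiased estimate, standard error and p-value.
#' The first p coefficients are the natural direct effects \eqn{\gamma},
#' the remaining q the mediator-to-outcome effects \eqn{\beta}.
#'
#' @param data a [MediationData-class] object.
#' @param s `"auto"` (trim every singular direction above the noise-bulk
#'   edge, [estimateTrimCount()]), `"ratio"` (the spike-count
#'   eigenvalue-ratio estimate, [estimateNumFactors()]), or an integer.
#' @param lambda,nodewiseLambda penalties passed to [debiasFit()].
#' @param seed integer seed (cross-validation folds).
#' @param maxS,ratioThreshold factor-count selection controls, see
#'   [estimateNumFactors()].
#' @return an [OutcomeFit-class] object.
#' @examples
#' sim <- simulateDataset(simulationConfig(n = 120, p = 8, q = 6, seed = 1))
#' fit <- fitOutcomeModel(sim$data, s = 2, seed = 1)
#' head(as.data.frame(fit@beta))
#' @export
fitOutcomeModel <- function(data, s = "auto", lambda = "cv",
                            nodewiseLambda = "cv", seed = NULL,
                            maxS = NULL, ratioThreshold = 1.5) {
  blk <- prepareBlocks(data)
  O <- cbind(blk$X, blk$M)
  if (ncol(O) < 2L) stop("need p + q >= 2 columns in the outcome design")
  sUsed <- resolveS(s, O, maxS = maxS, ratioThreshold = ratioThreshold)
  dd <- decorrelate(O, sUsed)
  yTilde <- applyDecorrelation(dd, blk$Y)
  ci <- debiasFit(dd, yTilde, lambda = lambda,
                  nodewiseLambda = nodewiseLambda, seed = seed)
  p <- ncol(blk$X)
  idx <- seq_len(p)
  sub <- function(keep) new("CoefficientInference",
                            label = ci@label[keep], estimate = ci@estimate[keep],
                            initial = ci@initial[keep], se = ci@se[keep],
                            pValue = ci@pValue[keep])
  new("OutcomeFit",
      gamma = sub(idx),
      beta = sub(setdiff(seq_along(ci@estimate), idx)),
      sUsed = as.integer(sUsed),
      noiseVariance = attr(ci, "noiseVariance"),
      dropped = blk$dropped,
      scaleX = blk$scaleX, scaleM = blk$scaleM)
}

setMethod("show", "OutcomeFit", function(object) {
  cat("OutcomeFit:", length(object@gamma), "exposures,",
      length(object@beta), "mediators; s =", object@sUsed, "\n")
  cat("  residual variance:", signif(object@noiseVariance, 4L), "\n")
})

#' Fit the exposure-to-mediator models column-wise
#'
#' Estimates the p x q coefficient matrix \eqn{\Theta} of the mediator
#' model by regressing each (standardized, covariate-adjusted, decorrelated)
#' mediator column on the decorrelated exposure design. The exposure design
#' is decorrelated once with its own factor count, and the p nodewise
#' projection directions are computed once and shared by all q column fits,
#' which may run in parallel. Results are identical for any `workers`
#' value: all per-column seeds are derived from `seed` before dispatch.
#'
#' @param data a [MediationData-class] object.
#' @param s `"auto"`, `"ratio"` or an integer factor count for the
#'   exposure design (see [fitOutcomeModel()]).
#' @param workers number of parallel workers for the q column fits.
#' @inheritParams fitOutcomeModel
#' @return a [MediatorEffectMatrix-class] object.
#' @export
fitMediatorModels <- function(data, s = "auto", workers = 1L, lambda = "cv",
                              nodewiseLambda = "cv", seed = NULL,
                              maxS = NULL, ratioThreshold = 1.5) {
  blk <- prepareBlocks(data)
  X <- blk$X
  M <- blk$M
  q <- ncol(M)
  sUsed <- resolveS(s, X, maxS = maxS, ratioThreshold = ratioThreshold)
  dd <- decorrelate(X, sUsed)
  dirs <- nodewiseDirections(trimmed(dd), lambda = nodewiseLambda,
                             seed = seed)
  colSeeds <- if (is.null(seed)) rep(list(NULL), q) else
    as.list(withSeed(seed, sample.int(.Machine$integer.max, q)))
  fitColumn <- function(l) {
    mTilde <- applyDecorrelation(dd, M[, l])
    ci <- debiasFit(trimmed(dd), mTilde, s = sUsed, directions = dirs,
                    lambda = lambda, nodewiseLambda = nodewiseLambda,
                    seed = colSeeds[[l]])
    list(est = ci@estimate, se = ci@se, p = ci@pValue)
  }
  runOne <- function(l) tryCatch(fitColumn(l), error = function(e)
    stop("mediator column ", l, " failed: ", conditionMessage(e), call. = FALSE))
  res <- if (workers > 1L)
    parallel::mclapply(seq_len(q), runOne, mc.cores = workers)
  else lapply(seq_len(q), runOne)
  bad <- vapply(res, inherits, logical(1L), "try-error")
  if (any(bad)) stop(res[[which(bad)[1L]]])
  dn <- list(colnames(X), colnames(M))
  new("MediatorEffectMatrix",
      thetaHat = matrix(unlist(lapply(res, `[[`, "est")), ncol = q, dimnames = dn),
      se = matrix(unlist(lapply(res, `[[`, "se")), ncol = q, dimnames = dn),
      pValues = matrix(unlist(lapply(res, `[[`, "p")), ncol = q, dimnames = dn),
      sUsed = as.integer(sUsed),
      dropped = blk$dropped,
      scaleX = blk$scaleX, scaleM = blk$scaleM)
}

setMethod("show", "MediatorEffectMatrix", function(object) {
  d <- dim(object@thetaHat)
  cat("MediatorEffectMatrix:", d[1L], "exposures x", d[2L],
      "mediators; s =", object@sUsed, "\n")
  cat("  min p-value:", signif(min(object@pValues), 4L), "\n")
})

#' Assemble natural direct and indirect effect estimates
#'
#' Combines the outcome-model and mediator-model fits into effect
#' estimates on the per-unit-exposure scale: the natural direct effect of
#' exposure k is \eqn{NDE_k = \hat\gamma_k}, and the natural indirect
#' effect through mediator l is \eqn{NIE_{kl} = \hat\theta_{kl}
#' \hat\beta_l}.
#'
#' @param outcomeFit an [OutcomeFit-class].
#' @param mediatorFit a [MediatorEffectMatrix-class].
#' @param rescale logical; `FALSE` (default) reports effects on the
#'   standardized scale the models were fit on, `TRUE` converts back to the
#'   original data units using the stored column standard deviations
#'   (\eqn{\gamma_k / \sigma_{X_k}}, \eqn{\beta_l / \sigma_{M_l}},
#'   \eqn{\theta_{kl} \sigma_{M_l} / \sigma_{X_k}}, so
#'   \eqn{NIE_{kl} = \theta_{kl} \beta_l / \sigma_{X_k}}).
#' @return list with `nde` (length-p vector), `nie` (p x q matrix), and the
#'   rescaled `betaHat` and `thetaHat` used to form them.
#' @export
assembleEffects <- function(outcomeFit, mediatorFit, rescale = FALSE) {
  stopifnot(is(outcomeFit, "OutcomeFit"),
            is(mediatorFit, "MediatorEffectMatrix"))
  theta <- mediatorFit@thetaHat
  beta <- outcomeFit@beta@estimate
  gamma <- coefEstimates(outcomeFit@gamma)
  if (length(outcomeFit@gamma) != nrow(theta) ||
      length(beta) != ncol(theta))
    stop("outcome and mediator fits disagree on dimensions (p, q)")
  if (rescale) {
    sx <- outcomeFit@scaleX
    sm <- outcomeFit@scaleM
    gamma <- gamma / sx
    beta <- beta / sm
    theta <- sweep(sweep(theta, 2L, sm, "*"), 1L, sx, "/")
  }
  nie <- sweep(theta, 2L, beta, "*")
  list(nde = gamma, nie = nie, betaHat = beta, thetaHat = theta)
}
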