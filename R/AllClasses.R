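#' @import methods
NULL

#' MediationData: exposures, mediators, outcome and covariates on a shared
#' sample axis
#'
#' Container for the observed blocks of a mediation analysis: an exposure
#' matrix \eqn{X} (n samples by p features), a mediator matrix \eqn{M}
#' (n by q), an outcome vector \eqn{Y} (length n) and an optional matrix of
#' baseline covariates \eqn{Z} (n by r). All blocks must share the same
#' samples in the same order.
#'
#' @slot X numeric matrix of exposures, n x p.
#' @slot M numeric matrix of mediators, n x q.
#' @slot Y numeric outcome vector of length n.
#' @slot Z numeric covariate matrix, n x r (r may be 0).
#' @slot sampleIds character vector of sample identifiers, length n.
#'
#' @seealso [MediationData()] for the user-facing constructor,
#'   [readMediationData()] to build one from delimited files.
#' @export
setClass("MediationData",
  representation(
    X = "matrix",
    M = "matrix",
    Y = "numeric",
    Z = "matrix",
    sampleIds = "character"
  )
)

setValidity("MediationData", function(object) {
  n <- nrow(object@X)
  msg <- character()
  if (is.null(n) || n < 4L)
    msg <- c(msg, "need at least 4 samples")
  if (ncol(object@X) < 1L) msg <- c(msg, "X must have at least one column")
  if (ncol(object@M) < 1L) msg <- c(msg, "M must have at least one column")
  if (nrow(object@M) != n) msg <- c(msg, "X and M disagree on sample count")
  if (length(object@Y) != n) msg <- c(msg, "Y length does not match X rows")
  if (nrow(object@Z) != n && ncol(object@Z) > 0L)
    msg <- c(msg, "Z rows do not match X rows")
  if (length(object@sampleIds) != n)
    msg <- c(msg, "sampleIds length does not match sample count")
  if (anyNA(object@X) || anyNA(object@M) || anyNA(object@Y) || anyNA(object@Z))
    msg <- c(msg, "missing values are not allowed")
  if (!all(is.finite(object@X)) || !all(is.finite(object@M)) ||
      !all(is.finite(object@Y)))
    msg <- c(msg, "non-finite values are not allowed")
  r <- ncol(object@Z)
  if (r > 0L) {
    if (r >= n) msg <- c(msg, "Z must have fewer columns than samples")
    else if (qr(object@Z)$rank < r)
      msg <- c(msg, "Z is rank deficient (collinear covariate columns)")
  }
  if (length(msg)) msg else TRUE
})

#' DecorrelatedDesign: spectrally trimmed design matrix
#'
#' Holds the thin singular value decomposition of a design matrix
#' \eqn{O = \sum_i \lambda_i u_i v_i^T} together with a trimmed factor count
#' \eqn{s} and the decorrelated design
#' \eqn{\tilde O = \sum_{i>s} \lambda_i u_i v_i^T}. The implied decorrelating
#' projector \eqn{F_{dc} = \sum_{i>s} u_i u_i^T} is never materialised:
#' applying it to new data ([applyDecorrelation()]) subtracts the rank-s
#' reconstruction \eqn{U_s U_s^T A}.
#'
#' @slot source the original design matrix O (n x d).
#' @slot u left singular vectors (n x min(n, d)).
#' @slot d singular values, non-increasing.
#' @slot v right singular vectors (d x min(n, d)).
#' @slot s integer, number of leading singular directions trimmed.
#' @slot trimmed the decorrelated design (n x d).
#'
#' @seealso [decorrelate()], [applyDecorrelation()], [estimateNumFactors()]
#' @export
setClass("DecorrelatedDesign",
  representation(
    source = "matrix",
    u = "matrix",
    d = "numeric",
    v = "matrix",
    s = "integer",
    trimmed = "matrix"
  )
)

setValidity("DecorrelatedDesign", function(object) {
  msg <- character()
  m <- min(dim(object@source))
  if (object@s < 0L || object@s >= m)
    msg <- c(msg, "s must satisfy 0 <= s < min(n, d)")
  if (!identical(dim(object@source), dim(object@trimmed)))
    msg <- c(msg, "trimmed must have the dimensions of the source")
  if (is.unsorted(rev(object@d), strictly = FALSE))
    msg <- c(msg, "singular values must be non-increasing")
  if (length(msg)) msg else TRUE
})

#' CoefficientInference: per-coefficient debiased estimates
#'
#' Parallel vectors of debiased point estimates, initial (lasso) estimates,
#' standard errors and two-sided Gaussian p-values for the d coefficients of
#' one regression fit. The p-value invariant
#' \eqn{p_j = 2(1 - \Phi(|\hat\alpha_j| / \hat\sigma_j))} is enforced by the
#' validity method.
#'
#' @slot label character, feature names.
#' @slot estimate debiased coefficient estimates.
#' @slot initial initial (penalised) estimates.
#' @slot se standard errors, finite and positive.
#' @slot pValue two-sided p-values in [0, 1].
#'
#' @seealso [debiasFit()]
#' @export
setClass("CoefficientInference",
  representation(
    label = "character",
    estimate = "numeric",
    initial = "numeric",
    se = "numeric",
    pValue = "numeric"
  )
)

setValidity("CoefficientInference", function(object) {
  d <- length(object@estimate)
  msg <- character()
  if (length(object@label) != d || length(object@initial) != d ||
      length(object@se) != d || length(object@pValue) != d)
    msg <- c(msg, "all slots must have equal length")
  if (!all(is.finite(object@se)) || any(object@se <= 0))
    msg <- c(msg, "standard errors must be finite and positive")
  if (any(object@pValue < 0 | object@pValue > 1))
    msg <- c(msg, "p-values must lie in [0, 1]")
  pv <- 2 * stats::pnorm(abs(object@estimate) / object@se, lower.tail = FALSE)
  if (d > 0 && max(abs(pv - object@pValue)) > 1e-12)
    msg <- c(msg, "p-values inconsistent with estimate/se")
  if (length(msg)) msg else TRUE
})

#' OutcomeFit: inference for the outcome model
#'
#' Result of regressing the outcome on the concatenated exposure and
#' mediator design \eqn{[X, M]} with the decorrelated debiased-lasso engine.
#' The first p coefficients are the direct effects \eqn{\gamma}, the last q
#' the mediator-to-outcome effects \eqn{\beta}.
#'
#' @slot gamma [CoefficientInference-class] for the p exposure coefficients.
#' @slot beta [CoefficientInference-class] for the q mediator coefficients.
#' @slot sUsed integer, factor count trimmed from the concatenated design.
#' @slot noiseVariance plug-in residual variance of the fit.
#' @slot dropped names of constant columns removed before fitting.
#' @slot scaleX,scaleM standard deviations used to standardize the exposure
#'   and mediator columns; estimates divided by these return to the
#'   original units (see [assembleEffects()]).
#'
#' @seealso [fitOutcomeModel()]
#' @export
setClass("OutcomeFit",
  representation(
    gamma = "CoefficientInference",
    beta = "CoefficientInference",
    sUsed = "integer",
    noiseVariance = "numeric",
    dropped = "character",
    scaleX = "numeric",
    scaleM = "numeric"
  )
)

#' MediatorEffectMatrix: inference for the exposure-to-mediator effects
#'
#' p x q matrices of estimates, standard errors and p-values for the
#' exposure-to-mediator coefficient matrix \eqn{\Theta} obtained from q
#' column-wise decorrelated debiased-lasso fits sharing one set of nodewise
#' projection directions.
#'
#' @slot thetaHat p x q matrix of debiased estimates.
#' @slot se p x q matrix of standard errors.
#' @slot pValues p x q matrix of two-sided p-values.
#' @slot sUsed integer, factor count trimmed from the exposure design.
#' @slot dropped names of constant columns removed before fitting.
#' @slot scaleX,scaleM standard deviations used to standardize the exposure
#'   and mediator columns (for rescaling estimates to original units).
#'
#' @seealso [fitMediatorModels()]
#' @export
setClass("MediatorEffectMatrix",
  representation(
    thetaHat = "matrix",
    se = "matrix",
    pValues = "matrix",
    sUsed = "integer",
    dropped = "character",
    scaleX = "numeric",
    scaleM = "numeric"
  )
)

setValidity("MediatorEffectMatrix", function(object) {
  msg <- character()
  if (!identical(dim(object@thetaHat), dim(object@se)) ||
      !identical(dim(object@thetaHat), dim(object@pValues)))
    msg <- c(msg, "thetaHat, se and pValues must share dimensions")
  if (any(object@pValues < 0 | object@pValues > 1, na.rm = TRUE))
    msg <- c(msg, "p-values must lie in [0, 1]")
  ok <- is.finite(object@thetaHat)
  if (any(object@se[ok] <= 0))
    msg <- c(msg, "standard errors must be positive where estimates are finite")
  if (length(msg)) msg else TRUE
})

#' PathTestResult: screened, tested and selected mediation paths
#'
#' Outcome of the path-selection stage: the K pairs retained by MinScreen
#' with their min-p values, the joint-significance (maxP) p-values, the
#' Benjamini-Hochberg data-driven threshold \eqn{P^*} (NA when no ordered
#' p-value satisfies the step-up criterion) and the selected paths with
#' their estimated natural indirect effects.
#'
#' @slot screened data.frame with columns `k`, `l`, `pMin`, `pMax`, `qValue`
#'   for the K screened pairs.
#' @slot selected data.frame with columns `k`, `l`, `pMax`, `nie` for the
#'   selected pairs (subset of `screened`).
#' @slot bhThreshold numeric, the BH threshold P* (NA if none qualifies).
#' @slot alpha nominal FDR level.
#' @slot K integer, number of screened pairs.
#'
#' @seealso [testPaths()], [minScreen()], [bhSelect()]
#' @export
setClass("PathTestResult",
  representation(
    screened = "data.frame",
    selected = "data.frame",
    bhThreshold = "numeric",
    alpha = "numeric",
    K = "integer"
  )
)

setValidity("PathTestResult", function(object) {
  msg <- character()
  if (nrow(object@screened) != object@K)
    msg <- c(msg, "screened set size must equal K")
  if (object@alpha <= 0 || object@alpha >= 1)
    msg <- c(msg, "alpha must lie in (0, 1)")
  if (nrow(object@selected) > 0 && is.na(object@bhThreshold))
    msg <- c(msg, "selection must be empty when no BH threshold exists")
  if (length(msg)) msg else TRUE
})
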