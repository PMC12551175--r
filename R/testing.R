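#' MinScreen: retain the K most promising mediation paths
#'
#' For every exposure-mediator pair (k, l) computes the screening statistic
#' \eqn{P^{min}_{kl} = \min(P_{\hat\theta_{kl}}, P_{\hat\beta_l})} and
#' returns the K pairs with the smallest values. Ties at the boundary are
#' broken by lexicographic (k, l) order so exactly K pairs are returned,
#' deterministically. Screening discards the least promising paths before
#' the joint-significance test, reducing the multiplicity burden.
#'
#' @param pTheta p x q matrix of p-values for the exposure-to-mediator
#'   coefficients.
#' @param pBeta length-q vector of p-values for the mediator-to-outcome
#'   coefficients.
#' @param K number of pairs to retain, between 1 and p*q.
#' @return data.frame with columns `k`, `l`, `pMin`, ordered by increasing
#'   `pMin` (ties by k, then l).
#' @export
minScreen <- function(pTheta, pBeta, K) {
  pTheta <- as.matrix(pTheta)
  p <- nrow(pTheta)
  q <- ncol(pTheta)
  if (length(pBeta) != q)
    stop("pBeta length must equal the number of mediator columns")
  K <- as.integer(K)
  if (K < 1L || K > p * q) stop("K must lie in [1, p*q]; got ", K)
  pMin <- pmin(pTheta, matrix(pBeta, nrow = p, ncol = q, byrow = TRUE))
  kIdx <- rep.int(seq_len(p), q)
  lIdx <- rep(seq_len(q), each = p)
  ord <- order(as.vector(pMin), kIdx, lIdx)[seq_len(K)]
  data.frame(k = kIdx[ord], l = lIdx[ord], pMin = as.vector(pMin)[ord])
}

#' Joint-significance (maxP) p-values for screened pairs
#'
#' The joint-significance test rejects the composite null "no indirect
#' effect through path (k, l)" only when both component coefficients are
#' significant; its p-value is
#' \eqn{P^{max}_{kl} = \max(P_{\hat\theta_{kl}}, P_{\hat\beta_l})}.
#'
#' @param pairs data.frame with integer columns `k` and `l` (as returned by
#'   [minScreen()]).
#' @inheritParams minScreen
#' @return numeric vector of maxP p-values, one per row of `pairs`.
#' @export
jstPvalues <- function(pairs, pTheta, pBeta) {
  pTheta <- as.matrix(pTheta)
  if (any(pairs$k < 1L | pairs$k > nrow(pTheta)) ||
      any(pairs$l < 1L | pairs$l > ncol(pTheta)))
    stop("pair indices out of range")
  pmax(pTheta[cbind(pairs$k, pairs$l)], pBeta[pairs$l])
}

#' Benjamini-Hochberg data-driven threshold and selection
#'
#' Finds the rejection threshold
#' \deqn{P^* = \max\{p_{(i)} : K p_{(i)} / \#\{j : p_j \le p_{(i)}\} \le
#'   \alpha\}}
#' over the ordered p-values \eqn{p_{(1)} \le \ldots \le p_{(K)}} and
#' selects every p-value at or below it. When no ordered p-value satisfies
#' the criterion the threshold is `NA` and nothing is selected.
#'
#' @param pMax numeric vector of K p-values in [0, 1].
#' @param alpha nominal FDR level in (0, 1).
#' @return list with `threshold` (numeric, `NA` if none qualifies),
#'   `selected` (integer indices into `pMax`), and `qValue` (BH-adjusted
#'   p-values within the screened set, informational).
#' @export
bhSelect <- function(pMax, alpha) {
  if (any(pMax < 0 | pMax > 1)) stop("p-values must lie in [0, 1]")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  K <- length(pMax)
  if (K < 1L) stop("need at least one p-value")
  ps <- sort(pMax)
  nLe <- vapply(ps, function(x) sum(pMax <= x), numeric(1L))
  ok <- (K * ps / nLe) <= alpha
  threshold <- if (any(ok)) max(ps[ok]) else NA_real_
  selected <- if (is.na(threshold)) integer(0) else which(pMax <= threshold)
  ord <- order(pMax)
  qSorted <- pmin(rev(cummin(rev(K * pMax[ord] / seq_len(K)))), 1)
  qValue <- numeric(K)
  qValue[ord] <- qSorted
  list(threshold = threshold, selected = selected, qValue = qValue)
}

#' Screen, test and select significant mediation paths
#'
#' Chains [minScreen()] (top-K screening on the min-p statistic),
#' [jstPvalues()] (joint-significance maxP p-values) and [bhSelect()]
#' (Benjamini-Hochberg data-driven threshold at level `alpha`), attaching
#' natural-indirect-effect point estimates \eqn{\hat\theta_{kl}\hat\beta_l}
#' to the selected pairs.
#'
#' @param outcomeFit an [OutcomeFit-class].
#' @param mediatorFit a [MediatorEffectMatrix-class].
#' @param K `"auto"` (the default, `round(0.1 * p * q)` clipped to
#'   `[1, p*q]`) or an integer number of pairs to screen.
#' @param alpha nominal FDR level (default 0.1).
#' @return a [PathTestResult-class] object.
#' @export
testPaths <- function(outcomeFit, mediatorFit, K = "auto", alpha = 0.1) {
  stopifnot(is(outcomeFit, "OutcomeFit"),
            is(mediatorFit, "MediatorEffectMatrix"))
  pTheta <- mediatorFit@pValues
  pBeta <- outcomeFit@beta@pValue
  p <- nrow(pTheta)
  q <- ncol(pTheta)
  if (length(pBeta) != q)
    stop("outcome and mediator fits disagree on the number of mediators")
  if (identical(K, "auto")) K <- min(max(round(0.1 * p * q), 1L), p * q)
  K <- as.integer(K)
  screened <- minScreen(pTheta, pBeta, K)
  screened$pMax <- jstPvalues(screened, pTheta, pBeta)
  bh <- bhSelect(screened$pMax, alpha)
  screened$qValue <- bh$qValue
  nie <- sweep(mediatorFit@thetaHat, 2L, outcomeFit@beta@estimate, "*")
  sel <- screened[bh$selected, c("k", "l", "pMax"), drop = FALSE]
  sel$nie <- nie[cbind(sel$k, sel$l)]
  rownames(sel) <- NULL
  new("PathTestResult", screened = screened, selected = sel,
      bhThreshold = bh$threshold, alpha = alpha, K = K)
}

#' @rdname PathTestResult-class
#' @param object a `PathTestResult`
#' @section Accessors:
#' `selectedPaths()` returns the data.frame of selected pairs with NIE
#' estimates; `screenedPaths()` the K screened pairs; `bhThreshold()` the
#' BH threshold (NA when no pair qualifies).
#' @export
selectedPaths <- function(object) object@selected

#' @rdname PathTestResult-class
#' @export
screenedPaths <- function(object) object@screened

#' @rdname PathTestResult-class
#' @export
bhThreshold <- function(object) object@bhThreshold

setMethod("show", "PathTestResult", function(object) {
  cat("PathTestResult: K =", object@K, "screened pairs, alpha =",
      object@alpha, "\n")
  thr <- if (is.na(object@bhThreshold)) "none" else
    signif(object@bhThreshold, 4L)
  cat("  BH threshold P* =", thr, ";", nrow(object@selected),
      "path(s) selected\n")
})
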