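#' Project out observed baseline covariates
#'
#' Returns the residual of every column of `A` after orthogonal projection
#' onto the complement of the column span of `Z`, i.e.
#' \eqn{P_Z^\perp A = (I - Z (Z^T Z)^{-1} Z^T) A}. Columns of the result are
#' exactly orthogonal to the covariates, which removes any linear influence
#' of observed confounders before the spectral deconfounding step.
#'
#' @param A numeric matrix (n x d) or vector of length n.
#' @param Z numeric covariate matrix (n x r) of full column rank, r < n.
#' @return matrix (or vector, matching `A`) of covariate-adjusted residuals.
#' @examples
#' Z <- matrix(1, 4, 1)
#' projectOutCovariates(c(1, 2, 3, 4), Z)  # centering
#' @export
projectOutCovariates <- function(A, Z) {
  vec <- is.null(dim(A))
  A <- as.matrix(A)
  Z <- as.matrix(Z)
  n <- nrow(A)
  if (nrow(Z) != n) stop("A and Z disagree on the number of samples")
  r <- ncol(Z)
  if (r == 0L) return(if (vec) drop(A) else A)
  if (r >= n) stop("Z must have fewer columns (", r, ") than samples (", n, ")")
  qz <- qr(Z)
  if (qz$rank < r) {
    bad <- qz$pivot[(qz$rank + 1L):r]
    nm <- colnames(Z)
    lab <- if (is.null(nm)) as.character(bad) else nm[bad]
    stop("Z is rank deficient; collinear column(s): ",
         paste(lab, collapse = ", "))
  }
  out <- qr.resid(qz, A)
  if (vec) drop(out) else out
}

#' Estimate the number of latent factors by the eigenvalue-ratio rule
#'
#' Under dense latent confounding the design has a spiked singular spectrum:
#' a few large singular values carry the latent factors, the rest form a
#' bulk. The factor count is estimated as
#' \eqn{\hat s = \arg\max_{1 \le i \le maxS} \lambda_i / \lambda_{i+1}}
#' unless the largest ratio falls below `ratioThreshold`, in which case no
#' spike is declared and \eqn{\hat s = 0}.
#'
#' @param O numeric design matrix (n x d).
#' @param maxS largest admissible factor count; defaults to
#'   `floor(min(n, d) / 2)`.
#' @param ratioThreshold minimum dominant ratio required to declare at
#'   least one factor (default 1.5).
#' @return integer estimate of the factor count, between 0 and `maxS`.
#' @seealso [decorrelate()]
#' @export
estimateNumFactors <- function(O, maxS = NULL, ratioThreshold = 1.5) {
  O <- as.matrix(O)
  m <- min(dim(O))
  if (m < 2L) stop("design too small to estimate a factor count")
  if (is.null(maxS)) maxS <- max(1L, m %/% 2L)
  maxS <- as.integer(maxS)
  if (maxS < 1L || maxS > m %/% 2L)
    stop("maxS must lie in [1, floor(min(n, d)/2)]; got ", maxS)
  lam <- svd(O, nu = 0L, nv = 0L)$d[seq_len(maxS + 1L)]
  eps <- max(lam) * 1e-12
  ratios <- lam[seq_len(maxS)] / pmax(lam[seq_len(maxS) + 1L], eps)
  if (max(ratios) < ratioThreshold) return(0L)
  which.max(ratios)
}

#' Count singular values above the noise-bulk edge
#'
#' Returns the number of singular values exceeding the optimal
#' median-calibrated hard threshold \eqn{\omega(\beta) \cdot
#' \mathrm{median}(\lambda)} (Gavish & Donoho), with
#' \eqn{\beta = \min(n,d)/\max(n,d)} and \eqn{\omega(\beta) \approx 0.56
#' \beta^3 - 0.95 \beta^2 + 1.82 \beta + 1.43}. For a pure-noise matrix the
#' count is 0; latent-factor spikes and strong collinearity directions sit
#' above the bulk and are counted.
#'
#' This is the pipeline's default trimming rule (`s = "auto"`): trimming
#' every direction above the noise bulk removes both the leftover energy of
#' dense latent confounders and the leading collinearity directions of a
#' correlated design, both of which otherwise bias the debiased-lasso
#' coordinates. It deliberately trims more than the spike count that
#' [estimateNumFactors()] targets; the cost is a small loss of efficiency,
#' the benefit is calibrated inference on smaller panels.
#'
#' @param O numeric design matrix (n x d).
#' @return integer trim count, capped at `floor(min(n, d) / 2)`.
#' @seealso [estimateNumFactors()] for the spike-count (eigenvalue-ratio)
#'   estimator, [decorrelate()].
#' @export
estimateTrimCount <- function(O) {
  O <- as.matrix(O)
  n <- nrow(O)
  d <- ncol(O)
  m <- min(n, d)
  if (m < 2L) stop("design too small to estimate a trim count")
  b <- m / max(n, d)
  lam <- svd(O, nu = 0L, nv = 0L)$d
  omega <- 0.56 * b^3 - 0.95 * b^2 + 1.82 * b + 1.43
  s <- sum(lam > omega * stats::median(lam))
  min(as.integer(s), m %/% 2L)
}

#' Spectrally decorrelate a design matrix
#'
#' Computes the thin SVD \eqn{O = \sum_i \lambda_i u_i v_i^T} and removes
#' the top `s` singular directions, returning the decorrelated design
#' \eqn{\tilde O = O - \sum_{i \le s} \lambda_i u_i v_i^T}. This is the
#' action of the decorrelating projector
#' \eqn{F_{dc} = \sum_{i > s} u_i u_i^T}, which (for the estimated factor
#' scores \eqn{\hat H = \sqrt{n}(u_1, \ldots, u_s)}) equals the orthogonal
#' projector onto the complement of the span of \eqn{\hat H}; it suppresses
#' the bias that dense latent confounding induces in regression on O.
#'
#' @param O numeric design matrix (n x d).
#' @param s integer, number of leading singular directions to trim;
#'   `0 <= s < min(n, d)`.
#' @return a [DecorrelatedDesign-class] object.
#' @examples
#' O <- matrix(rnorm(60), 10, 6)
#' dd <- decorrelate(O, 1)
#' max(abs(svd(trimmed(dd))$d[1] - singularValues(dd)[2])) < 1e-8
#' @export
decorrelate <- function(O, s) {
  O <- as.matrix(O)
  m <- min(dim(O))
  s <- as.integer(s)
  if (s < 0L || s >= m)
    stop("s must satisfy 0 <= s < min(n, d) = ", m, "; got ", s)
  sv <- svd(O)
  if (s == 0L) {
    tr <- O
  } else {
    us <- sv$u[, seq_len(s), drop = FALSE]
    tr <- O - us %*% (diag(sv$d[seq_len(s)], s, s) %*%
                        t(sv$v[, seq_len(s), drop = FALSE]))
  }
  new("DecorrelatedDesign", source = O, u = sv$u, d = sv$d, v = sv$v,
      s = s, trimmed = tr)
}

#' @rdname DecorrelatedDesign-class
#' @export
setMethod("trimmed", "DecorrelatedDesign", function(object) object@trimmed)

#' @rdname DecorrelatedDesign-class
#' @export
setMethod("singularValues", "DecorrelatedDesign", function(object) object@d)

#' @rdname DecorrelatedDesign-class
#' @export
setMethod("numFactors", "DecorrelatedDesign", function(object) object@s)

#' @rdname applyDecorrelation
#' @export
setMethod("applyDecorrelation", "DecorrelatedDesign", function(object, a) {
  vec <- is.null(dim(a))
  a <- as.matrix(a)
  if (nrow(a) != nrow(object@source))
    stop("data to decorrelate must share the design's sample axis")
  if (object@s > 0L) {
    us <- object@u[, seq_len(object@s), drop = FALSE]
    a <- a - us %*% crossprod(us, a)
  }
  if (vec) drop(a) else a
})

#' @rdname DecorrelatedDesign-class
#' @details `factorScores()` returns the estimated latent factor scores
#'   \eqn{\hat H = \sqrt{n} (u_1, \ldots, u_s)} (an n x s matrix, empty when
#'   s = 0) under the usual factor-analysis identifiability convention
#'   \eqn{H^T H / n = I_s}.
#' @export
setMethod("factorScores", "DecorrelatedDesign", function(object) {
  n <- nrow(object@source)
  sqrt(n) * object@u[, seq_len(object@s), drop = FALSE]
})

setMethod("show", "DecorrelatedDesign", function(object) {
  d <- dim(object@source)
  cat("DecorrelatedDesign:", d[1L], "x", d[2L], "design,",
      object@s, "factor(s) trimmed\n")
  k <- min(5L, length(object@d))
  cat("  top singular values:",
      paste(signif(object@d[seq_len(k)], 4L), collapse = ", "), "\n")
})

#' Standardize columns of a matrix
#'
#' Centers every column to mean zero and (optionally) scales to unit
#' standard deviation. Constant columns cannot be scaled; they are dropped
#' with a warning and their names returned for bookkeeping.
#'
#' @param A numeric matrix.
#' @param scale logical, scale columns to sd 1 (TRUE) or only center.
#' @return list with elements `mat` (standardized matrix), `dropped`
#'   (names of removed constant columns), `center` and `scale` vectors.
#' @keywords internal
standardizeColumns <- function(A, scale = TRUE) {
  A <- as.matrix(A)
  mu <- colMeans(A)
  Ac <- sweep(A, 2L, mu, "-")
  sd <- sqrt(colSums(Ac^2) / max(nrow(A) - 1L, 1L))
  dropped <- character()
  if (scale) {
    const <- sd == 0
    if (any(const)) {
      dropped <- colnames(A)[const]
      if (is.null(dropped)) dropped <- as.character(which(const))
      warning("dropping constant column(s): ", paste(dropped, collapse = ", "))
      Ac <- Ac[, !const, drop = FALSE]
      sd <- sd[!const]
      mu <- mu[!const]
    }
    Ac <- sweep(Ac, 2L, sd, "/")
  }
  list(mat = Ac, dropped = dropped, center = mu, scale = if (scale) sd else rep(1, ncol(Ac)))
}
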