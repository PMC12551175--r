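#' Construct a MediationData object
#'
#' Bundles the exposure matrix X (n x p), mediator matrix M (n x q), outcome
#' Y (length n) and optional baseline covariates Z (n x r) into a validated
#' [MediationData-class] object. Row order must agree across blocks; when
#' all blocks carry row names they are checked against each other.
#'
#' @param X numeric matrix or data.frame of exposures, samples in rows.
#' @param M numeric matrix or data.frame of mediators, samples in rows.
#' @param Y numeric vector, or single-column matrix, of outcomes.
#' @param Z optional numeric matrix or data.frame of baseline covariates.
#' @param sampleIds optional character vector of sample identifiers;
#'   defaults to the row names of `X`, or `sample1..sampleN`.
#' @return a [MediationData-class] object
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(40), 10, 4)
#' M <- matrix(rnorm(30), 10, 3)
#' Y <- rnorm(10)
#' md <- MediationData(X, M, Y)
#' dim(exposures(md))
#' @export
MediationData <- function(X, M, Y, Z = NULL, sampleIds = NULL) {
  X <- as.matrix(X)
  M <- as.matrix(M)
  if (is.matrix(Y) || is.data.frame(Y)) {
    Y <- as.matrix(Y)
    if (ncol(Y) != 1L) stop("Y must be a vector or single-column matrix")
    Y <- drop(Y)
  }
  Y <- as.numeric(Y)
  n <- nrow(X)
  if (is.null(Z)) Z <- matrix(numeric(0), nrow = n, ncol = 0L)
  Z <- as.matrix(Z)
  storage.mode(X) <- "double"
  storage.mode(M) <- "double"
  if (ncol(Z) > 0L) storage.mode(Z) <- "double"
  if (is.null(sampleIds)) {
    sampleIds <- rownames(X)
    if (is.null(sampleIds)) sampleIds <- paste0("sample", seq_len(n))
  }
  ids <- list(rownames(X), rownames(M), rownames(Z))
  for (rn in ids) {
    if (!is.null(rn) && length(rn) == n && !identical(rn, as.character(sampleIds)))
      stop("sample identifiers disagree across blocks; align rows first")
  }
  if (is.null(colnames(X))) colnames(X) <- paste0("X", seq_len(ncol(X)))
  if (is.null(colnames(M))) colnames(M) <- paste0("M", seq_len(ncol(M)))
  if (ncol(Z) > 0L && is.null(colnames(Z)))
    colnames(Z) <- paste0("Z", seq_len(ncol(Z)))
  new("MediationData", X = X, M = M, Y = Y, Z = Z,
      sampleIds = as.character(sampleIds))
}

#' @rdname MediationData-class
#' @export
setMethod("exposures", "MediationData", function(object) object@X)

#' @rdname MediationData-class
#' @export
setMethod("mediators", "MediationData", function(object) object@M)

#' @rdname MediationData-class
#' @export
setMethod("outcome", "MediationData", function(object) object@Y)

#' @rdname MediationData-class
#' @export
setMethod("covariates", "MediationData", function(object) object@Z)

#' @rdname MediationData-class
#' @export
setMethod("sampleIds", "MediationData", function(object) object@sampleIds)

#' @rdname MediationData-class
#' @export
setMethod("dim", "MediationData", function(x)
  c(n = nrow(x@X), p = ncol(x@X), q = ncol(x@M), r = ncol(x@Z)))

setMethod("show", "MediationData", function(object) {
  d <- dim(object)
  cat("MediationData:", d[["n"]], "samples\n")
  cat("  exposures:", d[["p"]], " mediators:", d[["q"]],
      " covariates:", d[["r"]], "\n")
})

#' Read mediation data from delimited text files
#'
#' Loads the exposure, mediator, outcome and optional covariate blocks from
#' CSV or TSV files. Each file must have a header row of feature names and a
#' first column of sample identifiers. Blocks are aligned to the sample
#' order of the exposure file; a sample missing from any block is an error.
#'
#' @param xPath,mPath,yPath paths to the exposure, mediator and outcome files.
#' @param zPath optional path to the covariate file.
#' @param sep field separator; `NULL` (default) picks `\t` for `.tsv`
#'   files and `,` otherwise.
#' @return a [MediationData-class] object
#' @export
readMediationData <- function(xPath, mPath, yPath, zPath = NULL, sep = NULL) {
  readBlock <- function(path) {
    if (!file.exists(path)) stop("input file not found: ", path)
    sp <- sep
    if (is.null(sp)) sp <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
    df <- utils::read.table(path, header = TRUE, sep = sp, row.names = 1L,
                            check.names = FALSE, stringsAsFactors = FALSE)
    as.matrix(df)
  }
  X <- readBlock(xPath)
  M <- readBlock(mPath)
  Yb <- readBlock(yPath)
  align <- function(B, name) {
    missing <- setdiff(rownames(X), rownames(B))
    if (length(missing))
      stop("sample IDs in ", name, " do not match the exposure file; missing: ",
           paste(utils::head(missing, 5L), collapse = ", "))
    B[rownames(X), , drop = FALSE]
  }
  M <- align(M, "mediator file")
  Yb <- align(Yb, "outcome file")
  Z <- NULL
  if (!is.null(zPath)) Z <- align(readBlock(zPath), "covariate file")
  MediationData(X, M, Yb[, 1L], Z, sampleIds = rownames(X))
}
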