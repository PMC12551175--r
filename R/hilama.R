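#' Run the full mediation-path analysis pipeline
#'
#' End-to-end flow: standardize exposures and mediators and center the
#' outcome, project out observed covariates, fit the outcome model on
#' \eqn{[X, M]} and the q mediator models on X (each with its own spectral
#' decorrelation), then screen, joint-significance test and BH-select the
#' exposure-mediator-outcome paths at nominal FDR level `alpha`.
#'
#' @param data a [MediationData-class] object.
#' @param alpha nominal FDR level (default 0.1).
#' @param K screening size, `"auto"` (0.1 p q, rounded) or integer.
#' @param sOutcome,sMediator trimmed factor counts for the outcome design
#'   `[X, M]` and the exposure design X; `"auto"` trims every singular
#'   direction above the noise-bulk edge ([estimateTrimCount()]),
#'   `"ratio"` uses the eigenvalue-ratio spike count
#'   ([estimateNumFactors()]), an integer fixes the count.
#' @param lambda,nodewiseLambda penalties, see [debiasFit()].
#' @param workers parallel workers for the mediator-model fits.
#' @param seed master seed; all cross-validation fold seeds derive from it.
#' @return a list of class `"HilamaResult"` with elements `outcome`
#'   ([OutcomeFit-class]), `mediators` ([MediatorEffectMatrix-class]),
#'   `paths` ([PathTestResult-class]), `effects` (from
#'   [assembleEffects()]) and `call` metadata.
#' @examples
#' sim <- simulateDataset(simulationConfig(n = 150, p = 10, q = 8, seed = 3))
#' res <- runHilama(sim$data, seed = 3)
#' res$paths
#' @export
runHilama <- function(data, alpha = 0.1, K = "auto", sOutcome = "auto",
                      sMediator = "auto", lambda = "cv",
                      nodewiseLambda = "cv", workers = 1L,
                      seed = 1L) {
  out <- fitOutcomeModel(data, s = sOutcome, lambda = lambda,
                         nodewiseLambda = nodewiseLambda, seed = seed)
  med <- fitMediatorModels(data, s = sMediator, workers = workers,
                           lambda = lambda, nodewiseLambda = nodewiseLambda,
                           seed = seed)
  paths <- testPaths(out, med, K = K, alpha = alpha)
  effects <- assembleEffects(out, med)
  structure(list(outcome = out, mediators = med, paths = paths,
                 effects = effects,
                 call = list(alpha = alpha, K = paths@K,
                             sOutcome = out@sUsed, sMediator = med@sUsed,
                             seed = seed)),
            class = "HilamaResult")
}

#' @export
print.HilamaResult <- function(x, ...) {
  cat("HilamaResult\n")
  show(x$outcome)
  show(x$mediators)
  show(x$paths)
  invisible(x)
}

#' Write pipeline results to tab-separated files
#'
#' Writes `outcome_effects.tsv` (per-coefficient direct and mediator
#' effects), `theta_effects.tsv` (long-format exposure-to-mediator
#' effects) and `paths.tsv` (the K screened paths with maxP p-values and
#' selection flags; header comment lines record K, alpha, the BH
#' threshold, the factor counts, the seed and the package version), plus a
#' `run.log` with one line per pipeline stage.
#'
#' @param result a `"HilamaResult"` from [runHilama()].
#' @param dir output directory, created if missing.
#' @return invisibly, the paths of the files written.
#' @export
writeHilamaResults <- function(result, dir) {
  stopifnot(inherits(result, "HilamaResult"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- result$outcome
  med <- result$mediators
  paths <- result$paths

  f1 <- file.path(dir, "outcome_effects.tsv")
  oc <- rbind(cbind(role = "gamma", as.data.frame(out@gamma)),
              cbind(role = "beta", as.data.frame(out@beta)))
  utils::write.table(oc, f1, sep = "\t", quote = FALSE, row.names = FALSE)

  f2 <- file.path(dir, "theta_effects.tsv")
  p <- nrow(med@thetaHat); q <- ncol(med@thetaHat)
  th <- data.frame(k = rep.int(seq_len(p), q), l = rep(seq_len(q), each = p),
                   exposure = rep.int(rownames(med@thetaHat), q),
                   mediator = rep(colnames(med@thetaHat), each = p),
                   theta_hat = as.vector(med@thetaHat),
                   se = as.vector(med@se), p = as.vector(med@pValues))
  utils::write.table(th, f2, sep = "\t", quote = FALSE, row.names = FALSE)

  f3 <- file.path(dir, "paths.tsv")
  scr <- screenedPaths(paths)
  beta <- out@beta
  gammaNames <- out@gamma@label
  selKey <- paste(paths@selected$k, paths@selected$l)
  tab <- data.frame(
    exposure = rownames(med@thetaHat)[scr$k],
    mediator = colnames(med@thetaHat)[scr$l],
    theta_hat = med@thetaHat[cbind(scr$k, scr$l)],
    beta_hat = beta@estimate[scr$l],
    nie = med@thetaHat[cbind(scr$k, scr$l)] * beta@estimate[scr$l],
    p_theta = med@pValues[cbind(scr$k, scr$l)],
    p_beta = beta@pValue[scr$l],
    p_max = scr$pMax,
    q_value = scr$qValue,
    selected = as.integer(paste(scr$k, scr$l) %in% selKey))
  thr <- if (is.na(bhThreshold(paths))) "none" else
    format(bhThreshold(paths), digits = 15L)
  hdr <- c(
    paste0("# K=", paths@K, " alpha=", paths@alpha, " P_star=", thr),
    paste0("# s_outcome=", out@sUsed, " s_mediator=", med@sUsed,
           " seed=", result$call$seed,
           " package_version=", as.character(utils::packageVersion("hilama"))))
  con <- file(f3, "w")
  writeLines(hdr, con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)

  f4 <- file.path(dir, "run.log")
  writeLines(c(
    sprintf("outcome_model: d=%d s=%d noise_variance=%.6g",
            length(out@gamma) + length(out@beta), out@sUsed,
            out@noiseVariance),
    sprintf("mediator_models: p=%d q=%d s=%d", p, q, med@sUsed),
    sprintf("testing: K=%d alpha=%g P_star=%s n_selected=%d",
            paths@K, paths@alpha, thr, nrow(paths@selected)),
    sprintf("timestamp: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))),
    f4)
  invisible(c(f1, f2, f3, f4))
}

#' Write a simulated dataset to delimited files
#'
#' Companion to [simulateDataset()] for file-based workflows: writes
#' `X.csv`, `M.csv`, `Y.csv` (and `Z.csv` when covariates are present) in
#' the sample-ID + header layout read by [readMediationData()], plus
#' `truth.json` with the nonzero ground-truth effects.
#'
#' @param sim the list returned by [simulateDataset()].
#' @param dir output directory, created if missing.
#' @return invisibly, the directory.
#' @export
writeSimulatedDataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- sim$data
  wr <- function(mat, name) {
    df <- data.frame(sample_id = sampleIds(d), mat, check.names = FALSE)
    utils::write.csv(df, file.path(dir, name), row.names = FALSE, quote = FALSE)
  }
  wr(exposures(d), "X.csv")
  wr(mediators(d), "M.csv")
  wr(data.frame(Y = outcome(d)), "Y.csv")
  if (ncol(covariates(d)) > 0L) wr(covariates(d), "Z.csv")
  tr <- sim$truth
  nz <- which(tr$Theta != 0, arr.ind = TRUE)
  jsonlite::write_json(list(
    theta = data.frame(k = nz[, 1L], l = nz[, 2L], value = tr$Theta[nz]),
    beta = data.frame(l = which(tr$beta != 0),
                      value = tr$beta[tr$beta != 0]),
    gamma = data.frame(k = which(tr$gamma != 0),
                       value = tr$gamma[tr$gamma != 0]),
    active_set = tr$activeSet, s01 = tr$s01, s11 = tr$s11),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
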