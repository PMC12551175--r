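# Small deterministic fixtures built in code.

tinyMediationData <- function(n = 40, p = 4, q = 3, r = 2, seed = 11) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("X", 1:p)))
  M <- matrix(rnorm(n * q), n, q, dimnames = list(NULL, paste0("M", 1:q)))
  Z <- if (r > 0) matrix(rnorm(n * r), n, r) else NULL
  Y <- rnorm(n)
  MediationData(X, M, Y, Z)
}

# Independent brute-force BH threshold: try every order statistic.
bruteForceBH <- function(p, alpha) {
  K <- length(p)
  ps <- sort(p)
  ok <- ps[vapply(ps, function(x) K * x / sum(p <= x) <= alpha, logical(1))]
  if (length(ok) == 0) NA_real_ else max(ok)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# generator draws at toy dimensions (q < 20) routinely truncate a row
# support; that warning is expected and tested once in test-simulate.R
quietSim <- function(cfg) suppressWarnings(simulateDataset(cfg))
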