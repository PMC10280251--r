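#' FastICA (single data set baseline)
#'
#' Fixed-point ICA with the tanh contrast and symmetric decorrelation on
#' whitened data. Operates on one data set (D = 1).
#'
#' @param X K x L numeric matrix (or a `dataset_collection`, in which case
#'   only the first data set is used).
#' @param opts An [iva_options] list; `init = "identity"` gives a
#'   deterministic run, `init = "random"` draws a random orthogonal start
#'   from `opts$seed`.
#' @return An `unmixing_result` with D = 1; see [iva_g()].
#' @export
fastica <- function(X, opts = iva_options()) {
  Xlist <- as_dataset_list(X)
  Xd <- Xlist[[1]]
  K <- nrow(Xd)
  L <- ncol(Xd)
  if (K < 2) abort_bad_arg("X", "must have at least 2 channels to separate")
  wh <- whiten(Xd)
  Z <- wh$Z

  sym_decorrelate <- function(W) {
    e <- eigen(tcrossprod(W), symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-300)), K) %*%
      t(e$vectors) %*% W
  }
  W <- if (opts$init == "random") {
    local_seed(opts$seed, qr.Q(qr(matrix(stats::rnorm(K * K), K, K))))
  } else diag(K)
  W <- sym_decorrelate(W)

  converged <- FALSE
  iter <- 0L
  trace <- numeric(0)
  while (iter < opts$max_iterations) {
    iter <- iter + 1L
    Y <- W %*% Z
    G <- tanh(Y)
    gprime <- rowMeans(1 - G^2)
    W_new <- (tcrossprod(G, Z) / L) - diag(gprime, K) %*% W
    W_new <- sym_decorrelate(W_new)
    # fix row signs against the previous iterate for a stable criterion
    sgn <- sign(diag(tcrossprod(W_new, W)))
    sgn[sgn == 0] <- 1
    W_new <- W_new * sgn
    crit <- 1 - min(abs(diag(tcrossprod(W_new, W))))
    trace <- c(trace, crit)
    W <- W_new
    if (crit < opts$tolerance) {
      converged <- TRUE
      break
    }
  }
  finalize_result(list(W), list(Xd), list(Z), list(wh$V), list(wh$center),
                  "fastica", n_iterations = iter, cost_trace = trace,
                  converged = converged, opts = opts)
}

#' CCA-based blind source separation (single data set baseline)
#'
#' Canonical correlation between the recording and its `delay`-lagged copy:
#' in whitened space this reduces to the eigendecomposition of the
#' symmetrized lag-`delay` autocovariance. Components are mutually
#' uncorrelated at lag 0 and ordered by decreasing lag-`delay`
#' autocorrelation.
#'
#' @param X K x L numeric matrix (or a `dataset_collection`; first data set
#'   used).
#' @param delay Positive integer lag in samples (default 1).
#' @return An `unmixing_result` with D = 1; see [iva_g()].
#' @export
cca_bss <- function(X, delay = 1) {
  Xlist <- as_dataset_list(X)
  Xd <- Xlist[[1]]
  K <- nrow(Xd)
  L <- ncol(Xd)
  check_scalar_num(delay, "delay", positive = TRUE)
  delay <- as.integer(delay)
  if (L <= delay + K) abort_bad_arg("delay", "must be well below the signal length")
  wh <- whiten(Xd)
  Z <- wh$Z
  Z0 <- Z[, 1:(L - delay), drop = FALSE]
  Z1 <- Z[, (1 + delay):L, drop = FALSE]
  C1 <- tcrossprod(Z0, Z1) / (L - delay)
  M <- (C1 + t(C1)) / 2
  e <- eigen(M, symmetric = TRUE)
  W <- t(e$vectors)  # rows ordered by decreasing lag-`delay` autocorrelation
  finalize_result(list(W), list(Xd), list(Z), list(wh$V), list(wh$center),
                  "cca", n_iterations = 1L, cost_trace = numeric(0),
                  converged = TRUE, opts = iva_options())
}
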