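#' Whiten a multichannel signal matrix
#'
#' Centers each row and applies the symmetric whitening transform so the
#' sample covariance of the output is the identity. The whitening matrix is
#' returned so un-mixing matrices estimated in whitened space can be mapped
#' back to sensor space.
#'
#' @param X K x L numeric matrix with full row rank and L > K.
#' @return A list with `Z` (whitened K x L matrix), `V` (K x K whitening
#'   matrix), `center` (length-K row means): `Z = V %*% (X - center)`.
#' @export
whiten <- function(X) {
  stopifnot(is.matrix(X), is.numeric(X))
  K <- nrow(X)
  L <- ncol(X)
  if (L <= K) abort_bad_arg("X", "must have more samples than channels")
  mu <- rowMeans(X)
  Xc <- X - mu
  C <- tcrossprod(Xc) / L
  e <- eigen(C, symmetric = TRUE)
  tol <- K * max(e$values) * .Machine$double.eps * 100
  if (any(e$values < tol)) {
    n_ok <- sum(e$values >= tol)
    stop(sprintf("input is rank deficient: only %d of %d channels are independent",
                 n_ok, K), call. = FALSE)
  }
  V <- e$vectors %*% diag(1 / sqrt(e$values), K) %*% t(e$vectors)
  list(Z = V %*% Xc, V = V, center = mu)
}
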