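#' Options for the separation algorithms
#'
#' @param max_iterations Maximum number of optimization sweeps (default 512).
#' @param tolerance Convergence threshold on the maximum absolute change of
#'   any un-mixing matrix entry between sweeps (default 1e-6).
#' @param step_size Initial fraction of the (quasi-)Newton row step (default
#'   1); each row update backtracks by halving until the objective decreases.
#' @param ggd_shape Shape parameter beta of the generalized Gaussian source
#'   prior: a positive number, or `"estimate"` (default) for per-SCV
#'   maximum-likelihood estimation, re-solved each sweep by minimizing the
#'   same objective (including the GGD normalizing constant) over beta, so
#'   the cost trace remains non-increasing.
#' @param shrinkage SCV covariance shrinkage: the D x D SCV covariances are
#'   regularized as `Sigma_k + shrinkage * mean(diag(Sigma_k)) * I` in the
#'   covariance-based priors (default 0.025). Stabilizes the objective when
#'   SCVs are nearly singular (strongly correlated delayed copies) and caps
#'   the depth of degenerate duplicated-source minima.
#' @param seed Seed used when `init = "random"`.
#' @param whiten Whiten each data set before optimization (default `TRUE`).
#' @param init `"identity"` (default, deterministic) or `"random"` (random
#'   orthogonal matrix in whitened space, drawn from `seed`).
#' @param init_W Optional explicit initialization: a list of D K x K
#'   un-mixing matrices in sensor space (overrides `init`).
#' @param tie_unmixing `"auto"` (default), `"always"` or `"never"`. When
#'   the data sets are delayed copies of one recording, the true un-mixing
#'   matrix is identical in every data set; tying the estimates (one matrix
#'   fit jointly to all data sets) removes the redundant parameters, which
#'   matters most for short blocks. `"auto"` ties exactly when the
#'   collection was built as delayed copies of a single recording
#'   (orthogonal mode only).
#' @param orthogonal Constrain each whitened un-mixing matrix to be a
#'   rotation (default `TRUE`). After whitening, the noiseless solution is
#'   orthogonal; enforcing it regularizes the estimate under sensor noise
#'   and short blocks, and removes the scale indeterminacy. Set `FALSE` for
#'   the unconstrained decoupled-row optimizer.
#' @param scv_structure `"free"` (default) or `"stationary"`.
#'   When the D data sets are delayed copies of one stationary recording,
#'   the SCV covariance is a function of the delay difference only; the
#'   `"stationary"` option averages the estimated D x D SCV covariance over
#'   equal delay differences (a Toeplitz-type projection), which sharply
#'   reduces its estimation variance. `"auto"` enables this whenever the
#'   input is a delayed `dataset_collection`.
#' @return A list of class `iva_options`.
#' @export
iva_options <- function(max_iterations = 512, tolerance = 1e-6,
                        step_size = 1, ggd_shape = "estimate",
                        shrinkage = 0.025, seed = 1, whiten = TRUE,
                        init = "identity", init_W = NULL, orthogonal = TRUE,
                        tie_unmixing = "auto", scv_structure = "free") {
  check_scalar_num(max_iterations, "max_iterations", positive = TRUE)
  check_scalar_num(tolerance, "tolerance", positive = TRUE)
  check_scalar_num(step_size, "step_size", positive = TRUE)
  check_scalar_num(shrinkage, "shrinkage")
  if (shrinkage < 0) abort_bad_arg("shrinkage", "must be non-negative")
  if (!identical(ggd_shape, "estimate")) {
    check_scalar_num(ggd_shape, "ggd_shape", positive = TRUE)
  }
  init <- match.arg(init, c("identity", "random"))
  scv_structure <- match.arg(scv_structure, c("free", "stationary", "auto"))
  tie_unmixing <- match.arg(tie_unmixing, c("auto", "always", "never"))
  structure(list(max_iterations = as.integer(max_iterations),
                 tolerance = tolerance, step_size = step_size,
                 ggd_shape = ggd_shape, shrinkage = shrinkage, seed = seed,
                 whiten = whiten, init = init, init_W = init_W,
                 orthogonal = isTRUE(orthogonal),
                 tie_unmixing = tie_unmixing,
                 scv_structure = scv_structure),
            class = "iva_options")
}

# Coerce a dataset_collection or list/matrix into a list of K x L matrices.
as_dataset_list <- function(X) {
  if (inherits(X, "dataset_collection")) {
    lapply(X$datasets, `[[`, "mixed")
  } else if (is.matrix(X)) {
    list(X)
  } else if (is.list(X) && all(vapply(X, is.matrix, TRUE))) {
    X
  } else {
    abort_bad_arg("X", "must be a dataset_collection, a matrix, or a list of matrices")
  }
}

# SCV cost terms. Ylist: D matrices K x L. Returns total over SCVs of the
# prior's expected negative log-density (additive constants dropped).
scv_cost <- function(Ylist, prior, beta = NULL, shrinkage = 0, proj = NULL) {
  D <- length(Ylist)
  K <- nrow(Ylist[[1]])
  L <- ncol(Ylist[[1]])
  J <- 0
  for (k in seq_len(K)) {
    Yk <- do.call(rbind, lapply(Ylist, function(Y) Y[k, , drop = FALSE]))
    J <- J + scv_cost_one(Yk, prior, if (is.null(beta)) 1 else beta[k],
                          shrinkage, proj)
  }
  J
}

# Stationarity projection for SCV covariances of delayed data sets:
# entries with equal |delay_d - delay_d2| are averaged. Returns a function
# mapping a D x D symmetric matrix onto that subspace (trace-preserving).
make_scv_projector <- function(delays) {
  D <- length(delays)
  dd <- abs(outer(delays, delays, "-"))
  groups <- match(dd, sort(unique(as.vector(dd))))
  dim(groups) <- c(D, D)
  function(S) {
    means <- tapply(as.vector(S), as.vector(groups), mean)
    matrix(means[groups], D, D)
  }
}

# log normalizing constant (beta-dependent part) of the multivariate GGD
# density proportional to exp(-0.5 * (y' Sigma^{-1} y)^beta) in D dimensions
ggd_log_z <- function(beta, D) {
  lgamma(D / (2 * beta)) - log(beta) + (D / (2 * beta)) * log(2)
}

scv_cost_one <- function(Yk, prior, beta, shrinkage = 0, proj = NULL) {
  D <- nrow(Yk)
  L <- ncol(Yk)
  if (prior == "laplacian") {
    return(mean(sqrt(colSums(Yk^2) + 1e-14)))
  }
  Sk <- tcrossprod(Yk) / L
  if (!is.null(proj)) Sk <- proj(Sk)
  Sk <- Sk + diag(shrinkage * mean(diag(Sk)) + 1e-12, D)
  ch <- tryCatch(chol(Sk), error = function(e) NULL)
  if (is.null(ch)) return(Inf)
  logdet <- 2 * sum(log(diag(ch)))
  if (prior == "gaussian") return(0.5 * logdet)
  iSY <- backsolve(ch, backsolve(ch, Yk, transpose = TRUE))
  qk <- pmax(colSums(Yk * iSY), 1e-14)
  0.5 * logdet + 0.5 * mean(qk^beta) + ggd_log_z(beta, D)
}

iva_cost_internal <- function(Wlist, Zlist, prior, beta = NULL, shrinkage = 0) {
  Ylist <- Map(`%*%`, Wlist, Zlist)
  J <- scv_cost(Ylist, prior, beta, shrinkage)
  logdets <- vapply(Wlist, function(W) determinant(W)$modulus[1], 0)
  list(cost = J - sum(logdets), Ylist = Ylist)
}

#' IVA objective value
#'
#' Evaluates the mutual-information cost that the IVA optimizers minimize:
#' the sum over source component vectors (SCVs) of the prior's expected
#' negative log-density, minus the `log |det W^d|` terms. The additive
#' constant depending only on the data is dropped. For the Gaussian prior
#' the SCV term is `0.5 * log det(Sigma_k)` with `Sigma_k` the D x D sample
#' covariance of SCV k; for the Laplacian prior it is `E[ ||y_k|| ]`; for
#' the generalized Gaussian prior
#' `0.5 * log det(Sigma_k) + 0.5 * E[(y' Sigma_k^{-1} y)^beta]`.
#'
#' @param W List of D invertible K x K un-mixing matrices (a single matrix
#'   is treated as D = 1).
#' @param X A `dataset_collection`, matrix, or list of D K x L matrices; rows
#'   are centered before evaluation.
#' @param prior `"gaussian"`, `"laplacian"` or `"ggd"`.
#' @param ggd_shape Shape beta for `prior = "ggd"` (scalar, recycled per SCV).
#' @param shrinkage SCV covariance shrinkage as in [iva_options()] (default 0,
#'   i.e. the bare objective).
#' @return Finite scalar cost.
#' @export
iva_cost <- function(W, X, prior = c("gaussian", "laplacian", "ggd"),
                     ggd_shape = 0.5, shrinkage = 0) {
  prior <- match.arg(prior)
  if (is.matrix(W)) W <- list(W)
  Xlist <- as_dataset_list(X)
  stopifnot(length(W) == length(Xlist))
  for (Wd in W) {
    if (!is.matrix(Wd) || nrow(Wd) != ncol(Wd)) abort_bad_arg("W", "must contain square matrices")
    if (abs(det(Wd)) < 1e-12) stop("singular un-mixing matrix", call. = FALSE)
    if (nrow(Wd) != nrow(Xlist[[1]])) abort_bad_arg("W", "dimensions must match X")
  }
  Xlist <- lapply(Xlist, function(Xd) Xd - rowMeans(Xd))
  K <- nrow(Xlist[[1]])
  iva_cost_internal(W, Xlist, prior, rep(ggd_shape, K), shrinkage)$cost
}

# Maximum-likelihood GGD shape for one SCV: minimizes the same per-SCV
# objective (Mahalanobis moment term plus normalizing constant) over beta.
estimate_ggd_shape <- function(Yk, shrinkage = 0, proj = NULL) {
  D <- nrow(Yk)
  L <- ncol(Yk)
  Sk <- tcrossprod(Yk) / L
  if (!is.null(proj)) Sk <- proj(Sk)
  Sk <- Sk + diag(shrinkage * mean(diag(Sk)) + 1e-12, D)
  ch <- tryCatch(chol(Sk), error = function(e) NULL)
  if (is.null(ch)) return(1)
  iSY <- backsolve(ch, backsolve(ch, Yk, transpose = TRUE))
  qk <- pmax(colSums(Yk * iSY), 1e-14)
  f <- function(b) 0.5 * mean(qk^b) + ggd_log_z(b, D)
  stats::optimize(f, c(0.2, 3))$minimum
}

# Unit vector orthogonal to all rows of W except row k, oriented so that
# h' w_k > 0 (the decoupling vector: log|det W| = log(h' w_k) + const).
decoupling_vector <- function(W, k) {
  K <- nrow(W)
  h <- qr.Q(qr(t(W[-k, , drop = FALSE])), complete = TRUE)[, K]
  if (sum(h * W[k, ]) < 0) h <- -h
  h
}

# Decoupled block-coordinate IVA engine: sweeps over (data set, source)
# rows; each row takes a damped (quasi-)Newton step and is accepted only if
# the global objective decreases, so the cost trace is non-increasing.
iva_engine <- function(X, prior, opts, algorithm) {
  proj <- NULL
  if (opts$scv_structure == "stationary" &&
      inherits(X, "dataset_collection") && length(X$datasets) > 1) {
    delays <- vapply(X$datasets, function(d) d$delay %||% NA_integer_, 0L)
    if (!anyNA(delays)) proj <- make_scv_projector(delays)
  }
  if (opts$orthogonal) {
    return(iva_engine_orth(X, prior, opts, algorithm, proj))
  }
  Xlist <- as_dataset_list(X)
  D <- length(Xlist)
  K <- nrow(Xlist[[1]])
  L <- ncol(Xlist[[1]])
  if (K < 2) abort_bad_arg("X", "must have at least 2 channels")
  if (L < 10 * K) abort_bad_arg("X", "must have at least 10*K samples per channel")

  if (opts$whiten) {
    wh <- lapply(Xlist, whiten)
    Zlist <- lapply(wh, `[[`, "Z")
    Vlist <- lapply(wh, `[[`, "V")
    centers <- lapply(wh, `[[`, "center")
  } else {
    centers <- lapply(Xlist, rowMeans)
    Zlist <- Map(function(Xd, mu) Xd - mu, Xlist, centers)
    Vlist <- rep(list(diag(K)), D)
  }

  # cross-data-set second moments R[[d]][[d2]] = Z^d Z^{d2}' / L
  R <- lapply(seq_len(D), function(d) {
    lapply(seq_len(D), function(d2) tcrossprod(Zlist[[d]], Zlist[[d2]]) / L)
  })

  if (!is.null(opts$init_W)) {
    W_init <- if (is.matrix(opts$init_W)) rep(list(opts$init_W), D) else opts$init_W
    stopifnot(length(W_init) == D)
    Wlist <- Map(function(Wd, Vd) Wd %*% solve(Vd), W_init, Vlist)
  } else {
    W0 <- if (opts$init == "random") {
      local_seed(opts$seed, {
        Q <- qr.Q(qr(matrix(stats::rnorm(K * K), K, K)))
        Q * sign(det(Q))
      })
    } else diag(K)
    Wlist <- rep(list(W0), D)
  }
  Ylist <- Map(`%*%`, Wlist, Zlist)

  beta <- rep(1, K)
  if (prior == "ggd" && !identical(opts$ggd_shape, "estimate")) {
    beta <- rep(opts$ggd_shape, K)
  }
  get_Yk <- function(k) do.call(rbind, lapply(Ylist, function(Y) Y[k, , drop = FALSE]))

  lam <- opts$shrinkage
  cost_now <- function() {
    scv_cost(Ylist, prior, beta, lam, proj) -
      sum(vapply(Wlist, function(W) determinant(W)$modulus[1], 0))
  }
  cost_trace <- cost_now()
  converged <- FALSE
  iter <- 0L

  while (iter < opts$max_iterations) {
    iter <- iter + 1L
    if (prior == "ggd" && identical(opts$ggd_shape, "estimate")) {
      # exact minimization over beta of the same objective: never increases it
      beta <- vapply(seq_len(K), function(k) {
        estimate_ggd_shape(get_Yk(k), lam, proj)
      }, 0)
    }
    delta <- 0
    for (k in seq_len(K)) {
      Yk <- get_Yk(k)
      # prior-specific scv statistics shared by the row updates of SCV k
      if (prior != "laplacian") {
        Sk <- tcrossprod(Yk) / L
        if (!is.null(proj)) Sk <- proj(Sk)
        Sk <- Sk + diag(lam * mean(diag(Sk)) + 1e-12, D)
        iSk <- tryCatch(solve(Sk), error = function(e) NULL)
        if (is.null(iSk)) stop("singular SCV covariance", call. = FALSE)
        # chain rule through the (self-adjoint) stationarity projection
        iSkP <- if (is.null(proj)) iSk else proj(iSk)
      }
      for (d in seq_len(D)) {
        w <- Wlist[[d]][k, ]
        h <- decoupling_vector(Wlist[[d]], k)
        hw <- sum(h * w)
        if (prior == "gaussian") {
          # grad of 0.5 log det of the (projected, ridged) SCV covariance:
          # sum_d' M[d,d'] R^{dd'} w' with M the projected inverse plus the
          # trace-ridge path
          g_scv <- Reduce(`+`, lapply(seq_len(D), function(d2) {
            iSkP[d, d2] * (R[[d]][[d2]] %*% Wlist[[d2]][k, ])
          }))
          if (lam > 0) {
            g_scv <- g_scv +
              (lam / D) * sum(diag(iSk)) * (R[[d]][[d]] %*% w)
          }
          curv <- iSkP[d, d] + (lam / D) * sum(diag(iSk))
        } else if (prior == "laplacian") {
          qk <- sqrt(colSums(Yk^2) + 1e-14)
          g_scv <- (Zlist[[d]] %*% (Yk[d, ] / qk)) / L
          curv <- mean(1 / qk)
        } else {
          # exact gradient of 0.5 log det Sigma_k + 0.5 E[q^beta] with
          # Sigma_k the sample covariance (collapses to the Gaussian
          # gradient at beta = 1)
          U <- iSk %*% Yk
          qk <- pmax(colSums(Yk * U), 1e-14)
          bfac <- beta[k] * qk^(beta[k] - 1)
          grad_y <- U[d, ] * (1 + bfac) / L -
            as.vector(crossprod(Yk, U %*% (bfac * U[d, ]))) / L^2
          g_scv <- Zlist[[d]] %*% grad_y
          curv <- iSk[d, d] * (1 + mean(bfac)) / 2
        }
        grad <- as.vector(g_scv) - h / hw
        Hh <- h / hw^2
        # solve (curv I + (h h')/hw^2) p = -grad via Sherman-Morrison
        p <- -(grad / curv - h * (sum(h * grad) / hw^2) /
                 (curv * (curv + sum(h * Hh))))
        # objective restricted to this row (SCV k term and -log|h'w|)
        j_old <- scv_cost_one(Yk, prior, beta[k], lam, proj) - log(hw)
        t_step <- opts$step_size
        for (bt in 1:14) {
          w_try <- w + t_step * p
          hw_try <- sum(h * w_try)
          if (hw_try > 1e-12) {
            Yk_try <- Yk
            Yk_try[d, ] <- as.vector(w_try %*% Zlist[[d]])
            j_new <- scv_cost_one(Yk_try, prior, beta[k], lam, proj) - log(hw_try)
            # sufficient decrease: microscopic improvements are treated as
            # stationarity so the row stops moving and the sweep converges
            if (is.finite(j_new) &&
                j_new <= j_old - 1e-11 * (1 + abs(j_old))) {
              delta <- max(delta, max(abs(w_try - w)))
              Wlist[[d]][k, ] <- w_try
              Ylist[[d]][k, ] <- Yk_try[d, ]
              Yk <- Yk_try
              if (prior != "laplacian") {
                Sk <- tcrossprod(Yk) / L
                if (!is.null(proj)) Sk <- proj(Sk)
                Sk <- Sk + diag(lam * mean(diag(Sk)) + 1e-12, D)
                iSk_try <- tryCatch(solve(Sk), error = function(e) NULL)
                if (!is.null(iSk_try)) {
                  iSk <- iSk_try
                  iSkP <- if (is.null(proj)) iSk else proj(iSk)
                }
              }
              break
            }
          }
          t_step <- t_step / 2
        }
      }
    }
    cost_trace <- c(cost_trace, cost_now())
    if (delta < opts$tolerance) {
      converged <- TRUE
      break
    }
  }

  finalize_result(Wlist, Xlist, Zlist, Vlist, centers, algorithm,
                  n_iterations = iter, cost_trace = cost_trace,
                  converged = converged, opts = opts)
}

# Apply the unit-variance and sign conventions, map W back to sensor space
# and assemble the result object shared by all algorithms.
finalize_result <- function(Wlist, Xlist, Zlist, Vlist, centers, algorithm,
                            n_iterations, cost_trace, converged, opts) {
  D <- length(Wlist)
  K <- nrow(Wlist[[1]])
  W_out <- vector("list", D)
  Y_out <- vector("list", D)
  for (d in seq_len(D)) {
    Yd <- Wlist[[d]] %*% Zlist[[d]]
    sds <- sqrt(rowMeans(Yd^2))
    sds[sds == 0] <- 1
    Wd <- Wlist[[d]] / sds
    Yd <- Yd / sds
    # sign convention: largest-magnitude sample of each component is positive
    sgn <- vapply(seq_len(K), function(k) {
      v <- Yd[k, which.max(abs(Yd[k, ]))]
      if (v < 0) -1 else 1
    }, 0)
    Wd <- Wd * sgn
    Yd <- Yd * sgn
    W_out[[d]] <- Wd %*% Vlist[[d]]
    Y_out[[d]] <- Yd
  }
  structure(list(W = W_out, Y = Y_out, centers = centers,
                 n_iterations = n_iterations, cost_trace = cost_trace,
                 converged = converged, algorithm = algorithm, options = opts),
            class = "unmixing_result")
}

#' IVA with a multivariate Gaussian source prior (IVA-G)
#'
#' Joint blind source separation over D data sets exploiting second-order
#' dependence across data sets: each source component vector (SCV) is
#' modelled as multivariate Gaussian, so separation is driven by the D x D
#' SCV covariances. Optimized by decoupled row-wise damped Newton sweeps.
#'
#' @param X A `dataset_collection` (or list of D K x L matrices).
#' @param opts An [iva_options] list.
#' @return An `unmixing_result` with fields `W` (list of D K x K un-mixing
#'   matrices in sensor space), `Y` (list of D K x L unit-variance estimated
#'   sources, `Y[[d]] = W[[d]] %*% (X[[d]] - centers[[d]])`), `n_iterations`,
#'   `cost_trace`, `converged`, `algorithm`.
#' @export
iva_g <- function(X, opts = iva_options()) {
  iva_engine(X, "gaussian", opts, "iva_g")
}

#' IVA with a multivariate Laplacian source prior (IVA-L)
#'
#' Uses higher-order statistics through the heavy-tailed Laplacian SCV prior
#' (score `y / ||y||`), ignoring second-order temporal structure.
#'
#' @inheritParams iva_g
#' @return An `unmixing_result`; see [iva_g()].
#' @export
iva_l <- function(X, opts = iva_options()) {
  iva_engine(X, "laplacian", opts, "iva_l")
}

#' IVA with a multivariate generalized Gaussian source prior (IVA-GGD)
#'
#' Combines second-order (SCV covariance) and higher-order statistics through
#' the generalized Gaussian density with shape `beta`; `beta = 1` recovers
#' Gaussian-prior behavior, smaller `beta` approaches Laplacian-like
#' behavior. By default `beta` is estimated per SCV by kurtosis matching.
#'
#' @inheritParams iva_g
#' @return An `unmixing_result`; see [iva_g()].
#' @export
iva_ggd <- function(X, opts = iva_options()) {
  iva_engine(X, "ggd", opts, "iva_ggd")
}

#' @export
print.unmixing_result <- function(x, ...) {
  cat(sprintf("<unmixing_result> %s: D = %d, K = %d, %d iterations, %s\n",
              x$algorithm, length(x$W), nrow(x$W[[1]]), x$n_iterations,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

# Orthogonal-mode engine: each whitened un-mixing matrix is constrained to a
# rotation and updated along the manifold with a Cayley retraction; one
# shared step size with backtracking keeps the cost trace non-increasing.
iva_engine_orth <- function(X, prior, opts, algorithm, proj = NULL) {
  Xlist <- as_dataset_list(X)
  D <- length(Xlist)
  K <- nrow(Xlist[[1]])
  L <- ncol(Xlist[[1]])
  if (K < 2) abort_bad_arg("X", "must have at least 2 channels")
  if (L < 10 * K) abort_bad_arg("X", "must have at least 10*K samples per channel")

  tie <- opts$tie_unmixing == "always" ||
    (opts$tie_unmixing == "auto" && D > 1 &&
       inherits(X, "dataset_collection") && isTRUE(X$delayed_copies))

  if (tie) {
    # delayed copies of one recording: one whitening transform (covariance
    # pooled over all copies) and one shared un-mixing rotation
    centers <- lapply(Xlist, rowMeans)
    Xc <- Map(function(Xd, mu) Xd - mu, Xlist, centers)
    Cp <- Reduce(`+`, lapply(Xc, function(Z) tcrossprod(Z) / ncol(Z))) / D
    e <- eigen(Cp, symmetric = TRUE)
    if (any(e$values < K * max(e$values) * .Machine$double.eps * 100)) {
      stop("input is rank deficient", call. = FALSE)
    }
    V1 <- e$vectors %*% diag(1 / sqrt(e$values), K) %*% t(e$vectors)
    Zlist <- lapply(Xc, function(Z) V1 %*% Z)
    Vlist <- rep(list(V1), D)
  } else {
    wh <- lapply(Xlist, whiten)
    Zlist <- lapply(wh, `[[`, "Z")
    Vlist <- lapply(wh, `[[`, "V")
    centers <- lapply(wh, `[[`, "center")
  }

  R <- lapply(seq_len(D), function(d) {
    lapply(seq_len(D), function(d2) tcrossprod(Zlist[[d]], Zlist[[d2]]) / L)
  })

  orthonormalize <- function(W) {
    s <- svd(W)
    s$u %*% t(s$v)
  }
  if (!is.null(opts$init_W)) {
    W_init <- if (is.matrix(opts$init_W)) rep(list(opts$init_W), D) else opts$init_W
    stopifnot(length(W_init) == D)
    Wlist <- Map(function(Wd, Vd) orthonormalize(Wd %*% solve(Vd)),
                 W_init, Vlist)
  } else {
    W0 <- if (opts$init == "random") {
      local_seed(opts$seed, {
        Q <- qr.Q(qr(matrix(stats::rnorm(K * K), K, K)))
        Q * sign(det(Q))
      })
    } else diag(K)
    Wlist <- rep(list(W0), D)
  }
  Ylist <- Map(`%*%`, Wlist, Zlist)

  beta <- rep(1, K)
  if (prior == "ggd" && !identical(opts$ggd_shape, "estimate")) {
    beta <- rep(opts$ggd_shape, K)
  }
  lam <- opts$shrinkage
  get_Yk <- function(Yl, k) {
    do.call(rbind, lapply(Yl, function(Y) Y[k, , drop = FALSE]))
  }
  # -log|det W| = 0 on the rotation manifold: only the SCV terms remain
  cost_of <- function(Yl) scv_cost(Yl, prior, beta, lam, proj)

  # Euclidean gradient of the cost w.r.t. each W^d (K x K matrices)
  gradients <- function(Yl) {
    Gl <- lapply(seq_len(D), function(d) matrix(0, K, K))
    for (k in seq_len(K)) {
      Yk <- get_Yk(Yl, k)
      if (prior == "laplacian") {
        qk <- sqrt(colSums(Yk^2) + 1e-14)
        for (d in seq_len(D)) {
          Gl[[d]][k, ] <- (Zlist[[d]] %*% (Yk[d, ] / qk)) / L
        }
      } else {
        Sk <- tcrossprod(Yk) / L
        if (!is.null(proj)) Sk <- proj(Sk)
        Sk <- Sk + diag(lam * mean(diag(Sk)) + 1e-12, D)
        iSk <- solve(Sk)
        iSkP <- if (is.null(proj)) iSk else proj(iSk)
        if (prior == "gaussian") {
          for (d in seq_len(D)) {
            g <- Reduce(`+`, lapply(seq_len(D), function(d2) {
              iSkP[d, d2] * (R[[d]][[d2]] %*% Wlist[[d2]][k, ])
            }))
            if (lam > 0) {
              g <- g + (lam / D) * sum(diag(iSk)) * (R[[d]][[d]] %*% Wlist[[d]][k, ])
            }
            Gl[[d]][k, ] <- g
          }
        } else {
          U <- iSk %*% Yk
          qk <- pmax(colSums(Yk * U), 1e-14)
          bfac <- beta[k] * qk^(beta[k] - 1)
          for (d in seq_len(D)) {
            grad_y <- U[d, ] * (1 + bfac) / L -
              as.vector(crossprod(Yk, U %*% (bfac * U[d, ]))) / L^2
            Gl[[d]][k, ] <- Zlist[[d]] %*% grad_y
          }
        }
      }
    }
    Gl
  }

  cayley <- function(S, t) {
    # rotation exp(-t S) approximated by the Cayley transform (exact
    # orthogonality for skew-symmetric S)
    solve(diag(K) + (t / 2) * S, diag(K) - (t / 2) * S)
  }

  cost_cur <- cost_of(Ylist)
  cost_trace <- cost_cur
  converged <- FALSE
  iter <- 0L
  step <- opts$step_size

  while (iter < opts$max_iterations) {
    iter <- iter + 1L
    if (prior == "ggd" && identical(opts$ggd_shape, "estimate")) {
      beta <- vapply(seq_len(K), function(k) {
        estimate_ggd_shape(get_Yk(Ylist, k), lam, proj)
      }, 0)
      cost_cur <- cost_of(Ylist)
      cost_trace[length(cost_trace)] <- cost_cur
    }
    Gl <- gradients(Ylist)
    # Riemannian gradient: skew part of G W'
    Sl <- Map(function(G, W) {
      A <- G %*% t(W)
      A - t(A)
    }, Gl, Wlist)
    if (tie) Sl <- rep(list(Reduce(`+`, Sl)), D)
    gnorm <- max(vapply(Sl, function(S) max(abs(S)), 0))
    if (gnorm < 1e-14) {
      converged <- TRUE
      break
    }
    accepted <- FALSE
    for (bt in 1:20) {
      W_try <- Map(function(S, W) cayley(S, step) %*% W, Sl, Wlist)
      Y_try <- Map(`%*%`, W_try, Zlist)
      cost_try <- cost_of(Y_try)
      if (is.finite(cost_try) && cost_try <= cost_cur - 1e-12 * (1 + abs(cost_cur))) {
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) {
      converged <- TRUE
      break
    }
    delta <- max(mapply(function(a, b) max(abs(a - b)), W_try, Wlist))
    rel_drop <- (cost_cur - cost_try) / (1 + abs(cost_try))
    Wlist <- W_try
    Ylist <- Y_try
    cost_cur <- cost_try
    cost_trace <- c(cost_trace, cost_cur)
    step <- min(step * 2, 50 * opts$step_size)
    if (delta < opts$tolerance || rel_drop < 1e-8) {
      converged <- TRUE
      break
    }
  }

  finalize_result(Wlist, Xlist, Zlist, Vlist, centers, algorithm,
                  n_iterations = iter, cost_trace = cost_trace,
                  converged = converged, opts = opts)
}
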