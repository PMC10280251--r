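test_that("whiten produces identity sample covariance and is invertible", {
  set.seed(1)
  X <- random_mixing_matrix(4, 2) %*% matrix(rnorm(4 * 5000), 4)
  w <- whiten(X)
  C <- tcrossprod(w$Z) / ncol(X)
  expect_lt(max(abs(C - diag(4))), 1e-8)
  expect_equal(w$Z, w$V %*% (X - w$center), tolerance = 1e-12)
  # duplicated channel -> rank-deficiency error naming the channel count
  expect_error(whiten(rbind(X, X[1, ])), "rank deficient")
  expect_error(whiten(matrix(rnorm(12), 4, 3)), "more samples")
})

test_that("iva_cost reduces correctly in the unit-variance D = 1 case", {
  set.seed(2)
  X <- random_mixing_matrix(3, 5) %*% matrix(rnorm(3 * 2000), 3)
  w <- whiten(X)
  # whitened outputs have unit variance: Gaussian cost is -log|det W|
  expect_equal(iva_cost(w$V, X, "gaussian"),
               -determinant(w$V)$modulus[1], tolerance = 1e-6)
  # common row permutation leaves the cost unchanged
  W <- list(w$V)
  p <- c(3, 1, 2)
  expect_equal(iva_cost(lapply(W, function(x) x[p, ]), X, "laplacian"),
               iva_cost(W, X, "laplacian"), tolerance = 1e-10)
  expect_error(iva_cost(matrix(0, 3, 3), X), "singular")
})

test_that("true un-mixing beats random matrices on the clean cost", {
  sim <- make_gaussian_scv_collection(K = 3, D = 2, L = 3000,
                                      rho = c(0.9, 0.5, 0.1), seed = 4)
  Wtrue <- lapply(sim$A, solve)
  c_true <- iva_cost(Wtrue, sim$X, "gaussian")
  set.seed(5)
  worse <- 0
  for (i in 1:50) {
    Wr <- lapply(1:2, function(d) matrix(rnorm(9), 3))
    if (iva_cost(Wr, sim$X, "gaussian") >= c_true) worse <- worse + 1
  }
  expect_equal(worse, 50)
})

test_that("IVA-G recovers dependent Gaussian SCVs with distinct profiles", {
  sim <- make_gaussian_scv_collection(K = 4, D = 4, L = 10000,
                                      rho = c(0.95, 0.7, 0.4, 0.1), seed = 42)
  r <- iva_g(sim$X)
  expect_lt(isi_com(global_matrix(r$W, sim$A)), 0.01)
  expect_true(r$converged)
})

test_that("i.i.d. Gaussian sources with one data set are not identifiable", {
  set.seed(8)
  S <- matrix(rnorm(2 * 5000), 2)
  A <- matrix(c(cos(pi / 4), sin(pi / 4), -sin(pi / 4), cos(pi / 4)), 2)
  r <- iva_g(A %*% S)
  # the Gaussian cost is flat over rotations: the 45-degree mixing persists
  expect_gt(isi_com(global_matrix(r$W[[1]], A)), 0.2)
})

test_that("identity-mixing clean collections are unmixed accurately", {
  src <- ivaecg:::synth_cell_sources(10003, 360, 72, seed = 5, guard = 3)
  coll <- make_datasets(src, delays = c(0, 1, 2, 3), snr_db = "clean",
                        mixing = diag(4))
  expect_lt(isi_com(global_matrix(iva_g(coll), coll)), 0.01)
  expect_lt(isi_com(global_matrix(iva_ggd(coll), coll)), 0.01)
  # the Laplacian prior is the most model-mismatched on these sources
  expect_lt(isi_com(global_matrix(iva_l(coll), coll)), 0.1)
})

test_that("IVA-L separates dependent Laplacian-type SCVs", {
  set.seed(11)
  K <- 4; D <- 4; L <- 10000
  S <- lapply(1:D, function(d) matrix(0, K, L))
  for (k in 1:K) {
    r <- sqrt(rexp(L))  # shared radial scale couples the SCV entries
    for (d in 1:D) S[[d]][k, ] <- r * rnorm(L)
  }
  A <- lapply(1:D, function(d) random_mixing_matrix(K, seed = d + 30))
  X <- Map(function(Sd, Ad) Ad %*% Sd, S, A)
  r1 <- iva_l(X)
  expect_lt(isi_com(global_matrix(r1$W, A)), 0.02)
  # the adaptive-shape variant handles the same data
  r2 <- iva_ggd(X)
  expect_lt(isi_com(global_matrix(r2$W, A)), 0.02)
})

test_that("IVA-GGD with beta = 1 matches the Gaussian-prior solution", {
  coll <- make_test_collection(seed = 6, L = 2000)
  r_g <- iva_g(coll)
  r_b1 <- iva_ggd(coll, iva_options(ggd_shape = 1))
  expect_lt(abs(isi_com(global_matrix(r_b1, coll)) -
                  isi_com(global_matrix(r_g, coll))), 0.01)
})

test_that("cost traces are non-increasing after the first iterations", {
  coll <- make_test_collection(seed = 7, L = 1000)
  for (f in list(iva_g, iva_l, iva_ggd)) {
    ct <- f(coll)$cost_trace
    if (length(ct) > 6) {
      expect_true(all(diff(ct[-(1:5)]) <= 1e-6))
    }
  }
})

test_that("unmixing results satisfy their structural contract", {
  coll <- make_test_collection(seed = 8, L = 1000)
  r <- iva_g(coll)
  D <- length(r$W)
  for (d in seq_len(D)) {
    Xd <- coll$datasets[[d]]$mixed
    expect_equal(r$Y[[d]], r$W[[d]] %*% (Xd - r$centers[[d]]),
                 tolerance = 1e-10)
    expect_gt(abs(det(r$W[[d]])), 0)
    # unit-variance outputs and positive largest deflection
    expect_equal(unname(rowMeans(r$Y[[d]]^2)), rep(1, 4), tolerance = 1e-8)
    for (k in 1:4) {
      expect_gt(r$Y[[d]][k, which.max(abs(r$Y[[d]][k, ]))], 0)
    }
  }
  # seeded determinism
  r2 <- iva_g(coll)
  expect_identical(r$W, r2$W)
})

test_that("optimizers reach the brute-force rotation oracle at K = 2, D = 1", {
  set.seed(9)
  S <- rbind(sqrt(rexp(4000)) * rnorm(4000), runif(4000, -1, 1))
  S <- S - rowMeans(S)
  A <- random_mixing_matrix(2, 3)
  X <- A %*% S
  V <- whiten(X)$V
  rot <- function(th) matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  for (prior in c("gaussian", "laplacian", "ggd")) {
    grid <- vapply(seq(0, 179) * pi / 180, function(th) {
      iva_cost(rot(th) %*% V, X, prior, ggd_shape = 0.5, shrinkage = 0.025)
    }, 0)
    fit <- switch(prior,
                  gaussian = iva_g(X),
                  laplacian = iva_l(X),
                  ggd = iva_ggd(X, iva_options(ggd_shape = 0.5)))
    c_fit <- iva_cost(fit$W, X, prior, ggd_shape = 0.5, shrinkage = 0.025)
    expect_lt(abs(c_fit - min(grid)), 1e-3)
  }
})

test_that("separation is equivariant to diagonal source scaling", {
  sim <- make_gaussian_scv_collection(K = 4, D = 4, L = 5000,
                                      rho = c(0.95, 0.7, 0.4, 0.1), seed = 10)
  lam <- diag(c(3, 0.25, 1.5, 0.8))
  X_scaled <- lapply(sim$X, function(Xd) Xd)  # X = A S; rescale the sources
  S_scaled <- lapply(sim$S, function(Sd) lam %*% Sd)
  X_scaled <- Map(function(Ad, Sd) Ad %*% Sd, sim$A, S_scaled)
  A_eff <- lapply(sim$A, function(Ad) Ad %*% lam)
  isi1 <- isi_com(global_matrix(iva_g(sim$X)$W, sim$A))
  isi2 <- isi_com(global_matrix(iva_g(X_scaled)$W, A_eff))
  expect_lt(abs(isi1 - isi2), 0.02)
})

test_that("FastICA separates sub-Gaussian sources and validates input", {
  set.seed(3)
  S <- matrix(runif(2 * 5000, -1, 1), 2)
  S <- S - rowMeans(S)
  A <- random_mixing_matrix(2, 9)
  r <- fastica(A %*% S)
  expect_lt(isi_com(global_matrix(r$W[[1]], A)), 0.05)
  expect_true(r$converged)
  # already-separated input
  r2 <- fastica(S)
  expect_lt(isi_com(global_matrix(r2$W[[1]], diag(2))), 0.05)
  expect_error(fastica(matrix(rnorm(100), 1)), "channels")
})

test_that("CCA separation uses temporal structure and orders components", {
  t <- 1:2000
  S <- rbind(sin(2 * pi * 0.013 * t), sin(2 * pi * 0.047 * t))
  S <- S - rowMeans(S)
  A <- random_mixing_matrix(2, 4)
  r <- cca_bss(A %*% S)
  expect_lt(isi_com(global_matrix(r$W[[1]], A)), 0.05)
  # outputs ordered by non-increasing lag-1 autocorrelation
  ac <- apply(r$Y[[1]], 1, function(y) stats::acf(y, 1, plot = FALSE)$acf[2])
  expect_true(all(diff(ac) <= 1e-8))
  # lag-0 decorrelation
  expect_lt(max(abs(stats::cor(t(r$Y[[1]])) - diag(2))), 1e-6)
  expect_error(cca_bss(A %*% S, delay = 3000), "delay")
})

test_that("options are validated", {
  expect_error(iva_options(tolerance = -1), "tolerance")
  expect_error(iva_options(max_iterations = 0), "max_iterations")
  expect_error(iva_options(ggd_shape = -2), "ggd_shape")
  expect_error(iva_options(shrinkage = -0.1), "shrinkage")
})
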