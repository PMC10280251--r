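test_that("global_matrix forms G^d = W^d A^d and the absolute aggregate", {
  A <- list(random_mixing_matrix(3, 1), random_mixing_matrix(3, 2))
  W <- lapply(A, solve)
  G <- global_matrix(W, A)
  for (d in 1:2) expect_equal(G$per_dataset[[d]], diag(3), tolerance = 1e-12)
  expect_equal(G$aggregate, 2 * diag(3), tolerance = 1e-12)
  # sign cancellation does not occur: |G^1| + |G^2| with G^2 = -I
  G2 <- global_matrix(list(diag(2), -diag(2)), list(diag(2), diag(2)))
  expect_equal(G2$aggregate, 2 * diag(2))
  # D = 1 off-diagonal case
  G3 <- global_matrix(diag(2), matrix(c(0, 1, 1, 0), 2))
  expect_equal(G3$aggregate, matrix(c(0, 1, 1, 0), 2))
  expect_error(global_matrix(list(diag(2)), list(diag(3))), "shapes")
})

test_that("isi_com matches hand-computed values", {
  expect_equal(isi_com(diag(2)), 0)
  expect_equal(isi_com(diag(5)), 0)
  expect_equal(isi_com(matrix(c(0, 3, 2, 0), 2)), 0)  # scaled permutation
  expect_equal(isi_com(matrix(1, 2, 2)), 1)           # worst case, K = 2
  expect_equal(isi_com(matrix(1, 3, 3)), 1)
  expect_equal(isi_com(matrix(1, 4, 4)), 1)
  expect_equal(isi_com(matrix(c(1, 0.5, 0.5, 1), 2)), 0.5)
  expect_error(isi_com(rbind(c(1, 0), c(0, 0))), "all-zero")
})

test_that("u_wa is zero at ideal separation and grows with leakage", {
  expect_equal(u_wa(diag(3)), 0)
  expect_equal(u_wa(matrix(c(0, 5, 2, 0), 2)), 0)
  expect_equal(u_wa(matrix(c(1, 0.5, 0.5, 1), 2)), 1.0)
  expect_gt(u_wa(matrix(c(1, 0.2, 0.1, 1, 0.3, 0.2, 0.1, 0.4, 1), 3)), 0)
})

test_that("metrics are exactly zero on permutation-diagonal aggregates", {
  set.seed(1)
  for (i in 1:100) {
    K <- sample(2:6, 1)
    P <- diag(K)[sample(K), ]
    lam <- diag(runif(K, 0.1, 10), K)
    agg <- P %*% lam
    expect_equal(isi_com(agg), 0)
    expect_equal(u_wa(agg), 0)
  }
})

test_that("isi_com stays in [0, 1] and is permutation invariant", {
  set.seed(2)
  for (i in 1:1000) {
    K <- sample(2:5, 1)
    g <- matrix(runif(K * K), K)
    v <- isi_com(g)
    expect_gte(v, 0)
    expect_lte(v, 1)
  }
  for (i in 1:20) {
    g <- matrix(runif(16), 4)
    p <- sample(4)
    q <- sample(4)
    expect_equal(isi_com(g[p, q]), isi_com(g))
  }
})

test_that("u_wa is invariant to positive column rescaling", {
  set.seed(3)
  g <- matrix(runif(16, 0.1, 1), 4)
  r <- runif(4, 0.2, 5)
  expect_equal(u_wa(g %*% diag(r)), u_wa(g))
})

test_that("crmse matches its definition", {
  s <- c(1, -1, 1, -1)
  expect_equal(crmse(s, s), 0)
  expect_equal(crmse(s, rep(0, 4)), 1)
  expect_equal(crmse(s, 0.5 * s), 0.5)
  expect_error(crmse(rep(0, 4), s), "zero RMS")
  expect_error(crmse(s, c(1, 2)), "length")
})

test_that("align_sources recovers permutation, sign and scale", {
  set.seed(4)
  S <- matrix(rnorm(4 * 500), 4, 500)
  S <- S - rowMeans(S)
  Y <- S[c(3, 1, 4, 2), ]
  Y[2, ] <- -Y[2, ]
  al <- align_sources(Y, S)
  # aligned output matches the reference exactly
  expect_equal(al$aligned[[1]], S, tolerance = 1e-12)
  expect_equal(diag(stats::cor(t(al$aligned[[1]]), t(S))), rep(1, 4))
  # pure rescaling: scales invert the factor
  al2 <- align_sources(2 * S, S)
  expect_equal(al2$map$permutation, 1:4)
  expect_equal(as.vector(al2$map$scales), rep(0.5, 4))
  expect_error(align_sources(rbind(rep(0, 500), S[-1, ]), S), "zero variance")
})

test_that("assignment solver agrees with brute force on |cor| matrices", {
  set.seed(5)
  brute <- function(score) {
    K <- nrow(score)
    best <- NULL
    best_val <- -Inf
    for (p in ivaecg:::all_perms(K)) {
      val <- sum(score[cbind(1:K, p)])
      if (val > best_val) {
        best_val <- val
        best <- p
      }
    }
    best
  }
  for (i in 1:25) {
    sc <- matrix(runif(16), 4)
    expect_identical(ivaecg:::solve_assignment(sc), brute(sc))
  }
})

test_that("crmse after least-squares alignment never exceeds unaligned", {
  set.seed(6)
  for (i in 1:10) {
    s <- rnorm(200)
    y <- 1.7 * s + rnorm(200, sd = 0.3)
    a <- sum(s * y) / sum(y * y)
    expect_lte(crmse(s, a * y), crmse(s, y) + 1e-12)
  }
})
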