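#' Global mixing-unmixing matrix and its cross-data-set aggregate
#'
#' For each data set forms `G^d = W^d %*% A^d`; perfect separation makes each
#' `G^d` a permutation of a diagonal matrix. The aggregate combines all data
#' sets entrywise as `g[m, n] = sum_d |G^d[m, n]|` and is the input of the
#' joint separation metrics [isi_com()] and [u_wa()].
#'
#' @param W List of D K x K un-mixing matrices (or an `unmixing_result`).
#' @param A List of D K x K true mixing matrices (or a `dataset_collection`
#'   produced by [make_datasets()], from which they are taken).
#' @return Object of class `global_mix` with `per_dataset` (list of G^d) and
#'   `aggregate` (K x K non-negative matrix).
#' @export
global_matrix <- function(W, A) {
  if (inherits(W, "unmixing_result")) W <- W$W
  if (inherits(A, "dataset_collection")) {
    A <- lapply(A$datasets, `[[`, "mixing")
    if (any(vapply(A, is.null, TRUE))) {
      stop("collection carries no true mixing matrices", call. = FALSE)
    }
  }
  if (is.matrix(W)) W <- list(W)
  if (is.matrix(A)) A <- list(A)
  if (length(W) != length(A)) abort_bad_arg("A", "must have one matrix per W")
  G <- Map(function(Wd, Ad) {
    if (!all(dim(Wd) == dim(Ad))) abort_bad_arg("A", "shapes must match W")
    Wd %*% Ad
  }, W, A)
  agg <- Reduce(`+`, lapply(G, abs))
  structure(list(per_dataset = G, aggregate = agg), class = "global_mix")
}

as_aggregate <- function(G) {
  if (inherits(G, "global_mix")) G <- G$aggregate
  if (!is.matrix(G) || nrow(G) != ncol(G)) {
    abort_bad_arg("G", "must be a global_mix or square matrix")
  }
  if (any(G < 0)) G <- abs(G)
  if (any(rowSums(G) == 0) || any(colSums(G) == 0)) {
    stop("metric undefined: aggregate has an all-zero row or column",
         call. = FALSE)
  }
  G
}

#' Joint inter-symbol-interference index
#'
#' Normalized Amari-style index of the aggregate global matrix:
#' \deqn{ISI_{com} = \frac{1}{2K(K-1)} \left[ \sum_m \Big(\sum_n
#'   \frac{g_{m,n}}{\max_p g_{m,p}} - 1\Big) + \sum_n \Big(\sum_m
#'   \frac{g_{m,n}}{\max_p g_{p,n}} - 1\Big) \right]}
#' with row-max normalization in the first sum and column-max in the second.
#' 0 corresponds to ideal separation (aggregate equal to a permutation times
#' a positive diagonal), 1 to the worst case (all entries equal).
#'
#' @param G A `global_mix` from [global_matrix()] or a non-negative square
#'   matrix; with `per_dataset = TRUE`, a `global_mix` is required.
#' @param per_dataset If `TRUE`, return the mean of the index applied to each
#'   `|G^d|` separately instead of the aggregate form (default `FALSE`).
#' @return Scalar in `[0, 1]`.
#' @export
isi_com <- function(G, per_dataset = FALSE) {
  if (per_dataset) {
    stopifnot(inherits(G, "global_mix"))
    return(mean(vapply(G$per_dataset, function(Gd) isi_com(abs(Gd)), 0)))
  }
  g <- as_aggregate(G)
  K <- nrow(g)
  if (K < 2) abort_bad_arg("G", "needs K >= 2")
  row_term <- sum(sweep(g, 1, apply(g, 1, max), "/")) - K
  col_term <- sum(sweep(g, 2, apply(g, 2, max), "/")) - K
  (row_term + col_term) / (2 * K * (K - 1))
}

#' Un-mixing leakage index
#'
#' Column-wise leakage of the aggregate global matrix: after normalizing each
#' column by its maximum, \eqn{U = \sum_n (\sum_m g'_{m,n} - 1)}. Zero at
#' ideal separation (permutation times diagonal); grows with off-diagonal
#' leakage without an upper normalization.
#'
#' @inheritParams isi_com
#' @return Non-negative scalar.
#' @export
u_wa <- function(G) {
  g <- as_aggregate(G)
  gp <- sweep(g, 2, apply(g, 2, max), "/")
  sum(gp) - ncol(g)
}

# All permutations of 1..K in lexicographic order.
all_perms <- function(K) {
  go <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in go(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  go(seq_len(K))
}

# Exact assignment maximizing sum of scores over permutations.
# Exhaustive for K <= 8 (ties broken toward the lexicographically smallest
# permutation, i.e. lowest indices first).
solve_assignment <- function(score) {
  K <- nrow(score)
  stopifnot(ncol(score) == K)
  if (K > 8) stop("assignment supported for K <= 8", call. = FALSE)
  best <- NULL
  best_val <- -Inf
  for (p in all_perms(K)) {
    val <- sum(score[cbind(seq_len(K), p)])
    if (val > best_val + 1e-12) {
      best_val <- val
      best <- p
    }
  }
  best
}

#' Resolve permutation, sign and scale against reference sources
#'
#' Matches estimated components to reference sources by maximizing the total
#' absolute correlation over all assignments (one permutation shared by all
#' data sets, as the joint model requires), flips signs so matched
#' correlations are non-negative, and computes least-squares scales so the
#' scaled estimates best fit the references.
#'
#' @param Y Estimated sources: K x L matrix, list of D such matrices, or an
#'   `unmixing_result`.
#' @param S_ref Reference sources: a [source_set], K x L matrix, or list of D
#'   matrices (e.g. the per-data-set shifted truth stored by
#'   [make_datasets()]).
#' @return List with `map` (list: `permutation`, `scales` per data set as a
#'   K x D matrix, `signs`) and `aligned` (list of D aligned K x L matrices,
#'   `aligned[[d]][k, ] ~ S_ref[[d]][k, ]`).
#' @export
align_sources <- function(Y, S_ref) {
  if (inherits(Y, "unmixing_result")) Y <- Y$Y
  if (is.matrix(Y)) Y <- list(Y)
  if (inherits(S_ref, "source_set")) S_ref <- S_ref$signals
  if (is.matrix(S_ref)) S_ref <- rep(list(S_ref), length(Y))
  stopifnot(length(Y) == length(S_ref))
  D <- length(Y)
  K <- nrow(Y[[1]])
  stopifnot(nrow(S_ref[[1]]) == K, ncol(S_ref[[1]]) == ncol(Y[[1]]))

  for (d in seq_len(D)) {
    v <- apply(Y[[d]], 1, stats::sd)
    if (any(v == 0)) {
      stop(sprintf("estimated component %d has zero variance in data set %d",
                   which(v == 0)[1], d), call. = FALSE)
    }
  }
  # total |correlation| between reference m and estimate n across data sets
  score <- matrix(0, K, K)
  for (d in seq_len(D)) {
    score <- score + abs(stats::cor(t(S_ref[[d]]), t(Y[[d]])))
  }
  perm <- solve_assignment(score)

  scales <- matrix(0, K, D)
  signs <- matrix(1, K, D)
  aligned <- vector("list", D)
  for (d in seq_len(D)) {
    Yp <- Y[[d]][perm, , drop = FALSE]
    out <- Yp
    for (k in seq_len(K)) {
      s <- S_ref[[d]][k, ]
      y <- Yp[k, ]
      a <- sum(s * y) / sum(y * y)  # least-squares scale (carries the sign)
      scales[k, d] <- a
      signs[k, d] <- if (a < 0) -1 else 1
      out[k, ] <- a * y
    }
    aligned[[d]] <- out
  }
  list(map = list(permutation = perm, scales = scales, signs = signs),
       aligned = aligned)
}

#' Relative RMS error of the reconstructed ECG
#'
#' `RMS(s - y) / RMS(s)`: 0 when the reconstruction is exact, 1 when the
#' estimate is identically zero.
#'
#' @param s_ecg Reference ECG channel (numeric vector, non-zero RMS).
#' @param y_ecg Reconstructed ECG channel of the same length.
#' @return Non-negative scalar.
#' @export
crmse <- function(s_ecg, y_ecg) {
  stopifnot(is.numeric(s_ecg), is.numeric(y_ecg))
  if (length(s_ecg) != length(y_ecg)) {
    abort_bad_arg("y_ecg", "must have the same length as s_ecg")
  }
  r <- rms(s_ecg)
  if (r == 0) stop("reference ECG has zero RMS", call. = FALSE)
  rms(s_ecg - y_ecg) / r
}

#' Separation metrics for a simulated run
#'
#' Convenience wrapper: given an `unmixing_result` and the
#' `dataset_collection` it was fitted to (with ground truth), computes
#' `isi_com`, `u_wa` and the CRMSE of the ECG component (averaged over data
#' sets after alignment).
#'
#' @param result An `unmixing_result`.
#' @param collection The `dataset_collection` with true mixing matrices and
#'   per-data-set sources.
#' @return One-row tibble with columns `algorithm`, `isi_com`, `u_wa`,
#'   `crmse`, `n_iterations`, `converged`.
#' @export
evaluate_run <- function(result, collection) {
  stopifnot(inherits(result, "unmixing_result"),
            inherits(collection, "dataset_collection"))
  D_fit <- length(result$W)
  A <- lapply(collection$datasets[seq_len(D_fit)], `[[`, "mixing")
  S <- lapply(collection$datasets[seq_len(D_fit)], `[[`, "sources")
  G <- global_matrix(result$W, A)
  cr <- NA_real_
  ecg_row <- match("ECG", collection$labels)
  if (!is.na(ecg_row) && !any(vapply(S, is.null, TRUE))) {
    al <- align_sources(result$Y, S)
    cr <- mean(vapply(seq_len(D_fit), function(d) {
      crmse(S[[d]][ecg_row, ], al$aligned[[d]][ecg_row, ])
    }, 0))
  }
  tibble::tibble(algorithm = result$algorithm, isi_com = isi_com(G),
                 u_wa = u_wa(G), crmse = cr,
                 n_iterations = result$n_iterations,
                 converged = result$converged)
}
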