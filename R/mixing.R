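#' Random mixing matrix
#'
#' Draws a K x K matrix with i.i.d. standard-normal entries, redrawing until
#' the 2-norm condition number is at most 100 so that Monte-Carlo cells never
#' contain near-singular mixtures.
#'
#' @param K Number of channels (>= 2).
#' @param seed Integer seed.
#' @return A K x K numeric matrix with `kappa(A, exact = TRUE) <= 100`.
#' @export
random_mixing_matrix <- function(K, seed = 1) {
  check_scalar_num(K, "K")
  if (K < 2) abort_bad_arg("K", "must be at least 2")
  K <- as.integer(K)
  local_seed(seed, {
    repeat {
      A <- matrix(stats::rnorm(K * K), K, K)
      if (kappa(A, exact = TRUE) <= 100) return(A)
    }
  })
}

#' Mix sources through a matrix with optional additive white Gaussian noise
#'
#' Computes `X = A %*% S` and, unless `snr_db = "clean"`, adds white Gaussian
#' noise per channel scaled so the per-channel power ratio of the noiseless
#' mixture to the noise equals `snr_db` decibels.
#'
#' @param sources A [source_set] (or K x L numeric matrix).
#' @param A K x K mixing matrix.
#' @param snr_db Signal-to-noise ratio in dB, or `"clean"` for no noise.
#' @param seed Integer seed for the noise draw.
#' @return K x L mixed matrix.
#' @export
mix_sources <- function(sources, A, snr_db = "clean", seed = 1) {
  S <- if (inherits(sources, "source_set")) sources$signals else sources
  if (!is.matrix(S) || !is.numeric(S)) {
    abort_bad_arg("sources", "must be a source_set or numeric matrix")
  }
  if (!is.matrix(A) || nrow(A) != ncol(A)) abort_bad_arg("A", "must be square")
  if (ncol(A) != nrow(S)) {
    abort_bad_arg("A", sprintf("has %d columns but there are %d sources",
                               ncol(A), nrow(S)))
  }
  clean <- identical(snr_db, "clean")
  if (!clean) {
    check_scalar_num(snr_db, "snr_db")
  }
  X <- A %*% S
  if (clean) return(X)
  p_sig <- rowMeans(X^2)
  sd_noise <- sqrt(p_sig / 10^(snr_db / 10))
  N <- local_seed(seed, matrix(stats::rnorm(length(X)), nrow(X), ncol(X)))
  X + N * sd_noise
}

#' Delayed data-set collection for joint blind source separation
#'
#' Builds D data sets from one source set. With `shared_mixing = TRUE` (the
#' default) the sources are mixed once through a single random matrix, noise
#' is added once, and data set d is the resulting recording advanced by
#' `delays[d]` samples -- the recording and its delayed versions, exactly as
#' a single multichannel acquisition would be reused. With
#' `shared_mixing = FALSE` each data set gets its own independent random
#' mixing matrix and noise realization applied to the shifted sources
#' (multiple simultaneous acquisitions). All data sets are truncated to the
#' common length `L - max(delays)`.
#'
#' @param sources A [source_set].
#' @param delays Non-negative, strictly increasing integer delays; the first
#'   must be 0 and the largest must be below L/10. Its length sets D.
#' @param mixing_seed Seed for the mixing-matrix draw(s).
#' @param snr_db Signal-to-noise ratio in dB or `"clean"`.
#' @param shared_mixing If `TRUE` (default) all data sets are delayed copies
#'   of one noisy recording (one mixing matrix, one noise realization);
#'   if `FALSE`, independent mixing matrices and noise per data set.
#' @param mixing Optional list of D explicit K x K mixing matrices (or a
#'   single matrix recycled across data sets), overriding the random draws.
#' @param noise_seed Seed for the noise draws (derived per data set).
#' @return An object of class `dataset_collection`: a list with elements
#'   `datasets` (each holding `mixed`, `mixing`, `sources`, `delay`),
#'   `snr_db`, `fs`, `labels`.
#' @export
make_datasets <- function(sources, delays = c(0, 1, 2, 3), mixing_seed = 1,
                          snr_db = "clean", shared_mixing = TRUE,
                          mixing = NULL, noise_seed = mixing_seed + 1) {
  stopifnot(inherits(sources, "source_set"))
  if (length(delays) < 1 || delays[1] != 0) {
    abort_bad_arg("delays", "must start at 0")
  }
  if (any(delays < 0) || any(diff(delays) <= 0) && length(delays) > 1) {
    abort_bad_arg("delays", "must be non-negative and strictly increasing")
  }
  delays <- as.integer(delays)
  D <- length(delays)
  S <- sources$signals
  K <- nrow(S)
  L <- ncol(S)
  max_d <- max(delays)
  if (max_d >= L / 10) abort_bad_arg("delays", "must stay below L/10")
  Lc <- L - max_d

  if (!is.null(mixing)) {
    if (is.matrix(mixing)) mixing <- rep(list(mixing), D)
    stopifnot(length(mixing) == D)
    A_list <- mixing
  } else if (shared_mixing) {
    A_list <- rep(list(random_mixing_matrix(K, mixing_seed)), D)
  } else {
    A_list <- lapply(seq_len(D), function(d) {
      random_mixing_matrix(K, derive_seed(mixing_seed, d))
    })
  }

  if (shared_mixing || (!is.null(mixing) && D > 1 &&
                        all(vapply(mixing, identical, TRUE, mixing[[1]])))) {
    # one recording, delayed: mix and add noise once, then slice windows
    X_full <- mix_sources(S, A_list[[1]], snr_db = snr_db,
                          seed = derive_seed(noise_seed, 1))
    datasets <- lapply(seq_len(D), function(d) {
      idx <- (1 + delays[d]):(Lc + delays[d])
      list(mixed = X_full[, idx, drop = FALSE], mixing = A_list[[d]],
           sources = S[, idx, drop = FALSE], delay = delays[d])
    })
  } else {
    # independent acquisitions: own mixing matrix and noise per data set
    datasets <- lapply(seq_len(D), function(d) {
      S_d <- S[, (1 + delays[d]):(Lc + delays[d]), drop = FALSE]
      X_d <- mix_sources(S_d, A_list[[d]], snr_db = snr_db,
                         seed = derive_seed(noise_seed, d))
      list(mixed = X_d, mixing = A_list[[d]], sources = S_d, delay = delays[d])
    })
  }
  structure(list(datasets = datasets, snr_db = snr_db, fs = sources$fs,
                 labels = sources$labels,
                 delayed_copies = shared_mixing ||
                   (!is.null(mixing) && length(unique(mixing)) == 1)),
            class = "dataset_collection")
}

#' Wrap already-recorded data (no ground truth) as a delayed collection
#'
#' For real recordings the mixing matrices are unknown: this builds the D
#' delayed data sets directly from the observed channels so the joint
#' separation algorithms can be applied.
#'
#' @param X K x L numeric matrix of observed channels.
#' @param delays As in [make_datasets()].
#' @param fs Sampling rate in Hz.
#' @param labels Optional channel names.
#' @return A `dataset_collection` whose datasets carry no `mixing` element.
#' @export
embed_delayed <- function(X, delays = c(0, 1, 2, 3), fs = 360, labels = NULL) {
  stopifnot(is.matrix(X), is.numeric(X))
  if (length(delays) < 1 || delays[1] != 0 ||
      (length(delays) > 1 && any(diff(delays) <= 0)) || any(delays < 0)) {
    abort_bad_arg("delays", "must start at 0 and be strictly increasing")
  }
  delays <- as.integer(delays)
  max_d <- max(delays)
  L <- ncol(X)
  if (max_d >= L / 10) abort_bad_arg("delays", "must stay below L/10")
  Lc <- L - max_d
  datasets <- lapply(delays, function(dl) {
    list(mixed = X[, (1 + dl):(Lc + dl), drop = FALSE],
         mixing = NULL, sources = NULL, delay = dl)
  })
  structure(list(datasets = datasets, snr_db = NA_real_, fs = fs,
                 labels = labels %||% paste0("ch", seq_len(nrow(X))),
                 delayed_copies = TRUE),
            class = "dataset_collection")
}

#' @export
print.dataset_collection <- function(x, ...) {
  d1 <- x$datasets[[1]]
  cat(sprintf("<dataset_collection> D = %d data sets, %d x %d each (snr = %s)\n",
              length(x$datasets), nrow(d1$mixed), ncol(d1$mixed),
              if (identical(x$snr_db, "clean")) "clean" else
                paste0(format(x$snr_db), " dB")))
  invisible(x)
}

#' Number of data sets, channels, samples of a collection
#' @param x A `dataset_collection`.
#' @return Named integer vector `c(D =, K =, L =)`.
#' @export
collection_dims <- function(x) {
  stopifnot(inherits(x, "dataset_collection"))
  c(D = length(x$datasets), K = nrow(x$datasets[[1]]$mixed),
    L = ncol(x$datasets[[1]]$mixed))
}
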