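# Shared fixtures, built in code at test time.

# Independent peak finder: local maxima above a fraction of the global max,
# separated by at least min_dist samples.
find_peaks <- function(x, frac = 0.5, min_dist = 10) {
  thr <- frac * max(x)
  idx <- which(x > thr)
  idx <- idx[idx > 1 & idx < length(x)]
  idx <- idx[x[idx] >= x[idx - 1] & x[idx] >= x[idx + 1]]
  if (length(idx) == 0) return(integer(0))
  keep <- idx[1]
  for (i in idx[-1]) {
    if (i - keep[length(keep)] >= min_dist) keep <- c(keep, i)
  }
  keep
}

# Fraction of periodogram power at frequencies below f_hz.
power_below <- function(x, fs, f_hz) {
  sp <- stats::spec.pgram(x, taper = 0, plot = FALSE, detrend = TRUE)
  f <- sp$freq * fs
  sum(sp$spec[f < f_hz]) / sum(sp$spec)
}

# CUSUM-style step detector: counts mean shifts of the smoothed signal.
count_steps <- function(x, fs, thresh_sd = 3) {
  win <- round(fs * 0.25)
  sm <- stats::filter(x, rep(1 / win, win), sides = 2)
  d <- abs(diff(sm[!is.na(sm)], lag = win))
  thr <- thresh_sd * stats::mad(d)
  above <- d > thr
  # count rising edges of above-threshold runs separated by > 0.5 s
  edges <- which(diff(c(FALSE, above)) == 1)
  if (length(edges) == 0) return(0L)
  sum(diff(c(-Inf, edges)) > fs / 2)
}

# Small default mixture used across algorithm tests.
make_test_collection <- function(seed = 3, L = 2000, snr_db = 20,
                                 delays = c(0, 1, 2, 3), fs = 360) {
  src <- ivaecg:::synth_cell_sources(L + max(delays), fs, 72, seed,
                                     guard = max(delays))
  make_datasets(src, delays = delays, snr_db = snr_db,
                mixing_seed = seed + 1)
}

# Correlated Gaussian SCV collection with known mixing (white samples,
# distinct cross-data-set correlations): the canonical identifiable case.
make_gaussian_scv_collection <- function(K = 4, D = 4, L = 2000,
                                         rho = c(0.95, 0.7, 0.4, 0.1),
                                         seed = 1) {
  set.seed(seed)
  S <- lapply(seq_len(D), function(d) matrix(0, K, L))
  for (k in seq_len(K)) {
    base <- stats::rnorm(L)
    for (d in seq_len(D)) {
      S[[d]][k, ] <- sqrt(rho[k]) * base + sqrt(1 - rho[k]) * stats::rnorm(L)
    }
  }
  A <- lapply(seq_len(D), function(d) random_mixing_matrix(K, seed = seed + d))
  X <- Map(function(Sd, Ad) Ad %*% Sd, S, A)
  list(X = X, A = A, S = S)
}
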