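#' Synthetic ECG channel (sum-of-Gaussians PQRST template)
#'
#' Generates a clean single-lead ECG as a train of PQRST complexes. Each beat
#' is a sum of five Gaussian deflections (P, Q, R, S, T) with fixed relative
#' timings and widths; beat-to-beat (RR) intervals are jittered with Gaussian
#' noise of standard deviation 3% of the mean RR interval. The output has zero
#' mean and RMS equal to `amplitude`.
#'
#' @param fs Sampling rate in Hz (>= 100).
#' @param duration Length of the signal in seconds.
#' @param heart_rate Mean heart rate in beats per minute (30-220).
#' @param amplitude Target RMS of the output (0 gives an all-zero signal).
#' @param seed Integer seed; the generator is a pure function of its arguments.
#' @return Numeric vector of `round(fs * duration)` samples.
#' @examples
#' x <- gen_ecg(fs = 360, duration = 5, heart_rate = 72, seed = 1)
#' @export
gen_ecg <- function(fs = 360, duration = 10, heart_rate = 72,
                    amplitude = 1, seed = 1) {
  check_scalar_num(fs, "fs", positive = TRUE)
  check_scalar_num(duration, "duration", positive = TRUE)
  check_scalar_num(heart_rate, "heart_rate")
  check_scalar_num(amplitude, "amplitude")
  if (fs < 100) abort_bad_arg("fs", "must be at least 100 Hz")
  if (heart_rate < 30 || heart_rate > 220) {
    abort_bad_arg("heart_rate", "must be between 30 and 220 bpm")
  }
  rr_mean <- 60 / heart_rate
  if (duration <= 2 * rr_mean) {
    abort_bad_arg("duration", "must cover more than two beats")
  }
  n <- round(fs * duration)
  t <- (seq_len(n) - 1) / fs

  # PQRST template: offsets (s relative to R), widths (s), relative amplitudes.
  wave_dt <- c(P = -0.180, Q = -0.030, R = 0, S = 0.030, T = 0.250)
  wave_w  <- c(P = 0.035, Q = 0.012, R = 0.014, S = 0.012, T = 0.070)
  wave_a  <- c(P = 0.15, Q = -0.12, R = 1.0, S = -0.20, T = 0.35)

  local_seed(seed, {
    # jittered beat times covering the window plus a guard beat on each side
    n_beats <- ceiling(duration / rr_mean) + 2
    rr <- rr_mean * (1 + stats::rnorm(n_beats, 0, 0.03))
    rr <- pmax(rr, 0.3 * rr_mean)
    beats <- cumsum(c(-rr_mean / 2, rr[-1]))
    x <- numeric(n)
    for (b in beats) {
      for (w in seq_along(wave_dt)) {
        mu <- b + wave_dt[[w]]
        # restrict to a +-5 sigma window around the deflection
        lo <- max(1L, floor((mu - 5 * wave_w[[w]]) * fs) + 1L)
        hi <- min(n, ceiling((mu + 5 * wave_w[[w]]) * fs) + 1L)
        if (lo > hi) next
        idx <- lo:hi
        x[idx] <- x[idx] + wave_a[[w]] * exp(-((t[idx] - mu)^2) / (2 * wave_w[[w]]^2))
      }
    }
    scale_signal(x, amplitude)
  })
}

#' Baseline-wander artifact
#'
#' Low-frequency drift modelling respiration (random-phase sinusoids in
#' `drift_band`, default 0.15-0.3 Hz) plus a heavily smoothed random walk for
#' slow body movement. At least 90% of the spectral power falls below 0.7 Hz.
#'
#' @inheritParams gen_ecg
#' @param drift_band Length-2 numeric, respiration drift band in Hz; must lie
#'   inside (0, fs/2).
#' @return Zero-mean numeric vector with RMS `amplitude`.
#' @export
gen_baseline_wander <- function(fs = 360, duration = 10,
                                drift_band = c(0.15, 0.3),
                                amplitude = 1, seed = 1) {
  check_scalar_num(fs, "fs", positive = TRUE)
  check_scalar_num(duration, "duration", positive = TRUE)
  if (!is.numeric(drift_band) || length(drift_band) != 2 ||
      drift_band[1] <= 0 || drift_band[2] <= drift_band[1]) {
    abort_bad_arg("drift_band", "must be an increasing positive interval")
  }
  if (drift_band[2] >= fs / 2) {
    abort_bad_arg("drift_band", "must lie below the Nyquist frequency")
  }
  n <- round(fs * duration)
  t <- (seq_len(n) - 1) / fs

  local_seed(seed, {
    # respiration: a handful of random-phase tones inside the drift band
    k <- 12L
    f <- stats::runif(k, drift_band[1], drift_band[2])
    ph <- stats::runif(k, 0, 2 * pi)
    a <- stats::rnorm(k)  # Gaussian tone amplitudes: near-Gaussian marginal
    resp <- colSums(a * sin(outer(2 * pi * f, t) + ph))
    # body movement: random walk smoothed to well below the drift band
    walk <- cumsum(stats::rnorm(n))
    win <- max(3L, round(fs / 0.35))  # ~3 s moving average
    walk <- stats::filter(walk, rep(1 / win, win), sides = 2, circular = TRUE)
    walk <- as.numeric(walk)
    resp <- resp / max(rms(resp - mean(resp)), .Machine$double.eps)
    walk <- walk / max(rms(walk - mean(walk)), .Machine$double.eps)
    scale_signal(resp + 0.5 * walk, amplitude)
  })
}

#' Muscle (EMG) artifact
#'
#' Broadband Gaussian noise, high-pass filtered above 5 Hz, with a burst
#' envelope: muscle contraction arrives as intermittent bursts at
#' `burst_rate` bursts per second on top of a weak tonic floor. For
#' `burst_rate < 1` the intermittency gives positive excess kurtosis.
#'
#' @inheritParams gen_ecg
#' @param burst_rate Mean number of contraction bursts per second (>= 0).
#' @return Zero-mean numeric vector with RMS `amplitude`.
#' @export
gen_muscle_artifact <- function(fs = 360, duration = 10, amplitude = 1,
                                burst_rate = 0.2, seed = 1) {
  check_scalar_num(fs, "fs", positive = TRUE)
  check_scalar_num(duration, "duration", positive = TRUE)
  check_scalar_num(burst_rate, "burst_rate")
  if (fs < 100) abort_bad_arg("fs", "must be at least 100 Hz")
  if (burst_rate < 0) abort_bad_arg("burst_rate", "must be non-negative")
  n <- round(fs * duration)

  local_seed(seed, {
    noise <- stats::rnorm(n)
    bf <- signal::butter(4, 5 / (fs / 2), type = "high")
    noise <- as.numeric(signal::filtfilt(bf, noise))
    env <- rep(0.15, n)  # tonic floor
    n_bursts <- stats::rpois(1, burst_rate * duration)
    if (n_bursts > 0) {
      starts <- stats::runif(n_bursts, 0, duration)
      lens <- stats::runif(n_bursts, 0.5, 1.5)  # burst duration in s
      for (i in seq_len(n_bursts)) {
        i0 <- max(1L, round(starts[i] * fs))
        i1 <- min(n, round((starts[i] + lens[i]) * fs))
        if (i0 > i1) next
        m <- i1 - i0 + 1L
        env[i0:i1] <- pmax(env[i0:i1], sin(pi * seq_len(m) / (m + 1)))  # smooth on/off
      }
    }
    scale_signal(noise * env, amplitude)
  })
}

#' Electrode-movement artifact
#'
#' Sparse impedance transients: step events arrive as a Poisson process at
#' `event_rate` events per second; each has a random sign and magnitude and
#' decays exponentially with a time constant of 0.5-1.5 s. While the contact
#' is disturbed the changing skin-electrode impedance also produces wideband
#' "crackle": broadband noise amplitude-modulated by the transient envelope,
#' contributing the fraction `crackle` of the total power (real
#' electrode-motion noise records carry substantial wideband content, not
#' just the slow potential shift).
#'
#' @inheritParams gen_ecg
#' @param event_rate Mean number of transient events per second (>= 0).
#' @param crackle Fraction of signal power in the wideband component
#'   (in `[0, 1)`, default 0.35).
#' @return Zero-mean numeric vector with RMS `amplitude` (all zeros when no
#'   event occurs).
#' @export
gen_electrode_movement <- function(fs = 360, duration = 10, amplitude = 1,
                                   event_rate = 0.1, crackle = 0.35, seed = 1) {
  check_scalar_num(fs, "fs", positive = TRUE)
  check_scalar_num(duration, "duration", positive = TRUE)
  check_scalar_num(event_rate, "event_rate")
  check_scalar_num(crackle, "crackle")
  if (event_rate < 0) abort_bad_arg("event_rate", "must be non-negative")
  if (crackle < 0 || crackle >= 1) abort_bad_arg("crackle", "must be in [0, 1)")
  n <- round(fs * duration)

  local_seed(seed, {
    x <- numeric(n)
    env <- numeric(n)
    n_events <- stats::rpois(1, event_rate * duration)
    if (n_events > 0) {
      times <- sort(stats::runif(n_events, 0, duration))
      signs <- sample(c(-1, 1), n_events, replace = TRUE)
      mags <- stats::rlnorm(n_events, 0, 0.3)
      taus <- stats::runif(n_events, 0.5, 1.5)
      t <- (seq_len(n) - 1) / fs
      for (i in seq_len(n_events)) {
        idx <- which(t >= times[i])
        decay <- mags[i] * exp(-(t[idx] - times[i]) / taus[i])
        x[idx] <- x[idx] + signs[i] * decay
        env[idx] <- env[idx] + decay
      }
    }
    if (all(x == 0)) return(x)
    if (crackle > 0) {
      noise <- env * stats::rnorm(n)
      r_x <- max(rms(x - mean(x)), .Machine$double.eps)
      r_n <- max(rms(noise - mean(noise)), .Machine$double.eps)
      x <- sqrt(1 - crackle) * x / r_x + sqrt(crackle) * noise / r_n
    }
    scale_signal(x, amplitude)
  })
}

# The four-source benchmark configuration needs all sources present: redraw
# the Poisson event count (deterministically, by stepping the derived seed)
# until at least one electrode transient occurs.
gen_em_nonzero <- function(fs, duration, amplitude, event_rate, seed) {
  for (i in 0:100) {
    x <- gen_electrode_movement(fs, duration, amplitude, event_rate,
                                seed = seed + i)
    if (any(x != 0)) return(x)
  }
  x
}

#' Standard source set: ECG + baseline wander + electrode movement + muscle
#'
#' Convenience constructor for the four-source configuration used throughout
#' the benchmarks: one ECG channel and the three artifact channels, all at
#' unit RMS by default.
#'
#' @inheritParams gen_ecg
#' @param amplitudes Named numeric vector of per-source RMS values with names
#'   `ECG`, `BW`, `EM`, `MA`. Defaults reflect the artifacts' character:
#'   baseline wander carries large amplitude (body movement), muscle noise is
#'   low-amplitude, electrode transients are comparable to the ECG.
#' @return A [source_set] with labels `c("ECG", "BW", "EM", "MA")`.
#' @export
gen_standard_sources <- function(fs = 360, duration = 10, heart_rate = 72,
                                 amplitudes = c(ECG = 1, BW = 1.5, EM = 1,
                                                MA = 0.5),
                                 seed = 1) {
  stopifnot(all(c("ECG", "BW", "EM", "MA") %in% names(amplitudes)))
  s <- rbind(
    gen_ecg(fs, duration, heart_rate, amplitudes[["ECG"]], seed = derive_seed(seed, 1)),
    gen_baseline_wander(fs, duration, amplitude = amplitudes[["BW"]],
                        seed = derive_seed(seed, 2)),
    gen_em_nonzero(fs, duration, amplitude = amplitudes[["EM"]],
                   event_rate = 0.3, seed = derive_seed(seed, 3)),
    gen_muscle_artifact(fs, duration, amplitude = amplitudes[["MA"]],
                        burst_rate = 0.4, seed = derive_seed(seed, 4))
  )
  source_set(s, labels = c("ECG", "BW", "EM", "MA"), fs = fs)
}
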