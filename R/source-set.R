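#' Source set: labelled multichannel source signals
#'
#' Container for a K x L matrix of zero-mean source signals with one label per
#' row (`"ECG"`, `"BW"`, `"EM"`, `"MA"` or `"OTHER"`) and a sampling rate.
#'
#' @param signals K x L numeric matrix; each row is one source, rows must be
#'   zero-mean (|mean| <= 1e-8 * RMS).
#' @param labels Character vector of length K with values from
#'   `c("ECG", "BW", "EM", "MA", "OTHER")`.
#' @param fs Sampling rate in Hz.
#' @return An object of class `source_set` with fields `signals`, `labels`, `fs`.
#' @export
source_set <- function(signals, labels, fs) {
  if (!is.matrix(signals) || !is.numeric(signals)) {
    abort_bad_arg("signals", "must be a numeric matrix")
  }
  k <- nrow(signals)
  if (k < 2 || ncol(signals) < 2) {
    abort_bad_arg("signals", "must have at least 2 rows and 2 columns")
  }
  if (length(labels) != k) abort_bad_arg("labels", "must have one entry per row")
  bad <- setdiff(labels, c("ECG", "BW", "EM", "MA", "OTHER"))
  if (length(bad) > 0) {
    abort_bad_arg("labels", sprintf("contains unknown tags: %s",
                                    paste(bad, collapse = ", ")))
  }
  check_scalar_num(fs, "fs", positive = TRUE)
  mu <- rowMeans(signals)
  r <- apply(signals, 1, rms)
  if (any(r > 0 & abs(mu) > 1e-8 * r)) {
    abort_bad_arg("signals", "rows must be zero-mean (within 1e-8 of their RMS)")
  }
  structure(list(signals = signals, labels = as.character(labels), fs = fs),
            class = "source_set")
}

#' @export
print.source_set <- function(x, ...) {
  cat(sprintf("<source_set> %d sources x %d samples @ %g Hz [%s]\n",
              nrow(x$signals), ncol(x$signals), x$fs,
              paste(x$labels, collapse = ", ")))
  invisible(x)
}

#' @export
dim.source_set <- function(x) dim(x$signals)

#' Tidy a source set into a long tibble
#'
#' One row per (source, sample): columns `source`, `time` (seconds),
#' `value`.
#'
#' @param x A [source_set].
#' @param ... Unused.
#' @return A tibble in long format.
#' @export
tidy.source_set <- function(x, ...) {
  tibble::tibble(
    source = rep(x$labels, each = ncol(x$signals)),
    time = rep((seq_len(ncol(x$signals)) - 1) / x$fs, nrow(x$signals)),
    value = as.vector(t(x$signals))
  )
}

#' @rdname tidy.source_set
#' @param object A [source_set].
#' @importFrom ggplot2 autoplot
#' @export
autoplot.source_set <- function(object, ...) {
  df <- tidy.source_set(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$source), scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "amplitude")
}
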