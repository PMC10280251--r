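#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy an unmixing result
#'
#' One row per (data set, component, sample) of the estimated sources.
#'
#' @param x An `unmixing_result`.
#' @param ... Unused.
#' @return Tibble with columns `dataset`, `component`, `sample`, `value`.
#' @export
tidy.unmixing_result <- function(x, ...) {
  D <- length(x$Y)
  purrr::map_dfr(seq_len(D), function(d) {
    Y <- x$Y[[d]]
    tibble::tibble(dataset = d,
                   component = rep(seq_len(nrow(Y)), each = ncol(Y)),
                   sample = rep(seq_len(ncol(Y)), nrow(Y)),
                   value = as.vector(t(Y)))
  })
}

#' One-line summary of an unmixing result
#'
#' @param x An `unmixing_result`.
#' @param ... Unused.
#' @return One-row tibble: `algorithm`, `D`, `K`, `L`, `n_iterations`,
#'   `converged`, `final_cost`.
#' @export
glance.unmixing_result <- function(x, ...) {
  tibble::tibble(algorithm = x$algorithm, D = length(x$Y),
                 K = nrow(x$Y[[1]]), L = ncol(x$Y[[1]]),
                 n_iterations = x$n_iterations, converged = x$converged,
                 final_cost = if (length(x$cost_trace)) utils::tail(x$cost_trace, 1)
                              else NA_real_)
}

#' Plot the cost trace of an unmixing result
#'
#' @param object An `unmixing_result` from one of the IVA variants.
#' @param ... Unused.
#' @return A ggplot object (objective value versus iteration).
#' @export
autoplot.unmixing_result <- function(object, ...) {
  df <- tibble::tibble(iteration = seq_along(object$cost_trace) - 1,
                       cost = object$cost_trace)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$cost)) +
    ggplot2::geom_line() +
    ggplot2::labs(title = object$algorithm, x = "iteration",
                  y = "objective value")
}

#' Plot a benchmark grid
#'
#' Mean joint ISI (with +-1 standard-error ribbon) versus block length or
#' SNR, one line per algorithm.
#'
#' @param object Tibble from [run_grid()].
#' @param x_var `"L"` (default) or `"snr_db"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_grid_summary <- function(object, x_var = c("L", "snr_db"), ...) {
  x_var <- match.arg(x_var)
  summ <- summarize_grid(object)
  ggplot2::ggplot(summ, ggplot2::aes(x = .data[[x_var]], y = .data$mean_isi,
                                     color = .data$algorithm)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_isi - .data$se_isi,
                                      ymax = .data$mean_isi + .data$se_isi,
                                      fill = .data$algorithm),
                         alpha = 0.2, color = NA) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = x_var, y = "mean joint ISI")
}
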