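#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a simulated signal
#'
#' @param object A `syn_signal`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot syn_signal
#' @export
autoplot.syn_signal <- function(object, ...) {
  units <- attr(object, "units")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_ms, y = .data$value)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::labs(x = "time (ms)", y = paste0(attr(object, "modality"),
                                              " (", units, ")")) +
    ggplot2::theme_minimal()
}

#' Plot a reconstructed trace
#'
#' Anchor points (initiation, peak, decay) are filled; interpolated
#' points are hollow.
#'
#' @param object A `recon_trace`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot recon_trace
#' @export
autoplot.recon_trace <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$time_ms, y = .data$value)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$anchor), colour = "#d95f02") +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                name = "anchor") +
    ggplot2::labs(x = "time (ms)", y = "value",
                  subtitle = paste(object$stp_class, "|", object$provenance)) +
    ggplot2::theme_minimal()
}

#' Plot a fit against its trace
#'
#' Overlays the forward-simulated signal at the fitted parameters on the
#' trace's data points.
#'
#' @param object A `syn_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot syn_fit
#' @export
autoplot.syn_fit <- function(object, ...) {
  trace <- object$trace
  theta <- matrix(c(object$g_opt, object$params$tau_d, object$params$tau_r,
                    object$params$tau_f, object$params$U), 1)
  sim <- .forward_pop(theta, trace, object$conditions,
                      if (is.list(object$membrane) &&
                          !inherits(object$membrane, "membrane_model"))
                        NULL else object$membrane)[, 1]
  df <- dplyr::mutate(trace$points, simulated = sim)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_ms)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$value, shape = .data$anchor),
                        colour = "#d95f02") +
    ggplot2::geom_line(ggplot2::aes(y = .data$simulated), colour = "#1b9e77") +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                name = "anchor") +
    ggplot2::labs(x = "time (ms)", y = "value") +
    ggplot2::theme_minimal()
}

#' Plot covariate effect sizes
#'
#' @param x A [covariate_effect()] result.
#' @return A ggplot of per-connection SPD distributions per parameter
#'   with the trimmed-mean summary.
#' @export
plot_covariate_effect <- function(x) {
  stopifnot(inherits(x, "covariate_effect"))
  ggplot2::ggplot(x$per_connection,
                  ggplot2::aes(x = .data$parameter, y = .data$spd)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.4, colour = "#7570b3") +
    ggplot2::geom_point(data = x$summary,
                        ggplot2::aes(y = .data$spd_trimmed_mean),
                        colour = "#d95f02", size = 3) +
    ggplot2::labs(x = NULL, y = "SPD (%)",
                  subtitle = paste("covariate:", x$covariate)) +
    ggplot2::theme_minimal()
}
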