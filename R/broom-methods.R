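#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted synapse model
#'
#' @param x A `syn_fit`.
#' @param ... Unused.
#' @return Tibble with one row per parameter: `parameter`, `estimate`,
#'   and the spread (`sd`) of the kept optimization runs.
#' @method tidy syn_fit
#' @export
tidy.syn_fit <- function(x, ...) {
  kept <- x$runs[x$runs$run %in% x$kept, ]
  est <- c(g = x$params$g, tau_d = x$params$tau_d, tau_r = x$params$tau_r,
           tau_f = x$params$tau_f, U = x$params$U)
  sds <- if ("g" %in% names(kept)) {
    c(g = stats::sd(kept$g), tau_d = stats::sd(kept$tau_d),
      tau_r = stats::sd(kept$tau_r), tau_f = stats::sd(kept$tau_f),
      U = stats::sd(kept$U))
  } else rep(NA_real_, 5)
  tibble::tibble(parameter = names(est), estimate = unname(est),
                 sd = unname(sds))
}

#' Glance at a fitted synapse model
#'
#' @param x A `syn_fit`.
#' @param ... Unused.
#' @return One-row tibble: best objective, runs, kept runs, exclusion
#'   flag.
#' @method glance syn_fit
#' @export
glance.syn_fit <- function(x, ...) {
  tibble::tibble(objective = x$objective, runs = nrow(x$runs),
                 kept = length(x$kept), excluded = x$excluded,
                 boundary = length(x$boundary) > 0)
}

#' @method tidy syn_validation
#' @export
tidy.syn_validation <- function(x, ...) {
  dplyr::left_join(
    dplyr::left_join(x$per_parameter,
                     dplyr::rename(x$variability, variability = "value"),
                     by = "parameter"),
    dplyr::rename(x$reliability, reliability = "value"),
    by = "parameter")
}

#' @method glance syn_validation
#' @export
glance.syn_validation <- function(x, ...) {
  tibble::tibble(training_smape = x$training_smape,
                 prediction_smape = x$prediction_smape,
                 mode = x$mode, folds = x$k)
}

#' @method tidy synaptometrics
#' @export
tidy.synaptometrics <- function(x, ...) x$events

#' @method glance synaptometrics
#' @export
glance.synaptometrics <- function(x, ...) {
  tidyr::pivot_wider(x$kinetics, names_from = "metric",
                     values_from = "value_ms")
}
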