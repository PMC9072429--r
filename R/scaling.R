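#' Symmetric mean absolute percentage error
#'
#' `SMAPE = (200 / n) * sum(|p - t| / (|p| + |t|))`, bounded in
#' \[0, 200\] and symmetric in its arguments. A point where both
#' prediction and target are exactly zero contributes 0.
#'
#' @param prediction,target Numeric vectors (or matrices) of equal shape.
#' @return Scalar SMAPE value.
#' @examples
#' smape(3, 1)  # 100
#' @export
smape <- function(prediction, target) {
  p <- as.numeric(prediction); t <- as.numeric(target)
  if (length(p) != length(t)) stop("length mismatch", call. = FALSE)
  den <- abs(p) + abs(t)
  term <- ifelse(den == 0, 0, abs(p - t) / den)
  200 * mean(term)
}

#' Fit and apply the dataset scalers
#'
#' Features are divided by their per-column maximum absolute value
#' (preserving sparsity; all-zero columns are left unscaled), and targets
#' are mapped to \[0, 1\] per column by min-max so the model's sigmoid
#' output layer can represent them. Both transforms are invertible.
#'
#' @param features Numeric tibble/matrix of encoded features.
#' @param targets Numeric tibble of the five targets (no missing values).
#' @return List of class `syn_scalers` with `features`, `targets` (scaled
#'   tibbles) and `scalers` (needed by [unscale_targets()]).
#' @export
scale_dataset <- function(features, targets) {
  X <- as.matrix(features)
  Y <- as.matrix(targets)
  max_abs <- apply(abs(X), 2, max)
  max_abs[max_abs == 0] <- 1
  t_min <- apply(Y, 2, min)
  t_max <- apply(Y, 2, max)
  span <- t_max - t_min
  span[span == 0] <- 1
  scalers <- structure(list(max_abs = max_abs, t_min = t_min, t_max = t_max,
                            t_span = span), class = "syn_scalers")
  list(features = tibble::as_tibble(as.data.frame(scale_features(X, scalers))),
       targets = tibble::as_tibble(as.data.frame(scale_targets(Y, scalers))),
       scalers = scalers)
}

#' @rdname scale_dataset
#' @param x Numeric matrix/tibble to transform.
#' @param scalers A `syn_scalers` object.
#' @export
scale_features <- function(x, scalers) {
  sweep(as.matrix(x), 2, scalers$max_abs, "/")
}

#' @rdname scale_dataset
#' @export
scale_targets <- function(x, scalers) {
  sweep(sweep(as.matrix(x), 2, scalers$t_min, "-"), 2, scalers$t_span, "/")
}

#' @rdname scale_dataset
#' @export
unscale_targets <- function(x, scalers) {
  sweep(sweep(as.matrix(x), 2, scalers$t_span, "*"), 2, scalers$t_min, "+")
}

# Plausibility bounds on emitted parameters: g > 0, 0 < tau_d < 70 ms,
# tau_r > 50 ms, tau_f > 1 ms, 0 < U < 1.
.PLAUSIBLE_LO <- c(g = 1e-6, tau_d = 1e-3, tau_r = 50, tau_f = 1, U = 1e-6)
.PLAUSIBLE_HI <- c(g = Inf, tau_d = 70, tau_r = Inf, tau_f = Inf, U = 1 - 1e-6)

.clip_plausible <- function(Y) {
  nm <- colnames(Y)
  for (j in seq_len(ncol(Y))) {
    Y[, j] <- pmin(pmax(Y[, j], .PLAUSIBLE_LO[[nm[j]]]), .PLAUSIBLE_HI[[nm[j]]])
  }
  Y
}

#' Impute missing short-term-plasticity targets with a random forest
#'
#' Records that report only a single synaptic event lack the ST-P triple
#' (`tau_r`, `tau_f`, `U`). A random-forest regressor per target, trained
#' on the complete records' encoded features, fills the missing values;
#' the completed values are clipped to the plausibility bounds. Records
#' with a missing triple must have had their ISI feature zeroed at
#' encoding (the `NA` sentinel rule), which lets the forest distinguish
#' them from true zeros.
#'
#' @param features Encoded feature tibble (319 columns).
#' @param targets Target tibble with `NA` in `tau_r`, `tau_f`, `U` for
#'   incomplete records.
#' @param seed Integer seed for the forests.
#' @param num_trees Trees per forest.
#' @return The completed target tibble, with a logical attribute
#'   `"imputed"` marking the filled rows.
#' @export
impute_stp_targets <- function(features, targets, seed = 1L, num_trees = 300) {
  targets <- tibble::as_tibble(targets)
  miss <- is.na(targets$tau_r) | is.na(targets$tau_f) | is.na(targets$U)
  if (!any(miss)) {
    attr(targets, "imputed") <- miss
    return(targets)
  }
  if (all(miss)) stop("no complete records to train the imputer", call. = FALSE)
  X <- as.data.frame(features)
  names(X) <- make.names(names(X))
  out <- targets
  for (p in c("tau_r", "tau_f", "U")) {
    d <- X[!miss, , drop = FALSE]
    d$.y <- targets[[p]][!miss]
    rf <- ranger::ranger(dependent.variable.name = ".y", data = d,
                         num.trees = num_trees, seed = seed,
                         num.threads = 1)
    pred <- stats::predict(rf, X[miss, , drop = FALSE],
                           num.threads = 1)$predictions
    out[[p]][miss] <- pmin(pmax(pred, .PLAUSIBLE_LO[[p]]), .PLAUSIBLE_HI[[p]])
  }
  attr(out, "imputed") <- miss
  out
}
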