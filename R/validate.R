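#' Validate a prediction model by cross-validation or jackknife
#'
#' Computes the validation quantities of the normalization stage:
#' *training accuracy* (mean SMAPE of a model trained on all records,
#' evaluated on those records), *prediction accuracy* (mean out-of-fold
#' SMAPE under k-fold cross-validation with k = 4, or leave-one-out
#' jackknife), *target variability* (for groups of records sharing
#' identical features, the average SMAPE distance of each group member
#' from the group mean - the empirical accuracy ceiling), and
#' *prediction reliability* (the percentage of group predictions that
#' fall inside the 95% t-confidence interval of the group mean).
#'
#' @param features Encoded feature tibble.
#' @param targets Complete target tibble (impute first if needed).
#' @param mode `"kfold"` or `"jackknife"`.
#' @param k Number of folds for `"kfold"`.
#' @param seed Integer seed (fold assignment and training).
#' @param ... Passed to [mlp_train()] (e.g. `hidden`, `epochs`).
#' @return A list of class `syn_validation`: `training_smape`,
#'   `prediction_smape` (scalars), `per_parameter` (tibble of both per
#'   target), `variability` (tibble per parameter, `NA` if no duplicate
#'   groups), `reliability` (tibble per parameter, percentages),
#'   `assignments` (fold index per record).
#' @export
validate_model <- function(features, targets, mode = c("kfold", "jackknife"),
                           k = 4, seed = 1L, ...) {
  mode <- match.arg(mode)
  features <- tibble::as_tibble(features)
  targets <- tibble::as_tibble(targets)
  n <- nrow(features)
  params <- names(targets)
  sc <- scale_dataset(features, targets)
  Xs <- as.matrix(sc$features)
  Ys <- as.matrix(sc$targets)

  full <- mlp_train(Xs, Ys, seed = seed, ...)
  fit_full <- unscale_targets(predict(full, Xs), sc$scalers)
  colnames(fit_full) <- params
  train_sm <- smape(fit_full, as.matrix(targets))
  train_by_p <- vapply(params, function(p) smape(fit_full[, p], targets[[p]]),
                       numeric(1))

  set.seed(seed)
  folds <- if (mode == "kfold") sample(rep(seq_len(k), length.out = n)) else
    seq_len(n)
  n_folds <- length(unique(folds))
  oof <- matrix(NA_real_, n, length(params), dimnames = list(NULL, params))
  for (f in sort(unique(folds))) {
    hold <- folds == f
    m <- mlp_train(Xs[!hold, , drop = FALSE], Ys[!hold, , drop = FALSE],
                   seed = seed + f, ...)
    oof[hold, ] <- unscale_targets(
      predict(m, Xs[hold, , drop = FALSE]), sc$scalers)
  }
  pred_sm <- smape(oof, as.matrix(targets))
  pred_by_p <- vapply(params, function(p) smape(oof[, p], targets[[p]]),
                      numeric(1))

  # duplicate-feature groups
  key <- apply(as.matrix(features), 1, paste, collapse = "\r")
  grp <- split(seq_len(n), key)
  grp <- grp[lengths(grp) >= 2]
  if (length(grp) == 0) {
    variability <- reliability <- tibble::tibble(
      parameter = params, value = NA_real_)
  } else {
    variability <- purrr::map_dfr(params, function(p) {
      v <- vapply(grp, function(ix) {
        y <- targets[[p]][ix]
        mean(vapply(y, smape, numeric(1), target = mean(y)))
      }, numeric(1))
      tibble::tibble(parameter = p, value = mean(v))
    })
    reliability <- purrr::map_dfr(params, function(p) {
      inside <- vapply(grp, function(ix) {
        y <- targets[[p]][ix]
        m <- mean(y); s <- stats::sd(y); nn <- length(y)
        half <- stats::qt(0.975, nn - 1) * s / sqrt(nn)
        pr <- mean(fit_full[ix, p])
        as.numeric(pr >= m - half & pr <= m + half)
      }, numeric(1))
      tibble::tibble(parameter = p, value = 100 * mean(inside))
    })
  }
  structure(list(
    training_smape = train_sm,
    prediction_smape = pred_sm,
    per_parameter = tibble::tibble(parameter = params,
                                   training = unname(train_by_p),
                                   prediction = unname(pred_by_p)),
    variability = variability,
    reliability = reliability,
    assignments = folds,
    mode = mode, k = n_folds
  ), class = "syn_validation")
}

#' @export
print.syn_validation <- function(x, ...) {
  cat("<syn_validation>", x$mode, "| training SMAPE",
      format(x$training_smape, digits = 4), "| prediction SMAPE",
      format(x$prediction_smape, digits = 4), "\n")
  invisible(x)
}
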