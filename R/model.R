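#' Train a synaptic-parameter prediction model
#'
#' End-to-end trainer for one deep regressor: scales the encoded features
#' (max-absolute) and targets (min-max), optionally random-forest-imputes
#' missing ST-P triples first, trains the SMAPE-loss MLP, and bundles the
#' scalers, training-set bounds and feature schema with the network. An
#' optional iterative-feedback phase re-imputes the originally missing
#' targets with the latest deep model and retrains, up to
#' `feedback_rounds` rounds or until the training SMAPE stops improving.
#'
#' @param features Encoded feature tibble (319 columns, see
#'   [encode_features()]).
#' @param targets Target tibble `g`, `tau_d`, `tau_r`, `tau_f`, `U`
#'   (`NA` ST-P triples allowed when `impute = TRUE`).
#' @param schema The [feature_schema()] used for encoding.
#' @param impute Random-forest-impute missing ST-P triples first.
#' @param feedback_rounds Maximum deep-imputation feedback rounds
#'   (default 0; the printed protocol allows up to 30).
#' @param seed Integer seed.
#' @param ... Passed to [mlp_train()] (e.g. `hidden`, `epochs`).
#' @return An object of class `syn_model`.
#' @export
train_synapse_model <- function(features, targets, schema = feature_schema(),
                                impute = TRUE, feedback_rounds = 0,
                                seed = 1L, ...) {
  features <- tibble::as_tibble(features)
  targets <- tibble::as_tibble(targets)
  miss <- is.na(targets$tau_r) | is.na(targets$tau_f) | is.na(targets$U)
  if (any(miss)) {
    if (!impute) stop("targets contain missing ST-P triples; set impute = TRUE",
                      call. = FALSE)
    targets <- impute_stp_targets(features, targets, seed = seed)
  }
  sc <- scale_dataset(features, targets)
  net <- mlp_train(as.matrix(sc$features), as.matrix(sc$targets),
                   seed = seed, ...)
  round <- 0L
  while (round < feedback_rounds && any(miss)) {
    round <- round + 1L
    pred <- unscale_targets(predict(net, as.matrix(sc$features)), sc$scalers)
    colnames(pred) <- names(targets)
    upd <- targets
    for (p in c("tau_r", "tau_f", "U")) upd[[p]][miss] <- pred[miss, p]
    sc2 <- scale_dataset(features, upd)
    net2 <- mlp_train(as.matrix(sc2$features), as.matrix(sc2$targets),
                      seed = seed + round, ...)
    if (net2$loss >= net$loss) break
    targets <- upd; sc <- sc2; net <- net2
  }
  structure(list(net = net, scalers = sc$scalers, schema = schema,
                 target_names = names(targets),
                 train_bounds = list(lo = sc$scalers$t_min,
                                     hi = sc$scalers$t_max),
                 seed = seed),
            class = "syn_model")
}

#' @export
print.syn_model <- function(x, ...) {
  cat("<syn_model> training SMAPE =", format(x$net$loss, digits = 4),
      "| hidden:", paste(x$net$hidden, collapse = "-"), "\n")
  invisible(x)
}

#' Predict synaptic parameters from encoded features
#'
#' @param object A `syn_model`.
#' @param features Encoded feature tibble (unscaled; 319 columns) or raw
#'   record tibble (with `pre`/`post` columns), which is encoded first.
#' @param ... Unused.
#' @return Tibble of the five parameters on their natural scale, clipped
#'   to the plausibility bounds, with a logical `at_train_bound` column
#'   flagging predictions saturated at the training-set range.
#' @export
predict.syn_model <- function(object, features, ...) {
  features <- tibble::as_tibble(features)
  if ("pre" %in% names(features)) {
    features <- encode_features(features, object$schema)
  }
  Xs <- scale_features(as.matrix(features), object$scalers)
  Ps <- predict(object$net, Xs)
  at_bound <- apply(Ps < 1e-3 | Ps > 1 - 1e-3, 1, any)
  Y <- unscale_targets(Ps, object$scalers)
  colnames(Y) <- object$target_names
  Y <- .clip_plausible(Y)
  out <- tibble::as_tibble(as.data.frame(Y))
  out$at_train_bound <- at_bound
  out
}

#' Train an ensemble of prediction models
#'
#' Trains `n_models` networks that differ only in their random seed and
#' share one pair of scalers, mirroring the repeated-training protocol
#' used to quantify prediction spread (the production protocol uses 100
#' repeats; smaller ensembles are appropriate at desk scale).
#'
#' @inheritParams train_synapse_model
#' @param n_models Number of ensemble members.
#' @return An object of class `syn_ensemble`.
#' @export
train_ensemble <- function(features, targets, n_models = 10,
                           schema = feature_schema(), impute = TRUE,
                           seed = 1L, ...) {
  features <- tibble::as_tibble(features)
  targets <- tibble::as_tibble(targets)
  miss <- is.na(targets$tau_r) | is.na(targets$tau_f) | is.na(targets$U)
  if (any(miss)) {
    if (!impute) stop("targets contain missing ST-P triples", call. = FALSE)
    targets <- impute_stp_targets(features, targets, seed = seed)
  }
  sc <- scale_dataset(features, targets)
  members <- purrr::map(seq_len(n_models), function(i) {
    net <- mlp_train(as.matrix(sc$features), as.matrix(sc$targets),
                     seed = seed + 1000L * i, ...)
    structure(list(net = net, scalers = sc$scalers,
                   schema = schema,
                   target_names = names(targets),
                   train_bounds = list(lo = sc$scalers$t_min,
                                       hi = sc$scalers$t_max),
                   seed = seed + 1000L * i),
              class = "syn_model")
  })
  structure(list(members = members, scalers = sc$scalers,
                 schema = members[[1]]$schema,
                 target_names = names(targets), seed = seed),
            class = "syn_ensemble")
}

#' @export
print.syn_ensemble <- function(x, ...) {
  cat("<syn_ensemble>", length(x$members), "members\n")
  invisible(x)
}

#' Normalized per-connection parameter predictions
#'
#' Predicts the five synaptic parameters for an unambiguous (one
#' presynaptic type, one postsynaptic type) connection under a fully
#' specified covariate condition, from every member of a trained
#' ensemble, and summarises the spread. This is the normalization
#' operation: holding the condition fixed across connections removes the
#' covariate differences present in the training corpus.
#'
#' @param ensemble A [train_ensemble()] object.
#' @param pre,post Single neuron type names from the schema catalog.
#' @param condition One-row condition tibble; default
#'   [standard_condition()].
#' @return Tibble with one row per parameter: `parameter`, `mean`, `sd`,
#'   `min`, `max`, `range`, and `at_train_bound` (any member saturated).
#' @export
predict_normalized <- function(ensemble, pre, post,
                               condition = standard_condition()) {
  stopifnot(inherits(ensemble, "syn_ensemble"),
            length(pre) == 1, length(post) == 1)
  if (length(ensemble$members) == 0) stop("untrained ensemble", call. = FALSE)
  rec <- condition[1, , drop = FALSE]
  rec$pre <- pre
  rec$post <- post
  rec$modality <- NULL
  preds <- purrr::map_dfr(ensemble$members, function(m) {
    predict(m, rec)
  })
  params <- ensemble$target_names
  purrr::map_dfr(params, function(p) {
    v <- preds[[p]]
    tibble::tibble(parameter = p, mean = mean(v), sd = stats::sd(v),
                   min = min(v), max = max(v), range = max(v) - min(v),
                   at_train_bound = any(preds$at_train_bound))
  })
}
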