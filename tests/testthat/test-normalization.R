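test_that("feature encoding matches the versioned 319-column layout", {
  schema <- feature_schema()
  ds <- generate_ml_dataset(dataset_spec(n_records = 50, seed = 2))
  X <- encode_features(ds$records, schema)
  expect_equal(ncol(X), 319)
  expect_equal(names(X), schema$columns)
  # species / sex coding
  rec <- ds$records[1, ]
  rec$species <- "mouse"; rec$sex <- "male"
  x <- encode_features(rec, schema)
  expect_equal(x$species, -1)
  expect_equal(x$sex, 1)
  # fuzzy mapping: two candidate presynaptic types set two columns
  rec$pre <- paste(schema$catalog[1], schema$catalog[2], sep = "|")
  x <- encode_features(rec, schema)
  expect_equal(sum(x[paste0("pre_", schema$catalog[1:2])]), 2)
  expect_equal(sum(x[grep("^pre_", names(x))]), 2)
  # ISI sentinel: missing ST-P zeroes the ISI, otherwise NA becomes 50
  rec$stp_missing <- TRUE; rec$isi <- NA
  expect_equal(encode_features(rec, schema)$isi, 0)
  rec$stp_missing <- FALSE
  expect_equal(encode_features(rec, schema)$isi, 50)
  # catalog and age validation
  rec_bad <- rec; rec_bad$pre <- "NOPE"
  expect_error(encode_features(rec_bad, schema), "unknown level")
  rec_na <- rec; rec_na$age <- NA_real_
  expect_error(encode_features(rec_na, schema), "age")
})

test_that("scalers transform and invert exactly", {
  X <- tibble::tibble(a = c(0, 0, 5), b = c(-2, 4, 1), z = c(0, 0, 0))
  Y <- tibble::tibble(g = c(2, 4, 6), tau_d = c(1, 1, 3), tau_r = c(5, 7, 9),
                      tau_f = c(2, 8, 5), U = c(0.1, 0.5, 0.9))
  sc <- scale_dataset(X, Y)
  expect_equal(sc$features$a, c(0, 0, 1))
  expect_equal(sc$features$z, c(0, 0, 0))  # all-zero column left unscaled
  expect_equal(sc$targets$g, c(0, 0.5, 1))
  back <- unscale_targets(as.matrix(sc$targets), sc$scalers)
  expect_equal(unname(back), unname(as.matrix(Y)), tolerance = 1e-12)
})

test_that("SMAPE has its identities and bounds", {
  expect_equal(smape(3, 3), 0)
  expect_equal(smape(0, 7), 200)
  expect_equal(smape(3, 1), 100)
  expect_equal(smape(c(0, 0), c(0, 0)), 0)
  set.seed(4)
  p <- runif(50); t <- runif(50)
  expect_equal(smape(p, t), smape(t, p))
  expect_true(smape(p, t) >= 0 && smape(p, t) <= 200)
})

test_that("random-forest imputation recovers planted ST-P structure", {
  ds <- generate_ml_dataset(dataset_spec(n_records = 400, missing_stp = 0,
                                         seed = 31))
  X <- encode_features(ds$records)
  # plant tau_r as an exact function of two features
  targets <- ds$targets
  targets$tau_r <- 100 + 8 * ds$records$temperature +
    60 * (ds$records$species == "rat")
  miss <- seq_len(400) %% 5 == 0
  holdout <- targets$tau_r[miss]
  targets$tau_r[miss] <- NA
  targets$tau_f[miss] <- NA
  targets$U[miss] <- NA
  done <- impute_stp_targets(X, targets, seed = 7)
  relerr <- abs(done$tau_r[miss] - holdout) / holdout
  expect_lt(median(relerr), 0.10)
  expect_true(all(done$tau_f >= 1 & done$U > 0 & done$U < 1))
  # no-op on complete data, error when nothing to learn from
  expect_equal(impute_stp_targets(X, ds$targets, seed = 7), ds$targets,
               ignore_attr = TRUE)
  allna <- targets
  allna$tau_r <- NA
  expect_error(impute_stp_targets(X, allna, seed = 7), "complete")
})

test_that("the MLP is deterministic and can fit a smooth map", {
  set.seed(12)
  n <- 250
  X <- matrix(0, n, 8)
  X[, 1:5] <- matrix(runif(n * 5), n)
  Y <- cbind(0.2 + 0.6 * X[, 1],
             plogis(2 * X[, 2] - 1),
             0.5 * X[, 3] + 0.25 * X[, 4],
             0.3 + 0.4 * X[, 5],
             0.5 + 0.2 * X[, 1] * X[, 2])
  m1 <- mlp_train(X, Y, hidden = c(32, 16, 8, 16, 32), epochs = 1500,
                  dropout = 0, noise_sd = 0, seed = 99)
  m2 <- mlp_train(X, Y, hidden = c(32, 16, 8, 16, 32), epochs = 1500,
                  dropout = 0, noise_sd = 0, seed = 99)
  expect_equal(predict(m1, X), predict(m2, X))  # same seed, same model
  expect_lt(smape(predict(m1, X), Y), 5)
  expect_error(mlp_train(X[1:10, ], Y[1:5, ]), "nrow")
})

test_that("trained models emit plausible, bounded parameters", {
  ds <- generate_ml_dataset(dataset_spec(n_records = 300, missing_stp = 0.1,
                                         seed = 41))
  X <- encode_features(ds$records)
  mod <- train_synapse_model(X, ds$targets, seed = 3,
                             hidden = c(32, 16, 8, 16, 32), epochs = 300)
  pred <- predict(mod, X)
  expect_equal(nrow(pred), 300)
  expect_true(all(pred$g > 0))
  expect_true(all(pred$tau_d > 0 & pred$tau_d < 70))
  expect_true(all(pred$tau_r > 50))
  expect_true(all(pred$tau_f > 1))
  expect_true(all(pred$U > 0 & pred$U < 1))
})

test_that("validation partitions records and bounds its summaries", {
  ds <- generate_ml_dataset(dataset_spec(n_records = 120, missing_stp = 0,
                                         seed = 51))
  X <- encode_features(ds$records)
  # add duplicate-feature groups by repeating rows with jittered targets
  X2 <- dplyr::bind_rows(X, X[1:10, ])
  T2 <- dplyr::bind_rows(ds$targets, ds$targets[1:10, ] * 1.3)
  rep <- validate_model(X2, T2, mode = "kfold", k = 4, seed = 5,
                        hidden = c(16, 8, 4, 8, 16), epochs = 60)
  expect_equal(sort(unique(rep$assignments)), 1:4)
  expect_equal(length(rep$assignments), 130)
  # every record is held out exactly once
  expect_true(all(table(rep$assignments) >= 30))
  expect_true(rep$training_smape >= 0 && rep$training_smape <= 200)
  expect_true(rep$prediction_smape >= 0 && rep$prediction_smape <= 200)
  expect_true(all(rep$reliability$value >= 0 & rep$reliability$value <= 100))
  expect_true(all(rep$variability$value >= 0))
  td <- tidy(rep)
  expect_equal(nrow(td), 5)
})

test_that("target variability follows the SMAPE-from-group-mean definition", {
  # a group with targets {1, 3}: mean((SMAPE(1,2), SMAPE(3,2))) = 53.33
  X <- tibble::as_tibble(matrix(1, 4, 3, dimnames = list(NULL, c("a", "b", "c"))))
  X$a <- c(1, 1, 2, 3)  # rows 1 and 2 duplicate features
  Y <- tibble::tibble(g = c(1, 3, 5, 5), tau_d = c(2, 2, 2, 2),
                      tau_r = c(60, 60, 60, 60), tau_f = c(5, 5, 5, 5),
                      U = c(0.5, 0.5, 0.5, 0.5))
  rep <- validate_model(X, Y, mode = "kfold", k = 2, seed = 1,
                        hidden = c(4, 4, 4, 4, 4), epochs = 5)
  v_g <- rep$variability$value[rep$variability$parameter == "g"]
  expect_equal(v_g, mean(c(smape(1, 2), smape(3, 2))), tolerance = 1e-9)
  expect_equal(v_g, (200 / 3 + 40) / 2, tolerance = 1e-6)
})

test_that("ensembles summarise member spread and enumerate 32 conditions", {
  grid <- condition_grid()
  expect_equal(nrow(grid), 32)
  expect_equal(nrow(dplyr::distinct(grid[, c("species", "sex", "age",
                                             "temperature", "modality")])), 32)
  ds <- generate_ml_dataset(dataset_spec(n_records = 200, missing_stp = 0,
                                         seed = 61))
  X <- encode_features(ds$records)
  ens <- train_ensemble(X, ds$targets, n_models = 2, seed = 8,
                        hidden = c(16, 8, 4, 8, 16), epochs = 100)
  pre <- strsplit(ds$records$pre[1], "|", fixed = TRUE)[[1]][1]
  post <- strsplit(ds$records$post[1], "|", fixed = TRUE)[[1]][1]
  out <- predict_normalized(ens, pre, post)
  expect_equal(out$parameter, c("g", "tau_d", "tau_r", "tau_f", "U"))
  expect_true(all(out$range >= 0 & out$sd >= 0))
  expect_true(all(out$mean[out$parameter == "tau_r"] > 50))
  # a degenerate ensemble of identical members has zero spread
  ens1 <- ens; ens1$members <- list(ens$members[[1]], ens$members[[1]])
  out1 <- predict_normalized(ens1, pre, post)
  expect_equal(out1$sd, rep(0, 5))
  expect_equal(out1$range, rep(0, 5))
  # distinct connections receive distinct predictions (disambiguation)
  pre2 <- strsplit(ds$records$pre[2], "|", fixed = TRUE)[[1]][1]
  post2 <- strsplit(ds$records$post[2], "|", fixed = TRUE)[[1]][1]
  out2 <- predict_normalized(ens, pre2, post2)
  if (pre2 != pre || post2 != post) {
    expect_false(isTRUE(all.equal(out$mean, out2$mean)))
  }
})

test_that("potency pseudo-records convert g by the failure rate", {
  ds <- generate_ml_dataset(dataset_spec(n_records = 10, missing_stp = 0,
                                         seed = 71))
  rec <- ds$records
  rec$failure_rate <- c(0.2, rep(NA, 9))
  aug <- augment_potency(rec, ds$targets)
  expect_equal(nrow(aug$records), 11)
  expect_true(aug$records$potency[11])          # flag flipped
  expect_equal(aug$targets$g[11], ds$targets$g[1] / 0.8)
  # potency -> amplitude goes the other way
  rec$potency[1] <- TRUE
  aug2 <- augment_potency(rec, ds$targets)
  expect_false(aug2$records$potency[11])
  expect_equal(aug2$targets$g[11], ds$targets$g[1] * 0.8)
  # nothing to convert: pass-through
  none <- augment_potency(ds$records, ds$targets)
  expect_equal(nrow(none$records), 10)
})

test_that("iterative imputation feedback runs and keeps the better model", {
  ds <- generate_ml_dataset(dataset_spec(n_records = 150, missing_stp = 0.2,
                                         seed = 81))
  X <- encode_features(ds$records)
  mod <- train_synapse_model(X, ds$targets, seed = 2, feedback_rounds = 2,
                             hidden = c(16, 8, 4, 8, 16), epochs = 80)
  expect_s3_class(mod, "syn_model")
  expect_true(is.finite(mod$net$loss))
  pred <- predict(mod, X)
  expect_equal(nrow(pred), 150)
})
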