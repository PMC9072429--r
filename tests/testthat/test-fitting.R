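test_that("the weighted soft-L1 objective evaluates correctly", {
  expect_equal(weighted_soft_l1(c(1, 2, 3), c(1, 2, 3)), 0)
  # two equal-weight points with unit residuals
  expect_equal(weighted_soft_l1(c(0, 0), c(1, 1)), 2 * (sqrt(2) - 1))
  # invariant to reordering equal-weight points
  set.seed(3)
  s <- rnorm(10); o <- rnorm(10)
  perm <- sample(10)
  expect_equal(weighted_soft_l1(s, o), weighted_soft_l1(s[perm], o[perm]))
  expect_error(weighted_soft_l1(1:3, 1:2), "lengths")
})

test_that("first-event and anchor weights order the objective", {
  tr <- three_event_depressing()
  w <- synaptr:::.trace_weights(tr)
  # first event x2, interpolated x0.5, multiplicative
  expect_equal(w[tr$points$event == 1 & tr$points$anchor], rep(2, 3))
  expect_equal(w[tr$points$event == 1 & !tr$points$anchor], rep(1, 6))
  expect_equal(w[tr$points$event == 2 & tr$points$anchor], rep(1, 3))
  expect_equal(w[tr$points$event == 2 & !tr$points$anchor], rep(0.5, 6))
  # moving a unit residual from a later anchor to a first-event anchor
  # increases the error
  obs <- tr$points$value
  sim_late <- obs; sim_late[tr$points$event == 3 & tr$points$role == "peak"] <-
    sim_late[tr$points$event == 3 & tr$points$role == "peak"] - 1
  sim_first <- obs; sim_first[tr$points$event == 1 & tr$points$role == "peak"] <-
    sim_first[tr$points$event == 1 & tr$points$role == "peak"] - 1
  expect_gt(weighted_soft_l1(sim_first, obs, w),
            weighted_soft_l1(sim_late, obs, w))
})

test_that("slow-process correction triangulates offsets at initiation points", {
  tr <- three_event_depressing()
  obs <- tr$points$value
  # simulation matching all points: correction is a no-op
  same <- slow_process_correction(tr, obs)
  expect_equal(same$points$value, obs)
  # linear offsets 0 at t=0 and 2 at t=20 interpolate to 1 at t=10
  sim <- obs
  ini <- tr$points$role == "initiation"
  sim[ini] <- obs[ini] - c(0, 2, 4)
  corrected <- slow_process_correction(tr, sim)
  offset <- obs - corrected$points$value
  expect_equal(offset[ini], c(0, 2, 4))
  mid <- which(tr$points$time_ms == 10)  # none: check interpolant directly
  interp <- stats::approx(tr$points$time_ms[ini], c(0, 2, 4), xout = 10)$y
  expect_equal(interp, 1)
  # residuals at initiation points are exactly zero after correction
  expect_equal(corrected$points$value[ini], sim[ini])
})

test_that("noiseless traces are recovered by the fit", {
  p <- default_params()
  cond <- vc_conditions()
  trc <- generate_trace(trace_spec(p, regular_train(10, 20,
                                                    recovery_interval = 2000),
                                   conditions = cond, seed = 7))
  f <- fit_trace(trc, cond, options = fit_options(runs = 4, keep_best = 2,
                                                  seed = 5))
  est <- unlist(unclass(f$params))
  tru <- unlist(unclass(p))
  expect_true(all(abs(est - tru) / tru < 0.02))
  expect_false(f$excluded)
  # averaging bookkeeping: result is the mean over the kept runs
  kept <- f$runs[f$runs$run %in% f$kept, ]
  expect_equal(length(f$kept), 2)
  expect_equal(f$params$tau_d, mean(kept$tau_d))
  expect_equal(f$params$g, mean(kept$g))
})

test_that("scaling trace amplitudes scales g and leaves kinetics fixed", {
  p <- default_params()
  cond <- vc_conditions()
  trc <- generate_trace(trace_spec(p, regular_train(10, 20,
                                                    recovery_interval = 2000),
                                   conditions = cond, seed = 7))
  trc3 <- trc
  trc3$points$value <- 3 * trc3$points$value
  o <- fit_options(runs = 3, keep_best = 1, seed = 5)
  f1 <- fit_trace(trc, cond, options = o)
  f3 <- fit_trace(trc3, cond, options = o)
  expect_equal(f3$params$g / f1$params$g, 3, tolerance = 0.01)
  expect_equal(f3$params$tau_d, f1$params$tau_d, tolerance = 0.01)
  expect_equal(f3$params$U, f1$params$U, tolerance = 0.01)
})

test_that("the current-clamp forward model matches the reference integrator", {
  p <- default_params()
  cond <- recording_conditions(E_rev = 0, modality = "current_clamp")
  mem <- membrane_model(V_ss = -65, C_m = 150, tau_m = 15)
  train <- regular_train(4, 25)
  vsig <- simulate_voltage(simulate_conductance(p, train, dt = 0.02), mem, cond)
  pick <- seq(1, nrow(vsig), by = 100)
  pts <- tibble::tibble(event = findInterval(vsig$time_ms[pick],
                                             train$event_times),
                        time_ms = vsig$time_ms[pick],
                        value = vsig$value[pick],
                        anchor = TRUE, role = "decay")
  pts <- pts[pts$event >= 1, ]
  pts$role[!duplicated(pts$event)] <- "peak"
  trc <- reconstructed_trace(pts, train, stp_class = "depressing",
                             baseline = -65, provenance = "synthetic")
  theta <- matrix(c(p$g / p$U, p$tau_d, p$tau_r, p$tau_f, p$U), 1)
  fwd <- synaptr:::.forward_pop(theta, trc, cond, mem)[, 1]
  expect_equal(fwd, trc$points$value, tolerance = 2e-3)
})

test_that("pooling degenerates to a single-trace fit and re-expands", {
  p <- default_params()
  cond <- vc_conditions()
  trc <- generate_trace(trace_spec(p, regular_train(10, 20,
                                                    recovery_interval = 2000),
                                   conditions = cond, seed = 7))
  o <- fit_options(runs = 2, keep_best = 1, seed = 3)
  single <- fit_trace(trc, cond, options = o)
  pooled <- fit_pooled(list(trc), cond, options = o)
  expect_length(pooled, 1)
  expect_equal(pooled[[1]]$params, single$params)
  # two frequencies: one result per trace, sharing parameters
  trc2 <- generate_trace(trace_spec(p, regular_train(10, 50,
                                                     recovery_interval = 2000),
                                    conditions = cond, seed = 8))
  both <- fit_pooled(list(trc, trc2), cond,
                     options = fit_options(runs = 2, keep_best = 1, seed = 3))
  expect_length(both, 2)
  expect_equal(both[[1]]$params, both[[2]]$params)
  est <- unlist(unclass(both[[1]]$params))
  expect_true(all(abs(est - unlist(unclass(p))) / unlist(unclass(p)) < 0.02))
})

test_that("quality control excludes long decays and imputes amplitude-only rows", {
  tbl <- tibble::tibble(
    tau_d = c(800, 5, 7, 20, NA, 12),
    response = c("GABAergic", "GABAergic", "GABAergic", "GABAergic",
                 "GABAergic", "glutamatergic"),
    unitary = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE),
    amplitude_only = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE))
  out <- qc_and_impute(tbl)
  expect_true(out$excluded[1])
  expect_equal(out$tau_d[5], 7)  # median of {5, 7, 20}
  expect_true(out$tau_d_imputed[5])
  # complete tables pass through unchanged
  ok <- tbl[2:4, ]
  expect_equal(qc_and_impute(ok)$tau_d, ok$tau_d)
  # missing donors is an error
  bad <- tibble::tibble(tau_d = NA_real_, response = "glutamatergic",
                        unitary = FALSE, amplitude_only = TRUE)
  expect_error(qc_and_impute(bad), "no unitary")
})

test_that("fit metadata is exposed through tidy and glance", {
  p <- default_params()
  cond <- vc_conditions()
  trc <- generate_trace(trace_spec(p, regular_train(10, 20,
                                                    recovery_interval = 2000),
                                   conditions = cond, seed = 7))
  f <- fit_trace(trc, cond, options = fit_options(runs = 2, keep_best = 2,
                                                  seed = 5))
  td <- tidy(f)
  expect_equal(td$parameter, c("g", "tau_d", "tau_r", "tau_f", "U"))
  expect_true(all(is.finite(td$estimate)))
  gl <- glance(f)
  expect_equal(gl$runs, 2)
  expect_false(gl$excluded)
})
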