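test_that("nine-point events from measurements have consistent anchors", {
  ev <- nine_point_events(amplitude = 10, rise_20_80 = 1.2, half_decay = 4)
  expect_equal(nrow(ev), 9)
  expect_equal(sum(ev$anchor), 3)
  expect_equal(ev$value[ev$role == "peak"], 10)
  expect_equal(ev$time_ms[ev$role == "peak"], 1.2 / 0.6)  # linear-rise span
  expect_equal(ev$time_ms[ev$role == "decay_anchor"], 1.2 / 0.6 + 4)
  expect_equal(ev$value[ev$role == "decay_anchor"], 5)
  expect_true(all(diff(ev$time_ms) > 0))
  # interpolated points lie between initiation and decay anchor
  interp <- ev[!ev$anchor, ]
  expect_true(all(interp$time_ms > min(ev$time_ms) &
                    interp$time_ms < max(ev$time_ms)))
  expect_error(nine_point_events(amplitude = 10, rise_20_80 = 1.2,
                                 half_decay = -1), "positive")
  expect_error(nine_point_events(amplitude = 10, half_decay = 4), "rise")
})

test_that("curve-sourced interpolation is exact on collinear data", {
  curve <- tibble::tibble(time_ms = seq(0, 10, by = 0.5),
                          value = 2 + 3 * seq(0, 10, by = 0.5))
  ev <- nine_point_events(curve = curve)
  expect_equal(nrow(ev), 9)
  expect_true(all(abs(ev$value - (2 + 3 * ev$time_ms)) < 1e-9))
})

test_that("ST-P classification follows the terminal PPR with a dead band", {
  expect_equal(classify_stp(c(1.4, 1.6, 1.7)), "facilitating")
  expect_equal(classify_stp(c(0.8, 0.6, 0.55)), "depressing")
  expect_equal(classify_stp(c(0.8, 1.0)), "pseudolinear")
  expect_equal(classify_stp(1.04), "pseudolinear")
  expect_error(classify_stp(numeric(0)), "PPR")
})

test_that("depressing traces gain the 63% recovery point", {
  tr <- three_event_depressing()
  expect_equal(tr$stp_class, "depressing")
  ext <- extend_event_train(tr, n_events = 3)
  expect_false(is.null(ext$train$recovery_index))
  rec <- ext$points[ext$points$role == "recovery", ]
  expect_equal(nrow(rec), 1)
  expect_equal(rec$time_ms, 40 + 2000)
  expect_equal(rec$value, 4 + 0.63 * (10 - 4))  # 7.78
})

test_that("facilitating traces are returned unchanged once standardized", {
  pts <- dplyr::bind_rows(lapply(1:10, function(i) {
    amp <- 10 * (1 + 0.05 * (i - 1))
    tibble::tibble(event = i, time_ms = (i - 1) * 20 + c(0, 1, 3),
                   value = c(0, amp, amp / 2),
                   anchor = TRUE,
                   role = c("initiation", "peak", "decay_anchor"))
  }))
  tr <- reconstructed_trace(pts, regular_train(10, 20), provenance = "synthetic")
  expect_equal(tr$stp_class, "facilitating")
  ext <- extend_event_train(tr, n_events = 10)
  expect_equal(ext$points, tr$points)
  expect_true(is.null(ext$train$recovery_index))
})

test_that("exponential PPR extrapolation recovers its generator", {
  a <- 0.8; b <- 3; cc <- 0.25
  gen <- function(i) a * exp(-i / b) + cc
  pts <- dplyr::bind_rows(lapply(1:5, function(i) {
    amp <- 10 * gen(i) / gen(1)
    tibble::tibble(event = i, time_ms = (i - 1) * 20 + c(0, 1, 3),
                   value = c(0, amp, amp / 2), anchor = TRUE,
                   role = c("initiation", "peak", "decay_anchor"))
  }))
  tr <- reconstructed_trace(pts, regular_train(5, 20), provenance = "synthetic")
  expect_equal(tr$stp_class, "depressing")
  ext <- extend_event_train(tr, n_events = 10)
  pk <- ext$points[ext$points$role == "peak", ]
  got <- pk$value / pk$value[1]
  expect_equal(got[6:10], gen(6:10) / gen(1), tolerance = 1e-6)
  # standardized: >= 10 events plus a recovery point, anchors untouched
  expect_gte(length(unique(ext$points$event)), 10)
  orig <- tr$points[tr$points$anchor, ]
  kept <- dplyr::semi_join(ext$points, orig, by = c("event", "time_ms"))
  expect_equal(kept$value, orig$value)
})

test_that("an unfittable PPR series falls back to last-value carry", {
  expect_warning(
    out <- synaptr:::.extrapolate_ppr_depressing(1:2, c(1, 0.6), 3:10),
    "carrying")
  expect_equal(out, rep(0.6, 8))
})

test_that("measurement round trip preserves amplitude and widths", {
  ev <- nine_point_events(amplitude = 12, rise_10_90 = 2, half_decay = 5)
  tr <- reconstructed_trace(ev, stimulus_train(0), stp_class = "pseudolinear",
                            provenance = "synaptometrics")
  sm <- synaptometrics(tr)
  expect_equal(sm$events$A_i[1], 12)
  hd <- sm$kinetics$value_ms[sm$kinetics$metric == "half_decay"]
  expect_equal(hd, 5, tolerance = 0.05)
  r1090 <- sm$kinetics$value_ms[sm$kinetics$metric == "rise_10_90"]
  expect_equal(r1090, 2, tolerance = 0.05)
})

test_that("PPR grids are filled by separable cubic interpolation", {
  idx <- 1:6
  isi <- c(20, 50)
  f <- function(i, s) 1 - 0.08 * i + 0.001 * s
  m <- outer(idx, isi, f)
  m[3, 1] <- NA; m[5, 2] <- NA
  filled <- interpolate_ppr_grid(m, isi)
  expect_equal(filled[3, 1], f(3, 20), tolerance = 1e-9)
  expect_equal(filled[5, 2], f(5, 50), tolerance = 1e-9)
})
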