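#' Reconstructed synaptic trace
#'
#' A standardized representation of one synaptic recording: an ordered set
#' of nine-point events (three anchors - initiation, peak, decay - plus six
#' interpolated points each), the underlying stimulus train, the
#' short-term-plasticity class, the baseline, and the provenance of the
#' points (digitized curve vs reported synaptometrics).
#'
#' @param points Tibble with columns `event`, `time_ms`, `value`, `anchor`
#'   (logical), `role` (`"initiation"`, `"rise"`, `"peak"`, `"decay"`,
#'   `"decay_anchor"`, `"recovery"`).
#' @param train A [stimulus_train()].
#' @param stp_class `"facilitating"`, `"depressing"` or `"pseudolinear"`;
#'   classified from the paired-pulse ratios when `NULL`.
#' @param baseline Pre-initiation baseline value of the first event.
#' @param provenance `"digitized"`, `"synaptometrics"` or `"synthetic"`.
#' @return An object of class `recon_trace`.
#' @export
reconstructed_trace <- function(points, train, stp_class = NULL, baseline = 0,
                                provenance = "digitized") {
  stopifnot(is.data.frame(points), inherits(train, "stimulus_train"))
  need <- c("event", "time_ms", "value", "anchor", "role")
  if (!all(need %in% names(points))) {
    stop("points must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  out <- structure(list(points = tibble::as_tibble(points), train = train,
                        stp_class = stp_class, baseline = baseline,
                        provenance = provenance),
                   class = "recon_trace")
  if (is.null(stp_class)) {
    pprs <- .trace_pprs(out)
    out$stp_class <- if (length(pprs) >= 2) classify_stp(pprs[-1]) else "pseudolinear"
  }
  out
}

#' @export
print.recon_trace <- function(x, ...) {
  cat("<recon_trace>", length(unique(x$points$event)), "events,",
      x$stp_class, "|", x$provenance,
      if (!is.null(x$train$recovery_index)) "| recovery event" else "", "\n")
  invisible(x)
}

# PPR_i:1 per event (amplitude from each event's initiation point), regular
# events only (the recovery event, when flagged, is excluded).
.trace_pprs <- function(trace) {
  pts <- trace$points
  ev <- sort(unique(pts$event))
  rec <- trace$train$recovery_index
  if (!is.null(rec)) ev <- ev[ev != rec]
  amp <- vapply(ev, function(e) {
    p <- pts[pts$event == e, ]
    pk <- p$value[p$role %in% c("peak", "recovery")][1]
    init <- p$value[p$role == "initiation"]
    init <- if (length(init)) init[1] else trace$baseline
    abs(pk - init)
  }, numeric(1))
  amp / amp[1]
}

#' Build a standardized nine-point synaptic event
#'
#' Places the three anchor points (initiation, peak, decay) and six
#' interpolated points (three evenly spaced in time on the rise, three on
#' the decay). The source is either a digitized curve - in which case the
#' interpolated values are read off an Akima interpolant of the samples -
#' or reported synaptometric measurements (amplitude, a 10-90% or 20-80%
#' rise time, and the half-decay time), in which case the rise is taken as
#' linear and the decay as a single exponential whose time constant is
#' `half_decay / log(2)`.
#'
#' @param curve Optional tibble `time_ms`, `value`: the digitized samples of
#'   one event (from initiation onward).
#' @param amplitude Peak amplitude relative to baseline (pA or mV).
#' @param rise_10_90,rise_20_80 Rise times (ms); one is required for the
#'   measurement source.
#' @param half_decay Time from peak to 50% decay (ms).
#' @param onset Initiation time (ms).
#' @param baseline Baseline value.
#' @param event Event index to stamp on the points.
#' @return Tibble of exactly 9 points with columns `event`, `time_ms`,
#'   `value`, `anchor`, `role`; 3 rows are anchors.
#' @examples
#' nine_point_events(amplitude = 10, rise_20_80 = 1.2, half_decay = 4)
#' @export
nine_point_events <- function(curve = NULL, amplitude = NULL,
                              rise_10_90 = NULL, rise_20_80 = NULL,
                              half_decay = NULL, onset = 0, baseline = 0,
                              event = 1L) {
  if (!is.null(curve)) {
    return(.nine_from_curve(curve, baseline, event))
  }
  if (is.null(amplitude) || (is.null(rise_10_90) && is.null(rise_20_80)) ||
      is.null(half_decay)) {
    stop("measurement source needs amplitude, a rise time, and half_decay",
         call. = FALSE)
  }
  if (half_decay <= 0) stop("half_decay must be positive", call. = FALSE)
  rise_total <- if (!is.null(rise_10_90)) rise_10_90 / 0.8 else rise_20_80 / 0.6
  if (rise_total <= 0) stop("rise time must be positive", call. = FALSE)
  tau_d <- half_decay / log(2)
  t_pk <- onset + rise_total
  t_dec <- t_pk + half_decay
  t_rise <- onset + rise_total * (1:3) / 4
  t_fall <- t_pk + half_decay * (1:3) / 4
  tibble::tibble(
    event = event,
    time_ms = c(onset, t_rise, t_pk, t_fall, t_dec),
    value = c(baseline,
              baseline + amplitude * (1:3) / 4,
              baseline + amplitude,
              baseline + amplitude * exp(-(t_fall - t_pk) / tau_d),
              baseline + amplitude / 2),
    anchor = c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, TRUE),
    role = c("initiation", rep("rise", 3), "peak", rep("decay", 3),
             "decay_anchor")
  )
}

.nine_from_curve <- function(curve, baseline, event) {
  stopifnot(all(c("time_ms", "value") %in% names(curve)))
  t <- curve$time_ms; v <- curve$value
  if (any(diff(t) <= 0)) stop("curve times must be strictly increasing", call. = FALSE)
  sgn <- if ((v[which.max(abs(v - baseline))] - baseline) < 0) -1 else 1
  rel <- sgn * (v - baseline)
  i_pk <- which.max(rel)
  t0 <- t[1]; t_pk <- t[i_pk]; amp <- rel[i_pk]
  t_dec <- .cross_time(t, rel, amp / 2, from = t_pk, direction = "down")
  if (is.na(t_dec)) t_dec <- t[length(t)]
  interp <- function(xi) {
    y <- if (length(t) >= 5) {
      suppressWarnings(pracma::akimaInterp(t, v, xi))
    } else rep(NA_real_, length(xi))
    # the Akima scheme is undefined near the boundary nodes; fall back to
    # linear interpolation there
    na <- !is.finite(y)
    if (any(na)) y[na] <- stats::approx(t, v, xout = xi[na], rule = 2)$y
    y
  }
  t_rise <- t0 + (t_pk - t0) * (1:3) / 4
  t_fall <- t_pk + (t_dec - t_pk) * (1:3) / 4
  tibble::tibble(
    event = event,
    time_ms = c(t0, t_rise, t_pk, t_fall, t_dec),
    value = c(v[1], interp(t_rise), v[i_pk], interp(t_fall), interp(t_dec)),
    anchor = c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, TRUE),
    role = c("initiation", rep("rise", 3), "peak", rep("decay", 3),
             "decay_anchor")
  )
}

#' Classify short-term plasticity from paired-pulse ratios
#'
#' A trace is depressing when the terminal PPR falls below `1 - epsilon`,
#' facilitating when it exceeds `1 + epsilon`, and pseudolinear otherwise.
#'
#' @param pprs Numeric vector of paired-pulse ratios (later events : first).
#' @param epsilon Dead band around 1; default 0.05.
#' @return `"facilitating"`, `"depressing"`, or `"pseudolinear"`.
#' @examples
#' classify_stp(c(1.4, 1.6, 1.7))
#' @export
classify_stp <- function(pprs, epsilon = 0.05) {
  if (length(pprs) == 0) stop("at least one PPR required", call. = FALSE)
  terminal <- pprs[length(pprs)]
  if (terminal < 1 - epsilon) "depressing"
  else if (terminal > 1 + epsilon) "facilitating"
  else "pseudolinear"
}

# Bounded exponential-decay-to-a-floor extrapolation of depressing PPRs:
# ppr_i = a exp(-i / b) + c with a > 0, b > 0, c >= 0. Falls back to
# carrying the last value with a warning when the fit fails.
.extrapolate_ppr_depressing <- function(idx, ppr, new_idx) {
  if (length(idx) < 3) {
    warning("too few PPRs for the exponential fit; carrying the last PPR forward",
            call. = FALSE)
    return(rep(ppr[length(ppr)], length(new_idx)))
  }
  c0 <- max(min(ppr) * 0.9, 0)
  a0 <- max(ppr[1] - c0, 1e-3)
  st <- list(a = a0, b = max(diff(range(idx)), 1), c = c0)
  fit <- tryCatch(
    minpack.lm::nlsLM(ppr ~ a * exp(-idx / b) + c,
                      data = data.frame(idx = idx, ppr = ppr),
                      start = st,
                      lower = c(a = 1e-9, b = 1e-9, c = 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    warning("exponential PPR fit failed; carrying the last PPR forward",
            call. = FALSE)
    return(rep(ppr[length(ppr)], length(new_idx)))
  }
  stats::predict(fit, newdata = data.frame(idx = new_idx))
}

# Cubic extrapolation over event index for facilitating/pseudolinear PPRs.
.extrapolate_ppr_cubic <- function(idx, ppr, new_idx) {
  if (length(idx) < 2) return(rep(ppr[length(ppr)], length(new_idx)))
  stats::spline(idx, ppr, xout = new_idx, method = "fmm")$y
}

#' Interpolate a PPR surface over event index and inter-stimulus interval
#'
#' When the same connection was probed at several stimulation frequencies
#' the paired-pulse ratios form a grid over event index and ISI; missing
#' entries are filled by separable cubic interpolation (cubic over event
#' index within each ISI, then cubic over ISI). With a single ISI this
#' degrades to one-dimensional cubic interpolation over the event index.
#'
#' @param ppr_matrix Numeric matrix, rows = event index, columns = ISI;
#'   `NA` marks missing entries.
#' @param isi Numeric vector of ISIs (ms), one per column.
#' @return The matrix with `NA` entries filled.
#' @export
interpolate_ppr_grid <- function(ppr_matrix, isi) {
  stopifnot(is.matrix(ppr_matrix), length(isi) == ncol(ppr_matrix))
  idx <- seq_len(nrow(ppr_matrix))
  filled <- apply(ppr_matrix, 2, function(col) {
    ok <- !is.na(col)
    if (all(ok) || sum(ok) < 2) return(col)
    out <- col
    out[!ok] <- stats::spline(idx[ok], col[ok], xout = idx[!ok], method = "fmm")$y
    out
  })
  if (length(isi) >= 2) {
    filled <- t(apply(filled, 1, function(row) {
      ok <- !is.na(row)
      if (all(ok) || sum(ok) < 2) return(row)
      out <- row
      out[!ok] <- stats::spline(isi[ok], row[ok], xout = isi[!ok], method = "fmm")$y
      out
    }))
  }
  filled
}

#' Extend a reconstructed trace to the standard event count
#'
#' Ensures the trace carries at least `n_events` successive synaptic events
#' plus - for depressing and pseudolinear traces - a recovery event.
#' Missing paired-pulse ratios are extrapolated by cubic interpolation over
#' event index (facilitating/pseudolinear) or by a bounded fit of
#' exponential decay to a floor, `a exp(-i/b) + c` (depressing). Appended
#' events reuse the first event's nine-point shape scaled by the predicted
#' PPR. The recovery event is attached as a single data point
#' `recovery_interval` ms (default 2000) after the last event, with
#' amplitude from baseline equal to
#' `AB_last + recovery_fraction (A_1 - AB_last)`; facilitating traces get
#' no recovery event.
#'
#' @param trace A `recon_trace`.
#' @param n_events Minimum number of successive events (default 10).
#' @param recovery_interval Pause before the recovery point (ms).
#' @param recovery_fraction Recovered fraction of the first-to-last
#'   amplitude difference; default 0.63.
#' @return The extended `recon_trace`.
#' @export
extend_event_train <- function(trace, n_events = 10, recovery_interval = 2000,
                               recovery_fraction = 0.63) {
  stopifnot(inherits(trace, "recon_trace"))
  pts <- trace$points
  rec_idx <- trace$train$recovery_index
  has_recovery <- !is.null(rec_idx)
  reg_events <- sort(unique(pts$event))
  if (has_recovery) reg_events <- reg_events[reg_events != rec_idx]
  n_have <- length(reg_events)
  pprs <- .trace_pprs(trace)
  cls <- trace$stp_class
  isi <- trace$train$isi
  if (is.null(isi)) {
    reg_times <- trace$train$event_times[reg_events]
    isi <- if (n_have >= 2) stats::median(diff(reg_times)) else 50
  }
  template <- pts[pts$event == reg_events[1], ]
  amp1 <- abs(template$value[template$role == "peak"][1] - trace$baseline)
  new_pts <- pts
  times <- trace$train$event_times
  if (n_have < n_events) {
    idx_new <- (n_have + 1):n_events
    ppr_new <- if (cls == "depressing") {
      .extrapolate_ppr_depressing(seq_len(n_have), pprs, idx_new)
    } else {
      .extrapolate_ppr_cubic(seq_len(n_have), pprs, idx_new)
    }
    last_t <- times[if (has_recovery) rec_idx - 1L else length(times)]
    sgn <- sign(template$value[template$role == "peak"][1] - trace$baseline)
    add <- purrr::map2_dfr(idx_new, seq_along(idx_new), function(k, j) {
      t0 <- last_t + isi * j
      tibble::tibble(
        event = k,
        time_ms = t0 + (template$time_ms - template$time_ms[1]),
        value = trace$baseline +
          (template$value - trace$baseline) * ppr_new[j],
        anchor = template$anchor,
        role = template$role
      )
    })
    new_times <- last_t + isi * seq_along(idx_new)
    # renumber/insert before any recovery event
    if (has_recovery) {
      rec_pts <- new_pts[new_pts$event == rec_idx, ]
      rec_time <- times[rec_idx]
      new_pts <- new_pts[new_pts$event != rec_idx, ]
      rec_pts$event <- n_events + 1L
      new_pts <- dplyr::bind_rows(new_pts, add, rec_pts)
      times <- c(times[seq_len(rec_idx - 1L)], new_times, rec_time)
      rec_idx <- length(times)
    } else {
      new_pts <- dplyr::bind_rows(new_pts, add)
      times <- c(times, new_times)
    }
  }
  # recovery point for depressing / pseudolinear traces lacking one
  if (!has_recovery && cls %in% c("depressing", "pseudolinear")) {
    sm <- .trace_amps(new_pts, times, trace$baseline)
    a1 <- sm$A_i[1]
    ab_last <- sm$AB_i[length(sm$AB_i)]
    rec_amp <- ab_last + recovery_fraction * (a1 - ab_last)
    sgn <- sign(new_pts$value[new_pts$role == "peak"][1] - trace$baseline)
    rec_time <- times[length(times)] + recovery_interval
    new_pts <- dplyr::bind_rows(new_pts, tibble::tibble(
      event = max(new_pts$event) + 1L, time_ms = rec_time,
      value = trace$baseline + sgn * rec_amp, anchor = TRUE, role = "recovery"))
    times <- c(times, rec_time)
    rec_idx <- length(times)
  }
  out <- trace
  out$points <- dplyr::arrange(new_pts, .data$event, .data$time_ms)
  out$train <- stimulus_train(times, recovery_index = rec_idx, isi = trace$train$isi)
  out
}

.trace_amps <- function(pts, times, baseline) {
  ev <- sort(unique(pts$event))
  A_i <- AB_i <- numeric(length(ev))
  for (j in seq_along(ev)) {
    p <- pts[pts$event == ev[j], ]
    pk <- p$value[p$role %in% c("peak", "recovery")][1]
    init <- p$value[p$role == "initiation"]
    init <- if (length(init)) init[1] else baseline
    A_i[j] <- abs(pk - init)
    AB_i[j] <- abs(pk - baseline)
  }
  list(A_i = A_i, AB_i = AB_i)
}
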