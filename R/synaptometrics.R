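# Linear interpolation of the time at which a sampled curve crosses `level`,
# searching `direction = "up"` (first upward crossing) or "down" (first
# downward crossing at or after `from`).
.cross_time <- function(t, v, level, from = -Inf, direction = "up") {
  keep <- t >= from
  t <- t[keep]; v <- v[keep]
  if (direction == "up") {
    hit <- which(v[-1] >= level & v[-length(v)] < level)
  } else {
    hit <- which(v[-1] <= level & v[-length(v)] > level)
  }
  if (length(hit) == 0) return(NA_real_)
  i <- hit[1]
  if (v[i + 1] == v[i]) return(t[i])
  t[i] + (level - v[i]) / (v[i + 1] - v[i]) * (t[i + 1] - t[i])
}

#' Synaptometric readouts of a simulated or reconstructed signal
#'
#' Computes the field's standard per-event and kinetic measures: event
#' amplitudes from the initiation point (`A_i`) and from baseline
#' (`AB_i`), the paired-pulse ratios `PPR_{i:1} = A_i / A_1` (equivalently
#' the ratio of the `u+ R-` products) and `AB_i : A_1`, and - on the
#' continuous trace of the first event - the half-height width (50% rise
#' to 50% decay), 10-90% and 20-80% rise times, and the half-decay time.
#' Rise times are reported as `NA` for simulated conductance/current
#' traces, whose rise is instantaneous by construction; they are defined
#' for voltage traces and reconstructed data.
#'
#' @param signal A `syn_signal` with event annotations, or a
#'   `recon_trace`.
#' @return A list of class `synaptometrics` with elements `events` (tibble:
#'   `event`, `time_ms`, `A_i`, `AB_i`, `ppr_i1`, `ab_i_a1`) and
#'   `kinetics` (tibble: `metric`, `value_ms`).
#' @export
synaptometrics <- function(signal) {
  if (inherits(signal, "recon_trace")) {
    return(.synaptometrics_recon(signal))
  }
  stopifnot(inherits(signal, "syn_signal"))
  events <- attr(signal, "events")
  if (is.null(events) || nrow(events) == 0) {
    stop("signal carries no event annotations", call. = FALSE)
  }
  modality <- attr(signal, "modality")
  baseline <- attr(signal, "baseline") %||% 0
  t <- signal$time_ms; v <- signal$value
  sgn <- if (mean(v - baseline) < 0) -1 else 1
  vv <- sgn * (v - baseline)
  if (modality == "voltage" || !all(c("amp_init", "amp_base") %in% names(events))) {
    # measure amplitudes off the trace itself
    ev <- events$time_ms
    bounds <- c(ev, max(t) + 1e-9)
    A_i <- AB_i <- numeric(length(ev))
    for (i in seq_along(ev)) {
      seg <- t >= ev[i] & t < bounds[i + 1]
      pk <- max(vv[seg])
      init <- vv[which.max(t >= ev[i]) - 1]
      if (length(init) == 0 || is.na(init)) init <- 0
      A_i[i] <- pk - init
      AB_i[i] <- pk
    }
    rise_defined <- TRUE
  } else {
    A_i <- abs(events$amp_init)
    AB_i <- abs(events$amp_base)
    rise_defined <- FALSE
  }
  ev_tbl <- tibble::tibble(
    event = events$event, time_ms = events$time_ms,
    A_i = A_i, AB_i = AB_i,
    ppr_i1 = A_i / A_i[1],
    ab_i_a1 = AB_i / A_i[1]
  )
  # kinetics on the first event's transient
  t1 <- events$time_ms[1]
  t_stop <- if (nrow(events) > 1) events$time_ms[2] else max(t)
  win <- t >= t1 - 1e-9 & t <= t_stop
  tw <- t[win]; vw <- vv[win]
  pk <- max(vw); tpk <- tw[which.max(vw)]
  rise <- tw <= tpk + 1e-12  # upward crossings belong to the rise phase
  half_up <- .cross_time(tw[rise], vw[rise], 0.5 * pk, direction = "up")
  if (is.na(half_up)) half_up <- t1
  half_dn <- .cross_time(tw, vw, 0.5 * pk, from = tpk, direction = "down")
  rise_10_90 <- rise_20_80 <- NA_real_
  if (rise_defined) {
    r10 <- .cross_time(tw[rise], vw[rise], 0.1 * pk, direction = "up")
    r90 <- .cross_time(tw[rise], vw[rise], 0.9 * pk, direction = "up")
    r20 <- .cross_time(tw[rise], vw[rise], 0.2 * pk, direction = "up")
    r80 <- .cross_time(tw[rise], vw[rise], 0.8 * pk, direction = "up")
    rise_10_90 <- r90 - r10
    rise_20_80 <- r80 - r20
  }
  kin <- tibble::tibble(
    metric = c("half_height_width", "rise_10_90", "rise_20_80", "half_decay"),
    value_ms = c(half_dn - half_up, rise_10_90, rise_20_80,
                 if (is.na(half_dn)) NA_real_ else half_dn - tpk)
  )
  structure(list(events = ev_tbl, kinetics = kin), class = "synaptometrics")
}

.synaptometrics_recon <- function(trace) {
  pts <- trace$points
  base <- trace$baseline
  ev_ids <- sort(unique(pts$event))
  rows <- lapply(ev_ids, function(e) {
    p <- pts[pts$event == e, ]
    init <- p$value[p$role == "initiation"][1]
    pk <- p$value[p$role == "peak"][1]
    sgn <- if (pk - base < 0) -1 else 1
    tibble::tibble(event = e,
                   time_ms = p$time_ms[p$role == "initiation"][1],
                   A_i = sgn * (pk - init),
                   AB_i = sgn * (pk - base))
  })
  ev_tbl <- dplyr::bind_rows(rows)
  ev_tbl$ppr_i1 <- ev_tbl$A_i / ev_tbl$A_i[1]
  ev_tbl$ab_i_a1 <- ev_tbl$AB_i / ev_tbl$A_i[1]
  p1 <- pts[pts$event == ev_ids[1], ]
  sgn <- if (p1$value[p1$role == "peak"][1] - base < 0) -1 else 1
  tw <- p1$time_ms; vw <- sgn * (p1$value - base)
  pk <- max(vw); tpk <- tw[which.max(vw)]
  rise <- tw <= tpk + 1e-12
  half_up <- .cross_time(tw[rise], vw[rise], 0.5 * pk, direction = "up")
  if (is.na(half_up)) half_up <- tw[1]
  half_dn <- .cross_time(tw, vw, 0.5 * pk, from = tpk, direction = "down")
  r10 <- .cross_time(tw[rise], vw[rise], 0.1 * pk)
  r90 <- .cross_time(tw[rise], vw[rise], 0.9 * pk)
  r20 <- .cross_time(tw[rise], vw[rise], 0.2 * pk)
  r80 <- .cross_time(tw[rise], vw[rise], 0.8 * pk)
  kin <- tibble::tibble(
    metric = c("half_height_width", "rise_10_90", "rise_20_80", "half_decay"),
    value_ms = c(half_dn - half_up, r90 - r10, r80 - r20, half_dn - tpk)
  )
  structure(list(events = ev_tbl, kinetics = kin), class = "synaptometrics")
}

#' @export
print.synaptometrics <- function(x, ...) {
  cat("<synaptometrics>", nrow(x$events), "events\n")
  print(x$events)
  print(x$kinetics)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
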