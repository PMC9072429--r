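#' @importFrom rlang .data
NULL

# Pre-event decayed states after a pause of `dt` ms, given post-event values
# u, A, R. Vectorised over parameter vectors (all arguments may be vectors of
# equal length). The auxiliary Abar = A * tau_d / (tau_d - tau_r) has a
# removable singularity at tau_d == tau_r; within 1e-6 relative the analytic
# limit (dt/tau * exp(-dt/tau) term) is used instead.
.tpm_decay <- function(u, A, R, dt, tau_d, tau_r, tau_f) {
  ed <- exp(-dt / tau_d)
  er <- exp(-dt / tau_r)
  ef <- exp(-dt / tau_f)
  u_pre <- u * ef
  A_pre <- A * ed
  degen <- abs(tau_d - tau_r) < 1e-6 * tau_d
  if (any(degen)) {
    Abar <- ifelse(degen, 0, A * tau_d / (tau_d - tau_r))
    R_pre <- 1 - Abar * ed - (1 - R - Abar) * er
    R_lim <- 1 - (1 - R) * er - A * (dt / tau_r) * er
    R_pre <- ifelse(degen, R_lim, R_pre)
  } else {
    Abar <- A * tau_d / (tau_d - tau_r)
    R_pre <- 1 - Abar * ed - (1 - R - Abar) * er
  }
  list(u = u_pre, A = A_pre, R = R_pre)
}

# Event-driven evolution for a matrix of parameter sets (rows) over shared
# event times. Returns n_events x n_sets matrices of pre/post states.
.tpm_evolve_matrix <- function(tau_d, tau_r, tau_f, U, times) {
  n_ev <- length(times)
  n_set <- length(tau_d)
  z <- matrix(0, n_ev, n_set)
  out <- list(u_pre = z, u_post = z, A_pre = z, A_post = z,
              R_pre = z, R_post = z)
  u <- rep(0, n_set); A <- rep(0, n_set); R <- rep(1, n_set)
  t_prev <- times[1]
  for (i in seq_len(n_ev)) {
    dt <- times[i] - t_prev
    if (dt > 0) {
      s <- .tpm_decay(u, A, R, dt, tau_d, tau_r, tau_f)
      u <- s$u; A <- s$A; R <- s$R
    }
    out$u_pre[i, ] <- u; out$A_pre[i, ] <- A; out$R_pre[i, ] <- R
    # update order matters: u first, then A and R use u_plus
    u <- u + U * (1 - u)
    rel <- u * R
    A <- A + rel
    R <- R - rel
    out$u_post[i, ] <- u; out$A_post[i, ] <- A; out$R_post[i, ] <- R
    t_prev <- times[i]
  }
  out
}

#' Event-driven analytic evolution of the TPM states
#'
#' Advances the three-state model exactly from event to event: between
#' events the states decay in closed form; at each event the utilization is
#' incremented first (`u+ = u- + U (1 - u-)`) and the activated/recovered
#' fractions are then updated with `u+ R-`. The initial condition is rest
#' (`u = 0`, `A = 0`, `R = 1`).
#'
#' @param params A [synapse_params()] object.
#' @param train A [stimulus_train()] object.
#' @return A tibble with one row per event: `event`, `time_ms`, and the
#'   pre-/post-event values of `u`, `A`, `R`, `D`.
#' @examples
#' p <- synapse_params(1, 8, 400, 60, 0.3)
#' evolve_states(p, regular_train(5, isi = 20))
#' @export
evolve_states <- function(params, train) {
  stopifnot(inherits(params, "synapse_params"), inherits(train, "stimulus_train"))
  times <- train$event_times
  st <- .tpm_evolve_matrix(params$tau_d, params$tau_r, params$tau_f, params$U,
                           times)
  tibble::tibble(
    event = seq_along(times),
    time_ms = times,
    u_pre = st$u_pre[, 1], u_post = st$u_post[, 1],
    A_pre = st$A_pre[, 1], A_post = st$A_post[, 1],
    R_pre = st$R_pre[, 1], R_post = st$R_post[, 1],
    D_pre = 1 - st$A_pre[, 1] - st$R_pre[, 1],
    D_post = 1 - st$A_post[, 1] - st$R_post[, 1]
  )
}

# Conductance g(t) = g_opt * A(t) evaluated at arbitrary times, given the
# per-event post-activation values. `pre_event = TRUE` takes the left limit
# (value just before any event at exactly that time).
.tpm_g_at <- function(times, event_times, A_post, g_opt, tau_d,
                      pre_event = FALSE) {
  idx <- findInterval(times, event_times,
                      left.open = pre_event)
  val <- numeric(length(times))
  has <- idx > 0
  if (any(has)) {
    i <- idx[has]
    val[has] <- g_opt * A_post[i] * exp(-(times[has] - event_times[i]) / tau_d)
  }
  val
}

.new_signal <- function(time_ms, value, modality, units, events = NULL,
                        baseline = 0) {
  out <- tibble::tibble(time_ms = time_ms, value = value)
  class(out) <- c("syn_signal", class(out))
  attr(out, "modality") <- modality
  attr(out, "units") <- units
  attr(out, "events") <- events
  attr(out, "baseline") <- baseline
  out
}

#' @export
print.syn_signal <- function(x, ...) {
  cat("<syn_signal>", attr(x, "modality"), "(", attr(x, "units"), "),",
      nrow(x), "samples,",
      if (!is.null(attr(x, "events"))) nrow(attr(x, "events")) else 0,
      "events\n")
  NextMethod()
}

#' Simulate the synaptic conductance waveform
#'
#' Evaluates `g(t) = g_opt A(t)` on a time grid, with `g_opt = g / U` so
#' that the first-event peak conductance equals the reported `g`. The rise
#' is instantaneous (the ligand-gated channel is assumed to open
#' instantly); between events the conductance decays mono-exponentially
#' with `tau_d`.
#'
#' @param params A [synapse_params()].
#' @param train A [stimulus_train()].
#' @param dt Grid step (ms); default 0.05.
#' @param t_end End of the grid (ms); defaults to the last event plus
#'   `5 * tau_d`.
#' @return A `syn_signal` tibble (`time_ms`, `value` in nS) whose
#'   `"events"` attribute tabulates per-event peak amplitudes `A_i`
#'   (from the event's own initiation level) and `AB_i` (from baseline).
#' @examples
#' sig <- simulate_conductance(synapse_params(1, 8, 400, 60, 0.3),
#'                             regular_train(3, isi = 20))
#' @export
simulate_conductance <- function(params, train, dt = 0.05, t_end = NULL) {
  stopifnot(inherits(params, "synapse_params"), inherits(train, "stimulus_train"))
  if (dt > params$tau_d / 10) {
    warning("grid step coarser than tau_d / 10; the decay will be undersampled",
            call. = FALSE)
  }
  times <- train$event_times
  if (is.null(t_end)) t_end <- times[length(times)] + 5 * params$tau_d
  grid <- sort(unique(c(seq(min(0, times[1]), t_end, by = dt), times)))
  g_opt <- params$g / params$U
  st <- evolve_states(params, train)
  val <- .tpm_g_at(grid, times, st$A_post, g_opt, params$tau_d)
  events <- tibble::tibble(
    event = st$event,
    time_ms = st$time_ms,
    peak = g_opt * st$A_post,
    initiation = g_opt * st$A_pre,
    amp_init = g_opt * (st$A_post - st$A_pre),  # A_i, from initiation point
    amp_base = g_opt * st$A_post                # AB_i, from (zero) baseline
  )
  .new_signal(grid, val, "conductance", "nS", events)
}

#' Convert a conductance signal to a voltage-clamp current
#'
#' Applies Ohm's law `I(t) = g(t) (V_m - E_rev)` with the membrane
#' potential fixed at the junction-corrected holding potential
#' `V_m = V_h - E_j`. The sign follows this convention directly; callers
#' wanting the physiological inward/outward sign can negate.
#'
#' @param signal A conductance `syn_signal` (nS).
#' @param conditions Voltage-clamp [recording_conditions()].
#' @return A `syn_signal` in pA.
#' @export
simulate_current <- function(signal, conditions) {
  stopifnot(inherits(signal, "syn_signal"),
            inherits(conditions, "recording_conditions"))
  if (attr(signal, "modality") != "conductance") {
    stop("simulate_current expects a conductance signal", call. = FALSE)
  }
  if (conditions$modality != "voltage_clamp") {
    stop("simulate_current requires voltage-clamp conditions", call. = FALSE)
  }
  drive <- conditions$V_m0 - conditions$E_rev
  events <- attr(signal, "events")
  if (!is.null(events)) {
    events <- dplyr::mutate(events,
                            peak = .data$peak * drive,
                            initiation = .data$initiation * drive,
                            amp_init = .data$amp_init * drive,
                            amp_base = .data$amp_base * drive)
  }
  .new_signal(signal$time_ms, signal$value * drive, "current", "pA", events)
}

#' Integrate a current or conductance signal through the RC membrane
#'
#' Produces the synaptic potential by feeding the signal into a passive
#' resistor-capacitor membrane, `C_m dV/dt = g_in (V_ss - V) + I_syn`.
#' When a conductance signal is supplied the synaptic current is
#' recomputed at every step from the evolving membrane potential,
#' `I_syn = g(t) (E_rev - V)`; when an (injected) current signal is
#' supplied it enters additively as-is. Integration uses lsoda
#' (rtol 1e-8) piecewise between events so the conductance
#' discontinuities are never smoothed over.
#'
#' @param signal A `syn_signal` (conductance in nS or current in pA) on a
#'   uniform grid.
#' @param membrane A [membrane_model()].
#' @param conditions [recording_conditions()] supplying `E_rev`; required
#'   for conductance input.
#' @return A `syn_signal` in mV starting from `V_ss`.
#' @export
simulate_voltage <- function(signal, membrane, conditions = NULL) {
  stopifnot(inherits(signal, "syn_signal"), inherits(membrane, "membrane_model"))
  modality <- attr(signal, "modality")
  grid <- signal$time_ms
  dt <- stats::median(diff(grid))
  if (dt > membrane$tau_m / 10) {
    stop("signal grid step exceeds tau_m / 10; refine the grid", call. = FALSE)
  }
  f <- stats::approxfun(grid, signal$value, rule = 2)
  events <- attr(signal, "events")
  brk <- sort(unique(c(grid[1], if (!is.null(events)) events$time_ms,
                       grid[length(grid)])))
  if (modality == "conductance") {
    if (is.null(conditions)) {
      stop("conductance input needs recording_conditions for E_rev", call. = FALSE)
    }
    deriv <- function(t, y, parms) {
      list((membrane$g_in * (membrane$V_ss - y) +
              f(t) * (conditions$E_rev - y)) / membrane$C_m)
    }
  } else if (modality == "current") {
    deriv <- function(t, y, parms) {
      list((membrane$g_in * (membrane$V_ss - y) + f(t)) / membrane$C_m)
    }
  } else {
    stop("signal must be conductance or current", call. = FALSE)
  }
  v0 <- membrane$V_ss
  out_t <- numeric(0); out_v <- numeric(0)
  for (k in seq_len(length(brk) - 1)) {
    seg <- grid[grid >= brk[k] & grid <= brk[k + 1]]
    if (length(seg) < 2) seg <- c(brk[k], brk[k + 1])
    sol <- deSolve::lsoda(y = v0, times = seg, func = deriv, parms = NULL,
                          rtol = 1e-8, atol = 1e-10)
    keep <- if (k == 1) seq_len(nrow(sol)) else -1L
    out_t <- c(out_t, sol[keep, 1]); out_v <- c(out_v, sol[keep, 2])
    v0 <- sol[nrow(sol), 2]
  }
  ev <- NULL
  if (!is.null(events)) {
    ev <- tibble::tibble(event = events$event, time_ms = events$time_ms)
  }
  .new_signal(out_t, out_v, "voltage", "mV", ev, baseline = membrane$V_ss)
}

#' Four-state ODE reference oracle
#'
#' Dense numerical integration of the full four-state system (u, R, A, D)
#' with the Dirac event terms applied as exact discrete state jumps at the
#' event times, integrating piecewise between events with lsoda. This is
#' the brute-force reference the analytic event-driven solution is checked
#' against; resource conservation `A + R + D = 1` holds throughout.
#'
#' @param params A [synapse_params()].
#' @param train A [stimulus_train()].
#' @param dt Output grid step (ms).
#' @param t_end End of integration; defaults to last event + `5 * tau_d`.
#' @return A tibble `time_ms`, `u`, `R`, `A`, `D`.
#' @export
four_state_oracle <- function(params, train, dt = 0.05, t_end = NULL) {
  stopifnot(inherits(params, "synapse_params"), inherits(train, "stimulus_train"))
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  if (dt > min(params$tau_d, params$tau_r, params$tau_f) / 5) {
    stop("dt too large to resolve the smallest time constant", call. = FALSE)
  }
  times <- train$event_times
  if (is.null(t_end)) t_end <- times[length(times)] + 5 * params$tau_d
  deriv <- function(t, y, parms) {
    u <- y[1]; R <- y[2]; A <- y[3]; D <- y[4]
    list(c(-u / params$tau_f,
           D / params$tau_r,
           -A / params$tau_d,
           A / params$tau_d - D / params$tau_r))
  }
  y <- c(u = 0, R = 1, A = 0, D = 0)
  brk <- c(times, t_end)
  start <- min(0, times[1])
  out <- NULL
  t_cur <- start
  for (k in seq_along(brk)) {
    seg_end <- brk[k]
    if (seg_end > t_cur) {
      seg <- sort(unique(c(seq(t_cur, seg_end, by = dt), seg_end)))
      sol <- deSolve::lsoda(y, seg, deriv, NULL, rtol = 1e-10, atol = 1e-12)
      out <- rbind(out, if (is.null(out)) sol else sol[-1, , drop = FALSE])
      y <- sol[nrow(sol), -1]
      t_cur <- seg_end
    }
    if (k <= length(times)) {
      # exact jumps: u first, then the u_plus R_minus transfer; the output
      # carries both the pre-jump and post-jump row at the event time
      u_plus <- y[1] + params$U * (1 - y[1])
      rel <- u_plus * y[2]
      y[1] <- u_plus
      y[2] <- y[2] - rel
      y[3] <- y[3] + rel
      out <- rbind(out, c(t_cur, y))
    }
  }
  colnames(out) <- c("time_ms", "u", "R", "A", "D")
  tibble::as_tibble(as.data.frame(out))
}
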