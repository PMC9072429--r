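#' Synapse parameter set
#'
#' The five constants that characterise one synaptic connection in the
#' simplified three-state Tsodyks-Pawelzik-Markram (TPM) model: peak
#' conductance of the first event `g` (nS), deactivation (decay) time
#' constant `tau_d` (ms), recovery-from-depression time constant `tau_r`
#' (ms), facilitation-decay time constant `tau_f` (ms), and the
#' utilization increment ratio `U` (dimensionless, in (0, 1]).
#'
#' @param g Peak conductance of the first synaptic event (nS), > 0.
#' @param tau_d Decay time constant (ms), > 0.
#' @param tau_r Recovery time constant (ms), > 0.
#' @param tau_f Facilitation time constant (ms), > 0.
#' @param U Utilization increment ratio, in (0, 1].
#' @return An object of class `synapse_params` (named list).
#' @examples
#' synapse_params(g = 1, tau_d = 8, tau_r = 400, tau_f = 60, U = 0.3)
#' @export
synapse_params <- function(g, tau_d, tau_r, tau_f, U) {
  vals <- c(g = g, tau_d = tau_d, tau_r = tau_r, tau_f = tau_f, U = U)
  if (any(!is.finite(vals))) {
    stop("synapse parameters must be finite numbers", call. = FALSE)
  }
  if (g <= 0) stop("g must be positive", call. = FALSE)
  if (tau_d <= 0 || tau_r <= 0 || tau_f <= 0) {
    stop("all time constants must be positive", call. = FALSE)
  }
  if (U <= 0 || U > 1) stop("U must lie in (0, 1]", call. = FALSE)
  structure(list(g = g, tau_d = tau_d, tau_r = tau_r, tau_f = tau_f, U = U),
            class = "synapse_params")
}

#' @export
print.synapse_params <- function(x, ...) {
  cat("<synapse_params> g =", format(x$g), "nS, tau_d =", format(x$tau_d),
      "ms, tau_r =", format(x$tau_r), "ms, tau_f =", format(x$tau_f),
      "ms, U =", format(x$U), "\n")
  invisible(x)
}

#' @export
as.data.frame.synapse_params <- function(x, ...) {
  as.data.frame(tibble::as_tibble(unclass(x)))
}

#' Stimulus train
#'
#' Ordered presynaptic event times, optionally flagging the last event as a
#' recovery test pulse delivered after a long pause.
#'
#' @param event_times Strictly increasing event times (ms).
#' @param recovery_index Optional index of the recovery event; when given it
#'   must point at the last event.
#' @param isi Nominal inter-stimulus interval (ms) of the regular portion of
#'   the train, or `NULL` when the train is irregular.
#' @return An object of class `stimulus_train`.
#' @examples
#' stimulus_train(seq(0, 180, by = 20))
#' @export
stimulus_train <- function(event_times, recovery_index = NULL, isi = NULL) {
  event_times <- as.numeric(event_times)
  if (length(event_times) < 1L) stop("at least one event time required", call. = FALSE)
  if (any(diff(event_times) <= 0)) {
    stop("event times must be strictly increasing", call. = FALSE)
  }
  if (!is.null(recovery_index)) {
    recovery_index <- as.integer(recovery_index)
    if (recovery_index != length(event_times)) {
      stop("recovery_index must mark the last event", call. = FALSE)
    }
  }
  structure(list(event_times = event_times, recovery_index = recovery_index,
                 isi = isi),
            class = "stimulus_train")
}

#' Build a regular stimulus train, optionally with a trailing recovery pulse
#'
#' @param n_events Number of regular events.
#' @param isi Inter-stimulus interval (ms).
#' @param t0 Time of the first event (ms).
#' @param recovery_interval Pause before the recovery pulse (ms); `NULL` for
#'   no recovery event. The conventional pause is 2000 ms.
#' @return A `stimulus_train`.
#' @export
regular_train <- function(n_events, isi, t0 = 0, recovery_interval = NULL) {
  times <- t0 + isi * (seq_len(n_events) - 1)
  rec <- NULL
  if (!is.null(recovery_interval)) {
    times <- c(times, times[length(times)] + recovery_interval)
    rec <- length(times)
  }
  stimulus_train(times, recovery_index = rec, isi = isi)
}

#' @export
print.stimulus_train <- function(x, ...) {
  cat("<stimulus_train>", length(x$event_times), "events",
      if (!is.null(x$recovery_index)) "(last is recovery)" else "", "\n")
  invisible(x)
}

#' Passive membrane (RC) model
#'
#' Resistor-capacitor description of the postsynaptic membrane used to turn
#' synaptic currents into synaptic potentials. Any two of `C_m`, `tau_m`,
#' `g_in` determine the third via `tau_m = C_m / g_in` (with C_m in pF,
#' g_in in nS, tau_m in ms).
#'
#' @param V_ss Steady-state (resting) potential (mV).
#' @param C_m Membrane capacitance (pF).
#' @param tau_m Membrane time constant (ms).
#' @param g_in Input conductance (nS).
#' @return An object of class `membrane_model`.
#' @export
membrane_model <- function(V_ss, C_m = NULL, tau_m = NULL, g_in = NULL) {
  n_given <- sum(!vapply(list(C_m, tau_m, g_in), is.null, logical(1)))
  if (n_given < 2L) {
    stop("provide at least two of C_m, tau_m, g_in", call. = FALSE)
  }
  if (is.null(g_in)) g_in <- C_m / tau_m
  if (is.null(C_m)) C_m <- tau_m * g_in
  if (is.null(tau_m)) tau_m <- C_m / g_in
  if (any(c(C_m, tau_m, g_in) <= 0)) {
    stop("C_m, tau_m and g_in must be positive", call. = FALSE)
  }
  if (abs(tau_m - C_m / g_in) > 0.01 * tau_m) {
    stop("inconsistent membrane values: tau_m must equal C_m / g_in within 1%",
         call. = FALSE)
  }
  structure(list(V_ss = V_ss, C_m = C_m, tau_m = tau_m, g_in = g_in),
            class = "membrane_model")
}

#' Recording conditions
#'
#' Electrical and experimental context of a recording: reversal potential,
#' liquid junction potential, holding potential and the recording modality.
#' In voltage clamp the effective membrane potential is the holding
#' potential corrected for the junction potential, `V_m0 = V_h - E_j`; in
#' current clamp it is the junction-corrected resting/steady-state
#' potential supplied through the membrane model.
#'
#' @param E_rev Reversal potential of the synaptic conductance (mV).
#' @param V_h Holding potential (mV); required in voltage clamp.
#' @param E_j Liquid junction potential (mV).
#' @param modality `"voltage_clamp"` or `"current_clamp"`.
#' @return An object of class `recording_conditions`.
#' @examples
#' recording_conditions(E_rev = -70, V_h = -35)
#' @export
recording_conditions <- function(E_rev, V_h = NULL, E_j = 0,
                                 modality = c("voltage_clamp", "current_clamp")) {
  modality <- match.arg(modality)
  if (!is.finite(E_rev)) stop("E_rev is required", call. = FALSE)
  if (modality == "voltage_clamp" && (is.null(V_h) || !is.finite(V_h))) {
    stop("V_h is required in voltage clamp", call. = FALSE)
  }
  V_m0 <- if (modality == "voltage_clamp") V_h - E_j else NA_real_
  structure(list(E_rev = E_rev, E_j = E_j, V_h = V_h, modality = modality,
                 V_m0 = V_m0),
            class = "recording_conditions")
}
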