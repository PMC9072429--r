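# Shared fixtures, all built in code.

default_params <- function() synapse_params(1, 8, 400, 60, 0.3)

vc_conditions <- function() recording_conditions(E_rev = -70, V_h = -35)

# A depressing three-event trace with known amplitudes from baseline
# (A_1 = 10, then 6, then 4; initiation at baseline so A_i = AB_i).
three_event_depressing <- function() {
  pts <- dplyr::bind_rows(lapply(1:3, function(i) {
    amp <- c(10, 6, 4)[i]
    t0 <- (i - 1) * 20
    tibble::tibble(
      event = i,
      time_ms = t0 + c(0, 0.5, 1, 1.5, 2, 3, 4, 5, 6),
      value = c(0, amp * (1:3) / 4, amp, amp * exp(-(1:3) / 2.88), amp / 2),
      anchor = c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, TRUE),
      role = c("initiation", rep("rise", 3), "peak", rep("decay", 3),
               "decay_anchor"))
  }))
  reconstructed_trace(pts, stimulus_train(c(0, 20, 40), isi = 20),
                      baseline = 0, provenance = "synthetic")
}

# Random parameter set drawn inside the fitting bounds.
random_params <- function() {
  synapse_params(g = exp(stats::rnorm(1, 0, 0.4)),
                 tau_d = stats::runif(1, 4, 25),
                 tau_r = stats::runif(1, 100, 900),
                 tau_f = stats::runif(1, 15, 200),
                 U = stats::runif(1, 0.1, 0.7))
}

# Exhaustive pairwise-difference (Walsh) oracle for the unpaired
# Hodges-Lehmann estimate.
hl_oracle_unpaired <- function(a, b) {
  stats::median(outer(a, b, "-"))
}

hl_oracle_paired <- function(a, b) {
  d <- a - b
  w <- outer(d, d, "+") / 2
  stats::median(w[upper.tri(w, diag = TRUE)])
}
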