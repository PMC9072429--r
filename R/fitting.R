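#' Options controlling the trace-fitting procedure
#'
#' Defaults follow the method's protocol: each trace is optimized 30 times
#' by bounded differential evolution, the best 15 runs (lowest final
#' objective) are averaged, and a run terminates once the objective change
#' between successive generations drops below 0.001. Search bounds default
#' to `50 < tau_r < 3000` ms, `1 < tau_f < 300` ms, `0.001 < U < 1`; the
#' decay constant is searched in `(0.5, 1000)` ms (values above 700 ms are
#' flagged for exclusion downstream) and the conductance bound is ten
#' times a naive amplitude/driving-force estimate.
#'
#' @param runs Number of independent optimization repeats.
#' @param keep_best Number of lowest-objective runs averaged.
#' @param tolerance Objective-change termination tolerance.
#' @param seed Integer seed; run `i` uses `seed + i`.
#' @param optimize_membrane When `TRUE` and membrane values are missing,
#'   `tau_m` and `C_m` join the search vector (bounds `tau_m` in (5, 100)
#'   ms, `C_m` in (20, 400) pF).
#' @param bounds Named list of `c(lower, upper)` per parameter
#'   (`g_opt`, `tau_d`, `tau_r`, `tau_f`, `U`); entries override defaults.
#' @param polish Refine each run's best member with bounded L-BFGS-B
#'   (default `TRUE`), mirroring common differential-evolution practice.
#' @param maxiter Generation cap per run.
#' @return A list of class `fit_options`.
#' @export
fit_options <- function(runs = 30, keep_best = 15, tolerance = 0.001,
                        seed = 1L, optimize_membrane = FALSE, bounds = list(),
                        polish = TRUE, maxiter = 200) {
  if (runs < keep_best || keep_best < 1) {
    stop("need runs >= keep_best >= 1", call. = FALSE)
  }
  b <- list(g_opt = c(NA, NA), tau_d = c(0.5, 1000), tau_r = c(50, 3000),
            tau_f = c(1, 300), U = c(0.001, 1))
  for (nm in names(bounds)) b[[nm]] <- bounds[[nm]]
  structure(list(runs = runs, keep_best = keep_best, tolerance = tolerance,
                 seed = as.integer(seed), optimize_membrane = optimize_membrane,
                 bounds = b, polish = polish, maxiter = maxiter),
            class = "fit_options")
}

#' Weighted mean soft-L1 objective
#'
#' `error = (2 / sum(w)) * sum(w_i (sqrt(1 + r_i^2) - 1))` over the
#' residuals `r_i = signal_i - simulation_i`. With equal unit weights this
#' reduces to the plain mean soft-L1 squared error; the normalisation by
#' `sum(w)` keeps a perfect fit at exactly zero when weights differ.
#'
#' @param simulation Simulated values at the data-point times.
#' @param signal Observed (reconstructed) values.
#' @param weights Per-point weights; default all 1.
#' @return Non-negative scalar.
#' @examples
#' weighted_soft_l1(c(0, 0), c(1, 1))  # 2 * (sqrt(2) - 1)
#' @export
weighted_soft_l1 <- function(simulation, signal, weights = NULL) {
  if (length(simulation) != length(signal)) {
    stop("simulation and signal lengths differ", call. = FALSE)
  }
  if (is.null(weights)) weights <- rep(1, length(signal))
  r <- signal - simulation
  (2 / sum(weights)) * sum(weights * (sqrt(1 + r^2) - 1))
}

# Point weights: the whole first event carries twice the weight of other
# events; interpolated (non-anchor) points carry half the weight of
# anchors. The two factors combine multiplicatively.
.trace_weights <- function(trace) {
  pts <- trace$points
  w <- ifelse(pts$event == min(pts$event), 2, 1)
  w * ifelse(pts$anchor, 1, 0.5)
}

#' Correct a trace for slow superimposed processes
#'
#' The recorded and simulated signals should agree best at the initiation
#' points of the synaptic events, where the fast conductance is smallest.
#' The correction therefore measures the signal-minus-simulation offset at
#' each initiation point, interpolates those offsets linearly
#' (triangulation) between consecutive initiation points, and subtracts
#' the interpolated offset from every data point. After correction the
#' trace matches the simulation exactly at the initiation points.
#'
#' @param trace A `recon_trace`.
#' @param simulation Simulated values at the trace's data-point times
#'   (numeric vector aligned with `trace$points`).
#' @return The corrected `recon_trace`.
#' @export
slow_process_correction <- function(trace, simulation) {
  stopifnot(inherits(trace, "recon_trace"))
  pts <- trace$points
  if (length(simulation) != nrow(pts)) {
    stop("simulation must be evaluated at every trace data point", call. = FALSE)
  }
  ini <- pts$role == "initiation"
  if (!any(ini)) stop("trace has no initiation points", call. = FALSE)
  off_t <- pts$time_ms[ini]
  off_v <- pts$value[ini] - simulation[ini]
  corr <- if (sum(ini) == 1) rep(off_v, nrow(pts)) else
    stats::approx(off_t, off_v, xout = pts$time_ms, rule = 2)$y
  out <- trace
  out$points$value <- pts$value - corr
  out
}

# ---- forward evaluation of candidate parameter sets -------------------------

# Evaluate the forward model for a population of candidate vectors at the
# trace's data-point times. theta: matrix with columns g_opt, tau_d, tau_r,
# tau_f, U [, tau_m, C_m]. Returns an n_points x n_candidates matrix in the
# trace's units (pA for voltage clamp, nS for conductance, mV for current
# clamp).
.forward_pop <- function(theta, trace, conditions, membrane = NULL) {
  pts <- trace$points
  ev_times <- trace$train$event_times
  st <- .tpm_evolve_matrix(theta[, 2], theta[, 3], theta[, 4], theta[, 5],
                          ev_times)
  n_pts <- nrow(pts); n_c <- nrow(theta)
  if (is.null(conditions) || conditions$modality == "voltage_clamp") {
    drive <- if (is.null(conditions)) 1 else conditions$V_m0 - conditions$E_rev
    idx <- findInterval(pts$time_ms, ev_times) -
      (pts$role == "initiation") * (pts$time_ms %in% ev_times)
    out <- matrix(trace$baseline, n_pts, n_c)
    for (j in which(idx > 0)) {
      i <- idx[j]
      dt <- pts$time_ms[j] - ev_times[i]
      out[j, ] <- trace$baseline +
        theta[, 1] * st$A_post[i, ] * exp(-dt / theta[, 2]) * drive
    }
    out
  } else {
    .forward_pop_cc(theta, trace, conditions, membrane, st)
  }
}

# Current clamp: vectorised fixed-step RK4 across the candidate population.
# The synaptic drive tracks the evolving membrane potential; long
# inter-event gaps are completed analytically once the conductance has
# decayed to a negligible level.
.forward_pop_cc <- function(theta, trace, conditions, membrane, st) {
  pts <- trace$points
  ev_times <- trace$train$event_times
  n_c <- nrow(theta)
  tau_m <- if (ncol(theta) >= 6) theta[, 6] else rep(membrane$tau_m, n_c)
  C_m <- if (ncol(theta) >= 7) theta[, 7] else rep(membrane$C_m, n_c)
  g_in <- C_m / tau_m
  V_ss <- membrane$V_ss
  E <- conditions$E_rev
  V <- rep(V_ss, n_c)
  t_cur <- min(0, ev_times[1], pts$time_ms[1])
  bnds <- sort(unique(c(ev_times, max(pts$time_ms))))
  bnds <- bnds[bnds > t_cur]
  out <- matrix(NA_real_, nrow(pts), n_c)
  pt_t <- pts$time_ms
  before <- pt_t <= t_cur
  out[before, ] <- V_ss
  dt_int <- min(min(tau_m) / 20, min(theta[, 2]) / 10, 0.25)
  record <- function(tm, Vm) {
    hit <- which(abs(pt_t - tm) < dt_int / 2 & is.na(out[, 1]))
    for (j in hit) out[j, ] <<- Vm
    out
  }
  deriv <- function(tm, Vm, i_ev) {
    g <- if (i_ev > 0) {
      theta[, 1] * st$A_post[i_ev, ] * exp(-(tm - ev_times[i_ev]) / theta[, 2])
    } else rep(0, n_c)
    (g_in * (V_ss - Vm) + g * (E - Vm)) / C_m
  }
  for (b in bnds) {
    i_ev <- findInterval(t_cur + 1e-9, ev_times)
    span <- b - t_cur
    cut <- min(span, 14 * max(theta[, 2]))
    n_steps <- max(1L, ceiling(cut / dt_int))
    h <- cut / n_steps
    for (s in seq_len(n_steps)) {
      # capture points inside this step via linear placement at step start
      hit <- which(pt_t > t_cur - 1e-9 & pt_t <= t_cur + h / 2 & is.na(out[, 1]))
      for (j in hit) out[j, ] <- V
      k1 <- deriv(t_cur, V, i_ev)
      k2 <- deriv(t_cur + h / 2, V + h / 2 * k1, i_ev)
      k3 <- deriv(t_cur + h / 2, V + h / 2 * k2, i_ev)
      k4 <- deriv(t_cur + h, V + h * k3, i_ev)
      V <- V + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t_cur <- t_cur + h
      hit <- which(pt_t > t_cur - h / 2 & pt_t <= t_cur + 1e-9 & is.na(out[, 1]))
      for (j in hit) out[j, ] <- V
    }
    if (b - t_cur > 1e-9) {
      # conductance negligible: relax analytically toward V_ss
      hit <- which(pt_t > t_cur & pt_t <= b & is.na(out[, 1]))
      for (j in hit) {
        out[j, ] <- V_ss + (V - V_ss) * exp(-(pt_t[j] - t_cur) / tau_m)
      }
      V <- V_ss + (V - V_ss) * exp(-(b - t_cur) / tau_m)
      t_cur <- b
    }
  }
  miss <- is.na(out[, 1])
  if (any(miss)) for (j in which(miss)) out[j, ] <- V
  out
}

# ---- differential evolution -------------------------------------------------

# Bounded differential evolution (best/1/bin, dithered F in [0.5, 1],
# CR = 0.7, population 15 x dims) with greedy selection and optional
# L-BFGS-B polish of the best member. `obj` maps a candidate matrix to a
# vector of objective values. Terminates when the best objective improves
# by less than `tol` from one generation to the next (after a burn-in of
# 30 generations) or at `maxiter`.
.de_optimize <- function(obj, lower, upper, tol = 0.001, maxiter = 200,
                         pop_mult = 15, CR = 0.7, polish = TRUE,
                         min_gen = 30) {
  d <- length(lower)
  np <- pop_mult * d
  pop <- matrix(stats::runif(np * d, rep(lower, each = np),
                             rep(upper, each = np)), np, d)
  fit <- obj(pop)
  best_i <- which.min(fit)
  for (gen in seq_len(maxiter)) {
    f_prev <- fit[best_i]
    F <- stats::runif(1, 0.5, 1)
    r1 <- sample(np, np, replace = TRUE)
    r2 <- sample(np, np, replace = TRUE)
    mut <- matrix(pop[best_i, ], np, d, byrow = TRUE) +
      F * (pop[r1, , drop = FALSE] - pop[r2, , drop = FALSE])
    mut <- pmin(pmax(mut, matrix(lower, np, d, byrow = TRUE)),
                matrix(upper, np, d, byrow = TRUE))
    cross <- matrix(stats::runif(np * d) < CR, np, d)
    force_dim <- cbind(seq_len(np), sample(d, np, replace = TRUE))
    cross[force_dim] <- TRUE
    trial <- ifelse(cross, mut, pop)
    f_trial <- obj(trial)
    better <- f_trial < fit
    pop[better, ] <- trial[better, ]
    fit[better] <- f_trial[better]
    best_i <- which.min(fit)
    if (gen >= min_gen && (f_prev - fit[best_i]) < tol) break
  }
  x <- pop[best_i, ]
  f <- fit[best_i]
  if (polish) {
    sobj <- function(p) obj(matrix(p, 1))
    scale <- pmax((upper - lower) / 10, 1e-6)
    for (pass in 1:2) {
      pol <- tryCatch(
        stats::optim(x, sobj, method = "L-BFGS-B", lower = lower,
                     upper = upper,
                     control = list(factr = 10, maxit = 2000,
                                    parscale = scale)),
        error = function(e) NULL)
      if (!is.null(pol) && pol$value <= f) {
        x <- pol$par; f <- pol$value
      }
    }
  }
  list(par = x, value = f, generations = gen)
}

# ---- fit_trace --------------------------------------------------------------

.is_variable_isi <- function(train) {
  reg <- train$event_times
  if (!is.null(train$recovery_index)) reg <- reg[-train$recovery_index]
  length(reg) >= 3 && stats::sd(diff(reg)) > 1e-6 * mean(diff(reg))
}

.naive_g_estimate <- function(trace, conditions, membrane) {
  amp <- max(abs(trace$points$value - trace$baseline))
  if (is.null(conditions)) return(max(amp, 1e-3))
  if (conditions$modality == "voltage_clamp") {
    max(amp / max(abs(conditions$V_m0 - conditions$E_rev), 1e-6), 1e-3)
  } else {
    max(amp * membrane$g_in /
          max(abs(membrane$V_ss - conditions$E_rev), 1e-6), 1e-3)
  }
}

#' Fit TPM synapse parameters to a reconstructed trace
#'
#' Runs `runs` independent bounded differential-evolution optimizations of
#' the weighted soft-L1 objective between the forward-simulated signal and
#' the trace's data points, then averages the parameter vectors of the
#' `keep_best` lowest-objective runs. In voltage clamp the forward model is
#' the analytic event-driven conductance converted by Ohm's law; in
#' current clamp the simulated current is additionally integrated through
#' the RC membrane (with `tau_m`/`C_m` joining the search when
#' `optimize_membrane` is set and no membrane values are given). For
#' traces with variable inter-stimulus intervals the slow-process
#' correction is applied inside the objective. The reported conductance is
#' `g = g_optimization * U`, so it equals the first-event peak
#' conductance.
#'
#' @param trace A `recon_trace` (standardized: >= 10 events plus recovery
#'   where applicable).
#' @param conditions [recording_conditions()]; `NULL` fits a raw
#'   conductance trace.
#' @param membrane A [membrane_model()]; required for current clamp unless
#'   `optimize_membrane` is set.
#' @param options A [fit_options()].
#' @return An object of class `syn_fit`; see [tidy.syn_fit()] and
#'   [glance.syn_fit()].
#' @export
fit_trace <- function(trace, conditions = NULL, membrane = NULL,
                      options = fit_options()) {
  stopifnot(inherits(trace, "recon_trace"), inherits(options, "fit_options"))
  current_clamp <- !is.null(conditions) && conditions$modality == "current_clamp"
  opt_mem <- current_clamp && options$optimize_membrane &&
    (is.null(membrane) || is.null(membrane$tau_m))
  if (current_clamp && is.null(membrane) && !options$optimize_membrane) {
    stop("current clamp needs a membrane model or optimize_membrane = TRUE",
         call. = FALSE)
  }
  if (opt_mem && is.null(membrane)) {
    stop("optimize_membrane still needs V_ss via a membrane_model ",
         "(C_m/tau_m may be omitted by passing bounds-only values)",
         call. = FALSE)
  }
  b <- options$bounds
  if (any(is.na(b$g_opt))) {
    b$g_opt <- c(1e-6, 10 * .naive_g_estimate(trace, conditions, membrane))
  }
  lower <- c(b$g_opt[1], b$tau_d[1], b$tau_r[1], b$tau_f[1], b$U[1])
  upper <- c(b$g_opt[2], b$tau_d[2], b$tau_r[2], b$tau_f[2], b$U[2])
  if (opt_mem) {
    lower <- c(lower, 5, 20)
    upper <- c(upper, 100, 400)
  }
  w <- .trace_weights(trace)
  obs <- trace$points$value
  variable_isi <- .is_variable_isi(trace$train)
  ini <- trace$points$role == "initiation"
  pt_t <- trace$points$time_ms
  obj <- function(theta) {
    sim <- .forward_pop(theta, trace, conditions, membrane)
    vapply(seq_len(nrow(theta)), function(m) {
      s <- sim[, m]
      o <- obs
      if (variable_isi && sum(ini) >= 2) {
        off <- stats::approx(pt_t[ini], o[ini] - s[ini], xout = pt_t,
                             rule = 2)$y
        o <- o - off
      }
      weighted_soft_l1(s, o, w)
    }, numeric(1))
  }
  runs <- purrr::map(seq_len(options$runs), function(i) {
    set.seed(options$seed + i)
    .de_optimize(obj, lower, upper, tol = options$tolerance,
                 maxiter = options$maxiter, polish = options$polish)
  })
  run_tbl <- tibble::tibble(
    run = seq_len(options$runs),
    objective = vapply(runs, `[[`, numeric(1), "value"),
    g_opt = vapply(runs, function(r) r$par[1], numeric(1)),
    tau_d = vapply(runs, function(r) r$par[2], numeric(1)),
    tau_r = vapply(runs, function(r) r$par[3], numeric(1)),
    tau_f = vapply(runs, function(r) r$par[4], numeric(1)),
    U = vapply(runs, function(r) r$par[5], numeric(1))
  )
  if (opt_mem) {
    run_tbl$tau_m <- vapply(runs, function(r) r$par[6], numeric(1))
    run_tbl$C_m <- vapply(runs, function(r) r$par[7], numeric(1))
  }
  run_tbl$g <- run_tbl$g_opt * run_tbl$U
  kept <- dplyr::slice_min(run_tbl, .data$objective, n = options$keep_best,
                           with_ties = FALSE)
  par_means <- colMeans(kept[, setdiff(names(kept), c("run", "objective"))])
  # boundary diagnostics
  edge <- character(0)
  nm <- c("g_opt", "tau_d", "tau_r", "tau_f", "U")
  for (k in seq_along(nm)) {
    v <- kept[[nm[k]]]
    span <- upper[k] - lower[k]
    if (all(v < lower[k] + 1e-6 * span)) edge <- c(edge, paste0(nm[k], ":lower"))
    if (all(v > upper[k] - 1e-6 * span)) edge <- c(edge, paste0(nm[k], ":upper"))
  }
  if (length(edge)) {
    warning("all kept runs sit on bound edge(s): ", paste(edge, collapse = ", "),
            call. = FALSE)
  }
  tau_d_hat <- par_means[["tau_d"]]
  structure(list(
    params = synapse_params(par_means[["g"]], tau_d_hat, par_means[["tau_r"]],
                            par_means[["tau_f"]], min(par_means[["U"]], 1)),
    g_opt = par_means[["g_opt"]],
    membrane = if (opt_mem) list(tau_m = par_means[["tau_m"]],
                                 C_m = par_means[["C_m"]]) else membrane,
    objective = min(run_tbl$objective),
    runs = run_tbl,
    kept = kept$run,
    excluded = tau_d_hat > 700,
    exclusion_reason = if (tau_d_hat > 700) "tau_d > 700 ms" else NA_character_,
    boundary = edge,
    trace = trace, conditions = conditions, options = options
  ), class = "syn_fit")
}

#' @export
print.syn_fit <- function(x, ...) {
  cat("<syn_fit> objective =", format(x$objective, digits = 4),
      if (x$excluded) "[EXCLUDED]" else "", "\n")
  print(x$params)
  invisible(x)
}

#' Pool traces recorded at different stimulation frequencies
#'
#' Checks that the traces describe the same connection under the same
#' conditions and bundles them for a joint fit whose objective is the sum
#' of the per-trace objectives.
#'
#' @param traces List of `recon_trace` objects.
#' @return An object of class `syn_pool`.
#' @export
pool_frequencies <- function(traces) {
  stopifnot(length(traces) >= 1,
            all(vapply(traces, inherits, logical(1), "recon_trace")))
  structure(list(traces = traces), class = "syn_pool")
}

#' Jointly fit pooled traces and re-expand the result
#'
#' Optimizes one shared parameter set against all pooled traces (joint
#' objective = sum of per-trace weighted soft-L1 objectives) and attaches
#' the fitted parameters back to each source trace.
#'
#' @param pool A [pool_frequencies()] object (or list of traces).
#' @param conditions,membrane,options As in [fit_trace()].
#' @return A list of `syn_fit` objects, one per input trace, sharing the
#'   same fitted parameters.
#' @export
fit_pooled <- function(pool, conditions = NULL, membrane = NULL,
                       options = fit_options()) {
  if (!inherits(pool, "syn_pool")) pool <- pool_frequencies(pool)
  traces <- pool$traces
  if (length(traces) == 1) {
    f <- fit_trace(traces[[1]], conditions, membrane, options)
    return(list(f))
  }
  ws <- lapply(traces, .trace_weights)
  b <- options$bounds
  if (any(is.na(b$g_opt))) {
    est <- max(vapply(traces, .naive_g_estimate, numeric(1),
                      conditions = conditions, membrane = membrane))
    b$g_opt <- c(1e-6, 10 * est)
  }
  lower <- c(b$g_opt[1], b$tau_d[1], b$tau_r[1], b$tau_f[1], b$U[1])
  upper <- c(b$g_opt[2], b$tau_d[2], b$tau_r[2], b$tau_f[2], b$U[2])
  obj <- function(theta) {
    tot <- rep(0, nrow(theta))
    for (k in seq_along(traces)) {
      sim <- .forward_pop(theta, traces[[k]], conditions, membrane)
      obs <- traces[[k]]$points$value
      tot <- tot + vapply(seq_len(nrow(theta)), function(m) {
        weighted_soft_l1(sim[, m], obs, ws[[k]])
      }, numeric(1))
    }
    tot
  }
  runs <- purrr::map(seq_len(options$runs), function(i) {
    set.seed(options$seed + i)
    .de_optimize(obj, lower, upper, tol = options$tolerance,
                 maxiter = options$maxiter, polish = options$polish)
  })
  objv <- vapply(runs, `[[`, numeric(1), "value")
  keep <- order(objv)[seq_len(options$keep_best)]
  pars <- do.call(rbind, lapply(runs[keep], `[[`, "par"))
  pars <- cbind(pars, g = pars[, 1] * pars[, 5])
  pm <- colMeans(pars)
  params <- synapse_params(pm[["g"]], pm[[2]], pm[[3]], pm[[4]], min(pm[[5]], 1))
  lapply(traces, function(tr) {
    structure(list(params = params, g_opt = pm[[1]], membrane = membrane,
                   objective = min(objv),
                   runs = tibble::tibble(run = seq_along(objv), objective = objv),
                   kept = keep,
                   excluded = pm[[2]] > 700,
                   exclusion_reason = if (pm[[2]] > 700) "tau_d > 700 ms" else NA_character_,
                   boundary = character(0),
                   trace = tr, conditions = conditions, options = options),
              class = "syn_fit")
  })
}

#' Post-fit quality control and decay-constant imputation
#'
#' Flags fits whose decay constant exceeds 700 ms for exclusion, and fills
#' the decay constant of amplitude-only records (no kinetics reported)
#' with the median `tau_d` of the unitary responses of the same
#' neurotransmitter class present in the table.
#'
#' @param results Tibble with at least `tau_d`, `response`
#'   (`"GABAergic"`/`"glutamatergic"`), `unitary` (logical) and
#'   `amplitude_only` (logical) columns.
#' @return The tibble with `excluded`, `exclusion_reason` and
#'   `tau_d_imputed` columns added and `tau_d` filled where needed.
#' @export
qc_and_impute <- function(results) {
  stopifnot(all(c("tau_d", "response", "unitary", "amplitude_only") %in%
                  names(results)))
  out <- tibble::as_tibble(results)
  out$excluded <- !is.na(out$tau_d) & out$tau_d > 700
  out$exclusion_reason <- ifelse(out$excluded, "tau_d > 700 ms", NA_character_)
  out$tau_d_imputed <- FALSE
  need <- out$amplitude_only & (is.na(out$tau_d))
  for (cls in unique(out$response[need])) {
    donors <- out$tau_d[out$response == cls & out$unitary & !out$amplitude_only &
                          !out$excluded & !is.na(out$tau_d)]
    if (length(donors) == 0) {
      stop("no unitary ", cls, " records available to impute tau_d", call. = FALSE)
    }
    sel <- need & out$response == cls
    out$tau_d[sel] <- stats::median(donors)
    out$tau_d_imputed[sel] <- TRUE
  }
  out
}
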