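#' Specification of a synthetic trace
#'
#' Defines the study conditions for one generated trace: the generating
#' TPM parameters, the stimulus train, Gaussian measurement noise
#' (expressed as a fraction of the first-event amplitude), and an additive
#' slow drift modelled as a single slow exponential ramp
#' `drift_amp * A_1 * (1 - exp(-t / drift_tau))` - the simplest process
#' that exercises the triangulation-based slow-process correction.
#'
#' @param params A [synapse_params()].
#' @param train A [stimulus_train()].
#' @param noise_sd Noise standard deviation as a fraction of the
#'   first-event amplitude; default 0.
#' @param drift_amp Drift asymptote as a fraction of the first-event
#'   amplitude; default 0.
#' @param drift_tau Drift time constant (ms).
#' @param conditions Optional voltage-clamp [recording_conditions()]; when
#'   given the trace is emitted in pA, otherwise in nS.
#' @param baseline Baseline value added to all points.
#' @param seed Mandatory integer seed.
#' @return A list of class `trace_spec`.
#' @export
trace_spec <- function(params, train, noise_sd = 0, drift_amp = 0,
                       drift_tau = 1000, conditions = NULL, baseline = 0,
                       seed) {
  stopifnot(inherits(params, "synapse_params"),
            inherits(train, "stimulus_train"),
            noise_sd >= 0, drift_amp >= 0)
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  structure(list(params = params, train = train, noise_sd = noise_sd,
                 drift_amp = drift_amp, drift_tau = drift_tau,
                 conditions = conditions, baseline = baseline,
                 seed = as.integer(seed)),
            class = "trace_spec")
}

#' Generate a synthetic reconstructed trace with known ground truth
#'
#' Forward-simulates the event amplitudes with the analytic TPM model and
#' emits model-consistent nine-point events (initiation and peak at the
#' event time - the conductance rise is instantaneous - plus six
#' interpolated decay points and a decay anchor), then adds Gaussian
#' measurement noise and the slow drift. The generating parameters are
#' attached as the `"truth"` attribute for recovery tests.
#'
#' @param spec A [trace_spec()].
#' @return A `recon_trace` (provenance `"synthetic"`) with attribute
#'   `"truth"` holding the generating [synapse_params()].
#' @export
generate_trace <- function(spec) {
  stopifnot(inherits(spec, "trace_spec"))
  set.seed(spec$seed)
  params <- spec$params
  train <- spec$train
  times <- train$event_times
  st <- evolve_states(params, train)
  g_opt <- params$g / params$U
  drive <- if (is.null(spec$conditions)) 1 else
    spec$conditions$V_m0 - spec$conditions$E_rev
  a1 <- abs(params$g * drive)
  gaps <- c(diff(times), 5 * params$tau_d)
  pts <- purrr::map_dfr(seq_along(times), function(i) {
    t_dec <- min(params$tau_d * log(2), 0.85 * gaps[i])
    dt_rel <- c(0, 0, t_dec * (1:6) / 7, t_dec)
    role <- c("initiation", "peak", rep("decay", 6), "decay_anchor")
    val <- numeric(9)
    val[1] <- g_opt * st$A_pre[i] * drive
    val[-1] <- g_opt * st$A_post[i] * exp(-dt_rel[-1] / params$tau_d) * drive
    tibble::tibble(event = i, time_ms = times[i] + dt_rel,
                   value = spec$baseline + val,
                   anchor = c(TRUE, TRUE, rep(FALSE, 6), TRUE),
                   role = role)
  })
  if (spec$noise_sd > 0) {
    pts$value <- pts$value + stats::rnorm(nrow(pts), 0, spec$noise_sd * a1)
  }
  if (spec$drift_amp > 0) {
    pts$value <- pts$value +
      spec$drift_amp * a1 * (1 - exp(-pts$time_ms / spec$drift_tau))
  }
  out <- reconstructed_trace(pts, train, baseline = spec$baseline,
                             provenance = "synthetic")
  attr(out, "truth") <- params
  out
}

#' Specification of a synthetic feature-target corpus
#'
#' Defines a small synthetic analogue of a literature-mined synaptic
#' corpus: a network of neuron types, per-connection base parameters drawn
#' from log-normal distributions (logit-normal for U), multiplicative
#' covariate effects planted on chosen parameters, fuzzy pre/postsynaptic
#' mappings, and a controllable fraction of records missing the
#' short-term-plasticity triple (tau_r, tau_f, U).
#'
#' @param n_pre,n_post Number of pre-/post-synaptic neuron types used
#'   (drawn from the head of the 122-type catalog).
#' @param density Fraction of type pairs that form connections, in (0, 1].
#' @param n_records Number of records to generate.
#' @param effects Named list: for each covariate (`"species"`, `"sex"`,
#'   `"age"`, `"temperature"`, `"modality"`), a named numeric vector of
#'   multipliers applied to the targets when the covariate is in its
#'   non-reference state, e.g. `list(species = c(g = 2))`.
#' @param fuzzy_prob Probability that a record is fuzzily mapped (an extra
#'   candidate type added on each side).
#' @param missing_stp Fraction of records whose ST-P triple is missing.
#' @param noise_sdlog Log-scale SD of the multiplicative measurement noise
#'   on targets.
#' @param seed Mandatory integer seed.
#' @return A list of class `dataset_spec`.
#' @export
dataset_spec <- function(n_pre = 8, n_post = 8, density = 0.5,
                         n_records = 2000, effects = list(),
                         fuzzy_prob = 0.2, missing_stp = 0.2,
                         noise_sdlog = 0.1, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(density > 0, density <= 1, fuzzy_prob >= 0, fuzzy_prob <= 1,
            missing_stp >= 0, missing_stp <= 1)
  structure(list(n_pre = n_pre, n_post = n_post, density = density,
                 n_records = n_records, effects = effects,
                 fuzzy_prob = fuzzy_prob, missing_stp = missing_stp,
                 noise_sdlog = noise_sdlog, seed = as.integer(seed)),
            class = "dataset_spec")
}

.rlnorm_clipped <- function(n, meanlog, sdlog, lo, hi) {
  pmin(pmax(stats::rlnorm(n, meanlog, sdlog), lo), hi)
}

#' Generate a synthetic feature-target corpus with known structure
#'
#' @param spec A [dataset_spec()].
#' @param schema A [feature_schema()]; defaults to the standard catalog.
#' @return A list with `records` (raw metadata tibble ready for
#'   [encode_features()]), `targets` (tibble `g`, `tau_d`, `tau_r`,
#'   `tau_f`, `U` with `NA` for missing ST-P triples), and `truth`
#'   (per-connection base parameters and the planted effect map).
#' @export
generate_ml_dataset <- function(spec, schema = feature_schema()) {
  stopifnot(inherits(spec, "dataset_spec"))
  set.seed(spec$seed)
  catalog <- schema$catalog
  pre_types <- catalog[seq_len(spec$n_pre)]
  post_types <- catalog[61 + seq_len(spec$n_post)]
  pairs <- expand.grid(pre = pre_types, post = post_types,
                       stringsAsFactors = FALSE)
  keep <- stats::runif(nrow(pairs)) < spec$density
  if (!any(keep)) keep[1] <- TRUE
  conns <- tibble::as_tibble(pairs[keep, ])
  nc <- nrow(conns)
  conns$response <- ifelse(stats::runif(nc) < 0.5, "GABAergic", "glutamatergic")
  conns$g <- .rlnorm_clipped(nc, log(1.0), 0.6, 0.05, 20)
  conns$tau_d <- .rlnorm_clipped(nc, log(10), 0.4, 1.5, 65)
  conns$tau_r <- .rlnorm_clipped(nc, log(300), 0.4, 60, 2500)
  conns$tau_f <- .rlnorm_clipped(nc, log(50), 0.5, 2, 280)
  conns$U <- stats::plogis(stats::rnorm(nc, stats::qlogis(0.3), 0.5))
  idx <- sample(nc, spec$n_records, replace = TRUE)
  rec <- conns[idx, ]
  flips <- tibble::tibble(
    species = stats::runif(spec$n_records) < 0.5,
    sex = stats::runif(spec$n_records) < 0.5,
    age = stats::runif(spec$n_records) < 0.5,
    temperature = stats::runif(spec$n_records) < 0.5,
    modality = stats::runif(spec$n_records) < 0.5
  )
  targets <- rec[, c("g", "tau_d", "tau_r", "tau_f", "U")]
  for (cov in names(spec$effects)) {
    mult <- spec$effects[[cov]]
    on <- flips[[cov]]
    for (p in names(mult)) {
      targets[[p]][on] <- targets[[p]][on] * mult[[p]]
    }
  }
  noise <- exp(matrix(stats::rnorm(spec$n_records * 5, 0, spec$noise_sdlog),
                      ncol = 5))
  targets <- targets * noise
  targets$U <- pmin(targets$U, 0.99)
  # fuzzy mapping: add a neighbouring candidate type on each side
  fuzzy <- stats::runif(spec$n_records) < spec$fuzzy_prob
  pre_col <- rec$pre
  post_col <- rec$post
  if (any(fuzzy)) {
    alt_pre <- pre_types[(match(rec$pre[fuzzy], pre_types) %% spec$n_pre) + 1]
    alt_post <- post_types[(match(rec$post[fuzzy], post_types) %% spec$n_post) + 1]
    pre_col[fuzzy] <- paste(rec$pre[fuzzy], alt_pre, sep = "|")
    post_col[fuzzy] <- paste(rec$post[fuzzy], alt_post, sep = "|")
  }
  miss <- stats::runif(spec$n_records) < spec$missing_stp
  targets$tau_r[miss] <- NA; targets$tau_f[miss] <- NA; targets$U[miss] <- NA
  records <- tibble::tibble(
    pre = pre_col,
    post = post_col,
    stimulation = "unitary",
    response = rec$response,
    contamination = FALSE,
    slow_status = "absent",
    monoamine = TRUE,
    cpampa = "absent",
    e_rev_ampa = 0, e_rev_nmda = 0,
    e_rev_gabaa = -70, e_rev_gabab = -90,
    v_m = ifelse(flips$modality, -65, -70),
    temperature = ifelse(flips$temperature, 22, 32),
    isi = ifelse(miss, NA_real_, sample(c(20, 50, 100), spec$n_records,
                                        replace = TRUE, prob = c(0.3, 0.5, 0.2))),
    species = ifelse(flips$species, "mouse", "rat"),
    sex = ifelse(flips$sex, "female", "male"),
    age = ifelse(flips$age, 14, 56),
    slice_region = "hippocampus|dorsal",
    orientation = "transverse",
    thickness = 300,
    subregion = "soma",
    potency = FALSE,
    stp_missing = miss
  )
  list(records = records,
       targets = tibble::as_tibble(targets),
       truth = list(connections = conns, effects = spec$effects,
                    flips = flips, connection_index = idx))
}
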