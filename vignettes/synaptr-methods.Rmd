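---
title: "Methods: synapse modeling, trace fitting, and deep-learning normalization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synapse modeling, trace fitting, and deep-learning normalization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

`synaptr` describes every synaptic connection with five constants: the
peak conductance of the first event $g$ (nS), the deactivation (decay)
time constant $\tau_d$ (ms), the recovery-from-depression time constant
$\tau_r$ (ms), the facilitation-decay time constant $\tau_f$ (ms), and
the utilization increment ratio $U \in (0, 1]$. The underlying dynamics
are the simplified three-state Tsodyks--Pawelzik--Markram (TPM) model:
synaptic resources are partitioned into activated ($A$), deactivated
($D$) and recovered ($R$) fractions with $A + R + D = 1$, and a
utilization variable $u$ that is incremented at each presynaptic event
by $u_+ = u_- + U (1 - u_-)$ and decays to zero with $\tau_f$. At an
event the fraction $u_+ R_-$ shifts instantaneously from $R$ to $A$; $A$
decays to $D$ with $\tau_d$, and $D$ recovers to $R$ with $\tau_r$.

Because the forcing is a sum of Dirac impulses, the system can be
advanced *exactly* from event to event (`evolve_states()`): between
events the states decay in closed form, and at each event the discrete
update is applied, with $u$ updated strictly before $A$ and $R$. The
closed form for $R$ involves the auxiliary quantity
$\bar A = A \tau_d / (\tau_d - \tau_r)$, which has a removable
singularity at $\tau_d = \tau_r$; whenever
$|\tau_d - \tau_r| < 10^{-6}\,\tau_d$ we switch to the analytic limit
(the $\Delta t\, e^{-\Delta t/\tau}$ form) instead of evaluating the
singular quotient.

A dense four-state ODE integration (`four_state_oracle()`, lsoda with
rtol $10^{-10}$, events applied as exact state jumps, never as narrow
pulses) serves as an independent brute-force reference; the analytic
and numerical solutions agree to better than $10^{-6}$ relative across
random parameter sets, and resource conservation holds to $10^{-9}$.

The conductance waveform is $g(t) = g_{\mathrm{opt}} A(t)$ with
$g_{\mathrm{opt}} = g / U$, so the first-event peak equals the reported
$g$; the channel is assumed to open instantaneously, so simulated
conductance and current traces have no rise phase and rise-time metrics
are only defined for voltage traces and reconstructed data.
Voltage-clamp currents follow Ohm's law,
$I(t) = g(t)\,(V_m - E_{\mathrm{rev}})$ with
$V_m = V_h - E_j$ (holding potential corrected for the liquid junction
potential). Current-clamp potentials are obtained by feeding the
conductance into a passive RC membrane,
$C_m \dot V = g_{\mathrm{in}} (V_{ss} - V) + g(t) (E_{\mathrm{rev}} - V)$,
integrated piecewise between events with lsoda at rtol $10^{-8}$ (the
solver family matches the published pipeline; the tolerance is our
choice, verified against the closed-form constant-current response to
$10^{-4}$ relative).

# Trace reconstruction

Each synaptic event is standardized to nine points: three anchors
(initiation, peak, decay) and six interpolated points. The placement of
the six interpolated points is not fully specified by the source
material beyond its figure; we place three evenly spaced in time on the
rise and three on the decay, which matches the figure's layout and
spreads weight along the transient. When the source is a digitized
curve, interpolated values are read off an Akima interpolant of the
samples; when the source is reported synaptometrics (amplitude, a
10--90% or 20--80% rise time, half-decay time), the rise is taken as
linear and the decay as a single exponential with
$\tau = t_{1/2} / \ln 2$.

Traces are classified by their terminal paired-pulse ratio with a
$\pm 0.05$ dead band: depressing below $1 - \epsilon$, facilitating
above $1 + \epsilon$, pseudolinear otherwise. Standardization extends
every trace to at least ten successive events: facilitating and
pseudolinear PPR series are extended by cubic interpolation over event
index (a separable index-by-ISI cubic surface when several stimulation
frequencies exist; with a single frequency true bicubic interpolation is
undefined and we degrade to one dimension), while depressing series are
fitted with a bounded exponential decay to a floor,
$\mathrm{PPR}_i = a e^{-i/b} + c$ with $a, b > 0$, $c \ge 0$ (the floor
implements "decay to a minimum"); if that fit is impossible the last
value is carried forward with a warning. Depressing and pseudolinear
traces lacking a recovery event receive one 2000 ms after the last
event, attached as a single data point whose amplitude from baseline is
$AB_{\mathrm{last}} + 0.63\,(A_1 - AB_{\mathrm{last}})$; facilitating
traces get no recovery event. The baseline is the pre-initiation value
of the first event and all $AB_i$ are measured from it.

# Fitting

Parameters are estimated by minimizing the weighted mean soft-L1 error
$$\mathrm{error} = \frac{2}{\sum_i w_i} \sum_i w_i
  \left(\sqrt{1 + r_i^2} - 1\right),$$
where $r_i$ is the residual at data point $i$. The first event carries
twice the weight of other events and interpolated points half the
weight of anchors; the two factors multiply (so a first-event
interpolated point has weight 1), and the normalisation by $\sum w$
keeps a perfect fit at zero while reducing to the plain mean for equal
weights. The optimizer is bounded differential evolution (best/1/bin,
population $15 \times$ dimensions, dithered mutation factor in
$[0.5, 1]$, crossover 0.7 -- standard defaults, recorded with the seed)
with bounds $50 < \tau_r < 3000$ ms, $1 < \tau_f < 300$ ms,
$0.001 < U < 1$; the decay constant is searched in $(0.5, 1000)$ ms and
fits with $\tau_d > 700$ ms are flagged for exclusion. No conductance
bound is stated by the source protocol, so we bound
$g_{\mathrm{opt}}$ by ten times a naive amplitude/driving-force
estimate. A run terminates when the best objective improves by less
than the tolerance (default 0.001) from one generation to the next,
after a 30-generation burn-in, and is then polished with bounded
L-BFGS-B using `parscale` set to a tenth of each bound span -- without
that scaling the polish stalls on the very differently scaled
parameters. Each trace is optimized 30 times and the parameter vectors
of the best 15 runs (in reported space, $g = g_{\mathrm{opt}} U$) are
averaged unweighted -- the only reading of "averaging the best fits"
that yields a single parameter set.

Slow superimposed processes (GABA_B/NMDA tails, membrane fluctuations)
are corrected by the triangulation method for variable-ISI traces:
signal-minus-simulation offsets at the initiation points are linearly
interpolated and subtracted inside the objective. Constant-ISI traces
are instead rebuilt from the first event's amplitude and decay plus the
PPR series at reconstruction time. When several stimulation frequencies
exist for one connection the traces are pooled into a joint objective
(the sum of per-trace objectives) and the single fitted parameter set is
re-expanded to each trace afterwards: pooling is what makes $\tau_f$ and
$\tau_r$ identifiable across frequencies, and our parameter-recovery
suite uses exactly this two-frequency design (10 events at 20 ms and at
50 ms ISI, each with a recovery event, 2% amplitude noise).

Open choices we fixed: the doubled first-event weight applies to the
whole first event including its interpolated points (multiplying with
the halved interpolation weight), and when membrane values are missing
in current clamp, `optimize_membrane` adds $\tau_m \in (5, 100)$ ms and
$C_m \in (20, 400)$ pF to the search vector (the bounds are ours).
Inter-trial variability is defined as the maximum over the five
parameters of $|p_1 - p_2| / \mathrm{mean}(p_1, p_2)$ between two full
fitting protocols -- the strictest simple choice.

# Normalization by deep learning

Records are encoded into a fixed, versioned 319-column feature space:
122 presynaptic and 122 postsynaptic one-hot columns (binary multi-hot
for fuzzy mappings -- the source describes one-hot encoding and never
fractional weights) and 75 covariate columns (stimulation method in
three columns with all-zero meaning miniature; species 1/-1/0 for
rat/mouse/guinea pig; sex 1/-1/0; reversal potentials; membrane
potential; temperature; ISI; age; slice geometry; 36 ionic
concentrations; a potency flag). The covariate list contains no
explicit recording-modality column, yet the condition grid flips
voltage vs current clamp; we represent that flip through the membrane
potential feature (holding $-70$ mV vs resting $-65$ mV). Records
missing the ST-P triple ($\tau_r$, $\tau_f$, $U$) have those targets
zeroed *and* the ISI feature zeroed, so the model can distinguish the
sentinel from a true zero; otherwise an unreported ISI defaults to 50
ms, the mode of typical ISIs. Ages must be provided (estimating age
from weight and strain is out of scope). Features are scaled by
per-column maximum absolute value (preserving sparsity), targets by
min-max to $[0, 1]$ for the sigmoid output layer.

Missing ST-P triples are first imputed by a random forest per target
trained on the complete records. The deep regressor itself is a
five-hidden-layer encoder--decoder perceptron (default widths
256--128--64--128--256; the exact widths are unstated by the source, so
they are configurable and our tests use narrower profiles), mish
activations, batch normalization, dropout with a max-norm constraint,
additive Gaussian input noise (sd 0.01 on scaled features -- magnitude
unstated, our choice), a 5-unit sigmoid output, SMAPE loss
$\frac{200}{n}\sum |p - t| / (|p| + |t|)$, AdamW (learning rate 0.015,
weight decay 0.001) wrapped in lookahead averaging, full-batch training
(the printed batch size equals the corpus size), plateau learning-rate
decay (patience 100, factor 0.9) and early stopping with best-weight
restoration. Everything is deterministic given the seed. An optional
feedback phase re-imputes the originally missing targets with the
latest deep model, up to 30 rounds, stopping when the training SMAPE no
longer improves.

Validation reports training accuracy (SMAPE on seen data), prediction
accuracy (k = 4 cross-validation or jackknife), target variability (the
within-group SMAPE spread of records sharing identical features -- the
empirical accuracy ceiling) and prediction reliability (the percentage
of predictions inside the 95% confidence interval of the group mean;
the CI construction is unstated in the source, we use the
t-distribution on the group mean). Ensembles of repeated trainings
(production 100, desk scale fewer) share scalers and report
mean/sd/range per parameter; predictions are clipped to the
plausibility ranges $g > 0$, $0 < \tau_d < 70$ ms, $\tau_r > 50$ ms,
$\tau_f > 1$ ms, $0 < U < 1$, and saturation at the training-set range
is flagged. Where the failure rate $f$ of the first event is known, an
amplitude/potency pseudo-record can be added via
$\mathrm{potency} = \mathrm{amplitude} / (1 - f)$ with the potency flag
set accordingly.

# Statistics

Changes are expressed as the symmetric percentage distance
$\mathrm{SPD} = 200 (v_1 - v_2)/(|v_1| + |v_2|)$ (a two-fold increase
is $+66.7$), summarised by a trimmed mean that excludes
$\lfloor 0.025 n \rfloor$ values per tail. Group comparisons use
Wilcoxon tests (signed-rank when paired) with the Hodges--Lehmann
estimate and CI converted to SPD units by
$200 / (\mathrm{median}(-) + \mathrm{median}(+))$, and
Benjamini--Hochberg FDR correction across each family (the source cites
an FDR reference without naming the variant; BH is the standard
choice). Coefficients of variation across a neuron type's potential
connections carry the small-sample correction $(1 + 1/(4n))$ -- the
source cites a correction without printing its formula; ours is one
published convention, isolated so it can be swapped -- with seeded
percentile-bootstrap CIs (2000 resamples). Covariate effects flip one
condition at a time over the 32-permutation grid (species, sex, age,
temperature, modality), compute per-connection SPDs, and label
trimmed-mean magnitudes above 10 and 20 as moderate and strong.
Parameter correlations are Pearson with t-distribution p-values.

# Synthetic data and what the tests show

The generator produces model-consistent traces (event amplitudes from
the analytic forward model, nine points per event, Gaussian noise as a
fraction of the first amplitude, and an additive slow exponential drift
-- the simplest process that exercises the triangulation correction)
and feature--target corpora with log-normal base parameters
(logit-normal for $U$) drawn inside the fitting bounds, planted
multiplicative covariate effects, fuzzy multi-hot mappings and a
controllable missing-ST-P fraction. Defaults (8 x 8 types, density 0.5,
2000 records, 2% trace noise, 8--10% target noise) are desk-scale
stand-ins for the literature corpus. What passing tests show is
internal consistency -- exact integration, objective arithmetic,
recovery of planted structure; they do not show that real digitized
traces satisfy the model's assumptions (mono-exponential decay, no
rise, stationary baselines) nor reproduce corpus-level biology, which
requires the released experimental dataset.

Problem sizes used by the test and acceptance suites are deliberate
desk-scale choices: 25 pooled two-frequency traces for recovery, a
2000-record corpus with a narrower 64--32--16--32--64 network for the
planted-effect check, and ensembles of one to two members where only
bookkeeping is under test.

# Known limitations

Single-exponential decay cannot represent dual-component (AMPA+NMDA)
kinetics; facilitating synapses fit slightly worse than depressing ones
under this model family; $\tau_f$ is weakly identified from a single
stimulation frequency (hence pooling); the feature catalog shipped here
is a synthetic 122-name stand-in, not the curated type catalog; and the
iterative imputation feedback mixes forest and deep estimates in one
specific way (latest-deep-model re-imputation) among several the source
would admit.
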