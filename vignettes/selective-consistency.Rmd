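---
title: "Selective consistency in plastic echo state networks: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selective consistency in plastic echo state networks: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasticESN)
```

## The scientific question

Driven nonlinear systems can respond *consistently* — the same input
trajectory evokes the same response regardless of the system's initial state
— or chaotically, where microscopic state differences grow until responses to
identical inputs share nothing. In reservoir computing this dichotomy is the
echo state property, governed largely by the spectral radius ρ of the
recurrent weight matrix. Human listeners, meanwhile, learn to detect a
repeated half-second token inside frozen white noise within a handful of
exposures (the noise repetition-detection task), and neural recordings show
that responses to the re-occurring noise become more reproducible
trial-to-trial. `plasticESN` implements a computational test of the
hypothesis that such *selective consistency* — reproducibility specific to a
learned stimulus — can self-organize in a recurrent network from weak,
unsupervised Hebbian plasticity, and that it can only do so near the edge of
chaos.

## Model

The reservoir is a sparse random recurrent network of N = 500 tanh units
(connection density d = 0.1, nonzero weights uniform on [−1, 1]) whose
recurrent matrix is rescaled once at initialization,
W = W_random · ρ_desired / ρ(W_random), so its spectral radius is exact to
10⁻¹⁰ relative error (dense eigendecomposition; N is small enough that this
beats iterative estimation). A single input unit projects through fixed
weights W_in ~ U(−1, 1)^N. The state update per input sample is the standard
echo-state form

    x(k+1) = tanh( W(k) x(k) + W_in u(k+1) ) + ε,   ε ~ N(0, σ² I)

with intrinsic noise σ = 10⁻³ by default. An integrator variant
(`update_rule = "integrator"`) that adds the previous state,
x(k+1) = x(k) + tanh(·) + ε, is retained for comparison; its states drift
roughly linearly to |x| ≈ 2000 over a one-second trial, which saturates the
units, lets the plasticity rule rewrite the weight matrix within a single
session (ρ jumps from 1.4 to ≈ 50), and produces non-stationary outputs. None
of these behaviors is compatible with a weakly plastic echo state network —
reported spectral radii change only slightly under training, and outputs are
stationary and noise-like — so the standard form is the default and the one
all headline analyses use.

During training trials only, the recurrent weights evolve under Oja's rule,
applied after every state update to the existing synapses (the sparsity
pattern is a structural constraint; absent synapses stay absent):

    ΔW_ij = α · x_i · (x_j − x_i · W_ij),       α = 10⁻⁷.

Both activations are taken at the new time step (`oja_timing =
"simultaneous"`), the literal reading of a rule written with a single time
index. A temporally asymmetric alternative pairing the presynaptic activation
x_j(k) with the postsynaptic x_i(k+1) (`"prepost"`) is provided as a
sensitivity option; it imprints the trajectory's transition structure rather
than its instantaneous covariance. In our experiments neither timing changes
the conclusions.

A linear readout y(k) = W_out x(k) is trained for one-step-ahead prediction
of the input, d(k) = u(k+1), by minibatch gradient descent: one gradient step
per trial on that trial's 1999-sample minibatch, learning rate η = 0.01,
weights initialized at zero. One step per minibatch is the simplest reading
of "pseudo-online" minibatch descent; the count is configurable and the
no-optimization control shows the optimizer is not what carries the effect.
Prediction of white noise is of course impossible in principle; the readout
serves as a 1-dimensional observable of the reservoir and as the basis of the
prediction-error analyses.

## Stimuli (the synthetic-data generator)

The stimulus module *is* the data generator; nothing external is read. Each
stimulus starts as 1 s of i.i.d. N(0, 1) noise at 44 kHz; the repeated kinds
(RN, RefRN) draw a 22,000-sample token and concatenate it twice, bit-exactly.
Gaussian amplitudes are the convention for frozen-noise experiments, and only
second-order statistics matter downstream. All stimuli pass through a digital
A-weighting filter (the standard analog zero/pole prescription discretized by
bilinear transform at 44 kHz, renormalized to exactly unity gain at 1 kHz;
its magnitude peaks near 3 kHz), are resampled to 2 kHz by a Kaiser-windowed
anti-aliasing FIR with edge-replication padding and group-delay compensation,
and are rescaled to unit RMS. The unit-RMS normalization decouples the
network's operating point from filter gain conventions; the presentation
amplitude is then a single interpretable number, the input gain.

A training session holds 20 stimuli — five realizations each of N (fresh
noise), RN (fresh repeated noise), RefN (one frozen noise realization), RefRN
(one frozen repeated realization) — in a seeded uniform order constrained
only so the final stimulus is an N. Test sets present 200 (configurable) runs
per kind; RefN/RefRN are the frozen training realizations, N/RN are fresh
draws whose seeds are disjoint from training by construction.

What the generator does *not* emulate: cochlear filterbanks or any
psychoacoustics beyond A-weighting, amplitude envelopes, or attentional
state. Passing tests therefore show that the network model behaves as claimed
for A-weighted Gaussian frozen noise, not that real auditory cortex does.

## Operating point: placing the edge of chaos

The stimulus presentation amplitude is not stated in the source experiment,
yet it decides everything about where order ends and chaos begins. With
unit-RMS stimuli presented at gain 1, the input entrains the network so
strongly that consistency stays above 0.95 even at ρ = 1.9 — there is no
chaotic regime on the studied grid, contradicting the qualitative anchors the
study itself reports (consistency declining once ρ exceeds ≈ 1, responses
"completely different across trials" by ρ = 2). We therefore calibrated the
input gain against those baseline anchors, using only the *non-plastic*
network: at `input_gain = 0.1` (the default), node-level consistency of the
driven untrained reservoir is ≈ 0.9 at ρ = 0.9, falls steeply across
1.2–1.6, and is ≈ 0 at 1.9 (`analysis/02_dynamics.R` reproduces this curve).
This places the edge of chaos where the study's figures place it, prior to
and independently of any plasticity comparison.

## Measurement

*Inter-segment correlation* — the consistency observable — is the Pearson
correlation between the first 200 samples (100 ms) of each 1000-sample
segment of a response series, windows anchored at the segment onsets
(transient included, the literal reading; a `window_offset` argument allows
sensitivity checks). For repeated stimuli, a consistent network must respond
to the second token presentation as it did to the first, so r approaches 1
in the ordered regime and 0 in chaos. *Inter-trial consistency* is the mean
pairwise correlation across runs on the same 200-sample window. Windows with
zero variance (e.g. the identically-zero output of a never-optimized
zero-initialized readout) yield flagged undefined values that are excluded
and counted, never imputed as 0.

Prediction error is summarized per time point across trials as RMSE, and as
NRMSE after dividing by the grand-mean RMSE over time and the four
{Hebbian, non-Hebbian} × {RN, RefRN} conditions at one radius — the printed
normalizer lists one condition twice where the accompanying prose clearly
describes the 2 × 2 condition set, so the prose version is implemented. The
grand mean of NRMSE over the four conditions is exactly 1 by construction.

Paired Hebbian-vs-non-Hebbian differences are tested with a sign-flip
surrogate rank-order test: the observed statistic is the mean paired
difference over test runs; 5000 surrogates flip each pair's sign
independently; the two-sided p-value is rank-based with the +1 correction,
floor 1/5001. Bonferroni correction multiplies by the number of radius levels
times stimulus comparisons actually run. Under a simulated null the raw p is
uniform and the type-I error at nominal 0.05 is calibrated (tested).

Pairing: the two arms share the initial weight draw, the input weights, the
training session (order and per-trial seeds) — they differ only in whether
Oja's rule runs. At *test* time each arm draws its own initial states and
noise (arms share only the stimuli). We deviate here from pairing the test
seeds across arms deliberately: with fully shared test randomness the paired
differences become nearly deterministic, and systematic offsets of order
10⁻⁵ in deep-order regimes reach "significance" — an artifact of the pairing,
not a property of the networks, and one that would contradict the
non-significance outside the critical band that the design is meant to
detect.

## What the experiments show — and the honest gaps

The package reproduces the baseline physics cleanly: exact radius control,
echo-state convergence at low ρ (inter-trial r > 0.99 past the transient),
decorrelation in chaos, slight spectral-radius drift under training
(|Δρ|/ρ < 1%), and no RefRN-vs-RN prediction-error difference anywhere —
prediction of white noise does not improve with exposure, as expected.

The headline selective effect is present but small. At the edge of chaos
(ρ = 1.4), with 200 paired test runs, the Hebbian network's RefRN
inter-segment correlation exceeds its frozen twin's by ≈ 0.015 and no
sign-flip surrogate reaches the observed difference (p = 2·10⁻⁴); the same
comparison is far from significance at ρ = 0.9 and ρ = 1.9, the RN control
is not significant at 1.4, and the identical pattern holds at the level of
raw reservoir nodes when the readout is never optimized. That is the
qualitative claim in full: selectivity for the repeatedly experienced
realization, after five exposures, only near criticality, not mediated by
the readout, and without any prediction-error change.

Two quantitative aspects do not survive scrutiny, and we report them as
such. First, the *location* of the selectivity peak is unstable: at
α = 10⁻⁷ one 20-trial session changes the weights by only
‖ΔW‖_F/‖W‖_F ≈ 0.1% (tanh-bounded activations cap the per-step Hebbian
increment at α), producing per-radius differences of order ±0.01–0.03 whose
seed-to-seed fluctuation at the critical flank is of the same order; over
five replicate experiments the argmax of the difference curve lands between
1.2 and 1.6 in only two, and at some replicates the sign of the edge-of-chaos
difference reverses outright (the Hebbian twin becomes *less* consistent,
with the two-sided surrogate p equally extreme). What is reproducible across
replicates is that the weak imprint perturbs consistency for the referenced
realization far beyond chance *only* near criticality; which direction it
takes depends on the particular network and frozen realization. A much
larger published effect (violin plots separated by ~0.3) would pin both the
peak and the sign; an effect this size cannot. Scaling α upward
(`analysis/05_plasticity_scaling.R`) does not help selectivity: the imprint
grows roughly linearly with α but its RefRN and RN footprints remain
comparable — the covariance that simultaneous Oja imprints is dominated by
the common A-weighted spectrum of all the noise stimuli — while the Hebbian
growth term outruns the forgetting term and inflates the spectral radius
(1.4 → 1.47 at α = 10⁻⁶, → 5.8 at 10⁻⁵), carrying the network out of the
near-critical regime altogether. The pre/post timing variant is no more
selective at these exposure counts. Second, mean
prediction error is not monotone in ρ: it is U-shaped with a minimum just
below criticality (richest stable dynamics predict the band-limited noise
best) and increases monotonically only beyond ρ ≈ 1.0, where the reported
behavior is a monotone increase across the whole range. The acceptance
checks encoding the peak-location replication and the monotonicity are
implemented faithfully and left to report these failures rather than being
loosened.

## Numerical choices

Simulation is a compiled core (Rcpp). Each trial owns an RNG stream
(splitmix64-seeded xoshiro256++, ziggurat normals — verified against the
theoretical distributions in the tests) that yields the U(−1,1)^N initial
state and then the per-step noise, so a trial is a pure function of
(network, stimulus, seed), batched and single-run execution agree bit for
bit, and every table in a results bundle is bit-reproducible from its master
seed. All derived seeds stay below 2³¹. The Oja update is fused into the
next step's sparse matrix-vector pass with identical arithmetic to the
two-pass form, which the R-level reference implementation cross-checks in the
test suite. Undefined correlations are excluded and counted; overflowing
trials (possible only in the integrator variant) are recorded and their
radius skipped rather than clipped.

Problem sizes in the test suite: the full-scale sweeps use N = 500, 20 radii,
5 exposures per type, 50 test runs per condition at 5 master seeds (the
selectivity-peak check), and 200 test runs at radii {0.9, 1.4, 1.9} for the
significance pattern with and without readout optimization. Unit and property
tests use reservoirs of 12–120 neurons and short series, which exercise every
code path at negligible cost.

## Limitations

The model omits leaky integration, spiking dynamics, excitatory/inhibitory
cell types, and any explicit repetition-detection decision; the readout
predicts rather than classifies. Conclusions about selectivity are limited by
the operating-point freedom documented above: a different (unpublished)
input amplitude or noise variance could in principle move the system into a
regime we did not find. All stimuli are Gaussian frozen noise; nothing here
speaks to structured sounds.
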