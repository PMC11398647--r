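# plasticESN

Selective consistency of plastic echo state networks on the noise
repetition-detection task.

## The problem

Listeners learn — implicitly, within about five exposures — to detect a
repeated half-second token inside frozen white noise, and neural recordings
show that responses to the re-occurring noise realization become more
reproducible across trials. `plasticESN` is a simulation study of the
hypothesis that this *selective consistency* — response reproducibility
specific to a repeatedly experienced stimulus — can self-organize in a
recurrent network from weak, unsupervised Hebbian plasticity, and that it
emerges only near the edge of chaos. The package is aimed at computational
neuroscientists studying reservoir dynamics, consistency of driven nonlinear
systems, and unsupervised perceptual learning.

## Model

A sparse random echo state network of N = 500 tanh units (density d = 0.1,
weights U(−1,1), rescaled so ρ(W) equals a chosen spectral radius exactly)
driven by A-weighted, 2 kHz-resampled Gaussian noise stimuli u(k) through
fixed input weights:

    x(k+1) = tanh( W(k) x(k) + W_in u(k+1) ) + ε,     ε ~ N(0, σ²I), σ = 1e-3

During training, W evolves under Oja's rule on the existing synapses,

    ΔW_ij = α x_i (x_j − x_i W_ij),                    α = 1e-7

and a linear readout y(k) = W_out x(k) learns one-step-ahead prediction
d(k) = u(k+1) by minibatch gradient descent (one step per trial, η = 0.01).
The training session presents 20 one-second stimuli — five each of fresh
noise (N), fresh repeated noise (RN), a frozen noise realization (RefN) and a
frozen repeated realization (RefRN). For each spectral radius on a 0.1–2.0
grid, a plastic ("Hebbian") and a frozen ("non-Hebbian") twin sharing all
initial weights and training randomness are trained, then evaluated on
seeded test runs with plasticity and optimization halted. Consistency is the
Pearson correlation between the onsets of the two 500 ms response segments;
Hebbian-vs-non-Hebbian differences are tested with a 5000-fold sign-flip
surrogate rank-order test, Bonferroni-corrected.

## Worked example

Train and compare the twin reservoirs at the edge of chaos (ρ = 1.4), then
test whether the plastic network responds more consistently to the frozen
repeated-noise realization:

```r
library(plasticESN)

cfg  <- sweep_config(radii = 1.4, n_test_runs = 200,
                     test_kinds = "RefRN", master_seed = 1)
res  <- run_sweep(cfg)
res$tests[, c("radius", "comparison", "observed_diff", "p_raw")]
#>   radius comparison observed_diff      p_raw
#> 1    1.4      RefRN    0.01453244 0.00019996
```

The Hebbian network's mean inter-segment correlation for RefRN exceeds its
frozen twin's by ≈ 0.015, and no sign-flip surrogate reaches the observed
paired difference (p = 2·10⁻⁴, the test's floor region). Running the same
comparison at ρ = 0.9 and ρ = 1.9 gives p = 0.92 and p = 0.97: deep in the
ordered regime both networks are consistent anyway, and in chaos neither is —
the plasticity effect is confined to the critical band. Across the full
sweep (`analysis/03_sweep.R`) the Hebbian-minus-non-Hebbian difference peaks
at ρ = 1.4 (+0.033 with 50 test runs, seed 1), while the same comparison for
fresh repeated noise (RN) stays non-significant there, and prediction error
shows no RefRN-vs-RN difference at any radius — consistency changes without
prediction improving.

The numbered scripts under `analysis/` reproduce the full study: stimulus
corpus construction and diagnostics (`01`), the order-to-chaos baseline that
fixes the operating point (`02`), the main spectral-radius sweep with
surrogate statistics (`03`), the no-readout-optimization control at node
level (`04`), and the learning-rate sensitivity analysis (`05`). Each writes
tidy CSV tables under `results/`.

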