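---
title: "Classifying stochastic intracellular calcium dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying stochastic intracellular calcium dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Cytosolic calcium (Ca²⁺) in stimulated cells oscillates in qualitatively
distinct temporal patterns — resting steady states, simple periodic spiking,
bursting, period-2/3/4 alternations, chaos, and quasiperiodicity — and these
regimes carry physiological meaning (resting state, normal signaling,
apoptosis-associated bursting, and so on). Deterministic models predict which
biochemical parameters produce which regime, but a real cell is a finite
reactor: with ~10⁴–10⁵ molecules of Ca²⁺ and InsP₃ in a 1–2 pL cytoplasm,
intrinsic reaction noise blurs exactly the fine temporal signatures
(amplitude alternation, aperiodicity) that distinguish the subtle regimes.
`castate` asks, operationally: can a classifier trained purely on simulated
trajectories still read the regime through realistic intrinsic noise — and
how does it compare with conventional spectral-feature classifiers?

## The model

The deterministic core is the Houart three-variable model of InsP₃-gated
Ca²⁺-induced Ca²⁺ release (CICR), with cytosolic Ca²⁺ `x`, store Ca²⁺ `y`
and InsP₃ `z` (all µM, time in minutes):

    dx/dt = V0 + V1·β − V2(x) + V3(x,y,z) + kf·y − k_out·x
    dy/dt = V2(x) − V3(x,y,z) − kf·y
    dz/dt = β·V4 − V5(x,z) − ε·z

with Hill-type rates: pumping `V2 = VM2·x²/(k2²+x²)`, CICR release
`V3 = VM3 · xᵐ/(kxᵐ+xᵐ) · y²/(ky²+y²) · z⁴/(kz⁴+z⁴)`, and Ca²⁺-activated
InsP₃ 3-kinase degradation `V5 = VM5 · zᵖ/(k5ᵖ+zᵖ) · xⁿ/(kdⁿ+xⁿ)`.
β ∈ [0, 1] is the agonist stimulation degree, ε (1/min) the 5-phosphatase
rate. The exchange terms cancel in pairs, giving the mass balance
`ẋ + ẏ = V0 + V1β − k_out·x`, which the test suite checks algebraically.

### Intrinsic noise: the chemical Langevin equation

The rate equations are decomposed into 12 elementary birth–death channels
(each term above is one channel; `V2` and `V3` each appear twice because
they move Ca²⁺ between two pools). Each channel j with concentration-scale
rate r_j contributes a drift r_j·ν_j and an independent Gaussian noise term
√(r_j)·ν_j·ξ_j/√V, where V is the system size (µm³). One Euler–Maruyama
step is

    s' = s + F(s)·dt + √(dt/V) · Σ_j ν_j √(r_j) η_j ,   η_j ~ N(0,1) iid.

V sets the noise amplitude: fluctuations scale as 1/√V (verified as a
log–log slope −0.5 ± 0.1 property test), and V → ∞ recovers the
deterministic path *exactly* (the noise prefactor is zero, so the CLE path
at V = ∞ is bit-identical to explicit Euler — also a test). Following the
birth–death decomposition, the 12 noise processes are mutually independent;
the alternative convention of correlating the noise of paired channels is
noted as a modeling choice we did not take, since the per-species table
decomposition is what the channel list expresses.

Numerical choices: channel rates are clamped at 0 before the square root
and concentrations clamped at 0 after each step (negative excursions are
rare at V ≥ 10⁵ where the CLE is valid, but the clamp keeps small-V runs
well-defined). The step defaults to dt = 10⁻⁴ min; the stochastic scheme is
Euler–Maruyama at fixed step, and a finer reference step of 10⁻⁶ min is
available by argument when the weak-convergence margin matters. Each
trajectory owns a counter-seeded xoshiro256++ stream with a ziggurat normal
sampler, so a recorded integer seed reproduces it bit-for-bit regardless of
R's RNG state.

### Parameter regions

Three canonical parameter regions span the model's regime menagerie, with
(β, ε) drawn uniformly per region and all other constants fixed:

| | Region 1 | Region 2 | Region 3 |
|---|---|---|---|
| β range | [0, 0.8] | [0.65, 0.8] | [0, 0.8] |
| ε range (1/min) | [0, 10] | [10, 16.8] | [0, 2.5] |
| regimes | bursting, oscillatory, steady | chaotic, P-2, P-3, P-4, steady, oscillatory | quasiperiodic, steady, oscillatory |
| Hill (m, p, n) | 4, 1, 2 | 2, 1, 4 | 2, 2, 4 |

The full constants are in `castate:::.region_fixed`. Two constants deserve
comment because commonly reproduced value tables for these regions are
inconsistent with the regimes they are supposed to produce. With kf = 10
min⁻¹ in Region 1 the fixed point is stable over the whole (β, ε) box
(we verified this by Jacobian eigenvalue scans and multi-start trajectory
probes), so the package uses kf = 1 min⁻¹, which restores the documented
bursting/oscillatory/steady structure. In Region 2, V4 = 2 µM/min caps
InsP₃ at β·V4/ε ≤ 0.16 µM — far below the release threshold kz = 0.4 µM —
so CICR could never fire anywhere in the printed ε ∈ [10, 16.8] window; the
package uses V4 = 10 µM/min, which places InsP₃ at 0.4–0.6 µM (inside the
physiological 0.1–1 µM range) and produces the documented period-doubling
cascade with chaos windows. Both choices are single-constant corrections
selected as the minimal change that realizes each region's published regime
menu inside its printed (β, ε) ranges.

## Automatic regime labeling

Class labels come from the deterministic dynamics at each sampled parameter
point; a noisy trajectory inherits the label of its noiseless twin. The
cascade, applied to a 120-min RK4 run (dt = 10⁻³ min) after a 20-min
transient, sampled at 0.02 min for diagnostics:

1. **steady state** if the post-transient amplitude range is below 0.02 µM
   (an absolute band, deliberately below the smallest oscillation
   amplitudes the model produces);
2. **bursting** if prominent spikes cluster into ≥ 2 groups of ≥ 3 spikes
   separated by quiescent gaps ≥ 3× the intra-burst inter-spike interval;
3. **periodicity order**: peaks with topographic prominence ≥ 5% of the
   range (heights refined by parabolic interpolation so sharp spikes don't
   alias against the sampling grid) are tested for the smallest q ∈ 1..4
   such that amplitudes and inter-peak intervals repeat with period q
   within 5% tolerance; q = 1 is simple oscillatory, q = 2/3/4 the
   multiple-periodicity classes;
4. **aperiodic** peaks: chaotic if the Benettin two-trajectory largest
   Lyapunov exponent exceeds 0.05 min⁻¹, else quasiperiodic if the spectrum
   shows two dominant frequencies whose ratio is not within 10⁻² of any
   small-integer ratio (p/q ≤ 8); anything else is `undetermined` and the
   parameter point is rejected and resampled, never force-labeled.

The initial condition is the located fixed point perturbed by +0.1 µM in
`x` (so unstable equilibria actually leave), with a multi-start damped
Newton root finder behind `find_steady_state()`. Because near-bifurcation
draws can land on long transients or marginal patterns, rejection plus
`undetermined` is the honest policy at region boundaries.

## Datasets

`build_dataset()` samples, per class, parameter points from the class's
admissible regions (round-robin when several regions produce it), verifying
every point with the labeler; thin regimes (P-3, P-4, chaos windows) are
found by mixing uniform draws with Gaussian proposals around previously
verified points — every accepted point is still labeler-verified. Each
point is then simulated at every requested system size
(V ∈ {∞, 10⁸, 10⁷, 10⁶, 10⁵} by default; the deterministic path for
V = ∞), over 120 min with a 20-min burn-in at 0.1-min sampling — exactly
1000 recorded points. Classifier inputs are linearly interpolated to 1000
points and min–max normalized to [0, 1] per trajectory: normalization is
the single most consequential unstated preprocessing choice, made so
synthetic µM series and Fura-2-derived experimental series share one input
scale. Splits are stratified by (class, V), so class balance holds exactly
within every level and split.

## The classifier

`lkcnn()` implements the large-kernel 1-D CNN: conv(16 filters, kernel k,
stride 2) → maxpool(2) → conv(32, k, stride 2) → maxpool(2) → dropout(0.5)
→ flatten → dense(64) → dropout(0.5) → dense(32) → softmax, ReLU
throughout, valid (unpadded) convolutions — at k = 28 on 1000-point inputs
this is 127,832 trainable parameters, a count the tests recompute
layer-by-layer. Training minimizes categorical cross-entropy (probabilities
clipped at 10⁻¹² inside the loss) with Adam at α = 10⁻⁴ and batch 32, early
stopping on validation accuracy (ties keep the earliest epoch) with
best-weights restoration. One master seed drives initialization, shuffling
and dropout, so single-threaded training is bit-reproducible — a property
the tests assert. Inference disables dropout and is deterministic.

Because no deep-learning runtime is a dependency, the network is
implemented directly on BLAS matrix products (im2col convolutions) with
hand-written backpropagation verified against finite differences in the
test suite, and small compiled kernels for the memory-bound steps. The
kernel size k is the one scanned hyperparameter (`kernel_scan()`); the
defaults elsewhere follow the fixed architecture above.

## Baselines and robustness

The conventional baselines consume log(1+·)-compressed magnitudes of the
first 128 DFT bins (DC included) of the same normalized inputs — 128 bins
comfortably cover the ≤ ~50 oscillation cycles a 1000-point window
contains. A linear-kernel SVM (`e1071`) and a 500-tree random forest
(`randomForest`) are fitted on the identical training split as the LKCNN.
The robustness experiment corrupts test series with sparse positive
impulses — by default 1% of positions, amplitudes uniform in [2, 5]× the
series range — and reports the accuracy drop per model. The corruption
family is only loosely constrained by its published description
("sparse, large-amplitude spikes"), so density, amplitude and sign are
configurable; this matters, because the drops depend enormously on the
severity. At the default severity every classifier trained on clean and
intrinsic-noise data loses most of its accuracy: ten spikes towering 2–5×
over the signal contaminate, through stride-2 kernel-28 convolutions and
max pooling, roughly a third of the CNN's feature positions, and they
perturb every Fourier bin of the baselines (a delta of height A adds
magnitude A to each bin). Reference results with far smaller drops imply a
much milder corruption than this default. The observable that survives the
severity unknowns is relative: the CNN's drop is the smallest of the three.
The experiment reports all three drops honestly rather than calibrating the
corruption until published magnitudes reappear.

## Problem sizes

Full-scale reproduction (≥ 1000 trajectories per class per level at
dt = 10⁻⁶ min, 2000-epoch training, 20 seeds × 97 kernel sizes) is a
cluster-scale computation. The package's desk scale, used by
`benchmark_suite()`, the acceptance script and the test suite, is chosen to
run end to end on one CPU: 100 parameter points per class (70 train / 12
validation / 18 test per level), five noise levels, dt = 10⁻⁴ min, at most
200 epochs with patience 30. At this scale the noiseless test accuracy
reaches the high 90s (a couple of points below the full-scale printed
figures) and the combined noisy-set accuracy lands within a few points of
its reference; the tests gate the noiseless accuracy at 95%.

## What the synthetic generator does and does not emulate

It emulates: regime-structured deterministic dynamics over three published
parameter regions, intrinsic (system-size) noise with the correct 1/√V
scaling and exact deterministic limit, 1000-point uniformly sampled
physiological-range Ca²⁺ series. It does not emulate: measurement noise,
photobleaching or drift, regime transitions within one recording,
birhythmic state switching near phase boundaries, or the indicator's
nonlinear saturation (experimental traces are converted through the
ratiometric calibration instead). Passing tests therefore certify the
method on stationary single-regime stochastic dynamics, not on every
artifact of fluorescence recordings — the impulsive-corruption experiment
probes exactly one such artifact family.

## Experimental traces

`read_trace()` ingests two-column (time, value) text files;
`grynkiewicz_convert()` applies the standard ratiometric calibration
[Ca²⁺] = Kd·(R−Rmin)/(Rmax−R)·(Sf2/Sb2) — the shipped constants are
documented placeholders, not ground truth, since published experimental
evaluations rely on per-instrument estimates; `resample_to_1000()` linearly
interpolates to the classifier's input length over the full recorded
window (no cropping). Predictions from the 8-class model are projected onto
the 3-class experimental scheme (bursting / steady state / others). Since
the curated experimental recordings themselves are external data, the
package validates this path with synthetic surrogates: generated
bursting/steady/oscillatory trajectories replayed through the trace
pipeline must classify consistently with their known labels after
projection.

## Known limitations

- Region-boundary parameter draws are rejected rather than labeled, so the
  datasets under-represent near-bifurcation dynamics by construction.
- The labeler's chaos/quasiperiodicity split rests on a Lyapunov threshold
  (0.05 min⁻¹) and a spectral incommensurability test; marginal tori and
  weakly chaotic orbits near the threshold are assigned by fiat.
- Desk-scale runs exhibit a seed-to-seed accuracy spread of several
  percentage points, driven mostly by which parameter points the seeded
  sampler draws for the thin chaotic and period-3/4 windows; full-scale
  training data averages this away. The benchmark suite fixes one seed end
  to end and reports that seed's numbers.
- The Euler–Maruyama step at 10⁻⁴ min is a weak-convergence relaxation of
  the fine-step reference; summary statistics agree between dt and dt/10 in
  spot checks, but pathwise agreement is not claimed.
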