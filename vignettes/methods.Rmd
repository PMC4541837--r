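---
title: "Methods: per-patient migraine forecasting from wearable signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: per-patient migraine forecasting from wearable signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(migrainecast)
```

# Scope and model

`migrainecast` forecasts migraine pain per patient from four ambulatory
hemodynamic channels (TEMP, EDA, HR, SpO2). The pipeline is: annotation →
symptomatic curve; multi-rate channels → synchronized 1/min frame → GP gap
repair; per-migraine N4SID identification over a (past horizon × order)
grid; cross-validated ranking; averaged best-third ensemble per feature
subset; a sensor-availability hierarchy (SDMS²); and event-based scoring.
This vignette records the modeling assumptions, the tunable parameters and
their defaults, the numerical choices, and what a passing test suite does
and does not establish.

# The symptomatic curve

A patient's signed punctual pain marks (positive when pain grows, negative
when it recedes, on an unbounded personal scale) are cumulatively summed
into a piecewise-linear profile anchored at zero at the aura start,
normalized to unit maximum. The curve model is two semi-Gaussians sharing
the peak: `exp(-(t-μ₁)²/2σ₁²)` rising, `exp(-(t-μ₂)²/2σ₂²)` falling, value
1 on `[μ₁, μ₂]`. Because the marks are relative changes, only the profile
shape is meaningful; the unbounded scale exists precisely because a patient
cannot know in advance whether the maximum has been reached, so
normalization is mandatory.

Two fitting choices were genuinely open:

* **μ placement.** Whether the shared peak sits at the annotated pain start
  or at the profile's maximum is not dictated by the annotation scheme. We
  place `μ₁ = μ₂ =` the profile's peak time — the curve is a model of
  intensity, and its maximum should coincide with the reported maximum.
* **σ estimation.** `σ₁` and `σ₂` are least-squares fits of each half
  against the profile (`method = "ls"`). For sparse marks (fewer than three
  on a half) the fallback anchor rule solves `curve = 0.05` at the aura
  start / pain end, giving `σ = Δ/√(2 ln 20) ≈ Δ/2.45`.

A profile whose final value stays above 25% of the peak is flagged
`truncated`: medicated attacks end abruptly and the decay half-width is
then an anchor-rule extrapolation, not an estimate.

# Synchronization and gap repair

Channels arrive at native rates (TEMP/EDA 1 Hz, SpO2 3 Hz, ECG 250 Hz; HR
is derived from ECG at 1 Hz). Faster-than-target channels are low-pass
filtered with a linear-phase windowed-sinc FIR (Hamming window, order ≈ 10×
the decimation factor, cutoff at the 1/120 Hz Nyquist of the 1/min target)
and sampled on the shared minute grid with the group delay compensated;
already-slow channels are linearly resampled, so a 1/min input is passed
through unchanged. The FIR order factor trades transition width against
edge loss; 10× gives ≳50 dB stopband attenuation with a transition narrow
enough that circadian-scale content is untouched.

Dropout gaps are imputed per feature by a Gaussian process with a
squared-exponential + white-noise kernel, hyperparameters fitted once per
feature by marginal-likelihood maximization on a subsample of observed
points; each gap is conditioned on up to 300 observed points within ±240
min. The posterior standard deviation is stored as a per-point confidence
band. Observed samples are never modified, and gaps longer than 120 min are
left unimputed: a stationary SE kernel reverts to the prior mean over long
gaps, and pretending otherwise would feed fabricated data to the
identifier. A feature observed at fewer than 10 grid points is declared
absent (consumed by SDMS²). The SE kernel choice is ours; the smoothness of
minute-scale autonomic trends justifies it, and the recovery property
(criterion 6 of the acceptance suite) is deliberately tested on a smooth
withheld segment — noise-dominated channels recover to the posterior mean,
which is the correct but weaker behavior.

R-peak detection for HR is Pan–Tompkins-style (5–15 Hz band-pass,
derivative, squaring, 150 ms integration, adaptive threshold with 250 ms
refractory period). The derived HR re-enters the GP repair stage like any
other feature.

# Subspace identification

The combined deterministic–stochastic N4SID scheme is implemented from
scratch (no subspace package exists in the target environment): block-Hankel
matrices with `ph` past/future block rows, oblique projection of future
outputs onto the past along future inputs, SVD truncation at order `nx`,
state-sequence least squares for `A, B, C` (`D = 0` by default, matching
the usual no-feedthrough convention for physiological outputs), innovation
covariance estimates, and a fixed-point discrete Riccati solve for the
predictor gain `K`. Numerical choices that matter:

* **Normalization.** Inputs are z-scored with training-window statistics,
  and the output is centered by its training mean. The centering is not
  cosmetic: a nonzero offset acts as an unmodeled constant input and
  injects a spurious rank into the oblique projection.
* **Stability.** `A` is eigenvalue-clipped into the disk of radius 0.98
  (k-step prediction rolls powers of `A`), and `K` is halved until the
  predictor `A − KC` is strictly stable; both events are flagged on the
  model. A mild relative ridge (1e-8) regularizes the state regression —
  the four features are readouts of a shared autonomic state and can be
  nearly collinear.
* **Feasibility.** `ph` block rows require more Hankel columns than rows;
  when a window is too short the effective row count is reduced and
  flagged, and a window too short for any realization at the requested
  order skips that grid row with a log entry, so the 200-combination grid
  (`ph ∈ {5,…,100}` × `nx ∈ {1,…,10}`) always enumerates completely.

The training fit is reported at the fixed 30-min future horizon — the
pharmacokinetically motivated target — as a *prediction* fit by default.
Whether the original protocol's training fit was a prediction fit or a pure
simulation fit is ambiguous; both are implemented (`fit_type`), and
prediction fit is the default because it is the quantity the horizon
analysis then sweeps.

k-step prediction iterates the predictor over observed data, then rolls the
state forward `k` steps with innovations set to zero and inputs held at
their last observed value (zero-order hold): at deployment time only past
data exist, so extending inputs by anything smarter would leak the future.
Raw outputs are clamped to `[−0.2, 1.2]` before probability mapping;
identification-oriented uses can disable the clamp.

# Decider, repair, ranking, ensemble

The linear decider maps the prediction linearly to a migraine probability,
`100 × clamp(ŷ, 0, 1)`, with detections open at ≥ 50%. The repair loop
removes supra-threshold excursions whose farthest supra-threshold points
span less than 60 min — unrepaired N4SID predictions oscillate around zero
between attacks, and these oscillations are too short to be migraines.
Kept events receive Marks A/B at the zero crossings of the positive
excursion. The scan window of the iteration defaults to 6 h; the loop is
idempotent, and removal can only raise the fit when the removed excursions
lie outside the true event.

A model's achievable horizon is read off its fit-vs-horizon curve as the
largest `k` before the first *sustained* (≥ 3 consecutive horizons) drop
below 70%; fit curves oscillate near the threshold, and a single dip is
noise, not loss of predictive power. Curves never reaching 70% contribute
horizon 0 and are flagged. Ranking sorts by average horizon, ties by the
minimum horizon ("ensure the higher minimums"), remaining ties by model
index — the published validation table is reproduced exactly by this rule,
and a max-horizon tie-break would contradict it. The deployed predictor
averages the top `round(M/3)` models unweighted and repairs the averaged
trace (repair applied after averaging, matching the documented order).

# Evaluation and SDMS²

An event is a true positive only if a detection overlaps it by ≥ 1 min
*and* the fit over its evaluation segment (aura − 120 min to pain end + 60
min, configurable) reaches 70%: a late or shapeless detection is a miss.
Surviving detections touching no event are false positives. With zero
detections the PPV is reported as 100% by convention (no claims, no false
claims), reproducing the published zero-TPR rows. The fault suites
overwrite a feature with 0 (loss) or its stuck-at constant (saturation:
TEMP 35 °C, EDA 25 μS, HR 100 bpm, SpO2 80%) over the whole window, purely
(copies, never mutation), and re-validate. SDMS² returns the first
hierarchy entry whose feature subset is fully available; two-feature
subsets are excluded from the hierarchy by default (their fits are
consistently lower than triads').

The real-time replay runs ensemble members in *simulation* mode —
innovations identically zero — because the measured output (pain) does not
exist at deployment time; validation, by contrast, uses the predictor form
on recorded data, as offline toolboxes do. Alarms fire on the rising edge
of the 50% threshold applied to the newest streamed prediction; an
excursion that ends before spanning 60 min is retracted and logged as a
suppressed false positive. Waiting the full 60-min span before alarming
would guarantee the alarm arrives *after* the achievable lead, defeating
the purpose, so confirmation is traded for timeliness and honesty is kept
via the retraction log.

# The synthetic patient

The generator emulates: four channels at native rates; per-channel circadian
sinusoid plus a slow random walk; a latent stable LTI state (spectral
radius 0.6, randomized per seed) excited by a pre-ictal driver — the true
pain curve advanced by `lead_time` (default 60 min) — with per-channel
readouts scaled to physiologically plausible effect sizes (TEMP +0.8 °C,
EDA +3 μS, HR +12 bpm, SpO2 −3%); intrinsic AR(1) variability at 10% of the
effect size; white measurement noise at a configurable SNR (default 20 dB);
Poisson dropout gaps; and optionally a template-based 250 Hz ECG pulse
train whose instantaneous rate follows the target HR. Events are placed in
disjoint slots (a capacity error refuses impossible requests), and
annotations are sampled from the true curve the way a patient would mark
them.

Two generator choices deserve emphasis:

* **Intrinsic variability is always on.** Without broadband content the
  four noise-free channels are smooth rank-3 readouts of the latent state;
  the input Hankel matrices are then numerically rank-deficient and
  subspace identification is ill-posed. Real autonomic signals are never
  that degenerate, so the 10% AR(1) component is part of the stated world,
  not a tuning knob.
* **Effect sizes are free parameters.** No quantitative description of
  pre-ictal hemodynamic change magnitudes exists in the literature the
  package draws on; the defaults are one-time plausibility choices. A
  green end-to-end test therefore establishes that the *pipeline* recovers
  the horizons its stated world supports — it does not validate clinical
  effect sizes, waveform morphology, or medication effects (explicitly out
  of scope).

# Protocol defaults

| Parameter | Default | Meaning |
|---|---|---|
| `split_fraction` | 0.75 | per-episode train/test split |
| `horizons` | 1–100 min | validation sweep |
| `fit_threshold` | 70% | horizon-defining similarity |
| `decider_threshold` | 50% | detection probability |
| `repair_span_min` | 60 min | minimum real-event span |
| `future_horizon` | 30 min | trained look-ahead (drug lead time) |
| `ph_grid × nx_grid` | 20 × 10 | the 200-combination search |
| `context_before_min` | 1200 | pre-attack context in training windows |
| `eval_before/after` | 120 / 60 min | fit evaluation segment |

The split rounds `n_train = round(0.75 n)`; the smaller-cohort 8/4 split of
a 12-episode patient corresponds to `split_fraction = 2/3` and is exercised
in the tests.

# Known limitations

* Linear time-invariant models only; nonlinear or time-varying
  identification is out of scope.
* The per-patient premise is untested on real humans here by construction:
  the synthetic generator shares its latent structure across "patients"
  up to reseeding.
* GP repair assumes stationary smoothness; artifacts that are themselves
  structured (motion, detachment ramps) would be imputed confidently and
  wrongly.
* The acceptance suite scales some simulations down for CPU budget (a
  thinned training grid in the end-to-end criterion); grid completeness is
  asserted separately at full size.
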