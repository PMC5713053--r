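---
title: "Methods: the mifala motor-imagery processing chain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the mifala motor-imagery processing chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mifala)
```

`mifala` classifies four-class motor-imagery EEG through a fixed chain:
band-pass → epoch → local characteristic-scale decomposition (LCD) →
one-vs-rest CSP over the ISC-augmented montage → serial feature fusion →
firefly/learning-automaton (FA-LA) wrapper selection → SRDA classification.
This vignette explains each stage's model and assumptions, the parameters
that matter, the numerical choices, and what the synthetic benchmarks do and
do not demonstrate.

## Signal model and preprocessing

Motor imagery expresses itself as event-related (de)synchronization of the
mu and beta rhythms, so all analysis happens in 8–30 Hz. Trials are filtered
with a fifth-order Butterworth band-pass. Offline the filter is applied
forward–backward (`zero_phase = TRUE`): this doubles the effective
attenuation and removes group delay, which matters because the epoch is only
one second long. A causal single-pass mode exists for parity with real-time
use, where future samples are unavailable. A 50 Hz notch is provided for
ingested recordings; the generator simulates no line noise, so it is off the
default path.

Epochs are cut 2.5–3.5 s after the cue (the most discriminative window for
this paradigm), half-open `[start, end)`, giving 250 samples at 250 Hz.
Sample indices are 1-based throughout — the natural convention for R
containers; onsets in `mi_recording` events are therefore 1-based too.

## Local characteristic-scale decomposition

LCD decomposes a channel into intrinsic scale components (ISCs): locally
monocomponent oscillations with no riding waves, obtained by repeatedly
subtracting a local mean curve ("sifting") until the iterate is balanced
about zero. The mean curve is built from consecutive extrema
$(\tau_{k-1},X_{k-1}), (\tau_k,X_k), (\tau_{k+1},X_{k+1})$: the control
value at $\tau_k$ is $a L_k + (1-a) X_k$, where $L_k$ is the straight line
joining the two neighbours evaluated at $\tau_k$ and $a$ =
`baseline_ratio` = 0.5 (the symmetric choice; values away from 0.5 bias the
baseline toward either the envelope or the signal). Control points are
joined by linear interpolation; the first and last extrema obtain neighbours
by mirror extension of the two nearest extrema.

Sifting stops when
$SD = \sum_t |h_k(t)-h_{k-1}(t)|^2 / h_{k-1}(t)^2$ falls below
`sd_threshold` (default 0.3, the conventional sifting range) or after
`max_sift_iters` = 30 passes. Samples where the previous iterate is exactly
zero are skipped — the ratio is undefined there — and counted in a
`skipped` attribute rather than poisoning the sum. Three components per
channel are extracted (`max_components = 3`); decomposition is applied to
C3, C4 and Cz, the channels most engaged by hand/foot/tongue imagery.
A signal with fewer than three extrema cannot be sifted and becomes the
residue. Conservation `x = Σ ISC + residue` holds to numerical precision by
construction and is asserted to 1e−8 over random band-limited signals.

One honest limitation: with a piecewise-linear baseline, a sifted component
can retain a small local offset, so counting its zero crossings leaves
roughly one extremum pair in twenty without a crossing. The no-riding-wave
property is therefore checked about each component's own local mean — the
form in which the condition is actually defined — where it holds with the
usual at-most-one discrepancy.

Each ISC is summarized by 20 log sub-band powers: a periodogram (single
FFT segment — with 250-sample epochs and 1.1 Hz-wide bands there is no room
for multi-segment averaging) integrated over 20 equal bands spanning
8–30 Hz, then `log10` with a power floor of 1e−12 so silent components map
to a finite floor instead of −Inf.

## One-vs-rest CSP and fusion

Per-trial spatial covariances are trace-normalized (`XXᵀ/tr(XXᵀ)`) before
averaging, making the estimate invariant to per-trial amplitude and
consistent with the normalized log-variance features. For each class, CSP is
fitted between that class and the pooled rest: the composite covariance
`R_A + R_B` is whitened by `P = ε^{−1/2}U₀ᵀ`, the whitened class covariance
is diagonalized, and `W = UᵀP`. All `N` filters per class are kept — the
fused geometry (4N spatial features) requires the full set; an optional
`m`-truncation keeps the `m` most discriminative filters from each end of
the eigenvalue spectrum. Determinism across linear-algebra backends is
enforced by sorting eigenvalues descending and flipping each eigenvector so
its largest-magnitude entry is positive. A rank-deficient composite
covariance (few trials) is ridge-repaired by `1e−10·trace/N` on the diagonal
and flagged.

The fused vector is `F = [F1, F2]`: nine frequency sub-vectors (one per
ISC, length 20) and four spatial sub-vectors (one per class, length 31),
each divided by its own Euclidean norm before concatenation. Normalization
is per sub-vector, not global, so no block dominates by scale; a zero-norm
sub-vector is an error naming the offending block. Default geometry:
9·20 + 4·31 = 304 features.

## FA-LA wrapper selection

Each swarm member is a weight vector θ ∈ [0,1]^D; feature j is active when
θ_j > 0.5 (strict). If no weight qualifies, the single largest is activated
so every member encodes a classifiable subset. Fitness is 1/CAv, the
reciprocal of SRDA accuracy on a stratified 25 % validation split held
fixed for the whole run; CAv = 0 maps to a finite penalty of 1e6. The split
lives inside the selection loop, so the test set never influences the mask.

Per generation, each member draws an absorption coefficient γ from its own
row of the transition matrix (20 levels, the uniform quantization
`{0.05, …, 1.00}` of (0,1], initialized at 1/20 = 0.05), moves toward the
incumbent best with attractiveness
$\beta(r) = \beta_{min} + (\beta_0-\beta_{min})e^{-\gamma r^2}$
plus the uniform random step α(u−0.5), is re-evaluated, and its row is
rewarded when the move improved that member's own previous fitness,
penalized otherwise (linear reward–penalty scheme, a = b = 0.1, both
branches preserving row-stochasticity exactly). Positions are clamped to
[0,1]^D. Elitism re-inserts the incumbent best over the worst member
whenever a generation loses it, so the best-fitness history is
non-increasing. Defaults follow the published swarm setting: 50 members,
β_min = 0.3, β₀ = 1, α = 1.

Two design choices deserve explanation:

* **Distance scale.** r is the Euclidean distance measured in units of the
  expected distance between two uniform random points in [0,1]^D,
  $\sqrt{D/6}$. This keeps the γ quantization meaningful in any dimension:
  typical swarm spreads sit near r ≈ 1, where γ ∈ (0,1] spans attenuation
  from $e^{-0.05}$ to $e^{-1}$. Normalizing by $\sqrt D$ alone leaves
  typical $r^2 \approx 1/6$ and compresses the whole γ range into a few
  percent of attractiveness — the parameter the automaton adapts would be
  inert.
* **Update order.** γ is drawn before the move it parameterizes, and the
  automaton is updated after the move's fitness is known. The judged
  outcome is thus causally downstream of the chosen action; comparing
  against the member's own previous-generation fitness (rather than the
  population best) keeps the reinforcement signal per-member.

On the planted-feature benchmark used in the tests, selection reliably
recovers the informative columns, but the fitness landscape turns out to be
nearly absorption-neutral: a fixed-γ sweep changes mean validation accuracy
by under one point across the whole γ range, and the learned rows stay
close to uniform. The adaptation is therefore verified as mechanism (exact
reinforcement updates, roulette fidelity, non-inferiority against a fixed-γ
ablation at identical budget) rather than as a performance gain — a
benchmark whose optimum γ varied by member or stage would be needed to show
the latter, and synthetic Gaussian feature sets do not provide one.

## SRDA and metrics

SRDA solves discriminant analysis as regression: the class-indicator
vectors are orthogonalized against the constant vector (QR), giving
`n_classes − 1` response vectors; each is regressed on mean-centered
features by ridge least squares with `alpha_reg` = 0.01 (a small
conditioning ridge; the solution approximates LDA, which the tests verify
against an explicit scatter-matrix eigendecomposition oracle). Trials are
assigned to the nearest class centroid in the discriminant space, ties to
the smallest label. Because nearest-centroid assignment is scale-invariant,
ridge shrinkage collapses the projection's magnitude without collapsing the
label geometry — heavy regularization degrades the subspace direction, not
the decision rule.

Metrics come from the confusion matrix: accuracy, Cohen's kappa
(`(p_o − p_e)/(1 − p_e)`; on balanced four-class data this coincides with
`(acc − 0.25)/0.75`, which is how the published per-subject kappas
reproduce), and per-class precision, recall and F = 2PR/(P+R), with
zero-denominator rates reported as 0 and counted in `undefined_rates`.

## The synthetic generator

`generate_synthetic_mi` emulates exactly the structure the chain exploits:
each trial of class k is unit-variance broadband Gaussian noise plus a
shared band-limited carrier (eight sinusoids at random frequencies in
8–30 Hz, random phases, unit power) loaded onto the informative channels by
a class-specific gain pattern, giving class covariance
`I + snr·g_k g_kᵀ`. Defaults — 100 trials/class, 22 channels of which 4
informative, snr = 2, 250 Hz, 1 s epochs — describe a clean, strongly
separable subject. What it does **not** emulate: non-stationarity within and
across sessions, 1/f background spectra, artifacts (EOG/EMG), volume-
conduction correlation structure among noise channels, or class-dependent
timing. Passing end-to-end tests therefore demonstrates that the chain is
implemented correctly and recovers planted structure, not that it attains
any particular accuracy on recorded EEG.

`generate_synthetic_features` plants class-dependent means (effect 1.5, a
clearly detectable but not trivial separation) in the first columns of an
otherwise standard-normal feature matrix; it grounds the selection
benchmark where ground truth for "informative" is needed.

## Problem sizes and runtime choices

The test suite and the acceptance script run at desk scale by design:
end-to-end checks use 100 trials/class with a 20-member swarm over 30
generations (three cohorts in the acceptance script, five seeds in the
acceptance test), the recovery benchmark uses 30 features over 10 (tests)
or 5 (script) seeds, and identity checks use 50 random SPD pairs and 100
random band-limited signals. These sizes were chosen so the full suite
exercises every claim in minutes while keeping Monte-Carlo noise well below
the asserted margins.

## Known limitations

* LCD endpoints rely on mirror extension; the first and last half-cycles of
  a component are less trustworthy than the interior.
* The periodogram-based descriptors have 1 Hz resolution on one-second
  epochs; finer sub-band structure is not resolvable.
* The firefly random step (α = 1) dominates late-stage refinement; the
  search behaves as a guided stochastic search around the incumbent best,
  which suits mask spaces but would stall on smooth continuous objectives.
* SRDA is linear; no kernelization or probabilistic output is provided.
* EDF/GDF ingestion is not built in: recordings must be exported to
  delimited text (`read_trials`) or constructed as `mi_recording` objects
  from any reader available in the session.
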