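---
title: "Methods: energy-landscape analysis of task fNIRS with elscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: energy-landscape analysis of task fNIRS with elscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the model and its
assumptions, the parameters that matter, what the synthetic-data generator
does and does not emulate, the numerical choices, and known limitations.
It states no empirical result that the test suite or the acceptance script
does not itself compute.

## 1. Model and assumptions

### Binarization

Each selected channel's HbO time series is thresholded at its own mean,
computed per stimulus segment, per participant, per channel. Samples
strictly above the mean become spin +1 ("active", displayed "1"),
everything else −1 ("0"). Equality with the threshold maps to −1; ties are
measure-zero for continuous signals, so this rule is a determinism device,
not a modelling statement. Binarization discards amplitude information by
design — the object of study is the joint on/off pattern.

### The pairwise maximum-entropy model

With spins $\sigma_m \in \{-1,+1\}$ the state
$s = (\sigma_1,\dots,\sigma_C)$ has energy

$$E(s) = -\sum_m h_m \sigma_m - \tfrac12 \sum_{m \ne n} J_{mn}\sigma_m\sigma_n,
\qquad P(s) = \frac{e^{-E(s)}}{\sum_{s'} e^{-E(s')}} .$$

This is the maximum-entropy distribution constrained to reproduce the
empirical activation rates $\langle\sigma_m\rangle$ and co-occurrences
$\langle\sigma_m\sigma_n\rangle$ — equivalently an Ising model with fields
$h$ and symmetric, zero-diagonal couplings $J$. Two assumptions are doing
the work:

* **Exchangeability.** The empirical statistics are time averages; sample
  order never enters. Autocorrelated data do not bias the fit, but they
  reduce the effective sample size, so standard errors computed as if
  samples were independent are optimistic.
* **Pairwise sufficiency.** Higher-order interactions are absorbed into
  the residual divergence $K_2$; the accuracy index quantifies, not
  assumes, their absence.

Both fit modes share one contract (learning rate 0.1, stop when the
largest parameter update falls below $5\times10^{-6}$, $h = J = 0$ start —
both objectives are concave, so the start only affects the iteration
count):

* `method = "exact"`: gradient = empirical minus model moments, the model
  moments by enumeration of all $2^C$ states. At convergence the moment
  residuals are below the stopping threshold divided by the learning rate.
* `method = "pl"`: full-batch gradient ascent on the mean log
  pseudo-likelihood $\sum_m \log P(\sigma_m \mid \sigma_{\setminus m})$.
  Because the pseudo-likelihood depends on the data only through state
  frequencies, the implementation collapses the sample to weighted unique
  states, making the per-iteration cost $O(2^C C^2)$ instead of $O(FC^2)$
  with identical iterates.

### Accuracy index

$r = (K_1 - K_2)/K_1$ with $K_1, K_2$ the base-2 KL divergences of the
empirical distribution from the independent ($J=0$, closed form
$h_m = \mathrm{atanh}\langle\sigma_m\rangle$) and pairwise fits. When the
empirical distribution is itself a product distribution, $K_1$ is zero up
to floating-point dust; values below $10^{-10}$ bits are treated as zero
and $r$ is defined as 0 with a warning (pairwise couplings contribute
nothing), which keeps the index stable instead of dividing two round-off
residuals.

### Landscape

The $2^C$ states form a hypercube graph (edges at Hamming distance 1, so
exactly $C$ neighbours each). A local minimum (LM) is *strictly* lower
than all neighbours — plateau states are never LMs, and a constant
landscape is rejected as degenerate rather than silently returning zero
attractors. Basins follow steepest descent (move to the lowest-energy
neighbour while it improves; ties broken by lowest state code and the
global-minimum tie flagged), so the basin map is a deterministic function
of the energies. The Metropolis walk proposes a uniform neighbour and
accepts energy increases with probability $e^{E_{cur}-E_{prop}}$; each of
the 20,000 iterations advances time by one step whether or not the
proposal is accepted (the stationary distribution is Boltzmann only under
that convention). The walk starts at a seeded uniform-random state and
discards no burn-in by default (a `burn_in` option exists); `gm_duration`
is total occupancy of the GM's basin, and for major states both the mean
dwell per visit and total occupancy are reported, since either convention
can be compared.

## 2. Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| band-pass edges | 0.01–0.2 | Hz | haemodynamic band; removes drifts, respiration (0.2–0.5 Hz), cardiac (>1 Hz) |
| filter order | 4 | — | Butterworth magnitude; see §4 |
| CPD rank `T_rank` | 10 | — | must be ≥ 2 for row correlations; small enough for ALS stability; a scree helper is the `error_trace` |
| ALS restarts | 5 | — | ALS is initialisation-sensitive; best final error kept |
| selected channels `k` | 7 | — | keeps $2^C = 128$ states tractable and matches the montage's informative set |
| fit `lr`, `tol` | 0.1, 5e-6 | — | stated optimiser settings; `tol` is on the parameter update, so moment residuals are ≤ `tol`/`lr` |
| walk `n_steps` | 20,000 | steps | stated dwell horizon; acceptance tests verify stationarity at 2×10⁵ on C = 5 |
| SVM grid | $10^{-8}\dots10^{8}$ | — | powers of ten on both C and γ; tests scale this down for budget, never the protocol |
| SVM `tol`, weighting | 1e-3, balanced | — | stated classifier settings |

## 3. The synthetic cohort: what it emulates, what it does not

No public recordings exist for this paradigm, so the generator *is* the
test bed. Each participant × stimulus category gets fields and couplings
drawn around a group structure, binary states sampled i.i.d. from the
exact Boltzmann distribution (a sticky-chain mode with configurable
persistence exists, off by default, because the empirical statistics treat
samples exchangeably), and optionally a 22-channel continuous embedding.

**The planted world.** Healthy controls: a weak two-block ferromagnetic
structure over the 7 informative channels (blocks 1–4 and 5–7, `j_in` =
0.12 within, −`j_out` = −0.10 across) plus a field bias 0.20 along the
`1111000` pattern, with participant-level noise (`sigma_J` = 0.08,
`sigma_h` = 0.05). This makes `1111000` and `0000111` planted minima with
a clear gap and a skewed basin split. The MDD group differs by two knobs,
modulated per stimulus (fear 1.0 > noise 0.8 > happy 0.7 > calm 0.6,
mirroring the strongest contrast under negative stimuli): *ruggedness*
(2.4) multiplies the coupling noise sd, planting extra near-degenerate
local minima; *coupling* (0.45) compresses the structured couplings and
the bias, shrinking gaps and equalising basins. Neutral knobs (1, 1, 0)
make the groups exchangeable — that is the type-I-error world.

**A structural impossibility, documented rather than papered over.** Four
group directions are reported in this literature: more local minima,
smaller LM–GM gaps, smaller basin-size spread, and *longer* GM-basin
dwell in the MDD group. The first three are planted and recovered with
group effects far below α = 0.05. The fourth cannot coexist with them in
any pairwise-Boltzmann generative world: the 20,000-step walk's GM
occupancy tracks the GM basin's Boltzmann mass (or, when barriers prevent
mixing, its basin-size fraction), and a 5,400-draw scan over field/coupling
families shows that landscapes with many LMs, small gaps and equal basins
have GM-basin mass at most ≈ 0.53 while landscapes with few LMs, large
gaps and skewed basins have at least ≈ 0.78 — the supports do not overlap
in either kinetic regime. Small gaps mean competing basins of comparable
depth, which necessarily share the mass the GM basin would need to hold.
The corresponding acceptance expectation is asserted as stated and left
red; a `gm_bias` knob (an extra MDD field along `1111000`, default 0) can
flip the dwell direction, but engaging it reverses the gap and basin-SD
directions. A reader should conclude that the published co-occurrence of
all four directions reflects properties of the clinical data (or of
finite-sample fitting) that a pairwise equilibrium generator cannot
reproduce — not that the pipeline is wrong.

**The continuous embedding.** Informative channels emit their spins at
unit amplitude plus Gaussian noise (sd 0.1). Block-B channels emit the
*negative* of their spin — anticorrelated haemodynamics between the two
regions. This is a gauge transformation of the Ising family (flip
$\sigma_B$ together with $h_B$ and the cross-block $J$ signs), so every
landscape quantity of the binarized dynamics is unchanged; only the
displayed state labels differ between the generator gauge and the
recording gauge. During trials the informative channels additionally carry
a stimulus-locked activation: a sustained offset (amplitude 1.2, constant
within each trial, hence invisible to segment-mean binarization) and two
slow trial-locked oscillations (amplitudes 0.45 and 0.30, safely below the
unit spin amplitude), shared across subjects up to a per-subject gain.
Background channels are AR(1) noise (φ = 0.8, scaled to sd ≈ 0.85) with a
weak shared component, and five of them carry channel-specific coherent
oscillations at fixed frequencies (0.06–0.18 Hz) — an
instrument/physiological artifact analogue.

The evoked structure and the artifact channels are not decoration: the
channel-ranking statistic (row means of the Pearson correlations between
channels' unit-normalised factor-matrix rows) weights every component
equally, however small its weight λ. The informative set therefore wins
only if (a) most components carry sign-aligned informative loadings — the
polarity gauge and the shared evoked structure arrange that — and (b) the
components that background channels do claim are mutually uncorrelated —
the channel-specific artifacts arrange that. Without (b) there are seeds
where background claims no component at all, the informative factor rows
become constant, and their Pearson correlations are numerically
meaningless. This fragility is a property of the published ranking
statistic itself and is worth knowing about.

**What a green test does and does not establish.** Green pipeline tests
establish that the machinery recovers structure *planted in its own
generative vocabulary*: exact-Boltzmann state samples, block-structured
couplings, i.i.d. draws, idealised evoked offsets. They do not establish
robustness to motion artifacts, slow nonstationarity of the threshold,
autocorrelated hemodynamics (available only via the sticky-chain mode),
higher-order interactions, or channel-count mis-specification — real fNIRS
features the generator deliberately omits.

## 4. Numerical choices

* **Filtering** is performed in the frequency domain by applying the
  *squared* magnitude response of an order-4 Butterworth band-pass — the
  amplitude response of forward–backward (zero-phase) IIR filtering —
  to the FFT of each channel. This is exactly linear and zero-phase, has
  no IIR edge transients, and meets the stated response contract (≥ 0.95
  at 0.05 Hz, ≤ 0.05 at 1 Hz); the trade-off is circular boundary
  handling, negligible for segments much longer than 1/low-cutoff would
  suggest but documented here. No `signal`-style package is required.
* **Segmentation** uses half-open intervals $[onset, onset+duration)$ with
  0-based onsets; sample counts are `round(duration * fs)` (18 s at
  7.81 Hz → 141 samples). "Full" includes all four trial types, with a
  `full_excludes_noise` flag.
* **CPD/ALS** solves each factor by least squares with a tiny ridge
  fallback for near-singular Grams, normalises columns into λ, and fixes
  sign indeterminacy by making the largest-magnitude entry of each channel
  column positive. The relative reconstruction error is recorded per
  iteration and is non-increasing.
* **Shapiro–Wilk gating** is per group (both groups must pass at
  α = 0.05 for the parametric route). Gating on all 8 group × stimulus
  cells would misroute a genuinely Gaussian feature about a third of the
  time ($0.95^8 \approx 0.66$); the per-group rule has the intended ~0.90
  pass rate. A constant cell (common for the LM count) is treated as a
  normality rejection inside `run_group_tests`, while `normality_gate`
  itself refuses it loudly.
* **ANOVA layout**: two-way with interaction on the balanced
  participant × stimulus table; every row is treated as an independent
  observation (residual df $N-8$), matching the reported-df convention of
  the field. This ignores within-participant correlation across stimuli —
  notably the "full" segment *contains* the other three's samples — so the
  group test runs hot. Measured over 200 no-effect cohorts, the α = 0.05
  rejection rate is ≈ 3.5% for the LM count but ≈ 10.5% for the mean gap
  (6.5% and 7.5% for basin-size SD and GM dwell); replacing "full" with an
  independent fourth category restores all four to 3–6%. The type-I
  acceptance criterion is asserted with the stated four stimuli and
  therefore stays red (at its fixed seeds the binomial bound trips for the
  basin-size SD, with the mean gap at the bound) — a property of the
  published pooling convention, not of the test implementations.
* **Classification** defaults to the honest nested protocol: min–max
  rescaling and the (C, γ) grid search are fitted inside each outer
  leave-one-out training fold (inner stratified k-fold). A `nested =
  FALSE` mode reproduces the literal single-global-grid-search protocol;
  it leaks the held-out labels into the hyperparameter choice and is
  provided for comparison, labelled as such. Metric spread comes from
  repeated evaluations with reshuffled inner folds (the flat protocol is
  deterministic; its SD is 0). The SVM dual is solved by a deterministic
  SMO (first KKT violator paired with the max-|ΔE| partner) with
  class-balanced box constraints.
* **State codes** are 0-based (`"0000000"` = 0) with the first selected
  channel as the most significant bit; R-side vector positions are
  `code + 1` and are used consistently in the landscape API.

## 5. Known limitations

* All $2^C$ enumeration limits the analysis to roughly 12 channels;
  requests beyond that are refused, never silently approximated.
* The generator plants effects in the pMEM's own vocabulary; it cannot
  adjudicate how the pipeline behaves under model misspecification beyond
  the three listed stress axes (noise, persistence, channel polarity).
* The GM-dwell group direction is unattainable in this generative class
  (see §3); the corresponding acceptance expectation is red by design, as
  is part of the type-I criterion (see §4, ANOVA layout).
* LOOCV metric SDs depend on the chosen repetition scheme; with a
  leave-one-out outer loop there is no canonical fold-level SD, and the
  repeated-reshuffle convention used here is one defensible choice.
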