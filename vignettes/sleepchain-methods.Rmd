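---
title: "Methods: four-state sleep-wake modelling in sleepchain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: four-state sleep-wake modelling in sleepchain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(sleepchain)
```

## The model

`sleepchain` treats a scored recording as a discrete-time stochastic
process: every 5-s epoch carries one of four behavioural states — long
wake (WKL), REM, NREM, brief wake (WKB) — and the sequence is modelled as
a first-order Markov chain with one transition matrix per circadian
phase (dark/light). The key quantities are:

- the transition probabilities `P_ij = Pr(X_{n+1} = j | X_n = i)`,
  estimated row-wise by maximum likelihood `p̂_ij = n_ij / n_i` with
  binomial standard errors `sqrt(p(1-p)/n_i)`;
- the state-maintenance probabilities `p_ii`, whose geometric-dwell
  closure `epoch_s / (1 - p_ii)` gives the mean bout duration of each
  state;
- the stationary distribution (left unit eigenvector), the long-run
  occupancy of each state.

The wake split is definitional: a wake bout strictly shorter than 150 s
is brief wake, 150 s or longer is long wake. Two structural consequences
are built in rather than estimated. First, `P(WKB -> WKL) = 0`: a brief
wake cannot become a long wake without having been a long wake all
along. Second, the per-state dwell distribution of a Markov chain is
geometric, so a *bimodal* wake-duration distribution is evidence that
"wake" is two states, not one — which is exactly what the four-state
model encodes.

First-order dependence is an assumption, not a finding; the optional
`markov_order_test()` (a first- vs second-order likelihood-ratio
diagnostic, off the main path) is provided for users who want to probe
it.

## Reference matrices and their known anomaly

`ld_transition_matrices()` ships a reference dark/light pair of 4x4
matrices at printed nine-digit precision. Rows are renormalised at
construction; a warning fires when a raw row misses 1 by more than 1e-4.
Exactly one row does: the light-phase brief-wake row sums to about
1.0090 at source precision (the dark brief-wake row closes exactly, and
the worst of the remaining rows misses by ~1e-6). Which of its cells is
wrong cannot be determined from the printed values, so the package
renormalises the row, reports it via `validate_reference_matrices()`,
and keeps quantitative validation targets away from it.

## Simulation

`simulate_hypnogram()` draws the first epoch from the stationary
distribution of the first segment's matrix (the source analysis does not
specify an initialisation; stationary start is the neutral choice), and
the matrix in force at epoch `t` governs the `t -> t+1` transition — so
the transition out of a segment's last epoch still uses that segment's
matrix, and a transition spanning the dark/light boundary is attributed
to the earlier epoch's phase (the same attribution rule used when
counting).

Internally the simulator works bout by bout: dwell in state `i` is
geometric with parameter `1 - p_ii`, and the exit state is drawn from
the off-diagonal row renormalised. This is exactly equivalent in
distribution to stepping the chain epoch by epoch (the geometric is
memoryless, so redrawing the residual dwell when the phase matrix
changes is exact) and runs in time proportional to the number of bouts:
a 2,000,000-step chain simulates in under a second.

Two modes differ in how they treat the 150-s definition:

- `matrix_faithful` uses the matrices verbatim. Dwells are unconstrained,
  so a nominal WKB state can occasionally dwell past 150 s. This mode is
  the right one for parameter-recovery work, where the estimator must see
  the chain the matrix actually generates.
- `duration_faithful` truncates dwells so every WKB bout is strictly
  shorter than the cutoff and every WKL bout at least as long, using
  analytic inverse-CDF truncated-geometric sampling (exact, no rejection
  loop). Allowances carry across phase boundaries, and a WKL bout cut
  short by the end of the recording is relabelled WKB so the labels stay
  consistent with duration-based relabelling. In this mode
  `relabel_four_state(collapse_wake(h))` reproduces the simulated truth
  exactly, which is what the staging and bout modules are validated
  against.

## Signal synthesis

`synthesize_signals()` turns a 4-state hypnogram into cortex EEG,
hippocampus EEG and EMG channels at `fs = 250` Hz. The native rate of
typical acquisition systems is higher, but 250 Hz keeps every analysis
band below Nyquist while holding a 24-h three-channel recording at
desk-scale memory; nothing in the pipeline assumes a particular rate.

Each channel is a sum of band-limited Gaussian noise components and
sinusoidal oscillators. Noise is generated per epoch in the frequency
domain (independent complex-Gaussian coefficients on the band's bins,
scaled to unit RMS) and multiplied by the state's gain; adjacent epochs
are joined by a 0.1-s linear overlap-add cross-fade so state changes do
not create discontinuities. Oscillators use a continuous phase with one
random offset per recording — an epoch-wise random phase would
reintroduce exactly the jumps the cross-fade removes — and a state-gated
amplitude faded with the same ramp.

The default model (`default_spectral_model()`) encodes the qualitative
state signatures: NREM with dominant cortical delta, spindle-band and
beta power, low gamma and low EMG; REM with strong 8-Hz hippocampal
theta and the lowest EMG; long wake with 8-Hz theta (type I), elevated
hippocampal slow/fast gamma and the highest EMG tone; brief wake with a
slower 6-Hz theta peak (type II), reduced fast gamma and intermediate
EMG. The numeric gains are package defaults chosen once so that the four
states are linearly separable in the staging feature space — they are a
test harness, not measurements. The fast-gamma band is capped at 124 Hz
(and the staging γ₂ band at 120 Hz) because the nominal 125-Hz edge sits
exactly at Nyquist for `fs = 250`.

What the generator deliberately does not emulate: real EEG morphology
(spindle events, K-complexes, sharp waves), 1/f background structure,
within-phase circadian drift, artifacts, or inter-animal variability. A
staging accuracy measured on this model is therefore an upper bound — it
shows the classifier recovers states whose spectral signatures match its
feature set, not that it matches a human scorer on real data (for which
no deposited recordings exist to test against).

## Staging

`compute_epoch_features()` computes, per epoch and band, the RMS of the
band-filtered channel, then z-scores each band across the recording's
epochs. Choices worth knowing:

- **Filter realisation.** The band filter is a zero-phase 4th-order
  Butterworth band-pass. By default its squared magnitude response is
  applied to the epoch's DFT and the RMS taken by Parseval
  (`method = "fft"`); `method = "butter"` runs literal forward-backward
  time-domain filtering of the whole channel. The two differ only by
  epoch-edge effects (they correlate at r > 0.98 on synthetic data — see
  the test suite) but the frequency-domain path is orders of magnitude
  faster, which is what makes staging a 139-h recording (100,000 epochs,
  1.25e8 samples per channel) a ~2-minute operation.
- **Z-scoring** uses the population (n-denominator) standard deviation;
  a spread at floating-point noise level is treated as constant and maps
  to all-zero z-scores. Artifact epochs — broadband RMS z above 5 — are
  excluded from the z-score fit but still transformed and classified.
- **Indices.** The θ/δ and β/γ₁ indices are computed as differences of
  z-scores (`z(θ) − z(δ)`), the bounded analogue of a log-ratio on
  standardised scales; a literal ratio on shifted-positive values is
  available via `staging_config(index_mode = "ratio")` but divides by
  near-zero denominators on standardised inputs, which is why the
  difference form is the default.

`seed_labels()` applies fixed-threshold rules (±0.5 z by default; the
threshold values are package defaults, the source procedure specifies
only that thresholds are fixed): wake = low β/γ₁, high θ/δ, high EMG;
NREM = low θ/δ, high β/γ₁, low EMG; REM = high θ/δ, low EMG. The wake
and REM rules require opposite EMG levels, so they cannot overlap;
epochs matching no rule stay unassigned.

`kmeans_refine()` then runs two deterministic K-means passes (k = 3,
Lloyd iterations, no random restarts) on the full 9-dimensional feature
space (seven band z-scores plus both indices — γ₂ enters here even
though no seeding rule uses it). Pass 1 starts from the seed-class
centroids and classifies the unassigned epochs. Thresholds are then
recalculated as midpoints between the centroids of the classes each rule
separates — EMG between the wake centroid and the higher of the two
sleep centroids, θ/δ between NREM and the lower of wake/REM, β/γ₁
per rule side. (A naive midpoint between ordered centroids fails here:
the two sleep states are nearly tied on EMG, and a threshold wedged
between them strands NREM.) The rules are re-applied with the new
thresholds and a second pass from the re-seeded centroids fixes the
definitive staging. Epoch order never enters the computation, so
permuting epochs permutes labels, and z-scoring makes labels invariant
to positive rescaling of any channel.

No post-hoc bout smoothing is applied by default; a minimum-bout merge
is available via `staging_config(min_bout_epochs = )` for users who want
it.

## Bout statistics

Bouts are maximal runs; a bout spanning the dark/light boundary belongs
wholly to its onset phase, and the first/last bouts are flagged
boundary-truncated (their true duration is unobserved). Flagged bouts
are kept by default — downstream code can filter on the flag.

The Kaplan-Meier curve is computed on the 5-s grid with no censoring
machinery: every bout ends observationally, in which case the
product-limit recursion collapses to `1 − ECDF` exactly (a property the
test suite asserts to 1e-12 over ten thousand random duration sets).
The log-rank test is the standard two-sample chi-squared form on
uncensored data, cross-checked against `survival::survdiff`.

Duration mixtures are geometric, not exponential: durations live on the
epoch grid, and the geometric is the grid-exact dwell law of a Markov
state. Components are reported with their continuous-equivalent mean
`epoch_s / q`. EM uses a deterministic quantile-split initialisation, a
500-iteration cap with a convergence flag (never an exception), and BIC
with `2k − 1` free parameters for order selection. The 150-s cutoff is
a fixed default throughout; the mixture machinery can locate a
data-driven valley, but nothing overrides the cutoff silently.

## Spectra

`epoch_psd()` computes one Hamming-windowed periodogram per 5-s epoch —
a single full-epoch window is forced by the 0.20-Hz resolution — scaled
so the one-sided bins sum exactly to the windowed time-domain energy.
State profiles z-score each frequency bin across all artifact-free
epochs of the recording (the within-animal normalisation), then average
within state; consequently the epoch-count-weighted mean of all state
profiles is zero in every bin, and a state with no usable epochs yields
an `NA` profile rather than a fabricated one. Theta peaks are the argmax
in 4–10 Hz after 3-bin moving-average smoothing, with a flat-profile
flag; EMG "tone" is quantified as 55–90 Hz band power, matching the
staging EMG band.

## Multi-animal comparisons

`compare_cells()` performs the paired per-animal dark-vs-light test per
matrix cell (paired t by default, Wilcoxon optionally), reporting raw
p-values alongside Bonferroni-adjusted ones across the tested cells —
raw first because per-cell tests at a handful of cells are how such
matrices are conventionally read, adjusted alongside because 16 cells
invite it. Pooling transitions across animals (the default elsewhere in
the package) and averaging per-animal matrices are both legitimate;
`fit_markov()` per animal plus `tidy()` feeds either workflow.

## Problem sizes and validation scales

The package's own validation (test suite plus `scripts/acceptance.R`)
uses: 2,000,000-step single-phase chains for parameter recovery
(cellwise agreement within 3 binomial standard errors) and dwell
closures; 1,000,000-step duration-faithful chains for the wake
bimodality and the dark-vs-light long-wake log-rank comparison;
a 100,000-epoch (139-h) recording for the end-to-end staging bound
(≥95% epoch accuracy against ground truth); and ~1,800-epoch recordings
for spectral sign checks (8 ± 0.4 Hz vs 6 ± 0.4 Hz theta peaks,
long-wake > brief-wake fast gamma and EMG). These sizes were chosen so
every stochastic tolerance is comfortably calibrated (standard errors
well below the effects being checked) while the whole suite stays in the
minutes range on one CPU.

## Known limitations

- Staging is validated against the synthetic generator only; its
  accuracy on real recordings depends on how well the band signatures
  and artifact model match the data, and no human-scorer correction
  workflow is provided.
- The Markov model is first-order and phase-homogeneous within each
  segment; within-phase circadian drift, semi-Markov dwell laws and
  hidden-state formulations are out of scope.
- Real-recording ingest is per-channel CSV or pre-scored hypnogram TSV;
  EDF files are not read or written.
- The light-phase brief-wake reference row carries its source's printing
  anomaly; after renormalisation its cells are good to ~1%, and nothing
  quantitative is anchored to that row.
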