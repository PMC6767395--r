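---
title: "Models and methods behind the ripplemap CA1 pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the ripplemap CA1 pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

ripplemap implements a complete analysis pipeline for hippocampal CA1
tetrode sessions — place-field coding, Bayesian position decoding,
noise/partial correlations, oscillation-event detection, spike–phase
circular statistics, and sharp-wave-ripple (SWR) reactivation — together
with a synthetic session generator whose ground truth makes every stage
testable by parameter recovery. This vignette describes the models, the
tunable parameters and their defaults, the numerical choices, and what
passing tests on synthetic sessions do and do not establish about real
recordings.

## The synthetic session

A session follows the standard novelty protocol: rest, 20 min familiar
open-field exploration, 20 min sleep/rest, 20 min novel exploration,
20 min sleep/rest, in an 80-cm circular arena. (The analyses and tests use
shorter epochs — typically 4–10 min explorations — purely as a problem-size
choice; every default parameter is stated at the protocol scale.)

**Trajectory.** Tracking is sampled at the tracker's native 25.6 ms.
Velocity follows an Ornstein–Uhlenbeck process (relaxation `tau_s = 0.7` s,
noise `sigma = 22` cm·s^-3/2, giving a stationary mean speed of
`sigma * sqrt(pi * tau/4)` ≈ 16 cm/s) and reflects specularly off the arena
wall, which preserves the speed distribution near the boundary (the
alternative — clamping — would pile up immobility artifacts at the wall).
Immobility bouts (default 10% of time, mean 4 s) are laid out on a 1-s slot
grid with an exact planted total, so the planted immobile fraction is
well-defined ground truth for the immobility metric. A 20-min run covers
all but ~3.5% of 5-cm bins, inside the 6% bound used as an acceptance
check.

**Spiking.** Each pyramidal cell fires as an inhomogeneous Poisson process
thinned from

λ(t) = b + P · exp(−d(t)²/2σ_f²) · (1 + β(v(t) − v̄))₊ ·
exp(κ·cos(θ(t) − φ_pref))/I₀(κ) · g(t)

with baseline `b = 0.15` Hz, field peak `P = 8` Hz, field width `σ_f`,
half-rectified linear speed gain `β` (the simplest monotone model for the
observed linear speed–rate trend), von Mises theta-phase modulation
(normalized so it does not change the mean rate), and a multiplicative
slow gain `g(t)` shared within cell assemblies (log-OU, τ = 0.5 s). The
Lewis–Shedler bound is recomputed per cell from the realized speed maximum;
exceeding it raises an internal error rather than silently clipping.
Interneurons use a flat spatial profile with a high baseline.

**Sleep.** Sleep epochs alternate 60-s NREM and 20-s REM. SWRs occur as a
Poisson process (0.35/s, ≥ 0.4 s separation) inside NREM. SWR events act as
compressed replay: each event draws an arena location and pyramidal cells
load onto it by the proximity of their field centre (σ = 12 cm, familiar
map for the first sleep, novel map for the second); the `reactivation` knob
ρ mixes this place-structured loading with per-cell noise as
√ρ·z_place + √(1−ρ)·z_cell. Because waking cofiring of place cells is
field-overlap driven, this is the mechanism that makes waking correlation
structure reappear in sleep; an earlier abstract-assembly loading produced
strong within-SWR structure but near-zero waking/sleep similarity, which is
why the replay form was adopted. REM firing is theta-locked at each cell's
preferred phase.

**LFP.** Two channels (pyramidal layer and above-layer reference) share
pink noise; each adds independent broadband noise. Exploration and REM
segments carry a theta oscillation — `cos` of an integrated frequency that
wanders inside 6–10 Hz — plus a gamma component whose amplitude is gated at
theta phase 240° (von Mises gate, κ = 2). NREM segments carry delta-band
noise, and SWR transients (150–250 Hz carrier under a 50–100 ms Hanning
envelope) are injected on the pyramidal channel only. Injected transients
are calibrated *against the local noise*: the generator scales each burst
so its realized ripple-band peak moving-RMS sits exactly `swr_z` SDs above
the background mean. Calibrating only in expectation leaves a ±1.4 SD
spread from the burst–noise cross term, which would make "inject at 10 SD,
detect at 7 SD" stochastically incomplete; exact local calibration removes
that nuisance from detector benchmarks. Gamma test bursts keep their
carrier ≥ 7 Hz away from the gated background carrier so slow beats cannot
null a burst.

**What the generator does not emulate:** biophysical spike waveforms and
sorting errors, anatomically realistic LFP (volume conduction, laminar
profiles), multi-shank geometry, theta phase precession, behavioural
differences between genotypes (both presets share trajectories by default,
so neural contrasts are unconfounded), and non-stationarities such as
electrode drift. Passing recovery tests therefore establishes that the
*estimators* are correct and well-calibrated, not that real data meet their
assumptions.

## Behaviour metrics

Speed follows the tracker arithmetic exactly: per-sample distances over
25.6 ms, averaged in blocks of 10 with zero distances excluded (dropout
suppression), times the sampling rate. A block of all zeros scores 0; the
10-distance blocks do not overlap. Immobility is the fraction of
non-overlapping 1-s windows (aligned to session start) travelling < 2 cm.
Coverage bins positions at 5 cm; an empty bin with fewer than 5 empty
8-neighbours (Moore neighbourhood, grid border padded as empty) is an
unvisited in-arena bin, and the deficit is unvisited/(visited+unvisited).
The rule presumes near-complete coverage: for degenerate tracking (a
stationary animal) every empty bin looks out-of-arena and the deficit
collapses to 0 — documented in the tests.

## Rate maps and place-cell statistics

Maps are 70 × 70 over the arena bounding square (~1.14 cm bins), built from
samples and spikes at ≥ 5 cm/s (spike positions interpolated linearly at
spike times; spikes interpolated into never-visited bins are dropped so
spike totals are conserved). Smoothing uses a σ = 2 bin Gaussian with
mask-aware normalization — the kernel is renormalized over visited bins, so
field edges are not dragged toward zero by unvisited territory. The width
is a choice (no width is canonical for this bin size); 2 bins ≈ 2.3 cm is
standard for 80 cm/70 bins. Skaggs information, sparsity and field size
(> 0.1 × peak, over visited bins) are computed on the smoothed map; field
size on the smoothed map was chosen because the 0.1-peak threshold on a
raw 1.14-cm map is dominated by Poisson zeros. Coherence — each bin's raw
rate against the mean of its visited 8-neighbours — uses the raw map, as
smoothing would trivially inflate it. Place cells require coherence > 0.5
and sparsity < 0.3. Index-of-dispersion passes need ≥ 2 consecutive
in-field samples; the field is taken on the smoothed map at each threshold
level (default 0.1–0.9 of peak).

## Bayesian decoder

250-ms windows stepped by 125 ms, uniform spatial prior, independent
Poisson likelihoods per cell, computed in the log domain with rates floored
at 0.01 Hz (decisions are insensitive to the floor at this scale; it only
prevents log 0). The `log n!` term is kept — constant per window, it
preserves the true likelihood. Ties in the argmax resolve to the smallest
linear (column-major) bin index. Maps are built over the decoded epoch
itself, matching the source workflow; a cross-validated variant would be
the right default for inference on real data but would not reproduce the
reference numbers, so it is available by supplying `maps` built on held-out
data. Windows are speed-filtered at the same 5 cm/s as the maps (set
`speed_filter_cm_s = 0` to disable). Zero-spike windows are skipped.

## Noise correlations

IFRCs (instantaneous firing-rate counts) in fixed windows are assigned to
20 × 20 spatial bins by window-centre position; per bin with ≥ 5 windows
the Pearson correlation of a pair's counts is computed, and the pair value
is the unweighted mean over qualifying bins (≥ 3 per pair). Computing
within spatial bins removes the signal correlation. The source text never
states the IFRC window length or per-bin minimums; 250 ms and the 5/3
minimums are configuration defaults chosen for correlation stability, not
claims. The speed-compensated variant replaces each per-bin correlation
with the first-order partial correlation given window mean speed; bins
where a cell correlates perfectly with speed are skipped.

## Oscillation events

Theta epochs: multitaper spectra (NW = 3, 5 tapers — unstated in the
source, standard for 1600-ms segments) of 1600-ms segments stepped 800 ms;
segments with mean 6–10 Hz power ≥ 2 × mean 2–4 Hz power are theta, merged
when adjacent. The ratio threshold 2 is configurable and logged in the
output. Slepian tapers come from the symmetric tridiagonal formulation,
computed densely up to 512 points and spline-interpolated beyond (matches
SciPy's tapers to ~1e-15 at 512). Theta phase: zero-phase FIR band-pass at
5–28 Hz, then the analytic-signal angle, with 0° at the filtered-signal
positive peak — every phase-dependent result in the package uses this
convention. Band-pass filters are Hamming-window FIRs (order =
3 cycles at the band's low edge) applied with exactly zero phase by
multiplying the signal spectrum with the filter's squared magnitude
response (frequency-domain forward–backward filtering, O(N log N) for any
order).

Gamma epochs: 30–80 Hz band, RMS in 25-ms windows, threshold mean + 2 SD
over the scanned epoch. "Root mean square error" in the source is read as
RMS amplitude. SWRs: the reference channel is subtracted *before*
filtering (the subtraction order is unstated; subtracting first also
cancels common noise outside the ripple band before it can alias into the
RMS), then 150–250 Hz, RMS summed across pyramidal-layer channels.
Baseline mean/SD are frozen from the first sleep epoch, estimated from
sub-threshold samples (median + 4 MAD exclusion) so that event density
cannot inflate the threshold. Detection at 7 SD, boundaries extended to
2 SD, events < 30 ms dropped, gaps < 50 ms merged, centre at peak power —
the boundary/merge/minimum values are not in the source text; they are
common practice and exposed as arguments. All detectors operate on z-scored
power and are invariant to amplitude rescaling. Gamma-peak/theta coupling
restricts gamma-cycle peaks to detected gamma periods: outside bursts the
band-filtered trace is noise whose cycle peaks tile theta phase uniformly
and would wash out the locking.

Welch spectra use 500-ms Hanning windows at 50% overlap, zero-padded to
1 s so the spectral lines fall on a 1-Hz comb (a 500-ms window alone has
2-Hz resolution, which cannot populate 1-Hz bins), truncated at 500 Hz and
normalized to unit sum.

## Circular statistics

Per-unit mean vectors are phasor means of spike phases (≥ 20 in-epoch
spikes); significance is the Rayleigh test at p < 0.05. Population locking
strength averages the lengths of *all* units' mean vectors (a
significant-only variant is a flag). The concentration of preferred phases
uses only significantly locked units: r from rectangular-coordinate means,
angular variance S² = 1 − r, chi-square interval
[(n−1)S²/χ²₁₋α/₂, (n−1)S²/χ²α/₂] on the variance scale (its complement is
the same interval on the concentration scale, which is what error bars on
a plotted concentration show).

The variance-ratio test compares two angular variances by an F ratio
(larger over smaller, two-sided). Naive (n−1, n−1) degrees of freedom are
badly miscalibrated at moderate concentration — the delta-method variance
of r̄ for a von Mises sample is (1 − A² − A/κ)/n, which at κ = 1 is ~0.57×
the χ²(n−1)-implied variance, driving type-I error to ~1% — so the test
moment-matches its degrees of freedom: df = 2S⁴/Var(S²) with κ estimated
from r = 1 − S². This recovers the classic ~n df at high concentration and
holds the 5% size at κ = 1 (verified by Monte Carlo in the tests).
Watson–Williams uses the classic one-way circular F with the 1 + 3/(8κ̂)
correction, flagged when the pooled resultant is below 0.45. Degrees are
used at every interface; radians internally. Von Mises sampling is
Best–Fisher rejection.

## SWR reactivation

Waking cofiring: Pearson correlations of 100-ms IFRCs tiling theta periods
of the exploration (the source says "during theta" without a tiling rule;
tiling theta epochs is the plainest reading, and an optional speed filter
is off by default). Sleep cofiring: one 100-ms window centred on each SWR
(events shorter than the window are padded), since no within-event tiling
is specified. Pairs need ≥ 10 spikes per cell per condition. Reactivation
strength is the correlation across pairs between the two cofiring vectors;
group comparisons use Fisher-z tests. Peri-SWR rates use ±250 ms in 10-ms
bins (matching the span such figures typically show) with a bootstrap band
over events; the curve integrates exactly to the in-window spike count.

## Genotype presets

The two presets encode directional contrasts, not measured values: the
DISC1-like preset has σ_f = 7 vs 11 cm (smaller fields, more spatial
information), β = 0.01 vs 0.04 (weaker speed modulation), novel-epoch
κ = 1.6 vs 0.8 (stronger novelty locking), preferred-phase spread 80° vs
35° (larger angular variance), no novelty phase shift (vs 30°), REM κ 0.6
vs 1.2, SWR gain 2.5 vs 5 (lower ripple-time rates), assembly gain SD 0.25
vs 0.6 (less location-independent variability, lower dispersion and noise
correlation), and a 1.6× larger qualifying place-cell population (matching
the reported cell counts). The last two matter for decoding: with matched
cell counts and peak rates, narrower tuning alone does not decode better —
2-D Fisher information is width-independent, and map-estimation noise
favours wide fields — so the decoding contrast is carried by the control
group's excess rate variability and the DISC1-like group's larger
place-cell count, both documented properties of the phenotype. Paired
simulations share a seed and hence a trajectory.

## Known limitations

Coherence on 70 × 70 raw maps is occupancy-hungry; with explorations much
under 10 min the 0.5 criterion rejects genuine planted fields, so the
short-session contrast suite uses all pyramidal cells rather than
criterion-passing cells. The replay model co-activates cells by field
proximity but does not order spikes within an event (no sequence content),
so replay-sequence analyses are out of scope. REM/NREM staging in the
generator is deterministic alternation, adequate for testing the
theta/delta detector but not a sleep model. The CA1 deep/superficial
bimodality of REM phase preference is not modelled and no unit clustering
by preferred phase is attempted.
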