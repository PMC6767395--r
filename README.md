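# ripplemap

Place-field coding, oscillation and reactivation analysis for hippocampal
CA1 recordings — with a ground-truth synthetic session generator, so every
stage of the pipeline is testable by parameter recovery without animal
data.

## Who this is for

Systems neuroscientists analysing tetrode recordings from freely moving
rodents: sorted spike trains, 2-D tracking, and local field potentials
(LFP) across exploration and sleep epochs. The package covers the standard
chain of analyses such studies run, end to end:

- **Behaviour** — movement speed from 25.6-ms tracking (zeros excluded in
  256-ms blocks), immobility in 1-s windows, arena coverage at 5-cm bins
  with an 8-neighbour rule that separates in-arena gaps from the outside.
- **Place coding** — 70×70 occupancy-normalized rate maps (5 cm/s speed
  filter, mask-aware Gaussian smoothing), Skaggs spatial information
  `sum_i p_i (lambda_i/lambda_bar) log2(lambda_i/lambda_bar)` in
  bits/spike, field-size fraction (> 0.1 × peak), sparsity
  `(sum p_i lambda_i)^2 / sum p_i lambda_i^2`, Muller–Kubie coherence, the
  place-cell criteria (coherence > 0.5, sparsity < 0.3), rate-remapping
  scores `|FR1 − FR2|/(FR1 + FR2)`, per-pass index of dispersion, and
  speed–rate correlations of 500-ms IFRCs.
- **Bayesian decoding** — `P(x|n) ∝ P(n|x) P(x)` with a uniform prior and
  independent Poisson spike counts per cell in 250-ms windows (125-ms
  step); position is the maximum-posterior bin, error the distance from
  bin centre to the animal.
- **Cofiring** — noise correlations of IFRCs within 20×20 spatial bins
  (removing signal correlation), speed-compensated partial correlations
  `(r_xy − r_xv r_yv)/sqrt((1−r_xv²)(1−r_yv²))`, and half-session
  stability with Fisher-z group tests.
- **LFP events** — theta epochs by the multitaper theta/delta (6–10 vs
  2–4 Hz) power ratio in 1600-ms segments, theta phase from a zero-phase
  5–28 Hz filter and the analytic signal, gamma epochs by 30–80 Hz RMS
  above 2 SD, SWRs by reference-subtracted 150–250 Hz power above 7 SD
  (baseline frozen in the first sleep), Welch spectra in 1-Hz bins
  normalized to unit sum, and gamma-peak-to-theta-phase coupling.
- **Circular statistics** — per-unit spike–phase mean vectors with
  Rayleigh significance, population locking strength, preferred-phase
  concentration r with angular variance S² = 1 − r and chi-square
  intervals, a moment-matched variance-ratio test for angular variances,
  and the Watson–Williams test for circular mean shifts.
- **SWR reactivation** — peri-SWR population firing (±250 ms, 10-ms bins,
  bootstrap bands) and the correlation between waking-theta and sleep-SWR
  100-ms cofiring across cell pairs.

The generator (`simulate_session`) produces full sessions — foraging
trajectories, inhomogeneous-Poisson place cells with speed gain and theta
phase locking, replay-structured SWR bursts, and a composite two-channel
LFP — under two genotype presets (`control`, `tgDISC1like`) that encode
the qualitative contrasts of a DISC1-overexpression phenotype.

## Worked example

```r
library(ripplemap)

ses <- simulate_session(ripple_preset("control"), n_pyr = 20, n_int = 4,
                        epoch_durations_s = c(rest_pre = 30,
                                              familiar_explore = 360,
                                              sleep_familiar = 180,
                                              novel_explore = 180,
                                              sleep_novel = 180),
                        seed = 42)
ses
#> ca1 session (control): 20 pyr + 4 int, 930 s, 95 SWRs

fam  <- session_epoch(ses, "familiar_explore")
pyr  <- which(ses$units$cell_class == "pyr")
maps <- lapply(ses$spike_times[pyr],
               function(s) build_rate_map(ses$tracking, s, epoch = fam))
colMeans(do.call(rbind, lapply(maps, place_cell_stats))[, 1:5])
#> spatial_info_bits_per_spike         field_size_fraction
#>                       1.374                       0.267
#>                   coherence                    sparsity
#>                       0.299                       0.280
#>                peak_rate_hz
#>                      16.201

decode_position(ses$tracking, ses$spike_times[pyr], epoch = fam, maps = maps)
#> decoder: 2419 windows, median error 8.15 cm, mean 12.31 cm

ev <- detect_swrs(ses$lfp, rbind(session_epoch(ses, "sleep_familiar"),
                                 session_epoch(ses, "sleep_novel")))
nrow(ev)                                  # 95 detected, 95 injected

ph <- theta_phase(ses$lfp)
te <- detect_theta_epochs(ses$lfp, fam)
mv <- spike_phase_mean_vector(ses$spike_times[pyr], ph,
                              epochs = iv_intersect(te, fam))
population_locking_strength(mv)
#> 0.333   (20 units, all Rayleigh-significant)
```

Reading the numbers: each cell carries ~1.4 bits of position information
per spike and its field covers ~27% of the visited arena; decoding from 20
cells localizes the animal to ~8 cm (median) against a ~36 cm chance
level; every injected 10-SD ripple is recovered at the 7-SD detection
threshold; and the population locks to theta with a mean vector length of
0.33 under the planted von Mises modulation.

The `analysis/` directory holds numbered drivers
(`01_simulate_sessions.R` … `09_preset_contrasts.R`) that run the same
pipeline narrative-style over a stored control and DISC1-like session pair
and write their tables under `results/`.

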