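---
title: "Quantifying firing regularity, synaptic input, and cholinergic cell density in striatal slices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying firing regularity, synaptic input, and cholinergic cell density in striatal slices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lciphys)
```

## The scientific problem

Striatal large cholinergic interneurons (LCIs) are tonically active
pacemakers: in healthy tissue most fire single action potentials at
0.3–3.9 Hz with remarkably regular interspike intervals (ISIs). In
Huntington's-disease model mice this regularity degrades — firing rates
stay the same, but more cells fire irregularly or in bursts — and the
leading candidate mechanism is increased GABAergic synaptic input onto
these cells. Testing that story requires several quantitative pipelines
that are usually spread across commercial tools:

1. scoring firing **regularity** from cell-attached spike trains
   (ISI statistics, spike-train autocorrelograms, a three-way
   classification),
2. detecting and summarizing **spontaneous postsynaptic currents** (PSCs)
   in voltage-clamp traces, including the tetrodotoxin (TTX) test for the
   action-potential-dependent share of events,
3. measuring **evoked responses** (earliest-component peak, charge, decay,
   paired-pulse ratio, input–output curves) and **passive membrane
   properties** from voltage steps,
4. **stereology**: Cavalieri volume, Abercrombie-corrected counts and
   neuronal density from serial sections,
5. the **group statistics** applied to all of these (Fisher exact for
   proportions, Welch t / Mann–Whitney for means, Kolmogorov–Smirnov for
   cumulative interevent-interval distributions).

`lciphys` implements all five stages as plain R functions, plus a
synthetic-data generator that emulates each input modality with known
ground truth, so every stage is testable end to end without any recording.

## Regularity scoring

`compute_isis()` returns the ISI vector, mean, sample SD (n−1), the
coefficient of variation CV = SD/mean, and the firing rate
(spike count / duration). CV is undefined with fewer than two ISIs; such
cells are flagged and excluded from group summaries.

`autocorrelogram()` bins the train into spike counts and correlates the
count series with itself at lags of 1..K bins (Pearson), excluding lag 0
(which is always 1 and carries no information). We use the *binned
spike-train* autocorrelogram rather than ISI serial correlation because
the classification criteria speak of "lag periods" and an origin peak —
properties of the spike-train autocorrelogram; an ISI serial-correlation
diagnostic is exposed separately as `isi_serial_correlation()` but plays
no role in classification.

Defaults: bin width = mean ISI/5 clamped to [10, 500] ms and maximum lag
= 5 mean ISIs. Across the 0.3–3.9 Hz range this resolves the first period
peak with ~5 bins per period and always covers ≥ 4 periods, so a periodic
cell can show the repeating peaks the "high" class requires. Fewer than
three occupied bins makes the correlogram unanalyzable and the cell is
classed "none" — the deterministic stand-in for cells that cannot be
rated by eye.

`detect_ac_peaks()` takes strict local maxima above a floor of 0.08 (the
bottom of the reported low-correlation coefficient range, 0.08–0.2).
`classify_regularity()` then applies the published rule set:

* **none** — no peaks beyond lag 0;
* **high** — first-peak coefficient > 0.2 *and* at least 3 peaks
  (repeating lag-period structure);
* **low** — everything else (coefficient ≤ 0.2, or > 0.2 with only 1–2
  peaks; the peak-count arm replaces the original visual inspection).

The 0.2 boundary is strict on both sides, matching the printed coefficient
ranges (0.203–0.8 for high vs 0.08–0.2 for low). The same 0.2 value
dichotomizes CV (`cv_class()`: low_cv ⇔ CV < 0.2), and
`frequency_cv_relationship()` quantifies the rate–CV coupling (OLS of CV
on rate plus the Pearson correlation with two-sided p) that healthy
pacemaker populations show as a strong negative correlation.

## PSC detection

The detector (`detect_events()`) is a Clements–Bekkers sliding template
fit: a unit-peak double-exponential template (defaults 2 ms rise, 20 ms
decay) is fit at every offset by closed-form least squares (scale +
offset), with two gates both set by one multiplier (default 3):

* **amplitude gate** — fitted scale > 3 × noise SD, where the noise SD is
  the MAD of *first differences* / √2 (the raw-trace MAD is inflated by
  the events themselves);
* **shape gate** — detection criterion scale/SE(scale) > 3, rejecting
  slow drifts that scale unlike the template.

Candidate onsets are prominence-filtered local maxima of the criterion
(prominence ≥ the threshold, so noise wiggles on one event's profile are
not split into extra events), merged within a 5 ms minimum interevent
interval. Because a second event inside the fit window biases the fit at
the first event's alignment, one subtract-and-redetect pass re-scans the
residual after reconstructing detected events from the template; this is
what recovers the earlier, smaller member of close pairs. Per event we
report onset, amplitude (peak minus local pre-onset baseline), 10–90%
rise time and a log-linear single-exponential decay constant; fits without
enough clean samples give `NA`, never an error.

Event summaries follow the field's reporting conventions: frequency =
count/duration; amplitude histograms in left-closed 10 pA bins starting at
10 pA (sub-threshold events counted separately so totals are conserved);
interevent-interval ECDFs compared across groups with the two-sample
Kolmogorov–Smirnov test (`compare_ecdf()` — the test is named in every
report since cumulative-distribution p-values are otherwise ambiguous),
with the "shift" direction defined by the medians; and
`percent_reduction()` for the TTX drop in frequency, whose magnitude
estimates the action-potential-dependent fraction of events.

## Evoked responses and passive properties

`measure_evoked()` reports the **earliest** baseline-subtracted local
maximum exceeding 3 × noise SD inside the analysis window — not the global
maximum — because intrastriatal stimulation typically evokes polysynaptic
responses with multiple peaks and the shortest-latency component is the
presumed monosynaptic one. Peaks are found on a 1 ms boxcar-smoothed
segment with a prominence rule (≥ 3 × noise SD) so noise bumps on a rising
limb cannot pose as an early component. Charge is the trapezoidal integral
over the window (pA·s = pC); "decay time" is not defined in common usage,
so we label our choice explicitly: the single-exponential τ fit from the
last suprathreshold peak, reported as `decay_tau`. A sweep with no
suprathreshold deflection returns `responded = FALSE`, distinct from a
zero-amplitude response.

`paired_pulse_ratio()` estimates p2/p1 with overlap handled by model-based
subtraction. We first tried the textbook mono-exponential
extrapolation–subtraction; with single sweeps at realistic noise it is
limited by fitting τ from only the inter-stimulus stretch (15 ms of decay
at the 25 ms interval) and by single-sample peak reads, and its worst-case
ratio error was ~0.2 at a peak SNR of 10. The implemented method uses
three facts about paired responses: both share kinetics, so (i) the late
tail *after* the second peak is again a single exponential with the shared
τ (fit there, where data are plentiful); (ii) response 1 over the first
interval determines the remaining kernel parameters (a bounded
Levenberg–Marquardt fit of amplitude, onset and rise, decay pinned);
(iii) the ratio is then the least-squares scale of the corrected second
window on the *model* waveform, using the response's whole energy rather
than one noisy sample. Worst-case error over intervals {25, 50, 100} ms ×
ratios {0.8, 1.0, 1.2} at SNR 10 is < 0.04, and the noise-free
overlapping case is recovered to 0.1%. The mono-exponential subtraction
remains as the fallback when the model fit fails to converge.

`passive_properties()` analyzes the standard seal-test response to a
10 mV command: steady-state current → total resistance; back-extrapolated
instantaneous jump → series resistance Rs; Rm = R_total − Rs; τ from the
transient. Capacitance comes from charge integration,
Cm = (Q/ΔV)·((Rs+Rm)/Rm)², where Q is the integral of the transient above
the steady state; the quadratic factor undoes the attenuation series
resistance imposes on the charging transient (the naive Q/ΔV
underestimates Cm by ~9% at Rs = 10 MΩ, Rm = 200 MΩ). The τ-based
estimate Cm = τ(Rs+Rm)/(Rs·Rm) is reported alongside for diagnostics.
`current_density()` is peak current over capacitance (pA/pF).

## Stereology

`cavalieri_volume()` is the Cavalieri principle verbatim: section spacing
× summed profile areas. For the correction factor we follow Abercrombie's
logic rather than any particular symbol table: a particle of height *h*
is transected by, on average, (T + h)/T sections of thickness T, so raw
profile counts are multiplied by N = T/(T + h). Our `abercrombie_factor()`
therefore takes named `thickness_um` and `diameter_um` arguments — the
formula is sometimes printed with its two symbols swapped, and with the
swapped reading the "correction" would push counts *away* from truth
(the 500-particle phantom recovers ~250 instead of 500). With h = T =
30 µm the factor is 0.5 either way. Each slice uses its own measured mean
diameter by default (a `global_diameter` switch applies one value
everywhere), and density = corrected count / Cavalieri volume.

## The synthetic-data generator

Every input modality has a generator returning data plus ground truth,
each a pure function of an explicit integer seed (Mersenne-Twister via a
local-RNG wrapper; global RNG state is never touched):

* `gen_spike_train()` — gamma renewal process with shape k = 1/CV² and
  scale 1/(rate·k), so the target rate and ISI CV are exact analytic
  properties (CV = 0 degenerates to a periodic train). "Bursting" is an
  alternating renewal process: geometric burst lengths (default mean 5
  spikes), gamma within-burst ISIs at 10 Hz (CV 0.3), exponential pauses
  (mean 1 s). No published quantitative burst criterion exists, so these
  are free knobs and the generator's labels define the class for tests.
  The first spike sits at a (seed-driven) random phase so periodic cells
  are not phase-locked across a cohort.
* `gen_psc_trace()` / `gen_ttx_pair()` — Poisson arrivals, lognormal
  amplitudes (median 25 pA, log-SD 0.3; the heavier tail matches typical
  PSC amplitude histograms), unit-peak double-exponential kernel,
  Gaussian noise, and a per-event action-potential-dependent flag;
  the TTX pair renders the same truth twice (all events vs the
  flag-negative subset) with independent noise.
* `gen_evoked_sweep()` — stimulus-locked sums of double-exponential
  components with per-component latency/amplitude/kinetics, for
  input–output and paired-pulse protocols.
* `gen_rc_step()` — the exact single-compartment seal-test waveform
  (jump ΔV/Rs decaying with τ = Cm·Rs·Rm/(Rs+Rm) to ΔV/(Rs+Rm)).
* `gen_sections()` — serial 30 µm sections of a 300 µm-radius sphere
  seeded with particles; areas are mid-plane cross-sections and counts
  follow the transect model (a particle is counted in every section its
  extent crosses), which is exactly the overcount the Abercrombie factor
  corrects.
* `gen_cohort()` — bundles all of the above into a two-group study. The
  defaults encode the study conditions: 33 control-like vs 39
  disease-like cells recorded for 300 s at 0.3–3.9 Hz; regular-class
  shares 36% vs 13%, bursting shares 6% vs 30% (rare and mild in healthy
  tissue — 3-spike bursts at 8 Hz — vs frequent 5-spike bursts in the
  disease-like group); in the control-like group CV falls with rate
  within both firing classes (regular cv ≈ 0.16 − 0.025·rate, irregular
  cv ≈ 0.9 − 0.15·rate, noise added and clamped), reproducing the healthy
  pacemaker's negative frequency–CV coupling, while the disease-like
  group draws CV independently of rate; bursting cells derive their
  inter-burst pause from the target rate so bursting does not pile up at
  one end of the rate axis; PSC rates 2 vs 3 Hz with
  action-potential-dependent fractions 0.45 vs 0.6; membrane values
  Cm 90/80 pF, Rm 200/335 MΩ; and 500 phantom neurons in spheres of 300
  vs 270 µm radius (atrophy with preserved cell number, so density
  rises).

What the generator does *not* emulate — and therefore what passing tests
do not establish about real recordings: no biophysical (conductance-based)
spiking, no electrode drift or seal instability, no correlated or 1/f
noise (noise is white Gaussian), no PSC kinetic heterogeneity within a
trace, no stimulus artifacts, and sections are perfect geometric slabs
with no tissue shrinkage or lost caps. Detector and estimator performance
on real data will be somewhat worse than the synthetic benchmarks.

## Numerical choices and degenerate inputs

* All sliding detector sums use cumulative sums and an FFT
  cross-correlation zero-padded to a 2-3-5-smooth length; detection is
  O(n log n) in trace length.
* Exact-zero noise is legal everywhere: a template that fits perfectly
  gives SE = 0 and is treated as an unambiguous detection; flat traces
  give zero events; MAD = 0 falls back to the plain SD where a scale is
  still needed.
* Decay fits are log-linear on samples above a floor (10% of peak, raised
  to ~3 noise SDs on noisy data) because the log transform is unstable
  near zero; non-convergent fits yield `NA`.
* Fisher's exact test uses the minimum-likelihood two-sided rule (sum of
  all tables in the hypergeometric support no more probable than the
  observed one, with the customary 1e-7 relative tolerance) — the most
  common convention; alternatives such as doubling the one-sided tail
  exist, which is why the rule is stated here.
* p-values are reported to 3 significant figures at presentation only.
* Repeated-measures ANOVA over input–output curves is out of scope;
  reports use per-intensity two-sample comparisons and say so.

## Problem sizes used in checks

The shipped tests and the acceptance script use 2,000-ISI trains for CV
recovery, 300 s cohort recordings, 60 s PSC traces at 2 Hz (20 seeds) for
the detection benchmark, 300 s TTX pairs, single sweeps per paired-pulse
cell, 20-seed phantoms for stereology, and 200 simulations per type-I
calibration. These sizes put Monte-Carlo error comfortably inside each
stated tolerance (e.g. SE of the empirical CV at n = 2000 is ≈ 0.016 for
exponential trains, against a 0.05 band).

## Known limitations

* The autocorrelogram classification depends on the bin-width heuristic;
  pathological rates far outside 0.3–3.9 Hz may need explicit `bin_width`.
* The detector assumes one kinetic class per trace; mixed fast/slow event
  populations would need two passes with different templates.
* `paired_pulse_ratio()` assumes the two responses share kinetics and
  latency — the usual situation for a fixed stimulation site, and exactly
  true for the generator, but not guaranteed for polysynaptic responses.
* Stereology assumes sections are complete and equally spaced; the
  Cavalieri estimate inherits any systematic area-tracing bias as-is.
* In the synthetic cohort the pooled frequency–CV correlation of the
  control-like group is directionally right (negative and usually
  significant) but weaker than in real pacemaker populations: the
  alternating-renewal bursting model produces CVs of 1.5–2.5, more
  extreme than real bursting cells, and those few points dilute the
  pooled Pearson r even when every firing class is individually coupled.
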