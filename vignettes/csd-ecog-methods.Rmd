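---
title: "Methods: CSD and epileptiform analysis of awake-mouse ECoG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CSD and epileptiform analysis of awake-mouse ECoG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csdscope)
```

## The measurement problem

Cortical spreading depression (CSD) — the slowly propagating depolarization
wave believed to underlie migraine aura — appears in DC-coupled ECoG as a
large, slow negative potential shift: a brief depolarizing deflection, a
deep trough of roughly a minute, and a slow recovery. Susceptibility is
quantified by two numbers per animal: the CSD *frequency* (events per hour
of continuous KCl application) and the *propagation speed* (electrode
distance divided by the onset-time difference of the wave between two
ipsilateral electrodes 2 mm apart, in mm/min). In FHM2 models
(heterozygous G301R mutation of the astrocytic alpha2 Na+/K+-ATPase), KCl
challenge additionally evokes generalized epileptiform activity: 0.5–4 Hz
spike discharges that begin in bouts and can escalate to continuous
activity, quantified by onset time, terminal class
(none / bouts / continuous), and a band-power severity ratio.

`csdscope` implements this measurement chain end to end, plus the
group-statistics battery used to compare genotypes and groups, and a
synthetic ECoG generator with exact ground truth so that every stage can be
validated without access to animal recordings.

## Signal conditioning

All analyses run on zero-phase Butterworth-filtered traces, second-order
sections designed in pole-zero form (an expanded polynomial at a
0.005 Hz corner on a 300 Hz trace is numerically meaningless). Two chains
are applied independently to the same raw trace:

* **DC chain** (0.005 Hz high pass, 100 Hz low pass): preserves the slow
  CSD shift. Input to CSD detection.
* **Epileptiform chain** (0.5 Hz high pass, 100 Hz low pass): removes the
  DC shift so spike transients stand out. Input to spike detection,
  severity and cross-correlation.

Zero-phase filtering is the average of the forward-then-backward and
backward-then-forward passes on an odd-reflection-padded signal; the
padding length is six decay constants of the slowest filter pole, and the
averaging makes filtering commute exactly with time reversal, so onset
times carry no filter-induced bias in either direction. Filter order
defaults to 2 per stage (effective 4th-order magnitude after the two
passes); the offline filter order is a free design choice, and any
zero-phase design meeting the attenuation checks in the test suite would
serve. When a trace's Nyquist frequency lies below 100 Hz the low-pass
stage is dropped — such a trace is already bandlimited.

Downsampling (`downsample()`) low-passes at 0.4 of the target rate with an
8th-order zero-phase Butterworth and resamples by linear interpolation,
preserving duration to within one sample.

## CSD detection

`detect_csds()` operates on the DC-chain trace:

1. An internal zero-phase 0.5 Hz low pass removes spike transients that
   ride on the DC shift (their energy is at 0.5 Hz and above; CSD energy is
   below ~0.1 Hz). This matters in escalated recordings where continuous
   spiking is superimposed on every CSD.
2. Threshold: `max(8 × MAD-spread, 2 mV)` below the baseline median. The
   spread is estimated twice: a provisional threshold masks candidate
   events (±30 s margin), and the final spread comes from the event-free
   baseline. Without this, high event rates and high-pass rebound inflate
   the estimate and shallow events are missed. Because the threshold is
   spread-relative, detection is invariant under amplitude rescaling of
   the trace; the 2 mV absolute floor guards near-flat traces.
3. Sub-threshold runs closer than 60 s merge into one event (spreading
   depression has a refractory period; two troughs a half-minute apart are
   one event), and an event must spend at least 10 s below threshold in
   total — spike transients cannot fake that.
4. Onset is the last crossing of 20% of the trough depth before the
   trough, linearly interpolated between samples; the event duration runs
   from onset to the first recovery above that level after the trough.

Frequency is counted on S1_left by default — the electrode nearest the
occipital KCl site, hence the first to register each wave; the counting
channel is configurable since the choice is not dictated by the
measurement definition. Speed uses the first event pair only, as the
headline definition requires; per-event speeds are exposed
(`per_event = TRUE`) but not used in summaries. Onset differences below
one sample raise an undefined-speed error rather than returning an
unbounded speed.

## Epileptiform analysis

Spikes are absolute deflections beyond 5 × the MAD-based spread
(consistent sigma estimate) of the epileptiform-chain trace; suprathreshold
samples cluster within a 50 ms refractory window and each cluster
contributes its largest deflection. Bouts are maximal runs of ≥3 spikes
with inter-spike gaps ≤2 s. The terminal class looks at the final 10
minutes: *continuous* requires gap-free spiking (no gap above 2 s)
spanning the whole window; anything else with spikes is *bouts*; a
recording without spikes is *none*. Onset is simply the earliest detected
spike. Severity is the mean 0.5–4 Hz Welch power density over the last 10
minutes divided by the first 10 minutes — the band mean, not a single
"dominant frequency" bin, which would be unstable at 1/30 Hz resolution.
Spectra use 30 s Hann segments with 50% overlap. Severity and onset are
read from M1_left (where activity begins); recordings aborted early (under
an hour, but at least 20 minutes) use the last 10 available minutes and
are flagged. Activity counts as *generalized* when the contralateral
channel shows spikes with onset within 60 s of the ipsilateral onset.

## Cross-correlation timing

`xcorr_coeff()` computes the normalized cross-correlogram on a signed lag
grid at 1/fs resolution, scaled so any trace's zero-lag autocorrelation is
1. Traces are demeaned first: the classic "coeff" normalization does not
remove the mean, but on high-passed traces the two agree, and demeaning
makes the coefficient invariant under per-channel gain *and* offset.
Positive lag means the first-named channel leads. Peak ties resolve to the
smallest |lag|, then to the negative lag. The analysis window defaults to
the terminal 10 minutes (where activity is strongest, matching the
severity window), with a ±2 s lag bound — generous relative to the tens of
milliseconds of real propagation lags, but a guard against secondary
peaks. A flat channel raises a QC error and excludes the subject from the
paired comparisons, mirroring bad-electrode exclusion in real cohorts.

## Group statistics

`run_study()` emits the full battery over per-subject summaries: per-group
WT-vs-G301R Mann-Whitney tests on frequency and speed; within-genotype
Kruskal-Wallis across the four groups with Dunn-Bonferroni post hocs when
significant; onset Kruskal-Wallis over pooled wild types plus the four
G301R groups (10 post-hoc pairs); regressions of severity and onset
against CSD frequency (and severity against onset) in G301R subjects only;
and paired t-tests on the three cross-correlation coefficients and their
absolute lags. All tests are two-tailed at alpha = 0.05.

Mann-Whitney reports the larger of the two U values — the convention under
which complete separation prints U = n1·n2 — with exact enumeration
p-values when n1+n2 ≤ 25 without ties (the study's group sizes all fall in
this regime) and the tie- and continuity-corrected normal approximation
otherwise. Dunn's test is the standard mean-rank z with tie-corrected
pooled variance and Bonferroni multiplication. Commercial packages print
post-hoc statistics labelled "t" on other scales; only direction and the
significance pattern are comparable across implementations, and that is
what the tests here assert. Subjects that never develop epileptiform
activity are excluded from onset tests with the count reported.

## The synthetic generator

`simulate_recording()` builds 1-hour, 3-channel, 300 Hz recordings:

* **CSD events** on the ipsilateral channels only; S1_left trails M1_left
  by distance/speed exactly (ground truth stores the operational onset:
  the 20%-of-depth crossing of the noiseless template). Inter-event
  intervals are a 60 s dead time plus a gamma(shape 8) interval —
  continuous KCl application produces quasi-periodic, not Poisson, CSD
  trains. The template (−10 mV trough, 60 s span) has a brief positive
  deflection, a steep descent, a unique trough equal to the amplitude
  parameter exactly, and a slow recovery with a mild after-depolarization.
* **Epileptiform spikes**: a master spike train (first spike exactly at
  the configured onset; within-bout intervals gamma-distributed around the
  2 Hz spike rate; bouts of ~8 s separated by ~45 s gaps; under
  `continuous` escalation, gap-free firing over the last 60% of the
  post-onset span) is copied to all three channels with fixed lags
  (S1_left +8 ms, M1_right +25 ms; M1_left leads) plus per-channel timing
  jitter (0 / 2 / 4 ms) and independent lognormal amplitude jitter. The
  jitter structure makes the S1_left–M1_right pair the least correlated at
  the group level, the direction seen in real cohorts. A linear amplitude
  ramp from 1 at onset to `severity_growth` at the end drives the severity
  ratio. The spike template is a biphasic sharp-wave/slow-wave complex
  ~250 ms long, placing its energy in the 0.5–4 Hz band.
* **Noise**: 1/f background (exponent 1), standard deviation 0.5 mV,
  giving a CSD trough SNR of ~20:1 and spike SNR of ~6:1 at the default
  amplitudes.

Group presets fix only what the biology orders: G301R above WT in rate and
speed for every group, earlier G301R onset, reduced rate in post-menopausal
G301R females (still above WT), wild types mostly bouts-or-nothing.
Magnitudes are free parameters. They were chosen *before* any acceptance
run by a summary-level power analysis: with WT ≈ 6/hr and G301R PM ≈ 8/hr
(an earlier sketch), the WT-vs-PM Mann-Whitney comparison at n = 7 vs 9 has
power ≈ 0.2 under count noise, which contradicts the complete separation
(U = n1·n2) those comparisons show in real data — so the real effects must
be much larger. The frozen values are WT 5/hr, G301R 12/hr, G301R
PM-female 8.5/hr, speeds 3.5 vs 5 mm/min, between-subject lognormal jitter
of CV 0.07 on rate (0.05 on speed, 0.25 on onset), and gamma(8) renewal
regularity. These are fixed study conditions, not tuning knobs.

What the generator does **not** emulate: electrode drift and movement
artifacts, true 2-D wave geometry (lags are constants, not a propagating
front), state-dependent background (sleep/wake spectra), amplitude
asymmetries between channels, or seizure semiology. Passing recovery tests
on this generator therefore demonstrates the correctness of the
measurement chain under its stated assumptions, not robustness to every
artifact of real recordings.

## Cohort orchestration and problem sizes

`run_cohort()` derives per-subject seeds from the master seed by a fixed
counter scheme (`(master_seed · 1000003 + 7919 · i) mod 2147483399 + 1`),
draws each subject's parameters around its group preset, simulates,
analyzes, and runs the battery; reruns are bit-identical, and the
provenance block records every seed and drawn parameter. The default
design replicates the study's cell sizes (WT 8/8/7/7, G301R 9/9/9/9;
66 subjects).

Test-suite problem sizes: detection, severity and lag-recovery checks use
20 independent full-rate (300 Hz, 1 h) recordings each. The cohort-level
calibration check runs 20 master seeds of the full 66-subject design with
the CSD stage only, simulated at 75 Hz: CSD event counts, and therefore
every rank statistic computed from them, are invariant to the sampling
rate (event times are drawn in seconds and detection operates far below
either Nyquist), so this is a pure problem-size reduction. The
type-I-error calibrations use 1000 null replicates at the study's n.

## Numerical choices and degenerate inputs

* Thresholds are MAD-based throughout (consistent sigma scaling); flat
  traces (zero spread) raise quality errors rather than detecting on
  numerical dust, and a DC-offset-dominated trace (|median| > 5 spreads)
  is rejected as unfiltered.
* Perfectly collinear regression input returns t = Inf, p = 0 (flagged)
  instead of dividing by a zero standard error; a paired test on a
  constant nonzero shift does the same, and on identical vectors raises a
  degenerate-case error.
* All-tied Kruskal-Wallis input returns H = 0, p = 1 (the tie-correction
  denominator would otherwise be 0/0).
* Correlogram peak ties (exact to 1e-12 relative) resolve deterministically
  (smallest |lag|, then negative).
* Event packing beyond the CSD refractory period truncates to dead-time
  spacing with a warning rather than overlapping templates.

## Known limitations

Onset detection reports the first *detectable* spike, which trails the
true process onset by up to a few tens of seconds when activity starts
with sparse low-amplitude spikes. The severity ratio conflates spike-band
power with any other 0.5–4 Hz nonstationarity. Speed from a single
electrode pair assumes a straight propagation path; real waves curve. The
EDF writer quantizes to 16 bits (about 0.3 µV at typical ranges) — use the
container format for lossless round trips.
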