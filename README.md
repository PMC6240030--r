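# csdscope

Analysis of cortical spreading depression (CSD) and epileptiform activity
in multi-channel DC-coupled ECoG from awake mice.

CSD — the slowly propagating cortical depolarization wave underlying
migraine aura — shows up in DC-coupled ECoG as a large slow negative
potential shift. In mouse models of familial hemiplegic migraine type 2
(FHM2; heterozygous G301R mutation of the astrocytic α2 Na⁺/K⁺-ATPase),
continuous occipital KCl application evokes CSDs at a measurable rate and,
in mutants, generalized epileptiform activity superimposed on them. The
package implements the full measurement chain used to quantify this
phenotype, for electrophysiologists who need a reproducible, scriptable
version of it:

* **Signal conditioning** — zero-phase Butterworth filtering (0.005 Hz
  high pass for the DC/CSD chain, 0.5 Hz for the epileptiform chain,
  100 Hz low pass for both), anti-aliased downsampling, EDF / delimited /
  container file I/O.
* **CSD quantification** — event detection on the DC trace with a robust
  (MAD-based) two-pass threshold; CSD frequency (events/hour) and
  propagation speed `v = d / Δt_onset` (electrode distance d = 2 mm,
  onset = last 20%-of-depth crossing before the trough), in mm/min;
  contralateral-silence check.
* **Epileptiform quantification** — spike detection (5 × MAD threshold,
  50 ms refractory), bout grouping, onset (first spike), terminal class
  (none / bouts / continuous over the final 10 min), and the severity
  ratio: mean 0.5–4 Hz Welch power in the last 10 minutes over the first
  10 minutes.
* **Cross-correlation timing** — normalized correlograms ("coeff"
  scaling, demeaned) for the three channel pairs, peak coefficient and
  signed lag (positive = first channel leads).
* **Group statistics** — Mann-Whitney U (larger-U convention, exact p for
  the study's sample sizes), Kruskal-Wallis with Dunn-Bonferroni post
  hocs, OLS slope t-tests, paired t-tests; `run_study()` emits the whole
  battery over per-subject summaries.
* **Synthetic ECoG generator** — 1-hour, 3-channel, 300 Hz recordings
  with exact ground truth (CSD onsets, spike times) emulating the eight
  genotype × group cells, so every stage is testable end to end.

## Worked example

Simulate one G301R female recording and analyze it:

```r
library(csdscope)

p   <- group_preset("G301R", "female", seed = 8)
sim <- simulate_recording(p, subject_meta("G301R", "female", "gf08"))
sim$recording
#> <ecog_recording> 3 channels x 1080000 samples @ 300 Hz (3600.0 s)
#>   channels: M1_left, S1_left, M1_right
#>   subject: gf08 [G301R, female], t0 = 0 s

s <- analyze_subject(sim$recording)
```

The summary row reproduces the simulated ground truth:

```
CSD frequency: 11 /hr (truth 11 events)
propagation speed: 5.00 mm/min (truth 5.0)
contralateral silent: TRUE
epileptiform onset: 600 s, class continuous, severity 19.4
generalized: TRUE; xcorr peaks 0.94 / 0.93 / 0.93, lags 6.7 / 26.7 / 16.7 ms
```

The 11 CSDs/hour and 5 mm/min are read off the two ipsilateral channels
(the wave never crosses to M1_right); the epileptiform activity starts at
600 s, escalates to continuous spiking, raises terminal 0.5–4 Hz power
19-fold over baseline, and appears on both hemispheres with M1_left
leading by ~7 ms (S1_left) and ~27 ms (M1_right).

Two fully separated groups give the textbook Mann-Whitney value
U = n₁·n₂:

```r
mann_whitney_u(c(3,4,5,4,6,5,4,5), c(10,12,11,13,9,14,12,11,10))
#> Mann-Whitney U: statistic = 72, df = 15, p = 0.0005833
#>     [WT male vs G301R male; n = 8, 9]
```

A full cohort (the study's design: WT 8/8/7/7, G301R 9 per group) runs
with `run_cohort(study_config(master_seed = 1))`; the report bundles every
test of the battery plus per-subject summaries and a provenance block with
all seeds and drawn parameters. A thin CLI (`inst/cli/csdscope`) exposes
`simulate`, `convert`, `csd`, `epi`, `xcorr` and `run` subcommands.

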