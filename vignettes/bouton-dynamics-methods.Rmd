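---
title: "Methods: activity and structural dynamics of axonal boutons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: activity and structural dynamics of axonal boutons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boutondyn)
```

`boutondyn` analyses longitudinal two-photon recordings of corticostriatal
axonal boutons in head-fixed mice performing a cued lever-pushing task. A
trial starts with a tone; a push that crosses a displacement threshold
(1.5 mm after the first session) within the task period is rewarded with
water (a rewarded movement, RM); sub-threshold attempts and pushes during
the inter-trial interval (ITI) are unrewarded movements (UM). The package
implements the full chain from the lever voltage trace and the ROI
fluorescence matrices to the population and structural statistics, plus a
synthetic-data generator that provides ground truth for every stage. This
vignette explains each method, its assumptions and tunables, and the
design choices made where the procedure was genuinely open.

## Movement segmentation and labelling

A movement bout starts where the lever position crosses a threshold
separating rest from movement and ends where it falls back below. Bouts
separated by less than 0.5 s are one continuous movement and are merged
(`merge_gap_s`). A bout with any other movement ending in the 3 s before
its onset is flagged `excluded` so that every analysed movement has a
clean pre-movement baseline (`exclusion_window_s`). The movement
threshold, when not supplied, is the trace median plus 3 MAD — movements
are sparse, so the median and MAD estimate the resting distribution; the
threshold is exposed because experimenters typically set it per rig.

Labels: a bout whose peak exceeds `push_threshold_mm` inside a trial's
task window `[cue, cue + task window)` is RM; a sub-threshold bout in the
task window, or any bout in the ITI, is UM. Because a trial de facto ends
at its outcome, the effective task window is truncated at the next cue.
The ITI runs from the end of one trial (reward or punishment) to the next
cue. Session metrics are the success rate (rewarded/cued trials), the
mean cue-to-threshold-crossing latency over RM trials, and UM pushes per
minute of ITI.

Conventions used throughout: times are seconds from segment start, frame
indices are 1-based in R code, windows are half-open `[start, end)`, and
seconds convert to frames by `round(t * fs)`; at 15 Hz the canonical
durations (0.33, 0.67, 0.93, 1.67, 2.33 s) are exact frame multiples.

## dF/F, event detection, and same/unique peaks

The baseline `F0` of each ROI is the 30th percentile of raw fluorescence
in a 30-s sliding window, centred on the frame and truncated at the
segment edges (a trailing window is available via `baseline_align`). dF/F
is `(F − F0)/F0` and is z-scored over the segment, so every later
threshold is in units of the segment s.d. The sliding percentile is exact
(type-7 quantile, maintained incrementally in C++) and is tested
frame-by-frame against a brute-force reimplementation.

Events are strict local maxima of the z trace above `threshold_sd`
(default 1); plateaus count once at their first frame; endpoints are never
peaks. Peak amplitude is the z value at the apex, without interpolation.

Two events on different ROIs within 670 ms are the *same peak*; unmatched
events are *unique peaks*. Matching is greedy one-to-one by ascending
time difference (ties: earlier event, then first series), which keeps the
partition deterministic and conserves counts (`n_same + n_unique = total`
per ROI). The per-bouton same-peak fraction is matched/total for that
bouton within a pair, averaged over the bouton's pairings, then over the
boutons of an axon, then over axons — the per-mouse mean. The per-pair
total is ambiguous between per-bouton and per-pair denominators; the
per-bouton reading is used because it is the one under which a generator
with a known shared fraction `s` is recovered at value `s`. Events within
0.33 s before to 0.67 s after an RM or UM onset are RM- or UM-related;
when several onset windows contain an event the nearest onset wins and
the collision is counted.

## Responsiveness classification

Per bouton, z traces are aligned to movement onsets over −1 to +3 s (the
second before onset is the baseline), separately for RM and UM. A bouton
is responsive in a condition when the peak of its trial-averaged trace in
−0.2 to 3 s minus the 5th percentile of that averaged trace exceeds 0.9
(z units — 90% of the segment s.d.; the Methods' "s.d." is read as the
s.d. of the z-scored segment, which the z-scoring makes 1). Axon-level
classification pools all axon peak responses of a mouse, takes the modal
bin (0.1-s.d. bins, ties to the lowest bin) of the RM and UM
distributions, and thresholds at the mean of the two modes, capped at 1
s.d.; with fewer than 10 axons the histogram is unreliable and the cap is
used directly. Categories follow from the two flags: `RM_only`,
`UM_only`, `both`, `unresponsive`; `RM_only` plus `both` form the
RM-responsive group. Units with fewer than `min_trials` (default 5)
usable trials in a condition are left unclassified rather than guessed.
Fate tables cross-tabulate early-stage against late-stage categories;
rows are normalised for fates, columns for origins, and empty rows are
flagged rather than propagated as NaN.

A bouton whose trial-averaged peak in reward-delay trials lags its
RM-trial peak by more than 0.93 s is delay-reward modulated (it tracks
the reward, not the movement); omission analysis reports the mean z in
1.67–2.33 s after onset for delay trials and 0.67–1.33 s for omission
trials. Cue-only and punishment-only modulation have no stated criterion
and are deliberately not classified.

## Population analyses

*Embedding.* Each bouton's trial-averaged RM and UM activity over the
−1 to +3 s window is concatenated into one column of a `2M × N` matrix
(`M` timepoints per condition, `N` boutons). PCA across timepoints gives
per-bouton scores on the first three components; scores are loadings
scaled by the component s.d. (principal coordinates), so degenerate
components collapse to the origin, and each component's sign is fixed by
making its largest-magnitude loading positive (signs are arbitrary and
must not affect distances).

*Trajectory selectivity.* PCA is fit on the continuous segment (frames ×
boutons); the first three PC time courses are cut into one trajectory per
movement onset (−1 to +3 s). The mean RM and UM trajectories are
element-wise averages of the single-trial trajectories. For a trial
trajectory, the Euclidean distance to each mean trajectory is computed
frame by frame and summed (sum versus mean does not change the index,
which is a ratio). The RM-trial selectivity index is
`(d_UM − d_RM)/(d_RM + d_UM)`; UM trials swap the roles. The index is 1
when the trial coincides with its own type's mean, −1 at the opposite
mean, 0 when equidistant, undefined only when both distances vanish.

*Curves against movement similarity.* Movement-trajectory correlations
(Pearson, on bout trajectories resampled to 64 points over −0.5 to +2 s
around onset — the window is a package choice, exposed in configuration)
bin trial pairs into the standard bins −0.2–0, 0–0.2, …, 0.8–1. Binned
against them are (a) the correlation of concatenated responsive-bouton
activity vectors per trial and (b) the activated-ensemble difference
`|a − b| / (0.5 (a + b))`, where `a`, `b` count responsive boutons with
at least one event within 3 s after each trial's onset ("activated" has
no printed definition; an event in the post-onset window is the natural
reading and the window is configurable). Empty bins are reported missing,
never as zero; pairs with zero-variance vectors or `a = b = 0` are
skipped and counted.

*Axon heterogeneity and axon pairs.* Heterogeneity is the fraction of an
axon's responsive boutons carrying the minority RM/UM label (0 =
homogeneous, 0.5 = even split, ties flagged). `both` boutons count toward
the dominant side by default (`heterogeneity_both_policy = "exclude"`
drops them); unresponsive boutons never enter the denominator. Axon-pair
Pearson correlations on the segment z traces are split at r = 0.7 into
highly and less correlated pairs.

## Structural turnover and spatial clustering

Bouton maps give per-session positions along each axon. Between adjacent
sessions, boutons present in both are persistent; gone, eliminated; new,
formed. Synthetic maps match by persistent id; maps without ids match by
greedy nearest position within 2 µm (configurable). Formation and
elimination rates share the previous-session count as denominator so the
two are comparable; density is count per µm of traced axon. Survival of a
formed cohort (boutons present at a session but absent the session
before) is the fraction still present at each later session, and is
non-increasing by construction. An entirely empty later map is total
elimination; an axon missing from one non-empty session is excluded and
reported.

*Nearest-neighbour clustering test.* Within each axon, every bouton of
interest gets the distance to its nearest neighbour (NND); values pool
across axons into an empirical CDF on a 1-µm grid. The null repositions
the same number of boutons uniformly along each axon 1,000 times
(`shuffle = "permute"` instead permutes observed positions across axons)
and rebuilds the pooled CDF each time; the pointwise 2.5/97.5 percentile
band and the range where the observed CDF exceeds the upper band are
reported. The clustering *decision*, however, is not "exceeds the
pointwise band anywhere": on a ~100-point grid that rule rejects far too
often under the null (about 22% in our calibration). The test therefore
computes, from the same shuffles, the null distribution of the largest
excursion above the pointwise band and declares clustering when the
observed excursion exceeds its 95th percentile — a max-statistic (global
envelope) correction. Calibrated this way, unclustered maps reject in
about 4% of runs while maps with 10-µm Gaussian clusters of formed
boutons are detected essentially always, with the exceedance range
covering 5–30 µm.

## The synthetic-data generator

The generator is first-class, tested code: it provides the ground truth
against which every stage is validated, under one master seed with a
named substream per generator so parts can be regenerated independently.

*Behaviour.* Trials are scheduled sequentially (cue, task window, ITI
drawn from `iti_range_s`); rewarded pushes are raised-cosine pulses
crossing the threshold with lognormal reaction times, failed attempts are
sub-threshold pulses, and ITI pushes arrive as a thinned Poisson process
with a 3.2-s minimum spacing so pre-movement baselines stay mostly clean.
At rest the lever follows an Ornstein–Uhlenbeck-like jitter (s.d. 0.04
mm, 0.1-s correlation). Reward-delay, omission, cue-only and
punishment-only trials are emitted per `trial_type_probs`.

*Activity.* Each axon draws a response category from `category_mix`; each
of its boutons conforms to the axon's category with probability
`shared_event_fraction` and otherwise re-draws from the mix. One
parameter thus couples the shared/unique event split to within-axon
category heterogeneity, which is exactly the co-variation the analysis is
meant to detect (lower unique fraction going hand in hand with lower
heterogeneity late in learning). At each compatible movement onset the
axon emits a *shared* event with probability `p_respond × s` (expressed
by the shaft and by every category-compatible bouton, with a common
amplitude); a bouton whose compatible onset carries no shared event emits
its own *unique* event with probability `p_respond (1 − s) / (1 −
p_respond s)`, so every bouton responds to a compatible onset with
probability `p_respond` and the expected per-bouton shared fraction is
exactly `s`. Movement-unlocked (`unresponsive`) units instead draw
Poisson event times, split `s : (1 − s)` between an axon-wide pool and
per-bouton events. Transients are difference-of-exponential kernels
(rise 0.05 s, decay 1.5 s, GCaMP6s-like) with lognormal amplitudes
centred on `snr` noise s.d. (sdlog 0.25); traces add temporally smoothed
Gaussian noise (independent across ROIs, 1-s correlation), a slow
sinusoid-plus-linear drift of at most 10% of baseline (so the percentile
baseline has work to do), and a positive baseline offset.

Three of these choices need justification, because the detection rule
they must support — a strict local maximum of the z trace above 1 s.d. —
is unforgiving. First, with frame-independent noise the rule is
inoperable: an expected-upcrossing argument puts thousands of
above-threshold noise maxima in any realistic segment, so the noise must
be temporally correlated (real dF/F noise is, through the indicator and
background). Second, because the trace variance is signal-dominated, the
1-s.d. threshold lands near half the median transient amplitude; a wide
amplitude distribution then leaves substantial mass near threshold, and
shared events detected on one bouton but missed on the partner bias the
same-peak fraction downward — hence the tight amplitude spread and the
common amplitude of a shared event across boutons. Third, the noise
correlation time must exceed the ripple scale of the transient's decay
shoulder, or noise riding a slow decay creates secondary above-threshold
maxima that count as spurious unique peaks; with a 1.5-s decay this
requires roughly 1-s smoothness. These are properties the generator needs for the field's standard
thresholds to behave as described; they are defaults, all exposed in
`sim_config()`.

The matcher itself constrains usable event densities: with a 670-ms
window, two *unique* events on different boutons collide by chance at
rate ≈ `1 − exp(−1.34 λ)` for partner event rate λ. Recovering a shared
fraction to ±0.05 therefore needs sparse events; the validation
experiments spread 200 events per bouton over a 2400-s recording (rate
0.08 Hz, chance-match probability ≈ 4% per unique event). At
movement-locked densities the same-peak fraction is systematically
inflated by co-responding boutons — true of the method on real data as
well — so locked-configuration comparisons are interpreted
directionally, never as absolute recoveries.

*Structure.* Session 1 places boutons uniformly; later sessions eliminate
each bouton with `p_elim` and form `Binomial(previous count, p_form)` new
ones, uniformly or around a per-axon Gaussian cluster centre
(`cluster_sigma_um`), with persistent ids and per-session-pair
formed/eliminated sets recorded as truth.

## What the generator does and does not emulate

It reproduces the statistical structure the analysis assumes: trial
timing, threshold crossings, shared-versus-unique transient composition,
category-dependent movement locking, baseline drift, and id-stable
structural turnover with optional clustering. It does not emulate pixel
data, motion artifacts, neuropil contamination, bleaching, indicator
nonlinearity and saturation, bursty amplitude correlations, or
non-Gaussian noise. Tests passing on synthetic data therefore validate
the *implementation* of the analysis rules against known truth; they do
not certify performance on real recordings, where motion and neuropil
terms violate the generator's assumptions.

## Validation scales and numerical choices

The packaged tests validate: shared-fraction recovery (50 axons × 5
boutons, 200 events/bouton, snr 8, 20 seeds at s = 0.65 and 0.80; all
estimates within ±0.05 of truth in our runs); bouton category recovery
(~30 RM and ~30 UM usable trials, snr 8; ≥ 95% accuracy); NND
calibration and power (100 seeds each, 1,000 shuffles; ~4% null
rejections, 100% detection at σ = 10 µm within 5–30 µm); exact
turnover/survival against generator truth; the early/late direction test
(unique fraction 0.35 vs 0.20 → lower heterogeneity and higher same-peak
fraction late, 20 seed pairs); and frame-exact equivalence of the
baseline and detector with brute-force reimplementations on 100 random
traces. Degenerate inputs follow fixed rules rather than erroring where a
value is representable: zero-variance correlations, empty bins, empty
fate rows and undefined ensemble differences are NA with flags;
empty-cohort survival and all-flat lever traces return empty results.

Two ambiguities were resolved as follows and are exposed in
configuration: the 3-s clean-baseline exclusion applies to the merged
bout's onset (whether it applies to a merged pair's partner is
unstated), and PCA for selectivity is fit per continuous segment with
trajectories pooled across segments of a day (per-segment fit is the only
reading compatible with fitting on "each continuous imaged segment").
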