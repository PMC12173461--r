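---
title: "Quantifying contextual fear and place-field remapping in head-fixed VR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying contextual fear and place-field remapping in head-fixed VR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fearfield)
```

## The experimental system

`fearfield` analyzes contextual fear conditioning (CFC) experiments in
head-fixed mice navigating virtual-reality (VR) linear tracks. A mouse runs
on a treadmill along a 2 m virtual corridor; completing a traversal (a
*lap*) teleports it back to the start after a brief imposed pause. One
virtual context is paired with mild tail shocks; fear memory is then read
out as *freezing* — epochs of zero treadmill velocity — when the animal is
returned to the shock-paired context versus a neutral context.
Simultaneous two-photon calcium imaging of hippocampal CA1 provides
ΔF/F traces whose spatial structure (place fields) can be compared within
and across sessions to quantify remapping after conditioning.

The package implements the complete analysis chain — behavior parsing, lap
segmentation, freezing quantification, place-field detection, remapping
statistics and the mixed-model extinction analysis — together with
seed-deterministic synthetic-data generators that carry ground truth, so
every stage is testable end to end without access to raw recordings.

## Behavioral quantification

**Freezing.** A frame is freezing when its instantaneous velocity is zero;
`detect_freezing()` exposes a tolerance `epsilon` (default 0, the faithful
definition) because real rotary encoders quantize velocity — `0.05` cm/s is
a reasonable setting for noisy logs. Freezing *epochs* are maximal runs of
freezing frames strictly longer than 1 s: at 30 frames/s a run of exactly
30 frames is not an epoch, 31 frames is. The strict reading is tested
explicitly at the boundary.

**Laps.** A lap ends on the frame where position first reaches the track
end. The 1.5 s end-of-lap teleport pause is imposed by the rig, not
behavior, so by default pause frames belong to no lap: lap durations and
per-lap freezing denominators cover behavior only. `segment_laps()` can
instead attach pause frames to the finishing lap (`include_pause = TRUE`)
for logs where that convention is wanted; whether published freezing
denominators include the pause is not documented, so both are supported and
the exclusion is the default. An incomplete traversal at the session end is
reported separately, never as a lap. Velocity is signed: backward movement
is movement (not freezing), and a lap completes only on reaching the track
end regardless of intermediate retreats.

**Session metrics.** Per-lap freezing percent is freezing frames over total
frames in the lap; the session average weighs laps equally (this is the
published formula — note it differs slightly from the frame-weighted
fraction when freezing bouts lengthen laps). First-lap metrics come from
the first completed lap. The discrimination delta is the shock-paired-
context value minus the neutral-context value; positive means correct
discrimination. Sessions with no completed lap yield undefined (`NA`)
metrics rather than zeros. Shock responses are summarized as mean speed in
a 5 s window before versus after each shock; a session is flagged
"responsive" when the post-shock speed is higher for at least two-thirds of
shocks — a QC flag only, since no published threshold exists.

## The behavior simulator

`simulate_session()` is the minimal generator matching the freezing-epoch
structure of the data: a two-state (run/freeze) Markov chain sampled per
frame, with deterministic overlays for the post-shock sprint (instant jump
in speed, exponential decay) and the teleport pause. Running frames draw a
truncated-Normal speed (20 ± 5 cm/s by default, giving 4–5 laps/min —
comfortably above the >3 laps/min training criterion); freezing frames have
velocity exactly zero. The chain keeps the analytic stationary freezing
fraction `p_rf / (p_rf + p_fr)` available for tests, and
`freezing_rates()` inverts it given a target fraction and a mean bout
length (default 2 s, a realistic freezing-bout scale). Rates are held
constant within a session: the source experiments report no within-session
extinction time-course, so modeling one would add unverifiable structure.

`simulate_cohort()` reproduces the three experimental designs: Paradigm 1
(trained Familiar context + novel shock context, conditioning with six 1 s
shocks at 60 s intervals), Paradigm 2 (two novel contexts with a Day −1
habituation), and Paradigm 3 (shorter 22.5 s inter-shock intervals and the
tail-coat worn during recall). Exploration sessions last 10 min and recall
tests 10 min per context, matching the published protocol. Context order on
recall days alternates with mouse parity (counterbalancing). Recall-day
freezing targets are `baseline + effect` in the shock-paired context
(defaults 16% and +8 points, the magnitudes reported for recall day 1) with
between-mouse sd 5 and within-pair sd 4 percentage points. The latent pair
sd was set so that the *realized* sd of per-mouse context differences —
latent variability plus the sampling noise of estimating freezing from a
10-min session — is ≈ 8–9 points, comparable to what the published group
statistics imply. Shock metadata (intensity in mA, intervals) is carried as
session parameters but only the sprint response is simulated.

What the generator does *not* emulate: acquisition dynamics during
conditioning, lick microstructure, slow drifts in running speed, or
video-scorable postures. Tests passing on this generator therefore validate
the estimators' correctness and calibration, not robustness to every
artifact of real recordings.

## Spatial maps and place-field detection

`bin_activity()` divides the 2 m track into 40 bins of 5 cm (half-open
intervals, the last closed at 200 cm) and averages each cell's ΔF/F per
lap and bin over running frames only: frames with |velocity| < 1 cm/s are
excluded, so spatial coding is estimated from active exploration and never
from freezing bouts. Lap/bin combinations without an included frame are
unobserved (`NA`), not zero.

`detect_place_fields()` accepts a candidate field only if all four criteria
hold:

1. the session-mean ΔF/F in the candidate bins exceeds the cell's baseline
   by more than 10%. The baseline is the 20th percentile of the cell's
   40-bin mean map — the criterion's "baseline" is not defined precisely in
   the source, and a low map quantile is robust to the field's own
   occupancy of the map; it is configurable, and the threshold is
   `baseline + 0.10 |baseline|` so that it degrades sensibly for
   near-zero baselines;
2. the cell shows significant calcium transients on strictly more than 30%
   of laps inside the field during running (reliability);
3. the rising flank of the spatial profile begins on the track: candidates
   touching the first bin — where the teleport deposits the animal and a
   rise cannot be observed — are rejected. The source describes this
   criterion temporally without a recipe; the spatial operationalization
   rejects exactly the boundary-truncated profiles it is meant to exclude;
4. a bootstrap p-value below 0.05 (below).

Multiple candidate fields in one cell are evaluated independently;
rejections carry the first failed criterion. All four criteria are ratio-
or rank-based, so detection is invariant to multiplicative rescaling of a
cell's trace (tested).

**Transients.** Calcium transients are detected with a dual-threshold
(hysteresis) rule: an event is a maximal run above a low offset threshold
(0.5 σ above baseline) containing at least one frame above the high onset
threshold (2 σ); its onset is the first frame above the high threshold.
The per-cell noise σ comes from sub-baseline residuals mirrored about the
median, floored at 1/20 of the trace's dynamic range so that noiseless or
near-noiseless traces (whose sub-baseline residual vanishes) still get a
meaningful threshold. Two numerical choices matter here. First, hysteresis rather than a
single threshold: near-threshold noise dips split genuine transients into
fragments and destroy duration filtering. Second, the minimum event
duration is 0.25 s: a fast-indicator transient with 0.5 s decay stays above
a 2 σ threshold for only `ln(SNR/2) × 0.5` s — about 0.35–0.46 s at
SNR 4–5 — so demanding 0.5 s would reject genuine events outright, while
0.25 s (8 frames) keeps suprathreshold noise runs vanishingly rare (the
null false-event rate stays far below 0.02 events/s; tested).

**Bootstrap null.** The significance test rotates each lap's bin vector
independently by a uniform random circular offset, preserving within-lap
autocorrelation while destroying across-lap spatial alignment. The
statistic is the mean ΔF/F over in-candidate (lap, bin) entries minus the
out-of-candidate mean; the p-value uses the add-one estimator
`(1 + #{null ≥ observed}) / (1 + n_shuffles)`, so p is never zero and the
smallest attainable value is `1/(n_shuffles + 1)`. The published analysis
names bootstrapping without specifying the null; this one is documented,
swappable, and — the pipeline's core statistical guarantee — calibrated:
on spatially untuned synthetic cells the rejection rate at p < 0.05 lies in
[0.03, 0.07] (tested on 1000 cells). The default shuffle count is 1000;
the tests and the acceptance script use 200, which makes the smallest
attainable p ≈ 0.005 and keeps the suite inside its runtime while leaving
the calibration property intact.

**Field parameters.** COM is the activity-weighted mean position over the
field's bins. Width is the contiguous extent around the field peak where
the mean profile stays at least 25% of (peak − baseline) above baseline,
linearly interpolated between bin centers and clamped below at one bin
width. The out/in-field firing ratio divides the mean ΔF/F outside the
field bins by the mean inside (negative outside means clamp to zero).
For a Gaussian tuning curve of sd σ the 25% width is `2σ√(2 ln 4)` ≈
3.33 σ, which is what the recovery tests observe.

## The calcium simulator

`simulate_traces()` gives place cells Gaussian spatial tuning: on each lap
where the cell activates (per-lap Bernoulli with probability
`reliability`), its noiseless signal is the tuning curve evaluated at the
animal's position, peaking at `amplitude` at the field center. The spatial
profile is modeled directly rather than as a triggered event with a causal
calcium tail: a transient fired at the field crossing and decaying only
forward in time would displace the apparent COM downstream by roughly
`run_speed × tau` ≈ 10 cm at defaults, which would contradict the exact
COM/width ground truth that the recovery tests rely on. The
instant-rise/exponential-decay kinetics (tau 0.5 s, fast-indicator-like)
are instead carried by the discrete background transients of non-place
cells, whose Poisson event rate per lap is matched to the place cells'
activation rate so that detection cannot separate the populations by event
rate alone (tested within 10%). Gaussian white noise is added throughout;
nominal SNR is `amplitude / noise_sd`.

`simulate_two_sessions()` models across-day comparisons: session 2 copies
session 1's tuning except that a chosen fraction of place cells draws new
centers uniformly on the track (no displacement law is reported, so
remapped centers are independent of old ones) and all tuning widths are
multiplied by `width_scale_session2` (< 1 models across-day narrowing).
The returned identity cell map stands in for the image-alignment-based
cell matching of a real experiment, which the package consumes as input
and never computes.

## Remapping statistics

`split_half_correlation()` is the stability control: the Pearson
correlation between mean spatial profiles of the first and second half of
laps (the extra lap of odd counts goes to the first half; cells need at
least 4 laps). `across_session_correlation()` correlates matched cells'
session-mean profiles, restricted — as in the published design — to cells
holding an accepted field in the reference session; COM pairs use the
reference field's bins in both sessions. Pearson is the default
(the source says only "correlation coefficients"); Spearman is available.
Bins unobserved in either profile are dropped pairwise, and pairs with
fewer than 10 common bins are undefined. Distribution comparisons use the
two-sample KS test.

`compare_field_populations()` performs the across-day parameter
comparison (width, reliability, out/in ratio) at the *mouse* level:
per-mouse means enter a paired t-test across mice, avoiding
pseudoreplication from pooling cells, while pooled per-cell medians are
reported descriptively to mirror the published panels. With one mouse only
descriptives are produced.

## The statistical layer

Paired comparisons use the two-sided paired t-test with t-based 95%
confidence intervals. The paired effect size defaults to
d_z = mean(diff)/sd(diff) — the variant is not named in the source, and
d_z is the natural within-subject choice; d_av is available by option.
Bonferroni correction is `min(1, p m)` with `m` allowed to exceed the
number of supplied p-values. The extinction model is
`freezing_pct ~ day + (1 | mouse_id)` per context, with the
pre-conditioning Day 0 session as reference, fitted by REML via `lme4`;
p-values are Wald normal approximations, since the published tables name
neither the estimation method nor the p-value recipe — likelihood-ratio or
Satterthwaite p-values would differ slightly in small samples. Singular
fits are flagged but still report estimates.

## Problem sizes, determinism and runtime choices

All randomness flows from explicit integer seeds; identical parameters and
seed give byte-identical sessions, traces, bootstrap p-values and pipeline
outputs (`run_pipeline()` writes a manifest with the seeds and a config
hash so a run can be reproduced exactly). The verification suite uses these
problem sizes, chosen to exercise the study-scale conditions:
27-mouse paradigm-1 cohorts with recall freezing 24% vs 16% for behavioral
power (200 replicates); 1000 untuned cells for bootstrap calibration; 90
place cells (30 per tuning width 5/10/20 cm, SNR 5, reliability 0.8, ~30
laps) for parameter recovery; 200 matched cells for remapping
discrimination; 50 replicate cohorts of 8 mice × 100 cells at width scale
0.7 for narrowing detection; and 100 replicate fits for LME recovery.
Imaging sessions in the replicate cohorts run ~16 laps — enough for the
reliability criterion and split-half stability while keeping the full
suite fast.

## Known limitations

- The simulator's freezing process has no within-session extinction and no
  shock-acquisition dynamics; it validates estimators, not learning models.
- Per-lap freezing percent (the published formula) is a mean of ratios; it
  differs by a few points from the frame-weighted freezing fraction when
  long freezing bouts lengthen laps, and estimates of it from a single
  session carry several points of sampling noise.
- The bootstrap null and the transient-significance recipe are documented
  reconstructions; the source defers both to prior work without formulas.
- Cross-session cell identity is consumed as an input map; no image-based
  matching is performed.
- The published headline values (group freezing percentages, Cohen's d,
  LME tables) are statistics of the study's deposited dataset; without that
  download the package verifies the machinery on simulations that emulate
  those magnitudes rather than reproducing the printed numbers.

## A worked example

```{r example, eval = FALSE}
co <- simulate_cohort(1, n_mice = 8, effect = 8, seed = 1)
met <- cohort_metrics(co)
r1 <- subset(met, day == 1)
paired_test(r1$avg_freezing_pct[r1$context_role == "cfc"],
            r1$avg_freezing_pct[r1$context_role == "neutral"])

p <- behavior_sim_params(session_duration = 300, seed = 2)
beh <- simulate_session(p)
cp <- calcium_sim_params(60, frac_place_cells = 0.4, seed = 3)
tr <- simulate_traces(beh$session, cp)
fields <- detect_place_fields(tr$dff, beh$session, n_shuffles = 1000,
                              seed = 4)
place_cell_fraction(fields)
```
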