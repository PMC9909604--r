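---
title: "Movement metrics and energy expenditure: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Movement metrics and energy expenditure: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(movemetrics)
```

## The problem

Clinical trials in neuromuscular disease need objective, continuous measures
of upper-limb motor function. Wrist-worn smartwatches carry inertial sensors
(triaxial accelerometer and gyroscope) that can quantify arm movement in
daily life, but the derived metrics must first be validated against a
physiological reference. The reference used here is whole-room indirect
calorimetry: a subject performs a standardised protocol of slow arm
exercises inside a metabolic chamber while the watch records at 20 Hz, and
the chamber measures energy expenditure (EE) from gas exchange at its
~10-minute effective resolution. movemetrics implements the full analysis
chain from raw sensor CSV exports to the statistics that relate movement
intensity to the energy cost of movement, together with a synthetic-data
generator so the chain can be validated end to end with known ground truth.

## The movement pipeline

**Magnitude extraction.** The device reports user acceleration (gravity
removed, m/s²) and rotation rate (rad/s) on three axes. Each triaxial
sample is collapsed to its Euclidean norm. The norm is invariant under any
rigid re-orientation of the watch on the wrist, which per-axis analyses are
not; this also matches reporting movement intensity as a single scalar per
channel. Whether a dominant-axis convention would behave differently is an
open question we resolve in favour of the norm.

**Onset detection.** Recordings begin when the subject starts the app, not
when movement starts, so each trace is aligned to the onset of rhythmic
movement. A centred moving RMS of the acceleration magnitude (window =
`sustain`, default 2 s) is compared with `k` (default 3) times a baseline
level estimated from the first `baseline_window` seconds (default 5 s).
Two refinements make the detector well-defined on degenerate inputs:

* The baseline level is the 10th percentile of the moving RMS inside the
  baseline window rather than the window's plain RMS. For burst-like
  movement that starts at the first sample, the moving RMS dips to the
  sensor noise floor between bursts; the low quantile recovers that floor,
  whereas the plain RMS would equal the signal level and the criterion
  could never fire.
* A series whose baseline window is already at movement-level intensity
  (RMS at least `min_active`, default 1 m/s² — well above wrist sensor
  noise, below deliberate arm movement) is taken as already moving and
  gets onset 0. This covers continuous ergometer cranking, which has no
  quiet floor at all; a purely relative criterion cannot trigger on a
  signal that never was quiet.

The reported onset is the right edge of the first sustained window (the
earliest time by which the trailing `sustain` seconds were above
threshold), which in simulation lands within half a second of the true
movement start. If the criterion is never met the trace is skipped and the
failure enumerated in the run report; a manual onset override is available
per trace. One failing subject does not abort a cohort run.

**Uniform window.** All exercises are trimmed to 500 s (8 min 20 s, the
shortest execution in the standard protocol) from onset: 10,000 samples at
20 Hz, partial final sample dropped. Summaries use the sample standard
deviation (n − 1) and CV = SD/mean; a CV over a non-positive mean is
reported as `NA` with a warning.

## Activity counts

The acceleration magnitude is reduced to one value per non-overlapping
1-s epoch and compared against a threshold T:

* **total** counts epochs with value > T,
* **medium** those with value > 2T,
* **low** is the remainder, i.e. values in (T, 2T].

Two conventions here are interpretations fixed by this package. First, a
literal reading of "low = above T, medium = above 2T" would make low a
superset of medium; we implement the tiers as a partition because the
published cohort means satisfy total = medium + low exactly. Second,
comparisons are strict (> not ≥), so a constant series yields zero counts
under its own variable threshold (mean + 2·SD of a constant equals the
constant).

The free rhythmic exercises (1–3) use a **variable threshold**,
mean + 2·SD computed on the same trimmed 500-s window being counted, per
subject and exercise; this adapts to each subject's noise and intensity
level. The mechanically guided ergometer exercise (4) uses a **fixed
threshold** of 0.05 m/s², appropriate because its signal has essentially
no noise floor to adapt to. The per-epoch reducer is the epoch **peak** by
default (selectable to the epoch mean): with one movement every 4 s and a
mean + 2·SD threshold, peak reduction is what makes an epoch containing a
burst count as active, giving occupancy fractions on the scale of a few
hundred of the 500 epochs rather than nearly zero.

## Energy expenditure

Oxygen consumption in mL/min is converted to kcal/min as
(VO₂ / 1000) × 4.867 kcal per litre of O₂. Note the mL→L step is a
*division* by 1000; descriptions of this conversion sometimes state it as
a multiplication, which is dimensionally inverted. kcal are converted to
kJ with the thermochemical factor 4.184.

The chamber session is modelled as contiguous 10-min blocks following the
standard template: 30 min air equilibration, 30 min rest, then for each of
the four exercises (in the session's randomised order) 10 min of exercise
followed by 10 min of complete rest — 140 min in all. No sub-block
interpolation is attempted; the chamber's temporal resolution is a hard
floor of the method.

ΔEE for exercise k is its block EE minus a resting reference. Whether the
reference should be the immediately preceding rest/pause block or the
initial 30-min resting phase is genuinely ambiguous; both pairings are
implemented (`preceding_rest`, the default, and `session_rest`) and the
one used is recorded in the report. ΔEE may legitimately be negative.
Within-subject exercise comparisons use paired t-tests; the fasted versus
non-fasted contrast uses an unpaired two-sided t-test on ΔEE per exercise.
Associations between ΔEE and each movement metric (mean acceleration, mean
rotation rate, total counts) are reported both as Spearman rank
correlations (large-sample t approximation for p; exact distribution
available for small tie-free samples) and as ordinary least-squares
regressions, side by side, because both appear in practice for this kind
of validation. A flat α = 0.05 is used with no multiple-testing
correction; the report states how many tests were run so a reader can
judge the family-wise risk themselves.

## The synthetic-data generator

The generator emulates the study conditions, not arbitrary data:

* **Rhythmic exercises (1–3):** one raised-cosine acceleration burst per
  metronome beat at 15 movements/min, burst width ~1 s (per-subject
  U(0.8, 1.6) s — movement speed is left free in the protocol), each burst
  in a fresh random 3-D direction with lognormal amplitude jitter
  (sdlog 0.3), over Gaussian per-axis sensor noise. Per-subject burst
  amplitudes are lognormal with median 12 m/s² and per-axis noise SD is
  U(0.2, 0.5) m/s²; these place per-exercise cohort-average window means
  in the 1.5–3.5 m/s² band typical of slow upper-limb exercise. The
  rotation channel is built analogously (median 10 rad/s).
* **Ergometer (exercise 4):** circular crank motion at a per-subject
  cadence U(40, 45) rpm — sinusoidal per-axis acceleration at cadence/60
  Hz in a fixed random plane, magnitude ~N(3.2, 0.4) m/s² with 10%
  relative jitter. The magnitude series is nearly constant, reproducing
  the much lower CV of machine-guided movement.
* **Chamber:** resting EE ~N(5.0, 0.7) kJ/min, exercise blocks raised by
  the per-subject true increments, independent Gaussian noise per 10-min
  block (default SD 0.2 kJ/min).
* **Coupling (ground truth):** each subject's true ΔEE for exercise k is
  `coupling_slope × expected_counts_k` plus a subject-level Gaussian
  deviation (default SD 0.6 kJ/min, matching the wide between-subject
  spread seen in slow-exercise calorimetry). The *expected counts* are
  computed by running the deterministic noise-free twin of the trace — the
  latent burst envelope each trace carries as an attribute — through the
  same counting chain; they are therefore a pure function of the subject's
  movement parameters, not of the sensor noise. The default coupling slope
  of 0.005 kJ/min per count yields increments of roughly 0.5–2.5 kJ/min
  across exercises, the order of magnitude expected for slow arm movement.

All distribution defaults live in `config/generator_defaults.yaml` inside
the package and are overridable through `cohort_params()`. Generation is
fully deterministic under a fixed seed, with no time-dependent state.

What the generator does **not** model: autocorrelated sensor noise,
biomechanically realistic joint kinematics, gravity leakage into user
acceleration, postural transitions, or disease-specific movement patterns.
Real wrist data are also far less silent between movements than the
raised-cosine archetype, so real magnitude CVs will be lower than
synthetic ones. Passing tests therefore demonstrate that the *pipeline
arithmetic and statistics* are correct and well calibrated, not that any
particular physiological effect size will be observed in patients.

## Numerical and design notes

* Epoch partitioning drops a trailing partial epoch; window trimming drops
  a partial final sample.
* Tier counts are validated against brute-force enumeration; aggregation
  ("average of the means, SDs, CVs" across subjects — not pooled-sample
  statistics) against an explicit loop; least squares against the normal
  equations; Spearman against explicit average ranks.
* The paired t-test of two identical samples is defined to return t = 0,
  p = 1 (the generic routine refuses constant differences).
* CSV round-trips are bit-exact: values are written in shortest
  round-trip notation and parsed with strtod.
* Validation problem sizes: oracle equivalence uses 1,000 random epoch
  vectors; t-test calibration uses 2,000 null replicates (type-I error
  required within [3.5%, 6.5%] at α = 0.05) and 500 shifted replicates;
  coupling recovery uses one 100-subject low-noise cohort (slope required
  within 15%) and 500 null cohorts of 14 subjects (rejection rate required
  near α). These sizes make the checks statistically meaningful while
  keeping a full validation run to a few minutes.

## Known limitations

* The variable threshold adapts to whatever is in the window; if movement
  occupies most of it, mean + 2·SD rises and counts shrink. This is a
  property of the published method itself, inherited deliberately.
* With the fixed 0.05 m/s² threshold, continuous ergometer motion
  saturates all 500 epochs for every subject, so count-based associations
  are undefined for exercise 4 (constant regressor); the association table
  reports `NA` there.
* Onset detection assumes either a quiet lead-in or movement from the
  start; a recording that begins mid-way through a *fade-in* of activity
  may be aligned up to a couple of seconds late.
* The 10-min chamber resolution means each exercise contributes a single
  EE value; no within-exercise dynamics are recoverable, and multilevel
  correlation models are out of scope for that reason.
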