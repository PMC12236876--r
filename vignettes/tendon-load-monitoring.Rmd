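---
title: "Methods: cumulative Achilles tendon load from insole sensors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cumulative Achilles tendon load from insole sensors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tendonload)
```

## The problem

People rehabilitating from Achilles tendinopathy are told to load the
tendon progressively, but what actually matters — the load accumulated
during ordinary life, outside supervised exercise — is hard to observe.
A force-sensing insole with three plantar pads (heel, midfoot, forefoot)
logging at 20 Hz makes multi-day field monitoring feasible. This package
implements the full analysis chain for such recordings: tendon load
estimation, cumulative load metrics, quality control, monitoring-day
requirements, and correlation with clinical plantar-flexor measures. A
synthetic cohort generator with analytic ground truth makes every stage
testable without any recorded data.

## Tendon load from three plantar forces

Each sensor force is assumed perpendicular to the sole and applied at a
fixed per-sensor center of pressure with a signed moment arm about the
ankle ($r_{heel} < 0 < r_{mid} < r_{fore}$; anterior positive). Per
sample,

$$M_{PF} = f_{heel}\,r_{heel} + f_{mid}\,r_{mid} + f_{fore}\,r_{fore},
\qquad
F_{AT} = \frac{\max(M_{PF}, 0)}{r_{AT}},$$

reported in multiples of body weight (×BW), with BW = mass × 9.81 N/kg
(the constant is configurable via `body_weight_n()`). Defaults:
$r_{heel} = -0.06$, $r_{mid} = 0.04$, $r_{fore} = 0.11$ m for a nominal
adult shoe size, scalable by a size factor, and a tendon moment arm
$r_{AT} = 0.05$ m, which is anatomical and therefore *not* scaled with
shoe size. Negative (dorsiflexion) moments are clamped to zero because
the tendon cannot transmit a compressive push; heel-only loading
contributes no tendon load.

## Cumulative load metrics

Two thresholds delimit accumulation: an *overall* level of 0.3 ×BW (the
load of the lowest-loading tendon exercise, seated heel raises) and a
*high* level of 3.0 ×BW (approximately the peak load of walking, so
anything above it is attributed to dynamic activity). For a load series
$F_t$ at rate $1/\Delta t$:

* total loading time $T_{load} = \sum [F_t \ge 0.3]\,\Delta t$ (hours);
* overall impulse $I_{overall} = \sum [F_t \ge 0.3]\,F_t\,\Delta t$
  (×BW·hour), and analogously $T_{high}$, $I_{high}$ at 3.0 ×BW;
* normalized loads $L_{overall} = I_{overall}/T_{load}$ and
  $L_{high} = I_{high}/T_{load}$ (×BW per loading hour). Both divide by
  the *total* loading time, not the high-level time, which accounts for
  differences in how long each person wore the insole.

Three numerical conventions deserve emphasis:

* **Full-F impulse.** Supra-threshold samples contribute their full load
  $F$, not the excess $F - \theta$. Under this convention $L_{overall}$
  is interpretable as a mean supra-threshold load (≈ 1 ×BW for
  walking-dominated wear); the excess convention would sit ≈ 0.3 ×BW
  lower and lose that interpretation.
* **Rectangle rule at the native rate.** Sample-and-hold integration
  with a per-sample threshold mask is exact for the masked definition;
  trapezoids interact badly with threshold crossings.
* **Closed comparisons.** Thresholds use `>=`, so a series sitting
  exactly at a threshold accumulates.

By construction $T_{high} \le T_{load}$, $I_{high} \le I_{overall}$,
$I_{overall} \ge 0.3\,T_{load}$, and $L_{overall} \ge 0.3$ whenever
$T_{load} > 0$; the test suite asserts these invariants on random
series.

## Quality control

Field insole data carry two characteristic artifacts: slow nonphysical
baseline drift (the sensor reads nonzero when unloaded) and wholly
erroneous sessions from bad initialization or misfit.

**Drift correction** estimates each channel's baseline as a rolling
lower envelope: the minimum over non-overlapping 30 s windows, smoothed
by taking each window's minimum with its neighbours. Under normal wear,
swing and rest phases recur within any 30 s, so the envelope tracks the
offset while staying at zero on clean signal. Where the envelope
exceeds 0.02 ×BW of channel force it is subtracted and the result is
clipped at zero; clean recordings pass through bit-identically, and the
operation is idempotent. A session whose envelope-implied *load* offset
never falls below 0.5 ×BW has no trustworthy zero reference anywhere;
it is flagged `drift_excessive` and dropped rather than corrected.

**Erroneous-session screening** flags (all fatal): (a) estimated load at
or above 0.3 ×BW for more than 95 % of samples with no unloaded
interval of at least 2 s — a session with no swing or rest ever is
physically implausible; (b) a channel below −0.05 ×BW for more than 1 %
of samples; (c) duration under 60 s. These rule values are package
defaults justified on plausibility grounds, not published constants,
and all live in `qc_rules()`.

**Adherence.** A participant who wears the insole only briefly each day
(e.g. only while exercising) misrepresents habitual loading. The
criterion is the median daily total loading time. `check_adherence()`
defaults to a 4 h threshold, but the pipeline configuration defaults to
1.0 h: a full wear day typically yields roughly 1–2.5 loading hours
(loading time excludes swing phases, standing rest below 0.3 ×BW and
non-wear), so 1.0 h separates a sparse 1–3 recorded-hours-per-day
pattern from compliant wear without excluding normal days. The
threshold is deliberately configurable because no canonical value
exists.

## The synthetic cohort generator

The generator emulates the study design — 15 participants monitored for
about 10 days with one or more recordings per day — with known ground
truth at every level.

**Stance waveforms.** Walking stances use a two-hump raised cosine
(loading response and push-off peaks at 25 % and 75 % of stance);
running and jumping use a single asymmetric raised cosine peaking at
40 %. These shapes are qualitative placeholders: real per-sensor
waveforms vary between people and shoes, and only the peak magnitude
and timing materially affect thresholded cumulative metrics. Both
families were chosen so that the time above a threshold $\theta$ and
the (full-F) impulse above it have the same closed form per stance with
peak $P$ and duration $d$:

$$\phi = \arccos(1 - 2\theta/P), \quad
t_{\ge\theta} = d\left(1 - \frac{\phi}{\pi}\right), \quad
I_{\ge\theta} = \frac{P d}{2}\left(1 - \frac{\phi}{\pi} +
\frac{\sin\phi}{\pi}\right),$$

which gives an analytic ground-truth oracle that never touches the
20 Hz signal path. `stance_supra_time()` / `stance_supra_impulse()` are
cross-checked in the tests against fine-grid quadrature of the
continuous waveforms.

**Force allocation.** A target load series is rendered into three
channel forces through phase-dependent fractions (heel-carrying at
contact, forefoot-dominant at push-off) whose effective moment arm is
always positive, so the estimator recovers the constructed load
exactly. This is deliberate: the generator tests the metric chain, not
the estimator's biomechanical validity, which has its own hand-computed
and validation tests.

**Two sampling details.** Standalone stance segments align their grid
so one sample lands exactly on the waveform argmax, making the
constructed peak attainable at 20 Hz. Inside a day, stances fall on the
session's continuous grid with naturally varying phase; cadences
(walking 55, running 82, jumping 31 per minute) are chosen
incommensurate with the 20 Hz grid so stance phases decorrelate across
steps and discretization error averages out instead of accumulating —
with a cadence of exactly 80/min the step period is a whole number of
samples and every stance is sampled at identical phases, producing a
systematic bias of several percent in the high-level metrics.

**Day structure.** A full-scale day contains about 3.8 recorded hours:
three walking blocks (peak ≈ 2.0 ×BW, the casual end of walking), two
low-intensity shuffling blocks (0.8 ×BW), rests, and one non-wear gap
that splits the day into two recordings. On *active* days a 25 min run
(≈ 4.3 ×BW) and 3 min of jumps (≈ 5.2 ×BW) are appended. Each
participant carries a latent high-activity volume $v \sim U(0,1)$; days
are active with probability $0.25 + 0.5v$, and participants with
$v < 0.15$ never perform high-level activity (their true high-level
load is exactly zero, mirroring the zero lower end of the observed
range). Per-stance peaks jitter with 5 % relative SD; the ground truth
uses the *realized* peaks, so it remains exact under jitter. Bout
durations scale with a single factor so tests can run compressed days
with identical structure.

**Clinical measures.** Each of the 13 measures (7 dynamometer capacity,
3 dynamic function, age, VISA-A, PAS) is generated as
`intercept + slope * v + N(0, sd)`, clamped to its valid range, with
age given a negative slope. Defaults keep noiseless values strictly
inside their ranges so that with zero noise the measures are exactly
linear in $v$ (sample correlation ±1). PAS is additionally rounded to
its integer 1–6 scale, as the instrument defines it, which leaves its
noiseless correlation slightly below 1. The implied population
correlation with $v$ is available in closed form
(`implied_effect_r()`), which the tests verify by simulation. Gaussian
noise is the simplest model supporting those closed-form targets.

**What the generator does not emulate.** Real waveform shapes and
between-day wear-time variability; sensor quantization and saturation;
load during cycling/swimming and other non-ambulatory exercise;
tendinopathy progression; any kinematic content. Passing tests
demonstrate the *pipeline's* correctness on signals with known truth,
not the field validity of the insole or the estimator.

## Day-subsampling analysis

For each participant the full-data estimates are the reference; subset
estimates use $k$ of the *first six* recorded days, for all
$\binom{6}{k}$ combinations. The singleton ($k=1$) and leave-one-out
($k=5$) schemes generalize symmetrically to all combinations for
$k = 2..4$; the $k=6$ subset is the single first-six-days estimate.
Error is the mean absolute percent difference from the reference,
pooled over participants and subsets, with dispersion reported as the
SD of those absolute percent errors, and a Pearson correlation between
subset and full estimates pooled over subsets. Reference-zero pairs
(participants whose full-data high-level load is exactly zero, which
the design produces) count as 0 % error when the estimate is also zero
and are otherwise excluded with a reported count — this avoids division
by zero while preserving the error signal. Participants with fewer
than six days contribute subsets from what they have and are flagged.

## Correlation analysis

The 2 × 13 grid of Pearson correlations between
$\{L_{overall}, L_{high}\}$ and the clinical measures uses
pairwise-complete rows with per-cell n. p-values come from the t
transform on $n-2$ degrees of freedom (via `stats::cor.test`),
two-sided — the conservative default where sidedness is not otherwise
fixed — and are ancillary to the strength classification:
$|r| \ge 0.6$ strong, $0.4 \le |r| < 0.6$ moderate, $|r| < 0.4$ weak,
with the boundaries closed exactly as stated. No multiple-testing
correction is applied, consistent with treating strengths rather than
p-values as the primary readout. The tests cross-check the t-transform
p against a 10⁴-draw permutation oracle at n = 15.

## Problem sizes and degenerate inputs

The validation suite runs the full pipeline on a 15 × 10-day cohort at
full day length (≈ 38 M samples, about half a minute), and unit tests
on structurally identical compressed cohorts. Degenerate inputs are
defined rather than rejected where a value exists: empty series give
all-zero summaries; a participant with zero loading time has undefined
normalized loads, is flagged, and is excluded from correlations; an
empty schedule yields no recordings and zero ground truth.

## Known limitations

* The lower-envelope drift corrector will misread genuinely sustained
  loading (constant load with no unloaded sample for longer than the
  30 s window) as baseline; under normal wear this does not occur, but
  it bounds the method's applicability to, e.g., long static holds.
* Sensor moment arms are configurable defaults, not subject-specific
  measurements; absolute load levels inherit that uncertainty even
  though within-participant cumulative comparisons do not.
* The generator's waveforms are placeholders (above); conclusions about
  real insoles require real recordings.
* Normalized per-hour loads assume recorded wear is representative of
  the wearer's day; the adherence screen bounds, but cannot eliminate,
  selective-wear bias.
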