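---
title: "Models and methods behind glaucodrive"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind glaucodrive}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glaucodrive)
```

## Overview

`glaucodrive` implements the analysis pipeline of a fixed-base
driving-simulator protocol for drivers with glaucomatous visual field
loss, together with a synthetic-cohort simulator that exercises every
stage of that pipeline. The protocol it models has four 278 s sessions on
a 7534 m two-lane highway at an automatically maintained 100 km/h:
S1 plain lane keeping, S2 lane keeping plus verbalisation of letters
projected at peripheral screen positions, S3 evasion of nine static
obstacles by changing to the left lane, and S4 letters and obstacles
combined. The measured outcomes are lane keeping (SDLP), steering
activity, obstacle avoidance distances and collisions, letter misses and
reaction times, eye-scanning measures from a 60 Hz gaze stream, perimetric
summaries of each participant's visual fields, and NASA-TLX workload.

Because no participant-level data from such studies is publicly
deposited, the package is validated in three ways: (i) worked examples on
the published course constants, (ii) closed-form and brute-force oracle
checks of every signal-processing primitive, and (iii) qualitative
pattern recovery on replicate synthetic cohorts. The vignette documents
the models behind each stage and the design decisions that were genuinely
open.

## Course model

The course is deterministic (`course_spec()`): cruise speed
$v_c = 100/3.6$ m/s is reached 17 s after the start, and the nine
obstacles sit at fixed longitudinal positions. In the constant-speed
phase, encounter times follow from one (time, position) anchor:
$t = t_0 + (s - s_0)/v_c$ (`encounter_time()`). The published timetable
is rounded to 0.1 s, so adjacent anchors reproduce the next obstacle's
time to better than 0.06 s, while chaining a single anchor across the
whole course accumulates up to ~0.5 s of rounding drift; the tests
therefore check adjacent pairs.

The acceleration law during the first 17 s is not specified by the
protocol, and the first obstacle's published time (19.7 s at 350 m) is
inconsistent with constant acceleration up to 17 s. `position_at_time()`
therefore takes a configurable monotone acceleration profile whose
default is a two-phase ramp (linear speed increase, then cruise) scaled
so the distance covered by 17 s equals $350 - 2.7\,v_c = 275$ m, which
anchors the model exactly on the printed 19.7 s. Only cruise-phase
arithmetic is used for validation.

Letter schedules (`generate_letter_schedule()`) place 32 letters per
session on 25 preprogrammed positions, first onset at 6 s, display time
4 s, and a uniform 3-6 s gap. The protocol's "interval between letters"
is read as the gap between a letter's disappearance and the next
appearance: the onset-to-onset reading would overlap the 4 s display
whenever the interval is below 4 s. The default 25-position layout is a
5 x 5 grid in visual-angle space whose extremes match the estimated
letter eccentricities of the emulated setup (-6.4 to +36.1 degrees
horizontally, -2.9 to +16.8 degrees vertically at the default eye
point 780 mm in front of the screen point (250, 300) mm, which doubles
as the focus of expansion). Rightward of about +21 degrees these letters
fall outside the perimetric field (see below).

## Visual fields and the integrated field

`build_grid_24_2()` reproduces the standard 24-2 automated-perimetry
pattern: 54 locations on a 6 degree offset lattice with rows at
$y = \pm 3 \ldots \pm 21$, a nasal column at 27 degrees, and the
blind-spot pair at 15 degrees temporally. Sensitivities are in dB; the
mean deviation (MD) is always an input, never recomputed, since no
normative database is shipped.

The integrated visual field (IVF, `integrate_fields()`) takes the best
monocular sensitivity at each of 52 visual-space locations around
fixation. The exact treatment of the 52 "corresponding positions" is not
fully pinned down by the protocol text; the package adopts the
convention that yields exactly 52 points with 13 per quadrant: the
symmetric part of the lattice (dropping the two single-eye nasal
27-degree columns), with each eye's blind-spot locations covered by the
fellow eye alone. Quadrant sensitivity loss (`quadrant_loss()`) is the
percentage of points per quadrant falling strictly below 25 dB — strict,
because the criterion is "below" the threshold — so IVF quadrant values
are multiples of $100/13$. For monocular fields the denominator is the
eye's own non-blind-spot count in that quadrant. The better eye is the
one with the higher MD, ties going to the right eye.

## Driving measures

All vehicle signals are sampled at 60 Hz. Steering is low-pass filtered
with a 2nd-order Butterworth at 2 Hz ("high", removing sensor noise) and
0.5 Hz ("low", isolating slow steering oscillation). Filtering is
zero-phase (forward-backward, `signal::filtfilt`): the analysis is
offline and phase lag would smear event-locked windows. A consequence,
stated and tested rather than hidden, is that the gain at the cutoff
frequency is $0.5$ (the square of the single-pass $-3$ dB point).

Steering activity (`steering_activity()`) is the mean absolute steering
rate, computed by central differences *after* filtering, with samples
within 0.5 s of the session edges discarded to suppress filter
transients. For a sinusoid $A\sin(2\pi f t)$ it equals $4Af$, which the
tests verify to 1%. SDLP (`sdlp()`) is the sample standard deviation
(n−1) of lateral position. Obstacle windows run from 150 m before to
200 m after each obstacle and are applied in *every* session, whether or
not obstacles were present; SDLP is reported for non-obstacle periods.

LongDtO (`long_dto()`) is the distance from the obstacle at which the
vehicle *committed* to the left lane: the last upward crossing of the
road-centre line within the 150 m approach after which the vehicle stays
left of centre until the obstacle (linearly interpolated between
samples). The committed-crossing rule is this package's interpretation —
drivers may weave — and a trace that never commits yields an undefined
value, which is excluded from means and counted. LatDtO is the absolute
interpolated lateral clearance when passing. A collision is a strict
lateral distance below 1.6 m while overlapping the obstacle
longitudinally; vehicle and obstacle lengths default to 4.5 m
(configurable; the protocol specifies only the 1.6 m rule).

## Letter scoring

A letter is detected if any voice event falls between its onset and 1 s
after its 4 s display ends. Matching is greedy one-to-one, earliest
onset first; because gaps are at least 3 s, response windows cannot
overlap. Reaction time is voice time minus onset. The session summary
sums misses over S2 and S4 and pools all detected letters for the mean
LRT (per-session averaging is available as an option; the protocol does
not say which the original analysis used). Spearman correlations between
the letter measures and the quadrant loss percentages of the IVF,
better-eye and worse-eye fields are computed within the patient group
only (12 correlation pairs).

## Eye-scanning measures

Gaze preprocessing (`preprocess_gaze()`) removes 0.5 s on either side of
every invalid run (blinks/missing data), drops surviving segments
shorter than 1 s, and low-pass filters each segment at 20 Hz. The
removed fraction is taken over the whole session; a participant whose
any session exceeds 60% removed data is excluded from all eye-scanning
analyses.

Fixations use the classic dispersion-threshold algorithm (I-DT): a
window of at least 150 ms (the protocol's "150 m" is read as a typo for
milliseconds — 150 m is not a duration) whose dispersion, defined as
horizontal extent plus vertical extent, stays within 3 degrees. The
mm-to-degree conversion uses a configurable viewing distance, default
780 mm: with a 1090 mm screen subtending roughly 70 degrees, the eye
point sits at about $1090/(2\tan 35°) \approx 780$ mm. Windows never
span removed gaps. The implementation is verified against a brute-force
re-scanning oracle on hundreds of random segments — boundary-exact, not
approximate.

Fixation rate divides by *retained* time, not session time: removed data
cannot contain detectable fixations (configurable). Saccade amplitude is
the mean distance between consecutive fixation centroids within the same
retained segment; pairs spanning a gap are dropped. Dwell percentages
count retained samples inside named screen rectangles; the default top
and bottom regions are full-width bands covering 20% of the screen
height each (the emulated study's exact extents are not published).

## Statistics and report

Group comparisons use Welch's t-test (unequal variances,
Welch-Satterthwaite df, two-tailed, $\alpha = 0.05$, no multiplicity
correction, as in the emulated protocol); session effects use a paired
t-test; associations use Spearman's rank correlation with midranks and a
t-approximation p-value (an exact permutation option exists for small
tie-free samples). The Welch implementation wraps `stats::t.test`; the
tests check it against a direct evaluation of the textbook formulas at
1e-10 and verify a 4-6% empirical type-I error over 5000 null replicates
at the study's group sizes (12 vs 23) under unequal variances. NASA-TLX
totals rescale the six 1-21 items to 0-100%:
$100(\bar{x} - 1)/20$. `build_report()` emits the five study-style
tables (descriptives, driving, letters, eye-scanning with exclusions
applied, correlation matrix).

## The synthetic cohort

`generate_cohort()` produces complete records for 12 controls and 23
patients by default. The emulated protocol recruited 25 patients in five
scotoma-pattern strata (4 left-eye-only, 7 right-eye-only, 5 alternated,
6 both-upper, 3 both-lower) of whom two withdrew before testing; since
the withdrawn strata are unknown, the default analysed cohort trims one
patient from each of the two largest strata (right-eye-only 6,
both-upper 5). All randomness flows from one master seed through a
single sub-seed draw per participant stream.

**Visual fields.** Baseline sensitivity is $31 - 0.1\,e$ dB at
eccentricity $e$, with 1.8 dB measurement noise and a small diffuse
loss. The scotoma pattern marks the predominant defect: locations there
are depressed by the participant's scotoma depth (mean 25 dB, jittered
per location, floored at 0) with 85% coverage. Because glaucomatous
damage is rarely monocular, locations outside the predominant region are
also hit with ~30% probability; this secondary bilateral involvement is
what gives the cohort the strongly negative MDs in both eyes and a mean
integrated-field loss near 42% that such cohorts show, and it spreads
upper-field IVF loss continuously across patients instead of
concentrating it in one stratum. Control fields have well under 5% of
points below 25 dB.

**Driving.** A proportional-derivative steering controller tracks a
target lateral position along the course: the right-lane centre, with a
trapezoidal excursion to 3.15 m left beginning ~118 m before each
obstacle and returning 90 m after it. Steering noise has two
band-limited components (0.8 Hz and 0.18 Hz corners) scaled by a
per-participant gain, and the tracked target wanders slowly (0.24 m sd)
to emulate imperfect lane keeping. The fixed gains and noise scales were
calibrated once against the emulated study's control-group levels —
SA-high ≈ 1.9 deg/s, SA-low ≈ 1.0 deg/s outside obstacle windows, SDLP
≈ 0.4 m, commitment ≈ 50 m before the obstacle, clearance > 3 m, no
collisions — and patients differ only through a 1.22x noise gain and a
1.25x stiffer position gain, reproducing the study's signature: higher
steering activity with *equal* lane keeping and obstacle clearance.
There is no human driver model to copy here; the PD-plus-noise form is
the simplest controller whose steering activity and SDLP are separately
tunable.

**Letters.** With gaze at the focus of expansion, each letter's
visual-field direction follows from the eye point; the nearest IVF
sensitivity (a configurable 20 dB floor beyond the 21-degree field
margin — about a third of the default letter positions lie beyond it)
drives a logistic miss probability in (threshold − sensitivity) with a
2.5 dB slope. Detected letters respond at base RT + 8 ms/degree of
eccentricity + letter-level and participant-level slowing proportional
to field loss + lognormal noise, truncated at the 5 s window.
Excursions of the gaze model toward letters deliberately do not alter
detection: detection is driven by the field, keeping the
miss/visual-field correlation mechanism explicit.

**Gaze.** A sequence of fixation targets around the focus of expansion
(horizontal-dominant scatter, occasional full-screen glances), brief
excursions to displayed letters, small within-fixation jitter, Poisson
blinks (0.2 Hz) and tracking dropouts; a fraction of participants
(30% of patients, 8% of controls — patients wear glasses more often)
get long dropout episodes that push them over the 60% exclusion
threshold, reproducing the study's exclusion pattern. The protocol
publishes no quantitative gaze-excursion dynamics, so the excursion
shape is a free modelling choice; simulated fixation rates (~0.8/s) and
saccade amplitudes (~170 mm) are in the right order but not tuned to the
published means, and the tests assert only what the study found — no
group difference.

**Workload.** TLX items scatter around a participant-level percentage
with a per-group linear session trend: controls flat-to-decreasing from
~26%, patients increasing ~4.5%/session from ~17%, reproducing the
published interaction (patients' workload rises as tasks are added).

### What passing tests do and do not show

The simulator reproduces the *structure* the analysis assumes — group
differences with the study's signs, a positive upper-field-loss/miss
correlation stronger than the lower-field one, matched lane keeping and
eye-scanning — under idealised conditions: stationary noise, no
learning or fatigue across sessions, no simulator sickness, no head
movement, instantaneous saccades, and a detection model that ignores
letter conspicuity differences (the study noted letters inside the
rear-view mirror were missed disproportionately). Passing tests
validate the measurement pipeline and the qualitative mechanism, not
quantitative agreement of every simulated magnitude with the published
human data; simulated patients, for instance, miss roughly twice as many
letters as the published group mean, within the published
between-patient spread.

## Numerical choices and degenerate inputs

* Zero-phase filtering halves the gain at the cutoff; tested explicitly.
* Central differences for steering rate; 0.5 s edge trim.
* Undefined values are first-class: LongDtO without a committed
  crossing, mean LRT with zero detections, saccade amplitude with fewer
  than two same-segment fixations, Spearman under zero rank variance —
  all yield `NA` with counts/flags, and are dropped pairwise from group
  statistics.
* Paired t with zero difference variance is flagged degenerate rather
  than dividing by zero.
* Letter windows cannot overlap (minimum 3 s gap vs 1 s grace), so the
  greedy earliest-onset matching is unambiguous.
* The I-DT window length for a 150 ms minimum at 60 Hz is 10 samples
  (duration measured first-to-last sample).
* Replicate studies in the tests and the acceptance script use 20
  cohorts with gaze simulated for S1 only — fixation-rate comparisons do
  not need all four sessions and driving/letter measures are unaffected.

## Limitations

The simulator is a validation instrument, not a digital twin: effect
sizes are configurable but defaults were fixed once against the
published group-level descriptives; road curvature is abstracted into
lane-relative coordinates; gaze-letter coupling is one-directional; and
perimetric fields use a single global baseline rather than age-corrected
normative values (MD is therefore a model-relative quantity).
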