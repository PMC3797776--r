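# glaucodrive

Analysis pipeline for fixed-base driving-simulator studies of drivers
with glaucomatous visual field loss — and a synthetic-cohort simulator
that lets every stage of the pipeline be exercised and validated without
access to participant data.

## The problem

Glaucoma produces peripheral visual field loss, and a central question
for fitness-to-drive assessment is which driving subtasks that loss
actually degrades. The protocol this package analyses puts participants
through four 278 s simulator sessions on a 7534 m two-lane highway at an
automatically maintained 100 km/h (steering is the only control):
plain lane keeping (S1), lane keeping plus verbalisation of letters
projected at peripheral screen positions (S2), evasion of nine static
obstacles by changing to the left lane (S3), and both tasks combined
(S4), while a 60 Hz eye tracker records gaze.

The package computes, from per-session CSV streams:

* **Driving** — steering activity `SA = mean |dθ/dt|` on the 2 Hz
  ("high") and 0.5 Hz ("low") zero-phase Butterworth-filtered steering
  angle, inside and outside obstacle windows (150 m before to 200 m
  after each obstacle); SDLP, the standard deviation of lateral
  position; LongDtO, the distance at which the vehicle committed to the
  left lane (last road-centre crossing held until the obstacle); LatDtO,
  the lateral clearance when passing; collisions (lateral distance
  < 1.6 m while alongside).
* **Letter task** — a letter is detected if any voice event falls
  between its onset and 1 s after its 4 s display; misses and mean
  letter reaction time (LRT) over S2+S4.
* **Eye scanning** — blink-aware preprocessing (±0.5 s margins, < 1 s
  segments dropped, 20 Hz low-pass, participants with > 60% removed data
  in any session excluded), I-DT fixation detection (3° dispersion,
  150 ms minimum), fixation rate, saccade amplitude, and top/bottom
  screen dwell percentages.
* **Visual fields** — Humphrey 24-2 grids per eye; the integrated visual
  field `IVF(x) = max(OD(x), OS(x))` over 52 locations; percentage of
  points per quadrant below 25 dB; better/worse eye by mean deviation.
* **Statistics** — Welch's t (two-tailed, α = 0.05, no multiplicity
  correction), paired t, Spearman correlations, NASA-TLX 0–100% totals,
  and the five study-style report tables.

The synthetic-cohort module (`generate_cohort()`) emulates the study
conditions: 12 controls and 23 patients in five scotoma-pattern strata,
a PD-controller driver model with calibrated two-band steering noise,
a field-driven logistic letter-detection model, gaze concentrated at the
focus of expansion, and group-specific workload trends.

## Worked example

```r
library(glaucodrive)

cohort  <- generate_cohort(n_control = 4, n_glaucoma = 6,
                           pattern_counts = c(both_upper = 2, both_lower = 1,
                                              left_eye_only = 1,
                                              right_eye_only = 1,
                                              alternated = 1),
                           rng_seed = 42, gaze_sessions = "S1")
metrics <- cohort_metrics(cohort, gaze_sessions = "S1")
report  <- build_report(metrics)
report$driving[c(1, 4), c("measure", "control", "glaucoma", "p")]
#>                                                      measure     control    glaucoma     p
#>                       SDLP, non-obstacle periods (S1-S4) (m) 0.40 (0.04) 0.41 (0.05) 0.746
#>  Steering Activity-low, non-obstacle periods (S1-S4) (deg/s) 1.01 (0.15) 1.31 (0.27) 0.057
report$letters[, c("measure", "control", "glaucoma", "p")]
#>                                 measure     control     glaucoma        p
#>  Letter Reaction Time (LRT) (S2,S4) (s) 1.20 (0.08)  1.63 (0.11) 8.9e-05
#>         Number of letter misses (S2,S4) 4.25 (2.63) 15.50 (6.41) 6.2e-03
```

The cells are group means (SD); `p` is the Welch two-sample p-value. The
simulated patients steer more actively and miss more letters, while lane
keeping is indistinguishable — the qualitative signature the pipeline is
designed to detect. Drilling into one patient with bilateral upper-field
defects:

```r
p <- cohort$participants[[5]]
p$ivf
#> Integrated visual field: 52 locations; % points < 25 dB: 63.5
#> Quadrant loss (%): UL 92.3, UR 84.6, LL 38.5, LR 38.5
session_driving_metrics(p$traces$S3, cohort$course, "S3")
#> Driving metrics, S3
#>   SA-high non-obst/obst: 2.91 / 3.50 deg/s
#>   SA-low  non-obst/obst: 1.42 / 2.13 deg/s
#>   SDLP (non-obst): 0.430 m
#>   LongDtO 52.1 m, LatDtO 3.14 m, collisions 0
score_letters(p$events$S2$letters, p$events$S2$voice_events)
#> Letter score: 22 detected, 10 missed; mean LRT 1.83 s
```

Upper-field loss is what costs letters here: most letter positions lie
above the focus of expansion, so upper-quadrant IVF loss correlates
strongly with misses while lower-quadrant loss does not.

A thin command-line front end over the same functions lives at
`inst/scripts/run_pipeline.R`
(`Rscript run_pipeline.R --task all --seed 7 --outdir out/`).

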