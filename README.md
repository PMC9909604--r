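# movemetrics

Validating wrist-worn inertial-sensor movement metrics against whole-room
indirect calorimetry.

## What it is for

Upper-limb motor function is a key but under-measured outcome in
neuromuscular disease. A smartwatch on the wrist records user acceleration
(gravity-removed, m/s²) and rotation rate (rad/s) at 20 Hz while a subject
performs a standardised protocol of slow arm exercises — three free
rhythmic movements paced by a metronome at 15 movements/min and hand-bike
cranking at 40–45 rpm — inside a metabolic chamber that measures energy
expenditure (EE) at 10-minute resolution. `movemetrics` implements the
full analysis chain that relates the two:

1. **Kinematics** — read the sensor CSV export, collapse each triaxial
   sample to its Euclidean magnitude `|a| = √(aₓ² + a_y² + a_z²)`, detect
   the onset of rhythmic movement, and trim every exercise to a uniform
   500-s window (10,000 samples).
2. **Activity counts** — reduce the magnitude to one value per 1-s epoch
   (epoch peak by default) and count epochs against a threshold *T*:
   total = #{v > T}, medium = #{v > 2T}, low = total − medium. Free
   exercises use the per-window variable threshold *T* = mean + 2·SD;
   the ergometer uses a fixed *T* = 0.05 m/s².
3. **Calorimetry** — segment the chamber session (30 min equilibration +
   30 min rest + 4 × (10 min exercise + 10 min pause) = 140 min), convert
   VO₂ with 4.867 kcal per litre O₂ (and 4.184 kJ/kcal), and compute
   ΔEE = EE(exercise) − EE(resting reference) per exercise.
4. **Statistics** — cohort tables as the *average of the per-subject
   means, SDs and CVs* (CV = SD/mean), Spearman rank correlation and
   ordinary least squares of ΔEE on each movement metric, and two-sample
   t-tests (including the fasted vs non-fasted contrast), all at a flat
   α = 0.05.
5. **Synthetic data** — a seeded generator for traces, chamber sessions
   and whole cohorts with known ground truth (expected activity counts
   and a configurable count→ΔEE coupling slope), so every stage is
   testable end to end without any recorded data.

See `vignettes/movement-energy-methods.Rmd` for the models, parameter
defaults, and design decisions.

## Worked example

```r
library(movemetrics)

trace <- gen_rhythmic_trace(generator_config(seed = 42))
trace
#> <imu_trace> subject synthetic, exercise 1: 10000 samples, 499.9 s at nominal 20 Hz

acc <- vector_magnitude(trace, "user_acc")
summarize_series(acc)
#> # A tibble: 1 × 6
#>    mean    sd    cv   max    min     n
#>   <dbl> <dbl> <dbl> <dbl>  <dbl> <int>
#> 1  1.95  3.56  1.82  27.1 0.0242 10000

thr <- variable_threshold(acc)
thr
#> <threshold_spec> variable: 9.074 m/s^2 (mean + 2 SD of 10000-sample window)
count_activity(epoch_reduce(acc), thr)
#> <activity_counts> total 106 (medium 11 + low 95) of 500 epochs; T = 9.074 m/s^2 (variable)
```

The window mean of 1.95 m/s² is a typical slow-arm-exercise intensity; the
variable threshold lands at 9.07 m/s², and 106 of the 500 one-second
epochs contain a movement peak above it (95 low, 11 medium).

A whole synthetic cohort, analysed end to end:

```r
cohort <- gen_cohort(14, seed = 1)
report <- analyze_cohort(cohort)
report
#> <run_report> 56 subject-exercise windows, 0 failure(s)
#>   27 association/contrast tests at alpha = 0.05 (uncorrected)

subset(report$cohort_movement, metric == "acceleration")
#> # A tibble: 4 × 8
#>   metric       exercise_id avg_of_mean avg_of_sd avg_of_cv avg_of_max avg_of_min
#>   <chr>              <int>       <dbl>     <dbl>     <dbl>      <dbl>      <dbl>
#> 1 acceleration           1        2.42     3.97      1.65       28.0      0.0298
#> 2 acceleration           2        2.28     3.98      1.74       29.1      0.0230
#> 3 acceleration           3        2.40     4.10      1.72       29.6      0.0224
#> 4 acceleration           4        3.40     0.340     0.100       4.73     2.06

report$cohort_delta_ee
#> # A tibble: 4 × 7
#>   exercise_id  mean    sd    cv   max    min n_subjects
#>         <int> <dbl> <dbl> <dbl> <dbl>  <dbl>      <int>
#> 1           1 0.444 0.755 1.70   1.56 -0.723         14
#> 2           2 0.524 0.656 1.25   1.73 -0.310         14
#> 3           3 0.567 0.648 1.14   1.84 -0.388         14
#> 4           4 2.67  0.701 0.263  3.94  1.77          14
```

Cohort-average acceleration means sit between 2.3 and 3.4 m/s², with the
machine-guided ergometer (exercise 4) showing the highest mean and by far
the lowest dispersion (CV 0.10 vs ≈1.7 for the free exercises), and the
largest energy increment (2.67 kJ/min — it saturates all 500 epochs).
Negative per-subject ΔEE minima are expected at this noise level: an
exercise block can measure below its reference rest block. The association
table (`report$associations`) gives Spearman ρ and OLS r/r²/slope per
exercise and metric; at n = 14 with subject-level EE noise these are
individually weak, which is exactly what the null/recovery calibration
below quantifies.

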