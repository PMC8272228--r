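# brachytherm

Locating and differentiating activated upper-arm muscles from infrared
thermal imaging during resistance training.

When a muscle contracts against resistance, the heat it produces perfuses
to the skin with a delay — mostly during the recovery between sets — and
an infrared camera sees a localized warm spot over the active muscle.
`brachytherm` turns sequences of skin-temperature frames of the brachium
(upper arm) into quantitative activation calls for the three muscles that
isolated training movements target: **biceps brachii** (arm curl),
**triceps brachii** (kick back), and **deltoid** (lateral raise). It is
aimed at sports-science and biomedical-imaging work where a noncontact
alternative to surface EMG is wanted.

Because such recordings are not freely available, the package includes a
synthetic thermal-session simulator with the spatial and temporal
structure the analysis assumes, so the entire pipeline is testable and
benchmarkable end to end.

## Method

For a session of `n` sets, frames are selected at the start (S) and end
(E) of every set. Each selected frame is aligned (biceps left), smoothed
(3 × 3 moving average), segmented by Otsu's global threshold (largest
8-connected component, holes filled), and cropped. The arm ROI is reduced
to a **heat map** `H ∈ ℝ^{60×20}`: the ROI bounding box is divided into
60 × 20 near-equal cells and each cell takes the mean temperature of its
foreground pixels (cells under 50 % coverage are missing).

Activation is exposed by **difference heat maps** `D = H_later − H_earlier`
for the pairs (S1-E1), (S1-S2), (S1-E2), (S1-S3), (S1-E3), so heating is
positive. Three fixed grid regions carry the muscle identities — upper
half: deltoid; lower-left quadrant: biceps; lower-right quadrant:
triceps — and the region mean of `D` measures each muscle's warming.
On top of this sit:

* **elevation rates** `v = ΔT / Δt` (°C/min) per exercise/recovery phase,
* a **Kruskal–Wallis** test of training-order effects on the (S1-E3)
  target-region difference,
* per-session **pair ranking** (which pair shows the largest target
  warming, floor-rounded percentage shares), and
* a small four-block **CNN** (conv-ReLU-maxpool ×4 + softmax; Adam,
  lr 10⁻⁴, batch 16, 50 epochs) classifying difference heat maps into
  biceps / triceps / deltoid / vague, with the standard rotation–scale–
  noise ×18 augmentation factorial available for small datasets.

The simulator renders a warm elliptical arm on a cool background with
piecewise-linear dynamics (0.13 °C/min during sets, 0.47 °C/min during
recovery, plateau after 3 min) and a Gaussian hotspot over the target
muscle, plus sensor noise at 0.05 °C. See the methods vignette
(`vignettes/thermal-activation-pipeline.Rmd`) for every modeling and
design decision.

## Worked example

```r
library(brachytherm)

protocol <- session_protocol(3, 12, recovery_s = 92, weight_kg = 10,
                             target_muscle = "biceps", arm_side = "left")
frame_times(protocol)
#>   label time_s
#> 1    S1      0
#> 2    E1     48
#> 3    S2    140
#> 4    E2    188
#> 5    S3    280
#> 6    E3    328

config <- sim_config(frame_shape = c(128, 96), noise_sd = 0.05, seed = 1)
recording <- simulate_session(protocol, config)
recording
#> <session_recording> sim/sim: 83 frames, 0..328 s, 128 x 96 px

maps <- select_set_heatmaps(recording)
round(region_means(diff_heatmap(maps, "S1-E3")), 2)
#> deltoid  biceps triceps
#>    0.68    1.72    0.88

rank_pairs(maps, "biceps")
#> [1] "S1-E3"

rates <- session_rates(maps)
round(c(exercise = rates$exercise_rate, recovery = rates$recovery_rate), 2)
#> exercise recovery
#>     0.13     0.46
```

Twelve repetitions at 15 rpm last 48 s, so the three sets with 92 s
recoveries span 0–328 s. Over the session the biceps region warms by
1.72 °C — far more than the deltoid (0.68 °C) and triceps (0.88 °C)
regions, which see only diffuse warming — so the activation is localized
to the trained muscle, and the start-of-first-set vs end-of-last-set pair
(S1-E3) is the most informative contrast. The recovered elevation rates
match the configured dynamics (0.13 and 0.47 °C/min).

## Analysis workflow

The study-style analyses are numbered drivers over the package:

```sh
Rscript analysis/01_simulate.R   # simulate a 24-session cohort + I/O demo
Rscript analysis/02_process.R    # difference maps and region summaries
Rscript analysis/03_analyze.R    # rates, contrasts, pair ranking, order test
Rscript analysis/04_classify.R   # 120-session CNN benchmark
```

Each step prints what it found and writes its tables under `results/`
(large intermediates go to `scratch/`).

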