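# ovisense

Behavior classification for grazing sheep from neck-mounted IMU sensors.

Precision-livestock researchers label sheep behavior — walking, standing,
grazing, lying, running — from 20 Hz six-channel inertial streams
(three-axis accelerometer, ±2 g; three-axis gyroscope, ±2000 °/s).
`ovisense` implements the complete analysis chain as a tested R package,
with a synthetic ethogram/IMU generator standing in for field recordings so
every stage runs and is verifiable on a laptop:

* **Wavelet denoising** — Daubechies `db6`, 5 levels, per-level soft
  thresholding under the heuristic-SURE rule, symmetric extension, exact
  reconstruction.
* **Movement-period analysis** — one-sided FFT dominant frequency
  `f = (n − 1)·fs/N`, period `T = 1/f`, and the window recommendation that
  turns a 2.15 s maximum movement period into the 3/5/11 s window ladder
  (`ceiling(c(1, 2, 5) * T)`).
* **Feature bank** — 15 time/frequency statistics per axis, signal
  magnitude area / energy / entropy per sensor, and 15 VeDBA
  (`sqrt(ax² + ay² + az²)`) statistics: 63 features from the accelerometer,
  48 from the gyroscope, 111 from both.
* **Classifiers** — an extreme learning machine (random fixed hidden layer,
  output weights by minimum-norm least squares) written from first
  principles, multiclass AdaBoost (SAMME) over `rpart` trees, and a
  stacking ensemble (AdaBoost + random forest + SVM base learners, ELM
  meta-learner on strictly out-of-fold probabilities), with stratified
  5-fold cross-validation for hyperparameter selection.
* **Consensus decoding** — continuous streams decoded per second with
  jump-moving (non-overlapping) or slide-moving (every-second-offset)
  windows; each second's label is the behavior with the highest prediction
  score accumulated over all windows covering it.
* **Evaluation** — per-second accuracy, Cohen's kappa from the confusion
  matrix, per-class precision/recall/F-score, and behavior time budgets
  with standing + lying merged into resting.

## Worked example

The canonical continuous-behavior segment: a sheep grazes, is startled,
runs 4 s, walks 6 s, then stands. Under a perfect window classifier
(every window labelled with its majority truth behavior), per-second
decoding accuracy depends only on window size and moving mode:

```r
library(ovisense)
sched <- cbs_demo_schedule()
sched
#> Behavior schedule: 4 segments, 33 s total
#>  behavior seconds
#>   grazing      11
#>   running       4
#>   walking       6
#>  standing      12

sapply(c(3, 5, 11), function(s) round(100 * oracle_decode(sched, s, "jump")$accuracy, 1))
#> [1] 97.0 93.9 84.8
sapply(c(3, 5, 11), function(s) round(100 * oracle_decode(sched, s, "slide")$accuracy, 1))
#> [1] 100.0 100.0  87.9
```

Small windows lose little at bout boundaries; an 11 s jump window smears
the 4 s run into its neighbors (28/33 s correct), and slide-mode consensus
recovers all but the running seconds (29/33). The 11 s slide decoding shows
where those errors live:

```r
oracle_decode(sched, 11, "slide")$decoding
#> Second-wise decoding (slide-moving 11 s windows): 33 s
#> grazing x14s, walking x7s, standing x12s
```

A full run with a real classifier — simulate a balanced training stream,
denoise, window, featurize, standardize, train an ELM, decode the 33 s
segment per second:

```r
train <- make_schedule(rep(c("walking", "standing", "grazing", "lying", "running"), 5),
                       rep(12, 25))
cfg <- pipeline_config(train_schedule = train, eval_schedule = sched,
                       window_sizes = 3, model = "elm",
                       model_args = list(hidden = 120),
                       exclude_running_at = c(), seed = 17)
res <- run_pipeline(cfg)
res$w3$test_report$accuracy   # held-out window accuracy
#> [1] 1
res$w3$cbs_report             # per-second decoding of the continuous segment
#> Accuracy: 100.0%   Kappa: 1.000
time_budget(res$w3$decoding)
#> Behavior time budget:
#>   walking    18.2%
#>   grazing    33.3%
#>   resting    36.4%
#>   running    12.1%
```

On these well-separated synthetic signatures all three model families
exceed 95% held-out accuracy; real field recordings are harder (see the
methods vignette, `vignettes/behavior-classification-methods.Rmd`).

A thin command-line wrapper over the same functions ships in
`inst/cli/ovisense.R` (subcommands `simulate`, `denoise`, `period`,
`features`, `pipeline`).

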