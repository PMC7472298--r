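# swingseg

Golf swing phase segmentation from a single body-worn IMU.

A full golf swing splits into five phases — before-swing (BF), backswing
(BS), downswing (DS), follow-through (FT), after-swing (AF) — separated by
four dividing points: address (**ADD**), backswing top (**BST**), impact
(**IMP**) and finish (**FIN**), all defined on the clubhead kinematics
(speed local minima, plus the ball-marker crossing for IMP). `swingseg`
estimates those four instants from one six-axis IMU (3-axis acceleration
±16 g, 3-axis angular velocity ±2000 dps, 200 Hz) worn at the wrist, head
or waist, and evaluates the estimators with leave-one-subject-out (LOSO)
cross-validation.

Three estimators are implemented end to end:

* **heuristic** — per-placement indicator rules: the minimum/maximum/zero
  crossing of a specific filtered channel inside a search window anchored
  on the acceleration-peak impact proxy (e.g. wrist ADD = min of ω_y,
  waist IMP = zero crossing of a_x);
* **blstm** — a 5-layer bidirectional LSTM (32 units per direction,
  ~110 K parameters) classifying each of the 700 window samples into a
  phase, with dividing points decoded from the cleaned class changes;
* **cnn** — a two-block 1-D CNN (conv–tanh–maxpool–tanh ×2, ~89 K
  parameters) regressing the four dividing points directly as fractions of
  the 3.5 s impact-centred window.

Both networks (forward, backprop, Adam, validation stopping) are
implemented in compiled code inside the package. Preprocessing follows the
standard chain: order-10 zero-phase Butterworth low-pass at 10 Hz,
jump-peak clock alignment, a 700-sample window from 2.5 s before to 1 s
after impact, and per-swing min–max normalization of the 7×700 (or 4×700
single-modality) input matrix.

Because the original motion-capture/IMU recordings were never deposited,
the package also ships a calibrated synthetic swing generator
(`simulate_dataset()`): phase durations match the published reference
statistics (BS 1.163 ± 0.232 s, DS 0.317 ± 0.050 s, FT 0.670 ± 0.119 s),
body segments move in a proximal-to-distal sequence (waist → head →
wrist), signals carry an impact transient, subject-level random effects,
sensor noise and saturation, and — in the noiseless limit — every shipped
indicator event sits exactly on the ground-truth dividing point, so the
generator doubles as a construction oracle for the whole pipeline. See the
methods vignette (`vignettes/methods.Rmd`) for the full model and design
rationale.

## Worked example

```r
library(swingseg)

cfg   <- generator_config()                       # calibrated defaults
prof  <- sample_subject_profile(cfg, subject_id = "01", seed = 11)
swing <- simulate_swing(prof, cfg, club = "driver", seed = 101)
swing
#> <swing_set> subject 01, driver, placements: wrist, head, waist
#> <dividing_points> ADD 2.300  BST 3.323  IMP 3.647  FIN 4.202 s

imu <- filter_recording(swing$recordings$wrist)   # 10 Hz zero-phase low-pass
est <- heuristic_segment(imu)                     # wrist indicator rules
est
#> <dividing_points> ADD 2.345  BST 3.323  IMP 3.645  FIN 4.255 s
round(1000 * (unclass(est) - unclass(swing$truth)), 1)
#>  add_s  bst_s  imp_s  fin_s
#>   45.0    0.0   -1.8   52.9
phase_lengths(est)
#>      bs_s      ds_s      ft_s    full_s
#> 0.9779806 0.3220194 0.6100000 1.9100000
```

The error pattern is the characteristic one: BST and IMP are sharp events
(errors of a sample or two), while ADD and FIN are gentle speed minima and
carry tens of milliseconds of error — the regime where the learned models
pay off. A full comparison on a synthetic cohort:

```r
swings <- simulate_dataset(8, 10, cfg, seed = 7)
rep_h  <- loso_cv(swings, "heuristic", "wrist", "a+g")
rep_c  <- loso_cv(swings, "cnn", "wrist", "a+g",
                  train_config(learning_rate = 2e-3, max_epochs = 300,
                               patience = 40, augment = 4,
                               aug_jitter_s = 0.4, tta = 5, seed = 21))
summary(rep_h)    # grand-mean MAE (ms) and between-subject SD per point
render_report(list(rep_h, rep_c), "report/")   # CSV tables + bar charts
```

A command-line front end covering the same workflow ships in
`inst/exec/swingseg` (`simulate`, `segment`, `train`, `evaluate`).

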