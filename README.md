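# graspdecode

Decoding continuous hand-grasp kinematics from low-frequency scalp EEG.

During natural reach-to-grasp movements, the time-domain amplitude of scalp
EEG in the 0.1–1 Hz band is modulated by hand kinematics. `graspdecode`
implements the complete offline analysis for quantifying that relationship
in a five-object grasping task:

* **Signal conditioning** — zero-phase 4th-order Butterworth filtering
  (0.3–1 Hz), a spatial-projection hook for ocular-artifact removal,
  exclusion of six peripheral channels, downsampling to 100 Hz,
  differentiation, temporal lag embedding (11 lags, 0–100 ms), trial
  segmentation (−400 ms to offset +100 ms) and feature standardization.
* **Kinematic synergies** — PCA of the 15 joint angular velocities
  (covariance eigen-decomposition; the first 3 components are decoded).
* **Wiener decoding** — the lagged linear model
  `PC_i[t] = b0_i + sum_n sum_k b_nki EEG_n[t−k]`, ordinary least squares
  with 8-fold stratified cross-validation; accuracy is the median Pearson
  r between predicted and observed trajectories across folds. Channel
  ranking `R_n`, best-N accuracy curves with a double-exponential peak fit,
  and per-lag contributions `%T_k` map where and when the information lives.
* **Surrogate chance levels** — phase-scrambled (magnitude-preserving) and
  trial-scrambled (derangement) nulls, 5 repetitions each, run through the
  full decoding procedure.
* **Grasp classification** — a simplex-weighted multiple-kernel SVM
  (SimpleMKL; 8 scalp regions × 3 RBF widths = 24 basis kernels) classifies
  100 ms EEG windows into the five grasp types from −1 to +3 s around
  movement onset; the confusion matrix at each window time yields an
  information timeline in bits.
* **Synthetic data** — a generator producing 64-channel EEG at 1000 Hz and
  15-joint kinematics with the exact lagged linear coupling, low-rank
  synergy structure, 1/f noise and trial statistics the analysis assumes,
  with full ground truth, so the entire pipeline is testable end to end
  without access to human recordings.

The methods vignette (`vignettes/grasp-decoding-methods.Rmd`) documents the
models, the numerical choices and the generator's design in detail.

## Worked example

Simulate a small session (10 trials per object at 100 Hz for speed; the
defaults are a full 250-trial session at 1000 Hz), run the decoding
pipeline, and inspect the result:

```r
library(graspdecode)

spec <- synthetic_spec(fs = 100, trials_per_object = 10)
sim  <- simulate_recording(spec, seed = 42)
sim$recording
#> <grasp_recording> 64 EEG channel(s) x 17280 samples @ 100 Hz (172.8 s)
#>   kinematics: 15 joints
#>   events: 50 trials (can:10, card:10, cd:10, penny:10, screwdriver:10)

run <- run_decoding(sim$recording, pipeline_config())
run
#> <decoding_run>
#> <decoding_result> 8 fold(s), outputs: PC1, PC2, PC3
#>   median r: PC1=0.907, PC2=0.843, PC3=0.773
#>   synergies: first 3 explain 100.0% of velocity variance
#>   top channels: CP5, C3, C5, CP3, P1
```

The three decoded synergies are grasp aperture (finger MCP/PIP flexion),
hand spread (abduction) and thumb action; at the generator's in-band SNR of
10 the small session above cross-validates at r ≈ 0.91/0.84/0.77 (a full
250-trial session reaches ≈ 0.96/0.93/0.83). The channel ranking recovers
the informative sensorimotor/parietal channels, and the lag-contribution
map (`run$lag_contrib`) shows how the 0–100 ms lags share the decoding
weight. Chance levels from surrogate data sit at zero:

```r
chance_level_suite(sim$recording, pipeline_config(surrogate_reps = 2),
                   method = "fold")
#> <null_result> method=fold, 2 repetition(s)
#>   mean median-r: PC1=0.055 (sem 0.057), PC2=0.025 (sem 0.061), PC3=-0.093 (sem 0.033)
```

A command-line wrapper for the same stages
(`simulate | preprocess | decode | null | classify | report`) is installed
under `inst/cli/graspdecode`.

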