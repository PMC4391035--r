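---
title: "Decoding grasp kinematics from low-frequency EEG: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding grasp kinematics from low-frequency EEG: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(graspdecode)
```

## The problem

During a natural reach-to-grasp movement, the fifteen finger-joint angles of
the hand do not move independently: a handful of coordinated patterns —
*kinematic synergies* — carry most of the motion. The amplitude of scalp EEG
in the lowest frequency band (0.1–1 Hz) is modulated in the time domain by
these movements. `graspdecode` implements the offline analysis that makes
this quantitative: it reconstructs continuous joint angular velocities and
their synergies from multichannel EEG with a lagged linear (Wiener) decoder,
establishes empirical chance levels with surrogate data, maps which channels
and lags carry the information, and measures how much information 100 ms EEG
windows carry about *which* object is being grasped, using a multiple-kernel
SVM classifier.

Because no public recording accompanies this kind of experiment, the package
ships a synthetic-data generator that produces EEG/kinematics sessions with
exactly the statistical structure the analysis assumes. Every stage of the
pipeline is exercised, end to end, against data whose ground truth is known.

## The decoding model

The decoder is a Wiener filter: each decoded output $y_i[t]$ (a synergy
score or a joint angular velocity) is a linear readout of the preprocessed
EEG over a short causal history,

$$ y_i[t] = \beta_{0i} + \sum_{n=1}^{N}\sum_{k=0}^{L} \beta_{nki}\,
   \mathrm{EEG}_n[t-k], $$

with $N = 58$ channels and $L+1 = 11$ lags spanning 0–100 ms in 10 ms steps
at the 100 Hz decoding rate. Coefficients are estimated by ordinary least
squares per output. Accuracy is assessed with stratified 8-fold
cross-validation: within each fold the Pearson correlation $r$ between
predicted and observed outputs is computed over the concatenated test
samples, and the median across folds is reported. The per-sample (rather
than per-trial) correlation follows from the model being a time-invariant
readout; the stratified, seeded fold assignment is this package's choice —
the original fold construction is not specified anywhere we could follow.

Two derived statistics summarize a fitted model over the three synergy
outputs. The channel weight
$R_n = \tfrac{1}{L+1}\sum_k \sqrt{\sum_i \beta_{nki}^2}$
ranks channels for the best-$N$ accuracy curves, to which a double
exponential $a e^{bN} + c e^{dN}$ is fitted (Levenberg–Marquardt from eight
seeded starts spanning the rise-and-saturate sign patterns; the peak is the
integer argmax of the fitted curve, falling back to the raw argmax if no
start converges). The per-lag contribution
$\%T_k = 100 \cdot \sum_n \sqrt{\sum_i \beta_{nki}^2} \,/\,
\sum_{k'}\sum_n \sqrt{\sum_i \beta_{nk'i}^2}$
always sums to 100 and is exported together with the channel × lag map for
topographic plotting.

### Numerical notes on the least-squares solve

Band-limited EEG sampled at 100 Hz is extremely smooth, so the eleven lag
copies of a channel are nearly collinear and the normal-equations matrix is
numerically rank deficient *in the generic case*, not only for pathological
inputs. The solver therefore attempts a Cholesky solve first and falls back
to the minimum-norm least-squares solution via a symmetric
eigen-decomposition with a $10^{-10}$ relative eigenvalue cutoff.
`fit_wiener()` warns when this happens; `cross_validate()` reports it once
per run as a message rather than once per fold. Predictions are invariant to
whether features were standardized with global or training-fold statistics
(OLS with an intercept is invariant to affine feature rescaling), so the
choice matters only for coefficient-based statistics ($R_n$, $\%T_k$), which
are defined on the full-data model.

Cross-validation never re-stacks design matrices: per-fold moment matrices
($X^\top X$, $X^\top V$, sums) are accumulated once, training-fold normal
equations are obtained by subtracting the test fold, and best-$N$ channel
subsets reduce to sub-matrix solves. This makes the 58-step accuracy curve
and the surrogate repetitions affordable.

## Preprocessing chain

The order of operations is: detrend and zero-phase high-pass the EEG at
0.3 Hz (4th-order Butterworth, forward–backward, so the effective magnitude
response is squared and no group delay is introduced); an optional spatial
projection hook (see below); zero-phase low-pass at 1 Hz; exclusion of the
six peripheral channels (M1, M2, TP9, TP10, PO9, PO10); decimation to
100 Hz; first-difference differentiation scaled by the sampling rate.
Kinematics are low-passed at 1 Hz (no detrend — joint angles have meaningful
offsets), decimated and differentiated to angular velocities; the
signal-to-error ratio $\mathrm{SER} = 10\log_{10}(\mathrm{Var}/\mathrm{MSE})$
per joint quantifies what the filter removed. Both streams are segmented
from 400 ms before movement onset to 100 ms after movement offset, and the
(channel, lag) features are standardized to zero mean and unit variance.

Three choices deserve comment:

* **Differentiation scaling.** The first difference is multiplied by the
  target rate, giving physical units (deg/s, µV/s). This affects no
  correlation or subspace, but makes SER values and amplitudes
  interpretable.
* **Projection hook instead of interactive ICA.** Ocular-component
  identification is a manual, interactive step in the original workflow.
  The pipeline instead accepts any channels × channels projection matrix
  (e.g. identity minus an artifact subspace projector) between the
  high-pass and low-pass; estimating that subspace is out of scope.
* **Fold-safe vs. across-all-trials statistics.** Standardizing features
  and fitting the synergy PCA "across all trials" leaks summary statistics
  from test folds into training. The package defaults to a fold-safe mode
  (synergy model refitted per training fold; the OLS predictions themselves
  are unaffected by the standardization choice, see above) and retains the
  across-all-trials convention behind `fold_safe = FALSE`.

Sample indexing is 1-based with inclusive trial intervals, the native R
convention; a trial from onset − 400 ms to offset + 100 ms at 100 Hz spans
`offset − onset + 51` samples.

## Kinematic synergies

Synergies are the principal components of the pooled joint angular
velocities (sum of trial lengths × 15 matrix): covariance eigen-decomposition
with centering and no per-joint rescaling, since all joints share units.
Components are ordered by variance and sign-fixed so each column's
largest-magnitude loading is positive. The first three components are
retained for decoding. Projection onto all 15 components inverts exactly;
`reconstruct_velocities()` exposes the inverse map.

## Surrogate chance levels

Two empirical nulls bracket what "no association" looks like under the full
decoding procedure:

* **Phase scrambling** randomizes the Fourier phases of each channel of the
  continuous, band-limited, differentiated EEG (independently per channel)
  while preserving the magnitude spectrum exactly, hence also each
  channel's autocovariance. It is applied immediately before lag embedding:
  scrambling earlier would be partially undone by filtering, and scrambling
  after embedding would break the internal consistency of the lag copies.
* **Fold scrambling** permutes the lagged EEG tensors across trials while
  kinematics stay in place. The permutation is a derangement — no trial may
  keep its own EEG, otherwise some pairings survive by construction.
  Mismatched trial lengths are reconciled by truncating the pair to the
  shorter trial, and the truncation count is logged.

Each method is repeated (5 repetitions by default) with recorded derived
seeds, the full cross-validated decoding runs on each surrogate, and the
per-repetition median correlations are aggregated as mean ± s.e.m.

A caution on interpreting the fold-scrambled null: if the task's
trajectories were strongly stereotyped *in phase* across trials, a decoder
trained on scrambled pairings could still learn the pooled event-locked mean
trajectory from event-locked EEG and score well above zero. This is a real
property of the statistic, not a bug; the generator below is designed so
that, as in real grasping data where this null is observed to sit near zero,
the across-trial mean trajectory is weak.

## Grasp classification and information

For each window time $t$ relative to movement onset (−1000 to 3000 ms in
250 ms steps), each trial contributes one feature vector: the standardized
58 × 11 lagged EEG sample at onset + $t$, split into eight scalp
regions-of-interest (left/right frontal, temporal, sensorimotor,
parietal-occipital; midline channels deliberately unassigned so the regions
stay disjoint). Each region contributes RBF basis kernels at three relative
widths $\sigma \in \{5, 10, 15\}$ — 24 kernels in total. "Relative" is
interpreted as multiplying a data-derived scale: the median pairwise
distance of the region's training features. The kernel widths are fixed
configuration; data-driven width selection (e.g. by kernel alignment) is
deliberately out of scope.

The classifier is a simplex-weighted multiple-kernel SVM in the SimpleMKL
family: for fixed weights $d_m$ the C-SVC dual for the combined kernel
$K = \sum_m d_m K_m$ is solved exactly as a QP; a reduced-gradient step on
$d$ within the probability simplex follows, with a backtracking line search
that only accepts objective decreases. The objective is therefore
non-increasing across outer iterations, $d$ stays on the simplex at every
iterate, and with a single basis kernel the procedure reduces exactly to a
standard SVM. Multiclass problems use one-vs-rest with weights learned per
binary problem and argmax of the decision values; the multiclass variant is
a design choice here. The SVM cost defaults to $C = 1$ (also not determined
by anything we could follow).

Test predictions from a stratified 8-fold cross-validation are pooled into
a single 5 × 5 confusion matrix per window time, from which the mutual
information between measured and predicted grasp,
$I = \sum p(PG, MG) \log_2 \frac{p(PG,MG)}{p(PG)p(MG)}$ (with $0\log 0 = 0$),
is computed; $I$ is bounded by $\log_2 5 \approx 2.32$ bits. Pooling counts
across folds (rather than averaging per-fold matrices) is the package's
choice. Note that cross-validated mutual information carries a positive
small-sample bias of roughly $(C-1)^2 / (2 N \ln 2)$ bits for $C$ classes
and $N$ trials, so "zero information" at rest shows up as a small positive
number at realistic trial counts.

## The synthetic generator

`synthetic_spec()` defaults describe one session of the study conditions:
64-channel 10–20 EEG at 1000 Hz, 50 trials for each of 5 objects (can,
card, CD, penny, screwdriver), movement time 1.9 ± 0.3 s, 1–2 s inter-trial
rests, and 15 joint angles driven by 3 latent synergies.

* **Latent synergies.** Each trial's synergy velocity profiles are biphasic
  (an opening and a closing Gaussian bump, scaled so the net excursion is
  zero — the hand returns to rest within a trial). Per-object amplitude,
  timing and width constants live in `default_object_profiles()`. The
  object table was fixed by a one-off numerical design with three targets:
  the three synergies are mutually uncorrelated over the pooled session
  (so PCA identifies them individually, also after the 1 Hz low-pass, which
  widens bumps); the amplitude-weighted across-object mean of each profile
  nearly cancels (trials are mutually out of phase — without this the
  fold-scrambled chance level would be biased upward, see above); and the
  pooled velocity variance splits roughly in the 50/29/10 proportions
  typical of the first three grasp synergies. Per-trial amplitude jitter
  (10%) and timing jitter (5% of movement duration) emulate self-paced
  variability.
* **Kinematics.** Joint velocities are $W_\mathrm{true}\,\mathrm{PC}(t)$
  plus sensor noise (1 deg/s); angles are their running integral plus
  resting offsets. $W_\mathrm{true}$ is orthonormal with disjoint support:
  aperture on finger MCP/PIP, spread on the abduction joints, thumb on the
  thumb joints.
* **EEG forward model.** Twelve informative channels over contralateral
  sensorimotor/parietal sites each carry a linear mixture of the *running
  integrals* of the synergy profiles, at a channel-specific lead of
  40–100 ms. The integral (position-like) form is deliberate: the
  preprocessing chain differentiates EEG, and the discrete first difference
  of a running integral returns the original samples exactly, so after
  preprocessing the EEG is an exactly lagged linear image of the velocity
  synergies — the premise of the decoder, and the reason noise-free data
  cross-validate at $r \to 1$. Coupling EEG to the velocities directly
  would make the processed EEG a *derivative* of the decoding target, which
  no 100 ms FIR readout can integrate back.
* **Noise.** Channel noise is a mixture of white (30%) and $1/f$-shaped
  (70%) processes, scaled so that the ratio of clean-signal to noise
  variance *within the 0.1–1 Hz analysis band* on the informative channels
  equals the requested SNR (default 10); only that band survives
  preprocessing, so a broadband SNR would be misleading. `snr_sweep()`
  reuses one realization and rescales only the noise.
* **Ocular artifact (off by default).** A frontal spatial pattern times a
  low-frequency random walk, used by the artifact-robustness tests of the
  spatial-projection hook.

What the generator does *not* emulate: volume conduction between channels
(noise is independent per channel), non-stationary background rhythms,
movement or muscle artifacts in the pass band, electrode drift or
re-referencing effects, and any nonlinearity in the EEG–kinematics map.
Passing tests on this generator therefore demonstrate the correctness and
internal consistency of the pipeline under its own model assumptions — not
that real scalp EEG supports any particular accuracy. On real recordings
the attainable correlations are far lower than on SNR-10 synthetic data.

## Problem sizes used in validation

The acceptance checks (and `scripts/acceptance.R`) run one full session at
the default study conditions: 250 trials at 1000 Hz, the 58 × 11 feature
space, 8-fold cross-validation, 5 surrogate repetitions per method, and the
17-point information timeline. Unit tests use a 100 Hz, 10-trials-per-object
version of the same conditions, which keeps the full suite fast while
exercising identical code paths; thresholds in those tests are scaled to
the fixture (e.g. the surrogate-null envelope is wider, because a test fold
then holds only ~15 s of 0.3–1 Hz signal, about 30 effective samples).

## Known limitations

* The minimum-norm fallback makes coefficient *magnitudes* depend on the
  eigenvalue cutoff in the rank-deficient regime; $R_n$ and $\%T_k$ are
  stable in practice but are, strictly, properties of the regularized
  solution.
* The EDF writer quantizes to 16 bits of the per-channel range; round trips
  are exact only to that step. BrainVision float32 round trips to ~1e-7
  relative.
* `information_timeline()` windows are valid whenever they fall inside the
  recording; late windows (e.g. +3 s after onset of a 1.9 s movement)
  mostly sample rest and inter-trial activity, which is the intended
  behaviour for the timeline's falling edge.
* SimpleMKL's inner QP adds a tiny diagonal jitter when a combined kernel
  is numerically singular (warning above a threshold); with near-duplicate
  kernels the weight vector among duplicates is not identifiable, only
  their sum.
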