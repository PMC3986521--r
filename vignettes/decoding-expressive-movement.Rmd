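---
title: "Decoding expressive movement qualities from mobile EEG: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding expressive movement qualities from mobile EEG: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`mobidecode` implements a complete pipeline for decoding Laban effort
qualities — the dynamic factors Space, Flow, Weight and Time, each with
a condensing and an indulging element — from delta-band scalp EEG
recorded while a subject moves freely, together with body-worn
accelerometry used to audit motion artifact. This vignette explains the
model and the choices behind each stage, in the order data flows
through them.

## The experimental structure the package assumes

A session consists of trial blocks. Each block presents a *neutral*
segment (functional movement without expressive intent), then, for each
of the eight effort elements, a *think* segment (functional movement
while imagining the effort) and a *do* segment (enacting it). Within
each factor the condensing element (direct, bound, strong, quick) is
presented before the indulging one (indirect, free, light, sustained).
Two labeling schemes follow: *action* (neutral/think/do, 3 classes) and
*effort* (neutral plus think and do crossed with the 8 elements, 17
classes — all neutral segments collapse into one class).

## The synthetic session generator

The generator exists so every downstream stage is testable without any
recording. It emulates, by default, a 64-channel extended 10–20 montage
at 1000 Hz and 10 tri-axial inertial sensors at 128 Hz (head, torso,
lumbar, paired arms/thighs/shanks and a foot), three trial blocks, and
10 s condition segments. Its components:

* **Background EEG** is 1/f-shaped Gaussian noise per channel
  (amplitude shaped in the Fourier domain, with the shaping floored
  below 0.1 Hz so ultra-slow power stays finite), scaled to a 10 µV
  standard deviation.
* **Class signatures**: each of the 17 classes owns a delta-band
  (0.2–4 Hz) Gaussian-process time course and a random unit spatial
  pattern over channels, both fixed by the session seed. During a
  class's segments the signature enters the EEG scaled by
  `class_snr × 10 µV`. The default `class_snr = 2` — a class component
  twice the background SD along its pattern — was chosen once, at
  design time, as representative of a strongly decodable delta-band
  signal: the regime this method targets is one where effort classes
  are recovered with high accuracy, which requires the
  class-conditional in-band structure to dominate the background along
  some scalp direction. Because the signatures are zero-mean processes,
  class information lives in the class-conditional *covariance*
  (a direction of excess delta variance), not in class means; this is
  precisely the structure LFDA's locality weighting can exploit and
  classical FDA cannot.
* **Accelerometry**: each sensor/axis stream is 0.3–8 Hz band-limited
  noise under a class-conditional log-normal amplitude envelope (a slow
  0.03–0.3 Hz modulator exponentiated, heavier-tailed for vigorous
  classes). Envelope scales encode the qualitative kinematics of the
  classes: enacted free-flow and quick-time move most (scale 2.5),
  enacted light-weight and sustained-time least (0.3), think classes
  continue moderate functional movement. The log-normal modulation
  produces the mix of super- and sub-Gaussian first-PC distributions
  that heavy versus restrained movement shows.
* **Artifact coupling**: the head sensor's acceleration magnitude,
  interpolated to the EEG rate and standardized, is added to the EEG
  through a fixed nonnegative spatial pattern, scaled per class by
  `artifact_coupling` (κ ∈ [0, 1]). A single-sign pattern models the
  broadly common-mode deflections of cap/cable movement and makes the
  per-channel correlation medians respond monotonically to κ.
  κ scales, but never redraws, the underlying signals, so sessions
  differing only in κ (or in `class_snr`) are sample-path matched.

Generation is bit-identical for equal configurations and seeds; all
randomness is drawn under the seed in a fixed order. What the generator
does **not** emulate: genuine neurophysiological source geometry,
ocular/myogenic artifact, electrode drift or impedance changes,
non-stationary background spectra, or any coupling between the class
signature and the actual movement time course. Passing tests on this
synthetic data therefore demonstrate correctness of the pipeline's
machinery and its statistical behavior under the assumed structure —
not that real recordings decode at any particular accuracy.

## Preprocessing

The stage order is fixed: reject peripherals → resample → band-pass →
standardize → lag-embed → label.

* **Channel rejection** removes 25 peripheral electrodes (frontal pole,
  anterior-frontal rim, temporal chains, posterior rim, occiput) most
  exposed to muscle and motion artifact, leaving 39 of 64.
* **Transition trimming** shrinks every schedule segment by 500 ms at
  both onset and offset. Whether a trim applies at offsets as well as
  onsets is genuinely open; trimming both ends is the conservative
  choice. Trimming the *schedule* rather than deleting samples keeps
  filter context intact; segments shorter than twice the trim are
  dropped with a warning.
* **Resampling** to 100 Hz uses a zero-phase polyphase FIR
  (Hamming-window design, taps normalized to exact unit DC gain,
  linear-phase delay compensated, replicate-padded edges). DC signals
  pass unchanged to 1e-9 and in-band tones keep their amplitude to
  within 1%.
* **Band-pass** to 0.2–4 Hz uses a 3rd-order Butterworth applied
  forward and backward (zero phase). The high-pass edge at 0.2 Hz also
  removes slow trends and offsets. Because that edge's transient lasts
  on the order of 1/0.2 s, the signal is odd-reflection padded by
  3·rate/low samples before filtering; signals shorter than the minimal
  padding are refused.
* **Standardization** z-scores each channel over the whole trial using
  the population (1/n) SD convention — the convention is arbitrary but
  is documented and used consistently; a zero-variance channel is an
  error naming the channel.
* **Lag embedding** concatenates, channel by channel, the `l = 10` most
  recent samples (a 100 ms window at 100 Hz) into one row per time
  point: `n − l + 1` rows, `N·l` columns. Embedding never crosses
  trial-block boundaries when blocks are supplied as separate
  recordings. Rows are labeled by the trimmed segment containing their
  current-sample timestamp (half-open intervals, so boundary samples
  are never double-counted); unlabeled rows are dropped.

## Local Fisher discriminant analysis

LFDA maximizes locally weighted between-class scatter against
within-class scatter. Same-class pair affinities are
`A_ij = exp(−‖x_i−x_j‖²/(σ_i σ_j))` with the local scale σ_i the
distance to the `k_nn`-th nearest *same-class* neighbor (restricting
neighbors to the same class follows the formulation this pipeline
adopts; `k_nn = 7` default). Pair weights are `A_ij/n_c` within class,
`A_ij(1/n − 1/n_c)` within class for the between-scatter, and `1/n`
across classes; scatters are `½ Σ W_ij (x_i−x_j)(x_i−x_j)ᵀ`, assembled
in O(Σ n_c² d) via per-class Laplacians plus closed-form cross-class
terms. The transform is the top-`r` generalized eigenvectors of
`S^b v = λ S^w v` (Cholesky whitening, symmetric eigensolve), each
column unit-norm — no λ-weighting, since the mixture stage is
scale-adaptive — with a deterministic sign convention (largest-|entry|
positive) so fits are reproducible up to nothing at all. With all
affinities forced to 1 the construction reduces exactly to classical
FDA, which the tests exploit as a closed-form oracle.

Numerical choices: if the within-scatter Cholesky fails (lag-embedded
features are highly collinear), a ridge of `1e-9·trace/d` is added,
escalating by 10³ steps to at most `1e-3·trace/d`, with a warning.
Classes larger than 5 000 rows are reproducibly subsampled for scatter
estimation, since affinities are quadratic in class size.

## The Gaussian mixture classifier

Each class is modeled by its own full-covariance Gaussian mixture in
the reduced space. For each candidate component count `K ∈ 1..K_max`
(default `K_max = 10`), EM runs from a seeded k-means partition until
the relative log-likelihood improvement drops below 1e-6 or 500
iterations; three k-means restarts per `K` are kept as a greedy
best-of-restarts scheme (the insertion-schedule variant of greedy EM is
deliberately not implemented: no schedule is canonical, and restarted
k-means initialization achieves the same guard against poor local
optima). The `K` minimizing BIC wins.

Two BIC forms are provided. The default "standard" form is
`−2L + p·log n` with the full free-parameter count
`p = (K−1) + Kr + Kr(r+1)/2`. The "as-printed" form `−2L + 2·log n`
carries no parameter-count term and therefore cannot penalize larger
`K`; it is retained as a fidelity mode only, and model selection under
it is not meaningful. Because BIC is in practice quasi-convex in `K`
on this data, the scan stops after two consecutive BIC increases
(`k_patience = 2`; set it to `Inf` for the exhaustive scan).

Degenerate situations are handled explicitly: data with no spread at
all is a hard error; a covariance that loses positive definiteness
during EM gets a `1e-6·I` jitter, and since a jittered step is no
longer an exact EM step, a likelihood decrease immediately after one
reverts to the pre-jitter iterate and stops (a decrease in an exact
step remains a hard error — EM monotonicity is asserted every
iteration). At `K > 1` a numerically failed candidate (component
collapse on unimodal data) is dropped from the scan with a warning
rather than aborting model selection; `K = 1` failures propagate.

Posteriors assume equal class priors — the cross-validation design
enforces balanced classes, and the paper-style evaluation compares
against a uniform chance floor — and exact ties in the argmax break to
the lexicographically smallest class label.

## Evaluation

Cross-validation is balanced random subsampling: per iteration,
`floor(pct_train% · min_class_size)` training rows per class and an
equally balanced, disjoint test set of `min_class_size − n_train` rows
per class (balancing the test set the same way as the training set is a
design choice that keeps accuracy directly comparable to 1/#classes).
Ten iterations are the default; the standard error is SD/√n_iter.
Confusion counts pool over iterations; per-class sensitivity,
precision and F_β (default β = 1, where the weighted harmonic mean
coincides with both written forms of the F formula) come from the
pooled matrix. Forward channel selection scores each channel's lag
block alone, then greedily grows the selected-channels list, using a
light 3-iteration inner CV per candidate (the search is quadratic in
channel count) and re-estimating the reported curve at 30 iterations;
ties break in channel-label order.

## Motion-artifact QC

The audit correlates *raw* EEG — resampled to the analysis rate but
unfiltered, so broadband artifact is visible — with the head-sensor
acceleration magnitude or the first acceleration PC ("first synergy"),
per class and per channel, at zero lag only (no lag search; one ρ per
channel/class, per-class segments rather than the full session).
Accelerometer streams are linearly interpolated onto the EEG grid.
PCA of the ten per-sensor magnitude series summarizes movement
synergies; per-class kurtosis of PC1 (plain convention, Gaussian = 3)
summarizes tail weight. Spectrograms use 1024-sample windows with 93%
overlap over 0.1–40 Hz; coherence uses Welch averaging of Hann-windowed
1024-sample segments at 50% overlap (the canonical Welch parameters,
since only the method, not its parameters, is prescribed by
convention). The F1-versus-correlation audit pairs each class's median
channel ρ with its F1 score and reports a Spearman rank correlation
with a one-sided permutation p-value (10 000 shuffles); constant inputs
yield a rank correlation of 0 by convention.

## Laban-space projection

Classifier posteriors map linearly onto the four effort axes: the
coordinate on factor f is the signed posterior mass of the classes on
that factor, indulging elements positive, condensing negative, think
and do posteriors of the same element pooled, neutral contributing
nothing. The projection formula itself is underdetermined by its
originating description; signed posterior mass is the canonical choice
here because it is linear, bounded in [−1, 1] by posterior
normalization, sends a neutral-only posterior to the origin, and
reproduces the octahedral clustering of confidently classified samples
with unclassifiable samples near the center. Rows whose largest
absolute coordinate falls below τ = 0.1 are flagged non-expressive; τ
is a display threshold, not a statistical one.

## Problem sizes used in tests and the acceptance script

End-to-end checks run on 16 central channels at 100 Hz with the default
three blocks of 10 s segments (45 900 feature rows, 2 700 per class),
LFDA at r = 70, k_nn = 7, K_max = 10, ten 50% subsampling iterations —
a size at which every stage's statistics are stable and a full run
completes comfortably on one CPU. Unit tests use smaller sessions
(typically 8 channels, one block, 4–6 s segments) and low-dimensional
Gaussian class clouds where the property under test does not need EEG
structure.

## Known limitations

* **Temporal leakage of random subsampling.** Delta-band EEG is
  autocorrelated over seconds, so rows milliseconds apart are nearly
  identical, and random subsampling places such neighbors in training
  and test sets. On signal-free sessions (`class_snr = 0`) the pipeline
  therefore scores far above the 1/17 or 1/3 chance floors: LFDA's
  locally scaled affinities convert slow in-band background components
  into segment-specific "time stamps" that identify a segment — and
  hence its label — rather than any class signal. This is a property
  of the evaluation design being implemented, and it is surfaced, not
  silently repaired: the leakage-free guard is the label-shuffle test
  (shuffling labels breaks the label–time association, and measured
  accuracy falls to chance), which the test suite asserts, while the
  null-session accuracies are reported as computed. Block-wise or
  temporally stratified splits would remove the leakage but would be a
  different evaluation protocol than the one this package reproduces.
* The generator's class signatures are stationary single-pattern
  processes; real effort-specific EEG is presumably nonstationary and
  multi-source. High synthetic accuracies should be read as machinery
  validation, not as forecasts for real data.
* LFDA subsampling caps scatter estimation at 5 000 rows per class;
  far larger classes contribute a random subset per fit (seeded, so
  reproducible).
* The BrainVision writer emits multiplexed IEEE float-32 with a minimal
  marker file; exotic header variants (segmented recordings, non-µV
  units) are out of scope, as are EDF/BDF/XDF.
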