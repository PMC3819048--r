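---
title: "A current-source-density index of extended-text reading comprehension"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A current-source-density index of extended-text reading comprehension}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csdread)
```

## The problem and the design

Reading a story engages integration processes that single-word paradigms do
not reach.  The design this package analyzes contrasts two readings of the
same word stream: a *scrambled* condition (words in random order) and a
*comprehension* condition (words in story order, followed by a comprehension
test), both with a concurrent detection task on a rare target word
(about 2.4% of tokens, one word every 500 ms).  Because the target word is
identical in both conditions, the ERP difference between conditions isolates
comprehension-related processing from word-level decoding.

The derived measure — the *CSD index* — is the scrambled-minus-comprehension
difference of the current-source-density (CSD) transformed target-word ERPs
at a frontal-midline site (AFz) averaged over 400–500 ms after target onset.
Readers who comprehend well flip a frontal current source (scrambled) into a
current sink (comprehension); poor comprehenders show a source in both
conditions, so the difference tracks comprehension ability.

The pipeline has five analysis stages, each exposed as ordinary functions:

1. **Epoching** (`extract_epochs`, `select_target_trials`, `apply_baseline`,
   `average_erp`): 500-ms target-locked epochs, baselined to the first
   50 ms *after* onset (at one word per 500 ms the previous word's response
   is still unfolding at onset, so a pre-stimulus baseline is unusable);
   targets are kept only if correctly detected and if none of the four
   preceding word positions was also a target (a repetition-priming guard).
2. **CSD transform** (`build_gh_matrices`, `csd_transform`,
   `difference_csd`): spherical-spline surface Laplacian.
3. **Classification** (`bin_features`, `run_titration`, `permutation_null`,
   `classify_bins`): eight overlapping 100-ms bins, two-stage random-forest
   titration, 1000-run averaging (configurable), scrambled-label null.
4. **Index statistics** (`extract_csd_index`, `correlate_with_ellipse`,
   `condition_group_unpack`, `behavioral_anova`, `order_analysis`).
5. **Synthesis** (`cohort_config`, `generate_cohort`, `run_pipeline`):
   a ground-truth generator and an orchestrated, seeded pipeline.

## The CSD transform

Scalp potentials are interpolated with the spherical spline
$u(x) = c_0 + \sum_i c_i\, g(\cos\theta(x, x_i))$, where
$g(t) = \frac{1}{4\pi}\sum_{n\ge1} \frac{2n+1}{(n(n+1))^m} P_n(t)$ and the
coefficients solve the augmented system with smoothing $\lambda$ on the
diagonal of $G$ and the zero-sum constraint $\sum_i c_i = 0$.  Because the
Laplace–Beltrami operator maps $P_n$ to $-n(n+1)P_n$, the surface Laplacian
of the spline only changes the kernel: $h(t) = \frac{1}{4\pi}\sum_{n\ge1}
\frac{2n+1}{(n(n+1))^{m-1}} P_n(t)$.  The CSD is defined as *minus* the
surface Laplacian scaled to physical units,
$\mathrm{CSD}_j = \frac{1}{r^2}\sum_i c_i\, h(\cos\theta_{ij})$ in
µV/cm², so current sources are positive and sinks negative.

Numerical properties that the tests pin down:

* adding any channel-constant to the input leaves the CSD unchanged
  (reference independence is exact in the augmented solve, verified to
  1e-8 relative);
* a channel-constant input maps to exactly zero;
* on a degree-1 spherical harmonic the output correlates > 0.99 with an
  independent finite-difference Laplace–Beltrami oracle computed on a dense
  polar grid;
* magnitude scales as $r^{-2}$ with the head radius, so doubling the radius
  quarters the CSD.

Defaults follow the common spherical-spline convention: order $m = 4$,
$\lambda = 10^{-5}$, 50 Legendre terms (the $h$-series tail at $n = 50$ is
below $10^{-6}$ of the diagonal; a warning is recorded if a configuration
has not converged), and a 10-cm head radius, which fixes the µV/cm² scale
reported everywhere.

### The montage

Electrode positions are an idealized unit-sphere 10-10 layout generated
geometrically: the nasion–inion–preauricular plane is the equator, the
20-site circumferential ring (Fpz, Fp2, AF8, ..., Oz, ..., Fp1) sits at 72°
inclination at 18° azimuth steps, midline sites step 18° along the sagittal
arc, and each inner row is spaced at equal arc fractions along the circle
through its two ring ends and its midline site.  No digitized coordinates
are bundled; for this analysis the identity of the site (AFz) matters far
more than millimetric accuracy.

## The classifier

Per time bin, the feature matrix is subjects × 64 sites of bin-averaged
difference-CSD.  One *run* of the two-stage titration is:

* **Stage 1** — a bagged ensemble of 300 decision trees, each trained on a
  fresh random 65% of the subjects with $\lceil\sqrt{p}\rceil$ candidate
  sites per split, yielding per-site weights (permutation importance:
  held-out accuracy drop when a site's values are shuffled, averaged over
  trees and clamped at zero — chance importances can dip below zero).
* **Stage 2** — the same ensemble restricted to the 10 highest-weight sites
  (ties broken by fixed site order).  The run's accuracy is the mean over
  stage-2 trees of each tree's accuracy on its own held-out 35% of
  subjects; per-tree averaging keeps the variance bookkeeping symmetric
  with the permutation null.

Runs are averaged (1000 by default; the examples and tests use 30–100) and
compared with an equal number of scrambled-label runs — a uniform
permutation of the good/poor labels, which preserves class counts — using
three statistics: an independent-groups t test over run accuracies, the
effect size d (mean difference over pooled SD), and hit/false-positive
proportions at an unbiased criterion midway between the two means.  A note
on the t test: with 1000 runs per distribution its degrees of freedom are
huge and the statistic is not a conventional inferential quantity; it is
reported as a descriptive separation measure alongside d, as is standard
for this procedure.  Accuracy distributions, mean site weights and the
statistics are assembled per bin by `classify_bins()`; no multiple-testing
correction is applied across bins.

Two contract details are worth stating because the procedure leaves them
open: (i) the 1000 runs re-draw both the trees and each tree's 65% subject
subsample; (ii) stage-2 accuracy uses per-tree held-out subjects rather
than a pooled vote.  Both are recorded in the report output.

## The synthetic cohort generator

`generate_cohort()` simulates complete studies with known ground truth; it
is the package's test bed and ships a ledger (abilities, true effect
site/window/amplitude, injected saccade counts) with every cohort.

**What it emulates.**  28 subjects; 1182 words per condition at a 500-ms
SOA; 28 targets placed uniformly (re-drawn per subject in the scrambled
condition, fixed across subjects in the comprehension condition, as the
story's text is fixed); a posterior visual evoked response after every word
in all subjects and conditions; and the frontal effect: a target-locked
component at AFz that is a current source for everyone in the scrambled
condition and flips toward a sink in the comprehension condition in
proportion to the subject's latent ability, so the difference amplitude is
$2 \cdot \texttt{effect\_amplitude\_uv} \cdot a$.

**Forward model.**  Each component is injected as the scalp potential of a
focal radial current source: a zero-sum center–surround Gaussian patch in
source space (10° core, 25° return) mapped through the same spherical-spline
volume-conduction model the analysis assumes.  The potential is therefore
spatially broad (volume-conducted) while the component's true
current-source distribution — what the surface Laplacian estimates — is
focal at its site.  A plain interpolation-kernel smear was tried first and
rejected: its Laplacian is nearly flat across neighboring sites, which
makes site recovery meaningless rather than hard.

**Nuisance structure** is chosen so that each preprocessing step of the
pipeline is load-bearing:

* a per-subject frontal gain (SD 16 µV) shared by both conditions defeats
  single-condition classification and cancels exactly in the difference;
* a channel-constant slow drift (24 µV, 0.3–1.2 Hz, re-drawn per subject
  and condition) defeats classification of non-CSD difference-ERPs and is
  removed exactly by the Laplacian;
* background noise is AR(1) (stationary SD 3 µV, lag-1 0.9) plus an
  alpha rhythm (4 µV, frequency drawn per channel from 8–12 Hz — a fixed
  10-Hz alpha would phase-lock to the 500-ms word cadence and survive
  averaging, which real, frequency-wandering alpha does not) plus 1 µV
  white sensor noise; brain noise is mixed across channels through the
  spline kernel (weight 0.85) because scalp background activity is
  volume-conducted, while only sensor noise is channel-independent.

**Ability and scores.**  Latent ability is bimodal — a poor cluster
U(0.05, 0.35) and a good cluster U(0.65, 0.95), with an exact seeded composition of 15 good and 13 poor per 28-subject cohort (a recruited sample, not an iid draw) — reflecting
the two reader populations the comprehension test dichotomizes.  Scores are
produced by actually answering a synthetic 4-question multi-select test
(scored with `score_test`, all-or-none per question); each question is
answered correctly with probability `plogis(-6.9 + 16 * ability)`, giving
the good cluster near-ceiling scores, the poor cluster mostly 0–2, and an
expected 13/15 split at the 0–2 / 3–4 cutoff.

**Behavior.**  Both groups respond slower (450 vs 520 ms) and less
accurately (2% vs 7% errors) in the comprehension condition, with no
built-in group effect or interaction — so the behavioral 2×2 mixed ANOVA
shows a condition main effect only, confirming equivalent task engagement.
Condition order is counterbalanced and unrelated to anything by
construction.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: no lexical or semantic content (no N400 congruity
structure), no blink/EMG/line-noise artifact zoo beyond EOG saccade steps,
no realistic head geometry (the forward model is the analysis sphere), and
noise levels scaled so that a 28-subject study has stable recovery rather
than human-scale inter-subject variance.  Amplitudes (16 µV effect, 24 µV
drift) are stylized operating points, not physiological estimates.

**Simulation paths.**  The default fast path draws the target-locked epochs
directly; the continuous path (`simulate_subject_eeg`, used by the EDF/CLI
workflow) materializes whole recordings and cuts epochs from them.  The two
share all parameter draws, the epoch-level distributions match, and both
are exercised in the tests.  The default sampling rate is 256 Hz for speed;
1024 Hz is supported and changes nothing but the grid.

## Statistics downstream of the index

* `correlate_with_ellipse` fits a bivariate normal (sample mean and
  covariance), flags points whose Mahalanobis distance exceeds the
  chi-square(2) quantile at the coverage (95% default), and reports Pearson
  r with and without them in a single pass — no iterative re-trimming, so
  28 subjects with 3 outliers give the trimmed df of 23.  Exactly collinear
  input degenerates the ellipse; nothing is trimmed and r is ±1.  Raw
  values, not ranks, are used.
* The 2×2 mixed ANOVA (condition within, group between) is computed from
  the per-subject condition difference and mean with sum contrasts, which
  handles unequal group sizes Type-III style and matches `aov()` with
  Error strata on balanced designs (cross-checked in the tests); degenerate
  0/0 F ratios are defined as 0, and a zero-residual fit with a nonzero
  effect reports an unbounded F.
* `order_analysis` combines a score-by-order t test, per-order ellipse
  correlations (skipped with a notice below n = 4), and an OLS regression
  of score on index and order with per-coefficient t statistics.
* `count_saccades` uses a two-sided sliding-mean step estimator (30-ms
  windows, 40-µV threshold, 80-ms refractory, pooled across EOG channels);
  it recovers injected step counts on noiseless EOG in > 99% of epochs.

## Numerical and engineering choices

* Time intervals are half-open and floor-aligned to the sample grid: the
  [0, 50) ms baseline at 256 Hz is samples 1–12, a 100-ms bin is 26
  samples, and the epoch [0, 500) at 1024 Hz is exactly 512 samples.
* A single global seed fans out to every stage through a multiplicative
  counter scheme (`derive_seed`), so cohorts, runs, and permutations are
  independently reproducible; all derived seeds stay below 2^31.
* The EDF reader/writer implements the continuous 16-bit subset of the
  format (uniform sampling rate, 1-s records, final record padded with the
  true sample count recorded in the header); round-trips are exact to
  quantization and cross-checked against an independent reader.
* Problem sizes in the test-suite: unit tests use reduced word streams
  (60 words, 8 targets) and 3–50 run titrations; the end-to-end recovery
  checks use the full 28-subject default cohort with 100-run averaging and
  20 replications, and the null calibration uses 10 cohorts at 50 runs.
  These counts are the package's chosen verification sizes; the analysis
  defaults themselves (300 trees, 1000 runs) match the procedure the
  pipeline implements.

## Known limitations

* The spline Laplacian's spatial resolution is bounded by electrode
  spacing; adjacent sites (AFz vs AF3/AF4) carry strongly correlated CSD
  signal, which is why the generator's source must be genuinely focal for
  site recovery to be well-posed.
* Permutation importance divides credit among correlated sites; the
  top-weight site is a statement about the ensemble average, not any
  single tree.
* The blink/artifact rejection of a full EEG lab pipeline is reduced to
  the saccade counter plus the assumption of pre-filtered input
  (0.1–100 Hz); no ICA or regression-based ocular correction is provided.
* `load_cohort` expects the dataset layout this package writes; it is not
  a general BIDS/BrainVision importer.
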