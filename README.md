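# csdread

An R package for deriving a **current-source-density (CSD) index of
extended-text reading comprehension** from event-related potentials (ERPs),
and for validating the full derivation pipeline on synthetic cohorts with
known ground truth.

## The problem

When people read a story rather than isolated words, comprehension engages
integration processes that word-level ERP paradigms cannot isolate.  The
design implemented here contrasts two presentations of the same word stream
— a *scrambled* order and the original *comprehension* order — while the
reader performs a detection task on a rare target word (~2.4% of tokens, one
word every 500 ms).  Because the target word is physically identical in both
conditions, the condition difference of its ERP isolates comprehension-
related processing.

The core measure is the **CSD index**: the scrambled-minus-comprehension
difference of the CSD-transformed target-word ERPs at the frontal-midline
site AFz, averaged over 400–500 ms after target onset.  Good comprehenders
flip a frontal current source (scrambled) into a current sink
(comprehension); poor comprehenders do not, so the index tracks
comprehension ability.

The CSD transform is the spherical-spline surface Laplacian: potentials are
interpolated as u(x) = c₀ + Σᵢ cᵢ g(cos θ(x, xᵢ)) with
g(t) = (1/4π) Σₙ (2n+1)/(n(n+1))ᵐ Pₙ(t), and the CSD is minus the surface
Laplacian, obtained by swapping in the kernel with exponent m−1 and scaling
by 1/r² (µV/cm², sources positive).  Site-by-time-bin difference-CSD
features feed a two-stage random-forest *titration*: stage 1 ranks all 64
sites by permutation importance (300 trees, each trained on a random 65% of
subjects), stage 2 re-classifies from the top 10 sites; run accuracy is the
mean per-tree held-out accuracy, averaged over many runs and compared with
a scrambled-label permutation null via t, effect size d, and hit/false-
positive rates at an unbiased criterion.

## A worked example

```r
library(csdread)

# simulate a 28-subject study with the default effect at AFz in 400-500 ms
cohort <- generate_cohort(cohort_config(seed = 300))
cohort
#> <cohort> 28 subjects (15 good / 13 poor), 28 targets/1182 words, fs 256 Hz,
#>          effect 16 uV at AFz 400-500 ms

# ERPs -> CSDs -> difference maps -> binned features
mm    <- cohort_maps(cohort)                       # difference-CSD per subject
feats <- bin_features(mm$maps, mm$labels)          # 8 bins x 64 sites

# two-stage titration with permutation null (30 runs here for speed)
report <- classify_bins(feats, titration_config(n_runs = 30, n_null_runs = 30,
                                                seed = 1))
report
#> <classification_report> feature mode: difference_csd
#>       bin mean_accuracy sd_accuracy null_mean null_sd top_site
#> 1  50-150         0.566       0.021     0.594   0.039       P8
#> ...
#> 7 350-450         0.796       0.012     0.589   0.052      AFz
#> 8 400-500         0.906       0.008     0.603   0.048      AFz
#> best bin: 400-500 ms; top site there: AFz

# the CSD index and its relation to the comprehension score
idx <- extract_csd_index(mm$maps)                  # AFz, [400, 500) ms
correlate_with_ellipse(idx$csd_index, cohort$subjects$score)$r_trimmed
#> [1] 0.958
```

The classifier singles out the 400–500 ms bin and AFz (the site and window
where the generator injected the effect), with held-out accuracy 0.91
against a 0.60 permutation-null baseline, and the index correlates 0.96
with the comprehension score after 95%-confidence-ellipse trimming — the
full parameter-recovery loop.

`run_pipeline(run_config(...))` orchestrates the same stages end to end and
writes a report bundle (classification JSON, subject CSV, statistics JSON,
ground-truth ledger, human-readable summary).  A thin command-line front
end lives at `inst/cli/csdread.R` (subcommands `simulate`, `classify`,
`all`).

## Package layout

| area | contents |
|---|---|
| `R/montage.R`, `R/edf.R`, `R/events.R`, `R/epochs.R`, `R/saccades.R` | montage/.sfp, minimal EDF I/O, event tables, epoching/baselining/averaging, EOG saccade counting |
| `R/csd.R` | spherical-spline G/H kernels, CSD transform, difference maps |
| `R/scoring.R` | multi-select test scoring, exact chance distribution, group split |
| `R/features.R`, `R/classify.R` | time-bin features, two-stage titration, permutation null, significance |
| `R/index_stats.R` | CSD index, ellipse-trimmed correlation, 2×2 mixed ANOVAs, order controls |
| `R/synthetic.R` | ground-truth cohort generator (fast epoch path + continuous EDF path) |
| `R/pipeline.R`, `inst/cli/csdread.R` | orchestration, YAML config, CLI |

The methods vignette (`vignettes/csd-comprehension-index.Rmd`) documents the
model, the generator's assumptions and limitations, and every numerical
convention (half-open sample-grid intervals, seed fan-out, units).
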