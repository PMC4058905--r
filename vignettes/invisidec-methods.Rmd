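---
title: "Methods: simulated multivoxel decoding of visible and invisible object categories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated multivoxel decoding of visible and invisible object categories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The analysis this package implements

`invisidec` re-implements, as a tested and reusable pipeline, a whole-brain
region-of-interest (ROI) multivoxel pattern analysis for two-class category
decoding (faces vs. tools) from fMRI response patterns acquired under three
presentation methods: fully visible viewing (`VIS`), continuous flash
suppression (`CFS`, a dichoptic suppression method) and chromatic flicker
fusion (`CFF`, isoluminant counterphase flicker above the fusion threshold).
The scientific question the design serves is whether the *method* used to
render a stimulus invisible changes where in the brain category information
survives — so the pipeline must support within-method decoding, decoding
that generalizes across methods, and group inference that compares them.

The chain is:

1. **Design** — per-subject randomized run orders that minimize first- and
   second-order category-transition predictability, with slow event-related
   timing (2 s trials, 6 or 8 s ISIs, 242 volumes of 2 s per run).
2. **Behavioral QC** — breakthrough trials discarded; (run, method) blocks
   with invisible guessing accuracy strictly above 75% discarded; runs
   lacking two usable exemplars per category discarded per method.
3. **Decoding** — cross-exemplar leave-one-run-out linear SVM
   classification per (subject, ROI, regime), scored as d′.
4. **Group inference** — one-sided t-tests of d′ against chance, visible
   gating, Benjamini–Hochberg FDR within each analysis family, and paired
   method contrasts.

Because no raw scans are distributed with the source study, the pipeline is
exercised end-to-end on synthetic multivoxel data whose statistical
structure matches what the analysis assumes; the generator is first-class,
tested code.

## The synthetic data model

Each ROI `r` carries one unit *coding axis* per method,
`w_{r,m} = ρ_r w_shared + sqrt(1 − ρ_r²) w_unique,m`, with the unique parts
orthogonal to the shared axis. The overlap parameter `ρ_r ∈ [0, 1]` controls
how similar the category representation is across methods — `ρ = 1` makes
cross-method transfer as easy as within-method decoding, `ρ = 0` abolishes
it in expectation. A trial of category sign `s` (face +1, tool −1), method
`m`, exemplar `e` and outline color `c` has mean pattern

```
μ = s · a_{r,m} · w_{r,m} + ε_e + c · σ_color · v_r
```

where `a_{r,m} ≥ 0` is the planted amplitude, `ε_e` is an exemplar-specific
offset drawn once per subject (sd 0.3) and *reused across runs* — so the
cross-exemplar split genuinely tests generalization beyond exemplar
identity — and `v_r` is a color-nuisance direction constructed exactly
orthogonal to every category axis (color never enters the analysis; the
orthogonality guarantees it cannot masquerade as category signal). The color
term vanishes for CFF trials, whose two scheduled "color slots" are
physically the same flickering red/green compound. Trial mode adds i.i.d.
Gaussian noise (sd 1 by default); timeseries mode instead convolves trial
means with a double-gamma HRF (peak 5 s, undershoot 15 s, conventional
values — acquisition modeling is out of scope) sampled at TR = 2 s and adds
AR(1) noise (coefficient 0.3).

Scenario presets encode the source study's qualitative map: `paper_like`
plants visible information in all 12 ROIs, CFS information only in the
lateral/medial occipital subset (MOG, LG, MLOS), CFF information in LG, FG
and SPCS, and high ρ (0.9) only in posterior-occipital ROIs — so
cross-invisible transfer is expected only in LG, the lone ROI carrying both
invisible signals with a shared axis. `null` zeroes every amplitude;
`full_transfer` sets ρ = 1 everywhere.

**What a green test does and does not establish.** The generator emulates
planted linear category structure with Gaussian noise, exemplar offsets and
an orthogonal nuisance. It does not emulate retinotopic spatial structure
within ROIs, physiological or motion noise, inter-subject anatomical
variability, or non-linear coding. Recovery of the planted map therefore
validates the *pipeline logic* (splits, exclusions, pooling, inference), not
any empirical claim about brains.

### Parameter choices and calibration

Behavioral rates are the study's reported group means: invisible guessing at
chance (0.5), breakthrough on 3.1% (CFS) and 4.3% (CFF) of invisible
trials, visible accuracy 99.4%, visible "seen" reports 96.2%. Cohort size
defaults to 17 subjects × 8 runs (= 136 runs).

Planted amplitudes default to 1.5 (visible) and 1.2 (invisible) at noise sd
1. These were chosen *a priori* so that planted (ROI, method) cells are
detected with near-1 power at n = 17 — the recovery property the test suite
demands in ≥ 90% of replications — rather than to reproduce the source
study's d′ magnitudes (~0.2–0.7); simulated group d′ values are accordingly
larger (~1). The amplitude is a per-condition effect size in pattern-space
units of noise sd, not a calibrated BOLD quantity.

## Numerical and procedural choices

* **Transition score.** The optimization target is
  `|P(repeat at lag 1) − 0.5| + |P(repeat at lag 2) − 0.5|` over the run's
  category sequence — the stated counterbalancing goal made computable. The
  lag-2 term uses the *marginal* repetition probability; a variant
  conditioning on the intermediate trial would be a config extension, not
  the default. The search draws 10,000 uniform shuffles by default
  (desk-scale; the candidate stream is sequential, so the best score is
  non-increasing in the candidate count for a fixed seed) and only
  optimizes category labels; exemplar/color/method slots are filled by an
  independent uniform shuffle. `run_full_analysis()` defaults to 200
  candidates because order quality cannot affect decoding of trial-mode
  synthetic data.
* **Timing layout.** 48 trials at mean 9 s spacing occupy ~436 s of the
  484 s run; a 4 s lead-in and trailing rest fill the remainder (the layout
  of padding is not specified by the design, only the totals).
* **Exclusion rules.** "Greater than 75%" is a strict inequality on
  observed accuracy; the exact cumulative binomial tail (P(X ≥ 13 | 16,
  0.5) ≈ 0.011 for a full block) is computed and logged but the accuracy
  threshold is operative. The minimum-exemplar rule is implemented as
  "every category × exemplar-set cell non-empty", the weakest condition
  under which the averaged cell patterns exist. CFS and CFF guessing are
  tested separately per run ("per trial type"); pooling is a flag.
* **Cell averaging.** Usable trials are averaged within run × method ×
  category × exemplar-set — two patterns per category per run per method —
  the only reading that reconciles "a single pattern per category per run"
  with exemplar-disjoint train/test sets.
* **Folds.** Within-method: for each held-out run and each exemplar-set
  direction, train on the other set's cells from the remaining runs
  (2 × runs folds; the held-out run and the test exemplars never appear in
  training). Cross-method: train on method A's cells from runs other than
  the held-out run, test on method B's cells of that run; the
  cross-exemplar constraint is kept by default for comparability and can be
  disabled.
* **Classifier.** Linear SVM (hinge loss, C = 1), fit by deterministic
  cyclic dual coordinate descent implemented in C++ (no SVM dependency is
  available in the target environment). Stopping tolerance 1e-4 on the
  projected gradient — far tighter than the common liblinear default of
  0.1. Features are z-scored per voxel on training statistics only.
  Decision ties (score exactly 0) predict "tool", deterministically.
* **Scoring.** Confusion counts are pooled across a plan's folds before one
  d′ computation (per-fold counts are tiny: two test patterns per fold);
  per-fold averaging is available as a flag. d′ uses the log-linear
  (+0.5) correction so perfect classification stays finite.
* **Inference.** One-sided one-sample t against 0 per (ROI, regime), df =
  n − 1 with pairwise-complete subjects; BH step-up FDR at q = 0.05 within
  each analysis family; the visible family over all ROIs gates every
  downstream family. Paired method contrasts run where at least one of the
  two regimes was significant, one-sided in the direction of the observed
  mean difference (the study's reported paired t ≈ 1.8 values at df 16 are
  only significant one-sided), with raw and BH-adjusted p both reported —
  whether such contrasts should themselves be FDR-corrected is left to the
  reader, so both are emitted.
* **Degenerate inputs.** Single-category order sequences score 0.5 + 0.5
  and are flagged degenerate; zero-variance t-tests return NA with a
  warning; subjects with fewer than two retained runs for a method yield NA
  d′ for that regime (dropped pairwise at group level, n reported); an
  empty visible gate skips downstream families with a warning.

## Known limitations

* The NIfTI-1 support is deliberately minimal (single-file uncompressed
  volumes, float/int types, endian detection) — enough for round-tripping
  the package's own outputs and reading simple preprocessed volumes, not a
  general neuroimaging i/o layer.
* No GLM/deconvolution: trial patterns are the mean of the volumes 4 s and
  6 s post-onset, as in the original analysis; overlapping responses from
  the 6–8 s ISIs are treated as noise.
* Group inference is a fixed-effects-across-subjects t on d′; no
  mixed-effects or Bayesian models, no searchlight, no surface
  visualization.
* The generator is symmetric in training and testing method: wherever
  `cross:VIS-CFS` transfer is planted, `cross:CFS-VIS` transfer follows. It
  therefore cannot emulate the empirically reported asymmetry in which only
  visible-trained classifiers generalize (plausibly a training-SNR effect);
  the cross-method machinery itself distinguishes the two directions.
* With 17 subjects the binomial granularity of pooled confusion counts
  (32 test patterns per subject) makes subject-level d′ discrete; t-tests
  treat it as continuous, which is standard but approximate.
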