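---
title: "Methods: simulation, preprocessing and biomarker discovery for 1D 1H NMR metabonomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation, preprocessing and biomarker discovery for 1D 1H NMR metabonomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmrage)
```

`nmrage` implements the analysis chain used in NMR-based metabonomic studies
of metabolic ageing in mice: full-resolution 1D ^1^H spectra of urine or
plasma are normalized, aligned and log-transformed, then interrogated with
unsupervised PCA, supervised maximum-margin-criterion (MMC) discrimination
with leave-animal-out cross-validation, and FDR-controlled univariate ANOVA
to produce biomarker tables. Because studies of this kind rarely deposit raw
spectra, the package also ships a fully seeded synthetic-cohort generator
whose ground truth makes every stage of the chain testable.

## The synthetic cohort generator

A cohort is described by a `cohort_design()`: metabolite templates, base
concentrations, a group layout (genotype × week, mice per group, spectra per
mouse), planted log~2~ fold-change effects, and noise settings. Each
spectrum is built as a sum of Lorentzian multiplets. Lines are pure
Lorentzians: acquisition pipelines apply exponential apodisation, which
preserves Lorentzian line shape, so a pseudo-Voigt model would add a
parameter the data do not need. First-order multiplet rules are used (line
spacing $J/\nu_0$ ppm, binomial ratios 1 / 1:1 / 1:2:1 / 1:3:3:1); arbitrary
patterns, including roof-effect AB systems, can be given as explicit line
lists. Strong-coupling simulation is deliberately out of scope.

Per sample, the generator draws, in this order, from a per-sample substream
keyed by the sample index (so enlarging a design never perturbs earlier
samples):

* **concentrations** — base × planted fold change × a per-mouse lognormal
  effect (CV `mouse_cv`, default 5 %, shared by all spectra of one animal)
  × lognormal multiplicative noise (CV `mult_noise_cv`, default 15 %);
* **chemical-shift jitter** — one Gaussian draw per metabolite (sd
  `shift_jitter_sd`), displacing all of that metabolite's multiplets
  together, as pH/ionic-strength effects do; by default only citrate and
  taurine carry jitter, the signals for which a second, custom-interval
  alignment pass exists;
* **dilution** — a whole-spectrum factor drawn log-uniformly (default
  [0.5, 2]), the variation probabilistic quotient normalization exists to
  remove; log-uniform sampling makes the multiplicative range symmetric;
* **additive Gaussian noise** (default sd 0.5 intensity units against
  default peak heights of order 10^4^).

Protein binding is modelled for the mouse sex pheromone
6-hydroxy-6-methylheptan-3-one (6H6MH3O), which is in fast exchange with
major urinary proteins: the observed width is the population-weighted
average `(1 - f) * free + f * bound` (`broadened_width()`). The default
template (free 1.36 Hz, bound fraction 0.3, bound width 3.3 Hz) reproduces
an observed unfiltered width of ≈1.94 Hz, and simulating with
`ultrafiltered = TRUE` sets `f = 0`, emulating a 10 kDa spin-filter.

The default template library holds 26 metabolites with literature ^1^H
shifts, mirroring the ~30 metabolites routinely assigned in mouse urine.
Breadth matters: PQN estimates dilution as a median over metabolite
quotients, so a sparse library would make synthetic PQN recovery look worse
than it is on real spectra. The concentration scale is arbitrary (equal
base concentrations of 100); no public concentration table exists for this
matrix and the analysis is scale-free after normalization, so this is
documented rather than tuned.

What the generator does **not** emulate: water-suppression artefacts,
baseline roll, ^13^C satellites, and the T~2~-editing physics of CPMG
(plasma CPMG exists only as an exclusion preset). Passing tests therefore
demonstrate correctness of the algorithms under the stated statistical
structure, not robustness to every instrumental artefact of real spectra.

## Preprocessing

The default grid is 0.5–10 ppm at 0.00025 ppm, stored descending. Stages
run in a fixed order: **calibrate → exclude → align (global, then custom
intervals) → PQN → log**. The order is a design choice: exclusion first so
water/noise regions can never drive dilution factors or segment shifts;
alignment before normalization so PQN sees aligned variables but alignment
sees unnormalized, water-free spectra.

* **Calibration** (`calibrate_ppm()`) shifts each spectrum so the maximum in
  a search window (TSP at 0.0 ppm for urine; the α-glucose anomeric doublet
  at 5.233 ppm for plasma) sits at its target, erroring if no peak rises
  above the noise floor.
* **Exclusion** (`exclude_regions()`) drops the open interior of each
  interval, keeping endpoints: urine retains [0.8, 4.7] ∪ [4.9, 10];
  plasma 1D [0.2, 4.2] ∪ [5.2, 10]; plasma CPMG [0.8, 4.6] ∪ [5.15, 10].
* **PQN** (`pqn_normalize()`) uses the element-wise median spectrum as
  reference (the canonical choice), computes per-variable quotients where
  the reference exceeds `floor_frac` × its maximum, and divides each sample
  by its median quotient. The floor default is 10^−3^: with a numerically
  tiny floor the quotient set is dominated by baseline-noise variables
  whose sample/reference ratios scatter like a Cauchy around zero and wreck
  the median; 10^−3^ keeps only variables with real signal. No total-area
  pre-scaling is applied — the dilution factor absorbs scale.
* **Log transform** (`log_transform()`) applies `ln(x + offset)` to turn
  multiplicative noise additive. The automatic offset is the smallest
  positive entry; when noise takes the baseline below zero the offset is
  raised by `−min(x)` plus a noise-scale MAD so the logarithm stays
  defined. The offset is configurable and recorded in the processing log.

Every step appends to the container's processing log, so a processed
matrix carries its own provenance.

## Recursive segment-wise peak alignment

`rspa()` aligns every spectrum to a reference — the sample with the highest
mean Pearson correlation to all others, ties broken by smallest sample id —
by rigid integer-grid segment shifts chosen by cross-correlation, recursing
into sub-segments. Design choices, all surfaced in `alignment_params()`:

* **Integer-grid shifts only.** The grid step (0.00025 ppm ≈ 0.15 Hz) is far
  below observed line widths, so sub-grid interpolation would add cost
  without precision. Local insertion/deletion-style stretching is not
  implemented; the shifts are rigid per segment.
* **Segment boundaries from the reference only** (shared by all samples,
  deterministic): each segment splits at the deepest local minimum of the
  reference *within the central half* of the segment. Restricting the split
  to the central half keeps the recursion balanced — splitting at the
  global deepest minimum tends to peel slivers off one end of noisy
  baselines and exhausts the depth budget before any peak region is
  isolated.
* **Peak-prominence floor** (default 1 % of the reference maximum): segments
  whose reference never rises above the floor are left untouched, so
  baseline noise is never "aligned" to noise, which would otherwise lower
  whole-spectrum correlation and break idempotence.
* **Acceptance**: a candidate shift is kept only if it improves the segment
  correlation by at least a relative `acceptance` (default 10^−3^) and
  never if it lowers it. Defaults: `max_shift` 0.02 ppm globally, 0.05 ppm
  for custom intervals (the citrate/taurine scale of pH-driven variation),
  minimum segment width 0.01 ppm. None of these values is dictated by the
  underlying studies, which do not publish RSPA parameters.

`align_interval()` is the second pass: researcher-defined, baseline-
separated intervals (e.g. `citrate = c(2.50, 2.75)`, `taurine = c(3.20,
3.50)`) are aligned as single rigid segments, leaving everything outside
bit-identical. Edge handling everywhere is constant padding (repeat the
edge value) — wrap-around would teleport intensity across the spectrum.

## Multivariate pattern recognition

`pca_fit()` is a mean-centred SVD with a sign convention (largest-magnitude
loading element positive). The rank worth interpreting is chosen by
bi-cross-validation (`bcv_rank()`): rows and columns are partitioned into
folds; each held-out row×column block `A` is predicted from the
complementary blocks as `B D_k^+ C` with `D_k` the rank-k truncated SVD of
`D`; the rank minimising mean squared prediction error wins, and rank 0
(mean-only) is allowed — and selected — for structureless data. Columns are
centred using training rows only.

`mmc()` maximises `tr(W' (S_b − S_w) W)`: discriminant loadings are the top
eigenvectors of the difference between between-class and within-class
scatter. Unlike Fisher LDA there is no `S_w` inversion, which matters at
n ≈ 8–10 animals per group. MMC runs on PCA scores (rank from `bcv_rank()`,
capped at `n − classes`) rather than on 10^4^–10^5^ spectral variables —
the standard reduction that keeps the within-class scatter meaningful at
small n; the number of returned axes defaults to `classes − 1`.

`leave_mouse_out_cv()` withholds all spectra of one animal per fold —
subject-level blocking, so replicate spectra of an animal can never
vouch for themselves. Inside every fold the pipeline is refit from
scratch: optional feature selection (one-way ANOVA at liberal p < 0.05 on
training animals only), PCA reduction, MMC, then a quadratic classifier in
discriminant space with per-class covariance shrunk toward its diagonal
(`Σ_c ← (1−λ)Σ_c + λ diag Σ_c`, λ = 0.1 by default) because per-class
sample sizes are tiny. Held-out spectra are assigned to the class with the
smallest quadratic distance `(z−μ_c)' Σ_c^{-1} (z−μ_c) + ln det Σ_c`. The
report aggregates a confusion matrix, accuracy, and a **predicted
variance** defined here as one minus the held-out residual sum of squares
after projection onto the training discriminant space over the held-out
total centred sum of squares; the literature uses the term without a
formula, so this definition is ours and is stated rather than asserted.

## Univariate biomarker detection

`anova_f()` computes a vectorised one-way F per spectral variable on the
log scale — directions of change (↑/↓) therefore refer to log-mean
differences. Degenerate variables (zero between- and within-group sums of
squares) take p = 1 by convention. `bh_adjust()` is the Benjamini–Hochberg
step-up rule; it returns the significance mask and the attained p-value
threshold, the number quoted next to FDR-filtered tables. Tiers follow the
reporting convention of such tables: `FDR_significant`, `potential`
(p < 0.05 but failing FDR — the "p" flag), `ns`. `significance_profile()`
provides the signed difference profile behind ANOVA plots (positive peaks
where group A is more intense, coloured by p).

`build_biomarker_table()` chains these for one comparison (e.g. week 60
vs. 15 within a genotype) and optionally collapses variables to annotated
metabolites via ppm windows (`read_annotation_windows()`; the shipped urine
library uses ±0.02 ppm windows around literature shifts). A metabolite's
tier is the best tier among its windows; its direction is the consensus
across windows, with conflicts flagged rather than silently resolved.
Tests are marginal per variable; no longitudinal mixed-effects modelling is
attempted (the underlying design is analysed as cross-sectional pairwise
comparisons).

## Line widths and identification scoring

`fwhm_fit()` least-squares fits a four-parameter Lorentzian
(Levenberg–Marquardt via minpack.lm), reporting FWHM in Hz via the
spectrometer frequency (600.44 MHz default) and flagging poor fits by
relative residual. `half_max_width()` is the "manual" measurement made
explicit: baseline = median of the outer 10 % of window points, then linear
interpolation of the two half-maximum crossings around the apex; it is
invariant to intensity scaling and additive baseline. For triplets the
central line is taken as the window maximum; the window is the user's tool
to isolate it. `welch_t()` compares filtered vs unfiltered width sets with
the two-tailed unequal-variance t test (delegating to `stats::t.test`).
`mice_score()` reports metabolite identification carbon efficiency — total
identification-information bits divided by carbon count (24 bits over 8
carbons = 3.0 for 6H6MH3O); the per-kind bit rubric lives with the user,
and the shipped evidence file is an illustrative reconstruction whose only
anchored quantity is the total. Topological variants of the score are out
of scope because the two tautomers have different topologies.

## Numerical and testing choices

Problem sizes in the test-suite simulations are chosen for desk-scale
reproducibility: grids of 0.001–0.002 ppm over 0.5–4.5 ppm (several points
per line width), cohorts of 8–40 spectra, and 50–500 seeded replicate runs
for power/null-rate checks. Determinism is treated as a contract: a fixed
`cohort_design()` seed reproduces cohorts bit for bit, `run_study()`
reproduces byte-identical output tables from the same config, and CV
reports are invariant to sample order (samples are sorted internally).

Known limitations: rigid segment shifts cannot correct differential
within-multiplet shifts; PQN assumes the majority of quotient-bearing
variables are unchanged between samples (strong global compositional
shifts would bias it); the QDA shrinkage default (λ = 0.1) is a
small-sample stabiliser, not an estimate; and the F-test's normality
assumption is only approximate for log-transformed near-baseline
variables.
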