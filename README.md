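# nmrage

Biomarker discovery for 1D ¹H NMR metabonomics of ageing mouse cohorts
(wild-type and FMO5-knockout), for researchers who profile urine or plasma
at full spectral resolution and need the complete statistical chain —
preprocessing, alignment, pattern recognition, FDR-controlled univariate
testing, line-width binding analysis — as tested, reusable R functions.
Raw spectra from studies of this kind are rarely deposited, so the package
includes a seeded synthetic-cohort generator with complete ground truth;
every stage is validated against what was actually planted.

## What it implements

* **Synthetic cohorts** — Lorentzian multiplets of a 26-metabolite urine
  template library; per-sample log-uniform dilution, lognormal
  concentration noise, pH-driven chemical-shift jitter (citrate, taurine),
  planted genotype×week log₂ fold changes, and fast-exchange line
  broadening for protein-bound metabolites
  (`cohort_design()`, `simulate_cohort()`).
* **Preprocessing** — ppm calibration to a reference peak, fluid-specific
  region exclusion, probabilistic quotient normalization (PQN), and
  variance-stabilising log transform
  (`calibrate_ppm()`, `exclude_regions()`, `pqn_normalize()`,
  `log_transform()`).
* **Alignment** — recursive segment-wise peak alignment (RSPA) to a
  data-chosen reference by cross-correlated rigid segment shifts, plus a
  custom-interval second pass for high-variation signals
  (`rspa()`, `align_interval()`).
* **Pattern recognition** — PCA with bi-cross-validated rank selection
  (Owen–Perry hold-outs); maximum margin criterion (MMC) discriminant
  analysis, whose loadings are the top eigenvectors of `S_b − S_w`; and
  leave-mouse-out cross-validation with a shrunken quadratic classifier,
  with all selection steps refit inside each fold
  (`pca_fit()`, `bcv_rank()`, `mmc()`, `leave_mouse_out_cv()`).
* **Univariate biomarkers** — vectorised one-way ANOVA per variable on the
  log scale, Benjamini–Hochberg FDR at 0.05/0.10 with the attained
  threshold reported, a liberal p < 0.05 "potential" tier, signed
  significance profiles, and metabolite-level tables via ppm-window
  annotation (`anova_f()`, `bh_adjust()`, `build_biomarker_table()`).
* **Line widths & identification** — Lorentzian FWHM fits and interpolated
  half-band-width measurement, Welch comparison of
  filtered-vs-unfiltered widths, and MICE scoring (identification bits per
  carbon) (`fwhm_fit()`, `half_max_width()`, `welch_t()`, `mice_score()`).
* **Orchestration** — `study_config()` + `run_study()` execute the full
  chain deterministically, with provenance; results are tibbles with
  `tidy()`/`glance()`/`autoplot()` methods throughout.

## Worked example

Simulate a two-timepoint wild-type urine cohort with a planted 2× citrate
increase and a halving of the pheromone 6H6MH3O at week 60, run the
preprocessing chain, and build a biomarker table:

```r
library(nmrage)

design <- cohort_design(
  templates = urine_templates(jitter_sd = 0.005),
  groups = tibble::tibble(
    genotype = "WT", week = c(15, 60), n_mice = 4, spectra_per_mouse = 1
  ),
  planted_effects = tibble::tibble(
    template = c("citrate", "6H6MH3O"), genotype = NA,
    week = 60, log2fc = c(1, -1)
  ),
  grid = c(0.5, 4.5, 0.001), seed = 42
)
cohort <- simulate_cohort(design)

sm <- exclude_regions(cohort$spectra, preset = "urine")
aligned <- rspa(sm)
sm <- align_interval(
  aligned$spectra, list(citrate = c(2.50, 2.75), taurine = c(3.20, 3.50)),
  reference = aligned$reference
)$spectra
pqn <- pqn_normalize(sm)
pqn
#> <pqn_result> 8 samples, dilution factors 0.607 .. 2.02
sm <- log_transform(pqn$spectra)

ann <- subset(read_annotation_windows(), ppm_hi <= 4.5)
tab <- build_biomarker_table(
  sm, comparison = list(a = list(week = 60), b = list(week = 15)),
  annotations = ann, fdr = 0.1
)
tab
#> <biomarker_table> 60 vs. 15 (FDR 0.10, attained threshold 0.01321)
#>   492 / 3701 variables FDR-significant; 134 potential
#>   8 annotated metabolites at tier >= potential
head(dplyr::arrange(tab$metabolites, p_min), 3)
#>   metabolite             ppm_windows                          tier    direction
#> 1 6H6MH3O                0.990-1.030,1.190-1.230,1.720-1.760 FDR_significant down
#> 2 3-methyl-2-oxovalerate 1.080-1.120                         FDR_significant down
#> 3 citrate                2.540-2.580,2.680-2.720             FDR_significant up
```

The dilution factors recovered by PQN span the simulated log-uniform
range; the attained BH threshold (0.0132 at FDR 0.10) is the adjusted
p-value cutoff that would be quoted alongside the table; both planted
metabolites are recovered at the FDR tier with the planted directions
(3-methyl-2-oxovalerate's window sits on the tail of the halved 6H6MH3O
triplet, so its "down" call is real signal bleeding into an overlapping
window — exactly the annotation-overlap caveat the conflict flags exist
for). The identification worked example:

```r
mice_score(24, 8)
#> # A tibble: 1 × 3
#>   total_bits n_carbons  mice
#> 1         24         8     3
```

24 bits of identification evidence over an 8-carbon molecule give a MICE
score of 3.0 bits/carbon — a confident identification.

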