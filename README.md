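# hepatofat

Liver fat quantification from multi-echo MRI, and the statistics a
population study builds on top of it — as one tested, fully simulatable
R package.

## What this is for

Proton density fat fraction (PDFF) is the quantitative imaging
phenotype for hepatic steatosis: per voxel, the fraction of MR-visible
proton signal attributable to fat. Population studies derive a single
PDFF per subject from a multi-echo abdominal MR slice, then use it as a
quantitative trait for genetics and as an anchor for proteomic
disease-stage models. This package implements that computational core
for researchers who want to study, stress-test or extend the methods
without access-controlled cohort data:

* **Synthetic ground truth** — phantom slices with known water/fat
  amplitudes, field map, R2\* and liver mask; genotype/phenotype
  cohorts with planted additive and interaction effects; protein panels
  with planted disease shifts. Everything takes an explicit seed.
* **Two PDFF estimators** for the voxelwise single-peak signal model

  y_i = (ρ_w + ρ_f e^(−j2πΔf t_i)) e^(−j2πφ t_i) e^(−R2\* t_i) + ε_i

  a **three-point Dixon** fit (echoes 2/4/6 of a 10-echo GRE train,
  R2\* neglected; variable projection over the field frequency with a
  swap-aware multi-basin search) and an **IDEAL** fit (6-echo train,
  all four parameters by damped Gauss–Newton with exact amplitude
  solves and multi-start field initialisation).
* **ROI reporting** — eight deterministic 5×5 ROIs in the liver mask;
  the reported PDFF is the mean of the lowest-s.d. ROI (water-fat swaps
  inflate local variability, so the quietest ROI avoids them), plus
  hepatic iron from R2\* via iron = 0.202 + 0.0254·R2\* (mg/g).
* **Statistical genetics** — rank-based inverse normal transform,
  additive association, the three-group genotype–genotype interaction
  likelihood-ratio test (β_gp = b + γ·gp, weighted by 1/se², χ² with
  1 df), fixed-effects inverse-variance meta-analysis with Cochran's Q,
  impact-tiered significance thresholds, genetic risk scores, and
  IVW/Egger Mendelian randomization.
* **Proteomic staging** — per-analyte logistic disease association with
  Bonferroni control, and an elastic-net classifier pipeline
  (shadow-feature selection, train-fitted Yeo–Johnson +
  standardisation, average-precision grid search) evaluated by repeated
  tenfold-stratified cross-validated AUC, against an enzymes-only
  clinical baseline.

## A worked example

```r
library(hepatofat)

# a 48x48 phantom at 15% fat, R2* = 40 1/s, mild field gradient
maps <- simulate_parameter_maps(c(48, 48),
                                pdff_dist = list(kind = "point", value = 0.15),
                                r2star_range = c(40, 40),
                                field_poly = c(0, 10, -5), seed = 1)
img  <- simulate_multiecho(maps, ideal_protocol(), seed = 2)
fit  <- ideal_pdff_map(img)
rep  <- select_roi(fit, place_rois(maps$mask))
rep
#> <hf_pdff_report: PDFF 15.00% from ROI 3 (s.d. 0.0000), iron 1.218 mg/g>
```

The reported PDFF recovers the planted 15% exactly (the acquisition is
noise-free), and the iron estimate is 0.202 + 0.0254·40 = 1.218 mg/g
from the selected ROI's mean R2\*. The same phantom pushed through the
GRE/Dixon arm and regressed against the IDEAL arm gives the
cross-acquisition calibration; `run_pipeline(pipeline_config(...))`
chains all stages and writes a JSON summary.

A cohort-side example:

```r
co <- simulate_cohort(20000, c(pnpla3 = 0.26, tm6sf2 = 0.07),
                      beta = c(0.25, 0.15), gamma = 0.15, seed = 3)
y  <- inverse_normal_transform(co$traits$trait,
                               co$covariates[, c("sex", "year_of_birth", "age")])
interaction_lrt(co$genotypes[, 1], co$genotypes[, 2], y)[c("gamma", "gamma_se", "p_value")]
#> $gamma
#> [1] 0.1152072
#> $gamma_se
#> [1] 0.03134545
#> $p_value
#> [1] 0.0002374736
```

The planted interaction (γ = 0.15) is recovered within its standard
error and detected by the 1-df likelihood-ratio test. Detecting
interaction coefficients of this size genuinely requires cohorts of
this scale — the per-group slope errors propagate directly into
γ̂'s standard error.

A thin command-line front end ships in `inst/cli/hepatofat.R`
(`simulate-phantom`, `fit-pdff`, `report`, `assoc`, `interaction`,
`meta`, `grs`, `mr`, `stage`, `run`, …), each subcommand a direct call
into the exported functions.

## Documentation

The methods vignette (`vignettes/liver-fat-pipeline.Rmd`) describes the
signal model, both fitters and their failure modes (swap bimodality,
R2\*-induced Dixon bias), the ROI heuristic and the conditions under
which it works, the genetics and staging models, and every numerical
design choice with its rationale.
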