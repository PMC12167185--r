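# mpmri

Quantitative multiparametric MRI analysis for preclinical tumor studies.

Small-animal immunotherapy studies increasingly read treatment response
from quantitative MRI rather than tumor size alone, because immune-cell
infiltration can transiently enlarge a responding tumor
("pseudoprogression") while changing its microstructure and perfusion.
`mpmri` implements the full quantitative chain such a study needs, for a
two-group (therapy/control), two-timepoint (baseline/follow-up) design:

- **DWI preprocessing** — rigid in-plane motion correction (normalized
  cross-correlation with subvoxel refinement), an explicit signal-dropout
  rule that excludes a slice-repetition whose mean foreground intensity
  falls below 2/3 of the bright-half mean for that slice and b-value,
  repetition averaging, and volumetric Gaussian smoothing (FWHM in mm;
  1.5 mm default).
- **Diffusion modelling** — voxel-wise monoexponential ADC,
  `S(b) = S0·exp(−b·ADC)`, and a triexponential IVIM model with a fixed
  free-water compartment,
  `S(b) = S0·[(f/100)·e^(−b·D*) + (f_water/100)·e^(−b·D_water) + (1 − f/100 − f_water/100)·e^(−b·D)]`
  with `D_water = 3.0×10⁻³ mm²/s` frozen, fitted by constrained
  Levenberg–Marquardt with deterministic multistart.
- **DCE-MRI modelling** — signal enhancement `S(t) − S0` as the
  concentration proxy, arterial input function extraction from an aorta
  ROI, and two-compartment exchange model (2CXM) fitting of plasma flow
  (PF, mL/100 mL/min) and plasma volume (PV, mL/100 mL), with an
  analytic-convolution forward model verified against an independent ODE
  integration to 1e−6.
- **Cohort statistics** — mean ± SD summaries, exact/approximate
  Mann–Whitney U (intergroup), Wilcoxon signed-rank after pairwise
  deletion (intragroup), Spearman correlation matrix with significance
  mask, raw p-values throughout (no multiplicity adjustment).
- **Synthetic data** — DWI/DCE phantoms and two-arm cohorts with known
  ground truth, Rician/Gaussian noise, injected dropout and shifts, fully
  reproducible from a seed, so the whole pipeline is testable without any
  data download.

## Worked example

Fit the triexponential IVIM model to one voxel of a noiseless phantom,
then run a full simulated 14 + 14 cohort study:

```r
library(mpmri)

bv <- default_b_values()   # {0, 10, ..., 800} s/mm^2
ph <- make_dwi_phantom(model = "ivim", noise_sigma = 0, seed = 42,
                       tumor_params = list(S0 = 800, f = 6, D_star = 55e-3,
                                           f_water = 3, D = 0.65e-3))
fit <- fit_ivim_triexp(ph$stack$volumes[12, 12, 2, 1, ], bv)
#> D = 0.00065 mm^2/s, D* = 0.055 mm^2/s, f = 6%, f_water = 3%
```

The fit returns the generating parameters exactly: tissue diffusion `D`,
pseudodiffusion `D*`, perfusion fraction `f` and free-water fraction
`f_water` (the free-water diffusivity is fixed at 3.0e−3 mm²/s).

```r
res <- run_all(default_run_config(seed = 7), "out/")
gs <- res$report$summary
gs[gs$parameter == "ADC", c("group", "timepoint", "n", "mean", "sd")]
#>     group timepoint  n  mean     sd
#> 1 control  baseline 10 0.768 0.0618
#> 2 therapy  baseline  7 0.779 0.0872
#> 3 control follow_up 14 0.857 0.0431
#> 4 therapy follow_up 14 0.740 0.0469
```

Units are 10⁻³ mm²/s; baseline `n` is below 14 because the generator
reproduces baseline missingness (tumors too small to assess). The
intergroup comparison per timepoint:

```r
tests <- res$report$tests
tests[tests$parameter == "ADC" & tests$comparison == "therapy vs control", ]
#>     stratum n1 n2 statistic        p                                             method
#> 1  baseline  7 10        33 8.87e-01                                              exact
#> 2 follow_up 14 14         9 4.78e-05 normal approximation, tie and continuity corrected
```

No group difference at baseline, a strongly significant lower ADC in the
therapy group at follow-up — the behaviour built into the cohort design's
effect sizes. `run_all()` also writes `cohort.csv`, `group_summary.csv`,
`stats_tests.csv`, the Spearman matrix with a heatmap, dropout/shift logs
(imaging modes) and the resolved `config.yaml` next to its outputs.

A thin CLI covers the same stages
(`inst/exec/mpmri <simulate|preprocess|fit-dwi|fit-dce|cohort-stats|run-all>`
with `--config`, `--seed`, `--out` and per-stage overrides; exit codes
0/2/3 for success/config error/stage failure).

## Package layout

| Path | Contents |
| --- | --- |
| `R/image_io.R` | NIfTI-1 I/O, spatial containers, ROI volumes, cohort CSV |
| `R/preprocess.R` | smoothing, dropout rule, registration, averaging |
| `R/dwi_fit.R` | ADC and triexponential IVIM fitting, parameter maps |
| `R/dce_fit.R` | enhancement, AIF, 2CXM forward models and fitting |
| `R/cohort_stats.R` | rank tests, Spearman matrix, group summaries |
| `R/synthetic_data.R` | phantom and cohort generators with ground truth |
| `R/pipeline.R` | config handling and end-to-end orchestration |
| `vignettes/mpmri-methods.Rmd` | models, assumptions, design choices |
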