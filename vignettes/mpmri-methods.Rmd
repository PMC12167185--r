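---
title: "Quantitative multiparametric MRI analysis with mpmri: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative multiparametric MRI analysis with mpmri}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpmri)
```

`mpmri` implements the quantitative arm of a two-group (therapy vs.
control), two-timepoint (baseline vs. follow-up) small-animal tumor MRI
study: diffusion-weighted imaging (DWI) with monoexponential and
triexponential intravoxel-incoherent-motion (IVIM) modelling, dynamic
contrast-enhanced (DCE) MRI with a two-compartment exchange model (2CXM),
and the nonparametric cohort statistics appropriate for group sizes of
7–14 animals. Because studies of this kind rarely deposit raw images, the
package ships a synthetic-phantom module that generates every input the
pipeline consumes with known ground truth, so each stage is verifiable
end to end.

## Signal models

**Monoexponential diffusion.** Voxel-wise signal decay over b-values is
modelled as \(S(b) = S_0 e^{-b \cdot \mathrm{ADC}}\), fitted by bounded
Levenberg–Marquardt least squares with \(\mathrm{ADC} \in [0, 10^{-2}]\)
mm²/s, initialized from a log-linear regression on the positive signals.
On noiseless curves the fit recovers \((S_0, \mathrm{ADC})\) to relative
error below \(10^{-8}\) (asserted by the test suite).

**Triexponential IVIM.** The IVIM variant used here adds a fixed
free-water compartment to the classic perfusion/tissue pair:

\[
S(b) = S_0\!\left[\tfrac{f}{100} e^{-b D^*}
 + \tfrac{f_\mathrm{water}}{100} e^{-b D_\mathrm{water}}
 + \big(1 - \tfrac{f}{100} - \tfrac{f_\mathrm{water}}{100}\big) e^{-b D}\right],
\qquad D_\mathrm{water} = 3.0\times10^{-3}\ \mathrm{mm^2/s\ (frozen)}.
\]

Fractions are stored in percent, matching how such results are reported.
Bounds are \(D \in [0.1, 2.0]\times10^{-3}\) mm²/s and
\(D^* \in [5\times10^{-3}, 0.5]\) mm²/s, with two constraints beyond the
boxes: \(D^* \ge 10\,D\) (prevents the pseudodiffusion and tissue
compartments from swapping labels — standard IVIM practice) and
\(f + f_\mathrm{water} \le 100\). Both are enforced by an internal
reparameterization, so every optimizer iterate is feasible and no penalty
terms distort the objective. Initialization is two-stage — a
monoexponential fit on \(b \ge 200\) s/mm² seeds \(D\) and the tissue
amplitude; the residual low-b amplitude seeds \(f\) — followed by a
deterministic 8-point multistart over \(D^*\) starts
\(\{10, 30, 80, 150\}\times10^{-3}\) mm²/s and \(f_\mathrm{water}\) starts
\(\{2, 6\}\%\); the lowest residual sum of squares wins. Five free
parameters on a single decay curve are only identifiable with dense low-b
sampling, hence the default 14-point grid
\(b = \{0, 10, 20, 30, 40, 60, 80, 100, 150, 200, 300, 400, 600, 800\}\)
s/mm² (config-overridable).

**Two-compartment exchange model.** Tissue tracer concentration is
modelled by the 2CXM mass balance

\[
v_p \dot c_p = F_p\,(c_a(t - t_0) - c_p) + PS\,(c_e - c_p), \qquad
v_e \dot c_e = PS\,(c_p - c_e), \qquad
C_t = v_p c_p + v_e c_e,
\]

reported as plasma flow PF (mL/100 mL/min), plasma volume PV (mL/100 mL),
permeability–surface product PS (mL/100 mL/min) and interstitial volume
ve (mL/100 mL); internal math uses SI-like units (s⁻¹, volume fractions)
with exact conversion at the API boundary. Two independent
implementations exist: the production route decomposes the 2×2 exchange
matrix into its exponential modes and convolves the linearly interpolated
arterial input function (AIF) exactly per linear segment (an exponential
integrator, cancellation-protected for small rates), and an oracle route
integrates the same system with `deSolve::lsoda`. Their agreement to
better than \(10^{-6}\) relative across a 192-point parameter sweep —
including the PS = 0 one-compartment limit and a PS = 500 near-well-mixed
limit — is the central correctness property of the DCE stage and is
asserted in the tests.

Concentration is approximated by the absolute signal enhancement
\(S(t) - S_0\), with \(S_0\) the mean over the pre-bolus frames: no T1
mapping, relaxivity conversion or hematocrit correction is applied.
Consequently PF and PV are calibrated only up to the common scaling of
tissue and AIF enhancement; a joint rescaling of both leaves the fitted
PF and PV unchanged (tested), but absolute values inherit whatever
scaling the enhancement proxy carries. This matches how such data are
commonly analysed when quantitative T1 is unavailable.

The per-voxel bolus delay \(t_0\) is fitted within \([0, 10]\) s.
`fit_2cxm` uses a deterministic 8-point multistart (PF ∈ {20, 120},
PV ∈ {5, 15}, PS ∈ {5, 20}, ve start 20, t₀ start 0) with the volume
budget \(PV + ve \le 100\) enforced by reparameterization. Noiseless
forward curves at 1.5-s sampling over 5 min are recovered with PF and PV
errors far below 1%; with Gaussian noise at 5% of the curve peak the
median PF/PV errors are a few percent (200-replicate check). Recovery
degrades monotonically as the frame interval grows from 1 to 8 s — an
identifiability characterization included in the tests, and the reason
the default sampling is 1.5 s.

## Preprocessing

The DWI stage order is: in-plane motion correction → signal-dropout
detection → exclusion → repetition averaging → Gaussian smoothing.
Smoothing is deliberately last so that misaligned or corrupted
repetitions are never blurred into the data used for fitting.

**Gaussian smoothing** interprets the filter "width" as the kernel FWHM
in mm (the common radiology convention), giving
\(\sigma_\mathrm{axis} = \mathrm{width} / (2\sqrt{2\ln 2}) /
\mathrm{spacing}_\mathrm{axis}\) voxels per axis; kernels are truncated
at 3σ, normalized to unit sum, and applied separably with reflective
boundaries. Defaults: 1.5 mm for DWI, 1.0 mm for DCE.

**Signal dropout.** A repetition of a given slice and b-value is excluded
when its mean foreground intensity falls below 2/3 of the mean foreground
intensity of the brightest half of all repetitions of that slice and
b-value (with odd R the brightest ⌈R/2⌉, inclusive). "Foreground" is
defined as the voxels above the Otsu threshold of the across-repetition
median image, computed once per (slice, b-value): the median is robust to
the dropout being tested, and a single mask scores every repetition so
the decision depends only on the multiset of per-repetition means (a
permutation-invariance property the tests assert). A slice whose
foreground is empty is flagged all-excluded with a warning rather than an
error. Averaging then uses only surviving repetitions; a slice with no
survivors propagates NaN so ROI means never silently include corrupted
data.

**Registration** is rigid translation only, estimated by exhaustive
normalized cross-correlation over integer shifts within ±5 voxels
(2-D per slice for DWI, 3-D per frame for DCE against the mean pre-bolus
volume), refined to subvoxel precision by quadratic interpolation of the
NCC peak. Small-animal bulk motion is small, which is why a translation
model with a modest search window suffices. Two robustness choices
matter on small grids: the per-axis search window is capped at half the
axis length so the overlap never falls below ~50% (spurious NCC peaks at
sliver overlaps were the failure mode this prevents), and near-equal
peaks are resolved toward the smaller shift. Known integer and
half-voxel shifts are recovered within 0.25 voxel in 2-D and 3-D
(tested); enhancement-only intensity changes without motion produce
shifts below 0.5 voxel.

## Cohort statistics

The statistical layer mirrors standard practice for small preclinical
cohorts: group cells are summarized as mean ± SD (n−1 denominator),
intergroup comparisons use the two-sided Mann–Whitney U test per
timepoint, intragroup baseline-vs-follow-up comparisons use the two-sided
Wilcoxon signed-rank test after pairwise deletion of incomplete pairs,
and parameter inter-correlation uses Spearman's ρ with a t-approximation
p-value on pairwise-complete observations. No multiplicity adjustment is
applied anywhere — all reported p-values are raw, which the report format
makes explicit.

Exact null distributions are used where the sample sizes make them
meaningful and ties do not intervene: Mann–Whitney when the smaller group
has ≤ 8 observations, signed-rank when ≤ 15 non-zero differences remain.
These switch points are not universal constants; they were chosen so
cohorts of 7–14 per group exercise both the exact and the approximate
path, and every result records which was used. The approximate paths
apply tie and continuity corrections. Zero differences are dropped by
the classic convention (`zero_method = "pratt"` is available). The test
suite proves the exact paths equal brute-force enumeration over all
labelings (Mann–Whitney, group sizes to 6) and all sign assignments
(signed-rank, n to 10), and that Spearman's ρ equals the classic
\(1 - 6\sum d_i^2 / (n(n^2-1))\) formula on tie-free data.

## The synthetic-data module

The generator emulates, with known truth: multi-b-value DWI stacks
(ellipsoidal "tumor" in a uniform background, Rician magnitude noise
\(\sqrt{(S+n_1)^2 + n_2^2}\), injected whole-slice dropout repetitions
scaled below the 2/3 threshold, injected in-plane shifts); DCE series
(gamma-variate bolus \(c_a(t) = a\,(t-t_0)^\alpha e^{-(t-t_0)/\tau}\)
carried by an "aorta" region, 2CXM tissue response in the tumor, additive
Gaussian noise, and distinct pre-contrast levels per region so
registration has anatomical contrast to work with); and subject-level
cohorts drawn from per-group, per-timepoint truncated normal
distributions whose default means and SDs reproduce the summary
statistics of a 14 + 14 murine immunotherapy study design (e.g.
follow-up ADC 0.833 ± 0.054 vs. 0.754 ± 0.051 ×10⁻³ mm²/s for control
vs. therapy). Baseline missingness — a subject's tumor being too small to
assess at the first timepoint — is applied per subject with default
probability 0.3, between the assessability rates such studies report for
volumetry and for DWI. Within-subject correlation between baseline and
follow-up values is unknowable from published summaries; the generator
exposes it as a knob with default 0.5, documented as an assumption.
Everything injected (noise σ, dropout list, shift list, seed) is recorded
in the returned truth object, and regeneration from the same arguments is
bit-identical.

What the phantoms do *not* emulate: anatomically realistic mouse
geometry, coil sensitivity profiles, EPI distortion, eddy currents,
cardiac/respiratory quasi-periodic motion, or any biological link between
immune infiltration and diffusion. Passing tests therefore demonstrate
the correctness of the computational pipeline on data obeying its own
models, not the fidelity of those models to in-vivo tissue.

## Numerical choices and degenerate inputs

- Least-squares (Gaussian) objectives are used for all fits even though
  DWI magnitude noise is Rician; Rician-aware likelihoods are out of
  scope. The resulting ADC bias is characterized instead: fitting the
  analytic Rician-mean signal shows the bias is *negative*
  (the noise floor slows the apparent decay) and its magnitude shrinks
  monotonically over SNR 10 → 100, which the tests assert. At SNR 50
  the median fitted ADC is within 2% of truth.
- Failed or non-converged voxels propagate NaN; ROI means are means of
  converged voxels only, with a warning when more than half a mask fails.
- The exponential-mode convolution guards against catastrophic
  cancellation at small rate×step via series expansion, and falls back to
  the ODE integrator in the (measure-zero) near-defective case of the
  exchange matrix.
- ROI means of smoothed maps carry partial-volume bias wherever the
  structure is small relative to the kernel: on the deliberately tiny
  test phantoms (tumor a few voxels thick) the 1.5-mm kernel pulls ROI
  ADC toward the background by up to ~25%, upward only; the end-to-end
  tests bound rather than hide this effect. In-vivo matrices are an
  order of magnitude larger, where the effect is correspondingly smaller.
- `compute_roi_volume` is the voxel count times the voxel volume —
  deliberately simple and axis-permutation invariant.

## Problem sizes used by the checks

The test suite and `scripts/acceptance.R` run entirely on synthetic
inputs at sizes chosen to characterize each property well: 500 voxels
for noisy ADC/IVIM recovery at SNR 50; 200 replicates for noisy 2CXM
recovery at 5%-of-peak noise; a 192-point parameter sweep for the
dual-route 2CXM equivalence; 100 seeded phantoms for dropout-rule
exactness; all group sizes to 6 (Mann–Whitney) and 10 (signed-rank) for
enumeration equivalence; and 100 seeded 14 + 14 cohort replicates for
the end-to-end power property, which flags the follow-up ADC group
difference at α = 0.05 in ~96% of replicates under the default design.

## Known limitations

Translation-only registration cannot correct rotation or deformation;
the enhancement proxy leaves PF/PV on an arbitrary common scale; the
triexponential IVIM fit is only trustworthy with dense low-b sampling;
exact p-values switch to approximations in the presence of ties; and the
synthetic cohort's truncated normals shift heavy-tailed cells (notably
baseline PF, mean ≈ SD·1.7) away from their nominal means — the
acceptance checks therefore compare against the generator's long-run
(truncated) means, not the nominal inputs.
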