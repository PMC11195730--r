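---
title: "Quantifying device-landing-zone calcification on contrast cardiac CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying device-landing-zone calcification on contrast cardiac CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dlzscore)
```

## The problem

Calcification of the aortic-root device landing zone (DLZ) — the native
leaflets, annulus and left-ventricular outflow tract where a transcatheter
aortic valve (TAVR prosthesis) seats — is associated with paravalvular
leakage, conduction disturbance and the need for balloon pre-/post-dilation.
The standard Agatston score needs a dedicated non-contrast acquisition, is
blind to where the calcium sits, and ignores relative density under
contrast. dlzscore quantifies DLZ calcium directly on the contrast-enhanced
CT angiogram used for TAVR planning, producing per-cusp, per-region
intensity-weighted volume scores on a patient-invariant map, plus a
statistical harness for relating those scores to procedural outcomes.

## Calcium detection by false-positive-rate minimization

On contrast CT the blood pool is bright, so a fixed HU cutoff confuses lumen
with calcium. Given a lumen segmentation and a root region of interest
(ROI), we sweep a threshold grid and compute, at each threshold $t$,

$$\mathrm{FPR}(t) = \frac{\#\{\text{lumen voxels with } HU \ge t\}}
                         {\#\{\text{ROI voxels with } HU \ge t\}},$$

the fraction of would-be calcific voxels that are actually lumen. The
calcific threshold $t_{\min}$ is the smallest $t$ with
$\mathrm{FPR}(t) \le \varepsilon$ (default $\varepsilon = 0.01$, i.e. at
most 1 % lumen contamination). Thresholds where no ROI voxel survives are
infeasible and never selected; if no threshold is feasible the documented
fallback is lumen mean + 3 SD. The default grid is integer HU steps between
the 50th and 99.9th percentile of ROI HU — a dense, transparent sweep.
Voxels at or above $t_{\min}$ within the ROI form the calcific segmentation;
connected components (26-connectivity) smaller than 1 mm³ are discarded as
contrast noise. Both choices are configurable.

## The patient-invariant 18-region map

Each patient supplies landmarks measured during routine TAVR planning: the
annular centre, a point on the root axis at the sinotubular junction (STJ),
the three commissures, and the annular area. From these we build a
normalized cylindrical frame:

* $r = \sqrt{A/\pi}$ — the area-derived annular radius normalizes the
  in-plane distance, $\rho = d_{\text{axis}} / r$;
* $h$ — the STJ height above the annular plane normalizes the signed axial
  coordinate, $\zeta = z / h$ (positive toward the aorta);
* the commissural bearings split the en-face circle into three half-open
  cusp sectors (NCC, RCC, LCC), each bounded by the two commissures adjacent
  to that cusp.

Because $\rho$, $\phi$, $\zeta$ are dimensionless, the same region grid
applies to every root regardless of size. The craniocaudal axis is split
into a leaflet zone ($0 < \zeta \le 0.5$) and an annular/LVOT zone
($-0.15 \le \zeta \le 0$; the annular plane itself counts as annular/LVOT).
The printed description of the lower bound in our source material is
anatomically implausible (it would sit above the STJ), so the depth below
the annulus is exposed as configuration with 0.15 · h as default. The DLZ is
the union of the two zones.

Within the DLZ window the bullseye map has 18 regions = 3 cusps × 2 angular
sectors per cusp (split at the sector midline) × 3 radial rings (edges at
$\rho$ = 1/3, 2/3, 1; $\rho > 1$ clamps into the outer ring — calcium can
protrude beyond the nominal annular radius). Region ids R1–R18 run
NCC → RCC → LCC, sector-major, ring-minor, and every boundary is half-open,
so each voxel lands in exactly one region and regional volumes sum exactly
to the windowed DLZ volume.

## Intensity weighting and cusp scores

Within-region density is summarized by an intensity weighting factor that
maps the region's mean HU linearly onto $[0.25, 1]$ over the scale from
$t_{\min}$ to $t_{\min} + 4\sigma$, where $\sigma$ is the HU standard
deviation of the entire calcific volume:

$$w = 0.25 + 0.75 \cdot
  \mathrm{clip}\!\left(\frac{\overline{HU} - t_{\min}}{4\sigma},\, 0,\, 1\right).$$

A region at threshold density contributes a quarter of its volume; a region
four standard deviations above threshold contributes all of it. We read the
scale's upper endpoint as $t_{\min} + 4\sigma$ — the only reading in which
both endpoints are attainable HU values; a stepped (quartile) variant is
available via `region_config(weight_steps = "quartile")` since the source
presentation does not decide between continuous and stepped weights. With
$\sigma = 0$ (degenerate, e.g. a single uniform deposit) any detected region
gets full weight; empty regions pin to the floor weight and contribute
nothing. The per-cusp score is the sum of its six regions' weighted volumes
(mm³); affine rescaling of the HU axis leaves all weights unchanged.

## Device metrics and the Agatston score

`area_cover_index()` is the usual oversizing percentage
$(A_{\text{THV}} - A_{\text{annulus}}) / A_{\text{THV}} \times 100$.
`expansion_deviation()` averages three post-implant diameters, assumes a
circular orifice, and reports the signed percentage deviation from nominal
area — negative means under-expansion (the sign convention is ours; the
convention and inner- vs outer-stent measurement are documented rather than
mandated). `agatston()` implements the standard per-slice non-contrast
score (lesions ≥ 130 HU and ≥ 1 mm², weight 1/2/3/4 by peak HU, assuming
the ~3 mm slice protocol) for use as a baseline covariate.

## The nested prognostic harness

`run_stats()` mirrors the nested multinomial analysis: exclusive outcome
classes (control, PVL, LBBB, pre-dilation, post-dilation) are modelled by
multinomial logistic regression with control as reference, in three nested
models — Model 3 (calcification grade, Agatston, valve size, area cover
index), Model 2 (+ leaflet and annular/LVOT volumes), Model 1 (+ the three
cusp scores). Model and parameter comparisons use the likelihood-ratio
statistic $\Delta\chi^2 = 2(\ell_{\text{full}} - \ell_{\text{reduced}})$;
discrimination uses one-vs-control ROC with the rank-formula AUC
(mid-rank tie correction), Youden-maximizing cutoffs, and the conventional
AUC bands (0.5–0.6 fail, 0.6–0.7 poor, 0.7–0.8 acceptable, ≥ 0.8
excellent). No multiplicity correction is applied — raw p-values are
reported, as is conventional for this analysis pattern. Interobserver
agreement uses ICC(2,1), the single-measure absolute-agreement coefficient
from the two-way random-effects ANOVA, with the standard F-based interval.

Numerically, fits are initialized by `nnet::multinom` and polished with
exact Newton steps on the multinomial log-likelihood, so likelihood
differences are reliable at the $10^{-9}$ level (the intercept-only fit
reproduces the closed form $\sum_k n_k \log(n_k/N)$ to that accuracy);
covariates are standardized internally and coefficients returned on the
original scale, making results invariant to linear covariate rescaling.
Perfect separation — likely with event counts of 10–26 — is caught and
refitted with a small ridge on the slopes, with a warning. ROC on in-sample
fitted probabilities is the default (cross-validated variants can be built
from `predict()`).

## Synthetic ground truth

`make_phantom()` builds a contrast-root phantom: a cylindrical lumen of
Gaussian HU (default N(400, 30)) in a darker background, with spherical
calcific deposits (default N(900, 50)) planted at known $(\rho, \phi,
\zeta)$ so their analytic region membership, analytic sphere volume and
voxelized volume are all known. It deliberately omits partial-volume blur,
motion, blooming and beam-hardening — passing phantom tests therefore
demonstrates the geometric and statistical machinery, not robustness to
scanner physics. Deposit positions in normalized coordinates make the
brute-force per-voxel classifier an exact oracle for region assignment.

`simulate_cohort()` draws covariates from fixed baseline distributions
(log-normal volumes and scores, ordinal grade, discrete valve sizes) and
assigns exclusive outcome classes from a generative multinomial logit with
intercepts calibrated to a control-dominated TAVR complication mix (67
control / 26 PVL / 19 postD / 11 LBBB / 10 preD per 133 — the cohort
structure our defaults emulate). The theoretical one-vs-control AUC of each
event is computed by brute force on a large independent draw scored with the
true conditional event probability.

## Validation design and problem sizes

The test suite validates, per run: exact agreement of region assignment
with the brute-force classifier on twenty 128³ phantoms with randomized
deposits; volume conservation to 1e-9 relative; the weight contract
(bounds, endpoints, HU-affine invariance); monotonicity of the selected
threshold in $\varepsilon$ and recovery of planted deposit volumes within
5 % for 3 mm spheres at 0.5 mm voxels; LRT type-I error within 5 % ± 1.5 %
over 2000 null replicates at n = 200; AUC recovery within ±0.03 on a seeded
n = 500 cohort; ICC exactness; and bit-exact reproducibility of CSV outputs
under a fixed config + seed. For the AUC-recovery check the n = 500 fit is
evaluated on an independent 20 000-patient draw from the same generative
process: this isolates the model's estimation error (what the check is
about) from the ±0.02–0.03 evaluation noise a 130-event test set would
add on top. These problem sizes keep the full suite comfortably within a
few minutes on one CPU while leaving Monte-Carlo noise well below each
tolerance.

## A worked example

```{r example, eval = FALSE}
library(dlzscore)

ph <- make_phantom(phantom_spec(seed = 1))
res <- run_score(run_config(seed = 1),
                 volume = ph$volume, lumen_mask = ph$lumen_mask,
                 roi_mask = ph$roi_mask, frame = ph$frame)
res$record
plot_bullseye(res$regional)

sim <- simulate_cohort(cohort_spec(seed = 1))
report <- run_stats(sim$cohort)
report
```

## Known limitations

* Landmarks are inputs; the package does not detect the annulus or
  commissures from images, and the annular plane is defined by the
  landmarks rather than re-fitted to a contour.
* The bullseye collapses the longitudinal axis over the DLZ window; no
  zone-resolved 3-D region map is produced.
* The phantom's noise model is Gaussian and blur-free; tolerances on real
  data will be dominated by partial-volume and motion effects the phantom
  does not emulate.
* ROC metrics are in-sample by default and optimistic in small cohorts.
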