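---
title: "Quantifying vitreous haze from raw OCT volumes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying vitreous haze from raw OCT volumes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitrehaze)
```

## The measurement

Debris in the vitreous body scatters light and raises the optical coherence
tomography (OCT) signal of the normally dark vitreous compartment. This
clouding — vitreous haze (VH) — is far too subtle for fundoscopy, but it is
measurable on a macular volume scan as an intensity ratio:

$$\mathrm{VH} \;=\;
\frac{\overline{I}_{\text{vitreous}}}{\overline{I}_{\text{below}}}
\;=\;
\frac{\operatorname{mean}\{\,I(b,a,d) : d < \mathrm{ILM}(b,a)\,\}}
     {\operatorname{mean}\{\,I(b,a,d) : d \ge \mathrm{ILM}(b,a)\,\}},$$

where the internal limiting membrane (ILM) surface separates the vitreous
(above) from the retina (below), and the means pool **all** pixels of all
B-scans (grand means, not per-B-scan scores that are then averaged — a
per-B-scan variant exists only as a sensitivity option). Three choices in
this definition deserve emphasis:

* **Raw data only.** Device viewers apply a display transform that
  brightens dark regions; relative to the retina, the vitreous signal is
  *artificially increased* in display images. The score is therefore
  defined on raw intensities, and both `segment_ilm()` and `compute_vh()`
  refuse contrast-adjusted volumes. `compute_vh(..., allow_adjusted =
  TRUE)` exists solely to demonstrate the inflation (it is a tested
  property: for any volume whose raw ratio is below 1, the
  contrast-adjusted ratio is strictly larger).
* **The denominator is the complement of the vitreous** — every pixel at or
  below the ILM, retina and sub-retinal tissue alike. Since the vitreous is
  defined as "pixels above the ILM", its complement is the natural
  denominator. A retina-only denominator (ILM down to a supplied lower
  boundary) is available behind the `denominator = "retina"` flag for
  sensitivity analyses.
* **Ratio of means, not mean of ratios.** This makes the score exactly
  invariant to any global intensity gain, which the tests verify.

Observed haze ratios sit near 0.17 (the vitreous is much darker than the
retina), and their distribution is right-skewed, so all analyses use
$\log(\mathrm{VH} + \varepsilon)$ with natural log and
$\varepsilon = 10^{-6}$. The offset only matters at a ratio of exactly
zero, where it keeps the transform finite ($\log\varepsilon$); the choice
of base is immaterial (it rescales every regression coefficient by the
same constant) and is documented rather than configurable.

## ILM detection

The device software that segmented the original scans is proprietary, so
the package defines its own detector, chosen to be the simplest rule that
is exact on phantoms and robust to speckle. Per A-scan:

1. median-3 smooth the intensity profile along depth;
2. estimate a robust noise scale as $1.4826 \times \mathrm{MAD}$ of the
   leading eighth of the profile (assumed vitreous — the detector requires
   the ILM to sit below the top 1/8 of the scan depth);
3. walk down the profile and take the first depth whose smoothed intensity
   exceeds the *running vitreous baseline* — the expanding median of all
   shallower samples — by more than $k = 4$ robust SDs. An absolute floor
   of $10^{-4}\max(I)$ breaks ties in noiseless data while keeping the
   rule scale-invariant (multiplying the volume by any $c > 0$ leaves the
   surface unchanged, a tested invariant).

The per-A-scan surface is then median-filtered laterally (window 5 across
B-scans and A-scans, NA-aware). A-scans with no qualifying rise are
flagged failed and are **excluded** from both haze means rather than
interpolated — interpolation would fabricate vitreous pixels. If more than
half of all A-scans fail, the volume as a whole is flagged unusable,
mirroring the quality-control rejection of scans with unusable
segmentation. On noise-free phantoms the unsmoothed detector equals the
ground-truth surface exactly; the lateral median filter legitimately
rounds the foveal pit by up to a pixel, which is why the exactness test
disables it. At 5% speckle the mean absolute error stays below 2 px.

Two numerical conventions: the expanding-median walk starts at the second
sample (one prior sample is needed for a baseline), and the lateral median
rounds half away from zero.

## The synthetic phantom

`generate_volume()` renders a macular volume with known ground truth: a
dark vitreous above a curved ILM (Gaussian foveal pit), piecewise-constant
layer intensities below it (bright RNFL, dimmer GCIPL/INL/outer retina),
and two narrow high-intensity peaks at the IS/OS junction and the RPE —
the qualitative A-scan profile of a real raw macular scan. The depth axis
is oriented with index 1 on the vitreous side, matching the displayed
B-scan. Default acquisition geometry follows the scanned protocol (49
B-scans × 512 A-scans over a 20° × 20° field, converted at 300 µm/degree;
depth 496 px).

Noise is a mean-one multiplicative log-normal speckle (relative SD
`noise_sigma`, default 0.05) plus optional additive Gaussian read noise,
clipped at zero. The mean-one parameterization keeps moments tractable:
the expected vitreous intensity is exactly `baseline + haze_level`, so
Monte-Carlo tests can compare against closed-form expectations. The
display transform emulated by `contrast_adjust()` is a max-normalized
gamma map $(v/\max v)^{\gamma}$ with $\gamma = 0.5$; any monotone concave
map reproduces the vitreous-inflation effect, and gamma is configurable.

What the phantom does **not** emulate: physical light propagation,
attenuation and shadowing below vessels, motion artifacts, mirror
artifacts, or the device's proprietary file format. Passing tests
therefore demonstrate correctness of the *scoring pipeline* given
plausible image structure, not robustness to every real-world artifact.

## The synthetic cohort

`generate_cohort()` draws a two-eye cohort with the statistical structure
the analysis assumes. Subject covariates use the observed cohort's
distributions (MS patients: age 51.5 ± 10.1 y, disease duration
17.9 ± 7.0 y, EDSS strata weighted 164:64:63, phenotypes 200:59:31
RRMS:SPMS:PPMS, NGMV 759.0 ± 58.4 mL, NWMV 665.2 ± 43.8 mL; controls
analogously). Eye-level thicknesses get a latent subject mean plus an
inter-eye deviation (2 µm for pRNFL/mGCIPL, 1 µm for mINL), with the
subject-level SD shrunk in quadrature so the *marginal* per-eye SD matches
the configured group SD.

Log haze is generated directly on the analysis scale:

$$\log \mathrm{VH}_{ij} = \beta_0 + \beta_g\,\mathrm{MS}_i +
\textstyle\sum_k \beta_k (x_{ijk} - \bar x_k) + b_i + e_{ij},
\qquad b_i \sim N(0, \sigma^2\rho),\;
e_{ij} \sim N(0, \sigma^2(1-\rho)),$$

so the inter-eye correlation of residual log-VH is exactly $\rho$
(default 0.6, a typical inter-eye correlation for OCT measures; nothing
in the source data pins it down). The default effect sizes are the
reported regression coefficients (age −0.007/y, duration −0.009/y,
pRNFL +0.004/µm, mGCIPL +0.006/µm, NGMV and NWMV +0.001/mL), the
intercept is $\log 0.17$ (the observed mean score), and raw
`vh_ratio = exp(log_vh)`.

Three calibration decisions matter and are deliberate:

* **Residual SD = 0.35.** The reported marginal SD of the raw score
  (± 0.21 at mean 0.17, a coefficient of variation ≈ 1.2) and the reported
  confidence-interval widths cannot both hold under a clean log-normal
  model: a CV of 1.2 implies a log-scale SD near 1, which would make the
  reported CI for the age coefficient (± 0.004 at 520 eyes) unattainable.
  The CI widths are what parameter-recovery behaviour depends on, so the
  generator is calibrated to them: a robust SE of 0.002 for the age
  coefficient at 260 two-eye clusters back-solves (with $\rho = 0.6$) to a
  conditional residual SD of ≈ 0.35. The marginal raw-score SD of the
  synthetic cohort is consequently smaller than the reported one; the
  excess real-world spread presumably reflects heavy tails and measurement
  artifacts that a log-normal residual does not model. (The skewed-right
  distributional family itself is a modelling convenience; the source data
  only support "skewed".)
* **`beta_group` is the observable adjusted contrast.** The reported group
  difference (+9.58% in patients, age/sex-adjusted) is an *adjusted
  marginal* contrast, while the generating model also routes group effects
  through covariates whose means differ by group (patients have thinner
  pRNFL/mGCIPL and smaller brain volumes, all with positive betas). The
  generator therefore offsets the direct group term by that mediated
  shift, so an age/sex-adjusted GEE on simulated data recovers
  `beta_group` itself. Without the offset the same fit would return ≈ −0.11.
* **Lesion volume is a null covariate** (`beta_lesion = 0`): the reported
  lesion association is non-significant and its per-unit scale is not
  stated; lesion volumes themselves are simulated log-normal with median
  5 mL, a realistic MS burden.

Covariates are drawn independently within group (real covariates are
correlated — e.g. duration with age); this keeps single-covariate recovery
unbiased and is the main idealization of the cohort generator. Quality
control failures (both-eye, single-eye) and excluding pathology are
simulated with configurable probabilities, default 0.

## Estimation: exchangeable GEE with sandwich variance

Eyes within a subject are correlated, so eye-level associations use
generalized estimating equations with Gaussian family, identity link and
an exchangeable working correlation. `fit_gee()` alternates the weighted
estimating-equation update

$$\hat\beta = \Big(\sum_i X_i^{\top} V_i^{-1} X_i\Big)^{-1}
\sum_i X_i^{\top} V_i^{-1} y_i,
\qquad V_i = \phi\,[(1-\rho) I + \rho J],$$

with moment re-estimation of $\phi$ (Pearson residual sum of squares over
$N - p$) and $\rho$ (cross-products of within-cluster Pearson residual
pairs over $N^\* - p$, $N^\*$ the number of pairs), until the largest
coefficient change falls below $10^{-8}$ or 100 iterations. The
exchangeable structure admits a closed-form inverse, so the update is
computed with grouped sums rather than per-cluster solves and scales to
$10^5$ clusters. $\hat\rho$ is clamped to $[0, 0.99]$ — a negative
inter-eye correlation is not a plausible working assumption here.

Reported uncertainty is always the robust sandwich
$B^{-1}\big(\sum_i X_i^\top V_i^{-1} r_i r_i^\top V_i^{-1} X_i\big)B^{-1}$
(the GEE standard; the source analysis does not state which variance it
used), with Wald 95% limits $\hat\beta \pm 1.96\,\mathrm{SE}$ and
two-sided normal p-values. Known small-sample behaviour: the uncorrected
sandwich is anticonservative with few clusters (empirical size ≈ 8% at
120 clusters in our null simulations); at the study's cluster count
(~290) it holds ≈ 5–6%, and the size test runs at that scale.

Degenerate cases are handled honestly: singleton clusters make the fit
collapse to ordinary least squares exactly; a rank-deficient design is an
error naming the collinear columns; non-convergence returns the last
iterate with `converged = FALSE`.

`run_association_suite()` wraps this into the full analysis: one GEE per
covariate, each adjusted for age and sex — except that the age model is
adjusted for sex only and the sex model for age only (a covariate cannot
adjust for itself); MS and control cohorts separately; MS-vs-HC and
phenotype-vs-HC contrasts as *pairwise* models with the control group as
reference (the source presentation is ambiguous between pairwise and
joint coding; pairwise is adopted and labelled); and stratified reruns
within each disability stratum (EDSS 0.0–3.5 mild, 4.0–5.5 moderate,
≥ 6.0 severe, on the half-point lattice). Missing model values are dropped
listwise per model with the count logged — which is why each results row
carries its own n. Strata with fewer than 3 clusters are flagged
not-estimable rather than fitted. No multiple-testing correction is
applied (matching the source convention, α = 0.05). Group differences on
the log scale are reported as percent differences
$(e^{\hat\beta}-1)\times 100$.

Subject-level comparisons use standard tools behind thin, documented
wrappers: the Mann–Whitney U (tie-corrected normal approximation with
continuity correction; the degenerate all-identical case returns
$U = n_a n_b / 2$, $p = 1$ by convention) and the Pearson chi-square
without continuity correction.

## ETDRS sector averaging

Macular layer summaries average an ETDRS-style grid of concentric
1.0 / 2.22 / 3.4 mm circles centred on the fovea: the central 1.0 mm
circle is excluded, the remaining annulus is split into inner
(0.5–1.11 mm) and outer (1.11–1.7 mm) rings and four quadrants, and the
grand mean is the **unweighted** mean of the 8 sector means (matching
"averaging the thickness for all 8 sectors"; pixel-count weighting is the
rejected alternative). Quadrants are half-open 90° arcs between the 45°
diagonals — each diagonal belongs to exactly one quadrant — so the four
arcs tile the annulus and a 90° rotation about the fovea permutes sector
means exactly, which is tested. Nasal/temporal orientation mirrors with
eye laterality (OD/OS). Degrees convert to millimetres at 300 µm/degree,
a documented constant the device literature leaves implicit. Deeper layer
boundaries (GCIPL, INL, RPE) are not segmented in-package — the source
pipeline took them from manufacturer software — so thickness maps come
from phantom ground truth or external tables.

## Quality control accounting

A subject is excluded when both eyes fail scan QC or an excluding ocular
pathology is present; a single failed eye only removes that eye. The
report counts exclusions per reason — QC assessed first, pathology among
the remainder — and a rejection rate in percent to one decimal. On the
published counts (316 eligible patients, 18 both-eye failures, 8
pathologies; 87 controls with one of each) this reproduces 290 + 85
included and an 8.2% patient rejection rate. One arithmetic quirk of the
published stratum table is preserved deliberately: the stratum counts
(164/64/63) sum to 291 against 290 included patients, and the printed
percentages (56.6/22.1/21.7) are each computed out of 290;
`stratum_percentages()` reproduces exactly that arithmetic.

## Pipeline profiles and problem sizes

`run_pipeline()` chains simulation → (optional imaging) → QC →
stratification → associations, with per-run manifest and report; a run is
reproducible byte-for-byte from `(config, seed)`. Two profiles:

* **tabular** (default): the cohort generator emits haze scores directly
  on the analysis scale, so the statistics run in seconds at any n;
* **image**: every eye is rendered as a phantom volume, ILM-segmented and
  scored from pixels. The target ratio is inverted to a haze level via the
  clean-profile sub-ILM mean (`haze = ratio × mean_below − baseline`,
  clipped at 0); the image-profile default baseline is lowered to 0.01 so
  that this floor sits well below realistic scores and low-haze eyes are
  not censored.

Problem sizes used by the shipped tests and the acceptance script are the
package's own choices balancing Monte-Carlo error against runtime:
phantom properties on 49 × 64 × 128 volumes (100 seeds), parameter
recovery on 200 replicates of 500-patient cohorts, null size on 800
replicates at the study's 290 clusters, and the large single-cohort
summaries at 10⁵ subjects where a printed value's comparison tolerance is
tight.

## Known limitations

* The ILM detector is a deliberately simple rise rule; it assumes a dark
  leading vitreous segment and will fail (honestly, via failure flags) on
  volumes where the retina reaches the top of the frame.
* The phantom's layer optics are piecewise-constant caricatures; absolute
  haze values are not comparable to any device's native scale, only the
  pipeline's relative behaviour is meaningful.
* The cohort generator draws covariates independently within group and
  places all inter-eye dependence in a single exchangeable term; real
  cohorts have correlated covariates and possibly more structured
  dependence (e.g. optic-neuritis asymmetry).
* Reported clinical coefficients are used as *generating values* for
  recovery experiments; nothing here re-estimates them from clinical data,
  which are not publicly deposited.
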