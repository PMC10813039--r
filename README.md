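# vitrehaze

Vitreous haze (VH) is a subtle clouding of the vitreous body caused by
light-scattering debris. It is invisible to fundoscopy but measurable on a
macular OCT volume scan, and in multiple sclerosis it has been proposed as
a window on the ocular glymphatic clearance of neurodegenerative waste.
`vitrehaze` is an R package for researchers who want to compute this score
from raw volumes and analyse its eye-level associations — and, because the
underlying clinical data are not publicly deposited, it ships a synthetic
OCT-phantom and cohort generator with known ground truth so that every step
of the pipeline is testable.

The score is the intensity ratio

```
VH = mean{ I(b, a, d) : d < ILM(b, a) } / mean{ I(b, a, d) : d >= ILM(b, a) }
```

— mean raw signal above the internal limiting membrane (ILM) over mean
signal below it, pooled across all B-scans. It must be computed on **raw**
device data: display images artificially brighten the vitreous, and the
package both refuses contrast-adjusted input and demonstrates the inflation
as a tested property. Analyses use `log(VH + 1e-6)`. Eye-level associations
are fitted with Gaussian generalized estimating equations (GEE) under an
exchangeable working correlation — two eyes per subject are correlated —
with robust sandwich standard errors, adjusted for age and sex.

## What's inside

* `generate_volume()`, `generate_ascan_profile()`, `contrast_adjust()` —
  OCT phantoms: curved ILM with foveal pit, layered retina with IS/OS and
  RPE peaks, mean-one log-normal speckle, display gamma transform; TIFF +
  JSON sidecar I/O.
* `segment_ilm()`, `surface_smooth()` — ILM detection on raw volumes
  (running-baseline rise rule, robust to speckle, exact on noiseless
  phantoms), with honest per-A-scan failure flags.
* `compute_vh()`, `log_transform()` — the haze score.
* `sector_average()`, `prnfl_mean()` — ETDRS-grid sector averaging
  (1.0/2.22/3.4 mm circles, central circle excluded) and circular-scan
  pRNFL means.
* `generate_cohort()`, `cohort_config()` — two-eye cohorts with configured
  covariate distributions, effect sizes on the log-VH scale and a known
  inter-eye correlation.
* `fit_gee()`, `group_contrast()`, `run_association_suite()`, `apply_qc()`,
  `stratify_edss()`, `mann_whitney_u()`, `chi_square_test()` — the
  statistical layer.
* `run_pipeline()` plus a CLI (`inst/cli/vitrehaze.R`:
  `simulate | segment-ilm | score-vh | metrics | analyze | run`).

## Worked example

Score a phantom eye, then fit the adjusted MS-vs-control model on a
simulated cohort:

```r
library(vitrehaze)

p <- phantom_params(n_bscans = 49, n_ascans = 64, n_depth = 128,
                    haze_level = 0.03, noise_sigma = 0.05)
ph <- generate_volume(p, seed = 1)
surface <- segment_ilm(ph$volume)
compute_vh(ph$volume, surface)
#> vh_score: ratio 0.2587 (log -1.3520), 140362 vitreous px / 261046 below, 0 A-scans excluded

coh <- generate_cohort(cohort_config(n_patients = 290, n_controls = 85), seed = 1)
eyes <- coh$eyes
eyes$ms <- as.integer(eyes$group == "MS")
fit <- fit_gee(eyes, log_vh ~ ms + age + sex)
fit
#> gee_fit (exchangeable): 750 obs in 375 clusters, rho_hat 0.648, phi_hat 0.1352
#>                beta robust_se  ci_low ci_high        p
#> (Intercept) -1.3469    0.0953 -1.5337 -1.1601 2.39e-45
#> ms           0.0816    0.0398  0.0036  0.1596 4.03e-02
#> age         -0.0053    0.0018 -0.0088 -0.0017 3.57e-03
#> sexM         0.0166    0.0360 -0.0540  0.0872 6.45e-01
group_contrast(fit, "ms")
#> [1] 8.50  # percent higher haze in patients at this cohort size and seed
```

Reading the output: the haze ratio 0.26 says the vitreous carries about a
quarter of the sub-ILM mean intensity (the phantom's injected haze level
was 0.03 on a baseline of 0.05). In the cohort fit, `rho_hat 0.648` is the
estimated inter-eye correlation the GEE corrects for; the `ms` coefficient
is the group difference on the log scale, back-transformed by
`group_contrast()` to a percent difference (+8.5% here, against a
generating value of +9.58%); the age coefficient (−0.005 per year) carries
a robust 95% CI and Wald p. `run_association_suite()` produces the full
covariate-by-cohort-by-stratum table in one call, and `run_pipeline()`
adds QC accounting, EDSS stratification, a markdown report and a manifest.

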