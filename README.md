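# stemallometry

Allometric covariation analysis and nondestructive stem-volume prediction
for single-species forest stands.

## The problem

Stem volume (and hence biomass) is usually estimated from power-law
allometries fitted to destructively sampled trees — expensive, slow, and
site-bound, because the fitted exponents and constants shift with site
quality and management. Within one species, however, the site-level scaling
relationships among total height *H* (m), breast-height diameter *D* (cm)
and stem volume *V* (m³) do not drift independently. Writing the log10–log10
fits as

- *H* vs *D*: exponent *x*, constant log β₃,
- *D* vs *V*: exponent *y*′, constant log β₅,
- *H* vs *V*: exponent *z*′, constant log β₆,

a single covariation parameter φ ties the exponents together:

    y′ = φ / (2 + x),    z′ = φ / (1 + 2/x),    y′ = (φ − z′) / 2,

with φ = 1 the idealized *V* ∝ *D*²*H* geometry, and the constants track
their exponents linearly across sites (positively for *D* vs *V* and
*H* vs *V*, negatively for *H* vs *D*). Once φ and the constant–exponent
line log β = *c*·α + *d* are calibrated on a set of development sites, a new
site needs only a nondestructive *H*–*D* fit: its V-vs-D exponent follows as
α = (2 + *x*)/φ, its constant as *c*·α + *d*, and each tree's stem volume as

    log10 V = (c·α + d) + α · log10 D,   V in m³, D in cm.

The package implements this pipeline end to end: RMA (standardized major
axis) and OLS site fits with slope CIs and a likelihood-ratio common-slope
heterogeneity test, closed-form least-squares estimation of φ under all
three curve forms, constant–exponent lines, model calibration and
prediction, MAPE evaluation, sectional (truncated-cone) stem volumes from
disc measurements, CSV I/O, and a synthetic multi-site forest generator
with known ground truth used to validate every stage.

## Worked example

```r
library(stemallometry)

# a 24-site study (12 development + 12 test), 50 trees/site, true phi = 1.10
study <- generate_study(seed = 1)

cfg <- study_config(study$dev_sites, study$test_sites, study$trees,
                    seed = 1, out_dir = tempfile())
res <- run_pipeline(cfg)

res$covariation
#>   curve_form      phi   ci_low  ci_high        r2 n_sites
#> 1         C1 1.115747 1.101038 1.130455 0.9618271      12
#> 2         C2 1.111562 1.097308 1.125817 0.9851098      12
#> 3         C3 1.114360 1.099736 1.128983 0.9087334      12

res$model
#> Stem-volume prediction model: phi = 1.1157, log10 beta = -1.1803 * alpha + -0.8880 (r2 = 0.999)
#> Calibrated on 12 sites; V in m^3, D in cm

res$evaluation
#> Evaluation: MAPE = 9.88% +/- 0.40 SE (across 12 sites), 600 trees
#>   APE < 5%: 31.3% of trees
#>   APE < 10%: 59.0% of trees
#>   APE < 20%: 90.3% of trees
```

The covariation fits recover the generator's φ = 1.10 to within ~0.016 from
noisy 50-tree sites, and the three algebraically related curve forms agree
with each other to within 0.005. The calibrated model predicts held-out test-site
volumes with a mean absolute percentage error just under 10%, with 59% of
trees under 10% error — the accuracy regime a practitioner should expect
from a well-behaved single-species plantation with log-scale scatter of
about 0.05.

Individual stages are exported too, e.g.

```r
f <- fit_power_law(c(8, 12, 17, 25), c(0.02, 0.07, 0.2, 0.6), method = "RMA")
f$exponent                     # fitted scaling exponent with CI and r2
covariation_predict(1.10, 0.9) # y' and z' implied by x = 0.9
mape(c(1, 2), c(1.1, 1.8))     # 10
```

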