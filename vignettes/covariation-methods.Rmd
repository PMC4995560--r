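---
title: "Methods: exponent covariation and nondestructive stem-volume prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exponent covariation and nondestructive stem-volume prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stemallometry)
```

## The model

Within a single species, each site's trees follow log-linear power laws
among height $H$ (m), breast-height diameter $D$ (cm) and stem volume $V$
(m³). We fit, per site on the $\log_{10}$ scale,

$$\log H = \log\beta_3 + x \log D, \qquad
  \log D = \log\beta_5 + y' \log V, \qquad
  \log H = \log\beta_6 + z' \log V.$$

If within a site the stem behaves like a tapered solid whose volume scales
as $V \propto (D^2 H)^{1/\varphi}$ — $\varphi = 1$ being the exact
$V \propto D^2 H$ cylinder-family geometry, $\varphi > 1$ a form factor
drifting systematically with tree size — then the three exponents cannot
vary freely. They are linked through one parameter:

$$y' = \frac{\varphi}{2 + x}, \qquad
  z' = \frac{\varphi}{1 + 2/x}, \qquad
  y' = \frac{\varphi - z'}{2}.$$

For fits sharing one set of trees, reduced-major-axis (RMA) algebra makes
two of these exact identities: the RMA slope is a signed ratio of standard
deviations, so $z' = x\,y'$ holds to machine precision, and all three lines
pass through the data centroid, forcing
$\log\beta_5 = (\log\beta_6 - \log\beta_3)/x$. The package exploits both as
internal consistency checks (`covariation_predict()`,
`predict_log_constant_DV()`), and the test suite asserts them at
`1e-12` tolerance.

The practical payoff is a nondestructive volume predictor. On development
sites with measured volumes we estimate $\varphi$ (from the RMA exponent
pairs) and an OLS line $\log\beta = c\,\alpha + d$ linking each site's
V-vs-D constant to its exponent. A new site then needs only an $H$–$D$ fit:
$\alpha = (2 + x)/\varphi$,
$\log_{10} \hat V = (c\alpha + d) + \alpha \log_{10} D$ with $V$ in m³ and
$D$ in cm. Units are part of the interface contract: $c$ and $d$ are only
meaningful for that unit pair, so inputs are validated rather than
converted silently.

## Fitting choices

**RMA vs OLS.** Functional relationships (the site exponents entering
$\varphi$, the constant–exponent lines of the descriptive analysis) use RMA,
which treats both variables symmetrically; the prediction chain (calibration
of $c, d$ and the $x$ used at prediction time) uses OLS, because prediction
targets the conditional mean and OLS minimizes exactly the prediction
residual. Whether the site exponent $x$ entering prediction should itself be
RMA or OLS is genuinely open; we default to OLS for consistency of the
prediction context and expose `x_method = "RMA"` in `study_config()`. On
OLS-consistent noise the OLS chain's MAPE is never worse, since the RMA
slope magnitude always exceeds the OLS magnitude by the factor $1/|r|$.

**The RMA slope CI** uses the standard F-based form
$b(\sqrt{B+1} \pm \sqrt{B})$, $B = F_{1-\alpha}(1, n-2)(1-r^2)/(n-2)$.
Fits are allowed from $n \ge 3$ but flagged `low_n` below $n = 6$, the
smallest site size the method is intended for. A zero correlation leaves
the RMA slope sign undefined and is treated as a degenerate-fit error, as
are constant predictors and non-positive inputs.

**Estimating $\varphi$.** Although the curves look nonlinear, $\varphi$
enters each of the three forms linearly (regressors $1/(2+x)$, $x/(2+x)$,
and the rearrangement $\varphi = 2y' + z'$), so the least-squares solution
is closed-form zero-intercept regression; an iterative optimizer adds
nothing but is kept as a test oracle (`optimize`, `nls`), and agreement to
$10^{-4}$ is asserted. $r^2$ for these one-parameter curves is defined as
$1 - \mathrm{SSE}/\mathrm{SST}$ with SST about the response mean, the usual
nonlinear-regression reporting convention; the CI comes from the
linear-model standard error with $n - 1$ degrees of freedom. Because the
three forms are algebraically linked, their estimates on one site table
agree closely; the suite asserts $|\hat\varphi_{C1} - \hat\varphi_{C3}| <
0.02$ on the default study.

**Slope heterogeneity.** Whether sites share one $H$–$D$ exponent is tested
with the likelihood-ratio common-SMA-slope procedure: at a candidate common
slope $b$, each group's residual scores $y - bx$ and axis scores $y + bx$
should be uncorrelated; the criterion
$-\sum_i (n_i - 2.5)\log(1 - r_i^2(b))$, minimized over $b$, is referred to
$\chi^2_{k-1}$. The $n - 2.5$ factor is the usual small-sample calibration;
Monte-Carlo checks in the suite verify type-I error within $[0.03, 0.07]$
at $\alpha = 0.05$ and power above 0.9 for slopes 0.7 vs 1.3 at $n = 50$,
and a permutation fallback (`p_method = "permutation"`) is compared against
the $\chi^2$ p-values on small samples. Perfectly collinear groups make the
criterion discontinuous at the true slope, so the per-group slopes are
always evaluated as candidate minimizers alongside the numeric optimum.

## Sectional stem volumes

Felled-tree volumes are sums of truncated-cone sections between discs,
$V = \pi L (d_1^2 + d_1 d_2 + d_2^2)/12$ (diameters converted cm→m;
volumes always m³). Disc heights follow the field protocol: 1.3 m, then
every 1 m below 10 m total height or every 2 m above, plus a 0.5 m disc for
trees under 10 m. Two choices the protocol leaves open are explicit,
configurable arguments of `total_stem_volume()`:

* the butt section (ground to lowest disc) defaults to a cylinder with the
  lowest disc's diameter — extrapolating the taper downward would inflate
  volumes in the butt-swell region — with `base_rule = "frustum"`
  available;
* the top section is a frustum down to a tip diameter of 0 (i.e. a cone),
  with `tip_diameter_cm` adjustable.

Non-monotone taper (butt swell) warns but is permitted. The frustum formula
is validated against adaptive quadrature of the linear taper to $10^{-9}$
relative error, and dense discs on an exact cone converge to the analytic
cone volume within 1%.

## What the synthetic generator emulates

`generate_site()` draws $\log_{10} D \sim N(1.0, 0.15)$ truncated at 2.5 sd
(median 10 cm — a plantation-thinning size distribution), then sets
noise-free $\log H$ and $\log V$ from the site's power laws and adds
independent $N(0, 0.05)$ noise on the $\log_{10}$ scale to both. The 0.05
default reproduces within-site $r^2$ in the 0.85–0.97 range typical of
single-species plantation allometries; noise is homoscedastic on the log
scale (the assumption under which log-linear fitting is efficient), and
heteroscedastic options are deliberately deferred.

Site structure: all sites share $\varphi = 1.10$ and a *pivot tree* —
every site's $H$–$D$ law passes through (15 cm, 15 m), so
$\log\beta_3 = \log_{10}(15)(1 - x)$. The pivot realizes, mechanically
rather than by fiat, the empirically observed sign structure: constants
fall with $x$ for $H$ vs $D$ and rise with their exponents for $D$ vs $V$
and $H$ vs $V$ (slopes $\mp\log_{10}$ of the pivot coordinates). The volume
constant is anchored geometrically: a pivot tree with taper
$d(h) = D_{base}(1 - h/H)^t$ (default $t = 0.7$, between a quadratic
paraboloid and a cone) has analytic volume
$\frac{\pi}{4} D_{base}^2 H/(2t+1)$, and optional stem profiles are scaled
so the taper integral equals each tree's noise-free volume exactly; discs
are placed at the protocol heights, so `total_stem_volume()` recovers the
generating volume within discretization error (a few percent at 1–2 m
spacing). The profile diameters represent the idealized volume-consistent
stem, not the over-bark breast-height tape measurement, so the profile's
1.3 m diameter is close to but not constrained to equal the recorded DBH.

`generate_study()` spreads the true $H$–$D$ exponents evenly over
$[0.6, 1.6]$ — the span observed across real plantation sites — and
alternates sites between the development and test partitions so both span
the range; defaults are 12 + 12 sites and 50 trees per site. All
randomness is local: per-site seeds derive from the study seed, and the
global RNG state is saved and restored.

**What passing tests do and do not show.** The generator satisfies the
covariation model by construction, with one exact $\varphi$ and exact
power laws; real sites deviate from the curves for biological reasons, so
recovery of $\varphi$ within $\pm 0.05$ and test-set MAPE below 15% here
demonstrate correctness of the estimators and pipeline, not field accuracy.
In particular the between-site $r^2$ of the covariation curves is higher on
synthetic tables (≈0.95) than on real ones, and the constant–exponent
slopes reflect the pivot's coordinates; the package's validation suite
documents these gaps rather than tuning the generator to mimic any
particular data set. Curvature of real $H$–$D$ relationships across wide
age ranges, heteroscedastic errors, and bark/wood partitioning are outside
the generator's scope.

## Numerical conventions and degenerate inputs

* $\log_{10}$ throughout; exponents and $r^2$ are dimensionless.
* CI level defaults to 0.95 everywhere and is configurable per call.
* CSV outputs round to 6 significant digits; tests compare numerically
  with tolerances, never by string equality.
* Domain violations (non-positive sizes, $x \le 0$, zero-spread
  calibration exponents, overlapping dev/test sets, duplicate tree ids)
  are errors raised before computation, labelled with the pipeline stage.
* Problem sizes used in the validation suite: 24 sites × 50 trees for
  end-to-end recovery, 500 replicate sites of $n = 100$ for CI coverage,
  1000/200 Monte-Carlo replicates for the heterogeneity test's size and
  power, 100 replicate studies for $(c, d)$ recovery.

## Known limitations

The predictor is calibrated for even-aged single-species stands; its $c, d$
are unit-bound (m³, cm) and species-bound. A site whose $H$–$D$ relation is
strongly nonlinear in log-log space violates the model's first assumption,
and $\varphi$ fitted across sites with genuinely heterogeneous taper
regimes averages over that heterogeneity. The common-slope test assumes
bivariate normal scatter on the log scale; for tiny or heavy-tailed groups
prefer the permutation p-value.
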