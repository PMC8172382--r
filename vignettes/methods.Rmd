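---
title: "Methods: geostatistical mapping of grain micronutrients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: geostatistical mapping of grain micronutrients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

geograin estimates and maps the spatial distribution of micronutrient
concentrations (Ca, Fe, Se, Zn) in staple cereal grain from georeferenced
survey samples, converts the maps into dietary supply relative to human
requirements, and links grain composition to human biomarkers and to
soil/environmental covariates with spatial mixed models. This vignette is
the package's own account of the statistical machinery, its assumptions,
and the design decisions taken where more than one defensible choice
existed.

## The model

A grain concentration surveyed at locations $x_i$ (lon/lat, WGS84) is
treated as a realisation of a second-order stationary random field $Z(x)$
with locally constant unknown mean. Its spatial dependence is summarised by
the semivariance $\gamma(h) = \tfrac{1}{2}\mathrm{E}[(Z(x) - Z(x+h))^2]$,
modelled with the exponential nugget function

$$\gamma(h) = c_0 + c\,(1 - e^{-h/a}), \qquad h > 0,$$

with nugget $c_0$ (measurement error plus micro-scale variation), partial
sill $c$ and distance parameter $a$ in km (effective range about $3a$). All
distances everywhere in the package — variogram lags, kriging covariances,
nearest-sample linkage, mixed-model correlations — are great-circle
distances on a sphere of radius 6,378,137 m, computed by one function
(`great_circle_distance()`, a thin wrapper over
`geosphere::distVincentySphere()`). The exponential family is used because
it guarantees positive-definite covariance matrices for distances on the
sphere; no projected coordinate system is ever introduced.

### Analysis scale

Geochemical concentrations are frequently near-log-normal. The octile
skewness $(O_7 + O_1 - 2O_4)/(O_7 - O_1)$ — a robust, bounded asymmetry
statistic — decides the analysis scale: original mg/kg if it lies in the
closed interval $[-0.2, 0.2]$; $\log_e$ if it is positive outside the
interval *and* the log transform reduces its absolute value. Negative skew
never triggers a transform. Percentiles use linear interpolation of order
statistics (`quantile()` type 7) throughout the package; the convention is
recorded in run metadata because octiles near a flat stretch of the
empirical distribution do depend on it.

### Variogram estimation and fitting

Three estimators of the empirical variogram are available per 10-km lag bin
(half-open $[l, u)$ bins from 0; each bin's representative lag is the mean
of its member pair distances rather than the midpoint, which matters in the
first bin where close pairs concentrate):

* **Matheron** (method of moments) — statistically most efficient under
  normality;
* **Cressie–Hawkins** — fourth power of the mean root absolute difference,
  with the $2(0.457 + 0.494/N)$ bias correction, robust to marginal
  outliers;
* **Dowd** — $2.198\,\mathrm{med}(|d|)^2/2$, robust to both marginal and
  spatial outliers.

The exponential model is fitted by weighted least squares with weights
$N_j/\gamma(h_j;\theta)^2$, iterated over three reweighting rounds
(pair-count weighting is available by option). The optimiser is bounded
L-BFGS-B from five starting points derived from bin statistics; ties break
by lowest weighted RSS then lowest nugget. A partial sill collapsing to
zero is returned flagged as a degenerate (pure nugget) fit rather than
silently.

### Cross-validation and model selection

Each candidate model is screened by leave-one-out ordinary kriging. The
standardized squared prediction error of site $i$ is
$\theta_i = (z_i - \hat Z_{-i}(x_i))^2/\sigma^2_{K,-i}$; under a valid
model with Gaussian kriging errors $\theta_i$ is approximately
$\chi^2_1$, whose median is $0.455$. The observed median is compared with
a 95% interval for the median of $n$ iid $\chi^2_1$ draws, built from
order statistics (the $k$-th order statistic of $n$ uniforms is
$\mathrm{Beta}(k, n-k+1)$, so the endpoints are $\chi^2_1$ quantiles of
Beta quantiles at the median ranks). This construction is distribution
free given the $\chi^2_1$ reference and requires no simulation.

Model selection follows the efficiency-first rule: the Matheron fit is
adopted if its median SSPE falls inside the interval; only then are the
robust fits *not* cross-validated. Otherwise all robust candidates are
validated and the one with median SSPE closest to 0.455 wins (flagged if
none validates).

Leave-one-out predictions are computed from a single inverse of the
bordered covariance-form kriging matrix
($e_i = (A^{-1}\tilde z)_i/(A^{-1})_{ii}$,
$\sigma^2_{K,-i} = 1/(A^{-1})_{ii}$), which makes $n$-fold refitting
unnecessary; a brute-force per-site mode is kept and the two are asserted
equal in the tests.

### Kriging, back-transformation, masking

Ordinary kriging solves $[\Gamma\; 1; 1^T\; 0][\lambda; \psi] =
[\gamma_0; 1]$ per target; weights sum to one by construction (asserted to
$10^{-8}$), data points are interpolated exactly when $c_0 = 0$, and the
kriging variance depends on the configuration only, never on the observed
values. The default neighbourhood is *all* observations (global ordinary
kriging, consistent with a locally-constant-mean model at survey scale); a
nearest-$n$ option (default 64) exists for large surveys. Grid nodes
outside the convex hull of the data are predicted rather than refused —
the variance mask is the mechanism that communicates extrapolation
uncertainty.

For log-scale analyses the prediction map is $\exp(\hat Z_{log})$, a
median-unbiased back-transform appropriate for skewed variables; the
kriging variance is *not* back-transformed (no meaningful back-transform
exists) and is reported on the log scale. Nodes whose kriging variance
strictly exceeds 75% (configurable) of the variance of the data are
masked; masked nodes are excluded from the quartile display classes of the
dietary maps.

Block kriging predicts the spatial mean over a polygon (e.g. an
administrative unit) by discretising it into regular interior nodes
(default 1-km spacing, refined until at least 100 nodes) and replacing
point semivariances with point-to-block and within-block means; the
degenerate one-node block reproduces point kriging to $10^{-6}$, and
halving the spacing changes test-block predictions by under 1%.

### Dietary supply

Percent of the estimated average requirement met by a reference staple
intake is $100 \times \text{conc} \times (\text{intake}/1000) /
\text{EAR}$. The shipped defaults are the FAO-based intakes (wheat 97.6,
teff 89.3, maize 342.8 g/day) and EARs for an adult woman aged 18–24 years
on an unrefined diet: Ca 860, Fe 22.4, Zn 10.2 mg/day — and Se 45
**µg**/day. Grain Se is measured in µg/kg while the other elements are in
mg/kg, and requirement tables commonly print the Se figure in a
milligram-denominated list; carrying the Se EAR in µg/day is the only
reading consistent with µg/kg Se maps (it also reproduces the expected
"under 25% of the Se requirement" magnitude for maize-based supply).
`percent_ear()` refuses any mg/µg mixing rather than converting silently.
Percentages are not capped at 100; the table is an editable argument, not
a constant.

### Spatial linear mixed models

Biomarker and covariate analyses use
$y = X\beta + u + \varepsilon$, $\mathrm{Var}(y) = \sigma^2_s
R(\phi,\nu) + \sigma^2_n I$, with $R$ the Matérn correlation
$\rho(h) = \frac{2^{1-\nu}}{\Gamma(\nu)}(h/\phi)^\nu K_\nu(h/\phi)$
on great-circle km. Writing $V = \sigma^2(\tau R + (1-\tau)I)$, the
overall scale $\sigma^2$ has a closed-form (RE)ML maximiser, leaving a
two-parameter Nelder-Mead search over $(\mathrm{logit}\,\tau, \log\phi)$
from three starts; $\beta$ is then the GLS solution with standard errors
from $(X^TV^{-1}X)^{-1}$. REML is the default for reporting; fixed-effect
hypothesis tests require ML fits and use $L = 2\Delta\ell$ against
$\chi^2$ with the difference in fixed-effect count as df — the function
refuses REML fits for this purpose.

The smoothness $\nu$ is weakly identified from typical survey geometry, so
it is profiled over the discrete grid $\{0.25, 0.5, 1, 2\}$ by default and
the best value reported (ties by likelihood then smaller $\phi$). Fixing
`nu = 0.5` — the exponential special case, which is also what the
synthetic generator uses — is both legitimate and materially faster, and
is what the package's own simulation studies do.

Forward covariate selection mirrors surveillance practice: predictors are
offered in a stated order (environment: precipitation, temperature,
topographic index; soil: pH, organic carbon), each tested by LRT against
the current model and provisionally retained at $p < 0.05$; all p-values
from the path are then treated as one family under Benjamini–Hochberg FDR
control at 0.05 (step-up via `p.adjust(method = "BH")`; the brute-force
textbook enumeration is kept as a test oracle), and the final model is
refit with the survivors. The family is the set of tests performed for one
response/crop/region path, recorded in the output. Enumeration-area
biomarker means are used unweighted (sample sizes per area are not part of
the data contract).

## The synthetic-data generator

Because the real surveys cannot ship with the package, every stage is
exercised on synthetic data with known truth:

* **Fields** — dense multivariate-normal draws with covariance
  $c\,e^{-h/a}$ (+ $c_0$ on the diagonal) via Cholesky with a
  $10^{-10}(c_0+c)$ jitter; log-Gaussian fields by exponentiation. Dense
  simulation is exact and entirely adequate at survey scale
  ($n \le$ a few thousand).
* **Designs** — compact-strata coverage sampling (k-means strata over a
  dense uniform point set, stratum centroids as sites) plus close pairs
  placed 100–1,000 m from distinct, randomly chosen main sites. Coverage
  sampling spreads sites more evenly than simple random sampling (tested);
  close pairs are what identifies the nugget. Balanced-sampling
  (inclusion-probability) machinery is deliberately out of scope: the
  estimation and kriging stages need spread plus close pairs, not design
  weights.
* **Covariate surveys** — independent Gaussian covariate fields, response
  $X\beta + u + \varepsilon$ with a Matérn $u$; the truth rides along as
  an attribute for recovery tests.
* **Biomarker surveys** — enumeration-area centroids uniform in the frame
  (real enumeration areas are not an independent random sample; uniform is
  the neutral documented choice), linked to the nearest grain sample, with
  $\log$ biomarker $= \beta_0 + \beta_1\,\text{grain} + u + \varepsilon$.
  The reference slope 0.09 used in the package's recovery studies is the
  magnitude reported for plasma Se on grain Se in Malawi.

All generators are deterministic given their seed, and frames live in the
mid-latitude band ($|\mathrm{lat}| \le 40^\circ$) to avoid metric
distortion pathologies. What the generator does **not** emulate: laboratory
error structure (detection limits, digestion batches), cropland masking,
preferential placement of real enumeration areas, and multi-crop mixtures.
Passing recovery tests therefore demonstrate correctness of the estimators
under the model's own assumptions, not robustness to those field realities.

## Numerical choices and degenerate inputs

* Distance-zero pairs are legal only with a positive nugget; duplicate
  sites under $c_0 = 0$ raise an error naming the offending sites.
* Kriging variances are clipped at zero within solver tolerance
  ($10^{-8}$); negative lags, non-positive Matérn parameters and empty lag
  structures all fail fast with diagnostics.
* $\nu > 50$ in the Matérn falls back to the unscaled Gaussian-limit
  approximation $\exp(-h^2/(4\nu\phi^2))$ with a warning (Bessel overflow
  territory; far outside the profiling grid).
* Pure-nugget WLS fits return $c \approx 0$ with the nugget at the mean
  semivariance, flagged degenerate.
* The variance mask uses a strict inequality ("exceeds 75%"), so a node at
  exactly the threshold is shown.

## Problem sizes used in the package's own studies

The simulation studies shipped with the package use: 500-site surveys
(20 replicates) for SSPE calibration; three replicate 2,000-site surveys
for WLS variogram recovery, averaging fitted parameters across replicates
because a single realisation's sample variance fluctuates well beyond the
estimator's own error; 300 enumeration areas (10–20 replicates) for
biomarker slope recovery; and 200 null replicates at $n = 100$ for the
LRT size check. These sizes give Monte-Carlo error comfortably below the
effect sizes being checked while keeping a full run on one CPU in minutes.

## Known limitations

* Ordinary kriging only: no external drift, co-kriging or lognormal
  variance correction; anisotropy and nested variogram structures are not
  modelled.
* REML variogram estimation is not offered for the kriging stage (the
  estimator-plus-WLS route is the package's contract); REML appears only
  in the mixed models.
* The Matérn $\phi$ follows the $(h/\phi)^\nu K_\nu(h/\phi)$ convention
  above; other parameterisations (e.g. with a $\sqrt{2\nu}$ factor) rescale
  $\phi$ and are not interchangeable without conversion.
* Multivariate (joint multi-nutrient) spatial models are out of scope.
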