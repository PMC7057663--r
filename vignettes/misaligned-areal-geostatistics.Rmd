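---
title: "Joint geostatistical modelling of misaligned areal health data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint geostatistical modelling of misaligned areal health data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(arealgp)
```

## The problem

Health indicators are often published as averages over administrative
polygons, and different agencies use different partitions of the same
region. The motivating case is life expectancy at birth (LEB), published
for two population groups (males and females) over a coarse partition
(MSOA-like units), and an index of multiple deprivation (IMD), published
over a finer, non-nested partition (LSOA-like units). Regressing one on
the other requires either coarsening everything to a common set of units —
discarding within-unit variation and distorting standard errors — or a
model that treats both sets of values as what they are: averages of a
spatially continuous surface over different polygons.

`arealgp` implements the second option. A single stationary Gaussian
process $U(x)$ with exponential covariance

$$\operatorname{Cov}\{U(x),U(x')\}=\tau^2\exp\{-\lVert x-x'\rVert/\delta\}$$

drives both observables through its polygon averages
$\bar U_j = |A_j|^{-1}\int_{A_j}U(x)\,dx$:

$$
\mathrm{LEB}_{ij}=\alpha_i+\beta_i\bar U_j+T_{ij},\qquad
\mathrm{IMD}_k=\gamma+\bar U^*_k+V_k,
$$

with $(T_{1j},T_{2j})\sim N_2(0,\Omega)$ iid across coarse units and
$V_k\sim N(0,\nu^2)$ iid across fine units. The $\beta_i$ measure the
strength of the deprivation–longevity association per group; $\Omega$
captures residual (non-spatial) variation in the outcome, correlated
across the two groups within a unit; $\nu^2$ is measurement noise in the
covariate. All areal variances and cross-covariances are double integrals
of the kernel over polygon pairs, which the package approximates by
regular-grid quadrature. Distances are Euclidean, so inputs must be in a
projected planar CRS in metres; geographic coordinates are rejected.

## Quadrature

`build_quadrature_grid()` lays a lattice of cell centres over the bounding
box and assigns each point to at most one unit per partition by
point-in-polygon (first-wins on shared boundaries, so partitions stay
disjoint). The normalised integral factor for a unit pair is then the mean
of $\exp(-d/\delta)$ over all pairs of assigned points. Two properties
anchor the approximation: it is exact in the point limit (units with a
single point recover the pointwise kernel), and halving the spacing
changes entries by monotonically shrinking amounts (both are enforced by
tests). The default spacing follows the reference analysis: 150 m for
simulation-grade work, 250 m for prediction lattices. A unit missed by
the lattice is an error by default; `on_empty = "centroid"` supplements
the lattice with one interior point per missed unit, which the synthetic
pipelines use so that arbitrarily small Voronoi cells never abort a
simulation.

Because the optimiser needs the factors at hundreds of values of
$\delta$, the pairwise distances are also binned once per grid (bin width
= spacing/4, representative = the mean distance within the bin, sparse
storage by unit pair). Each new $\delta$ then costs one sparse
matrix–vector product instead of a dense $q\times q$ exponential. The
binning error in any factor is below $5\times10^{-3}$ on the grids used
here and is checked against the exact path in the test-suite; the exact
path is always used for one-shot evaluations (public covariance
functions, prediction, residuals).

Quadrature-approximated covariance matrices can be numerically
indefinite, so every factorization adds an escalating diagonal jitter
starting at $10^{-8}$ of the mean diagonal.

## Likelihood and fitting

The exact Gaussian likelihood is evaluated through its factorization into
the covariate marginal and the conditional of the stacked outcome given
the covariate. The covariate marginal has covariance
$\Sigma_{\text{fine}}+\nu^2 I$, and the conditional uses the inverse of
that full marginal covariance — the internally consistent form, which the
test-suite pins against the directly evaluated joint Gaussian density to
$10^{-6}$ relative tolerance.

Optimisation runs on an unconstrained scale: variances as logarithms, the
cross-group covariance $\omega_{12}$ through $\mathrm{atanh}$ of its
correlation, so $\Omega$ stays positive definite and negative
cross-covariance remains representable (reporting $\log\omega_{12}$, as
reference tables do, would forbid $\omega_{12}\le 0$ for no modelling
reason). Starting values come from moments: intercepts from sample means,
a 50/50 split of the covariate variance between $\tau^2$ and $\nu^2$,
$\delta$ at a quarter of the domain diameter, $\beta$ from OLS of each
outcome on the coarse-averaged covariate. BFGS with numerical gradients
refines them.

Two well-known pathologies of this likelihood shaped the multi-start
design. First, the $(\tau^2,\delta)$ ridge: from a poor start the
optimiser can drift to $\tau^2\to 0$ with $\delta$ far beyond the domain.
Second, a boundary mode at $|\rho|\to 1$ (singular $\Omega$), where the
noise becomes perfectly correlated across groups, the model can
interpolate the data and the likelihood is spuriously inflated — the
analogue of the vanishing-variance mode of mixture likelihoods. The
fitter therefore runs up to `n_starts` starts (the moment start, a
deterministic "spatial-heavy" start with most covariate variance assigned
to $\tau^2$ and a short range, then random perturbations), stops as soon
as a non-degenerate optimum is found, and prefers the best non-degenerate
solution when both kinds exist. Degeneracy is flagged by simple scale
heuristics (collapsed or exploded $\tau^2$ relative to the covariate
variance, $\delta$ more than twice the domain diameter, $|\rho|>0.995$,
or an effect size beyond five outcome standard deviations per covariate
standard deviation). Wald 95% intervals come from the inverse observed
information on the transformed scale.

Derived summaries use their closed forms: the per-group fraction of
outcome variance explained $\beta_i^2\tau^2/(\beta_i^2\tau^2+\omega_i^2)$,
the cross-group residual correlation $\omega_{12}/(\omega_1\omega_2)$, the
practical range $-\delta\log 0.05$, and the likelihood-ratio test of
$\beta_1=\beta_2=0$ against $\chi^2_2$.

## Prediction and non-exceedance probabilities

The target surface is $\mathrm{LEB}_i(x)=\alpha_i+\beta_i U(x)$. All
predictive cross-covariances are derived from the single joint Gaussian
model — e.g. $\operatorname{Cov}\{\mathrm{LEB}_i(x),\mathrm{LEB}_{i'j}\}
=\beta_i\beta_{i'}\tau^2\,\overline{k}(x,A_j)$ with $\overline{k}$ the
area-averaged kernel — so continuous prediction, areal prediction and the
likelihood are mutually consistent; averaging the continuous predictive
mean over a unit's quadrature points reproduces the unit's areal
predictive mean to numerical precision (tested). Printed presentations of
this machinery sometimes drop the $\beta$ scaling and the area
normalisation in the cross terms; the package derives everything from the
model and verifies the results against simulation oracles instead of
reproducing those literal forms.

Two conditioning sets are supported. `"all_data"` (the default for maps)
conditions on both outcome vectors and the covariate, which is the
conditioning under which non-exceedance probabilities are defined.
`"leb_only"` conditions on the outcome vectors alone, reproducing the
classical kriging-from-outcome presentation of the predictive equations.
Parameters are plugged in at their estimates; parameter uncertainty is
deliberately ignored, and the coverage study below measures what that
costs.

`nep()` returns $\Pr(\mathrm{LEB}_i(x)<l\mid\text{data})$ in closed form
from the Gaussian marginals; `classify_nep()` applies the conventional
0.2/0.8 cut-offs (at least 80% probability of being below/above the
threshold). Joint sampling via `sample_predictive()` is seeded and
reproducible; its empirical moments converge to the closed forms
(tested).

## Validation: residual variogram with permutation envelopes

`extract_residuals()` estimates $T_{ij}$ as
$\mathrm{LEB}_{ij}-\hat\alpha_i-\hat\beta_i\hat U_j$ with $\hat U_j$ the
conditional mean of $\bar U_j$ given all data, tagged with area-weighted
unit centroids. `empirical_variogram()` bins centroid pairs into 12
equal-width distance classes on [0, 10] km by default (configurable for
other domain sizes; each unordered pair counted once; empty bins are
`NA`, not zero). `permutation_envelope()` permutes residuals over the
fixed centroids `B = 1000` times and takes pointwise 2.5%/97.5% quantiles
per bin; the verdict is "inside" when every non-empty bin's observed
value lies within its envelope. No multiplicity correction is applied
across bins — the pointwise envelope is the diagnostic as conventionally
presented. What is calibrated is the *per-bin* level: under exchangeable
residuals each bin's observed value falls outside its envelope about 5%
of the time (verified by simulation in the test-suite). The family-wise
"all bins inside" event is necessarily rarer: a permutation leaves the
sum of squared pairwise differences over all retained pairs almost
invariant, so the per-bin indicators are close to independent or mildly
negatively dependent, and with 12 bins the all-inside probability under
a correct model sits near $0.95^{11}\approx 0.55$, not near 0.95. The
all-or-nothing verdict is therefore a conservative screen — an "outside"
verdict should be read bin-wise, with attention to whether the
excursions form a systematic short-range pattern — and this is a
documented limitation of the uncorrected envelope, not a defect of the
implementation. Fewer, wider bins (e.g. matched to half the domain
diameter) raise the pairs-per-bin count and the family-wise inside rate.

## The synthetic-data generator and the coverage study

`make_misaligned_partitions()` builds two independent tessellations of a
rectangle: Voronoi cells from uniform seeds (non-nested by construction)
or rectangular tilings. `synthetic_scenario()` bundles domain, partitions,
a simulation grid and generating parameters. The default scenario is a
workstation-scale stand-in for a city-sized study: a 10 km square (taken as
Liverpool-sized, so the published $\delta$ is used unchanged; other
domains rescale $\delta$ with the domain diameter), 30 coarse and 90 fine
Voronoi cells, a 150 m simulation grid, and the published full-model
point estimates as truth. `simulate_dataset()` draws $U$ by dense
Cholesky factorization (exact; factor cached per scenario), averages it
over each partition, and adds the $\Omega$ and $\nu^2$ noises.

`coverage_study()` repeats simulate → fit → interval construction `B`
times and reports actual coverage against nominal levels
$\{0.05,\dots,0.95\}$ for (a) Wald intervals on $\beta_1,\beta_2$ and
(b) plug-in prediction intervals for the noise-free outcome at unit level
and on a point lattice (a regular thinning of the simulation grid, so the
true surface is known exactly at every lattice point; prediction
coverages are averaged over units/points within each replicate, and
failed fits are logged and excluded). The default `B = 200` with this
scenario runs in minutes on one CPU; the full-scale version is a
configuration change. Fitting reuses the simulation grid as quadrature —
affordable because of the binned factor path — so the fitted model is
exactly the generating model and no quadrature misspecification enters
the study. Prediction intervals in the study are built under `leb_only`
conditioning, the form in which the predictive equations are classically
printed; the study measures the calibration of exactly that machinery.

What passing does and does not show: the generator reproduces the model's
own assumptions (stationarity, isotropy, exponential decay, Gaussian
noise, correctly measured polygons). Real data can violate any of these,
and the coverage achieved under the model is an upper bound on what to
expect in practice. At this scenario's size (30 coarse units), plug-in
prediction intervals run a few points below nominal at high levels —
parameter uncertainty is not negligible relative to the narrow predictive
spread — which is visible in the study output and discussed in the test
suite; with more units the gap closes, which is the regime the reference
analysis operates in.

At known (true) parameters the same interval machinery is exactly
calibrated (`estimate = FALSE` runs this check), so the gap is
attributable to plug-in estimation, not to the conditioning algebra. For
the same reason the variogram calibration study evaluates residual
extraction at the known generating parameters rather than refitting in
every run: $\hat U_j$ is the same Gaussian conditional either way, and
the envelope machinery under test is identical.

## Numerical choices

* Factorization jitter $10^{-8}\times$ mean diagonal, escalating to
  $10^{-4}$ before failing with the smallest eigenvalue reported.
* Optimiser relative tolerance $10^{-8}$–$10^{-10}$ (context-dependent),
  `maxit` 120–300; refitting from an attained optimum moves the
  log-likelihood by less than $10^{-4}$ (tested).
* Degenerate inputs: fewer than 3 units per partition, or a constant
  covariate, are errors for fitting.
* Histogram factor path: bin width spacing/4, per-bin mean distance as
  representative, used only inside optimisation loops.
* Boundary points are assigned first-wins in unit row order; multi-part
  polygons integrate as unions of their parts; holes are unsupported.

## Interfaces and limitations

Boundaries are read from GeoJSON (`read_boundaries()`); outcome and
covariate tables from CSV, joined by id with hard errors on mismatches.
Surfaces export as gridded CSV plus contour tables; fit reports as
two-model CSV tables; a thin command-line wrapper
(`inst/scripts/arealgp.R`) chains the steps from a YAML/JSON config with
a global seed and a config hash in the run log.

Known limitations: a single shared spatial process (no second outcome
process — reported unidentifiable in the motivating analysis — and no
raster covariates); maximum likelihood only (no REML, so variance
estimates carry the usual small-sample downward bias; no Bayesian
uncertainty propagation); Euclidean distances on projected coordinates;
dense factorizations that cap simulation grids at a few thousand points;
Shapefile input and GeoTIFF output are not supported.
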