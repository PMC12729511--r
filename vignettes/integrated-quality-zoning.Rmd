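---
title: "Integrated quality zoning: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrated quality zoning: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`iqzone` delineates integrated quality regions for a medicinal plant by
fusing two spatial surfaces: the probability that the species occurs
(ecological suitability, from a maximum-entropy presence–background model)
and the expected concentration of its active compounds (quality suitability,
from ordinary co-kriging of site measurements). This vignette documents the
models, the tunable parameters, the numerical choices, and what the
synthetic test bed does and does not establish.

## 1. Spatial data model

All rasters live on one north-up regular lattice in geographic WGS84
coordinates (`grid_spec`): cell membership is half-open, `[edge, edge + d)`,
so boundary points are assigned unambiguously. Cell areas use the spherical
approximation `dx·dy·(π/180)²·R²·cos(lat)` with R = 6371.0088 km. We work on
the sphere throughout — areas and great-circle (haversine) distances are
reproducible to well under 1% at continental scales, and this removes any
projection-library dependency from the core. Nodata propagates: a cell that
is missing in any input layer is missing in every derived product.

I/O covers ESRI ASCII grids (the interchange format of the niche-modelling
ecosystem; `xllcenter` headers are accepted, files are always written with
`xllcorner`) and a minimal single-band little-endian Float64 GeoTIFF with
WGS84 geokeys and a GDAL-style nodata tag, read and written directly so that
no GIS stack is required.

## 2. Ecological suitability: the maximum-entropy model

Given presence cells and a background sample of the landscape (up to 10,000
cells drawn uniformly from the non-missing universe), the model is the Gibbs
distribution over background cells

$$q_\lambda(x) \propto \exp\Big(\sum_j \lambda_j f_j(x)\Big),$$

fitted by maximizing the L1-penalized average presence log-density. Features
are built from variables scaled to [0, 1] by their design range (predictions
clamp to that range): linear and quadratic terms plus forward and reverse
hinges at 10 sample-quantile knots per direction. Penalties are
$\beta_j = \mathrm{rm}\cdot c_{\mathrm{class}} \cdot \mathrm{sd}_{\mathrm{presence}}(f_j)/\sqrt{m}$
with $c_{L} = c_{Q} = 1$ and $c_{H} = 0.5$; a floor of 0.001 on the sd keeps
constant-on-presence features penalized. The regularization multiplier
defaults to 1.

Optimization is cyclic coordinate descent with soft-thresholding: each
update solves the local quadratic approximation, then step-halves until the
penalized objective does not decrease, so the objective is monotone by
construction. A cheap gradient screen skips inactive features whose
gradient is inside the penalty band. Convergence is declared when a full
cycle improves the objective by less than `tol` (default 1e-5); the cycle
cap defaults to 500 and is configurable — in our experience the default
landscape converges in well under 200 cycles, so an extremely large cap
would only matter for pathological inputs.

The reported output is the cloglog transform
$p = 1 - \exp(-e^{H} q)$, with the entropy $H$ of the fitted density and the
partition value frozen from training for all predictions, projections and
response curves, so that a fitted model is a fixed object. Percent
contribution accumulates the positive objective improvements credited to
each updated coefficient's parent variable during the (deterministic) cyclic
fit; jackknife importance refits with each variable alone and omitted,
reporting regularized training gain relative to the uniform model
($-\log B$). Evaluation is 10-fold cross-validation on the presences (folds
seeded; the background is shared), with AUC computed as the Mann–Whitney
rank statistic of held-out presence scores against background scores; a
single seeded 75/25 split mode is also provided since both protocols are
standard. Response curves sweep one variable across its observed range with
the others at background means; the suitable range is where `p >= 0.5` and
the adaptive threshold is the argmax (smallest value on ties).

Duplicate presence cells are collapsed before fitting, matching standard
duplicate-removal practice.

## 3. Predictor optimization

The two-step protocol: (i) a preliminary maxent fit drops variables with
zero contribution; (ii) pairs with `|r| > 0.8` are pruned in descending
`|r|`, keeping the higher-contribution member (ties drop the
lexicographically later code); (iii) variance inflation factors
(`1/(1 - R²)` from OLS of each variable on the rest) are recomputed
iteratively, dropping the worst until all are below 10, with perfect
collinearity treated as infinite VIF. Correlations are computed over the
background rows by default — collinearity is a property of the predictor
field, not of the presences — with a switch for using all rows. Because
"ecological significance" is not computable, expert retention is available
as an explicit `retain` list that shields variables from the pairwise step.

## 4. Quality suitability: geostatistics

Compound–environment association uses Spearman rank correlation
(tie-corrected average ranks; two-sided p from the t approximation with
n − 2 df), appropriate for small, non-normal literature-compiled samples.
Variables significant at α = 0.05 for a compound become its co-kriging
secondaries; each compound is modelled independently.

Semivariograms use equal-width distance bins up to half the maximum pairwise
distance (configurable), with γ̂ the classical moment estimator and empty
bins excluded. Model fitting is weighted least squares (weights
`N_bin/h²`) over spherical/exponential/gaussian families in the
practical-range convention, with nonnegativity constraints and multiple
starts. The multivariate model is a linear model of coregionalization
restricted to a nugget plus one shared-family, shared-range structure:
for each candidate range the per-pair coefficients are a linear WLS solve,
the best range is kept, and the coefficient matrices are projected to the
nearest positive semi-definite matrices by eigenvalue clipping (the
adjustment magnitude is recorded). The restriction guarantees a valid joint
model and a tractable, deterministic fit from 26 sites.

Ordinary co-kriging solves one linear system per target with unbiasedness
constraints (primary weights sum to one, each secondary's to zero); the
system matrix is shared across all grid cells and factorized once.
Leave-one-out validation removes one site at a time, holding the variogram
fixed, and reports mean error, RMSE, and the standardized RMSE — the root
mean square of errors divided by their kriging standard errors. We read the
standardized statistic as the calibration diagnostic: values near 1 mean the
kriging variances are trustworthy, which is how the validation figures of
the motivating workflow are interpreted. Aspect-like covariates are used as
supplied; an optional cosine transform was considered and rejected as the
default because the screening operates on ranks of the raw layer.

## 5. Integration and zoning

Kriged compound surfaces are min-max normalized over the valid mask and
fused cell-wise (mean by default; min and weighted mean available — the
fusion rule is a package choice, recorded in the run manifest, since no
standard exists). The integrated index is the convex combination
`C = w_e·E + w_q·Q` with equal weights by default. Habitat classes use the
fixed breaks 0.1/0.3/0.5 — printed class bounds take precedence over a
data-driven method for the habitat ledger — while the integrated index,
which has no printed bounds, is classified by exact Fisher–Jenks natural
breaks with k = 4 classes (symmetric with the four habitat classes). The
Jenks dynamic program is exact and deterministic, with ties broken toward
smaller early classes; above 10,000 values a seeded subsample is classified
and its breaks applied everywhere, keeping the O(kn²) cost bounded while
changing breaks negligibly. The top class is labelled the core quality
region.

Centroids of suitable habitat default to binary membership at `p >= 0.1`
(the lower bound of the total suitable area) with area weighting;
suitability weighting and other thresholds are switches recorded in each
centroid record, since the upstream convention does not pin them down.
Migration tracks report consecutive haversine distances and initial
bearings.

## 6. The synthetic test bed

The generator emulates the statistical structure the analysis assumes, at
desk scale, with full determinism under `(scenario, seed)`:

- **Environmental layers**: deterministic lon/lat gradients plus stationary
  Gaussian random fields simulated by circulant embedding on the cell-lattice
  torus (exact stationarity, O(n log n)); ranges are in cell units. Three
  nuisance layers are near-duplicates (r ≥ 0.9) of informative ones to
  exercise the pruning protocol.
- **Truth suitability**: a logistic law on z-scored layers (linear and
  squared terms). The default coefficients put roughly a fifth of the
  landscape above `p = 0.5`, concentrated toward the northeast quadrant —
  comparable to the suitable fraction of the motivating system — which sets
  the discriminability ceiling (oracle AUC ≈ 0.89) that a correct fit should
  approach.
- **Occurrences**: 170 presences drawn without replacement with probability
  proportional to truth, at cell centers; this matches the estimand of the
  presence–background model exactly.
- **Compounds**: concentration surfaces `intercept + β₁·z(cov1) + β₂·z(cov2)
  + correlated residual`, truncated at zero, sampled at 26 random sites with
  iid measurement noise. The couplings (β ≈ 0.8–0.9 against residual sill
  0.10 and site noise sd 0.15) make the two covariates clearly detectable by
  a rank screen at n = 26, mirroring a study design in which both
  associations are significant; the noise level for literature-compiled
  measurements is not observable and is therefore configurable.

What passing tests show: the engines recover known truth under their own
assumptions (correct model class, stationarity, no sampling bias). What they
do not show: robustness to the pathologies of real occurrence data —
collection bias, positional error, non-stationary residuals, or covariate
measurement error. The synthetic landscape validates the machinery, not the
biology.

## 7. Problem sizes and determinism

The default scenario is a 120×120 grid (14,400 cells), 8 layers, 170
presences, 10,000 background cells, and 26 compound sites — the package's
chosen desk-scale mirror of the motivating study's dimensions. A full
pipeline run (fit, 10-fold cross-validation, projection, two co-kriging
surfaces, zoning) completes in well under a minute on one core. A single
global seed is expanded into fixed per-stage seeds so stages can be rerun in
isolation; reruns under one configuration produce byte-identical artifacts,
and the run manifest records parameters, output hashes, and warnings
(non-convergence, dropped records, PSD adjustments) as first-class entries.

## 8. Known limitations

- Geographic coordinates only; no reprojection or resampling. Co-registered
  inputs are a precondition, not a service.
- The LMC is restricted to two shared structures; strongly differing spatial
  scales between compounds and covariates would need a richer model.
- Percent contribution is path-dependent (as is conventional for this model
  family); it is reproducible but not a causal decomposition.
- Polygon clipping is out of scope: region masks enter as nodata cells of a
  mask raster.
- The 75/25 split mode and the k-fold protocol share the background sample;
  spatially blocked validation is not implemented.
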