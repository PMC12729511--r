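# iqzone

Integrated quality zoning for medicinal plants: where a species can *grow*,
where its pharmacologically active compounds *accumulate*, and where both
coincide.

For species whose value lies in secondary metabolites (the motivating case is
*Cyclocarya paliurus*, a subtropical medicine-food-homology tree whose leaves
are valued for the flavonoids quercetin and kaempferol), the ecological
optimum and the quality optimum need not coincide: moderate environmental
stress often drives metabolite accumulation at the margins of the range.
`iqzone` implements a dual-dimensional assessment that fuses the two surfaces
into classified **integrated quality regions**, for ecologists, pharmacognosy
researchers, and cultivation planners.

## The model

**Ecological suitability** comes from a maximum-entropy presence–background
model. Over the background universe of landscape cells, the fitted Gibbs
density is

    q(x) = exp( Σ_j λ_j f_j(x) ) / Z

with linear, quadratic, and hinge features `f_j` of the environmental
variables, fitted by cyclic coordinate descent on the L1-penalized
log-likelihood

    max_λ  mean_presence(Σ_j λ_j f_j) − log Σ_background exp(Σ_j λ_j f_j) − Σ_j β_j |λ_j|

with per-feature penalties `β_j = rm · c_class · sd_presence(f_j)/√m` and
regularization multiplier `rm = 1`. Output is the cloglog occurrence
probability `p = 1 − exp(−e^H q)` with `H` the entropy of the fitted density.
The surrounding protocol: 10-km spatial rarefaction of occurrences, a
contribution screen plus `|r| > 0.8` / `VIF < 10` predictor pruning, 10-fold
cross-validated AUC, jackknife gains, response curves with `p ≥ 0.5` suitable
ranges, habitat classes at 0.1/0.3/0.5, spherical area ledgers, and
centroid-migration tracking.

**Quality suitability** comes from geostatistics on site-level compound
concentrations: Spearman screening against the environmental layers, direct
and cross semivariograms fitted under a linear model of coregionalization
(nugget + one shared structure, coefficient matrices projected to positive
semi-definite), ordinary co-kriging with unbiasedness constraints, and
leave-one-out validation (ME, RMSE, standardized RMSE).

**Integration**: each kriged compound surface is min-max normalized, fused
(cell-wise mean by default), and combined with the ecological layer as
`C = 0.5 E + 0.5 Q`; the index is classified by exact Fisher–Jenks natural
breaks (dynamic programming in C++) into quality zones, the top class being
the core quality region.

A synthetic-landscape generator (Gaussian random fields by circulant
embedding, a known truth suitability law, truth-proportional occurrence
sampling, covariate-coupled compound samples) provides a full known-truth
test bed, so every stage is validated without external downloads.

## Worked example

```r
library(iqzone)

scen   <- synthetic_scenario(seed = 42L)      # 120x120 grid, 8 layers, known truth
bundle <- gen_truth_bundle(scen)

occ    <- rarefy(occurrence_set(bundle$presences), radius_km = 10)
design <- assemble_design(occ, bundle$env, background_n = 10000, seed = 42L)

sel <- select_variables(design)
print(sel)
#> variable selection report
#>   initial: 8 variables
#>   |r|=0.971: dropped nuis1 (kept bio06)
#>   |r|=0.967: dropped nuis2 (kept bio12)
#>   |r|=0.966: dropped nuis3 (kept bio17)
#>   final: bio06, bio12, bio17, bio18, aspect

fit <- maxent(design[c("label", "lon", "lat", sel$final_vars)])
print(fit)
#> maxent model: 170 presences vs 10000 background cells, 110 features (22 active)
#>   regularized training gain 1.1183, entropy 8.0917, converged in 33 cycles

evaluate_cv(design, k = 10, seed = 42L)
#> kfold cross-validation: mean test AUC 0.8777 over 10 fold(s)

suit <- project_to_raster(fit, bundle$env)
cor(as.vector(suit$values), as.vector(bundle$true_suitability$values),
    method = "spearman")
#> [1] 0.9583
```

The three collinear nuisance layers are removed by the pruning protocol, the
cross-validated AUC (0.878) sits near the discriminability ceiling of the
generating law, and the projected cloglog surface ranks cells almost exactly
as the hidden truth does (ρ = 0.96). The full pipeline — including kriging
and the Jenks zoning — runs from one configuration object:

```r
cfg <- default_run_config(seed = 42L, scenario = synthetic_scenario(seed = 42L))
man <- run_pipeline(cfg)   # writes rasters, tables and manifest.json to cfg$out_dir
```

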