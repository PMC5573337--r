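# blmtu

Biotic ligand model (BLM) toxic units for metal-mixture toxicity in defined
nutrient solutions.

## The problem

Risk assessment of metal-contaminated soils and waters usually evaluates one
metal at a time, yet organisms are exposed to mixtures. For a Cu–Co mixture
acting on wheat (*Triticum aestivum*) root elongation, neither total nor free
metal concentrations predict joint toxicity well, because

* protective cations — here Mg²⁺ — compete with the toxic metals for binding
  sites on the root surface (the *biotic ligand*, BL), and
* at high pH a substantial share of toxicity is carried by inorganic
  complexes (CuHCO₃⁺, CuCO₃(aq), CuOH⁺, CoHCO₃⁺), not by the free ion alone.

`blmtu` implements the full analysis chain for this problem: inorganic
solution speciation, log-logistic dose–response fitting, estimation of BLM
binding constants from single-metal bioassays across Mg and pH gradients, and
mixture evaluation by toxic units computed on either the free-ion scale
(free ion activity model, FIAM) or the BL-occupancy scale (BLM). It is aimed
at ecotoxicologists analysing root-elongation (or comparable) bioassays in
synthetic media, and at modellers who need a transparent, testable
reimplementation of the BLM–toxic-unit workflow.

## The model

**Site occupancy.** The fraction of BL sites occupied by the toxic species of
metal M (Cu or Co) in a given solution is

```
        K_MBL·{M²⁺} + Σ K_IMBL·{IM}
f = ───────────────────────────────────────────────
    K_MBL·{M²⁺} + Σ K_IMBL·{IM} + K_MgBL·{Mg²⁺} + 1
```

where `{·}` are chemical activities from the speciation module, `K_MBL` and
`K_IMBL` are the stability constants of the free ion and of each toxic
inorganic complex at the BL, and `K_MgBL` is the Mg²⁺ competition constant.
(The trailing 1 represents unoccupied sites; a flag reproduces the
bound-forms-only convention without it.) In a mixture, the other metal's
toxic species join the denominator as competitors.

**Dose–response.** Toxicity follows a two-parameter log-logistic curve,
`RNE% = 100 / (1 + (x/x₅₀)^β)`, where RNE is relative net root elongation
and `x` is the exposure metric (free-ion activity, occupancy, or toxic
units).

**Toxic units.** For the mixture, concentration addition is expressed as

```
TU_M = {Cu²⁺}/EC50_Cu + {Co²⁺}/EC50_Co        (FIAM scale)
TU_f = f_Cu/f50_Cu   + f_Co/f50_Co            (BLM scale)
```

with `f50` the occupancy at 50% effect in single-metal exposure. A fitted
TU at 50% effect (TU50) near 1 indicates additivity; below/above 1,
synergism/antagonism.

**Speciation.** Media are speciated at fixed pH under an open CO₂ atmosphere
(Henry's law), with Davies activity corrections iterated with ionic strength,
hydroxide/carbonate metal complexes, and optional MgSO₄/CaSO₄ ion pairs.
Equilibrium constants ship as an editable JSON table.

## Worked example

```r
library(blmtu)

# 1. Chemistry of the base medium (0.05 mM Mg, pH 6) with 1 uM Cu
medium <- default_design()$media[["Mg0.05"]]
sp <- speciate(with_metal_dose(medium, Cu_uM = 1))
sp
#> <speciation_result>
#>   I = 0.0033 mol/L (gamma1 0.939, gamma2 0.778), 2 iterations
#>   activities (mol/L):
#>     {Cu} = 7.587e-07
#>     {Mg} = 3.865e-05
#>     {CuOH} = 1.514e-08
#>     {CuHCO3} = 5.755e-09
#>     {CuCO3} = 3.021e-09
round(100 * free_ion_activity_share(sp, "Cu"), 1)
#> [1] 75.9
```

Of 1 µM total Cu, the free ion carries about 76% of the activity at pH 6;
the rest is lost to the activity coefficient and minor complexation.

```r
# 2. Predicted EC50{Cu2+} across the Mg gradient from the published constants
params_cu <- published_blm_parameters("Cu")
specs <- lapply(default_design()$media[1:4], speciate)
round(sapply(specs, function(s) predict_ec50_free_ion(params_cu, s)) * 1e6, 2)
#> Mg0.05  Mg0.5  Mg1.0  Mg2.0
#>   0.54   0.67   0.80   1.02
```

Raising Mg from 0.05 to 2.0 mM roughly doubles the predicted EC50 (µM free
Cu²⁺): Mg²⁺ competition protects the root.

```r
# 3. Simulate a noisy Cu-Co mixture bioassay and compare TU models
design <- default_design()
params_co <- published_blm_parameters("Co")
mix <- simulate_mixture_assay(design, params_cu, params_co, seed = 1)
base <- speciate(design$media[[1]])
cmp <- compare_models(mix$data, params_cu, params_co,
                      ec50_Cu = predict_ec50_free_ion(params_cu, base),
                      ec50_Co = predict_ec50_free_ion(params_co, base))
cmp
#> <model_comparison_pair>
#>   <model_comparison> FIAM-TU: TU50 = 1.490, beta = 0.996, RMSE = 13.80, R2 = 0.836 (n = 288)
#>   <model_comparison> BLM-TU: TU50 = 1.002, beta = 4.059, RMSE = 4.84, R2 = 0.980 (n = 288)
classify_interaction(cmp$blm$tu50)
#> <interaction_call> TU50 = 1.002, interval [0.802, 1.202]: additive
```

On mixtures spanning the Mg and pH gradients, the occupancy (BLM) toxic-unit
scale collapses all twelve bioassay sets onto one dose–response curve
(RMSE 4.8, R² 0.98) while the free-ion (FIAM) scale scatters (RMSE 13.8,
R² 0.84); the fitted TU50 of 1.00 classifies the interaction as additive.

`run_pipeline(pipeline_config(out_dir))` runs the whole chain —
speciation table, single-metal EC50 and BLM-constant fits, mixture TU
computation, model comparison, interaction call — and writes the artifacts
plus a replayable run log.

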