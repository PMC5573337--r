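---
title: "Methods: speciation, BLM estimation and toxic-unit mixture analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: speciation, BLM estimation and toxic-unit mixture analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blmtu)
```

`blmtu` analyses single-metal and Cu–Co-mixture root-elongation bioassays
with the biotic ligand model (BLM). This vignette explains the models, the
numerical choices, and the design decisions behind the package, and states
what the validation on synthetic data does and does not demonstrate.

## 1. The chain of models

The analysis is a chain of four stages, each exposed as ordinary functions:

1. **Speciation** (`speciate`): from the total composition and pH of a test
   medium to the activities of the free ions and inorganic complexes.
2. **Dose–response** (`fit_loglogistic`): from relative net elongation (RNE)
   versus exposure to an EC50 and slope.
3. **Single-metal BLM** (`fit_single_metal_blm`): from EC50 series across Mg
   and pH gradients to binding constants and the occupancy at 50% effect.
4. **Mixture toxic units** (`compare_models`, `classify_interaction`): from
   mixture observations to toxic units on the free-ion (FIAM) or
   site-occupancy (BLM) scale, a fitted TU50, and an interaction call.

## 2. Speciation solver

### Scope and assumptions

The test media are synthetic electrolytes (K, Na, Ca, Mg chlorides and
sulfate, µM-level Cu and Co, pH buffered with MES or MOPS). They contain no
dissolved organic matter, so the solver is deliberately inorganic-only:
free ions, hydroxide and carbonate complexes of Cu and Co (CuOH⁺, CuCO₃(aq),
CuHCO₃⁺, CoOH⁺, CoHCO₃⁺), and the MgSO₄(aq)/CaSO₄(aq) ion pairs. This is a
fidelity limitation relative to full humic speciation codes: applying the
package to natural waters or soil solutions with organic ligands would
overestimate free-ion activities.

Three structural assumptions follow from how such bioassays are run:

* **pH is fixed.** Media are buffered and titrated to target pH; the solver
  treats {H⁺} = 10^−pH as a boundary condition and does not require charge
  balance of the stated totals.
* **Open CO₂.** The carbonate pool is fed by Henry's law at a constant CO₂
  partial pressure, so {CO₂(aq)}, {HCO₃⁻} and {CO₃²⁻} are fixed by pH and
  pCO₂ alone. The default pCO₂ is 10⁻³ atm rather than the open-atmosphere
  10⁻³·⁵ atm: the assays run 48 h in closed, dark growth chambers with
  respiring seedlings, and the elevated value is also the only way an
  inorganic model approaches the large carbonate-complex shares reported
  for such media at high pH. It is a single configurable number
  (`pCO2_atm`).
* **Buffers are non-complexing but ionic.** MES/MOPS do not bind metals
  appreciably, but their ionized fraction (with the Na⁺ added on titration)
  contributes to ionic strength as a 1:1 electrolyte; `default_design()`
  carries 1 mM MES (pKa 6.15) below pH 7 and 3.6 mM MOPS (pKa 7.18) at and
  above.

### Numerics

Because pH and the carbonate pool are fixed, every ligand activity ({OH⁻},
{HCO₃⁻}, {CO₃²⁻}) is known in closed form, and each metal's mass balance is
*linear* in its free-ion concentration — solved exactly, no Newton iteration
on the metal block. Only the sulfate ion pairs couple Mg, Ca and SO₄; that
block reduces to a scalar monotone root in free [SO₄²⁻], bracketed on
(0, SO₄ total] and solved with `uniroot` at near machine tolerance. Activity
coefficients use the Davies equation (A = 0.51, b = 0.3 at 25 °C, adequate
to I ≈ 0.5 mol/L); the outer loop alternates speciation and ionic strength
until ΔI/I ≤ 10⁻⁶ (typically 2–4 iterations for these media). Mass balance
is audited to 10⁻⁸ relative on every call and is exact by construction up
to root tolerance. Temperature corrections are not applied (assays at
20–25 °C; constants are 25 °C values).

Equilibrium constants are rounded critical-compilation values (NIST/
Smith–Martell-type) shipped as an editable JSON table with per-constant
provenance; `default_constants(overrides =)` switches individual reactions
off (`-Inf`) or replaces values. Literature constants for CuHCO₃⁺ diverge
by an order of magnitude; the shipped value (log K = 2.7 on the HCO₃⁻
basis) follows the MINTEQ-type compilations.

## 3. Dose–response fitting

The two-parameter log-logistic curve `RNE = 100/(1 + (x/x₅₀)^β)` fixes the
upper asymptote at 100% and the lower at 0%, the standard inhibition model
for this endpoint. Choices that matter:

* **Loss on untransformed RNE**, replicates unclipped: clipping negative or
  >100% replicates would bias the asymptotes. All replicate points are
  fitted by default; `aggregate = "mean"` reproduces analyses based on
  treatment means (triplicate averaging). Which convention the original
  analyses used is not stated, so both are exposed.
* **Positivity by parameterisation**: the optimiser works on log₁₀ x₅₀ and
  log β.
* **Multi-start**: Levenberg–Marquardt (`minpack.lm::nls.lm`) from a
  log-spaced grid of five x₅₀ values over the dose range crossed with two
  slope starts; best deviance wins. Fits require ≥ 4 distinct dose levels
  with level means on both sides of 50%, otherwise an informative
  non-identifiability error is raised.

## 4. Single-metal BLM estimation

### The occupancy model and the unity term

Site occupancy is `f = N/(N + K_MgBL{Mg²⁺} + 1)` with
`N = K_MBL{M²⁺} + Σ K_IMBL{IM}`. The literal bound-forms convention omits
the "+1" (unoccupied sites); under that form the predicted EC50 goes to 0
as {Mg²⁺} → 0, which contradicts the clearly nonzero EC50s observed at
0.05 mM Mg. The saturable form with the unity term is therefore the
default, and `include_unity_term = FALSE` reproduces the literal equation
for comparison.

Solving f = f50 gives the medium-specific EC50 as free-ion activity:

EC50{M²⁺} = θ·(1 + K_MgBL{Mg²⁺}) / (K_MBL + Σ K_IMBL·λ_IM),
θ = f50/(1−f50),

with λ_IM = {IM}/{M²⁺} fixed by pH and pCO₂. This is exactly linear in
{Mg²⁺} at fixed pH (slope/intercept = K_MgBL) and decreasing in each λ.

### Identifiability — two structural facts

Two non-obvious degeneracies shape the fitting interface:

1. **The occupancy scale is invisible to EC50 data.** Scaling K_MBL and all
   K_IMBL by a factor c while moving the f50 odds to c·θ leaves every
   predicted EC50 unchanged. Consequently `fit_single_metal_blm` *requires*
   f50 to be supplied (and holds it fixed) when fitting EC50-level data;
   only the response-level fit, where the unity term bends the curve shape
   near occupancy saturation, estimates f50 and β from data. H⁺ and
   Ca²⁺/K⁺/Na⁺ competition are deliberately excluded from the model: the
   observed pH effect is non-linear in {H⁺} and is carried by the complex
   terms instead, and the major-cation effects are minor relative to Mg²⁺
   in this system.
2. **OH and HCO₃ constants are collinear at fixed pCO₂.** {OH⁻} and
   {HCO₃⁻} are both proportional to 1/{H⁺}, so across any design run at one
   pCO₂ the products K_CuOHBL·λ_OH and K_CuHCO3BL·λ_HCO3 enter only through
   their sum. The fit returns *some* split of that lump (deterministically,
   from a fixed multi-start grid); the lump itself, K_MBL, K_MgBL and
   K_CuCO3BL (whose λ scales as 1/{H⁺}²) are the identified quantities,
   and the tests assert exactly those. Designs varying pCO₂ would break
   this collinearity.

### Optimisation

The loss is on log₁₀ EC50 (EC50s span more than a decade; log loss
equalises their weight) or on RNE percentage points for response-level
data. Levenberg–Marquardt multi-start runs from a coarse grid (logK_M ∈
{3,5,7}, logK_Mg ∈ {2,3.5,5}, complex constants started at logK_M; f50
starts {0.2, 0.5, 0.8} and β starts {1.5, 4} when free), with box bounds
logK ∈ [0, 10], f50 ∈ [0.01, 0.99]. Ties are broken by lowest deviance,
then lowest f50. Designs are screened before fitting: at least 3 distinct
Mg levels at a fixed pH and 3 distinct pH levels at a fixed Mg, with the
error naming the deficient axis. Standard errors are Gauss–Newton
(J'J-based) approximations and are reported as NA for exact fits.

## 5. Mixture toxic units

For each mixture observation, both metals' occupancies are computed with
the full mixture chemistry in the denominator (each metal's toxic species
compete for the other's sites), then

* TU_f = f_Cu/f50_Cu + f_Co/f50_Co (BLM scale), and
* TU_M = {Cu²⁺}/EC50_Cu + {Co²⁺}/EC50_Co (FIAM scale) with *fixed*
  reference EC50s — the FIAM deliberately does not re-normalise per medium,
  which is precisely why it scatters when chemistry varies.

The mixture dose–response is the same log-logistic curve with x = TU; RMSE
and R² between observed and fitted RNE compare the scales on identical
observations. The interaction call uses the TU50: additive when the
interval contains 1, synergistic entirely below, antagonistic entirely
above. Without a formal interval, a tolerance band of ±0.2 is used — made
explicit and configurable because the empirical "close to 1" range for
this system (set-wise TU50 0.88–1.15) was declared additive without a
formal test; a bootstrap CI can be passed instead.

## 6. Synthetic-data generator

`default_design()` reproduces the study layout: twelve media (Mg-set
0.05/0.5/1.0/2.0 mM at pH 6.0; pH-set 4.5–7.6 at 0.05 mM Mg) on the
0.08 K / 2.0 Na / 0.2 Ca (mM) background, seven-dose 2× geometric grids
(Cu 0.2–12.8 µM, Co 20–1280 µM — the stated ranges are consistent with
exact 2× spacing over seven levels, an inference since the grids are not
printed), mixtures at the fixed molar ratio Cu:Co = 1:100, triplicate.
The forward models are the same equations the estimators invert: single
metals respond to occupancy (`RNE = 100/(1+(f/f50)^β)`), mixtures to
TU_f (`RNE = 100/(1+(TU_f/λ)^β)`, λ = 1 for additivity, ≠ 1 to inject
interaction). Noise defaults to additive Gaussian RNE scatter of 5
percentage points, typical of root-elongation assays; EC50-level noise is
multiplicative lognormal with a given CV and unit mean. Every simulate
call seeds R's RNG once from its own integer seed and draws in a fixed
order, so results are byte-reproducible and independent of call order
across modules.

What passing the synthetic suite shows: the estimators invert their own
forward models correctly (exact round trips noise-free; calibrated
behaviour under noise), and the BLM-vs-FIAM comparison mechanism works for
chemistry-driven variation. What it does not show: that real wheat roots
obey the occupancy model, that the constant database matches the assay
chemistry, or that replicate noise is Gaussian — real data carry seedling
heterogeneity, measurement rounding and germination failures the generator
deliberately omits.

## 7. Validation against the printed study values

The published per-set summaries (the printed EC50/slope/TU50 table and the
fitted constants) anchor the test suite at desk scale: fold-change
arithmetic on the printed EC50s; OLS of the printed Mg-set Cu EC50s on
speciated {Mg²⁺} (R² ≈ 0.97–0.98); round-trip recovery of the published
constants (logK_CuBL 5.87, logK_MgBL 2.93, logK_CuCO3BL 5.44; logK_CoBL
4.72, logK_MgBL 3.84, logK_CoHCO3BL 5.81) to two decimals from noise-free
forward-simulated EC50s over the twelve media; TU50 = 1 for noise-free
additive mixtures. Typical problem sizes: 12 media × 8 doses × 3
replicates per simulated assay, 200 noise replicates for the stochastic
properties — sizes at which the whole suite runs in about a minute.

Two printed inconsistencies are flagged rather than corrected. The Co EC50
at Mg 0.5 mM (51.52 µM) lies *below* the 0.05 mM value, breaking the
otherwise linear Mg relationship, and the Co pH-set EC50s at pH 4.5–5.5
(104–129 µM) are irreconcilable with the printed Co constants under any
consistent speciation (they would require f50 ≈ 0.84 against the printed
0.66). Predicted-versus-printed agreement is therefore asserted within a
factor of 2 where the printed values are internally consistent: all twelve
Cu media, the Co Mg-set range endpoints, and the Co pH ≥ 6 rows. The
pooled mixture headline numbers (RMSE 6.70 vs 16.31, R² 0.97 vs 0.84)
depend on unpublished raw per-seedling data; the package reproduces the
qualitative result on synthetic data (BLM RMSE ≈ 5 vs FIAM ≈ 14 at 5%
noise) and keeps the printed values as documentation
(`published_mixture_fits()`).

## 8. Known limitations

* Inorganic-only speciation: no humic/fulvic binding, redox, solid phases,
  or temperature corrections.
* The BLM here is single-site and equilibrium-based; kinetic uptake and
  multi-site ligands are out of scope, as are >2-metal mixtures (the TU
  algebra generalises but is untested beyond two) and response-addition
  mixture models.
* K_CuOHBL/K_CuHCO3BL are reported as a deterministic split of an
  identified lump (Section 4); treat the individual values accordingly.
* The additive band (±0.2) is a declared convention, not a statistical
  test; use bootstrap CIs on TU50 where a formal call is needed.
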