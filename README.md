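# ligfid

Steady-state kinetics and fidelity analysis of DNA ligation, for
biochemists quantifying gel-based ligase assays. Human DNA ligase I
(LIG1) seals nicked DNA in three steps — enzyme adenylylation, AMP
transfer to the nick's 5′-phosphate, and nick sealing — and can fall off
the AMP-DNA intermediate before sealing ("abortive ligation"), leaving a
dead-end 5′-AMP product. How often it aborts, and how well it
discriminates a damaged 3′-OH base pair (8oxoG•A) from a canonical one
(C•G), both depend on the free Mg²⁺ concentration, which varies several
fold between tissues. `ligfid` turns gel band intensities into these
quantities.

## What it computes

Per lane, from the three band intensities (unreacted substrate *s*,
AMP-DNA intermediate *i*, sealed product *p*):

- fraction product `F_p = p/(p+s+i)` and abortive fraction
  `F_abort = i/(p+i)`, with its complement `F_sealed = 1 − F_abort`;
- initial velocities by linear fits over the window `F_p < 0.20`, scaled
  to per-enzyme turnover `v/[E] = slope × [DNA]/[E]` (s⁻¹);
- hyperbolic saturation fits `v/[E] = k_cat·x/(K½ + x)` over DNA
  concentration (`K_M`, nM) or free Mg²⁺ (`K_Mg`, mM), with standard
  errors and the catalytic efficiency `k_cat/K½`;
- the fidelity decomposition, with sum-of-squares error propagation:

  ```
  D_overall = (k_cat/K_M)_C•G / (k_cat/K_M)_8oxoG•A
  D_step3   = F_sealed(C•G) / F_sealed(8oxoG•A)
  D_overall = D_step2 × D_step3        (so D_step2 = D_overall / D_step3)
  ```

- active enzyme concentration from single-turnover titrations, by
  continuous two-segment ("segmental") linear regression.

A mechanistic simulator of the three-step cycle (8-state mass-action
system with open/closed clamp states, an abortive branch, and
Mg²⁺-scaled chemical steps, integrated by a built-in stiff Rosenbrock
solver) generates synthetic band tables with the structure the analysis
assumes, for validation and power analysis.

## Worked example

Simulate a Mg²⁺-activation experiment (7 free-Mg²⁺ levels, 1000 nM
nicked DNA, 1 nM enzyme, 3 replicate lanes, 2% gel-quantification
noise), quantify it, and fit the activation hyperbola:

```r
library(ligfid)
mg_grid <- c(0.1, 0.2, 0.3, 0.5, 1, 2, 5)
pilot_v <- c(1.3, 2.1, 2.6, 3.4, 4.2, 4.9, 5.3)   # s^-1, from a pilot run
des <- ligation_design(variant = "WT", substrate = "C:G", enzyme_nM = 1,
                       dna_nM = 1000, mg_free_mM = mg_grid, replicates = 3)
des$times <- lapply(pilot_v, function(v) {
  t_max <- 0.15 / (v / 1000)          # quench before F_p reaches ~0.15
  seq(t_max / 8, t_max, length.out = 8)
})
records   <- generate_dataset(des, noise_sigma = 0.02, seed = 42)
fractions <- band_fractions(records)
rates     <- initial_rates(fractions)
fit <- fit_michaelis_menten(rates$mg_free_mM, rates$v_init_per_E,
                            se = rates$v_SE, model_kind = "mg")
fit
#> Saturation fit over free Mg2+ (7 concentrations)
#>   k_cat    = 6.497 +/- 0.33 s^-1
#>   K_Mg (mM) = 0.4289 +/- 0.049
#>   k_cat/K  = 15.15 +/- 1.9 s^-1 mM^-1
```

The fitted `K_Mg` is the *effective* half-activation of turnover; it
sits below the microscopic Mg²⁺ constant of the sealing step whenever
sealing is only partially rate-limiting.

Fidelity decomposition from measured efficiencies and sealed fractions:

```r
fidelity_report(
  eff_canonical = 0.00256, eff_damaged = 0.0005,
  F_sealed_canonical = 0.98, F_sealed_damaged = 0.49,
  se_eff_canonical = 0.0004, se_eff_damaged = 0.0001,
  sd_sealed_canonical = 0.01, sd_sealed_damaged = 0.04,
  condition = "WT at 1.0 mM free Mg2+")
#> Ligation fidelity decomposition [WT at 1.0 mM free Mg2+]
#>   overall (efficiency ratio):       5.1 +/- 1.3
#>   step 2  (AMP transfer):           2.6 +/- 0.68
#>   step 3  (nick sealing):           2 +/- 0.16
```

Read: this enzyme ligates the canonical nick 5.1-fold more efficiently
than the damaged one; a 2.6-fold preference arises at AMP transfer and a
2.0-fold preference at nick sealing (the two multiply to the overall
factor by construction).

`run_pipeline(pipeline_config(...), records)` chains all stages
(quantify → rates → saturation fits → fidelity) and writes CSV/JSON
reports plus a run manifest to an output directory.

## Acceptance script

`scripts/acceptance.R` recomputes the headline fidelity quantities —
sealed-fraction complements at 0.2 mM free Mg²⁺ and reconstructed
discrimination factors — from their published measured inputs, using the
package's own operations, and writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
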