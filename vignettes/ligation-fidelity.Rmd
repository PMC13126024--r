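---
title: "Ligation kinetics and fidelity: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ligation kinetics and fidelity: models, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ligfid)
```

## The measurement problem

ATP-dependent DNA ligases seal single-strand nicks in three chemical
steps: the catalytic lysine is adenylylated by ATP (step 1), AMP is
transferred to the 5′-phosphate of the nick (step 2), and the
3′-hydroxyl attacks the activated phosphate to seal the nick (step 3).
Between steps the enzyme clamp can open, and an open complex can
dissociate. Dissociation before AMP transfer is kinetically silent on a
gel (the nick is unchanged); dissociation after AMP transfer deposits a
free AMP-DNA species — *abortive ligation* — that the re-adenylylated
enzyme cannot rescue.

A denaturing gel of a quenched reaction therefore shows three bands per
lane: unreacted nicked substrate ($s$), AMP-DNA intermediate ($i$) and
sealed product ($p$). Everything this package computes descends from
those three intensities:

$$F_p = \frac{p}{p+s+i}, \qquad
  F_{abort} = \frac{i}{p+i}, \qquad
  F_{sealed} = 1 - F_{abort} = \frac{p}{p+i}.$$

All three are ratios within a lane, so uncalibrated fluorescence units
and lane-to-lane loading differences cancel. Background subtraction is
assumed to have happened upstream, in the gel-quantification software.

## Initial rates and saturation fits

Initial velocities come from ordinary least-squares lines through the
$(t, F_p)$ points with $F_p$ below a window threshold (default 0.20),
converted to per-enzyme turnover:

$$v_{init}/[E] = \mathrm{slope} \times [\mathrm{DNA}]/[E] \quad
  (\mathrm{s}^{-1}).$$

Design choices here:

* **Free intercept.** Quench dead-time and residual background shift
  the line vertically without changing its slope; forcing the line
  through the origin would convert such offsets into slope bias.
* **Window on product fraction.** The 0.20 ceiling keeps the fit inside
  the phase where substrate depletion is negligible; it is configurable
  (`fp_threshold`) and adding points beyond the window never changes
  the estimate.
* **Total-DNA scaling.** $F_p$ is a fraction of *total* DNA, so the
  slope is multiplied by the total DNA concentration; the assays this
  supports use saturating DNA in large excess over enzyme. The code
  warns when DNA/enzyme < 5, where multiple-turnover velocities become
  unreliable.
* **Linear-phase pooling of $F_{abort}$.** The sealing/abortion split is
  a steady-state branching ratio, constant during the linear phase, so
  by default intensities are pooled over the in-window lanes before
  taking $i/(i+p)$ — this reduces quantification noise. A
  `per_timepoint` mode reports lane-by-lane values instead. (Whether
  published values are endpoint- or linear-phase-based is generally not
  stated; both modes exist, linear-phase is the default.)

Saturation behaviour in either the DNA substrate or the Mg²⁺ cofactor is
fit by the rectangular hyperbola

$$v_{init}/[E] = \frac{k_{cat}\, x}{K_{1/2} + x},$$

with $x$ the DNA concentration ($K_{1/2} = K_M$, nM) or the free Mg²⁺
concentration ($K_{1/2} = K_{Mg}$, mM). Although the ligase binds
several Mg²⁺ ions, the activation data behave as a single essential,
weakly bound cofactor, so no Hill coefficient is fit by default; an
exploratory Hill model is available behind `hill = TRUE`. Fitting is
weighted nonlinear least squares (`nls`, port algorithm, weights
$1/SE^2$ when velocity errors are supplied, data-driven starting values,
a restart polish so weighted and unweighted fits agree to better than
$10^{-8}$ when SEs are equal). Degenerate saturated designs (no
concentration dependence) are flagged as `K_half_not_identifiable`
rather than fit; a fitted $K_{1/2}$ more than 10× beyond the largest
tested concentration raises an extrapolation warning.

Replicates: by default each replicate's velocity enters the fit as its
own weighted point; an `averaged` mode (mean per condition first) is
available in the pipeline, since published work reports mean ± SD of
≥3 replicates without stating the pooling convention.

## Active-site titration

Single-turnover titrations (enzyme titrated against fixed DNA, no ATP so
the enzyme cannot recycle) are fit by the continuous two-segment model
$y = a + b\min(x, c)$: product rises with enzyme and then plateaus. The
breakpoint $c$ is profiled on a grid spanning the titration points and
refined by bounded optimisation, ties resolved toward the smaller
breakpoint so results are deterministic and reproducible by an
exhaustive grid search. The active fraction is the plateau level over
the breakpoint on the nominal (as-pipetted) axis. When the segmented fit
does not beat a single line, the code refuses to report a breakpoint and
advises widening the titration.

## The fidelity decomposition

Discrimination against a damaged 3′-OH pair is the efficiency ratio

$$D_{overall} = \frac{(k_{cat}/K_M)_{C\cdot G}}{(k_{cat}/K_M)_{8oxoG\cdot A}},$$

which factorises over the two chemical steps,
$D_{overall} = D_{step2} \times D_{step3}$, with the sealing-step
component measured directly from sealed fractions,
$D_{step3} = F_{sealed}^{C\cdot G} / F_{sealed}^{8oxoG\cdot A}$, and the
AMP-transfer component recovered as $D_{overall}/D_{step3}$. The
identity holds to machine precision by construction in every
`fidelity_report`. A cross-check mode accepts abortive-inclusive
efficiencies (total adenylylated product rather than sealed product
only); their ratio is the direct step-2 estimate and agrees with the
identity route algebraically, which the tests assert.

Errors are propagated by the sum-of-squares rule: relative standard
errors add in quadrature through any product/ratio chain. Errors are
treated as independent between substrates and conditions (separate
reactions). Two numerical notes:

* The rule is the first-order result for *multiplicative* (log-normally
  approximated) errors. The Monte-Carlo validation in the test suite
  samples exactly that model — median-matched log-normal inputs with
  SD/mean equal to the stated CV — and summarises the propagated spread
  by the central-68% interval half-width, because moment SDs of ratio
  distributions are tail-dominated (for Gaussian denominators the
  variance does not even exist). Within that model, quadrature agrees
  with simulation to well within 10% for input CVs up to 0.3.
* A damaged sealed fraction of zero would make step-3 discrimination
  infinite; it is returned as a *censored lower bound* against a
  detection limit (default 0.01), flagged so it cannot be mistaken for
  a measured number, and it blocks the step-2 division.

Fold factors are reported at two significant figures (the field's
convention), with full precision retained in the objects.

## The mechanism simulator

`simulate_mechanism()` solves the mass-action system for the scheme

```
E + S  <-> open E·S <-> closed E·S --(k2)--> closed E·(AMP-DNA)
                                                  |        ^
                                                  v        |
                                            open E·(AMP-DNA)
closed E·(AMP-DNA) --(k3)--> E + sealed P
open complexes --(k_diss)--> dissociation
```

with eight states: free adenylylated enzyme, free nicked DNA, open and
closed enzyme–substrate complexes, closed and open enzyme–intermediate
complexes, the free abortive AMP-DNA pool, and sealed product. Chemistry
(steps 2 and 3) happens only in the closed clamp; dissociation only from
the open clamp; both chemical rates scale hyperbolically with free Mg²⁺,
$k = k_{max}[\mathrm{Mg}]/(K_{Mg}+[\mathrm{Mg}])$, and the sealing step
is given the weaker Mg²⁺ affinity ($K_{mg,step3} > K_{mg,step2}$), which
is what makes abortive ligation grow as Mg²⁺ falls. Enzyme
re-adenylylation is treated as instantaneous because the assays it
emulates contain saturating (0.2 mM) ATP; this also means the abortive
AMP-DNA pool is absorbing — the AMP-charged enzyme cannot re-engage it.
Dissociation before AMP transfer is modelled as a separate flux but
returns DNA to the substrate pool, mirroring the assay in which
unproductive binding is observationally indistinguishable from
non-binding.

Gel observables sum over enzyme-bound and free species of the same
chemical state (a denaturing gel cannot tell them apart): $F_s$ counts
free and bound nicked DNA, $F_i$ counts bound and released AMP-DNA,
$F_p$ the sealed product. Mass conservation
($F_s + F_i + F_p = 1$) holds to $10^{-8}$ or better in every noiseless
trajectory.

**Numerics.** No ODE solver package is assumed; the package carries a
small linearly implicit Rosenbrock integrator (the classic second-order
L-stable triple with an embedded third-stage error estimate), with
analytic Jacobian, adaptive steps that land exactly on requested output
times, and defaults `rtol = 1e-9`, `atol = 1e-13`. Stiff parameter
regimes that defeat the step controller raise a diagnostic error rather
than returning garbage; states driven slightly negative by roundoff are
clipped at zero and anything beyond tolerance errors out. An exact
stochastic backend (direct-method SSA on integer copy numbers) exists
for small-copy-number questions; bulk observables use the ODE backend.

**Parameter defaults.** No microscopic rate constants have been measured
for this enzyme, so `default_mechanism_params()` aims for structural
realism rather than numerical reproduction: wild type on the canonical
nick at 1.0 mM free Mg²⁺ aborts ≈5% of AMP-transfer events, and the
perturbations the scheme predicts — faster clamp opening (the K845N
variant, which weakens an interdomain contact), faster intermediate
release and slower sealing (the damaged 8oxoG•A nick), or low Mg²⁺ —
push the abortive fraction into the 0.4–0.99 range. Long-time abortive
fractions from the simulator match the analytic absorbing-state
probabilities of the per-encounter Markov chain to $10^{-5}$ relative or
better, which is the property the test suite checks against an
independent linear-algebra oracle.

**What the generator does and does not emulate.** `generate_dataset()`
adds lane-wise Gaussian noise to the band *fractions* (clipped at zero,
renormalised — quantification is relative within a lane) and scales by a
total-signal constant; seeds are split hierarchically per condition and
replicate so fixtures are reproducible and order-independent. It does
not emulate lane-loading variation, band-shape overlap, image
saturation, or any systematic gel artefact — so a green recovery test
establishes that the *analysis chain* is unbiased and appropriately
precise under honest random noise, not that real gels are this
well-behaved.

## Parameter recovery: what the stated world supports

The end-to-end check generates Mg²⁺-activation data (grid 0.1–5 mM,
3 replicate lanes, fraction noise σ = 0.02) from a parameter set in
which nick sealing is rate-limiting by two orders of magnitude, so the
effective turnover is hyperbolic in Mg²⁺ with half-activation equal to
the microscopic $K_{mg,step3}$ (composite-cycle bias < 1%). The number
of quench timepoints per curve is a free design choice; it was set by a
prospective power calculation rather than trial and error: an $n$-point
even grid reaching $F_p = 0.18$ gives a slope CV of roughly
$\sigma / (0.18 \cdot 0.5\sqrt{n})$ per condition with 3 replicates,
so $n = 16$ yields ≈5.6% per condition and ≈8% on the fitted $K_{Mg}$,
which places a ±15% recovery band at ≈1.9 standard errors — the
criterion of 90 successes in 100 trials then holds with margin. With
8 points per curve the estimator is equally unbiased (trial mean
0.499 vs truth 0.5) but its 11% CV passes only ~80% of trials; the
recovery criterion is a statement about sampling density as much as
about the fitting code.

## Bookkeeping conventions

* **Free vs total Mg²⁺.** Conditions are labelled by *free* Mg²⁺;
  `free_mg(total, atp)` converts total to free by subtracting ATP 1:1
  (tight chelation), matching assay bookkeeping such as "0.2 mM free
  (0.4 mM total) with 0.2 mM ATP". The pipeline accepts either
  convention (`mg_mode`).
* **Substrate labels.** `"C:G"` is the canonical Watson–Crick nick,
  `"8oxoG:A"` the pro-mutagenic Hoogsteen pair at the 3′-OH side of the
  nick.
* **Formats.** Band records, fractions and rates travel as plain CSV;
  fits and fidelity reports as JSON with full double precision
  (`digits = NA`); every run writes a manifest recording config, seed
  and package version. Outputs round-trip losslessly at 15 significant
  digits.

## Known limitations

* The simulator collapses adenylylation and treats the HiFi (fidelity)
  Mg²⁺ site implicitly through the clamp-opening parameters; it has no
  explicit nucleotide-level DNA structure.
* Progress-curve (integrated rate equation) fitting and pre-steady-state
  analysis are out of scope; only linear-phase initial rates are
  supported.
* Quadrature error propagation assumes independent, moderate
  (CV ≲ 0.3), multiplicative errors; bootstrap or Bayesian propagation
  is future work.
* Microscopic rate constants in `default_mechanism_params()` are
  plausible, not measured; conclusions about real enzymes should come
  from fitted macroscopic parameters, not simulator defaults.
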