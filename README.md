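# axstab

Oxidative-stability analytics for antioxidant-enriched fats.

Natural carotenoid antioxidants — astaxanthin (AX) recovered from shrimp
processing by-products in particular — are candidates for slowing lipid
oxidation in animal fats such as lard. Deciding *how much* antioxidant to
add requires chaining four analyses that usually live in separate
instrument-software silos:

1. **Pigment quantification** by first-derivative UV-Vis spectrophotometry:
   dA/dλ peaks and areas under the curve in the 420–450 nm and 455–480 nm
   windows, calibration lines `feature = slope·[AX] + intercept`, and
   first-order degradation kinetics `c(t) = c0·exp(−k·t)` during storage.
2. **Thermal-oxidative stability** from DSC heat-flow curves: the oxidation
   onset temperature To (tangent or threshold construction) and the
   activation energy by the Ozawa–Flynn–Wall isoconversional method,

   &nbsp;&nbsp;&nbsp;log₁₀ β = log₁₀(A·Ea/R) − 2.315 − 0.4567·Ea/(R·T),

   regressed as log₁₀ β = a·(1/T) + b across heating rates
   β ∈ {5, 7.5, 10, 15} K/min, with Ea = −a·R/0.4567.
3. **Response-surface models** per response Y ∈ {To, Ea, PV, TBA}:

   &nbsp;&nbsp;&nbsp;Y = β₀ + β₁X₁ + β₂X₂ + β₃X₁² + β₄X₂² + β₅X₁X₂,

   with X₁ = concentration (mg/g), X₂ = storage time (days); full inference
   panels, dual df conventions, lack-of-fit, backward term elimination, and
   Tukey compact letter displays from summary statistics.
4. **Multi-response optimization and validation**: one-sided Derringer
   desirabilities (maximize To, Ea; minimize PV, TBA), overall desirability
   D = geometric mean, a grid search for the optimal concentration, and
   Bland–Altman agreement (bias ± 1.96·SD limits) between measured and
   model-predicted responses.

The package ships a 24-run storage-study design table
(8 concentrations × days {0, 10, 30}) as a packaged fixture, plus
synthetic-data generators with known ground truth for spectra, oxidation
exotherms and design tables, so every stage is testable offline.

## Worked example

Fit the onset-temperature surface on the packaged design table:

```r
library(axstab)
tab <- design_table7()
fit_rsm(tab, "To")
#> <rsm_model: To_C ~ second-order polynomial (natural units), n = 24>
#>     term   estimate        se        t          p
#> b0     1 238.025996 1.1551800 206.0510 8.1773e-32
#> b1    X1   3.135741 1.2480570   2.5125 2.1736e-02
#> b2    X2   0.855993 0.1508835   5.6732 2.2158e-05
#> b3  X1^2  -0.649051 0.3007497  -2.1581 4.4675e-02
#> b4  X2^2  -0.031732 0.0044854  -7.0745 1.3476e-06
#> b5 X1*X2  -0.032988 0.0264028  -1.2494 2.2751e-01
#> R2 = 0.8308, adj R2 = 0.7838 (conventional), residual SE = 2.0333, F = 17.6798
```

Onset temperature rises ~3.1 °C per mg/g of antioxidant with negative
curvature (an interior maximum near 2–2.4 mg/g), rises transiently with
storage day, and the concentration × time interaction is not significant
(p = 0.23) — the first candidate for backward elimination.

Optimize the concentration across all four responses:

```r
panel <- rsm_panel(tab)
optimize_concentration(panel$models, default_desirability_spec(tab))
#> <desirability_result> optimal concentration = 1.75 mg/g (D = 0.5103, time averaged over {0, 10, 30})
#>   per-response d at optimum: To = 0.634, Ea = 0.661, PV = 0.584, TBA = 0.375
```

The per-response desirabilities show the trade-off at the optimum: thermal
stability (To, Ea) and peroxide suppression favour mid-range concentrations
while the TBA column of this design table rises with concentration and
caps the overall desirability.

Recover a known activation energy from simulated DSC curves:

```r
set <- simulate_dsc_set(dsc_sim_config(noise_sd = 0))   # Ea_true = 95 kJ/mol
ea_profile(set, c(0.05, 0.1))
#>   alpha   slope_a intercept_b Ea_kJ_mol   A_pre_min r_squared
#> 1  0.05 -5379.280    12.72400  97.92716 92877375509 0.9999984
#> 2  0.10 -5374.378    12.40288  97.83791 44379593847 0.9999998
```

The ~3 % overestimate is the documented bias of the Doyle approximation at
x = Ea/RT ≈ 25; the profile is flat across conversion levels, as expected
for single-step kinetics.

A command-line wrapper over the same functions is installed at
`inst/cli/axstab-cli.R` with subcommands `simulate`, `quantify`, `kinetics`,
`rsm`, `optimize`, `agreement` and `reproduce` (exit codes: 0 ok, 2 usage,
3 parse, 4 domain).

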