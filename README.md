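# cagefold

Kinetic and thermodynamic analysis of protein folding inside the
GroEL/GroES chaperonin cage.

## The problem

GroES capping of GroEL forms a cavity ("cage") in which a substrate
protein folds in isolation from bulk solution. Whether that environment
thermodynamically stabilizes or destabilizes the substrate is measured
here indirectly, through the enzymatic activity of an encapsulated
dihydrofolate reductase (DHFR) reporter: a destabilized enzyme sits
mostly unfolded, and adding its substrates (DHF and the cofactor NADPH,
whose consumption is followed as a falling absorbance at 340 nm) pulls
the folding equilibrium toward the active state. That relaxation shows
up as a **lag phase** in the product progress curve.

`cagefold` implements the full inference chain for this experiment, for
biophysicists analyzing progress curves, chemical denaturation
titrations, thermal melts and time-resolved anisotropy decays:

1. **Lag-phase progress curves** — fit of
   `P(t) = V t + A (e^(-λt) - 1)` (plus a nuisance intercept), window
   selection before substrate depletion, residual runs test, and
   Michaelis–Menten analysis of the steady-state velocities.
2. **Rate-constant inference** — under conformational selection with
   fast binding, the lag rate constant obeys
   `λ(S) = k1 + k_minus1 / (Ka·S + 1)`
   (k1 folding, k_minus1 unfolding, Ka substrate association). A
   decreasing λ(S) is the signature of conformational selection; an
   increasing one indicates induced fit or substrate penetration.
   Weighted least squares with non-negativity, reduced-χ² surfaces over
   (k1, k_minus1) with the association constant profiled out, and
   Δχ²=1 profile confidence intervals.
3. **Stability** — cage folding free energy
   `ΔG = RT ln(k_minus1/k1)` (folding convention: positive = unfolded
   favored); bulk stability from two-state GuHCl denaturation with
   linear baselines,
   `F = [F_U0 + aD + (F_N0 + bD) e^(-(ΔG0+mD)/RT)] / [1 + e^(-(ΔG0+mD)/RT)]`,
   measured at several NADPH concentrations and extrapolated to zero
   cofactor through the Wyman linkage `ΔG(S) = ΔG0 - RT ln(1 + S/Km)`;
   the cage-vs-bulk difference ΔΔG is the headline number.
4. **Apparent Tm** from dye-based (SYPRO-style) thermal melts via a
   Savitzky–Golay first derivative.
5. **Rotational correlation times** from polarized photon-count decays,
   `r(t) = (I∥ - G·I⊥)/(I∥ + 2G·I⊥)`, single-exponential fit — used to
   ask whether the caged substrate tumbles freely or sticks to the
   cavity walls.
6. **Synthetic data** for every stage, with stated noise models, seeds
   and recorded ground truth, including an ODE simulator of the coupled
   folding–binding–catalysis scheme `EU ⇌ EF ⇌ ES → EF + P`.

## Worked example

```r
library(cagefold)

## rate constants reported for the caged enzyme
rates <- scheme_rates(k1 = 1.4e-4, k_minus1 = 7.3e-3, Ka = 3571)

## folding free energy inside the cage at 23 C
cage <- delta_g_from_rates(rates, k1_se = 0.4e-4, k_minus1_se = 0.8e-3)
print(cage)
#> Folding free energy: 2.327 +/- 0.180 kcal/mol at 296.15 K [rates]
#>   convention: folding (positive = unfolded favored)

## against the bulk-solution stability from linkage extrapolation
bulk <- stability_result(-3.45, 296.15, "extrapolation", 0.09)
print(destabilization(cage, bulk))
#> Cage-vs-bulk destabilization: 5.78 +/- 0.20 kcal/mol (folding convention)
```

The cage value (+2.33 kcal/mol) says the encapsulated enzyme is *less*
stable folded than unfolded; the bulk value (−3.45) says the same
protein is comfortably stable outside. The difference, ~5.8 kcal/mol,
is the thermodynamic cost of the cage environment.

A full synthetic experiment:

```r
ser <- simulate_lambda_series(rates,
         exp(seq(log(10e-6), log(500e-6), length.out = 8)),
         noise_frac = 0.05, seed = 1)
fit <- fit_lambda_curve(ser)
print(fit)
#> Fit of lambda(S) = k1 + k_minus1/(Ka S + 1)
#>   k1       = 0.0003225 +/- 0.00087 s^-1
#>   k_minus1 = 0.007089 +/- 0.00074 s^-1
#>   Ka       = 3601 +/- 1.2e+03 M^-1
#>   reduced chi2 = 0.9254 on 5 dof (weighted)
classify_mechanism(ser)$mechanism
#> [1] "conformational_selection"
```

## Command line

```sh
inst/scripts/cagefold simulate --what lambda --out data --seed 1
inst/scripts/cagefold fit-lambda --file data/lambda_series.csv
inst/scripts/cagefold pipeline --config config.json --out out
```

`pipeline` chains every stage present in a JSON manifest (progress
curves and/or λ tables, denaturation titrations, melts, anisotropy
decays) into `report.txt`, `report.json` and `results.csv`, always
stating the constants (R, T) and the ΔG sign convention used.

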