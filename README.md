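# cortcond

Growth-law analysis of short-lived cortical condensates.

During oocyte maturation, activation of the first contractile actomyosin
cortex is accompanied by thousands of transient cortical condensates rich
in the F-actin nucleator N-WASP (WSP-1), the ARP2/3 complex and F-actin.
Each condensate grows, turns around and dissolves — a condensate-scale
dynamic instability that limits condensate size and prevents runaway
F-actin nucleation. `cortcond` is an R package for the quantitative
analysis behind this picture, aimed at anyone reconstructing growth
kinetics of tracked multicomponent assemblies from intensity time series
(mass-balance imaging).

The core model is a pair of empirical mass-action growth laws for the two
integrated intensities `W` (WSP-1) and `A` (F-actin):

```
dW/dt = k_r W − k_l A W / V
dA/dt = k_b A W / V − k_d A,      V = v_A A + v_W W
```

The field is degree-1 homogeneous, so composition dynamics are intensive
(independent of condensate size), both nullclines are rays of constant
stoichiometry `s = A/(A+W)`, and the relative growth rates are linear in
the effective F-actin volume fraction `φ = v_A A / V` — which is what
makes the four coefficients identifiable by regression. The bounded
(grow-then-dissolve) and unbounded-growth regimes are separated by the
critical point `v_A k_r / k_l + v_W k_d / k_b = 1`.

The package provides:

* the dynamical system — rates, orbits, nullclines, dominant composition,
  critical point, regime classification;
* a stochastic track-ensemble generator (Poisson nucleation, intrinsic
  rate noise, multiplicative measurement noise, detection truncation) so
  every stage is testable without microscopy data;
* the linear volume-relation fit, concentrations and the line of constant
  total density;
* mass-flux phase portraits: per-point derivatives, binned vector fields,
  empirical nullclines, growth-vs-stoichiometry curves, occupancy
  contours, the preferred concentration pair, and the (φ, V)
  representation;
* kinetic-coefficient estimation (instrumented weighted regression),
  knockdown condition comparison and critical-point extrapolation;
* track TSV IO and an end-to-end pipeline (`run_pipeline()`, plus a thin
  CLI at `inst/scripts/cortcond.R`).

## Worked example

Analytic geometry at the canonical coefficient set (chosen to reproduce
the experimentally reported nullcline stoichiometries of ~0.85 and ~0.9
with the reported volume coefficients):

```r
library(cortcond)
nullcline_stoichiometries()
#>       s_W       s_A
#> 0.8500127 0.9000000
critical_kd()
#> [1] 0.219561
fixed_point_phi()$s   # dominant stoichiometry (slowest dynamics)
#> [1] 0.9067631
```

Generate a synthetic ensemble, reconstruct the portrait and recover the
coefficients:

```r
cfg <- generator_config(duration = 120, rng_seed = 7L)
ens <- generate_ensemble(cfg, n_condensates = 500)
pts <- estimate_derivatives(ens$tracks)
field <- bin_vector_field(pts)
extract_nullcline(field, "W")
#> Empirical W nullcline: stoichiometry 0.8706 (+/- 0.0118) from 17 crossings
extract_nullcline(field, "A")
#> Empirical A nullcline: stoichiometry 0.9010 (+/- 0.0018) from 19 crossings
fit_kinetics(pts, n_boot = 100)
#> Growth-law kinetic fit:
#>   k_r = 0.10321 (+/- 0.0028)
#>   k_l = 2.0126e-08 (+/- 5.1e-10)
#>   k_b = 2.4182e-07 (+/- 1.2e-09)
#>   k_d = 0.14928 (+/- 0.0008)
#>   R^2: WSP-1 0.0129, F-actin 0.2374; 52409 points, 476 condensates, phi in [0.550, 0.897]
```

The empirical nullclines land on the analytic rays and the four
generating coefficients (0.1, 1.9529e-8, 2.43e-7, 0.15) are recovered
within a few percent from noisy tracks. `rnai_preset()` provides
coefficient sets for graded ARP2/3 knockdown; `compare_conditions()`
reports fold changes (the dominant knockdown effect is the increase of
the F-actin loss rate `k_d`, by 1.7x/2.7x for mild/moderate), and
`predict_perturbed_portrait()` shows the nullcline switch into unbounded
growth beyond `critical_kd()`.

See the vignette (`vignettes/condensate-growth-laws.Rmd`) for the model,
the estimation subtleties and the generator's scope.

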