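# microvisc

Microscale rheometry of polymer solutions from microchannel velocity
profiles.

## The problem

Injectable hydrogels — for example liquid polyethylene-glycol (PEG)
precursors injected into infarcted myocardium — spread through
micrometre-scale tissue gaps before they gel, and most of the injected
material is lost in that window. Whether the liquid is Newtonian or
shear-thinning at that scale controls how fast it flows and hence how much
is retained, but macroscale rheometry cannot answer the question: polymer
solutions behave differently in 10–100 μm conduits (wall slip, confinement).

`microvisc` implements velocimetry-based microrheometry: it infers the
shear-rate-dependent viscosity of a solution from micro-PIV velocity
profiles measured across a microchannel (the experiment's stand-in for a
tissue gap), with no rheometer involved.

## The method

For each flow case (one flow rate), the midplane profile `v(y)` is

1. fitted to the empirical cosh family
   `v = v_w [cosh(0.5m) − cosh(|y*|m)]/[cosh(0.5m) − 1] + v0`
   (`y* = y/w`), a smooth bluntness-parameterized curve with explicit wall
   slip `v0`, by weighted Levenberg–Marquardt;
2. integrated for the average velocity, and normalized by it;
3. fitted to the power-law duct family
   `vN = ((3n+1)/(n+1)) v_avgN (1 − |ŷ|^((n+1)/n)) + v_0N` (`ŷ = 2y*`),
   giving the per-case power-law index `n` — valid for any duct section,
   since the index is shape-independent.

Across cases, differential viscometry integrates
`n(γ̇) = d ln μ / d ln γ̇ + 1` over the nominal shear rate
`γ̇ = mean velocity / width`, recovering the viscosity curve up to a
constant, and a log-log least-squares fit of `μ = K γ̇^(n−1)` yields the
consistency index `K` and overall index `n` (cases with per-case `n > 1`
are excluded as anomalies). A forward model — the planar slit power-law
solution with slip, or a finite-difference Picard solver for the full
rectangular duct (validated against the Newtonian series solution) —
predicts each case's profile for comparison with the measurements. A
synthetic micro-PIV generator (2.4 μm grid, 60-replicate averaging,
configurable noise) makes the whole chain testable end to end.

## Worked example

```r
library(microvisc)

# Overall rheology from the shipped 13-case measured summary table
tab <- read_rheology_table()
fit_power_law_rheology(tab)
#> <power_law_model> K = 1.012 kg.s^(n-2).m^-1, n = 0.8828 (12 cases; excluded: 04)
```

`K ≈ 1.0` and `n ≈ 0.88 < 1`: the solution is mildly shear-thinning in the
8–132 s⁻¹ range, with viscosity `μ = K γ̇^(n−1)` falling from ~0.78 Pa·s at
8 s⁻¹ to ~0.56 Pa·s at 132 s⁻¹. One case (n = 1.04) is dropped by the
anomaly rule.

```r
# Fully synthetic study: 13 cases, truth n = 0.883, 2% PIV noise
rep <- run_pipeline(pipeline_config(seed = 7))
rep
#> <comparison_report> 13 cases, K = 1.279, n = 0.8810
#>   99% CI coverage: 1.00 (min) ... 1.00 (max)
```

The inference recovers the generating index (0.881 vs 0.883; in relative
viscometry mode `K` absorbs the unidentified integration constant and is
not comparable), and every slit-model prediction lies inside the
measurements' 99% confidence band.

The numbered scripts under `analysis/` run the full study: `01` the
measured-table rheology, `02` the synthetic end-to-end pipeline, `03` the
duct-solver validation (series oracle, grid convergence, slit limit), `04`
the parameter-recovery experiment. Each writes its tables under `results/`.

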