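---
title: "Inferring microscale rheology from microchannel velocity profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring microscale rheology from microchannel velocity profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microvisc)
```

## The problem

Injectable polymer hydrogels (for example polyethylene-glycol solutions used
as myocardial injectates) are usually characterized as Newtonian on the
macroscale, but their behaviour in micrometre-scale gaps — the scale of the
cleavage planes in myocardial tissue through which an injected liquid
actually spreads — can differ. Micro particle image velocimetry (μPIV) in a
microchannel yields midplane velocity profiles at a series of flow rates;
`microvisc` turns such profiles into a shear-rate-dependent viscosity law.

The inference chain is:

1. **Empirical profile fit.** Each measured profile is fitted to the
   cosh-family curve
   $v(y^*) = v_w\,\frac{\cosh(0.5m)-\cosh(|y^*|m)}{\cosh(0.5m)-1} + v_0$,
   $y^* = y/w \in [-0.5, 0.5]$, by weighted Levenberg–Marquardt least
   squares. This smooths irregularities and mild asymmetry in raw PIV data
   and carries an explicit wall-slip parameter $v_0$, needed because PIV
   cannot read reliably within ~2 μm of the wall and because polymer
   solutions genuinely slip.
2. **Average velocity.** The case's mean velocity is the integral of the
   *fitted* curve (composite Simpson on 1001 uniform points), not of the raw
   points — the raw grid stops short of the walls and would bias the mean.
3. **Normalization and power-law index.** The profile normalized by its
   mean is fitted to the power-law duct family
   $v_N(\hat y) = \frac{3n+1}{n+1} v_{avgN}\,(1-|\hat y|^{(n+1)/n}) + v_{0N}$
   on the rescaled coordinate $\hat y = 2y^* \in [-1,1]$. The power-law
   index $n$ is independent of the duct cross-section shape, which is what
   lets a circular-duct family be applied to a square channel.
4. **Differential viscometry.** With the nominal shear rate defined as
   mean velocity over channel width, the per-case indices form a curve
   $n(\dot\gamma)$ and
   $\ln \mu(\dot\gamma) = \text{const} + \int (n(s)-1)\, d\ln s$
   recovers the viscosity curve up to one multiplicative constant.
5. **Overall power law.** Ordinary least squares of $\ln\mu$ on
   $\ln\dot\gamma$ gives the overall index $n$ (slope + 1) and consistency
   index $K$ (exp intercept) of $\mu = K\dot\gamma^{n-1}$.

A forward model closes the loop: the planar (slit) power-law Poiseuille
solution with constant slip predicts each case's profile from its fitted
parameters, and a finite-difference solver handles the true square duct.

## Coordinate convention of the power-law family

As written on $y^*\in[-0.5,0.5]$ the family does not integrate to one for
parameter triples that plainly describe unit-mean profiles; on
$\hat y = 2y^*$ its integral is
$v_{avgN}\frac{3n+1}{2n+1}+v_{0N}$, which is 1 (to 0.8%) for the reference
worked example (n = 0.9389, v_avgN = 0.5198, v_0N = 0.3186). The package
therefore evaluates the family on $\hat y$. Centre and wall values — the
quantities compared against published numbers — are unaffected by the
choice.

## The viscometry quadrature

The integration constant in step 4 is not identified by normalized profiles,
so the default is *relative* mode ($\mu = 1$ at the lowest shear rate); the
unknown constant is then absorbed into $K$, whose absolute value is only
meaningful when an anchored mode (a known $(\dot\gamma_{ref}, \mu_{ref})$
pair) or a measured viscosity column is used. The cumulative quadrature is
the midpoint/leapfrog scheme
$\ln\mu_{i+1} = \ln\mu_{i-1} + (n_i-1)(\ln\dot\gamma_{i+1}-\ln\dot\gamma_{i-1})$
with a trapezoid first step. It is second-order, exact for constant $n$,
and—unlike the plain trapezoid—its exact inverse is the standard
central-difference estimator of $d\ln\mu/d\ln\dot\gamma$, so
`differential_index(integrate_viscosity(x))` returns `x` at interior nodes
to machine precision. That exact-inversion property is the defining identity
of differential viscometry and is asserted in the tests.

## Anomaly exclusion

In a shear-thinning sweep an individual case occasionally fits with
$n > 1$ (apparent shear-thickening), typically from residual asymmetry the
cosh stage could not fully absorb. The overall fit drops such cases and
records them (`fit_power_law_rheology`, rule `"n_gt_1"`). The rule is
behavioural — it keys on the fitted index, not on a case label — and
idempotent; with no anomalous case the full set is used.

## The duct solver

Steady unidirectional flow of a generalized Newtonian fluid reduces the
Navier–Stokes equations exactly to a scalar nonlinear Poisson problem on the
cross-section, $\nabla\!\cdot(\mu(|\nabla u|)\nabla u) = -G$ with $u = u_0$
on the walls. A pressure–velocity-coupled CFD scheme is unnecessary for this
reduction; the package solves it directly, which is a deliberate difference
in *method*, not in *model*, from a general-purpose CFD code. Numerical
choices:

- five-point finite differences, arithmetic-mean face viscosities, uniform
  grid (default 65 × 65, as used for the validation results);
- Picard iteration with under-relaxation 0.7, converged when the maximum
  relative velocity update falls below 1e-8, capped at 10,000 iterations
  (non-convergence is an error, never a silent result);
- the shear rate is floored inside the viscosity law — the usual
  bounded-viscosity regularization of the power law's centreline
  singularity for $n<1$. The default floor adapts to the problem, 1e-3 of
  the wall shear-rate scale $(G\,\min(w,h)/2\,/\,K)^{1/n}$: a fixed
  absolute floor far below the plug region's residual shear rates leaves
  the viscosity there unboundedly sensitive to iteration noise and the
  Picard map settles into a limit cycle instead of converging. Cells below
  the floor carry negligible momentum flux, and halving or doubling the
  floor moves the computed maximum velocity at the 5e-5 relative level;
- a Newtonian fluid is detected and solved in a single exact linear pass;
- flow-rate / mean-velocity drives find $G$ by exploiting the exact
  $u - u_0 \propto G^{1/n}$ scaling of the homogeneous part, with secant
  correction to 1e-10 relative on Q (the scaling makes this converge in a
  couple of solves; Q(G) is strictly monotone).

The Newtonian rectangular-duct series (including the $\sin(k\pi z/h)$
factor, i.e. the alternating sign at mid-height, which is sometimes dropped
when the series is quoted) is the analytic oracle: the 65 × 65 solve matches
it to <0.5% on the midline, and the section mean/max ratio reproduces the
classical 0.4770 for a square duct. The midline *line* mean/max ratio of
the same solution is 0.6866 — a distinct number worth stating because blunt
measured profiles are naturally compared against it (shear-thinning + slip
pushes it towards ~0.75).

## The synthetic-data generator

The generator emulates the study conditions of a microchannel μPIV
experiment, and its defaults are those conditions:

- geometry 50 × 50 μm × 15 mm; measurement grid spacing 2.4 μm with every
  point ≥ 2 μm from the walls (the grid is symmetric about the axis, 20
  points across the width);
- 13 cases whose nominal shear rates span 8–132 s⁻¹ log-uniformly
  (mean velocities 4.0e-4 to 6.6e-3 m/s);
- truth profiles from the slit power-law solution with constant slip — the
  same two-dimensional idealization the validated forward model uses;
- wall slip per case equal to 0.33 × mean velocity, matching the roughly
  constant normalized slip (~0.32) observed across measured cases;
- per point, the reported velocity is the mean of 60 replicate draws
  (emulating 60 PIV image pairs) of
  truth × (1 + a_skew·ŷ) + N(0, σ), σ² = (σ_rel·truth)² + σ_abs², with
  σ_rel = 2% by default; the reported uncertainty is σ/√60. Seeds are
  mandatory.

What it does **not** emulate: particle-image formation and cross-correlation
(noise enters at the vector level, not the image level), depth-of-correlation
averaging across the channel depth, correlated noise between neighbouring
vectors, and systematic near-wall bias. Passing tests therefore demonstrate
the *inference* is correct and stable under the stated noise structure, not
that every PIV artefact is survivable.

## Forward comparison and its conventions

Per case the forward drive is the mean velocity implied by the power-law fit
itself (the family integral times the normalizing mean) with slip
$v_{0N}\times$ mean; this makes the prediction exactly the denormalized
fitted curve, so a zero-noise run closes to machine precision — the
pipeline's self-consistency invariant. Model profiles are interpolated onto
the measurement grid with a monotone (Hyman) cubic on the folded
half-profile, which cannot overshoot the blunt centre. The 99% confidence
band is mean ± 2.576 σ_v under a normal assumption, widened by a numerical
tolerance of 1e-8 × max|v| so the zero-noise band is well defined.
Reported flow rates are mean velocity × w × h — a stated convention, since
a single midplane line profile does not determine Q without an assumption
about the third dimension.

## Problem sizes and reproducibility

The shipped analyses use 13-case studies, 65 × 65 (validation) and 33 × 33
(property checks) duct grids, and 50–200 repetition recovery experiments;
the full inference on a 13-case study takes well under a second, a
shear-thinning duct solve a few seconds. Every random quantity flows from a
single integer seed (`pipeline_config(seed =)`), and identical (config,
seed) pairs produce byte-identical JSON reports.

## Worked example

```{r example}
tab <- read_rheology_table()       # 13-case measured summary
fit_power_law_rheology(tab)        # K ~ 1.0, n ~ 0.883, one case excluded

rep <- run_pipeline(pipeline_config(seed = 7))
rep
rep$summary[c(1, 13), c("case_id", "shear_rate_s1", "n", "v_0N",
                        "ci_coverage")]
```

## Known limitations

- Slip is a single constant Dirichlet velocity; asymmetric or shear-
  dependent slip laws are out of scope.
- The power law has no zero-shear plateau; extrapolating the fitted
  $\mu = K\dot\gamma^{n-1}$ below the measured shear-rate range is not
  meaningful.
- In relative viscometry mode $K$ carries the unidentified integration
  constant; only anchored or measured-viscosity fits give absolute $K$.
- The duct solver is steady, inertia-free (exact for unidirectional steady
  flow) and rigid-walled; transient (cardiac-cycle) driving, viscoelasticity
  and gelation kinetics are not modelled.
- Realistic tissue geometries (3-D unstructured domains) are outside the
  solver's scope; it handles rectangular sections only.
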