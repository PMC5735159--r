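---
title: "Membrane permeation thermodynamics: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Membrane permeation thermodynamics: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memperm)
```

This vignette is the package's own account of the science it implements:
the models, their assumptions, the tunable parameters with their defaults,
the numerical choices, and what the synthetic-data generators do and do not
emulate.

## The physical picture

A titratable amphiphile near a phospholipid bilayer lives on two coupled
free-energy surfaces, one per protonation state, along the membrane normal
z (bilayer center at z = 0, bulk water at large |z|, units kcal/mol and
Angstrom throughout; R = 1.9872e-3 kcal/(mol K)). The neutral base
typically pays a modest interfacial barrier and is stabilized in the
hydrophobic core; the protonated acid binds the anionic headgroups but
faces a large desolvation barrier at the center. Everything the package
computes — entropy decompositions, pKa shifts, partition coefficients —
follows from these two curves plus equilibrium statistical mechanics.

## Free-energy reconstruction (WHAM)

`wham_reconstruct()` implements binned WHAM over harmonic umbrella windows.
The self-consistent equations are solved by first minimizing the convex
WHAM negative log-likelihood in the window constants (BFGS with analytic
gradient, one constant pinned to fix the gauge) and then polishing with
plain self-consistent iteration until the largest change in any window
constant is below `tol` (default 1e-7 kcal/mol). The hybrid matters: plain
iteration alone approaches the fixed point geometrically with a rate near 1
for long window chains and cannot reach tight tolerances in reasonable
time.

Numerical choices:

* The bias factor per (bin, window) is the Simpson average over the bin,
  not the bin-center value. Center-point evaluation leaves a systematic
  bowl of order 0.05-0.1 kcal/mol for narrow windows on 0.5-Angstrom bins.
* Bins with zero pooled counts are reported as `NA`, never interpolated.
* The reference is the mean over the outermost 5 Angstrom at each grid end
  ("bulk water"), applied by `rereference()`.
* Per-bin standard errors are Poisson counting errors propagated through
  the log, kT/sqrt(pooled counts). These deliberately exclude the
  uncertainty of stitching window constants together, which accumulates
  like a random walk along the window chain; `stderr_method = "bootstrap"`
  (10-block bootstrap within each window, full re-solve per replicate)
  captures both and is the right scale for "is this profile flat"
  questions.

The estimator is validated three ways: a single zero-bias window must equal
Boltzmann inversion bin by bin (it does, to 1e-10); two-window sets must
sit at the optimum of a brute-force likelihood grid search (to 1e-3); and
generate-and-recover from a known double-Gaussian surface with 24 windows
(k = 2.5 kcal/mol/A^2, spacing 1.5 A, 1e4 samples each) must come back
within 0.15 kcal/mol RMS on bins with at least 100 pooled counts.

## Entropy / internal-energy decomposition

With the NVT identity dA = -S dT - p dV + mu dN (the p dV and mu dN terms
never arise: volume and composition are fixed), profiles at T - dT, T,
T + dT give

    -T dS(z) = T/(2 dT) [A(z, T + dT) - A(z, T - dT)],  dU = A + T dS.

Defaults T = 310 K, dT = 5 K (profile triplet 305/310/315 K; the prefactor
is then T/(2 dT) = 31). The central difference is exact for any profile
family linear in T — which the synthetic family A = U0 - T S0 is by
construction, making the zero-error case testable — and has O(dT^2)
truncation error otherwise. A subtlety the tests encode: the truncation
error vanishes for quadratic-in-T families too (central differences are
exact through second order), so the convergence-order test uses a cubic
family, the lowest order with a nonzero dT^2 term.

`compensation_fit()` regresses dU on -T dS (ordinary least squares). That
axis ordering is what makes "slope -1" mean exact compensation; slopes
below -1 indicate internal-energy-driven behavior, slopes between -1 and 0
an entropy-led pathway.

## Thermodynamic-cycle pKa

Closing the deprotonation cycle between bulk water and depth z with the
transfer free energies of both species gives

    pKa(z) = pKa_water + [dA_neutral(z) - dA_charged(z)] / (ln 10 * R * T).

Conventions: "charged" is the protonated acid AH+ (for an aminic base most
molecules in water are protonated), both profiles must be referenced to
bulk water, and T defaults to the profiles' temperature. With the
literature inputs for a borate-amine modulator — neutral center value
-1 kcal/mol, charged +8 kcal/mol, aqueous pKa 9.6, T = 310 K — the cycle
yields an interior pKa of 3.26, i.e. a shift of -9/(ln 10 * R * 310) =
-6.34 units. `find_pka_crossing()` locates protonation-state switches by
linear interpolation between grid nodes; no smoothing, so the result is
reproducible and assumption-free.

## Partitioning and the four-region model

`detect_regions()` encodes the standard four-region reading of a hydrated
bilayer density profile: b12 where water and lipid densities cross
("comparable"), b23 where water falls below 1% of its bulk mean, b34 where
the tail density falls to half its in-leaflet maximum on the way to the
center (the high/low-density tail split has no standard threshold;
half-maximum is the package's choice). Boundaries are found per leaflet and
averaged.

logP uses concentrations, not raw counts: the lipid compartment (regions
2-4, |z| <= b12) and water compartment have different volumes, so the count
ratio is normalized by compartment lengths (the x-y cross-section cancels).
The trajectory estimator accumulates running frame averages to each
checkpoint, mirroring how a converging partition run is monitored, with
block-averaged standard errors: blocks are groups of walkers when the
ensemble has enough independent particles (they are independent by
construction in the synthetic generator), else time blocks. The PMF
integral logP = log10[(int_lip e^(-A/kT) dz / L_lip) / (int_wat ... /
L_wat)] serves as the equilibrium oracle the trajectory estimate must
approach.

## Brownian dynamics generator

`gen_langevin_traj()` integrates overdamped motion with Euler-Maruyama:
z' = z - beta D A'(z) dt + sqrt(2 D dt) xi, reflective walls at the box z
edges, free periodic diffusion in x-y. Stability is enforced at run time:
the worst-case drift per step beta D max|A'| dt must stay below the PMF
grid spacing. Walkers start from independent Boltzmann draws, so the
recorded ensemble is stationary from the first frame and a wide ensemble of
short trajectories decorrelates a fixed particle-step budget far faster
than one long chain. Defaults: D = 50 A^2/ns (small-molecule scale), dt =
2e-4 ns; the consistency tests use D = 100 A^2/ns and dt = 2e-3 ns, where
the residual Euler occupancy bias is below the statistical resolution of
1e6 particle-steps (total-variation distance to exp(-A/kT) about 0.01-0.015
at 50 bins).

Umbrella samples are drawn by inverse CDF on a 48-fold refined grid with a
trapezoid cumulative sum. Both refinements are load-bearing: a rectangle
rule shifts every sample by half a fine-grid step, which WHAM integrates
into a spurious linear tilt of the whole profile, and a coarse grid smears
each window's variance enough to curve a flat reconstruction.

## Field and degrees-of-freedom diagnostics

`local_field_profile()` computes the z component of the Coulomb field at
probe points by direct sum with x-y minimum image and a real-space cutoff
(default 10 A; no Ewald — the observable is a local fluctuation profile and
truncation keeps desk-scale systems exactly testable). "Oscillation
amplitude" is defined as the standard deviation over frames of the
slab-mean field; the mean itself stays near zero by charge symmetry. The
slab generator places +/- pairs with a 2-4 A standoff from the probe plane
so the local amplitude, proportional to the slab's layout amplitude,
dominates over leakage from neighboring slabs; a 7:1 water:core amplitude
layout then reproduces a 6-8x oscillation ratio.

The degree-of-freedom summaries are deliberately simple estimators:
occupancy-grid footprint area (robust to outliers, unlike a convex hull),
per-depth histograms of cos(theta) between dipole and membrane normal,
dipole-magnitude moments per depth, and the two-ring insertion offset
dz = ring1_z - ring2_z per depth, each normalized to unit mass per
populated bin. The dipole of a point-charge set is mu = sum q_i (r_i -
r_ref), converted at 4.8032 D per e*A; for net-charged sets the reference
must be given (center of mass by convention — the choice is exposed because
no universal convention exists).

## Analog survey

SASA uses the rolling-probe test-point construction with a deterministic
golden-section spiral (960 points by default; the isolated-sphere value is
then exact and runs are reproducible). Points landing exactly on a
neighbor's accessible sphere count as buried, which makes coincident
duplicate atoms fully buried rather than half-exposed.

Density-peak clustering follows the decision-graph algorithm: cutoff
density rho (d_c default: 2nd percentile of pairwise distances), separation
delta to the nearest denser point, centers by gamma = rho * delta. Ties in
rho are broken by index and documented as such — which is also why exact
reorder invariance only holds as a partition on cleanly separated data. The
number of centers is auto-selected by the largest multiplicative gap in the
sorted gamma sequence (absolute gaps are dominated by the single densest
point) and can be overridden; the analog survey fixes 4 groups. Features
are z-scored first: SASA (A^2), dipole (D) and logP live on incomparable
scales. PCA is delegated to `stats::prcomp` on the correlation matrix with
a deterministic sign convention (largest-magnitude loading positive).

## What the synthetic data do and do not emulate

The generators reproduce the statistical structure the analysis consumes:
PMF families exactly linear in T (sums of Gaussians for U0 and S0, both
vanishing in bulk water), Boltzmann-consistent trajectories, exact biased
window densities, electroneutral slab charge fluctuations, planted analog
groups separated by at least 3 pooled SD in SASA. The neutral/charged
presets are calibrated at 310 K to the qualitative template of a weak-base
permeant: a ~2 kcal/mol neutral interfacial barrier near |z| = 22 A with an
entropy-stabilized -1 kcal/mol central plateau, and a charged profile with
a -2 kcal/mol headgroup well near |z| = 18 A and an 8 kcal/mol central
barrier narrow enough (width 4 A) that the protonation switch falls a few
Angstrom off-center. The base temperature 310 K is an assumption (the
flanking 305/315 K pair is the stated condition; the base is not printed
anywhere authoritative), as is harmonic-window umbrella sampling.

What they do not emulate: atomistic structure (no lipids, no water
molecules, no force field), membrane deformation by charged permeants,
polarization response, correlated window samples (windows are i.i.d. draws,
so WHAM error bars on real, autocorrelated MD data would be larger), or
quantum-mechanical dipoles (conformer dipoles come from fixed point
charges). Passing tests therefore demonstrate the correctness of the
estimators under their stated assumptions, not the accuracy of any MD
force field.

## Problem sizes

The test suite runs at desk scale by design: 1e6 particle-steps for the
sampling checks (10^4 walkers x 100 steps), 24-49 windows x 5e3-1e4
umbrella samples for WHAM, 120-200 frames x 400 charges for field
profiles, 54-record analog tables. The demo pipeline
(`run_demo_pipeline()`) completes in a few seconds and writes only
delimited text, byte-reproducible from one seed through a fixed per-stage
seed-splitting rule.

## Known limitations

* WHAM assumes uncorrelated window samples; no autocorrelation correction
  is offered beyond the block bootstrap.
* The Euler-Maruyama integrator has O(dt) occupancy bias; it is controlled,
  not eliminated, by the stability bound.
* pKa profiles inherit the PMF reference convention; profiles referenced to
  anything other than bulk water are rejected rather than silently shifted.
* The field profile is a truncated direct sum; absolute dielectric
  constants are out of scope, only the fluctuation profile and its ratios
  are meaningful.
* Density-peak label assignment depends on documented index tie-breaks for
  marginal configurations.
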