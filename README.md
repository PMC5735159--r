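# memperm

Thermodynamic analysis of membrane permeation for titratable, drug-like
molecules, in R.

Whether a weak base crosses a lipid bilayer depends on a chain of coupled
quantities: the potential of mean force A(z) of each protonation state along
the membrane normal z, the entropy/internal-energy split of that free
energy, the position-dependent pKa that decides which state dominates at
each depth, and the water/bilayer partition coefficient (logP) the whole
profile implies. `memperm` implements this chain as a tested pipeline,
together with the supporting diagnostics (local electric-field fluctuation
profiles, translational/orientational/conformational degree-of-freedom
summaries) and a descriptor survey for analog series (density-peak
clustering, PCA, size-logP correlation). Raw MD trajectories are not
required: a synthetic-data module generates Boltzmann-consistent inputs —
PMF families, overdamped Langevin trajectories, umbrella-window samples,
slab-structured charge snapshots, analog tables — so every stage is testable
end to end.

## The core quantities

With the bilayer center at z = 0, bulk water as the free-energy reference
and R = 1.9872e-3 kcal/(mol K):

* **WHAM.** Umbrella windows with harmonic biases k_i/2 (z − z_i)² are
  combined by the weighted-histogram estimator: the unbiased bin probability
  is p_b = Σ_i h_ib / Σ_i n_i exp(f_i/kT) c_ib with self-consistent window
  constants f_i, solved here by quasi-Newton minimization of the (convex)
  WHAM likelihood followed by self-consistent polishing to 1e-7 kcal/mol;
  A(z) = −kT log p(z).
* **Entropy decomposition.** In the NVT ensemble dA = −S dT − p dV + μ dN,
  so with profiles at T ± ΔT: −TΔS(z) = T/(2ΔT) · [ΔA_{T+ΔT}(z) −
  ΔA_{T−ΔT}(z)] and ΔU = ΔA + TΔS. The central difference is exact for
  profiles linear in T and O(ΔT²) otherwise. Entropy–enthalpy compensation
  is quantified by regressing ΔU on −TΔS.
* **pKa(z).** The deprotonation thermodynamic cycle between bulk water and
  depth z gives pKa(z) = pKa_water + [ΔA_neutral(z) − ΔA_charged(z)] /
  (ln 10 · R T), with "charged" the protonated acid.
* **logP.** The equilibrium definition log10 of the lipid/water
  concentration ratio, computed two ways: from trajectory occupancies of the
  four-region model (regions 2–4 = lipid phase) with block-averaged errors,
  and from the Boltzmann integral of the PMF as an internal consistency
  oracle.

## Worked example

```r
library(memperm)
s <- run_demo_pipeline(seed = 1, out_dir = "demo_out")
str(s)
#> $ wham_rms_kcal         : num 0.0612
#> $ compensation_slope    : num -0.378
#> $ pka_center            : num 3.26
#> $ pka_crossings         : num [1:2] -5.69 5.69
#> $ logp_trajectory       : num 0.275
#> $ logp_pmf              : num 0.359
#> $ field_water_core_ratio: num 6.31
#> $ n_clusters            : int 4
#> $ sasa_logp_r           : num 0.916
#> $ pc1_top_loading       : chr "sasa"
```

Reading the output: the WHAM reconstruction of the neutral-species PMF from
49 umbrella windows deviates from the analytic truth by 0.061 kcal/mol RMS;
the compensation regression over |z| ≤ 30 Å has slope −0.38 (entropy-led,
between 0 and −1); the thermodynamic cycle puts the interior pKa at 3.26 —
far below the aqueous 9.6, so the neutral form dominates in the core — and
the pKa = 7 switch sits at |z| ≈ 5.7 Å; the trajectory logP estimate
0.275 ± 0.044 brackets the PMF-integral oracle 0.359 at desk-scale
statistics; the electric-field oscillation amplitude in the water slabs is
6.3× the core value; and the 54-record analog table resolves into 4
size-dominated clusters with SASA–logP correlation r = 0.92 and PC1 carried
by SASA. All intermediate tables (PMF, decomposition, pKa, logP series,
field profile, cluster/PCA inputs) are written to `out_dir` as delimited
text; re-running with the same seed reproduces every file byte for byte.

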