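# glycotraj

Post-processing of molecular-dynamics ensembles of glycolipid ligands bound
to receptor proteins — contacts, interaction energetics, binding free
energies and NMR consistency — for systems like synthetic lipid A mimetics
with a rigid βGlcN(1↔1)αGlcN diglucosamine backbone bound to the
lipopolysaccharide co-receptor MD-2.

The package is aimed at structural modellers who already have trajectories
(or want fully synthetic, ground-truth test systems) and need the standard
post-hoc numbers:

* **Hydrogen bonds**: donor–acceptor distance < 0.35 nm *and* D–H–A angle
  > 150° (strict, distance from the donor heavy atom).
* **Salt bridges**: phosphate P to Arg Cζ / Lys Nζ within 0.7 nm
  (inclusive).
* **LIE binding free energy**: ΔG_bind = α Δ⟨V_vdw⟩ + β Δ⟨V_el⟩ with
  α = 0.18, β = 0.09, where Δ is bound minus unbound and the ligand–
  surrounding energies use 12-6 LJ + Coulomb under the cubic-in-r² switch
  between 1.0 and 1.2 nm.  Poses combine as
  −RT ln[(1/N) Σᵢ exp(−ΔGᵢ/RT)], and ΔG = RT ln K_d maps free-energy gaps
  to fold-differences in affinity.
* **NOE consistency**: ensemble distances reduced as ⟨r⁻³⟩⁻¹/³ and compared
  against NMR upper bounds; anything at or below the bound is allowed, the
  excess above it is the violation.
* **Block averaging** everywhere a trajectory statistic needs an error bar.
* A **conformer builder** for the β,α(1↔1) linkage: idealized ⁴C₁ chairs
  joined with controllable glycosidic torsions, whose double exo-anomeric
  well (φα ≈ +60°, φβ ≈ −60°) reproduces the short H1α–H1β contact that
  makes this linkage rigid.

## Worked example

```r
library(glycotraj)

# a synthetic receptor-ligand complex with 7 planted H-bonds and 4 salt
# bridges (plus decoys that miss exactly one criterion each)
toy <- make_toy_complex(toy_system_spec(seed = 42))
contact_timeseries(toy$trajectory, toy$topology, "hbond")
#> ContactTimeSeries: mean 7.000 +/- 0.000 over 5 frames, 7 partners
contact_timeseries(toy$trajectory, toy$topology, "salt_bridge")
#> ContactTimeSeries: mean 4.000 +/- 0.000 over 5 frames, 4 partners

# LIE on correlated synthetic energy series with known ground truth (-2.25)
es <- make_energy_series(energy_series_spec(seed = 42))
lie_free_energy(es$bound, es$unbound)
#> LIEResult: dG_bind = -2.255 +/- 0.023 kcal/mol (Kd ratio 0.0222)
dissociation_ratio(-2.255, -2.255 + 1.7741)   # a gap of RT ln 20 at 298 K
#> [1] 20.00238

# NOE check of the double exo-anomeric syn/syn ensemble
ens <- sample_ensemble(center = c(60, -60), spread_deg = 15, n = 200,
                       seed = 42)
rest <- data.frame(atom_a = c("AGN.H1", "AGN.H5"),
                   atom_b = c("BGN.H1", "BGN.H2"),
                   upper_bound_nm = c(0.25, 0.35))
violation_report(ens$trajectory, ens$topology, rest)
#>   atom_a atom_b upper_bound_nm effective_nm  error_nm mean_nm violation_nm
#> 1 AGN.H1 BGN.H1           0.25       0.2514 0.0006751  0.2537     0.001372
#> 2 AGN.H5 BGN.H2           0.35       0.3401 0.0028898  0.3496     0.000000
#> max violation: 0.0014 nm; 1 of 2 restraints violated
```

Reading the output: the planted contact counts are recovered exactly with
zero block error (the generator guarantees jitter cannot cross the
criteria margins); the LIE estimate matches the closed-form ground truth
within its propagated error; and the syn/syn torsion ensemble sits
essentially on the NMR bounds — H5–H2′ comfortably satisfied, H1–H1′ a
~0.001 nm overshoot that is an artefact of the idealized ring geometry
(see the methods vignette for the quantitative analysis).

## Command line

```sh
Rscript inst/cli/glycotraj synth --out fixtures/          # write demo inputs
Rscript inst/cli/glycotraj contacts --config run.json --out out/
Rscript inst/cli/glycotraj lie      --config run.json --out out/
Rscript inst/cli/glycotraj noe      --config run.json --out out/ --seed 1
```

Exit codes: 0 success, 2 configuration error, 3 data error.  Configs are
declarative JSON; every numeric default equals the standard methodology
values, so an override-free run reproduces the reference protocol.

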