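---
title: "Methods: contact, energy and NOE analysis of glycolipid-receptor ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contact, energy and NOE analysis of glycolipid-receptor ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycotraj)
```

## Scope and model

`glycotraj` post-processes molecular-dynamics (MD) ensembles of glycolipid
ligands bound to receptor proteins — the motivating system being synthetic
lipid A mimetics with a rigid βGlcN(1↔1)αGlcN diglucosamine backbone bound in
the hydrophobic pocket of the lipopolysaccharide co-receptor MD-2.  It does
not run MD; it consumes structures, coordinate frames, nonbonded parameters
and NMR-derived distance bounds, and produces three report surfaces:

1. **Contacts** — per-frame hydrogen-bond and salt-bridge counts with
   block-averaged errors, per-partner occupancies, and a marker-residue RMSD
   after a rotational fit (e.g. the Phe126 loop of MD-2, whose displacement
   correlates with agonist versus antagonist behaviour).
2. **Energetics** — ligand–surrounding van der Waals and electrostatic
   interaction energies and LIE binding free energies with pose combination
   and dissociation-constant ratios.
3. **NOE consistency** — `⟨r⁻³⟩⁻¹/³` effective inter-proton distances
   compared against NMR upper bounds.

All internal lengths are nm (PDB I/O converts Å at the boundary), energies
kcal/mol, public angles degrees.  Atom indices are R-native 1-based in the
API and in all file output.

## Contact criteria

A donor–hydrogen–acceptor triple is a hydrogen bond iff the donor–acceptor
distance is *strictly* below 0.35 nm **and** the D–H–A angle is *strictly*
above 150°; the distance is measured from the donor heavy atom, not the
hydrogen.  Acceptors are all N/O atoms; donor heavies are N/O bonded to at
least one hydrogen.  A phosphate salt bridge pairs a central phosphorus with
Arg Cζ or Lys Nζ within 0.7 nm, *inclusive* — the cut-off phrasing is
ambiguous, so the inclusive reading is pinned by a boundary test.  Detectors
raise an error when the donor/acceptor (or anion/cation) scope is empty, so
"no contacts" is never silently confused with "nothing to detect".

No periodic-boundary minimum-image correction is applied: the analysis
assumes whole, imaged complexes.  This is correct for a ligand buried in a
receptor pocket and for every synthetic system generated here, and it is the
single biggest caveat when importing frames from an engine without prior
re-imaging.

## Nonbonded model and LIE

Pair energies combine a 12-6 Lennard-Jones term (Lorentz–Berthelot:
arithmetic `rmin`, geometric ε) with a Coulomb term
(k = 33.2063711 kcal·nm/(mol·e²)), both multiplied by the cubic-in-r²
switching factor

S(r) = (c² − r²)² (c² + 2r² − 3s²) / (c² − s²)³,  s = 1.0 nm, c = 1.2 nm,

with S = 1 below s and S = 0 above c.  The engine that produced the
trajectories treats long-range electrostatics with PME; this evaluator
deliberately applies one documented, continuous real-space form to both
terms, which is a known model difference (the reciprocal-space part of the
original electrostatics is not reproduced).  Energies are identically zero
beyond the cut-off.

LIE estimates the binding free energy from ensemble averages only:

ΔG_bind = α Δ⟨V_vdw⟩ + β Δ⟨V_el⟩,  α = 0.18, β = 0.09,

where Δ is bound minus unbound.  The unbound reference (ligand at an
octane–water interface in the motivating study) is always an *input* series;
it is never re-simulated.  Errors propagate in quadrature from the four
block-average errors with α/β weights.  Poses combine with equal priors as
ΔG = −RT ln[(1/N) Σ exp(−ΔG_i/RT)]; the 1/N normalization makes equal poses
return their common value, and the combined value lies in
[min ΔG_i, min ΔG_i + RT ln N].  (A sum without 1/N — a "more bound states"
convention — would instead lie below the best pose; the normalized mean was
chosen because the equal-poses identity is the behaviour the reports rely
on.)  Kd fold-ratios follow from ΔG = RT ln Kd; only ratios are reported,
since the standard-state convention behind any absolute Kd is not specified
by the estimator.

## Block averaging

All trajectory statistics carry errors from contiguous-block averaging:
split the series into `n_blocks` near-equal blocks (remainder to the leading
blocks), error = sd(block means)/√n_blocks.  The default is 5 blocks,
recorded in every report.  Two calibration facts worth knowing:

* For iid data the estimate is distributed as σ/√N·√(χ²ₖ₋₁/(k−1)); with 5
  blocks the probability of landing within a factor 2 of σ/√N is only 0.907,
  with 10 blocks 0.987.  Tests assert the χ²-exact rates; the factor-2
  acceptance check is run at 10 blocks for that reason.
* For strongly autocorrelated series (AR(1), φ = 0.9) the block error
  correctly exceeds the naive iid standard error.

Flyvbjerg–Petersen plateau detection is a documented upgrade path, not
implemented.

## NOE effective distances

NOE intensities of slowly tumbling molecules scale as r⁻³ (distance series
are reduced as `⟨r⁻³⟩⁻¹/³`), which weights short excursions more than the
arithmetic mean; both values are reported side by side.  NMR distances are
upper bounds: violation = max(0, effective − bound), equality allowed.
Errors propagate from the block error of the r⁻³ series by the delta method
(d/dm m^(−1/3) = −m^(−4/3)/3).

## The disaccharide builder

The conformational model of the β,α(1↔1) linkage is a backbone-only
disaccharide: two D-glucosamine rings in idealized ⁴C₁ chairs (C–C
0.1526 nm, C–O 0.143 nm, C–H 0.109 nm, ring angles 111° with ring torsions
alternating ±55°, substituents on tetrahedral directions), joined
C1–O1–C1′ with a 117° C–O–C angle and user-controlled torsions
φα = tors(O5α, C1α, O1, C1β) and φβ = tors(C1α, O1, C1β, O5β).  Acyl chains
and phosphates are replaced by single-atom caps: NMR shows the backbone
conformation of these trehalose-type linkages is independent of the
substituents, so the bare scaffold carries all the inter-proton distance
information the NOE comparison needs.

Stereochemistry was pinned against force-field-minimized methyl
α/β-D-glucopyranoside references during development: the α-anomeric centre
has O1 axial (improper torsion O1–O5–C1–C2 ≈ −120°), the β centre O1
equatorial (≈ +120°), and the exo-anomeric (gauche) wells sit at
φα ≈ +60°, φβ ≈ −60° — the "double exo-anomeric" syn/syn geometry that
makes the (1↔1) linkage rigid and nearly co-planar.
`classify_conformation()` labels a torsion pair syn-exo/syn-exo iff both
torsions are within 40° of their well centres (strict edges).

The ensemble sampler draws torsion pairs independently from Gaussians about
a well centre with a default spread of 15°, mimicking thermal libration;
each pair is rebuilt rigidly.  What the sampler deliberately does **not**
emulate: ring-pucker dynamics, bond-length/angle fluctuations, correlated
φα/φβ motion, and excursions to minor wells.  A green NOE test on this
ensemble therefore establishes that the *torsion-well model* is consistent
with the bounds, not that a force-field trajectory would be.

### A known 0.002 nm tension at the H1–H1′ bound

At the well centre the idealized geometry gives d(H1α,H1β) = 0.2497 nm and
d(H5α,H2β) = 0.3496 nm — inside the experimental 0.23–0.25 nm and
≈0.35 nm ranges.  Libration at 15° spread pushes the ensemble-effective
H1–H1′ value to ≈ 0.2516 nm, 0.0016 nm above the 0.25 nm bound, so the
strict "≤ 0.25 nm" acceptance assertion fails by that margin and is left
failing rather than re-tuned.  The overshoot is an artefact of the
idealization: an MMFF-relaxed dimer constrained to the same (+60°, −60°)
torsions gives 0.238 nm, because real anomeric O–C–O angles (≈112–114°) and
the real glycosidic C–O–C angle (≈115°) are narrower than the idealized
tetrahedral/117° values.  For context, the motivating study's own MD
ensembles report NOE violations up to 0.018 nm, an order of magnitude above
this margin.

## Synthetic ground-truth systems

`make_toy_complex()` plants H-bond triads (d ≤ 0.33 nm, angle ≥ 170°) and
salt bridges (0.60–0.68 nm) at stations 3 nm apart, with decoys violating
exactly one criterion each (0.37 nm distance, or 140° angle) and inert
carbon noise atoms.  Per-frame Gaussian jitter is clamped at 3σ and the
generator refuses jitter that could cross the 0.02 nm margins, so detection
counts are *exact* in every frame, making count-recovery tests sharp rather
than probabilistic.  A widely separated calibration donor/acceptor pair and
phosphate/guanidinium pair are always present so that zero-contact systems
remain analyzable (the detectors' empty-scope error stays reserved for
genuinely empty topologies).  `make_energy_series()` produces AR(1) series
(default autocorrelation 0.5, sd 2 kcal/mol, 2000 frames) so block
averaging is exercised on correlated, MD-like data; the implied ΔG is known
in closed form from the prescribed means.

## Numerical choices and edge cases

* Strict inequalities for H-bonds, inclusive for salt bridges; both pinned
  by boundary fixtures evaluated at the exactly-realized threshold value to
  avoid one-ulp flakiness.
* Kabsch superposition excludes reflections by sign-correcting the smallest
  singular vector; collinear or <3-atom fits are errors.  The marker-residue
  RMSD is measured with the fit transform, never refit, and defaults to
  heavy atoms (configurable via the selection expression).
* Dihedrals follow the IUPAC sign convention, range (−180°, 180°];
  degenerate (collinear) geometry is an error.
* Single-frame series report error 0 with a warning — blocking is
  impossible, and pretending otherwise would fabricate precision.
* Trajectory frame times default to 0, 1, 2, … ps when the source format
  carries none; the equilibration discard removes frames with
  `time < discard_initial`.

## Known limitations

* No PME/Ewald, no free-energy perturbation, no fitting of α/β.
* No water-mediated bridges, contact-lifetime analysis, or
  intense/moderate occupancy labels (partners are ranked; labelling is left
  to the user because no threshold is defined).
* No full relaxation-matrix NOE back-calculation; only distance bounds.
* The builder does not minimize energies; clashes warn but still return.
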