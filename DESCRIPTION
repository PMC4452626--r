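Package: glycotraj
Title: Contact, Energy and NOE Analysis of Glycolipid-Receptor MD Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Post-processing of molecular-dynamics ensembles of glycolipid
    ligands bound to receptor proteins such as the lipopolysaccharide
    co-receptor MD-2.  Detects hydrogen bonds and phosphate salt bridges with
    geometric criteria, evaluates ligand-surrounding Lennard-Jones and Coulomb
    interaction energies with a smooth 1.0-1.2 nm switching scheme, estimates
    binding free energies by the linear interaction energy (LIE) method with
    Boltzmann pose combination and dissociation-constant ratios, compares
    r^-3-weighted effective inter-proton distances against NOE upper bounds,
    and models the double exo-anomeric conformation of the beta,alpha(1<->1)
    diglucosamine linkage with an idealized chair-geometry disaccharide
    builder and torsion sampler.  Block averaging supplies uncertainty
    estimates for all trajectory statistics.  Synthetic-system generators with
    known ground truth make the whole pipeline testable without an MD engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
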