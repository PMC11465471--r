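Package: gbion
Title: Implicit-Solvent, Explicit-Ion Generalized Born Model for
    Polyelectrolyte Ion Atmospheres
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Energy model and desk-scale simulator for explicit ions in an
    implicit (generalized Born) solvent. Implements pairwise Hawkins-Cramer-
    Truhlar effective Born radii with analytic gradients, a topology-class
    generalization of the Still pair energy in which each solute/cation/anion
    pair class carries its own exponent coefficient gamma(a,b) and internal
    dielectric eps_in(a,b), Lennard-Jones and flat-bottom spherical restraint
    terms, BAOAB Langevin dynamics and a Metropolis Monte Carlo equilibrium
    sampler. Includes SLTCAP ion-count setup arithmetic, Manning condensation
    reference values, an idealized B-DNA phosphate-lattice fixture generator,
    cylindrical/spherical ion-distribution analysis (association counts,
    charge-neutralization degree, potentials of mean force), PDB and XYZ
    trajectory input/output, and a small command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
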