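---
title: "An implicit-solvent, explicit-ion generalized Born model: theory, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An implicit-solvent, explicit-ion generalized Born model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbion)
```

## The model

The ion atmosphere around a highly charged biomolecule — the cloud of
enriched counterions and depleted co-ions — controls much of the molecule's
energetics. Fully explicit solvent resolves it at great cost; the canonical
generalized Born (GB) implicit solvent replaces it with a mean-field
continuum and cannot describe ion correlation or multivalent condensation at
all. This package implements the intermediate regime: *explicit* mobile ions
moving in an *implicit* (dielectric continuum) solvent.

The electrostatic solvation energy of a particle collection is built from
the Still pair function. For particles $i$, $j$ at distance $d_{ij}$ with
effective Born radii $R_i$, $R_j$,

$$ f_{ij} = \sqrt{d_{ij}^2 + R_i R_j
   \exp\!\left(-\frac{d_{ij}^2}{\gamma(a,b)\, R_i R_j}\right)},$$

and the pair interaction energy is

$$ E_{ij} = k_e\left[ \frac{q_i q_j}{\epsilon_{in}(a,b)\, d_{ij}}
   - \left(\frac{1}{\epsilon_{in}(a,b)} - \frac{1}{\epsilon_{out}}\right)
   \frac{q_i q_j}{f_{ij}} \right], $$

where $(a,b)$ is the unordered pair of *topology classes* of the two
particles — solute, cation, or anion. The two class-pair coefficients are
the whole point of the model:

* $\gamma(a,b)$ generalizes the canonical Still exponent (4). Sending
  $\gamma \to 0$ makes $f \to d$ and the whole pair term collapse to
  Coulomb's law screened by the solvent, $k_e q_i q_j / (\epsilon_{out} d)$
  — the appropriate description of two *solvent-separated* charges, which
  the canonical GB (designed for one connected solute) gets wrong.
* $\epsilon_{in}(a,b)$ interpolates the same way: raising it from 1 to
  $\epsilon_{out}$ moves the pair energy from canonical GB to
  Coulomb-in-water at all distances.

The solute–solute entry is pinned to $\gamma = 4$,
$\epsilon_{in} = 1$, so a system without ions *is* canonical GB — not
approximately, but bit-for-bit, which the test suite asserts against an
independent plain-R evaluation of the Still equations. Born self-energies
use each particle's diagonal class entry,
$-\tfrac{k_e}{2}(1/\epsilon_{in}(a,a) - 1/\epsilon_{out})\, q_i^2 / R_i$.
Whether the class coefficients should touch the self-energies at all is
genuinely open; we chose the diagonal-class convention because it is the
only one available when $i = j$, and we return to its consequences under
*Limitations*.

Effective Born radii come from Hawkins–Cramer–Truhlar pairwise descreening:
$R_i^{-1} = \rho_i^{-1} - \sum_j I(d_{ij};\rho_i,\rho_j)$ with the analytic
two-sphere integral $I$, no neck or rescaling corrections. This is the
simplest member of the analytic-GB family; its known bias (overlapping
descreeners are double-counted) is bounded in the tests by a quadrature
oracle that integrates $r^{-4}$ over the *union* of neighbour spheres
(exactly in the radial direction, Fibonacci quadrature over angles).
Pairwise radii stay within 5% of the oracle on random clusters and are
exact for isolated particles. Forces are the exact analytic gradient,
including the chain-rule term through $R_i(\mathbf{x})$; central finite
differences agree to $10^{-6}$ relative on 50-particle systems.

There are no periodic boundaries and no cutoff. The simulation volume is
defined instead by a flat-bottom spherical restraint: an ion beyond radius
$r_3$ from the anchor (a point, or the centre of mass of the solute) feels
$U = k\,(r - r_3)^2$, zero inside. With $k = 20$ kcal/mol/Å$^2$ thermal
excursions beyond $r_3$ are $\sim\sqrt{k_BT/k} \approx 0.17$ Å.

## Setting the salt content

Because the volume is finite and small, the number of ions that produces a
desired *bulk* concentration is not simply $c_0 V$: the solute's net charge
$Q$ partitions counter- and co-ions. With $N_0 = c_0 V_w$ (the
concentration converted at $6.02\times10^{-4}$ particles/Å$^3$ per mol/L,
$V_w$ the sphere volume minus the solute volume),

$$ N_\pm = \sqrt{N_0^2 + Q^2/4} \mp Q/2 , $$

rounded by taking the nearest integer for one species and deriving the
other from electroneutrality. `sltcap_counts()` implements this; the
package's reference checks confirm the worked cases (a $-22e$ duplex in a
40 Å sphere at 0.145 M takes 36 cations and 14 anions; the $-48e$, 25-bp
system with the explicit-water reference volume takes 104 and 56). The
solute volume defaults to 300 Å$^3$ per nucleotide; the counts are
insensitive to this estimate over roughly 5,000–17,000 Å$^3$ for the
worked example (slightly narrower than one might guess: at 4,500 Å$^3$ the
exact count 36.503 rounds up).

`manning_reference()` provides the condensation-theory reference: with
Bjerrum length $l_B = 7.1$ Å (water, 300 K, from the package constants) and
B-DNA charge spacing $b = 1.7$ Å, $\xi = 4.18$ and monovalent ions condense
$\theta = 1 - 1/(z\xi) = 76\%$ of the backbone charge (36.5 ions per 48
charges); trivalent ions, 92%.

## Sampling

Two samplers share one energy surface:

* **Langevin dynamics** (`run_simulation()`): BAOAB splitting, default time
  step 2 fs, friction 1 ps$^{-1}$ for production sampling (0.05 ps$^{-1}$
  is the gentle-thermostat protocol value for heating; we default to the
  stronger coupling because for single-bead ions the friction is a sampling
  device, not a physical claim, and faster decorrelation is what matters at
  desk scale). Masses are amu (Na 22.99, K 39.10, Cl 35.45, CoHex 161.1 as
  one rigid bead).
* **Metropolis Monte Carlo** (`mc_sample()`): single-ion displacement moves
  accepted on the *total* energy difference, radii recomputed for every
  proposal, so it samples the exact Boltzmann distribution of the same
  energy. It is the equilibrium oracle: the tests require binwise agreement
  of Langevin and MC radial profiles within their combined Monte-Carlo
  errors on 2- and 10-ion systems.

Physics checks on the samplers: a single free ion fills its restraint
sphere uniformly ($\chi^2$ over equal-volume shells); the kinetic
temperature of an interacting ion gas holds the target within 2%; a
tethered particle reproduces equipartition in position and velocity; and a
monovalent 0.145 M atmosphere around a fixed $-4e$ macroion reproduces the
Debye–Hückel profile within 15% over 10–25 Å. For that last check the
reference is the standard finite-size DH form — the screened-Coulomb
potential with Debye's distance-of-closest-approach factor
$e^{\kappa a}/(1+\kappa a)$, exponentiated into Boltzmann ion densities
($\kappa^2 = 8\pi l_B c_\infty$). The raw linearized density
$c_\infty(1 \mp z u)$ is *not* used as the reference: at 10 Å from a
$-4e$ charge $u \approx 0.8$, far outside the linear regime, while the
Boltzmann-in-DH-potential form is what a primitive-model electrolyte
actually approaches. The macroion is given a 16 Å Lennard-Jones diameter
so that the contact potential stays in the linear-response regime; a bare
point $-4e$ source condenses a couple of counterions at contact and
renormalizes its far field, which is real nonlinear physics but not what a
DH comparison should average over.

When the solute is fixed (the default for all ion-distribution runs), its
Born radii are computed once and cached; ion radii are recomputed every
step, including their descreening by the solute. The approximation error —
solute radii not responding to nearby ions — changes fixture total energies
by well under 0.5%.

## The fixture

`build_bdna()` is the no-download test bed: an ideal B-form double helix of
phosphate pseudo-beads (one $-1e$ bead per backbone phosphate, strand
radius 8.9 Å, rise 3.4 Å/bp, twist 36°/bp, strand offset 154°), with
$n_{bp}-1$ phosphates per strand (uncharged 5′ terminus) so that 25 bp
carries exactly $-48e$ and 12 bp $-22e$. Bead parameters: $\rho = 2.0$ Å,
$\sigma = 4.0$ Å. Ion Lennard-Jones parameters are single-bead stand-ins of
literature magnitude (intrinsic radii $\sigma/2$; CoHex$^{3+}$ one $+3e$
bead with $\rho = 3.1$ Å); all are per-particle overridable. What the
fixture does *not* emulate: sugar/base atoms, sequence-specific geometry, a
filled helix interior, distributed ion charge, or conformational response
of the DNA. Passing tests therefore validate the energy model, its
gradients and the sampling machinery — not force-field-quality ion binding
to real DNA.

Three parameter presets ship as flat key:value files using the AMBER-style
alias names (`gi_coef_1_p`, `intdiel_ion_1_pn`, ...): NaCl–DNA, KCl–DNA
(identical except $\epsilon_{in}(s,c) = \epsilon_{in}(c,c) = 36$ instead of
54) and CoHex–DNA. The alias mapping is $\gamma(a,b) = 4\,K_{GB}(a,b)$ and
$\epsilon_{in}(a,b) = K_\epsilon(a,b)$, which reproduces the canonical
model at $K_{GB} = K_\epsilon = 1$; the published qualitative guidance and
the printed coefficient lists are not mutually consistent under any simple
mapping, so the presets store the printed numbers verbatim and this mapping
is the documented convention.

## Analysis conventions

Ion distributions are measured in cylindrical coordinates about the ideal
helix axis (a deliberate replacement for curvilinear helicoidal coordinates
— valid because analyzed solutes are fixed ideal models). Concentrations
are histogram estimates in mol/L whose binwise integrals recover ion counts
exactly; the bulk value $c(\infty)$ is the mean over 28–30 Å (a parameter),
the slab length defaults to $n_{bp}\times3.4$ Å (85 Å for 25 bp). The
association count integrates the excess $c(r) - c(\infty)$ over the
cylinder; the neutralization degree is the mean signed ion charge within a
cylindrical cutoff (default 16 Å, the outer edge of the external binding
shell) over $|Q|$, always reported with its cutoff. PMFs are
$-\ln(c/c_\infty)$ in $k_BT$, masked where $c = 0$. The radial–angle map
bins the azimuth relative to the local phosphate phase
($\phi - 36° z/3.4$ Å) and marginalizes exactly back onto the 1D profile.
No printed formula exists for a scalar "cation affinity"; the PMF minimum
$W_{\min}$ is the closest available proxy and is labelled as such wherever
it appears.

## Numerical choices

* Units: Å, e, kcal/mol, K, amu, ps; $k_e = 332.0636$,
  $k_B = 0.0019872$, $\epsilon_{out} = 78.5$.
* $\gamma = 0$ is handled as the continuous limit $f = d$ (for $d > 0$);
  the pair function is $C^1$ across all descreening-branch boundaries,
  which is what makes the finite-difference force checks pass at
  $10^{-6}$.
* Over-descreened radii are floored at $\psi = 10^{-8}$ Å$^{-1}$ (never
  reached in the tested regimes).
* Coincident particles ($d = 0$) are rejected with both indices named.
* Degenerate salt requests clamp at zero ions and restore
  electroneutrality from the other species.
* Energy blow-ups ($|E| > 10^8$ kcal/mol by default) halt a run at the
  last stable frame with a warning rather than an error.
* Test problem sizes are desk-scale by design: sampling checks use $10^5$
  to $2\times10^6$ steps of 1–114 particles and Monte-Carlo runs of a few
  thousand sweeps, chosen once as the study conditions for this coarse
  model.

## Limitations

The single most instructive failure is the trivalent-ordering check. Under
an equal-treatment control — every interaction Coulomb/$\epsilon_{out}$,
the primitive electrolyte model — the fixture reproduces Manning's valence
ordering handsomely (16 CoHex$^{3+}$ neutralize ~94% of the 25-bp fixture
within 16 Å, versus ~69% for 48 Na$^+$; theory says 92% vs 76%). With the
published CoHex preset, however, the ordering inverts. The cause is
traceable and worth understanding: coarse-graining CoHex$^{3+}$ to a single
$+3e$ bead concentrates $q^2 = 9$ into one Born self-term, so the mutual
descreening of a condensed counterion layer costs ~11 $k_BT$ per ion in
solvation energy, while the preset's near-zero $\gamma(s,c)$ pins the
solute–ion attraction at plain Coulomb-in-water with no compensating radius
coupling. In the original atomistic setting the same coefficients act on an
ion whose charge is distributed over 25 atoms, making per-atom self-terms
an order of magnitude smaller. The lesson: the class-coefficient presets
are not transferable to single-bead ion models when the self-energy term is
active, and any quantitative multivalent work with this package should
either distribute the ion charge or treat the self-term convention as a
modelling decision to revisit. Other limitations: no nonpolar (surface
area) term (ion distributions in the source model are insensitive to it);
no salt-dependent screening inside the GB term (explicit ions are the
point); no free-solute dynamics; HCT radii without neck corrections
overestimate descreening slightly in dense clusters.
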