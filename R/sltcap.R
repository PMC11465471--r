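#' Solvent volume of a restraining-sphere simulation
#'
#' The simulation volume of a non-periodic implicit-solvent run is the
#' sphere enclosed by the flat-bottom restraint; the solvent volume is that
#' sphere minus the solute volume. Passing `v_solute = 0` gives the
#' sphere-only approximation, appropriate when the solute is small compared
#' with the sphere.
#'
#' @param r_sphere restraint radius in A (> 0).
#' @param v_solute solute volume in A^3 (default 0); must be smaller than
#'   the sphere volume.
#' @return solvent volume in A^3.
#' @examples
#' solvent_volume(40)          # 268083
#' solvent_volume(40, 7200)    # 260883
#' @export
solvent_volume <- function(r_sphere, v_solute = 0) {
  if (r_sphere <= 0) stop("sphere radius must be > 0")
  vs <- 4 / 3 * pi * r_sphere^3
  if (v_solute < 0 || v_solute >= vs)
    stop("solute volume must be in [0, sphere volume)")
  vs - v_solute
}

#' Approximate nucleic-acid solute volume
#'
#' Rough per-nucleotide volume estimator, 300 A^3 per nucleotide. The
#' resulting ion counts are insensitive to this choice over a wide range.
#'
#' @param n_nucleotides number of nucleotides (bases, both strands).
#' @param per_nucleotide volume per nucleotide in A^3.
#' @return volume in A^3.
#' @export
nucleic_volume <- function(n_nucleotides, per_nucleotide = 300) {
  n_nucleotides * per_nucleotide
}

#' SLTCAP ion counts for a target bulk concentration
#'
#' Number of cations and anions of a 1:1 salt to add around a solute of net
#' charge Q so that a finite solvent volume V_w exhibits bulk concentration
#' c0. With N0 = c0 * V_w (c0 in particles/A^3),
#' N+- = sqrt(N0^2 + Q^2/4) -+ Q/2,
#' the closed form of the salt-concentration-for-capped-systems expression.
#' Rounding takes the closest integer for one species and derives the other
#' from electroneutrality, so N+ - N- = -Q holds exactly.
#'
#' @param charge solute net charge Q in e (signed).
#' @param conc target bulk concentration c0 in mol/L.
#' @param v_w solvent volume in A^3.
#' @return list of class `salt_spec`: `n_plus`, `n_minus` (integers),
#'   `n_plus_exact`, `n_minus_exact`, `n0`, plus the inputs.
#' @examples
#' # 12-bp duplex (Q = -22) in a 40 A sphere at 0.145 M
#' sltcap_counts(-22, 0.145, solvent_volume(40, nucleic_volume(24)))
#' @export
sltcap_counts <- function(charge, conc, v_w) {
  if (v_w <= 0) stop("solvent volume must be > 0")
  if (conc < 0) stop("concentration must be >= 0")
  n0 <- conc_to_per_A3(conc) * v_w
  np <- sqrt(n0^2 + charge^2 / 4) - charge / 2
  nm <- sqrt(n0^2 + charge^2 / 4) + charge / 2
  qi <- round(charge)
  npi <- round(np)
  nmi <- npi + qi
  if (nmi < 0) { nmi <- 0; npi <- -qi }
  if (npi < 0) { npi <- 0; nmi <- qi }
  structure(list(n_plus = as.integer(npi), n_minus = as.integer(nmi),
                 n_plus_exact = np, n_minus_exact = nm, n0 = n0,
                 charge = charge, conc = conc, v_w = v_w),
            class = "salt_spec")
}

#' @export
print.salt_spec <- function(x, ...) {
  cat(sprintf("salt_spec: Q = %g e, c0 = %g M, V_w = %.0f A^3\n",
              x$charge, x$conc, x$v_w))
  cat(sprintf("  add %d cations and %d anions (exact %.3f / %.3f)\n",
              x$n_plus, x$n_minus, x$n_plus_exact, x$n_minus_exact))
  invisible(x)
}

#' Manning condensation reference values
#'
#' For a line charge with axial spacing b in a solvent with Bjerrum length
#' l_B, the dimensionless charge density is xi = l_B / b; counterions of
#' valence z condense when z*xi > 1 with condensed fraction
#' theta = 1 - 1/(z*xi). For B-DNA (b = 1.7 A) in water at 300 K
#' (l_B = 7.1 A), monovalent ions give theta = 76% and 36.5 condensed ions
#' per 48 phosphate charges.
#'
#' @param z counterion valence (>= 1).
#' @param l_b Bjerrum length in A.
#' @param b axial charge spacing in A.
#' @param n_charges number of backbone charges.
#' @return list with `xi`, `theta` (fraction), `percent`, `n_condensed`.
#' @examples
#' manning_reference()            # xi 4.18, theta 76%, 36.5 ions
#' manning_reference(z = 3)       # 92%
#' @export
manning_reference <- function(z = 1, l_b = 7.1, b = 1.7, n_charges = 48) {
  if (z < 1) stop("valence must be >= 1")
  if (b <= 0) stop("charge spacing must be > 0")
  xi <- l_b / b
  theta <- max(0, 1 - 1 / (z * xi))
  list(xi = xi, theta = theta, percent = 100 * theta,
       n_condensed = theta * n_charges)
}

#' Number of multivalent counterions that exactly neutralize a solute
#'
#' @param charge solute net charge in e (signed).
#' @param z counterion valence.
#' @return smallest integer count with total ion charge >= |charge|.
#' @examples
#' neutralizing_count(-48, 3)  # 16
#' @export
neutralizing_count <- function(charge, z) {
  if (z <= 0) stop("valence must be > 0")
  as.integer(ceiling(abs(charge) / z))
}
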