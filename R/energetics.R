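#' Generalized Born interaction distance function
#'
#' f(d) = sqrt(d^2 + R_i R_j exp(-d^2 / (gamma R_i R_j))). The canonical
#' Still form is gamma = 4. Decreasing gamma pushes the pair energy toward
#' pure Coulomb behaviour; at gamma = 0 the continuous limit f = d is used
#' (for d > 0). Always f >= d, and f(0) = sqrt(R_i R_j) for gamma > 0.
#'
#' @param d distance in A (>= 0), vectorized.
#' @param r_i,r_j effective Born radii in A (> 0).
#' @param gamma exponent coefficient (>= 0).
#' @return f in A.
#' @examples
#' f_gb(0, 2, 2, 4)     # 2
#' f_gb(1, 1, 1, 4)     # 1.33372
#' @export
f_gb <- function(d, r_i, r_j, gamma) {
  if (any(d < 0)) stop("d must be >= 0")
  if (any(r_i <= 0) || any(r_j <= 0)) stop("radii must be > 0")
  if (any(gamma < 0)) stop("gamma must be >= 0")
  n <- max(length(d), length(r_i), length(r_j), length(gamma))
  d <- rep_len(d, n); gamma <- rep_len(gamma, n)
  p <- rep_len(r_i, n) * rep_len(r_j, n)
  out <- d
  pos <- gamma > 0
  out[pos] <- sqrt(d[pos]^2 + p[pos] * exp(-d[pos]^2 / (gamma[pos] * p[pos])))
  out
}

#' Pair interaction energy with class-specific coefficients
#'
#' Total electrostatic interaction of two charges in the implicit solvent:
#' E = k_e \[ q_i q_j / (eps_in d) - (1/eps_in - 1/eps_out) q_i q_j / f \]
#' with f = [f_gb()]. Reduces exactly to the canonical Still pair term plus
#' vacuum Coulomb at gamma = 4, eps_in = 1; tends to Coulomb-in-water
#' k_e q_i q_j/(eps_out d) both as gamma -> 0 (any eps_in) and as
#' eps_in -> eps_out (any gamma).
#'
#' @param d distance in A (> 0).
#' @param q_i,q_j charges in e.
#' @param r_i,r_j effective Born radii in A.
#' @param gamma,eps_in class-pair coefficients.
#' @param eps_out solvent dielectric.
#' @return energy in kcal/mol.
#' @examples
#' gbion_pair_energy(1, 1, -1, 1, 1, gamma = 4, eps_in = 1)  # about -86.3
#' @export
gbion_pair_energy <- function(d, q_i, q_j, r_i, r_j, gamma, eps_in,
                              eps_out = 78.5) {
  if (any(d <= 0)) stop("d must be > 0 (self-energy is handled separately)")
  ke <- gbion_constants()$k_coulomb
  f <- f_gb(d, r_i, r_j, gamma)
  ke * (q_i * q_j / (eps_in * d) -
          (1 / eps_in - 1 / eps_out) * q_i * q_j / f)
}

#' Born self-energy of a particle
#'
#' -(k_e/2) (1/eps_in - 1/eps_out) q^2 / R with the particle's diagonal
#' class-pair parameters.
#'
#' @param q charge in e.
#' @param r effective Born radius in A (> 0).
#' @param eps_in diagonal-class internal dielectric.
#' @param eps_out solvent dielectric.
#' @return energy in kcal/mol.
#' @examples
#' self_energy(1, 2, 1)  # about -81.96
#' @export
self_energy <- function(q, r, eps_in, eps_out = 78.5) {
  if (any(r <= 0)) stop("radius must be > 0")
  ke <- gbion_constants()$k_coulomb
  -0.5 * ke * (1 / eps_in - 1 / eps_out) * q * q / r
}

#' Lennard-Jones 12-6 pair energy with Lorentz-Berthelot mixing
#'
#' @param d distance in A (> 0).
#' @param sigma_i,sigma_j per-particle sigma in A (arithmetic mean mixing).
#' @param eps_i,eps_j per-particle well depths in kcal/mol (geometric mean).
#' @return energy in kcal/mol.
#' @export
lj_energy <- function(d, sigma_i, sigma_j, eps_i, eps_j) {
  if (any(d <= 0)) stop("d must be > 0")
  s <- 0.5 * (sigma_i + sigma_j)
  e <- sqrt(eps_i * eps_j)
  sr6 <- (s / d)^6
  4 * e * (sr6 * sr6 - sr6)
}

# translate an R-side restraint list into the 0-based C++ layout
.cpp_restraints <- function(system, restraints, config = NULL) {
  out <- list()
  if (!is.null(restraints)) {
    stopifnot(inherits(restraints, "restraint_spec"))
    idx <- .resolve_selection(system, restraints$applies_to)
    anchor <- restraints$anchor
    if (is.character(anchor) && identical(anchor, "com:solute")) {
      grp <- which(system$class == "solute")
      if (!length(grp)) stop("no solute particles for a com:solute anchor")
      out$anchor_mode <- 1L
      out$anchor_pt <- c(0, 0, 0)
      out$anchor_grp <- grp - 1L
    } else if (is.numeric(anchor) && length(anchor) == 3) {
      out$anchor_mode <- 0L
      out$anchor_pt <- as.numeric(anchor)
      out$anchor_grp <- integer(0)
    } else if (is.numeric(anchor) && length(anchor) >= 1) {
      out$anchor_mode <- 1L
      out$anchor_pt <- c(0, 0, 0)
      out$anchor_grp <- as.integer(anchor) - 1L
    } else stop("anchor must be xyz coordinates, particle indices, or 'com:solute'")
    out$fb_idx <- idx - 1L
    out$r3 <- restraints$r3
    out$k <- restraints$k
  }
  k_pos <- if (!is.null(config)) config$k_pos else 0
  pr <- which(system$mobility == "restrained")
  if (length(pr) && k_pos > 0) {
    out$pr_idx <- pr - 1L
    out$pr_ref <- system$pos[pr, , drop = FALSE]
    out$k_pos <- k_pos
  }
  out
}

.resolve_selection <- function(system, sel) {
  if (is.null(sel) || identical(sel, "ions"))
    return(which(system$class %in% c("cation", "anion")))
  if (identical(sel, "all")) return(seq_len(n_particles(system)))
  if (identical(sel, "free")) return(which(system$mobility == "free"))
  if (is.numeric(sel)) return(as.integer(sel))
  stop("cannot resolve particle selection: ", sel)
}

#' Total energy and analytic forces of a particle system
#'
#' Sums the class-coefficient electrostic pair terms, Born self-energies,
#' Lennard-Jones interactions and restraint penalties, and returns the exact
#' negative gradient including the chain-rule contribution through the
#' position dependence of the effective Born radii. No periodic boundaries
#' and no cutoff are applied.
#'
#' @param system a [particle_system()].
#' @param pair_table a [pair_class_table()].
#' @param restraints optional [restraint_spec()] (flat-bottom sphere).
#' @param radii optional precomputed [effective_radii()]; rejected if stale.
#' @param forces compute forces as well (default TRUE).
#' @param k_pos harmonic constant (kcal/mol/A^2) for particles with
#'   mobility "restrained", anchored at their current positions; 0 disables.
#' @param skip_fixed_pairs drop interactions internal to the fixed particle
#'   set (they are constants of the motion); default FALSE so that reported
#'   energies are complete.
#' @return list of class `energy_breakdown` with components `coulomb`,
#'   `gb_cross`, `gb_self`, `lj`, `restraint`, `total` (kcal/mol), the 3x3
#'   `elec_by_class` subtotal matrix, the `radii` used, and (if requested)
#'   the n x 3 `forces` matrix in kcal/mol/A.
#' @export
total_energy_forces <- function(system, pair_table,
                                restraints = NULL, radii = NULL,
                                forces = TRUE, k_pos = 0,
                                skip_fixed_pairs = FALSE) {
  stopifnot(inherits(system, "particle_system"),
            inherits(pair_table, "pair_class_table"))
  if (!is.null(radii)) .check_radii_current(system, radii)
  n <- n_particles(system)
  fixedf <- as.integer(system$mobility == "fixed")
  res <- cpp_energy_forces(system$pos, system$charge, system$rho,
                           system$sigma, system$eps_lj,
                           .class_code(system$class),
                           pair_table$gamma, pair_table$eps_in,
                           pair_table$eps_out,
                           fixedf, skip_fixed_pairs,
                           rep(FALSE, n), numeric(0),
                           .cpp_restraints(system, restraints,
                                           list(k_pos = k_pos)),
                           system$mass, forces)
  dimnames(res$elec_by_class) <- list(.topo_classes, .topo_classes)
  class(res) <- "energy_breakdown"
  res
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat("energy breakdown (kcal/mol):\n")
  for (k in c("coulomb", "gb_cross", "gb_self", "lj", "restraint", "total"))
    cat(sprintf("  %-10s %14.6f\n", k, x[[k]]))
  invisible(x)
}

#' Canonical generalized Born electrostatic energy (reference path)
#'
#' Independent plain-R evaluation of the canonical Still model: vacuum
#' Coulomb q_i q_j / d_ij plus the Still cross term with gamma = 4 and the
#' Born self-energies, all at eps_in = 1. Used as the reduction oracle for
#' the class-coefficient model; deliberately implemented as a simple loop
#' separate from the compiled path.
#'
#' @param system a [particle_system()].
#' @param radii optional [effective_radii()] (computed if missing).
#' @param eps_out solvent dielectric.
#' @return list with `coulomb`, `gb_cross`, `gb_self` and `electrostatic`
#'   (their sum), in kcal/mol.
#' @export
canonical_gb_energy <- function(system, radii = NULL, eps_out = 78.5) {
  stopifnot(inherits(system, "particle_system"))
  if (is.null(radii)) radii <- effective_radii(system)
  .check_radii_current(system, radii)
  ke <- 332.0636
  n <- n_particles(system)
  pos <- system$pos; q <- system$charge; R <- radii$R
  ecoul <- 0; egb <- 0; eself <- 0
  if (n > 1) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        dx <- pos[i, 1] - pos[j, 1]
        dy <- pos[i, 2] - pos[j, 2]
        dz <- pos[i, 3] - pos[j, 3]
        d2 <- dx * dx + dy * dy + dz * dz
        d <- sqrt(d2)
        qq <- q[i] * q[j]
        ecoul <- ecoul + ke * qq / (1 * d)
        pref <- ke * (1 / 1 - 1 / eps_out) * qq
        P <- R[i] * R[j]
        e <- exp(-d2 / (4 * P))
        f <- sqrt(d2 + P * e)
        egb <- egb + (-pref / f)
      }
    }
  }
  for (i in 1:n) {
    prefs <- 0.5 * ke * (1 / 1 - 1 / eps_out) * q[i] * q[i]
    eself <- eself + (-prefs / R[i])
  }
  list(coulomb = ecoul, gb_cross = egb, gb_self = eself,
       electrostatic = ecoul + egb + eself)
}

#' Schematic pair-energy scan over distance
#'
#' Pair energy of two unit-Born-radius charges as a function of distance, in
#' reduced units of e^2/A (divide-by-k_e convention, Born self terms set to
#' zero), together with the pure Coulomb-in-water reference curve
#' q_i q_j / (eps_out d). Useful for visualizing how gamma and eps_in move
#' the interaction between the canonical GB and Coulomb regimes.
#'
#' @param q_i,q_j charges in e (default +1/-1).
#' @param gamma,eps_in class coefficients for the scanned pair.
#' @param d_grid distances in A.
#' @param eps_out solvent dielectric.
#' @return data.frame with columns `d`, `energy` (e^2/A), `coulomb_ref`.
#' @examples
#' head(energy_scan(gamma = 4, eps_in = 1, d_grid = c(1, 2, 4)))
#' @export
energy_scan <- function(q_i = 1, q_j = -1, gamma = 4, eps_in = 1,
                        d_grid = seq(0.5, 10, by = 0.1), eps_out = 78.5) {
  f <- f_gb(d_grid, 1, 1, gamma)
  e <- q_i * q_j / (eps_in * d_grid) -
    (1 / eps_in - 1 / eps_out) * q_i * q_j / f
  data.frame(d = d_grid, energy = e,
             coulomb_ref = q_i * q_j / (eps_out * d_grid))
}
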