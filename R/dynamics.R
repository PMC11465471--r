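#' Flat-bottom spherical restraint
#'
#' Defines the finite simulation volume of a non-periodic implicit-solvent
#' run: a particle inside radius `r3` of the anchor feels no force; beyond
#' it, a harmonic penalty U = k (r - r3)^2 pulls it back. Energy and force
#' are continuous at r3.
#'
#' @param anchor either xyz coordinates (length-3 numeric), particle indices
#'   whose mass-weighted centre is the anchor, or the string `"com:solute"`
#'   for the centre of mass of all solute particles (recomputed per step).
#' @param r3 flat-bottom radius in A (> 0).
#' @param k harmonic constant in kcal/mol/A^2 (>= 0, default 20).
#' @param applies_to particle selection: `"ions"` (default), `"free"`,
#'   `"all"`, or explicit indices.
#' @return object of class `restraint_spec`.
#' @export
restraint_spec <- function(anchor = c(0, 0, 0), r3, k = 20,
                           applies_to = "ions") {
  if (r3 <= 0) stop("r3 must be > 0")
  if (k < 0) stop("k must be >= 0")
  structure(list(anchor = anchor, r3 = r3, k = k, applies_to = applies_to),
            class = "restraint_spec")
}

#' Flat-bottom restraint energy and radial force
#'
#' @param r distance from the anchor in A (>= 0), vectorized.
#' @param r3 flat-bottom radius in A.
#' @param k harmonic constant in kcal/mol/A^2.
#' @return list with `energy` (kcal/mol) and `force` (radial component of
#'   the restoring force in kcal/mol/A; negative = pulling inward).
#' @examples
#' flat_bottom_energy(41, 40, 20)  # energy 20, force -40
#' @export
flat_bottom_energy <- function(r, r3, k) {
  if (any(r < 0)) stop("r must be >= 0")
  ex <- pmax(0, r - r3)
  list(energy = k * ex^2, force = -2 * k * ex)
}

#' Simulation configuration
#'
#' @param temperature target temperature in K.
#' @param dt_fs integration time step in fs (default 2).
#' @param friction_ps Langevin collision frequency in 1/ps. The default for
#'   production sampling here is 1/ps (fast decorrelation of the ion cloud);
#'   0.05/ps is the protocol value for gentle heating/equilibration.
#' @param n_steps number of integration steps.
#' @param seed RNG seed recorded in all outputs.
#' @param stride snapshot interval in steps.
#' @param k_pos positional-restraint constant (kcal/mol/A^2) for particles
#'   with mobility "restrained" (default 0.01).
#' @param cache_fixed_radii compute Born radii of fixed particles once at
#'   the start and hold them (documented approximation; ion radii are always
#'   recomputed each step, including their descreening by the solute).
#' @param blowup_threshold |E| above which the run halts at the last stable
#'   frame.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(temperature = 300, dt_fs = 2, friction_ps = 1,
                       n_steps = 10000, seed = 1, stride = 100,
                       k_pos = 0.01, cache_fixed_radii = TRUE,
                       blowup_threshold = 1e8) {
  if (dt_fs <= 0) stop("time step must be > 0")
  if (n_steps < 1) stop("need at least one step")
  structure(list(temperature = temperature, dt_fs = dt_fs,
                 friction_ps = friction_ps, n_steps = as.integer(n_steps),
                 seed = as.integer(seed), stride = as.integer(stride),
                 k_pos = k_pos, cache_fixed_radii = cache_fixed_radii,
                 blowup_threshold = blowup_threshold),
            class = "sim_config")
}

.make_trajectory <- function(raw, system, config, restraints, kind) {
  nf <- raw$n_frames
  frames <- raw$frames
  if (kind == "langevin") {
    energies <- as.data.frame(raw$energies)[seq_len(nf), , drop = FALSE]
  } else {
    energies <- data.frame(total = raw$energy[seq_len(nf)])
  }
  structure(list(
    frames = frames[, , seq_len(nf), drop = FALSE],
    energies = energies,
    n_frames = nf,
    system = system, config = config, restraints = restraints,
    kind = kind,
    status = if (!is.null(raw$status)) raw$status else 0L,
    acceptance = raw$acceptance,
    final_pos = raw$final_pos),
    class = "gbion_trajectory")
}

#' @export
print.gbion_trajectory <- function(x, ...) {
  cat("gbion_trajectory (", x$kind, "): ", x$n_frames, " frames of ",
      n_particles(x$system), " particles\n", sep = "")
  if (!is.null(x$acceptance)) cat("  MC acceptance:", round(x$acceptance, 3), "\n")
  if (identical(x$status, 1L)) cat("  NOTE: halted on energy blow-up\n")
  invisible(x)
}

#' Run Langevin dynamics
#'
#' BAOAB-discretized Langevin dynamics of the mobile particles under the
#' full model energy (class-coefficient electrostatics, Born self terms,
#' Lennard-Jones, flat-bottom and positional restraints). Fixed particles do
#' not move; "restrained" particles are tethered to their starting positions
#' with `config$k_pos`. Deterministic for a given seed. When the energy
#' exceeds the blow-up threshold the run halts and returns the frames
#' sampled so far, with `status = 1` and a warning.
#'
#' @param system a [particle_system()].
#' @param pair_table a [pair_class_table()].
#' @param restraints optional [restraint_spec()].
#' @param config a [sim_config()].
#' @return a `gbion_trajectory`: frame array `[particle, xyz, frame]`, a
#'   per-frame energy/temperature data.frame, and the run metadata.
#' @export
run_simulation <- function(system, pair_table, restraints = NULL, config) {
  stopifnot(inherits(system, "particle_system"),
            inherits(pair_table, "pair_class_table"),
            inherits(config, "sim_config"))
  fixedf <- as.integer(system$mobility == "fixed")
  rl <- .cpp_restraints(system, restraints, config)
  set.seed(config$seed)
  raw <- cpp_langevin(system$pos, system$charge, system$rho, system$sigma,
                      system$eps_lj, .class_code(system$class),
                      pair_table$gamma, pair_table$eps_in, pair_table$eps_out,
                      fixedf, system$mass, rl,
                      config$temperature, config$dt_fs * 1e-3,
                      config$friction_ps, config$n_steps, config$stride,
                      config$cache_fixed_radii, TRUE,
                      config$blowup_threshold)
  if (raw$status == 1L)
    warning("energy blow-up at step ", raw$last_step,
            "; returning the last stable frames", call. = FALSE)
  .make_trajectory(raw, system, config, restraints, "langevin")
}

#' Metropolis Monte Carlo equilibrium sampling
#'
#' Single-particle random displacements of the mobile particles with
#' Metropolis acceptance on the total model energy (effective Born radii are
#' recomputed for every proposal, so the sampled distribution is the exact
#' Boltzmann distribution of the same energy surface as the dynamics).
#' Serves as the equilibrium oracle for the Langevin sampler.
#'
#' @param system a [particle_system()].
#' @param pair_table a [pair_class_table()].
#' @param restraints optional [restraint_spec()].
#' @param temperature temperature in K.
#' @param n_sweeps number of sweeps (one attempted move per mobile particle
#'   per sweep).
#' @param seed RNG seed.
#' @param max_disp half-width of the uniform displacement proposal in A.
#' @param stride record a sample every `stride` sweeps.
#' @param k_pos positional-restraint constant for "restrained" particles.
#' @param cache_fixed_radii hold the Born radii of fixed particles at their
#'   initial values (same approximation as the dynamics).
#' @return a `gbion_trajectory` with `kind = "mc"` and the overall
#'   acceptance rate.
#' @export
mc_sample <- function(system, pair_table, restraints = NULL,
                      temperature = 300, n_sweeps = 1000, seed = 1,
                      max_disp = 2, stride = 1, k_pos = 0.01,
                      cache_fixed_radii = TRUE) {
  stopifnot(inherits(system, "particle_system"),
            inherits(pair_table, "pair_class_table"))
  fixedf <- as.integer(system$mobility == "fixed")
  rl <- .cpp_restraints(system, restraints, list(k_pos = k_pos))
  set.seed(seed)
  raw <- cpp_mc(system$pos, system$charge, system$rho, system$sigma,
                system$eps_lj, .class_code(system$class),
                pair_table$gamma, pair_table$eps_in, pair_table$eps_out,
                fixedf, system$mass, rl,
                temperature, as.integer(n_sweeps), max_disp,
                as.integer(stride), cache_fixed_radii)
  cfg <- list(temperature = temperature, n_sweeps = n_sweeps, seed = seed,
              max_disp = max_disp, stride = stride)
  .make_trajectory(raw, system, cfg, restraints, "mc")
}

#' Debye-Hueckel reference profile around a fixed point charge
#'
#' Ion concentration profiles predicted by Debye-Hueckel theory for a 1:1
#' electrolyte around a fixed charge Q: the electrostatic potential is the
#' linearized-Poisson-Boltzmann screened Coulomb form
#' psi(r) = k_e Q exp(kappa a) / (1 + kappa a) * exp(-kappa r) / (eps_out r)
#' for a central ion with distance of closest approach `a` (Debye's
#' finite-size form; a = 0 recovers the point-charge potential), and the
#' ion densities are the Boltzmann factors
#' c_(+/-)(r) = c_inf exp(-+ psi(r)/k_B T) in that potential, with
#' kappa^2 = 8 pi l_B c_inf.
#'
#' @param r distances from the charge in A.
#' @param charge central charge Q in e.
#' @param conc bulk 1:1 salt concentration in mol/L.
#' @param a distance of closest approach of the mobile ions to the central
#'   charge in A (default 0).
#' @param temperature temperature in K.
#' @param eps_out solvent dielectric.
#' @return data.frame with columns `r`, `kappa`, `u` (potential in k_B T per
#'   unit charge), `cation`, `anion` (mol/L).
#' @export
dh_profile <- function(r, charge, conc, a = 0, temperature = 300,
                       eps_out = 78.5) {
  cst <- gbion_constants()
  lb <- bjerrum_length(temperature, eps_out)
  c_a3 <- conc_to_per_A3(conc)
  kappa <- sqrt(8 * pi * lb * c_a3)
  u <- cst$k_coulomb * charge * exp(kappa * a) / (1 + kappa * a) *
    exp(-kappa * r) /
    (eps_out * r * cst$k_boltzmann * temperature)
  data.frame(r = r, kappa = kappa, u = u,
             cation = conc * exp(-u), anion = conc * exp(u))
}
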