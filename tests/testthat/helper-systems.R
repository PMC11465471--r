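# Shared fixtures: random non-overlapping particle systems and small named
# systems used across the test files.

# n particles in a box with a minimum pair separation (keeps Lennard-Jones
# forces on a physical scale so finite-difference checks are meaningful)
random_system <- function(n, seed, box = 16, min_d = 2.8,
                          classes = c("solute", "cation", "anion"),
                          charges = c(-1, 1, 2), mobility = "free") {
  set.seed(seed)
  pos <- matrix(NA_real_, 0, 3)
  while (nrow(pos) < n) {
    p <- runif(3, 0, box)
    if (nrow(pos) == 0 || min(sqrt(rowSums(sweep(pos, 2, p)^2))) >= min_d)
      pos <- rbind(pos, p)
  }
  particle_system(data.frame(
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    charge = sample(charges, n, TRUE),
    rho = runif(n, 1.2, 2.5),
    class = sample(classes, n, TRUE),
    mobility = mobility))
}

single_ion <- function(charge = 1, rho = 1.5, species = "NA", q0 = c(0, 0, 0)) {
  particle_system(data.frame(x = q0[1], y = q0[2], z = q0[3],
                             charge = charge, rho = rho, class = "cation",
                             species = species, mobility = "free",
                             mass = 22.99))
}

# fixed bead of charge q at the origin (a minimal "solute")
central_bead <- function(charge, sigma = 4, rho = 2) {
  particle_system(data.frame(x = 0, y = 0, z = 0, charge = charge,
                             rho = rho, sigma = sigma, eps_lj = 0.1,
                             class = "solute", species = "Q",
                             mobility = "fixed", mass = 100))
}

# finite-difference forces for a system/table/restraint combination
fd_forces <- function(sys, tab, rst = NULL, h = 1e-4) {
  E <- function(pos) {
    s <- sys; s$pos <- pos
    total_energy_forces(s, tab, rst, forces = FALSE)$total
  }
  n <- n_particles(sys)
  out <- matrix(0, n, 3)
  for (i in seq_len(n)) for (k in 1:3) {
    pp <- sys$pos; pp[i, k] <- pp[i, k] + h
    pm <- sys$pos; pm[i, k] <- pm[i, k] - h
    out[i, k] <- -(E(pp) - E(pm)) / (2 * h)
  }
  out
}
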