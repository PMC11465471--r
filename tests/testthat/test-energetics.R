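# Pair energies, self energies, limits, total energy and forces.

ke <- gbion_constants()$k_coulomb

test_that("f_gb has the closed form and its stated limits", {
  expect_equal(f_gb(0, 2, 2, 4), 2)                       # f(0) = sqrt(Ri Rj)
  expect_equal(f_gb(0, 1, 4, 4), 2)
  expect_equal(f_gb(1, 1, 1, 4), sqrt(1 + exp(-0.25)))    # 1.3337173
  expect_equal(f_gb(1, 1, 1, 4), 1.33372, tolerance = 1e-5)
  expect_equal(f_gb(5, 2, 2, 1e-12), 5, tolerance = 1e-9) # gamma -> 0
  expect_identical(f_gb(5, 2, 2, 0), 5)
  d <- seq(0.1, 20, by = 0.37)
  expect_true(all(f_gb(d, 1.3, 2.1, 4) >= d))             # f >= d always
  expect_error(f_gb(-1, 1, 1, 4), ">= 0")
  expect_error(f_gb(1, 1, 1, -4), ">= 0")
})

test_that("pair energy reproduces the derived value and both Coulomb limits", {
  # +1/-1 at 1 A with unit radii, canonical coefficients
  e <- gbion_pair_energy(1, 1, -1, 1, 1, gamma = 4, eps_in = 1)
  expect_equal(e, ke * (-1 + (1 - 1 / 78.5) / sqrt(1 + exp(-0.25))))
  expect_equal(e, -86.26, tolerance = 1e-4)

  cw <- -ke / 78.5  # Coulomb-in-water at 1 A
  expect_equal(gbion_pair_energy(1, 1, -1, 1, 1, gamma = 1e-12, eps_in = 1),
               cw, tolerance = 1e-9)
  expect_equal(gbion_pair_energy(1, 1, -1, 1, 1, gamma = 4, eps_in = 78.5),
               cw, tolerance = 1e-12)
  # both limits on a grid, any eps_in / any gamma
  for (d in c(0.5, 1, 3, 10, 20)) {
    ref <- -ke / (78.5 * d)
    for (ei in c(1, 8, 36, 54, 78.5))
      expect_equal(gbion_pair_energy(d, 1, -1, 1, 1, 1e-12, ei), ref,
                   tolerance = 1e-9)
    for (g in c(1e-6, 0.1, 1, 4))
      expect_equal(gbion_pair_energy(d, 1, -1, 1, 1, g, 78.5), ref)
  }
  expect_error(gbion_pair_energy(0, 1, 1, 1, 1, 4, 1), "> 0")
})

test_that("approach to Coulomb is monotone in eps_in and as gamma shrinks", {
  d <- seq(0.5, 20, by = 0.5)
  for (g in c(0.1, 1, 4)) {
    prev <- NULL
    for (ei in c(1, 8, 36, 54, 78.5)) {
      gap <- abs(gbion_pair_energy(d, 1, -1, 1, 1, g, ei) - (-ke / (78.5 * d)))
      if (!is.null(prev)) expect_true(all(gap <= prev + 1e-12))
      prev <- gap
    }
  }
  for (ei in c(1, 8, 36)) {
    prev <- NULL
    for (g in c(4, 1, 0.1, 1e-6)) {
      gap <- abs(gbion_pair_energy(d, 1, -1, 1, 1, g, ei) - (-ke / (78.5 * d)))
      if (!is.null(prev)) expect_true(all(gap <= prev + 1e-12))
      prev <- gap
    }
  }
})

test_that("self energy matches the closed form and its trivial limits", {
  expect_equal(self_energy(1, 2, 1), -0.5 * ke * (1 - 1 / 78.5) / 2)
  expect_equal(self_energy(1, 2, 1), -81.96, tolerance = 1e-4)
  expect_identical(self_energy(0, 2, 1), 0)
  expect_identical(self_energy(1, 2, 78.5, 78.5), 0)
})

test_that("Lennard-Jones term has its minimum, zero and tail", {
  expect_equal(lj_energy(2^(1 / 6) * 3, 3, 3, 0.2, 0.2), -0.2)
  expect_equal(lj_energy(3, 3, 3, 0.2, 0.2), 0)
  e <- lj_energy(50, 3, 3, 0.2, 0.2)
  expect_lt(e, 0); expect_gt(e, -1e-6)
  # Lorentz-Berthelot mixing
  expect_equal(lj_energy(2^(1 / 6) * 2.5, 2, 3, 0.1, 0.4), -0.2)
})

test_that("class-coefficient energies reduce to canonical GB at gamma=4, eps_in=1", {
  tab <- canonical_pair_table()
  for (seed in 1:25) {
    sys <- random_system(5, seed = seed, box = 10, min_d = 1.5)
    ef <- total_energy_forces(sys, tab, forces = FALSE)
    ref <- canonical_gb_energy(sys)
    expect_identical(ef$coulomb + ef$gb_cross + ef$gb_self, ref$electrostatic)
  }
})

test_that("pair energy is symmetric under particle exchange for all class pairs", {
  tab <- preset_species("NaCl-DNA")$pair_table
  cls <- c("solute", "cation", "anion")
  for (a in cls) for (b in cls) {
    prm <- pair_class_lookup(tab, a, b)
    e1 <- gbion_pair_energy(2.5, 1, -1, 1.4, 2.2, prm["gamma"], prm["eps_in"])
    e2 <- gbion_pair_energy(2.5, -1, 1, 2.2, 1.4, prm["gamma"], prm["eps_in"])
    expect_identical(unname(e1), unname(e2))
  }
})

test_that("the energy breakdown is internally consistent", {
  sys <- random_system(12, seed = 4)
  tab <- preset_species("KCl-DNA")$pair_table
  rst <- restraint_spec(anchor = c(8, 8, 8), r3 = 6, k = 20, applies_to = "all")
  ef <- total_energy_forces(sys, tab, rst)
  expect_equal(ef$total,
               ef$coulomb + ef$gb_cross + ef$gb_self + ef$lj + ef$restraint,
               tolerance = 1e-10)
  expect_equal(sum(ef$elec_by_class), ef$coulomb + ef$gb_cross,
               tolerance = 1e-10)
})

test_that("forces are the exact negative gradient (finite differences)", {
  tab <- preset_species("NaCl-DNA")$pair_table
  # 20 ions + 12-bead rod (mixed classes)
  sys <- random_system(32, seed = 3, box = 18, min_d = 2.8)
  rst <- restraint_spec(anchor = c(9, 9, 9), r3 = 10, k = 20,
                        applies_to = "all")
  ef <- total_energy_forces(sys, tab, rst)
  fd <- fd_forces(sys, tab, rst)
  expect_lt(max(abs(fd - ef$forces)) / max(abs(ef$forces)), 1e-6)
})

test_that("net force vanishes without restraints and pair forces are opposite", {
  tab <- preset_species("NaCl-DNA")$pair_table
  sys <- random_system(15, seed = 8)
  ef <- total_energy_forces(sys, tab)
  expect_lt(max(abs(colSums(ef$forces))), 1e-9 * max(abs(ef$forces)))

  two <- particle_system(data.frame(x = c(0, 3), y = 0, z = 0,
                                    charge = c(1, -1), rho = 1.5,
                                    class = c("cation", "anion")))
  ef2 <- total_energy_forces(two, tab)
  expect_equal(ef2$forces[1, ], -ef2$forces[2, ])
})

test_that("the schematic energy scan reproduces its reduced-unit values", {
  sc <- energy_scan(gamma = 4, eps_in = 1, d_grid = 1)
  expect_equal(sc$energy, -1 + (1 - 1 / 78.5) / sqrt(1 + exp(-0.25)))
  expect_equal(sc$energy, -0.2598, tolerance = 2e-4)
  # eps_in = 36 curve lies strictly between canonical and Coulomb
  d <- seq(0.5, 10, by = 0.1)
  e1 <- energy_scan(gamma = 4, eps_in = 1, d_grid = d)$energy
  e36 <- energy_scan(gamma = 4, eps_in = 36, d_grid = d)$energy
  ecl <- energy_scan(gamma = 4, eps_in = 1, d_grid = d)$coulomb_ref
  expect_true(all(e36 > e1 & e36 < ecl))
  # all curves decay to zero
  far <- energy_scan(gamma = 4, eps_in = 36, d_grid = 1e4)
  expect_lt(abs(far$energy), 1e-3)
  expect_lt(abs(far$coulomb_ref), 1e-3)
})
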