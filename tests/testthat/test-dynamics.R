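# Restraints, the Langevin integrator and the Monte Carlo oracle.

test_that("the flat-bottom restraint is zero inside and harmonic outside", {
  fb <- flat_bottom_energy(c(5, 40, 41, 43), r3 = 40, k = 20)
  expect_equal(fb$energy, c(0, 0, 20, 180))
  expect_equal(fb$force, c(0, 0, -40, -120))
  # continuity at r3
  eps <- 1e-9
  expect_lt(flat_bottom_energy(40 + eps, 40, 20)$energy, 1e-12)
})

test_that("trajectories are deterministic given a seed and fixed particles stay", {
  sys <- gbion:::.bind_systems(central_bead(-2), single_ion(q0 = c(6, 0, 0)))
  tab <- preset_species("NaCl-DNA")$pair_table
  rst <- restraint_spec(anchor = c(0, 0, 0), r3 = 15, k = 20)
  cfg <- sim_config(n_steps = 500, dt_fs = 2, seed = 77, stride = 50)
  t1 <- run_simulation(sys, tab, rst, cfg)
  t2 <- run_simulation(sys, tab, rst, cfg)
  expect_identical(t1$frames, t2$frames)
  # the fixed bead never moves
  expect_true(all(t1$frames[1, , ] == 0))
  # a different seed gives a different trajectory
  cfg2 <- sim_config(n_steps = 500, dt_fs = 2, seed = 78, stride = 50)
  expect_false(identical(run_simulation(sys, tab, rst, cfg2)$frames,
                         t1$frames))
})

test_that("a tethered particle equipartitions: position and velocity variance", {
  sys <- particle_system(data.frame(x = 0, y = 0, z = 0, charge = 0,
                                    rho = 1.5, class = "cation",
                                    species = "NA", mobility = "restrained",
                                    mass = 22.99, eps_lj = 0))
  k_pos <- 5
  cfg <- sim_config(n_steps = 2e5, dt_fs = 2, friction_ps = 5, seed = 3,
                    stride = 20, k_pos = k_pos)
  tr <- run_simulation(sys, coulomb_pair_table(), NULL, cfg)
  kbt <- gbion_constants()$k_boltzmann * 300
  x <- tr$frames[1, 1, -1]
  # U = k x^2 per coordinate => var(x) = kT / (2k); ~1e4 samples => few % SE
  expect_equal(var(x), kbt / (2 * k_pos), tolerance = 0.15)
  # kinetic temperature on target
  expect_equal(mean(tr$energies$temperature[-1]), 300, tolerance = 0.05)
})

test_that("kinetic temperature of an interacting ion gas stays within 2%", {
  set.seed(5)
  sys <- random_system(30, seed = 5, box = 24, min_d = 3.5,
                       classes = "cation", charges = c(0))
  sys$species <- rep("NA", 30); sys$mass <- rep(22.99, 30)
  rst <- restraint_spec(anchor = c(12, 12, 12), r3 = 15, k = 20)
  cfg <- sim_config(n_steps = 1e5, dt_fs = 2, friction_ps = 2, seed = 31,
                    stride = 50)
  tr <- run_simulation(sys, coulomb_pair_table(), rst, cfg)
  Tv <- tr$energies$temperature
  expect_equal(mean(Tv[-(1:200)]), 300, tolerance = 0.02)
})

test_that("ions essentially never stray beyond the restraint softness", {
  sys <- single_ion(charge = 0)
  rst <- restraint_spec(anchor = c(0, 0, 0), r3 = 12, k = 20)
  cfg <- sim_config(n_steps = 2e5, dt_fs = 5, friction_ps = 1, seed = 13,
                    stride = 20)
  tr <- run_simulation(sys, coulomb_pair_table(), rst, cfg)
  r <- sqrt(colSums(tr$frames[1, , ]^2))
  kbt <- gbion_constants()$k_boltzmann * 300
  r_soft <- 12 + 2 * sqrt(kbt / 20)
  expect_lt(mean(r > r_soft), 1e-3)
})

test_that("a blow-up halts the run with the stable frames", {
  # stiff tether integrated far beyond its stability limit => divergence
  sys <- particle_system(data.frame(x = 1, y = 0, z = 0, charge = 0,
                                    rho = 1.5, class = "cation",
                                    species = "NA", mass = 22.99,
                                    eps_lj = 0, mobility = "restrained"))
  cfg <- sim_config(n_steps = 5000, dt_fs = 100, seed = 1, stride = 10,
                    k_pos = 100, blowup_threshold = 1e6)
  expect_warning(tr <- run_simulation(sys, canonical_pair_table(), NULL, cfg),
                 "blow-up")
  expect_identical(tr$status, 1L)
  expect_true(all(is.finite(tr$frames)))
})

test_that("MC acceptance approaches one for vanishing step sizes", {
  sys <- single_ion(charge = 0)
  rst <- restraint_spec(anchor = c(0, 0, 0), r3 = 10, k = 20)
  acc <- sapply(c(2, 0.5, 0.05), function(step)
    mc_sample(sys, coulomb_pair_table(), rst, n_sweeps = 300, seed = 2,
              max_disp = step)$acceptance)
  expect_true(all(diff(acc) > 0))
  expect_gt(acc[3], 0.99)
})

test_that("Langevin and MC agree on the mean separation of an ion pair", {
  # +1/-1 pair confined to a small sphere (tight bound state)
  sys <- particle_system(data.frame(x = c(-2, 2), y = 0, z = 0,
                                    charge = c(1, -1), rho = c(1.225, 2.2),
                                    sigma = c(2.45, 4.4), eps_lj = 0.1,
                                    class = c("cation", "anion"),
                                    species = c("NA", "CL"),
                                    mobility = "free",
                                    mass = c(22.99, 35.45)))
  tab <- preset_species("NaCl-DNA")$pair_table
  rst <- restraint_spec(anchor = c(0, 0, 0), r3 = 10, k = 20)
  tr <- run_simulation(sys, tab, rst,
                       sim_config(n_steps = 2e5, dt_fs = 2, friction_ps = 1,
                                  seed = 4, stride = 100))
  mc <- mc_sample(sys, tab, rst, n_sweeps = 2e4, seed = 5, max_disp = 3,
                  stride = 10)
  sep <- function(tr, drop = 20) {
    d <- sqrt(colSums((tr$frames[1, , ] - tr$frames[2, , ])^2))
    d[-seq_len(drop)]
  }
  d_md <- sep(tr); d_mc <- sep(mc)
  se <- sqrt(var(d_md) / 100 + var(d_mc) / 100)  # conservative N_eff
  expect_lt(abs(mean(d_md) - mean(d_mc)), 3 * se + 0.05 * mean(d_mc))
})

test_that("the Debye-Hueckel reference profile behaves physically", {
  d <- dh_profile(c(10, 15, 20, 25), charge = -4, conc = 0.145)
  expect_true(all(d$cation > 0.145))       # counterions enriched
  expect_true(all(d$anion < 0.145))        # co-ions depleted
  expect_true(all(diff(d$cation) < 0))     # decays toward bulk
  expect_equal(d$kappa[1], sqrt(8 * pi * bjerrum_length() *
                                  conc_to_per_A3(0.145)), tolerance = 1e-12)
})
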