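# Effective Born radii: limits, oracle agreement, gradients, caching.

test_that("isolated particles have R equal to their intrinsic radius", {
  sys <- single_ion(rho = 2.0)
  expect_identical(effective_radii(sys)$R, 2.0)
})

test_that("a symmetric diatomic has equal radii and descreening raises R", {
  sys <- particle_system(data.frame(x = c(0, 4), y = 0, z = 0,
                                    charge = c(1, -1), rho = 1.7,
                                    class = c("cation", "anion")))
  R <- effective_radii(sys)$R
  expect_equal(R[1], R[2])
  expect_gt(R[1], 1.7)
})

test_that("pairwise radii track the quadrature oracle", {
  # two spheres within 2%
  sys <- particle_system(data.frame(x = c(0, 4), y = 0, z = 0,
                                    charge = c(1, -1), rho = 1.7,
                                    class = c("cation", "anion")))
  o <- radii_oracle(sys, 1)
  expect_lt(abs(effective_radii(sys)$R[1] - o$R) / o$R, 0.02)

  # random 5-particle cluster within 5% (union overlaps are the error)
  s5 <- random_system(5, seed = 7, box = 6, min_d = 2.2)
  R5 <- effective_radii(s5)$R
  for (i in 1:5) {
    o <- radii_oracle(s5, i, n_dir = 4096)
    expect_lt(abs(R5[i] - o$R) / o$R, 0.05)
  }
})

test_that("buried-descreener geometry matches the oracle", {
  # small particle near the centre of a large sphere
  sys <- particle_system(data.frame(x = c(0, 1.0), y = 0, z = 0,
                                    charge = c(1, -1), rho = c(0.8, 3.0),
                                    class = c("cation", "anion")))
  o <- radii_oracle(sys, 1, n_dir = 4096)
  expect_lt(abs(effective_radii(sys)$R[1] - o$R) / o$R, 0.02)
})

test_that("an ion approaching a charged rod is monotonically descreened", {
  # approach stops at Lennard-Jones contact with the strand (the ion stays
  # outside the phosphate cylinder; bead distances then shrink monotonically)
  rod <- build_bdna(12)
  R_prev <- -Inf
  for (d in seq(30, 14, by = -2)) {
    ion <- single_ion(q0 = c(d, 0, 0))
    sys <- gbion:::.bind_systems(rod, ion)
    R_ion <- effective_radii(sys)$R[n_particles(sys)]
    expect_gte(R_ion, R_prev)
    R_prev <- R_ion
  }
})

test_that("R >= rho on many random systems", {
  for (seed in 1:200) {
    sys <- random_system(6, seed = seed, box = 8, min_d = 1.0)
    expect_true(all(effective_radii(sys)$R >= sys$rho - 1e-12))
  }
})

test_that("coincident particles are rejected", {
  sys <- particle_system(data.frame(x = c(1, 1), y = 2, z = 3,
                                    charge = 1, rho = 1.5, class = "cation"))
  expect_error(effective_radii(sys), "coincident")
})

test_that("radius gradients match finite differences", {
  sys <- random_system(10, seed = 11, box = 10, min_d = 2.0)
  radii <- effective_radii(sys)
  g <- radii_gradients(sys, radii)
  h <- 1e-5
  worst <- 0
  for (i in c(1, 4, 9)) for (k in c(2, 7)) for (ax in 1:3) {
    pp <- sys; pp$pos[k, ax] <- pp$pos[k, ax] + h
    pm <- sys; pm$pos[k, ax] <- pm$pos[k, ax] - h
    fd <- (effective_radii(pp)$R[i] - effective_radii(pm)$R[i]) / (2 * h)
    worst <- max(worst, abs(fd - g[i, k, ax]) / max(1e-8, abs(fd)))
  }
  expect_lt(worst, 1e-6)
  # isolated ion: zero gradient
  iso <- single_ion()
  expect_equal(radii_gradients(iso, effective_radii(iso)),
               array(0, dim = c(1, 1, 3)))
})

test_that("stale radii are rejected", {
  sys <- random_system(4, seed = 2)
  radii <- effective_radii(sys)
  sys$pos[1, 1] <- sys$pos[1, 1] + 0.5
  expect_error(radii_gradients(sys, radii), "stale")
  expect_error(total_energy_forces(sys, canonical_pair_table(), radii = radii),
               "stale")
})

test_that("frozen-solute radius caching changes fixture energies by < 0.5%", {
  dna <- build_bdna(12)
  sys <- place_ions(dna, c("NA" = 10, CL = 4),
                    list(anchor = c(0, 0, 0), r3 = 25), seed = 3)
  tab <- preset_species("NaCl-DNA")$pair_table
  rst <- restraint_spec(anchor = c(0, 0, 0), r3 = 25, k = 20)
  # one Langevin step from identical states with and without caching
  cfg0 <- sim_config(n_steps = 1, dt_fs = 2, seed = 9, stride = 1,
                     cache_fixed_radii = FALSE)
  cfg1 <- sim_config(n_steps = 1, dt_fs = 2, seed = 9, stride = 1,
                     cache_fixed_radii = TRUE)
  e0 <- run_simulation(sys, tab, rst, cfg0)$energies$total[2]
  e1 <- run_simulation(sys, tab, rst, cfg1)$energies$total[2]
  expect_lt(abs(e0 - e1) / abs(e0), 0.005)
})
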