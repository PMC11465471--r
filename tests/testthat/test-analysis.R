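# Profiles, association counts, neutralization, PMFs and 2D maps.
# Synthetic trajectories are built directly so the estimators can be tested
# against constructions with known answers.

# wrap a bare frame array + system into a trajectory object
fake_traj <- function(frames, system) {
  structure(list(frames = frames, energies = NULL,
                 n_frames = dim(frames)[3], system = system,
                 config = list(seed = 0), restraints = NULL, kind = "synthetic",
                 status = 0L),
            class = "gbion_trajectory")
}

# n ions placed uniformly inside a cylinder (one frame per draw)
uniform_cylinder_traj <- function(n_ions, n_frames, r_max, h, seed = 1) {
  set.seed(seed)
  sys <- particle_system(data.frame(
    x = rep(0, n_ions), y = 0, z = 0, charge = 1, rho = 1.5,
    class = "cation", species = "NA", mobility = "free"))
  frames <- array(0, dim = c(n_ions, 3, n_frames))
  for (f in seq_len(n_frames)) {
    r <- r_max * sqrt(runif(n_ions))
    th <- runif(n_ions, 0, 2 * pi)
    frames[, , f] <- cbind(r * cos(th), r * sin(th),
                           runif(n_ions, -h / 2, h / 2))
  }
  fake_traj(frames, sys)
}

test_that("uniform ions give a flat profile at the known concentration", {
  h <- 40; r_max <- 30; n_ions <- 60; n_frames <- 400
  traj <- uniform_cylinder_traj(n_ions, n_frames, r_max, h)
  prof <- cylindrical_profile(traj, r_max = r_max, dr = 3, h = h,
                              bulk_range = c(27, 30))
  c_true <- per_A3_to_conc(n_ions / (pi * r_max^2 * h))
  expect_equal(prof$bins$conc, rep(c_true, nrow(prof$bins)), tolerance = 0.1)
  # count consistency: binwise integral returns the mean count exactly
  vol <- pi * (prof$bins$r_hi^2 - prof$bins$r_lo^2) * h
  expect_equal(sum(conc_to_per_A3(prof$bins$conc) * vol),
               mean(sapply(seq_len(n_frames), function(f) {
                 p <- traj$frames[, , f]
                 sum(sqrt(p[, 1]^2 + p[, 2]^2) < r_max & abs(p[, 3]) <= h / 2)
               })), tolerance = 1e-6)
})

test_that("a single parked ion lands all its mass in one bin", {
  sys <- particle_system(data.frame(x = 5, y = 0, z = 0, charge = 1,
                                    rho = 1.5, class = "cation"))
  frames <- array(rep(c(5, 0, 0), 3), dim = c(1, 3, 3))
  prof <- cylindrical_profile(fake_traj(frames, sys), r_max = 10, dr = 1,
                              h = 10, bulk_range = c(8, 10))
  expect_equal(prof$bins$mean_count[prof$bins$r_lo == 5], 1)
  expect_equal(sum(prof$bins$mean_count), 1)
})

test_that("empty trajectories and unknown species are rejected", {
  traj <- uniform_cylinder_traj(5, 4, 10, 10)
  expect_error(cylindrical_profile(traj, frames = integer(0)), "empty")
  expect_error(cylindrical_profile(traj, species = "XX"), "no particles")
})

test_that("ions_associated integrates excess concentration exactly", {
  h <- 85; dr <- 0.05
  edges <- seq(0, 30, by = dr)
  bins <- data.frame(r_lo = edges[-length(edges)], r_hi = edges[-1])
  bins$r_mid <- (bins$r_lo + bins$r_hi) / 2
  c_inf <- 0.145
  mkprof <- function(conc) {
    b <- bins; b$conc <- conc
    vol <- pi * (b$r_hi^2 - b$r_lo^2) * h
    b$mean_count <- conc_to_per_A3(conc) * vol
    structure(list(bins = b, c_inf = c_inf, h = h, geometry = "cylindrical",
                   bulk_range = c(28, 30), species = NULL, n_frames = 1),
              class = "ion_profile")
  }
  # flat profile at bulk: zero associated ions
  expect_equal(ions_associated(mkprof(rep(c_inf, nrow(bins)))), 0)
  # exponential excess: matches the closed form within 0.1%
  A <- 2; lam <- 5
  prof <- mkprof(c_inf + A * exp(-bins$r_mid / lam))
  R <- 28
  exact <- conc_to_per_A3(A) * 2 * pi * h *
    (lam^2 - exp(-R / lam) * (R * lam + lam^2))
  expect_equal(ions_associated(prof, r_cut = R), exact, tolerance = 1e-3)
  # flat excess shell holding exactly 10 ions
  shell <- bins$r_mid > 8 & bins$r_mid < 12
  vol_shell <- pi * (12^2 - 8^2) * h
  conc <- rep(c_inf, nrow(bins))
  conc[shell] <- c_inf + per_A3_to_conc(10 / vol_shell)
  expect_equal(ions_associated(mkprof(conc)), 10, tolerance = 1e-9)
  # linearity in the excess
  p1 <- mkprof(c_inf + A * exp(-bins$r_mid / lam))
  p2 <- mkprof(c_inf + 0.5 * exp(-bins$r_mid / 3))
  p12 <- mkprof(c_inf + A * exp(-bins$r_mid / lam) + 0.5 * exp(-bins$r_mid / 3))
  expect_equal(ions_associated(p12),
               ions_associated(p1) + ions_associated(p2), tolerance = 1e-9)
})

test_that("neutralization degree handles trivial shells", {
  # a bound shell exactly neutralizing a -6 solute
  sys <- gbion:::.bind_systems(
    central_bead(-6),
    particle_system(data.frame(x = c(3, -3, 0, 0, 0, 0),
                               y = c(0, 0, 3, -3, 0, 0),
                               z = c(0, 0, 0, 0, 3, -3),
                               charge = 1, rho = 1.5, class = "cation",
                               mobility = "free")))
  frames <- array(t(sys$pos), dim = c(3, n_particles(sys), 1))
  frames <- aperm(frames, c(2, 1, 3))
  traj <- fake_traj(frames, sys)
  expect_equal(neutralization_degree(traj, cutoff = 5)$percent, 100)
  # no ions at all
  bare <- fake_traj(array(0, dim = c(1, 3, 1)), central_bead(-6))
  expect_equal(neutralization_degree(bare, cutoff = 5)$percent, 0)
})

test_that("PMF transforms concentrations as -ln(c/c_inf)", {
  traj <- uniform_cylinder_traj(40, 50, 20, 30)
  prof <- cylindrical_profile(traj, r_max = 20, dr = 4, h = 30,
                              bulk_range = c(16, 20))
  pm <- pmf_profile(prof)
  expect_equal(pm$W, -log(prof$bins$conc / prof$c_inf))
  expect_equal(-log(1.6), -0.470, tolerance = 1e-3)  # the scale of the check
  # masked where empty
  prof$bins$conc[2] <- 0
  expect_true(is.na(pmf_profile(prof)$W[2]))
})

test_that("profile comparison returns (0, 1) for identical profiles and the
           scan ratio for a scaled peak", {
  traj <- uniform_cylinder_traj(40, 80, 20, 30, seed = 3)
  prof <- cylindrical_profile(traj, r_max = 20, dr = 2, h = 30,
                              bulk_range = c(16, 20))
  cmp <- profile_compare(prof, prof)
  expect_equal(cmp$max_dW, 0)
  expect_equal(cmp$peak_area_ratio, 1)

  # construct a peaked profile and a copy scaled by 1.62 in the peak region
  a <- prof
  a$bins$conc <- a$c_inf * (1 + 3 * exp(-(a$bins$r_mid - 6)^2 / 4))
  b <- a
  peak <- profile_compare(a, a)$peak_bins
  b$bins$conc[peak] <- a$bins$conc[peak] / 1.62
  cmp2 <- profile_compare(a, b)
  expect_equal(cmp2$peak_area_ratio, 1.62, tolerance = 1e-9)
  expect_equal(cmp2$max_dW, log(1.62), tolerance = 1e-9)
})

test_that("the radial-angle map marginalizes exactly to the 1D profile", {
  traj <- uniform_cylinder_traj(50, 60, 25, 40, seed = 9)
  map <- radial_angle_map(traj, r_max = 25, dr = 2.5, n_angle = 12, h = 40)
  prof_1d <- cylindrical_profile(traj, r_max = 25, dr = 2.5, h = 40,
                                 bulk_range = c(20, 25))
  from_map <- map_to_profile(map, bulk_range = c(20, 25))
  expect_equal(from_map$bins$mean_count, prof_1d$bins$mean_count)
  expect_equal(from_map$bins$conc, prof_1d$bins$conc)
  # uniform ions: map roughly flat in angle
  row_tot <- rowSums(map$mean_count)
  busy <- row_tot > 1
  flat <- sweep(map$mean_count[busy, , drop = FALSE], 1, row_tot[busy], "/")
  expect_lt(max(abs(flat - 1 / 12)), 0.12)
})

test_that("ions seeded in one groove sector give a single angular mode", {
  sys <- particle_system(data.frame(x = rep(0, 30), y = 0, z = 0, charge = 1,
                                    rho = 1.5, class = "cation",
                                    species = "NA", mobility = "free"))
  set.seed(4)
  frames <- array(0, dim = c(30, 3, 20))
  twist <- 36; rise <- 3.4
  for (f in 1:20) {
    z <- runif(30, -15, 15)
    # place each ion at helical phase ~40 degrees relative to the reference
    phi <- (40 + twist * z / rise + rnorm(30, 0, 5)) * pi / 180
    r <- runif(30, 9, 11)
    frames[, , f] <- cbind(r * cos(phi), r * sin(phi), z)
  }
  traj <- fake_traj(frames, sys)
  map <- radial_angle_map(traj, r_max = 15, dr = 3, n_angle = 12, h = 30,
                          twist = twist, rise = rise)
  ang_tot <- colSums(map$mean_count)
  expect_equal(which.max(ang_tot), 2)  # the 30-60 degree bin
  expect_gt(max(ang_tot) / sum(ang_tot), 0.5)
})

test_that("profile variance shrinks with longer averaging windows", {
  sys <- single_ion(charge = 0)
  rst <- restraint_spec(anchor = c(0, 0, 0), r3 = 15, k = 20)
  cfg <- sim_config(n_steps = 6e4, dt_fs = 5, friction_ps = 1, seed = 6,
                    stride = 50)
  tr <- run_simulation(sys, coulomb_pair_table(), rst, cfg)
  conv <- profile_convergence(tr, c(10, 40, 160), geometry = "spherical",
                              r_max = 16, dr = 4, bulk_range = c(12, 16))
  expect_true(all(diff(conv$variance) < 0))
})
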