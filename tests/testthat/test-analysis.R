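# Trajectory statistics against independent oracles and closed forms.

test_that("permeation counting matches a brute-force enumerator", {
  reg <- pore_region(-15, 15, 8)
  # random-walk fixtures: free diffusion with jumps through and around the
  # pore, several seeds
  for (seed in 1:4) {
    set.seed(seed)
    nfr <- 300; np <- 12
    coords <- array(NA_real_, c(nfr, np, 3))
    for (p in seq_len(np)) {
      coords[, p, 1] <- cumsum(rnorm(nfr, 0, 1.5))
      coords[, p, 2] <- cumsum(rnorm(nfr, 0, 1.5))
      coords[, p, 3] <- cumsum(rnorm(nfr, 0, 2.5)) + runif(1, -40, 40)
    }
    tr <- bd_trajectory(coords, rep("K", np), seq_len(nfr) - 1,
                        box = c(60, 60, 120))
    got <- suppressWarnings(count_permeations(tr, reg))
    want <- brute_crossings(tr, reg)
    expect_equal(got$counts$total[got$counts$species == "K"], nrow(want))
    expect_equal(sum(got$events$direction == "ext_to_int"),
                 sum(want$direction == "ext_to_int"))
  }
})

test_that("non-crossings never count", {
  reg <- pore_region(-20, 20, 10)
  # enter and return to the same side
  z <- c(seq(30, 0, length.out = 20), seq(0, 30, length.out = 20))
  tr <- bd_trajectory(array(c(rep(0, 80), z), c(40, 1, 3)), "K",
                      seq_len(40) - 1, box = c(60, 60, 140))
  expect_equal(count_permeations(tr, reg)$counts$total, 0)
  # full traverse but outside the pore radius (through the membrane)
  zz <- seq(30, -30, length.out = 40)
  tr2 <- bd_trajectory(array(c(rep(reg$wall_radius + 4, 40), rep(0, 40), zz),
                             c(40, 1, 3)),
                       "K", seq_len(40) - 1, box = c(60, 60, 140))
  expect_equal(count_permeations(tr2, reg)$counts$total, 0)
})

test_that("replica rates average with a population SD", {
  # counts {10, 12, 14} over 20 ns -> 0.6 /ns, SD of {0.5, 0.6, 0.7}
  out <- permeation_rate(c(10, 12, 14), sim_time = 20)
  expect_equal(out$mean_rate, 0.6)
  expect_equal(out$sd_rate, sqrt(mean((c(0.5, 0.6, 0.7) - 0.6)^2)))
  # single replica: SD 0 and flagged
  one <- permeation_rate(c(10), sim_time = 20)
  expect_equal(one$sd_rate, 0)
  expect_true(attr(one, "single_replica"))
  # all-zero counts
  zero <- permeation_rate(c(0, 0, 0), sim_time = 20)
  expect_equal(zero$mean_rate, 0)
  expect_equal(zero$sd_rate, 0)
  expect_error(permeation_rate(c(1, 2), sim_time = 0), "positive")
})

test_that("density profiles are AUC-normalised and correctly shaped", {
  # all particles at one z: a single nonzero bin
  coords <- array(0, c(5, 20, 3)); coords[, , 3] <- 12.3
  tr <- bd_trajectory(coords, rep("W", 20), 0:4, box = c(40, 40, 60))
  prof <- z_density(tr, "W")
  expect_equal(sum(prof$value > 0), 1)
  expect_equal(sum(prof$value) * 0.5, 1, tolerance = 1e-12)
  expect_true(prof$lower[prof$value > 0] <= 12.3 &&
                prof$upper[prof$value > 0] > 12.3)

  # single particle on the axis: innermost radial bin
  reg <- pore_region(-10, 10, 10)
  c2 <- array(0, c(3, 1, 3))
  tr2 <- bd_trajectory(c2, "W", 0:2, box = c(40, 40, 60))
  rp <- radial_density(tr2, "W", reg)
  expect_equal(which(rp$value > 0), 1L)
  expect_equal(sum(rp$value) * 0.5, 1, tolerance = 1e-12)

  # AUC = 1 within 1e-9 on assorted fixtures
  for (seed in 1:3) {
    cl <- gen_uniform_cloud(500, n_frames = 4, seed = seed)
    expect_equal(sum(z_density(cl, "W")$value) * 0.5, 1, tolerance = 1e-9)
    cy <- gen_uniform_cylinder(500, 6, reg, n_frames = 4, seed = seed)
    expect_equal(sum(radial_density(cy, "W", reg)$value) * 0.5, 1,
                 tolerance = 1e-9)
  }
  expect_error(z_density(tr, "Xe"), "species")
})

test_that("survival probability follows the product-form definition", {
  reg <- pore_region(-20, 20, 10)
  # always inside: Q = 1 at every lag
  tr <- gen_residence_traj(0, 30, 25, reg, seed = 1)
  expect_true(all(survival_probability(tr, reg)$Q == 1))
  # one particle leaving after k frames: Q(t) = max(k - t, 0) / k, so
  # exactly zero from lag k on
  k <- 8; nfr <- 20
  coords <- array(0, c(nfr, 1, 3))
  coords[(k + 1):nfr, 1, 3] <- 50
  tr1 <- bd_trajectory(coords, "W", seq_len(nfr) - 1, box = c(60, 60, 130))
  q <- survival_probability(tr1, reg)
  expect_equal(q$Q[1], 1)
  expect_true(all(q$Q[(k + 1):nfr] == 0))
  expect_equal(q$Q, pmax(k - q$t, 0) / k)
  # monotone non-increasing on a stochastic fixture
  trs <- gen_residence_traj(0.15, 300, 60, reg, seed = 5)
  expect_true(all(diff(survival_probability(trs, reg)$Q) <= 1e-12))
  expect_error(survival_probability(
    bd_trajectory(array(100, c(3, 1, 3)), "W", 0:2, c(300, 300, 300)), reg),
    "empty")
})

test_that("exponential fitting recovers known decays", {
  t <- seq(0, 60, by = 0.5)
  exact <- fit_exponential(t, exp(-t / 7))
  expect_equal(exact$A, 1, tolerance = 1e-6)
  expect_equal(exact$tau, 7, tolerance = 1e-6)
  # constant curve: infinite tau, flagged
  cst <- fit_exponential(t, rep(0.8, length(t)))
  expect_equal(cst$flag, "constant")
  expect_true(is.infinite(cst$tau))
  # rising curve: flagged failure
  ris <- fit_exponential(t, exp(t / 30))
  expect_equal(ris$flag, "non_decaying")
  # noisy exponential, sigma = 0.01: tau within 5%
  set.seed(31)
  noisy <- pmax(1e-6, 1.0 * exp(-t / 12) + rnorm(length(t), 0, 0.01))
  fit <- fit_exponential(t, noisy)
  expect_equal(fit$tau, 12, tolerance = 0.05)
})

test_that("dipole statistics match their closed forms", {
  reg <- pore_region(-20, 20, 10)
  up <- gen_dipole_traj("aligned", direction = 1, region = reg, seed = 2)
  dz <- dipole_dz(up, reg)
  expect_true(all(abs(dz$dz[dz$n > 0] - 1) < 1e-12))
  # isotropic: DZ ~ 0 within 3 / sqrt(n)
  iso <- gen_dipole_traj("isotropic", n_particles = 1000, n_frames = 3,
                         region = reg, seed = 8)
  dz0 <- dipole_dz(iso, reg, bin = 40)$dz[1]
  expect_lt(abs(dz0), 3 / sqrt(1000))
  # C(0) = 1 always; frozen dipoles stay at 1
  acf <- dipole_acf(iso, reg, max_lag = 10)
  expect_equal(acf$C[1], 1)
  expect_true(all(abs(acf$C - 1) < 1e-12))
  expect_error(dipole_acf(gen_uniform_cloud(5, n_frames = 3), reg),
               "dipole")
})

test_that("effective diameter recovers a hard cylinder edge", {
  reg <- pore_region(-10, 10, 12)
  R <- 6
  cyl <- gen_uniform_cylinder(40000, R, reg, n_frames = 5, seed = 13)
  prof <- radial_density(cyl, "W", reg, bin = 0.5, r_max = 12)
  # binned flat profile with a sharp edge: the 10%-of-peak crossing sits
  # between the last occupied bin centre and the first empty bin centre
  v <- prof$value
  k <- max(which(v >= 0.1 * max(v)))
  expected <- 2 * (prof$mid[k] + (v[k] - 0.1 * max(v)) /
                     (v[k] - v[k + 1]) * 0.5)
  expect_equal(effective_diameter(prof), expected, tolerance = 1e-12)
  # and that crossing brackets the true edge within one bin
  expect_lt(abs(effective_diameter(prof) - 2 * R), 1)
})

test_that("electrostatic slices obey Coulomb linearity and symmetry", {
  # single +0.4 e charge at 10.5 A from the grid centre
  slab <- drill_pore(build_lattice(compact_lattice()), pore_spec(20))
  one <- place_calps(slab, calp_spec(0.4, n_sites = 1, z_position = 6))
  sl <- electrostatic_slice(one, z_plane = 6)
  centre <- sl$phi[sl$x == 0, sl$y == 0]
  expect_equal(centre, 332.0636 * 0.4 / 10.5, tolerance = 1e-9)

  # X3 vs X1 CaLP-only contribution scales exactly 3x (linearity)
  m0 <- compact_model(0, 4); m1 <- compact_model(0.2, 4)
  m3 <- compact_model(0.6, 4)
  zc <- m1$specs$calps$z_position
  at_centre <- function(m) {
    sl <- electrostatic_slice(m, z_plane = zc)
    sl$phi[sl$x == 0, sl$y == 0]
  }
  phi0 <- at_centre(m0); phi1 <- at_centre(m1); phi3 <- at_centre(m3)
  expect_equal((phi3 - phi0) / (phi1 - phi0), 3, tolerance = 1e-6)

  # X0 at the mid-plane centre: antisymmetric ring contributions cancel
  sl0 <- electrostatic_slice(m0, z_plane = 0)
  expect_equal(sl0$phi[sl0$x == 0, sl0$y == 0], 0, tolerance = 1e-9)
})
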