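# Ground-truth fixture generators: scripted crossings, geometric residence,
# dipole modes, uniform clouds/cylinders.

test_that("scripted crossing fixtures contain exactly the scripted events", {
  reg <- pore_region(-20, 20, 10)
  for (script in list(c(3, 2), c(0, 0), c(1, 4))) {
    tr <- gen_crossing_traj(script[1], script[2], region = reg, seed = 7)
    pe <- count_permeations(tr, reg)
    k <- pe$counts[pe$counts$species == "K", ]
    expect_equal(k$ext_to_int, script[1])
    expect_equal(k$int_to_ext, script[2])
  }
  # distractor-only fixture: no events
  tr0 <- gen_crossing_traj(0, 0, region = reg, distractors = TRUE, seed = 2)
  expect_equal(count_permeations(tr0, reg)$counts$total, 0)
})

test_that("geometric residence fixtures decay with the designed tau", {
  reg <- pore_region(-20, 20, 10)
  # p = 0: nobody leaves
  q0 <- survival_probability(gen_residence_traj(0, 50, 30, reg, seed = 1), reg)
  expect_true(all(q0$Q == 1))
  # p = 1: everyone leaves after the first frame
  q1 <- survival_probability(gen_residence_traj(1, 50, 30, reg, seed = 1), reg)
  expect_true(all(q1$Q[q1$t > 1] == 0))
  # p = 0.1: tau = -1 / log(0.9) = 9.49
  tr <- gen_residence_traj(0.1, n_particles = 2000, n_frames = 120,
                           region = reg, dt = 1, seed = 42)
  fit <- fit_exponential(survival_probability(tr, reg))
  expect_equal(fit$flag, "ok")
  expect_equal(fit$tau, -1 / log(0.9), tolerance = 0.05)
})

test_that("dipole fixtures have the designed orientation statistics", {
  reg <- pore_region(-20, 20, 10)
  up <- gen_dipole_traj("aligned", direction = 1, region = reg, seed = 3)
  dzu <- dipole_dz(up, reg)$dz
  expect_true(all(abs(dzu[!is.na(dzu)] - 1) < 1e-12))
  dn <- gen_dipole_traj("aligned", direction = -1, region = reg, seed = 3)
  dzd <- dipole_dz(dn, reg)$dz
  expect_true(all(abs(dzd[!is.na(dzd)] + 1) < 1e-12))

  iso <- gen_dipole_traj("isotropic", n_particles = 800, n_frames = 5,
                         region = reg, seed = 9)
  dz_all <- dipole_dz(iso, reg, bin = reg$z_hi - reg$z_lo)$dz
  expect_lt(abs(dz_all[1]), 3 / sqrt(800))
  # frozen dipoles: C(t) = 1 for every lag
  acf <- dipole_acf(iso, reg)
  expect_true(all(abs(acf$C - 1) < 1e-12))
})

test_that("rotational-diffusion fixtures relax with tau = 1 / (2 D_r)", {
  reg <- pore_region(-20, 20, 10)
  tr <- gen_dipole_traj("rotdiff", n_particles = 400, n_frames = 250,
                        region = reg, dt = 0.1, D_r = 0.05, seed = 11)
  acf <- dipole_acf(tr, reg, max_lag = 120)
  expect_equal(acf$C[1], 1)
  fit <- fit_exponential(acf)
  expect_equal(fit$tau, 1 / (2 * 0.05), tolerance = 0.10)
})

test_that("uniform fixtures produce flat profiles", {
  tr <- gen_uniform_cloud(4000, box = c(30, 30, 60), n_frames = 10, seed = 5)
  prof <- z_density(tr, "W", bin = 2)
  expect_equal(sum(prof$value) * 2, 1, tolerance = 1e-9)
  expect_lt(max(abs(prof$value - 1 / 60)) / (1 / 60), 0.15)

  reg <- pore_region(-10, 10, 12)
  cyl <- gen_uniform_cylinder(5000, radius = 8, region = reg,
                              n_frames = 10, seed = 6)
  rp <- radial_density(cyl, "W", reg, bin = 1, r_max = 12)
  expect_equal(sum(rp$value) * 1, 1, tolerance = 1e-9)
  inside <- rp$mid < 7
  expect_lt(diff(range(rp$value[inside])) / mean(rp$value[inside]), 0.25)
  expect_true(all(rp$value[rp$lower >= 8] == 0))

  expect_error(gen_uniform_cloud(0), "positive")
  expect_error(gen_uniform_cylinder(0, 5), "positive")
})
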