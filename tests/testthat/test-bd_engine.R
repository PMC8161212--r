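# Engine physics: field conversion, pair forces, control potential,
# thermostat, determinism.

test_that("voltage and field convert per the constant-field relation", {
  expect_equal(voltage_to_field(500, 130), -500 / 130)
  expect_equal(voltage_to_field(0, 80), 0)
  # round trip: -Ez * Lz recovers the voltage exactly
  for (dv in c(-1000, 100, 500)) {
    ez <- voltage_to_field(dv, 130)
    expect_identical(-ez * 130, dv + 0)
  }
  expect_error(voltage_to_field(500, 0), "positive")
})

test_that("the field force is linear in charge with the right magnitude", {
  expect_equal(external_force(0, -3.846), 0)
  expect_equal(external_force(1, -2.5), -external_force(-1, -2.5))
  # +1 e in the 500 mV / 130 A field
  expect_equal(external_force(1, voltage_to_field(500, 130)),
               -0.08869577, tolerance = 1e-6)
})

test_that("pair forces are the analytic gradient of the pair potential", {
  # LJ force vanishes at the pair rmin
  p2 <- pair_forces(rbind(c(0, 0, 0), c(4, 0, 0)), c(0, 0), c(4, 4),
                    c(0.07, 0.07), c(50, 50, 50))
  expect_equal(p2$forces[1, 1], 0, tolerance = 1e-12)
  # K+ / Cl- Coulomb energy at 5 A under the shifted-force truncation
  p3 <- pair_forces(rbind(c(0, 0, 0), c(5, 0, 0)), c(1, -1), c(0, 0),
                    c(0, 0), c(60, 60, 60), cutoff = 12)
  expect_equal(p3$energy,
               332.0636 * (-1) * (1 / 5 - 1 / 12 + (5 - 12) / 144),
               tolerance = 1e-9)
  # finite differences on random mixed configurations
  h <- 1e-5
  for (seed in 1:3) {
    set.seed(seed)
    n <- 10
    pos <- matrix(runif(3 * n, -7, 7), ncol = 3)
    q <- sample(c(-1, -0.2, 0, 0.2, 1), n, TRUE)
    rmin <- runif(n, 3, 5); eps <- runif(n, 0.05, 0.2)
    box <- c(40, 40, 40)
    pf <- pair_forces(pos, q, rmin, eps, box)
    fmax <- max(abs(pf$forces))
    # third law: components cancel to rounding error
    expect_lt(max(abs(colSums(pf$forces))) / max(fmax, 1), 1e-12)
    for (i in sample(n, 4)) for (d in 1:3) {
      pp <- pos; pp[i, d] <- pp[i, d] + h
      pm <- pos; pm[i, d] <- pm[i, d] - h
      fd <- -(pair_forces(pp, q, rmin, eps, box)$energy -
                pair_forces(pm, q, rmin, eps, box)$energy) / (2 * h)
      expect_lt(abs(fd - pf$forces[i, d]) / max(fmax, 1), 1e-4)
    }
  }
  # overlapping particles are clamped with a warning
  expect_warning(pair_forces(rbind(c(0, 0, 0), c(0.01, 0, 0)), c(0, 0),
                             c(4, 4), c(0.1, 0.1), c(50, 50, 50)),
                 "clamped")
})

test_that("the ion-exclusion force has the stated profile", {
  spec <- repulsion_spec(f_max = 5, z_half = 20, r_gate = 10)
  # maximal magnitude at the pore centre
  expect_equal(abs(center_repulsion(c(0, 0, 0), spec)[3]), 5)
  # zero at the entrances and outside
  expect_equal(center_repulsion(c(0, 0, 20), spec)[3], 0)
  expect_equal(center_repulsion(c(0, 0, 30), spec)[3], 0)
  # radial gate
  expect_equal(center_repulsion(c(12, 0, 5), spec)[3], 0)
  # linear decay, directed outward
  expect_equal(center_repulsion(c(0, 0, 10), spec)[3], 2.5)
  expect_equal(center_repulsion(c(0, 0, -10), spec)[3], -2.5)
  # never applies to solvent
  expect_equal(center_repulsion(c(0, 0, 0), spec, species = "W")[3], 0)
})

test_that("a particle at a potential minimum stays put at T = 0", {
  # two K+-like LJ particles at their pair rmin, no charge, no field
  cfg <- engine_config(n_steps = 50, save_every = 10, seed = 1,
                       temperature = 1e-12, minimize_steps = 0)
  model <- structure(list(
    particles = data.frame(x = 0, y = 0, z = 0, charge = 0, rmin = 4,
                           epsilon = 0.1, role = "lattice", fixed = TRUE),
    specs = list(lattice = lattice_spec(30, 30, 30, 10, 4))),
    class = "pore_model")
  # place one mobile particle exactly at the pair minimum of the fixed one
  r_min_pair <- mobile_species()$K$rmin_half + 4 / 2
  tr <- cached_run("stationary", function() {
    set.seed(1)
    init <- list(ion_pos = matrix(c(r_min_pair, 0, 0), 1),
                 ion_vel = matrix(0, 1, 3),
                 w_com = matrix(numeric(), 0, 3), w_u = matrix(numeric(), 0, 3),
                 w_vel = matrix(numeric(), 0, 3),
                 w_omega = matrix(numeric(), 0, 3), ion_species = "K")
    run_bd(model, cfg, box = c(30, 30, 30), init = init)
  })
  expect_lt(max(abs(tr$coords[, 1, 1] - r_min_pair)), 1e-6)
  expect_lt(max(abs(tr$coords[, 1, 2:3])), 1e-6)
})

test_that("free ions equilibrate to the Maxwell velocity variance", {
  tr <- cached_run("gas", function() {
    run_bd(model = NULL, box = c(40, 40, 40),
           config = engine_config(n_steps = 20000, save_every = 20,
                                  seed = 11, minimize_steps = 0),
           plan = list(n_potassium = 50, n_chloride = 0), n_water = 0)
  })
  v <- tr$metadata$ion_vel
  vv <- as.vector(v[-(1:100), , ])        # discard the initial transient
  kT <- porelab_constants()$kB * 298 * porelab_constants()$f_conv
  expect_equal(var(vv), kT / 39.0983, tolerance = 0.05)
})

test_that("identical seeds give identical trajectories", {
  cfg <- engine_config(n_steps = 500, save_every = 50, seed = 77,
                       minimize_steps = 10)
  m <- compact_model(0, 4)
  run1 <- run_bd(m, cfg, n_water = 40)
  run2 <- run_bd(m, cfg, n_water = 40)
  expect_identical(run1$coords, run2$coords)
  expect_identical(run1$dipoles, run2$dipoles)
  # and the model itself is never touched by the engine
  expect_identical(m$particles, compact_model(0, 4)$particles)
})

test_that("neutral solvent shows no net drift at zero field", {
  tr <- cached_run("drift", function() {
    run_bd(model = NULL, box = c(30, 30, 30),
           config = engine_config(n_steps = 8000, save_every = 40, seed = 5,
                                  minimize_steps = 20),
           n_water = 60)
  })
  # mean z displacement from start, across solvent, last frame
  nf <- n_frames(tr)
  disp <- tr$coords[nf, , 3] - tr$coords[1, , 3]
  se <- stats::sd(disp) / sqrt(length(disp))
  expect_lt(abs(mean(disp)), 3 * se)
})

test_that("a zero-step run returns an empty trajectory with metadata", {
  cfg <- engine_config(n_steps = 0, save_every = 10, seed = 3,
                       minimize_steps = 0)
  tr <- run_bd(model = NULL, box = c(30, 30, 30), config = cfg, n_water = 5)
  expect_equal(n_frames(tr), 0)
  expect_equal(tr$metadata$seed, 3L)
  expect_s3_class(tr$metadata$config, "engine_config")
})

test_that("cell-list forces agree with the direct pair sum", {
  m <- compact_model(0, 12)
  cfg <- engine_config(n_steps = 0, save_every = 1, seed = 9,
                       minimize_steps = 0)
  tr <- run_bd(m, cfg, n_water = 60)
  st <- tr$metadata$final_state
  sp <- mobile_species()$W
  # reconstruct the site table the engine used
  o <- st$w_com - 0.5 * sp$d * st$w_u
  h <- st$w_com + 0.5 * sp$d * st$w_u
  p <- m$particles
  pos <- rbind(as.matrix(p[, c("x", "y", "z")]), o, h)
  nW <- nrow(o)
  q <- c(p$charge, rep(-sp$q, nW), rep(sp$q, nW))
  rmin <- c(p$rmin, rep(2 * sp$rmin_half, 2 * nW))
  eps <- c(p$epsilon, rep(sp$eps, 2 * nW))
  nf <- nrow(p)
  excl <- cbind(nf + seq_len(nW), nf + nW + seq_len(nW))
  direct <- pair_forces(pos, q, rmin, eps, box = tr$box, cutoff = 12,
                        dielectric = tr$metadata$config$dielectric,
                        exclusions = excl)
  eng <- tr$metadata$forces_final
  # engine site order: fixed, ions, then (O, H) interleaved
  idx_eng <- c(seq_len(nf), nf + 2 * seq_len(nW) - 1, nf + 2 * seq_len(nW))
  mob <- (nf + 1):nrow(pos)
  expect_equal(eng[idx_eng, ][mob, ], direct$forces[mob, ], tolerance = 1e-8)
})
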