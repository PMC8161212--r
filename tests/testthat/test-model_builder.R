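# Model construction: BCC lattice geometry, pore drilling, charged rings,
# CaLPs, LJ stretching, grid enumeration, solvation bookkeeping.

test_that("BCC lattice has the right geometry", {
  # one periodic cell: one corner-class and one centre-class site per
  # cubic period in x, y (half-open box), plus the closed z slab layers
  cell <- build_lattice(lattice_spec(4, 4, 12, slab_thickness = 4, spacing = 4))
  p0 <- cell$particles
  expect_equal(sum(p0$x == 0 & p0$y == 0), 1)    # corner class
  expect_equal(sum(p0$x == -2 & p0$y == -2), 2)  # centre class, z = +/-2
  expect_equal(nrow(p0), 3)

  # nearest-neighbour distance in a bigger slab = a * sqrt(3) / 2 (brute force)
  slab <- build_lattice(lattice_spec(8, 8, 130, slab_thickness = 8, spacing = 4))
  d <- as.matrix(stats::dist(slab$particles[, c("x", "y", "z")]))
  diag(d) <- Inf
  expect_equal(min(d), 2 * sqrt(3), tolerance = 1e-12)

  # no two sites coincide under the periodic minimum image (the box
  # boundary plane is generated once, not twice)
  pp <- slab$particles
  box <- c(8, 8, 130)
  dmin <- Inf
  for (i in seq_len(nrow(pp) - 1)) {
    dx <- pp$x[-(1:i)] - pp$x[i]; dx <- dx - box[1] * round(dx / box[1])
    dy <- pp$y[-(1:i)] - pp$y[i]; dy <- dy - box[2] * round(dy / box[2])
    dz <- pp$z[-(1:i)] - pp$z[i]; dz <- dz - box[3] * round(dz / box[3])
    dmin <- min(dmin, sqrt(dx^2 + dy^2 + dz^2))
  }
  expect_gt(dmin, 1)

  # corner-site spacing along x equals the lattice constant
  p <- slab$particles
  xs <- sort(unique(p$x[p$y == 0 & p$z == 0]))
  expect_equal(unique(diff(xs)), 4)

  # all neutral, all carbon LJ, all fixed
  expect_true(all(p$charge == 0))
  expect_true(all(p$rmin == 4))
  expect_true(all(p$fixed))

  expect_error(lattice_spec(spacing = -1), "spacing")
  expect_error(lattice_spec(slab_thickness = 200), "slab_thickness")
})

test_that("drilling produces the requested pore", {
  m <- compact_model(0, 4)
  g <- measure_geometry(m)
  # centre-to-centre diameter matches the request within half a spacing
  expect_lt(abs(g$diameter - 20), 0.5 * 4)
  # postcondition: no remaining wall atom inside the drill radius
  p <- m$particles
  r <- sqrt(p$x^2 + p$y^2)
  expect_true(all(r[p$role != "calp"] >= 10 - 1e-9))
  # brute-force oracle: reported diameter = min opposite-pair wall distance
  expect_equal(g$diameter, brute_min_opposite(m), tolerance = 1e-9)

  # diameter 0: nothing removed
  slab <- build_lattice(compact_lattice())
  m0 <- drill_pore(slab, pore_spec(0))
  expect_equal(nrow(m0$particles), nrow(slab$particles))

  # idempotent
  m2 <- drill_pore(m, pore_spec(20))
  expect_identical(m$particles, m2$particles)

  expect_error(drill_pore(slab, pore_spec(60)), "diameter")
})

test_that("ring charges are balanced and of the stated magnitude", {
  m <- compact_model(0, 4)
  p <- m$particles
  neg <- p[p$role == "ring_neg", ]
  pos <- p[p$role == "ring_pos", ]
  expect_gt(nrow(neg), 0)
  expect_equal(nrow(neg), nrow(pos))
  expect_true(all(neg$charge == -0.2))
  expect_true(all(pos$charge == 0.2))
  expect_true(all(neg$z > 0))  # extracellular ring on the +z side
  expect_true(all(pos$z < 0))
  expect_equal(sum(p$charge), 0)  # X0 is neutral

  # zero-size ring leaves the model unchanged
  slab <- drill_pore(build_lattice(compact_lattice()), pore_spec(20))
  m0 <- assign_ring_charges(slab, ring_spec(n_atoms_per_ring = 0))
  expect_equal(sum(m0$particles$charge != 0), 0)

  expect_error(assign_ring_charges(slab, ring_spec(z_extracellular = 90)),
               "outside the slab")
})

test_that("CaLPs sit on the stated ring with the stated charges", {
  m2 <- compact_model(0.4, 4)
  calp <- m2$particles[m2$particles$role == "calp", ]
  expect_equal(nrow(calp), 6)
  expect_true(all(calp$charge == 0.4))
  g <- measure_geometry(m2)
  expect_equal(g$calp_opposite_distance, 21, tolerance = 1e-9)
  # equal azimuthal spacing: sorted angles differ by 60 degrees
  ang <- sort(atan2(calp$y, calp$x))
  expect_equal(diff(ang), rep(pi / 3, 5), tolerance = 1e-9)

  m0 <- compact_model(0, 4)
  calp0 <- m0$particles[m0$particles$role == "calp", ]
  expect_equal(nrow(calp0), 6)
  expect_equal(sum(calp0$charge), 0)

  expect_error(calp_spec(charge_per_site = 0.3), "charge_per_site")
  expect_silent(calp_spec(charge_per_site = 0.3, allow_any_charge = TRUE))
})

test_that("stretching changes only the central wall band", {
  m16 <- compact_model(0, 16)
  p <- m16$particles
  expect_true(all(p$rmin[p$role == "stretch"] == 16))
  expect_true(all(p$rmin[p$role != "stretch"] == 4))
  expect_true(all(abs(p$z[p$role == "stretch"]) <= 4))
  expect_gt(sum(p$role == "stretch"), 0)

  # rmin 4 is the identity
  m4 <- compact_model(0, 4)
  expect_equal(sum(m4$particles$role == "stretch"), 0)

  expect_error(stretch_spec(rmin = 2), "rmin")
})

test_that("the model grid enumerates deterministically", {
  grid <- enumerate_models(lattice = compact_lattice())
  expect_length(grid, 24)
  expect_false(anyDuplicated(names(grid)) > 0)
  expect_true("X2_d9" %in% names(grid))
  # charge-major ordering, rmin (descending diameter label) within
  expect_equal(names(grid)[1:6],
               c("X0_d17", "X0_d13", "X0_d11", "X0_d9", "X0_d7", "X0_d5"))
  one <- enumerate_models(charges = 0.2, rmins = 10,
                          lattice = compact_lattice())
  expect_length(one, 1)
  expect_named(one, "X1_d11")
  # bit-for-bit determinism
  grid2 <- enumerate_models(lattice = compact_lattice())
  expect_identical(grid[["X3_d5"]]$particles, grid2[["X3_d5"]]$particles)

  # every model: roles partition, 6 CaLPs, X0 neutral, measured diameter ok
  for (lab in c("X0_d17", "X1_d11", "X3_d5")) {
    g <- measure_geometry(grid[[lab]])
    expect_equal(g$n_calp, 6)
    expect_lt(abs(g$diameter - 20), 2)
  }
  expect_equal(measure_geometry(grid[["X0_d5"]])$net_charge, 0)
})

test_that("solvation plans convert molarity and enforce neutrality", {
  m0 <- compact_model(0, 4)
  # hand arithmetic: 0.150 M * N_A * 3.25e-22 L = 29.4 -> 29 of each
  plan <- solvation_plan(default_model(0, 4), 0.150,
                         free_volume = 50 * 50 * 130)
  expect_equal(plan$n_potassium, 29)
  expect_equal(plan$n_chloride, 29)
  expect_true(plan$neutral)

  expect_equal(solvation_plan(m0, 0)$n_potassium, 0)

  # X3: net +3.6 e is not an integer -> extra Cl and a flagged residual
  p3 <- solvation_plan(compact_model(0.6, 4))
  expect_equal(p3$neutralization_adjustment, 4)
  expect_equal(p3$residual_charge, -0.4, tolerance = 1e-9)
  expect_false(p3$neutral)
  # X2 net +2.4 -> 3 extra Cl, residual -0.6
  p2 <- solvation_plan(compact_model(0.4, 4))
  expect_equal(p2$n_chloride - p2$n_potassium, 3)
  expect_false(p2$neutral)
})

test_that("geometry report flags an undrilled slab", {
  slab <- build_lattice(compact_lattice())
  g <- measure_geometry(slab)
  expect_false(g$drilled)
  expect_true(is.na(g$diameter))
})
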