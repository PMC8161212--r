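# Desk-scale Langevin dynamics of ions and coarse dipolar solvent in the
# fixed pore-model potential, under a constant transmembrane electric field.

#' Convert a transmembrane voltage to the constant electric field
#'
#' The constant-field method: a uniform field Ez along z produces a potential
#' difference `delta_Vz = -Ez * Lz` across the periodic box, so
#' `Ez = -delta_Vz / Lz`.
#'
#' @param delta_Vz Transmembrane potential in mV.
#' @param Lz Box length along z in Angstrom.
#' @return Field Ez in mV/Angstrom.
#' @export
voltage_to_field <- function(delta_Vz, Lz) {
  if (Lz <= 0) stop("Lz must be positive", call. = FALSE)
  -delta_Vz / Lz
}

#' Force on a charge in the applied field
#'
#' `F = q * Ez`, converted from e.mV/A to kcal/mol/A
#' (1 e.mV/A = 0.0230609 kcal/mol/A). The force acts along z.
#'
#' @param q Charge in e.
#' @param Ez Field in mV/Angstrom.
#' @return Force along z in kcal/mol/A.
#' @export
external_force <- function(q, Ez) q * Ez * .EMV

#' Field specification
#'
#' @param delta_Vz Transmembrane potential in mV (default 500).
#' @param Lz Box length along z in Angstrom; `NULL` resolves to the model box
#'   at run time.
#' @return An object of class `field_spec` with the derived `Ez` (mV/A) when
#'   `Lz` is known.
#' @export
field_spec <- function(delta_Vz = 500, Lz = NULL) {
  structure(list(delta_Vz = delta_Vz, Lz = Lz,
                 Ez = if (is.null(Lz)) NULL else voltage_to_field(delta_Vz, Lz)),
            class = "field_spec")
}

#' Engine configuration
#'
#' @param dt Time step in ps (default 5 fs).
#' @param temperature Thermostat temperature in K.
#' @param friction Langevin damping coefficient in 1/ps.
#' @param cutoff Nonbonded cutoff in Angstrom.
#' @param dielectric Background relative permittivity applied to all
#'   charge-charge interactions (default 1.78, the optical permittivity of
#'   water): an electronic-continuum correction for the missing electronic
#'   polarizability of the nonpolarizable coarse model.
#' @param seed Integer RNG seed (mandatory for reproducibility).
#' @param n_steps Number of dynamics steps.
#' @param save_every Save a frame every this many steps.
#' @param minimize_steps Steepest-descent steps before dynamics.
#' @param skin Neighbour-list skin in Angstrom.
#' @return An object of class `engine_config`.
#' @export
engine_config <- function(dt = 0.005, temperature = 298, friction = 1,
                          cutoff = 12, dielectric = 1.78, seed = 1,
                          n_steps = 10000, save_every = 100,
                          minimize_steps = 200, skin = 2) {
  if (dt <= 0 || temperature <= 0 || friction <= 0)
    stop("dt, temperature and friction must be positive", call. = FALSE)
  if (dielectric < 1) stop("dielectric must be >= 1", call. = FALSE)
  structure(list(dt = dt, temperature = temperature, friction = friction,
                 cutoff = cutoff, dielectric = dielectric,
                 seed = as.integer(seed), n_steps = n_steps,
                 save_every = save_every, minimize_steps = minimize_steps,
                 skin = skin),
            class = "engine_config")
}

#' Mobile species parameters
#'
#' LJ and charge parameters of the mobile species. `rmin_half` is the
#' per-atom half of the like-pair LJ minimum-energy distance; cross terms use
#' the Lorentz-Berthelot rules (arithmetic rmin, geometric epsilon). The
#' solvent `W` is a rigid two-site dumbbell: charges -q on the
#' oxygen-equivalent site and +q on the other at separation `d`, giving a
#' point dipole of `q * d` = 0.489 e.A (a 2.35 D equivalent); both sites
#' carry a water-like LJ site (sigma 3.15 A).
#'
#' Ions carry hydrated (Nightingale) radii rather than bare crystallographic
#' ones: the coarse solvent does not resolve hydration shells, and bare radii
#' let counterions collapse into permanently bound contact pairs.
#'
#' @return A named list with entries `K`, `Cl` and `W`.
#' @export
mobile_species <- function() {
  list(
    K  = list(charge = 1,  mass = 39.0983, rmin_half = 3.31, eps = 0.0870),
    Cl = list(charge = -1, mass = 35.453,  rmin_half = 3.32, eps = 0.1500),
    W  = list(q = 0.4893, d = 1.0, rmin_half = 1.7682, eps = 0.1521,
              site_mass = 9.0, dipole = 0.4893)
  )
}

#' Ion-exclusion control potential
#'
#' A z-directed repulsive force on ions (never on solvent) with magnitude
#' `f_max` at the pore mid-height, decaying linearly to zero at the two pore
#' entrances; zero outside the pore. It empties the pore of ions while water
#' flows freely, mirroring the control protocol used for ion-free pores.
#'
#' @param f_max Maximal force in kcal/mol/A (default 5).
#' @param z_half Half-length of the pore in Angstrom; `NULL` resolves to half
#'   the slab thickness at run time.
#' @param r_gate Radial gate in Angstrom (force applies only inside this
#'   radius); `NULL` resolves to the pore radius.
#' @return An object of class `repulsion_spec`.
#' @export
repulsion_spec <- function(f_max = 5, z_half = NULL, r_gate = NULL) {
  if (f_max < 0) stop("f_max must be >= 0", call. = FALSE)
  structure(list(f_max = f_max, z_half = z_half, r_gate = r_gate),
            class = "repulsion_spec")
}

#' Evaluate the control-potential force at a position
#'
#' @param position Numeric length-3 position (A), or an n x 3 matrix.
#' @param spec A [repulsion_spec()] with resolved `z_half` and `r_gate`.
#' @param species Species name; the force applies to ions (`"K"`, `"Cl"`)
#'   only and is zero for solvent.
#' @return An n x 3 matrix of forces in kcal/mol/A.
#' @export
center_repulsion <- function(position, spec, species = "K") {
  if (is.null(spec$z_half) || is.null(spec$r_gate))
    stop("spec needs resolved z_half and r_gate", call. = FALSE)
  pos <- if (is.matrix(position)) position else matrix(position, ncol = 3)
  F <- matrix(0, nrow(pos), 3)
  if (!species %in% c("K", "Cl")) return(F)
  r <- sqrt(pos[, 1]^2 + pos[, 2]^2)
  z <- pos[, 3]
  inside <- abs(z) < spec$z_half & r < spec$r_gate
  s <- ifelse(z >= 0, 1, -1)
  F[inside, 3] <- (s * spec$f_max * (1 - abs(z) / spec$z_half))[inside]
  F
}

#' Pairwise forces and energy for an arbitrary set of particles
#'
#' Direct double sum of the engine's pair potential (shifted 12-6 LJ plus
#' shifted-force Coulomb, minimum image, single cutoff). Exposed for force
#' validation; the dynamics engine uses the same kernel behind a cell-based
#' neighbour list.
#'
#' @param positions n x 3 matrix (A).
#' @param charges Charges in e.
#' @param rmin Like-pair LJ rmin per particle (A); cross pairs use the
#'   arithmetic mean.
#' @param epsilon LJ well depths (kcal/mol); 0 disables LJ for that particle.
#' @param box Length-3 box (A).
#' @param cutoff Cutoff (A).
#' @param dielectric Background relative permittivity (default 1, bare
#'   Coulomb).
#' @param exclusions Optional 2-column matrix of 1-based excluded pairs.
#' @return List with `forces` (n x 3, kcal/mol/A), `energy` (kcal/mol) and
#'   `n_clamped` (overlapping pairs whose force was clamped).
#' @export
pair_forces <- function(positions, charges, rmin, epsilon, box, cutoff = 12,
                        dielectric = 1, exclusions = NULL) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  charges <- rep_len(charges, n)
  rmin <- rep_len(rmin, n)
  epsilon <- rep_len(epsilon, n)
  if (is.null(exclusions)) exclusions <- matrix(integer(), 0, 2)
  res <- cpp_pair_forces(positions, charges, rmin / 2, epsilon,
                         as.numeric(box), cutoff,
                         as.integer(exclusions[, 1]) - 1L,
                         as.integer(exclusions[, 2]) - 1L, dielectric)
  if (res$n_clamped > 0)
    warning(sprintf("%d overlapping pair(s): force clamped", res$n_clamped))
  res
}

# Uniformly sample positions in the solvent-accessible volume: points at
# least 0.85 x (rh_fixed + rh_probe) from every fixed atom and min_sep from
# every previously placed particle. Deterministic given the RNG state.
.place_particles <- function(n, fixed, box, rh_probe, min_sep = 2.8,
                             existing = NULL, max_tries = 400) {
  out <- matrix(NA_real_, n, 3)
  placed <- if (is.null(existing)) matrix(numeric(), 0, 3) else existing
  have_fixed <- !is.null(fixed) && nrow(fixed) > 0
  if (have_fixed) {
    fx <- fixed$x; fy <- fixed$y; fz <- fixed$z
    fcontact <- 0.85 * (fixed$rmin / 2 + rh_probe)
  }
  for (i in seq_len(n)) {
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      p <- (stats::runif(3) - 0.5) * box
      if (have_fixed) {
        dx <- fx - p[1]; dx <- dx - box[1] * round(dx / box[1])
        dy <- fy - p[2]; dy <- dy - box[2] * round(dy / box[2])
        dz <- fz - p[3]; dz <- dz - box[3] * round(dz / box[3])
        if (any(dx * dx + dy * dy + dz * dz < fcontact^2)) next
      }
      if (nrow(placed) > 0) {
        dx <- placed[, 1] - p[1]; dx <- dx - box[1] * round(dx / box[1])
        dy <- placed[, 2] - p[2]; dy <- dy - box[2] * round(dy / box[2])
        dz <- placed[, 3] - p[3]; dz <- dz - box[3] * round(dz / box[3])
        if (any(dx * dx + dy * dy + dz * dz < min_sep^2)) next
      }
      ok <- TRUE
      break
    }
    if (!ok) stop("could not place particle ", i,
                  ": free volume too crowded", call. = FALSE)
    out[i, ] <- p
    placed <- rbind(placed, p)
  }
  out
}

#' Run Langevin dynamics
#'
#' Solvates the model (ions per the solvation plan, coarse dipolar solvent at
#' `solvent_density`), minimizes briefly, then integrates Langevin dynamics
#' with the BAOAB scheme at the configured temperature and friction under an
#' optional constant electric field and optional ion-exclusion control
#' potential. Periodic boundaries in all dimensions; fixed model particles
#' are never integrated. All randomness derives from `config$seed`, so
#' identical seeds give identical trajectories.
#'
#' @param model A `pore_model`, or `NULL` for a boxed system with no fixed
#'   particles (then `box` is required).
#' @param config An [engine_config()].
#' @param field A [field_spec()] or `NULL` for no field.
#' @param repulsion A [repulsion_spec()] or `NULL`.
#' @param plan A [solvation_plan()]; `NULL` means no ions.
#' @param n_water Number of solvent dumbbells; `NULL` uses
#'   `solvent_density` x free volume.
#' @param solvent_density Solvent number density in dumbbells per cubic
#'   Angstrom (default 0.0042, a coarse-grained mapping of water).
#' @param box Length-3 box override (A), required when `model` is `NULL`.
#' @param init Optional final-state list from a previous run (restart;
#'   skips solvation and minimization).
#' @param species Species parameter list, see [mobile_species()].
#' @return A [bd_trajectory()] with per-frame ion and solvent oxygen-site
#'   positions (unwrapped), solvent dipole vectors, and run metadata
#'   (including saved velocities and the final state for restarts).
#' @export
run_bd <- function(model = NULL, config = engine_config(), field = NULL,
                   repulsion = NULL, plan = NULL, n_water = NULL,
                   solvent_density = 0.0042, box = NULL, init = NULL,
                   species = mobile_species()) {
  if (is.null(box)) {
    if (is.null(model)) stop("box is required when model is NULL", call. = FALSE)
    ls <- model$specs$lattice
    box <- c(ls$box_x, ls$box_y, ls$box_z)
  }
  fixed <- if (is.null(model)) NULL else model$particles
  set.seed(config$seed)

  sp <- species
  if (is.null(init)) {
    n_k <- if (is.null(plan)) 0L else plan$n_potassium
    n_cl <- if (is.null(plan)) 0L else plan$n_chloride
    if (is.null(n_water)) {
      free_vol <- if (!is.null(model))
        solvation_plan(model, concentration = 0)$free_volume
      else prod(box)
      n_water <- round(solvent_density * free_vol)
    }
    ipos <- .place_particles(n_k + n_cl, fixed, box,
                             rh_probe = max(sp$K$rmin_half, sp$Cl$rmin_half),
                             min_sep = 0.9 * (sp$K$rmin_half + sp$Cl$rmin_half))
    wcom <- .place_particles(n_water, fixed, box, rh_probe = sp$W$rmin_half,
                             min_sep = 2.8, existing = ipos)
    u <- matrix(stats::rnorm(3 * n_water), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    ion_species <- c(rep("K", n_k), rep("Cl", n_cl))
    kT <- .kB * config$temperature
    imass <- ifelse(ion_species == "K", sp$K$mass, sp$Cl$mass)
    ivel <- matrix(stats::rnorm(3 * length(ion_species)), ncol = 3) *
      sqrt(kT * .F_CONV / imass)
    wvel <- matrix(stats::rnorm(3 * n_water), ncol = 3) *
      sqrt(kT * .F_CONV / (2 * sp$W$site_mass))
    I_w <- 0.5 * sp$W$site_mass * sp$W$d^2
    womega <- matrix(stats::rnorm(3 * n_water), ncol = 3) *
      sqrt(kT * .F_CONV / I_w)
    minimize <- config$minimize_steps
  } else {
    ipos <- init$ion_pos; ivel <- init$ion_vel
    wcom <- init$w_com; u <- init$w_u
    wvel <- init$w_vel; womega <- init$w_omega
    ion_species <- init$ion_species
    imass <- ifelse(ion_species == "K", sp$K$mass, sp$Cl$mass)
    n_water <- nrow(wcom)
    minimize <- 0L
  }
  n_ion <- length(ion_species)
  iq <- ifelse(ion_species == "K", sp$K$charge, sp$Cl$charge)
  irh <- ifelse(ion_species == "K", sp$K$rmin_half, sp$Cl$rmin_half)
  ieps <- ifelse(ion_species == "K", sp$K$eps, sp$Cl$eps)

  efz <- 0
  if (!is.null(field)) {
    Ez <- if (is.null(field$Ez)) voltage_to_field(field$delta_Vz, box[3]) else field$Ez
    efz <- Ez * .EMV
  }
  rep_fmax <- 0; rep_zhalf <- 1; rep_rgate <- 0
  if (!is.null(repulsion) && repulsion$f_max > 0) {
    rep_fmax <- repulsion$f_max
    rep_zhalf <- if (!is.null(repulsion$z_half)) repulsion$z_half
      else model$specs$lattice$slab_thickness / 2
    rep_rgate <- if (!is.null(repulsion$r_gate)) repulsion$r_gate
      else model$specs$pore$diameter / 2
  }

  empty_m <- function(n) matrix(numeric(), max(n, 0), 3)
  fpos <- if (is.null(fixed)) empty_m(0) else as.matrix(fixed[, c("x", "y", "z")])
  res <- cpp_run_bd(
    fpos,
    if (is.null(fixed)) numeric() else fixed$charge,
    if (is.null(fixed)) numeric() else fixed$rmin / 2,
    if (is.null(fixed)) numeric() else fixed$epsilon,
    if (n_ion) ipos else empty_m(0), iq, irh, ieps, imass,
    if (n_ion) ivel else empty_m(0),
    if (n_water) wcom else empty_m(0),
    if (n_water) u else empty_m(0),
    if (n_water) wvel else empty_m(0),
    if (n_water) womega else empty_m(0),
    sp$W$q, sp$W$d, sp$W$rmin_half, sp$W$eps, sp$W$site_mass,
    as.numeric(box), config$cutoff, config$skin,
    if (is.null(config$dielectric)) 1.78 else config$dielectric,
    config$dt, config$temperature, config$friction,
    config$n_steps, config$save_every, efz,
    rep_fmax, rep_zhalf, rep_rgate, as.integer(minimize))

  if (res$n_clamped > 0)
    warning(sprintf("engine clamped %d overlapping pair force(s)",
                    res$n_clamped))
  n_save <- res$n_save
  coords <- array(NA_real_, c(n_save, n_ion + n_water, 3))
  if (n_save > 0) {
    if (n_ion) coords[, seq_len(n_ion), ] <- res$ion_traj[seq_len(n_save), , , drop = FALSE]
    if (n_water) coords[, n_ion + seq_len(n_water), ] <-
        res$wO_traj[seq_len(n_save), , , drop = FALSE]
  }
  dip <- if (n_water && n_save > 0)
    res$dip_traj[seq_len(n_save), , , drop = FALSE] * sp$W$dipole else NULL
  final <- res$final
  final$ion_species <- ion_species
  bd_trajectory(
    coords = coords,
    species = c(ion_species, rep("W", n_water)),
    times = if (n_save > 0) res$times[seq_len(n_save)] else numeric(),
    box = box,
    dipoles = dip,
    metadata = list(
      config = config, field = field, repulsion = repulsion,
      model_label = if (!is.null(model)) model$label else NULL,
      seed = config$seed,
      energies = if (n_save > 0) res$energies[seq_len(n_save)] else numeric(),
      ion_vel = res$ion_vel, w_vel = res$w_vel,
      forces_final = res$forces_final,
      final_state = final,
      species_params = sp)
  )
}

#' Advance a trajectory's final state by one (or more) steps
#'
#' Convenience wrapper restarting the engine from a previous run's final
#' state for `n_steps` further steps (default one step).
#'
#' @param traj A trajectory produced by [run_bd()] with stored final state.
#' @param model The `pore_model` the run used (or `NULL`).
#' @param n_steps Steps to advance.
#' @return A new trajectory (continuation only).
#' @export
step_bd <- function(traj, model = NULL, n_steps = 1) {
  md <- traj$metadata
  cfg <- md$config
  cfg$n_steps <- n_steps
  cfg$save_every <- 1
  run_bd(model = model, config = cfg, field = md$field,
         repulsion = md$repulsion, box = traj$box,
         init = md$final_state, species = md$species_params)
}
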