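# Synthetic ground-truth trajectories: every analysis operation is testable
# against fixtures whose true answer is known analytically, with no
# simulation required. All generators emit the same `bd_trajectory`
# container the engine produces, and record their parameters (and the
# analytic ground truth) in the trajectory metadata.

.synth_box <- function(region, pad = 25) {
  c(4 * region$wall_radius + 2 * pad,
    4 * region$wall_radius + 2 * pad,
    2 * (abs(region$z_lo) + abs(region$z_hi)) / 2 + 2 *
      (region$z_hi - region$z_lo) + 2 * pad)
}

#' Scripted pore-crossing trajectories
#'
#' Piecewise-linear paths with exactly the scripted numbers of full pore
#' crossings per direction, plus optional distractor paths that must never
#' count: a particle that enters the pore and returns to its own side, and a
#' particle that traverses the slab outside the pore radius (through the
#' "membrane").
#'
#' @param n_ext_to_int,n_int_to_ext Scripted full crossings per direction.
#' @param region A [pore_region()].
#' @param species Species label of the crossing particles.
#' @param n_frames Frames per path segment set (default 40).
#' @param distractors Add the two non-counting paths (default TRUE).
#' @param seed RNG seed (jitters the radial offsets inside the pore).
#' @return A `bd_trajectory`; metadata field `truth` records the script.
#' @export
gen_crossing_traj <- function(n_ext_to_int = 3, n_int_to_ext = 2,
                              region = pore_region(), species = "K",
                              n_frames = 40, distractors = TRUE, seed = 1) {
  set.seed(seed)
  zspan <- region$z_hi - region$z_lo
  z_top <- region$z_hi + 0.3 * zspan
  z_bot <- region$z_lo - 0.3 * zspan
  box <- c(6 * region$wall_radius, 6 * region$wall_radius,
           2.2 * (z_top - z_bot))
  paths <- list()
  spc <- character()
  add_path <- function(z, r_off = 0) {
    paths[[length(paths) + 1L]] <<- cbind(rep(r_off, length(z)), 0, z)
    spc <<- c(spc, species)
  }
  for (i in seq_len(n_ext_to_int))
    add_path(seq(z_top, z_bot, length.out = n_frames),
             stats::runif(1, 0, 0.3 * region$wall_radius))
  for (i in seq_len(n_int_to_ext))
    add_path(seq(z_bot, z_top, length.out = n_frames),
             stats::runif(1, 0, 0.3 * region$wall_radius))
  if (distractors) {
    mid <- (region$z_lo + region$z_hi) / 2
    add_path(c(seq(z_top, mid, length.out = ceiling(n_frames / 2)),
               seq(mid, z_top, length.out = floor(n_frames / 2))))
    memb <- seq(z_top, z_bot, length.out = n_frames)
    paths[[length(paths) + 1L]] <- cbind(region$wall_radius + 3, 0, memb)
    spc <- c(spc, species)
  }
  nf <- max(vapply(paths, nrow, 0L))
  np <- length(paths)
  coords <- array(NA_real_, c(nf, np, 3))
  for (p in seq_len(np)) {
    path <- paths[[p]]
    n <- nrow(path)
    full <- rbind(path, matrix(rep(path[n, ], nf - n), ncol = 3, byrow = TRUE))
    coords[, p, ] <- full[seq_len(nf), ]
  }
  bd_trajectory(coords, spc, times = seq_len(nf) - 1, box = box,
                metadata = list(truth = list(
                  kind = "crossings", n_ext_to_int = n_ext_to_int,
                  n_int_to_ext = n_int_to_ext, seed = seed)))
}

#' Memoryless residence trajectories
#'
#' Particles start inside the pore region and leave permanently with
#' per-frame probability `p` (geometric residence), so the survival
#' probability decays as `(1 - p)^t` and the decay time is
#' `tau = -dt / log(1 - p)`.
#'
#' @param p Per-frame exit probability.
#' @param n_particles,n_frames Fixture size.
#' @param region A [pore_region()].
#' @param dt Frame spacing in ps.
#' @param seed RNG seed.
#' @return A `bd_trajectory` of species `"W"` (without dipoles); metadata
#'   field `truth` records `tau`.
#' @export
gen_residence_traj <- function(p, n_particles = 500, n_frames = 100,
                               region = pore_region(), dt = 1, seed = 1) {
  set.seed(seed)
  if (p < 0 || p > 1) stop("p must be in [0, 1]", call. = FALSE)
  box <- .synth_box(region)
  zmid <- (region$z_lo + region$z_hi) / 2
  z_out <- region$z_hi + 0.25 * (region$z_hi - region$z_lo) + 2
  # exit frame ~ 1 + Geometric(p): inside for frames 1..k
  k <- if (p == 0) rep(n_frames, n_particles)
       else if (p == 1) rep(1L, n_particles)
       else pmin(1L + stats::rgeom(n_particles, p), n_frames)
  coords <- array(NA_real_, c(n_frames, n_particles, 3))
  for (i in seq_len(n_particles)) {
    r <- stats::runif(1, 0, 0.5 * region$wall_radius)
    th <- stats::runif(1, 0, 2 * pi)
    inside <- c(r * cos(th), r * sin(th), zmid)
    f <- seq_len(n_frames)
    coords[, i, 1] <- ifelse(f <= k[i], inside[1], inside[1])
    coords[, i, 2] <- ifelse(f <= k[i], inside[2], inside[2])
    coords[, i, 3] <- ifelse(f <= k[i], inside[3], z_out)
  }
  tau <- if (p == 0) Inf else if (p == 1) 0 else -dt / log(1 - p)
  bd_trajectory(coords, rep("W", n_particles),
                times = (seq_len(n_frames) - 1) * dt, box = box,
                metadata = list(truth = list(kind = "residence", p = p,
                                             tau = tau, dt = dt, seed = seed)))
}

#' Dipole-vector trajectories
#'
#' Solvent particles held inside the pore region with dipole vectors in one
#' of three modes: `"aligned"` (all along +z or -z; DZ = +/-1),
#' `"isotropic"` (random fixed orientations; DZ ~ 0 and C(t) = 1), or
#' `"rotdiff"` (isotropic rotational diffusion with coefficient `D_r`, so
#' `C(t) = exp(-2 D_r t)` and `tau = 1 / (2 D_r)`).
#'
#' @param mode One of `"aligned"`, `"isotropic"`, `"rotdiff"`.
#' @param n_particles,n_frames Fixture size.
#' @param region A [pore_region()].
#' @param dt Frame spacing in ps.
#' @param D_r Rotational diffusion coefficient in rad^2/ps (rotdiff mode).
#' @param direction `+1` or `-1` for the aligned mode.
#' @param dipole Dipole magnitude in e.A.
#' @param seed RNG seed.
#' @return A `bd_trajectory` with dipoles; metadata field `truth` records
#'   the mode parameters and, for rotdiff, `tau = 1 / (2 D_r)`.
#' @export
gen_dipole_traj <- function(mode = c("aligned", "isotropic", "rotdiff"),
                            n_particles = 200, n_frames = 100,
                            region = pore_region(), dt = 0.1, D_r = 0.05,
                            direction = 1, dipole = 0.4893, seed = 1) {
  mode <- match.arg(mode)
  set.seed(seed)
  box <- .synth_box(region)
  zmid <- (region$z_lo + region$z_hi) / 2
  coords <- array(0, c(n_frames, n_particles, 3))
  r <- stats::runif(n_particles, 0, 0.5 * region$wall_radius)
  th <- stats::runif(n_particles, 0, 2 * pi)
  for (f in seq_len(n_frames)) {
    coords[f, , 1] <- r * cos(th)
    coords[f, , 2] <- r * sin(th)
    coords[f, , 3] <- zmid
  }
  rand_u <- function(n) {
    u <- matrix(stats::rnorm(3 * n), ncol = 3)
    u / sqrt(rowSums(u^2))
  }
  dip <- array(NA_real_, c(n_frames, n_particles, 3))
  if (mode == "aligned") {
    for (f in seq_len(n_frames)) {
      dip[f, , 1] <- 0; dip[f, , 2] <- 0
      dip[f, , 3] <- sign(direction)
    }
    truth <- list(kind = "dipole_aligned", dz = sign(direction))
  } else if (mode == "isotropic") {
    u <- rand_u(n_particles)
    for (f in seq_len(n_frames)) dip[f, , ] <- u
    truth <- list(kind = "dipole_isotropic", dz = 0)
  } else {
    u <- rand_u(n_particles)
    step_sd <- sqrt(2 * D_r * dt)
    for (f in seq_len(n_frames)) {
      dip[f, , ] <- u
      g <- matrix(stats::rnorm(3 * n_particles, sd = step_sd), ncol = 3)
      dot <- rowSums(g * u)
      g <- g - dot * u             # tangential increments only
      u <- u + g
      u <- u / sqrt(rowSums(u^2))
    }
    truth <- list(kind = "dipole_rotdiff", D_r = D_r, tau = 1 / (2 * D_r),
                  dt = dt)
  }
  truth$seed <- seed
  bd_trajectory(coords * 1, rep("W", n_particles),
                times = (seq_len(n_frames) - 1) * dt, box = box,
                dipoles = dip * dipole, metadata = list(truth = truth))
}

#' Uniform particle cloud
#'
#' i.i.d. uniform positions inside the box, redrawn each frame: the z
#' density profile is flat at 1/Lz.
#'
#' @param n Particles per frame (must be positive).
#' @param box Length-3 box in Angstrom.
#' @param n_frames Frames.
#' @param species Species label.
#' @param seed RNG seed.
#' @return A `bd_trajectory`.
#' @export
gen_uniform_cloud <- function(n, box = c(50, 50, 130), n_frames = 20,
                              species = "W", seed = 1) {
  if (n <= 0) stop("n must be positive", call. = FALSE)
  set.seed(seed)
  coords <- array(stats::runif(n_frames * n * 3) - 0.5, c(n_frames, n, 3))
  for (d in 1:3) coords[, , d] <- coords[, , d] * box[d]
  bd_trajectory(coords, rep(species, n), times = seq_len(n_frames) - 1,
                box = box,
                metadata = list(truth = list(kind = "uniform_cloud",
                                             seed = seed)))
}

#' Uniform cylinder of particles
#'
#' i.i.d. uniform positions inside a cylinder of radius `radius` spanning
#' the region's z band, redrawn each frame: after shell-volume correction
#' the radial density is flat up to a sharp edge at `radius`.
#'
#' @param n Particles per frame (must be positive).
#' @param radius Cylinder radius in Angstrom.
#' @param region A [pore_region()] providing the z band.
#' @param n_frames Frames.
#' @param species Species label.
#' @param seed RNG seed.
#' @return A `bd_trajectory`.
#' @export
gen_uniform_cylinder <- function(n, radius, region = pore_region(),
                                 n_frames = 20, species = "W", seed = 1) {
  if (n <= 0) stop("n must be positive", call. = FALSE)
  set.seed(seed)
  box <- .synth_box(region)
  coords <- array(NA_real_, c(n_frames, n, 3))
  for (f in seq_len(n_frames)) {
    r <- radius * sqrt(stats::runif(n))
    th <- stats::runif(n, 0, 2 * pi)
    coords[f, , 1] <- r * cos(th)
    coords[f, , 2] <- r * sin(th)
    coords[f, , 3] <- stats::runif(n, region$z_lo, region$z_hi)
  }
  bd_trajectory(coords, rep(species, n), times = seq_len(n_frames) - 1,
                box = box,
                metadata = list(truth = list(kind = "uniform_cylinder",
                                             radius = radius, seed = seed)))
}
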