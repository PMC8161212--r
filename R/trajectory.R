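# Trajectory container shared by the engine, the synthetic generators and
# every analysis: time-ordered frames of particle positions (ions and the
# solvent oxygen-equivalent site), optional solvent dipole vectors, species
# labels and the periodic box.

#' Construct a trajectory object
#'
#' @param coords Numeric array `(n_frames, n_particles, 3)` of positions in
#'   Angstrom. Coordinates are unwrapped (not folded into the box).
#' @param species Character vector of per-particle species (`"K"`, `"Cl"`,
#'   `"W"`, ...).
#' @param times Frame times in ps (equally spaced).
#' @param box Length-3 periodic box in Angstrom, centred at the origin.
#' @param dipoles Optional array `(n_frames, n_solvent, 3)` of dipole vectors
#'   (e.A) for the `"W"` particles, in the same frame order.
#' @param metadata Free-form list (specs, seeds, velocities, ...).
#' @return An object of class `bd_trajectory`.
#' @export
bd_trajectory <- function(coords, species, times, box, dipoles = NULL,
                          metadata = list()) {
  coords <- as.array(coords)
  if (length(dim(coords)) != 3 || dim(coords)[3] != 3)
    stop("coords must be an (n_frames, n_particles, 3) array", call. = FALSE)
  if (dim(coords)[2] != length(species))
    stop("species length must match particle count", call. = FALSE)
  if (dim(coords)[1] != length(times))
    stop("times length must match frame count", call. = FALSE)
  if (!is.null(dipoles)) {
    dipoles <- as.array(dipoles)
    if (length(dim(dipoles)) != 3 ||
        dim(dipoles)[1] != dim(coords)[1] ||
        dim(dipoles)[2] != sum(species == "W"))
      stop("dipoles must be (n_frames, n_W, 3)", call. = FALSE)
  }
  structure(list(coords = coords, species = species, times = times,
                 box = as.numeric(box), dipoles = dipoles,
                 metadata = metadata),
            class = "bd_trajectory")
}

#' Number of frames in a trajectory
#' @param traj A `bd_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' @export
print.bd_trajectory <- function(x, ...) {
  nf <- n_frames(x)
  tab <- table(x$species)
  cat(sprintf("Langevin/BD trajectory: %d frames, %d particles (%s)\n",
              nf, length(x$species),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  if (nf > 1)
    cat(sprintf("  t = %g..%g ps (dt_frame %g ps)\n", x$times[1],
                x$times[nf], x$times[2] - x$times[1]))
  cat(sprintf("  box %g x %g x %g A%s\n", x$box[1], x$box[2], x$box[3],
              if (is.null(x$dipoles)) "" else ", dipoles present"))
  invisible(x)
}

# Fold a coordinate array/matrix into the origin-centred box along each axis.
.wrap_centered <- function(v, L) v - L * round(v / L)

# Per-frame local coordinates of one particle: list of wrapped x, y, z and
# radial distance from the pore (z) axis.
.local_coords <- function(traj, p) {
  x <- .wrap_centered(traj$coords[, p, 1], traj$box[1])
  y <- .wrap_centered(traj$coords[, p, 2], traj$box[2])
  z <- .wrap_centered(traj$coords[, p, 3], traj$box[3])
  list(x = x, y = y, z = z, r = sqrt(x^2 + y^2))
}
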