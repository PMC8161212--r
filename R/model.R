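# Construction of the simplified hemichannel models: BCC carbon slab,
# drilled cylindrical pore, charged rings, CaLPs and LJ pore stretching.
# Construction is fully deterministic.

.sp2_eps  <- 0.07  # kcal/mol, sp2 carbon LJ well depth
.sp2_rmin <- 4.0   # A, like-pair LJ rmin for sp2 carbon

.new_pore_model <- function(particles, specs, label = NULL) {
  rownames(particles) <- NULL
  structure(list(particles = particles, specs = specs, label = label),
            class = "pore_model")
}

#' @export
print.pore_model <- function(x, ...) {
  p <- x$particles
  cat("Coarse pore model", if (!is.null(x$label)) sprintf("'%s'", x$label),
      "\n", sep = " ")
  cat(sprintf("  particles: %d  (net charge %+.3f e)\n",
              nrow(p), sum(p$charge)))
  tab <- table(p$role)
  cat("  roles:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  ls <- x$specs$lattice
  cat(sprintf("  box %g x %g x %g A, slab %g A, spacing %g A\n",
              ls$box_x, ls$box_y, ls$box_z, ls$slab_thickness, ls$spacing))
  if (!is.null(x$specs$pore))
    cat(sprintf("  pore diameter (nominal) %g A\n", x$specs$pore$diameter))
  if (!is.null(x$specs$stretch))
    cat(sprintf("  stretch rmin %g A over |z| <= %g A\n",
                x$specs$stretch$rmin, x$specs$stretch$z_half_width))
  invisible(x)
}

#' Build the undrilled BCC carbon slab
#'
#' Fills the membrane slab (|z| <= slab_thickness/2) with a body-centred cubic
#' lattice of neutral, position-fixed sp2 carbons: corner sites on a cubic
#' grid of the given spacing plus body-centre sites offset by half the spacing
#' in x, y and z. All charges are zero and all atoms carry the sp2 carbon LJ
#' parameters (rmin 4.0 A, epsilon 0.07 kcal/mol).
#'
#' @param spec A [lattice_spec()].
#' @return A `pore_model` containing the slab only (no pore).
#' @export
build_lattice <- function(spec = lattice_spec()) {
  stopifnot(inherits(spec, "lattice_spec"))
  a <- spec$spacing
  # periodic dimensions use a half-open interval [-L/2, L/2) so the two
  # boundary planes (one point under periodicity) are not double-counted
  grid1 <- function(half, offset, periodic) {
    k <- seq(ceiling((-half - offset) / a), floor((half - offset) / a))
    v <- k * a + offset
    if (periodic) v <- v[v < half - 1e-9]
    v
  }
  zhalf <- spec$slab_thickness / 2
  z_periodic <- abs(spec$slab_thickness - spec$box_z) < 1e-9
  sites <- rbind(
    as.matrix(expand.grid(x = grid1(spec$box_x / 2, 0, TRUE),
                          y = grid1(spec$box_y / 2, 0, TRUE),
                          z = grid1(zhalf, 0, z_periodic))),
    as.matrix(expand.grid(x = grid1(spec$box_x / 2, a / 2, TRUE),
                          y = grid1(spec$box_y / 2, a / 2, TRUE),
                          z = grid1(zhalf, a / 2, z_periodic)))
  )
  particles <- data.frame(
    x = sites[, 1], y = sites[, 2], z = sites[, 3],
    charge = 0, rmin = .sp2_rmin, epsilon = .sp2_eps,
    role = "lattice", fixed = TRUE,
    stringsAsFactors = FALSE
  )
  ord <- order(particles$z, particles$y, particles$x)
  .new_pore_model(particles[ord, ], specs = list(lattice = spec))
}

#' Drill the cylindrical pore
#'
#' Removes every lattice atom whose radial distance from the z axis is below
#' `diameter / 2`, leaving a straight pore through the whole slab. The
#' measured centre-to-centre diameter (twice the smallest remaining radial
#' distance) matches the request to within half a lattice spacing; the exact
#' value depends on which lattice sites straddle the requested radius.
#'
#' @param model An undrilled `pore_model` from [build_lattice()].
#' @param pore A [pore_spec()].
#' @return The drilled `pore_model`.
#' @export
drill_pore <- function(model, pore = pore_spec()) {
  stopifnot(inherits(model, "pore_model"), inherits(pore, "pore_spec"))
  ls <- model$specs$lattice
  if (pore$diameter > min(ls$box_x, ls$box_y))
    stop("pore diameter exceeds the box cross-section", call. = FALSE)
  p <- model$particles
  r <- sqrt(p$x^2 + p$y^2)
  keep <- r >= pore$diameter / 2
  model$particles <- p[keep, , drop = FALSE]
  rownames(model$particles) <- NULL
  model$specs$pore <- pore
  model
}

# Wall-shell atoms: remaining lattice-family atoms within one lattice spacing
# of the pore surface. Returns row indices into model$particles.
.wall_atoms <- function(model) {
  if (is.null(model$specs$pore)) stop("model has no pore", call. = FALSE)
  p <- model$particles
  R <- model$specs$pore$diameter / 2
  a <- model$specs$lattice$spacing
  r <- sqrt(p$x^2 + p$y^2)
  which(p$role %in% c("lattice", "ring_neg", "ring_pos", "stretch") &
          r >= R & r < R + a)
}

#' Assign the charged rings
#'
#' Gives the wall atoms in the lattice layer nearest each requested z plane a
#' partial charge: -q per atom on the extracellular (+z) ring and +q per atom
#' on the cytoplasmic (-z) ring. Atom counts are forced equal between the two
#' rings (trimming deterministically by azimuth if needed) so that the
#' calcium-free model is exactly neutral.
#'
#' @param model A drilled `pore_model`.
#' @param rings A [ring_spec()].
#' @return The decorated `pore_model`.
#' @export
assign_ring_charges <- function(model, rings = ring_spec()) {
  stopifnot(inherits(model, "pore_model"), inherits(rings, "ring_spec"))
  slab <- model$specs$lattice$slab_thickness
  z_ext <- if (is.null(rings$z_extracellular)) 0.35 * slab else rings$z_extracellular
  z_cyt <- if (is.null(rings$z_cytoplasmic)) -0.35 * slab else rings$z_cytoplasmic
  if (abs(z_ext) > slab / 2 || abs(z_cyt) > slab / 2)
    stop("ring z position lies outside the slab", call. = FALSE)
  if (rings$q == 0 ||
      (!is.null(rings$n_atoms_per_ring) && rings$n_atoms_per_ring == 0)) {
    model$specs$rings <- rings
    return(model)
  }
  wall <- .wall_atoms(model)
  p <- model$particles
  pick_ring <- function(z_target) {
    zs <- p$z[wall]
    layer_z <- unique(zs)[which.min(abs(unique(zs) - z_target))]
    idx <- wall[abs(zs - layer_z) < 1e-9]
    idx[order(atan2(p$y[idx], p$x[idx]))]  # deterministic azimuthal order
  }
  ext <- pick_ring(z_ext)
  cyt <- pick_ring(z_cyt)
  n <- min(length(ext), length(cyt))
  if (!is.null(rings$n_atoms_per_ring)) n <- min(n, rings$n_atoms_per_ring)
  ext <- ext[seq_len(n)]
  cyt <- cyt[seq_len(n)]
  model$particles$charge[ext] <- -rings$q
  model$particles$role[ext] <- "ring_neg"
  model$particles$charge[cyt] <- rings$q
  model$particles$role[cyt] <- "ring_pos"
  rings$z_extracellular <- z_ext
  rings$z_cytoplasmic <- z_cyt
  rings$n_atoms_per_ring <- n
  model$specs$rings <- rings
  model
}

#' Place the calcium-like particles
#'
#' Adds `n_sites` fixed point particles, equally spaced azimuthally on a
#' circle of `ring_radius` at the CaLP z position (default +0.25 x slab
#' thickness, in the extracellular half), each carrying `charge_per_site`.
#' CaLPs get carbon-like LJ parameters so mobile ions cannot collapse onto
#' the bare point charge.
#'
#' @param model A drilled `pore_model`.
#' @param calps A [calp_spec()].
#' @return The decorated `pore_model`.
#' @export
place_calps <- function(model, calps = calp_spec()) {
  stopifnot(inherits(model, "pore_model"), inherits(calps, "calp_spec"))
  if (is.null(model$specs$pore)) stop("drill the pore first", call. = FALSE)
  slab <- model$specs$lattice$slab_thickness
  zc <- if (is.null(calps$z_position)) 0.25 * slab else calps$z_position
  if (calps$n_sites > 0) {
    phi <- 2 * pi * (seq_len(calps$n_sites) - 1) / calps$n_sites
    add <- data.frame(
      x = calps$ring_radius * cos(phi),
      y = calps$ring_radius * sin(phi),
      z = zc,
      charge = calps$charge_per_site,
      rmin = .sp2_rmin, epsilon = .sp2_eps,
      role = "calp", fixed = TRUE,
      stringsAsFactors = FALSE
    )
    model$particles <- rbind(model$particles, add)
    rownames(model$particles) <- NULL
  }
  calps$z_position <- zc
  model$specs$calps <- calps
  model
}

#' Apply the Lennard-Jones pore stretching
#'
#' Sets the like-pair LJ `rmin` of every uncharged wall atom inside the
#' central z band to the stretch value and relabels those atoms with the
#' `stretch` role. `rmin = 4` is the identity (no atom changes).
#'
#' @param model A drilled `pore_model`.
#' @param stretch A [stretch_spec()].
#' @return The decorated `pore_model`.
#' @export
apply_stretch <- function(model, stretch = stretch_spec()) {
  stopifnot(inherits(model, "pore_model"), inherits(stretch, "stretch_spec"))
  if (is.null(model$specs$pore)) stop("drill the pore first", call. = FALSE)
  model$specs$stretch <- stretch
  if (stretch$rmin == .sp2_rmin) return(model)
  wall <- .wall_atoms(model)
  p <- model$particles
  band <- wall[abs(p$z[wall]) <= stretch$z_half_width & p$role[wall] == "lattice"]
  model$particles$rmin[band] <- stretch$rmin
  model$particles$role[band] <- "stretch"
  model
}

#' Build one complete pore model
#'
#' Convenience wrapper: lattice, drill, rings, CaLPs, stretch, in the standard
#' order, labelled `"<charge level>_<diameter label>"` (e.g. `"X2_d9"`).
#'
#' @param calp_charge CaLP charge per site in e (0, 0.2, 0.4 or 0.6).
#' @param rmin Stretch-atom like-pair LJ rmin in Angstrom (4 = unstretched).
#' @param lattice,pore,rings Optional specification overrides.
#' @param calp_args,stretch_args Extra arguments passed to [calp_spec()] and
#'   [stretch_spec()].
#' @return A labelled `pore_model`.
#' @export
build_model <- function(calp_charge = 0, rmin = 4,
                        lattice = lattice_spec(), pore = pore_spec(),
                        rings = ring_spec(), calp_args = list(),
                        stretch_args = list()) {
  calps <- do.call(calp_spec, c(list(charge_per_site = calp_charge), calp_args))
  stretch <- do.call(stretch_spec, c(list(rmin = rmin), stretch_args))
  m <- build_lattice(lattice)
  m <- drill_pore(m, pore)
  m <- assign_ring_charges(m, rings)
  m <- place_calps(m, calps)
  m <- apply_stretch(m, stretch)
  m$label <- paste0(calps$level_label, "_", .rmin_diameter_label(stretch$rmin))
  m
}

#' Enumerate the model grid
#'
#' Builds the Cartesian product of CaLP charge levels and stretch rmin values
#' (4 x 6 = 24 models by default), charge-major with rmin ascending, with
#' unique labels such as `"X2_d9"`. Construction is deterministic: repeated
#' calls give identical particle tables.
#'
#' @param charges CaLP charge levels in e.
#' @param rmins Stretch rmin values in Angstrom.
#' @param ... Passed on to [build_model()].
#' @return A named list of `pore_model` objects.
#' @export
enumerate_models <- function(charges = c(0, 0.2, 0.4, 0.6),
                             rmins = c(4, 8, 10, 12, 14, 16), ...) {
  charges <- sort(unique(charges))
  rmins <- sort(unique(rmins))
  out <- list()
  for (q in charges) {
    for (rm in rmins) {
      m <- build_model(calp_charge = q, rmin = rm, ...)
      out[[m$label]] <- m
    }
  }
  if (anyDuplicated(names(out))) stop("duplicate model labels", call. = FALSE)
  out
}

#' Plan the solvating electrolyte
#'
#' Converts a molar KCl concentration into ion counts for the free (solvent
#' accessible) volume, then adjusts the counts so the total system charge
#' (model plus ions) is as close to zero as whole ions allow. Models whose net
#' charge is not an integer multiple of e cannot be neutralised exactly; the
#' plan records the residual and flags it.
#'
#' @param model A `pore_model`.
#' @param concentration Target KCl concentration in mol/L (default 0.150).
#' @param free_volume Solvent-accessible volume in cubic Angstrom. `NULL`
#'   computes box volume minus the slab volume plus the pore volume.
#' @return An object of class `solvation_plan` with fields `n_potassium`,
#'   `n_chloride`, `target_concentration`, `free_volume`,
#'   `neutralization_adjustment`, `residual_charge` and `neutral`.
#' @export
solvation_plan <- function(model, concentration = 0.150, free_volume = NULL) {
  stopifnot(inherits(model, "pore_model"))
  ls <- model$specs$lattice
  if (is.null(free_volume)) {
    box_vol <- ls$box_x * ls$box_y * ls$box_z
    slab_vol <- ls$box_x * ls$box_y * ls$slab_thickness
    pore_vol <- if (!is.null(model$specs$pore))
      pi * (model$specs$pore$diameter / 2)^2 * ls$slab_thickness else 0
    free_volume <- box_vol - slab_vol + pore_vol
  }
  if (free_volume <= 0) stop("free volume must be positive", call. = FALSE)
  if (concentration < 0) stop("concentration must be >= 0", call. = FALSE)
  n0 <- round(concentration * .AVOGADRO * free_volume * 1e-27)
  net <- sum(model$particles$charge)
  adj <- if (net > 0) ceiling(net - 1e-9) else -ceiling(-net - 1e-9)
  n_k <- n0
  n_cl <- n0
  if (adj > 0) n_cl <- n_cl + adj else n_k <- n_k - adj
  if (n_k < 0 || n_cl < 0)
    stop("neutralization would need negative ion counts", call. = FALSE)
  residual <- net + n_k - n_cl
  structure(list(n_potassium = n_k, n_chloride = n_cl,
                 target_concentration = concentration,
                 free_volume = free_volume,
                 neutralization_adjustment = adj,
                 residual_charge = residual,
                 neutral = abs(residual) < 1e-9),
            class = "solvation_plan")
}

#' @export
print.solvation_plan <- function(x, ...) {
  cat(sprintf("Solvation plan: %d K+, %d Cl- (%.3f M in %.3g A^3)\n",
              x$n_potassium, x$n_chloride, x$target_concentration,
              x$free_volume))
  if (!x$neutral)
    cat(sprintf("  WARNING: non-neutralizable net charge, residual %+.3f e\n",
                x$residual_charge))
  invisible(x)
}

#' Measure the geometry of a built model
#'
#' Reports the constructional quantities used to validate a model: measured
#' pore centre-to-centre diameter (twice the smallest radial wall-atom
#' distance; undefined and flagged before drilling), CaLP count and
#' opposite-site distance, ring z positions and atom counts, net charge and
#' per-role particle counts.
#'
#' @param model A `pore_model`.
#' @return An object of class `geometry_report`.
#' @export
measure_geometry <- function(model) {
  stopifnot(inherits(model, "pore_model"))
  p <- model$particles
  drilled <- !is.null(model$specs$pore)
  lat <- p$role %in% c("lattice", "ring_neg", "ring_pos", "stretch")
  r <- sqrt(p$x^2 + p$y^2)
  diameter <- if (drilled && any(lat)) 2 * min(r[lat]) else NA_real_
  calp <- which(p$role == "calp")
  calp_opp <- if (length(calp) >= 2) {
    xy <- as.matrix(p[calp, c("x", "y", "z")])
    max(stats::dist(xy))
  } else NA_real_
  rings <- list(
    z_extracellular = if (any(p$role == "ring_neg"))
      unique(p$z[p$role == "ring_neg"]) else NA_real_,
    z_cytoplasmic = if (any(p$role == "ring_pos"))
      unique(p$z[p$role == "ring_pos"]) else NA_real_
  )
  structure(list(
    drilled = drilled,
    diameter = diameter,
    n_calp = length(calp),
    calp_opposite_distance = calp_opp,
    ring_z = rings,
    net_charge = sum(p$charge),
    role_counts = table(p$role),
    lattice_spacing = model$specs$lattice$spacing
  ), class = "geometry_report")
}

#' @export
print.geometry_report <- function(x, ...) {
  cat("Geometry report\n")
  if (!x$drilled) cat("  pore: not drilled (diameter undefined)\n")
  else cat(sprintf("  measured pore diameter: %.3f A\n", x$diameter))
  cat(sprintf("  CaLPs: %d (opposite-site distance %.2f A)\n",
              x$n_calp, x$calp_opposite_distance))
  cat(sprintf("  net charge: %+.3f e\n", x$net_charge))
  invisible(x)
}
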