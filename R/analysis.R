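# Trajectory statistics: permeation events and rates, AUC-normalised axial
# and radial densities, water survival probability, dipole orientation and
# relaxation, water-accessible effective diameter, electrostatic slice maps.

#' Pore region definition
#'
#' The cylindrical region used by the permeation counter and the water
#' statistics: the slab between `z_lo` and `z_hi`, within `wall_radius` of
#' the pore (z) axis. The +z mouth is the extracellular side.
#'
#' @param z_lo,z_hi Slab limits in Angstrom (`z_lo < z_hi`).
#' @param wall_radius Pore wall radius in Angstrom.
#' @return An object of class `pore_region`.
#' @export
pore_region <- function(z_lo = -37.5, z_hi = 37.5, wall_radius = 10) {
  if (z_lo >= z_hi) stop("z_lo must be below z_hi", call. = FALSE)
  structure(list(z_lo = z_lo, z_hi = z_hi, wall_radius = wall_radius),
            class = "pore_region")
}

#' Pore region of a built model
#'
#' @param model A drilled `pore_model`.
#' @param z_half_width Optional half-width to restrict the region to a band
#'   around the pore centre (e.g. the stretch band); `NULL` spans the slab.
#' @return A [pore_region()].
#' @export
pore_region_from_model <- function(model, z_half_width = NULL) {
  g <- measure_geometry(model)
  if (!g$drilled) stop("model is not drilled", call. = FALSE)
  zh <- if (is.null(z_half_width)) model$specs$lattice$slab_thickness / 2
        else z_half_width
  pore_region(-zh, zh, g$diameter / 2)
}

# ---------------------------------------------------------------------------
# Permeation

#' Count permeation events
#'
#' An event is one continuous passage through the pore: the particle enters
#' at one mouth (crossing `z_lo` or `z_hi` inward while inside the wall
#' radius) and exits at the other mouth. Events are credited at exit, with
#' the direction recorded (`ext_to_int` = extracellular +z mouth to
#' cytoplasmic -z mouth). Particles that return to their entry side, or that
#' traverse the slab outside the pore radius ("through the membrane"), never
#' count. Bookkeeping runs on box-folded coordinates via a four-state
#' (above / pore / below / membrane) automaton, so periodic re-entry through
#' the z boundary is handled without unwrapping artefacts.
#'
#' @param traj A `bd_trajectory`.
#' @param region A [pore_region()].
#' @param species Species to count (default all present).
#' @return An object of class `permeation_result`: per-species data frame of
#'   directional counts plus an event table.
#' @export
count_permeations <- function(traj, region,
                              species = unique(traj$species)) {
  stopifnot(inherits(traj, "bd_trajectory"), inherits(region, "pore_region"))
  nf <- n_frames(traj)
  events <- list()
  n_jumps <- 0L
  for (p in which(traj$species %in% species)) {
    lc <- .local_coords(traj, p)
    state <- ifelse(lc$z > region$z_hi, 1L,
                    ifelse(lc$z < region$z_lo, 3L,
                           ifelse(lc$r < region$wall_radius, 2L, 4L)))
    if (nf < 2) next
    chg <- which(diff(state) != 0L) + 1L
    entry <- NA_integer_
    for (f in chg) {
      prev <- state[f - 1L]
      cur <- state[f]
      if (cur == 2L) {
        entry <- if (prev %in% c(1L, 3L)) prev else NA_integer_
      } else if (prev == 2L && cur %in% c(1L, 3L)) {
        if (!is.na(entry) && entry != cur) {
          events[[length(events) + 1L]] <- data.frame(
            particle = p, species = traj$species[p], frame = f,
            direction = if (entry == 1L) "ext_to_int" else "int_to_ext",
            stringsAsFactors = FALSE)
        }
        entry <- NA_integer_
      } else {
        # above <-> below without visiting the pore: either a routine wrap
        # through the periodic z boundary (|dz| ~ Lz) or a genuinely missed
        # transit through the slab in one frame spacing
        if (prev %in% c(1L, 3L) && cur %in% c(1L, 3L) &&
            abs(lc$z[f] - lc$z[f - 1L]) < traj$box[3] / 2)
          n_jumps <- n_jumps + 1L
        entry <- NA_integer_
      }
    }
  }
  if (n_jumps > 0)
    warning(sprintf(paste0("%d direct reservoir-to-reservoir frame jump(s): ",
                           "frame spacing may be coarser than the typical ",
                           "transit (possible undercount)"), n_jumps))
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(particle = integer(), species = character(),
               frame = integer(), direction = character(),
               stringsAsFactors = FALSE)
  counts <- do.call(rbind, lapply(sort(unique(species)), function(s) {
    data.frame(species = s,
               ext_to_int = sum(ev$species == s & ev$direction == "ext_to_int"),
               int_to_ext = sum(ev$species == s & ev$direction == "int_to_ext"),
               stringsAsFactors = FALSE)
  }))
  counts$total <- counts$ext_to_int + counts$int_to_ext
  sim_time <- if (nf > 1) traj$times[nf] - traj$times[1] else 0
  structure(list(counts = counts, events = ev, sim_time = sim_time),
            class = "permeation_result")
}

#' @export
print.permeation_result <- function(x, ...) {
  cat(sprintf("Permeation events over %.3g ps:\n", x$sim_time))
  print(x$counts, row.names = FALSE)
  invisible(x)
}

#' Permeation rates across replicas
#'
#' Each replica's event count is divided by the simulation time to give a
#' rate, then the replicas are averaged; the spread is the population
#' standard deviation across replicas (SD = 0, flagged, for one replica).
#'
#' @param results A list of `permeation_result` objects (one per replica),
#'   or a numeric vector of event counts for a single species.
#' @param sim_time Simulation time per replica (same unit for all; use ns for
#'   events/ns). `NULL` takes each result's own recorded time.
#' @return A data frame with per-species (and, for result objects,
#'   per-direction) mean rate and SD. Attribute `single_replica` flags n = 1.
#' @export
permeation_rate <- function(results, sim_time = NULL) {
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  if (is.numeric(results)) {
    if (is.null(sim_time) || sim_time <= 0)
      stop("sim_time must be positive", call. = FALSE)
    rates <- results / sim_time
    out <- data.frame(species = "all", direction = "total",
                      mean_rate = mean(rates), sd_rate = pop_sd(rates))
  } else {
    stopifnot(all(vapply(results, inherits, TRUE, "permeation_result")))
    times <- if (is.null(sim_time))
      vapply(results, function(r) r$sim_time, 0) else
      rep_len(sim_time, length(results))
    if (any(times <= 0)) stop("sim_time must be positive", call. = FALSE)
    species <- sort(unique(unlist(lapply(results, function(r) r$counts$species))))
    rows <- list()
    for (s in species) {
      for (dir in c("ext_to_int", "int_to_ext", "total")) {
        rates <- vapply(seq_along(results), function(i) {
          cts <- results[[i]]$counts
          v <- cts[[dir]][cts$species == s]
          if (length(v) == 0) 0 else v / times[i]
        }, 0)
        rows[[length(rows) + 1L]] <- data.frame(
          species = s, direction = dir,
          mean_rate = mean(rates), sd_rate = pop_sd(rates),
          stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
  }
  attr(out, "n_replicas") <- length(results)
  attr(out, "single_replica") <- length(results) == 1L
  out
}

# ---------------------------------------------------------------------------
# Densities

.new_density_profile <- function(lower, upper, value, axis, species, bin) {
  structure(data.frame(lower = lower, upper = upper,
                       mid = (lower + upper) / 2, value = value),
            axis = axis, species = species, bin = bin,
            class = c("density_profile", "data.frame"))
}

#' Axial (z) relative density profile
#'
#' Bins particle z positions (folded into the box) in sections of `bin`
#' Angstrom, averages over frames, and normalises by the area under the
#' curve, giving a dimensionless relative density with AUC exactly 1. Water
#' is represented by its oxygen-equivalent site.
#'
#' @param traj A `bd_trajectory`.
#' @param species Species selection (single string or vector).
#' @param bin Bin width in Angstrom (default 0.5).
#' @param region Optional [pore_region()]: restrict to particles within the
#'   wall radius.
#' @return A `density_profile` data frame (`lower`, `upper`, `mid`, `value`).
#' @export
z_density <- function(traj, species, bin = 0.5, region = NULL) {
  sel <- which(traj$species %in% species)
  if (length(sel) == 0) stop("no particles of the requested species",
                             call. = FALSE)
  L <- traj$box[3]
  z <- .wrap_centered(as.vector(traj$coords[, sel, 3]), L)
  if (!is.null(region)) {
    x <- .wrap_centered(as.vector(traj$coords[, sel, 1]), traj$box[1])
    y <- .wrap_centered(as.vector(traj$coords[, sel, 2]), traj$box[2])
    keep <- sqrt(x^2 + y^2) < region$wall_radius
    z <- z[keep]
  }
  nb <- ceiling(L / bin)
  edges <- -L / 2 + bin * (0:nb)
  idx <- pmin(pmax(floor((z + L / 2) / bin) + 1, 1L), nb)
  counts <- tabulate(idx, nbins = nb)
  if (sum(counts) == 0) stop("no samples in the selection", call. = FALSE)
  value <- counts / (sum(counts) * bin)
  .new_density_profile(edges[-(nb + 1)], edges[-1], value, "z",
                       paste(species, collapse = "+"), bin)
}

#' Radial relative density profile inside the pore
#'
#' For particles inside the pore region, bins the radial distance from the
#' pore axis in sections of `bin` Angstrom, converts counts to a volume
#' density (atoms per cubic Angstrom) by dividing by the cylindrical-shell
#' volume of each bin, and AUC-normalises the result.
#'
#' @inheritParams z_density
#' @param region A [pore_region()] restricting z (and defining the default
#'   radial extent).
#' @param r_max Outer radius in Angstrom (default `region$wall_radius`).
#' @return A `density_profile` data frame.
#' @export
radial_density <- function(traj, species, region, bin = 0.5, r_max = NULL) {
  stopifnot(inherits(region, "pore_region"))
  sel <- which(traj$species %in% species)
  if (length(sel) == 0) stop("no particles of the requested species",
                             call. = FALSE)
  if (is.null(r_max)) r_max <- region$wall_radius
  x <- .wrap_centered(as.vector(traj$coords[, sel, 1]), traj$box[1])
  y <- .wrap_centered(as.vector(traj$coords[, sel, 2]), traj$box[2])
  z <- .wrap_centered(as.vector(traj$coords[, sel, 3]), traj$box[3])
  keep <- z >= region$z_lo & z <= region$z_hi
  r <- sqrt(x^2 + y^2)[keep]
  nb <- ceiling(r_max / bin)
  idx <- floor(r / bin) + 1
  idx <- idx[idx >= 1 & idx <= nb]
  counts <- tabulate(idx, nbins = nb)
  if (sum(counts) == 0) stop("no samples inside the region", call. = FALSE)
  lower <- bin * (0:(nb - 1))
  upper <- bin * (1:nb)
  shell_vol <- pi * (upper^2 - lower^2) * (region$z_hi - region$z_lo)
  dens <- counts / (shell_vol * n_frames(traj))
  value <- dens / (sum(dens) * bin)
  .new_density_profile(lower, upper, value, "radial",
                       paste(species, collapse = "+"), bin)
}

# ---------------------------------------------------------------------------
# Water dynamics

# Per-frame, per-particle "inside the pore region" mask for given species.
.inside_mask <- function(traj, region, species = "W") {
  sel <- which(traj$species %in% species)
  nf <- n_frames(traj)
  x <- .wrap_centered(traj$coords[, sel, 1, drop = FALSE], traj$box[1])
  y <- .wrap_centered(traj$coords[, sel, 2, drop = FALSE], traj$box[2])
  z <- .wrap_centered(traj$coords[, sel, 3, drop = FALSE], traj$box[3])
  dim(x) <- dim(y) <- dim(z) <- c(nf, length(sel))
  m <- z >= region$z_lo & z <= region$z_hi &
    sqrt(x^2 + y^2) < region$wall_radius
  list(mask = m, sel = sel)
}

#' Survival probability of loaded particles
#'
#' Multi-time-origin product-form survival: a particle contributes to Q at
#' lag t if it has remained continuously inside the region for t frames past
#' an origin at which it was inside. Only origins with t frames left in the
#' trajectory are valid at lag t (origin censoring), so a particle that
#' never leaves gives Q = 1 at every lag. Q(0) = 1 by construction.
#'
#' @param traj A `bd_trajectory`.
#' @param region A [pore_region()].
#' @param species Species to track (default solvent `"W"`).
#' @param max_lag Maximum lag in frames (default all).
#' @return A data frame with columns `t` (ps) and `Q`, class `sp_curve`.
#' @export
survival_probability <- function(traj, region, species = "W",
                                 max_lag = NULL) {
  nf <- n_frames(traj)
  im <- .inside_mask(traj, region, species)
  if (!any(im$mask)) stop("region is empty in every frame", call. = FALSE)
  if (is.null(max_lag)) max_lag <- nf - 1L
  # run-length census of continuous residence
  run_counts <- integer(nf)
  for (j in seq_len(ncol(im$mask))) {
    r <- rle(im$mask[, j])
    L <- r$lengths[r$values]
    for (l in L) run_counts[l] <- run_counts[l] + 1L
  }
  M <- nf
  s0 <- rev(cumsum(rev(run_counts)))                  # S0(k) = sum_{L>=k} n_L
  s1 <- rev(cumsum(rev(run_counts * seq_len(M))))     # S1(k) = sum_{L>=k} n_L L
  lags <- 0:max_lag
  qnum <- vapply(lags, function(t) {
    if (t + 1 > M) 0 else s1[t + 1] - t * s0[t + 1]
  }, 0)
  # valid origins at lag t: inside frames with at least t frames remaining
  inside_per_frame <- rowSums(im$mask)
  cum_inside <- cumsum(inside_per_frame)
  qden <- vapply(lags, function(t) {
    if (nf - t < 1) 0 else cum_inside[nf - t]
  }, 0)
  dt <- if (nf > 1) traj$times[2] - traj$times[1] else 1
  structure(data.frame(t = lags * dt,
                       Q = ifelse(qden > 0, qnum / qden, 0)),
            class = c("sp_curve", "data.frame"), dt = dt)
}

#' Fit a single-exponential decay
#'
#' Fits `y = A exp(-t / tau)` by nonlinear least squares (Levenberg-
#' Marquardt), initialised from a log-linear regression. Points below
#' `floor` times the curve maximum are excluded from the fit window.
#' Constant curves are flagged with `tau = Inf`; curves that do not decay
#' are flagged as fit failures.
#'
#' @param curve A data frame whose first two columns are time and value
#'   (e.g. an `sp_curve` or `acf_curve`), or a numeric vector of times when
#'   `y` is given.
#' @param y Values when `curve` is a time vector.
#' @param floor Relative fit floor (default 0.01).
#' @return List with `A`, `tau`, `converged` and `flag`
#'   (`"ok"`, `"constant"`, `"non_decaying"` or `"fit_failed"`).
#' @export
fit_exponential <- function(curve, y = NULL, floor = 0.01) {
  if (is.null(y)) {
    t <- curve[[1]]
    y <- curve[[2]]
  } else t <- curve
  keep <- is.finite(y) & is.finite(t) & y > 0 & y >= floor * max(y, na.rm = TRUE)
  t <- t[keep]; y <- y[keep]
  if (length(y) < 2)
    return(list(A = NA_real_, tau = NA_real_, converged = FALSE,
                flag = "fit_failed"))
  if (max(y) - min(y) < 1e-12 * max(y))
    return(list(A = y[1], tau = Inf, converged = TRUE, flag = "constant"))
  fit0 <- stats::lm(log(y) ~ t)
  slope <- stats::coef(fit0)[2]
  if (slope >= 0)
    return(list(A = NA_real_, tau = NA_real_, converged = FALSE,
                flag = "non_decaying"))
  A0 <- unname(exp(stats::coef(fit0)[1]))
  tau0 <- unname(-1 / slope)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(-t / tau),
                      start = list(A = A0, tau = tau0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(A = unname(A0), tau = unname(tau0), converged = FALSE,
                flag = "fit_failed"))
  cf <- stats::coef(fit)
  list(A = unname(cf["A"]), tau = unname(cf["tau"]), converged = TRUE,
       flag = "ok")
}

#' Water dipole orientation along the pore axis
#'
#' Per z-bin, the time-averaged ratio of the summed dipole z-components to
#' the summed dipole magnitudes of the solvent inside the pore region: +1
#' (-1) for full alignment with (against) z, 0 for no net alignment. Bins
#' with no samples are NA.
#'
#' @param traj A `bd_trajectory` with dipole vectors.
#' @param region A [pore_region()].
#' @param bin z bin width in Angstrom (default 0.5).
#' @return A data frame with `mid` (bin centre), `dz` and `n` (samples).
#' @export
dipole_dz <- function(traj, region, bin = 0.5) {
  if (is.null(traj$dipoles)) stop("trajectory has no dipole vectors",
                                  call. = FALSE)
  im <- .inside_mask(traj, region, "W")
  z <- .wrap_centered(traj$coords[, im$sel, 3, drop = FALSE], traj$box[3])
  dim(z) <- dim(im$mask)
  nb <- ceiling((region$z_hi - region$z_lo) / bin)
  mu <- traj$dipoles
  muz <- mu[, , 3, drop = FALSE]; dim(muz) <- dim(im$mask)
  mumag <- sqrt(mu[, , 1, drop = FALSE]^2 + mu[, , 2, drop = FALSE]^2 +
                  mu[, , 3, drop = FALSE]^2)
  dim(mumag) <- dim(im$mask)
  idx <- floor((z - region$z_lo) / bin) + 1
  ok <- im$mask & idx >= 1 & idx <= nb
  sum_z <- vapply(seq_len(nb), function(b) sum(muz[ok & idx == b]), 0)
  sum_m <- vapply(seq_len(nb), function(b) sum(mumag[ok & idx == b]), 0)
  n <- vapply(seq_len(nb), function(b) sum(ok & idx == b), 0L)
  data.frame(mid = region$z_lo + bin * (seq_len(nb) - 0.5),
             dz = ifelse(n > 0, sum_z / pmax(sum_m, .Machine$double.eps), NA),
             n = n)
}

#' Dipole orientational autocorrelation
#'
#' First-order reorientation autocorrelation of the solvent dipole unit
#' vector, `C(t) = <e(t0 + t) . e(t0)>`, averaged over multiple time origins
#' and over the particles loaded (inside the region) at each origin.
#' C(0) = 1 by construction.
#'
#' @param traj A `bd_trajectory` with dipole vectors.
#' @param region A [pore_region()] or `NULL` for all solvent.
#' @param max_lag Maximum lag in frames (default `n_frames - 1`).
#' @return A data frame with columns `t` (ps) and `C`, class `acf_curve`.
#' @export
dipole_acf <- function(traj, region = NULL, max_lag = NULL) {
  if (is.null(traj$dipoles)) stop("trajectory has no dipole vectors",
                                  call. = FALSE)
  nf <- n_frames(traj)
  if (nf < 2) stop("need at least 2 frames", call. = FALSE)
  nw <- dim(traj$dipoles)[2]
  mu <- traj$dipoles
  mag <- sqrt(mu[, , 1]^2 + mu[, , 2]^2 + mu[, , 3]^2)
  dim(mag) <- c(nf, nw)
  ux <- mu[, , 1] / mag; uy <- mu[, , 2] / mag; uz <- mu[, , 3] / mag
  dim(ux) <- dim(uy) <- dim(uz) <- c(nf, nw)
  loaded <- if (is.null(region)) matrix(TRUE, nf, nw)
            else .inside_mask(traj, region, "W")$mask
  if (is.null(max_lag)) max_lag <- nf - 1L
  max_lag <- min(max_lag, nf - 1L)
  C <- vapply(0:max_lag, function(l) {
    o <- seq_len(nf - l)
    d <- ux[o, , drop = FALSE] * ux[o + l, , drop = FALSE] +
      uy[o, , drop = FALSE] * uy[o + l, , drop = FALSE] +
      uz[o, , drop = FALSE] * uz[o + l, , drop = FALSE]
    w <- loaded[o, , drop = FALSE]
    if (!any(w)) return(NA_real_)
    sum(d[w]) / sum(w)
  }, 0)
  dt <- traj$times[2] - traj$times[1]
  structure(data.frame(t = (0:max_lag) * dt, C = C),
            class = c("acf_curve", "data.frame"), dt = dt)
}

# ---------------------------------------------------------------------------
# Effective diameter and electrostatics

#' Water-accessible effective diameter
#'
#' From an equilibrium radial water density profile at the constriction,
#' returns twice the outermost radius at which the density still reaches
#' `threshold` times the profile peak (linearly interpolated between bin
#' centres): the water-accessible width of the pore.
#'
#' @param profile A radial `density_profile` (from [radial_density()]).
#' @param threshold Relative density threshold (default 0.1).
#' @return Effective diameter in Angstrom.
#' @export
effective_diameter <- function(profile, threshold = 0.1) {
  v <- profile$value
  if (all(v == 0)) stop("no density in the profile", call. = FALSE)
  th <- threshold * max(v)
  idx <- which(v >= th)
  k <- max(idx)
  r <- if (k < length(v)) {
    profile$mid[k] + (v[k] - th) / (v[k] - v[k + 1]) *
      (profile$mid[k + 1] - profile$mid[k])
  } else profile$upper[k]
  2 * r
}

#' Electrostatic potential in a z slice
#'
#' Direct Coulomb sum of the model's fixed charges on a regular 2-D grid at
#' the given z plane (no periodic images, vacuum permittivity). Grid points
#' closer than `mask_dist` to any charge are masked (NA). Units are
#' kcal/(mol e).
#'
#' @param model A `pore_model`.
#' @param z_plane z of the slice in Angstrom; `NULL` uses the CaLP plane.
#' @param grid Grid spacing in Angstrom (default 1).
#' @param mask_dist Masking distance in Angstrom (default 0.5).
#' @return List with grid vectors `x`, `y`, matrix `phi` and `z_plane`,
#'   class `potential_slice`.
#' @export
electrostatic_slice <- function(model, z_plane = NULL, grid = 1,
                                mask_dist = 0.5) {
  stopifnot(inherits(model, "pore_model"))
  if (is.null(z_plane)) {
    if (is.null(model$specs$calps))
      stop("no CaLPs: give z_plane explicitly", call. = FALSE)
    z_plane <- model$specs$calps$z_position
  }
  ls <- model$specs$lattice
  xs <- seq(-ls$box_x / 2, ls$box_x / 2, by = grid)
  ys <- seq(-ls$box_y / 2, ls$box_y / 2, by = grid)
  ch <- model$particles[model$particles$charge != 0, , drop = FALSE]
  phi <- matrix(0, length(xs), length(ys))
  if (nrow(ch) > 0) {
    gx <- rep(xs, times = length(ys))
    gy <- rep(ys, each = length(xs))
    pot <- numeric(length(gx))
    mask <- logical(length(gx))
    for (i in seq_len(nrow(ch))) {
      d <- sqrt((gx - ch$x[i])^2 + (gy - ch$y[i])^2 + (z_plane - ch$z[i])^2)
      mask <- mask | d < mask_dist
      pot <- pot + .COULOMB * ch$charge[i] / pmax(d, 1e-12)
    }
    pot[mask] <- NA_real_
    phi <- matrix(pot, length(xs), length(ys))
  }
  structure(list(x = xs, y = ys, phi = phi, z_plane = z_plane),
            class = "potential_slice")
}
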