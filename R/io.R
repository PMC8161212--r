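# File formats: PDB (via bio3d), X-PLOR PSF, XYZ and DCD trajectories,
# YAML configs and parameter sidecars, CSV/JSON reports.
#
# Conventions: coordinates in Angstrom, pore axis = z, box centred at the
# origin, extracellular side = +z. The PDB B-factor column flags fixed atoms
# (1.0 fixed / 0.0 mobile), mirroring common restraint-file usage.

.role_resid <- c(lattice = "LAT", ring_neg = "RNG", ring_pos = "RPG",
                 calp = "CAL", stretch = "STR")

#' Write a pore model to PDB
#'
#' Roles are encoded in the residue name (LAT, RNG, RPG, CAL, STR; PDB
#' residue names are a three-character field) and fixed atoms are flagged
#' with B-factor 1.0.
#'
#' @param model A `pore_model`.
#' @param file Output path.
#' @return Invisibly, the file path.
#' @export
write_pdb <- function(model, file) {
  p <- model$particles
  n <- nrow(p)
  bio3d::write.pdb(
    file = file,
    xyz = as.vector(t(as.matrix(p[, c("x", "y", "z")]))),
    resno = seq_len(n),
    resid = unname(.role_resid[p$role]),
    elety = ifelse(p$role == "calp", "CAL", "C"),
    chain = rep("A", n),
    segid = rep("MODL", n),
    b = as.numeric(p$fixed),
    o = rep(1, n))
  invisible(file)
}

#' Read a pore-model PDB
#'
#' Returns the particle table (positions, roles, fixed flags). Charges and
#' LJ parameters live in the PSF / parameter sidecar; see [read_model()].
#'
#' @param file PDB path.
#' @return A data frame with columns `x`, `y`, `z`, `role`, `fixed`.
#' @export
read_pdb <- function(file) {
  pdb <- bio3d::read.pdb(file)
  a <- pdb$atom
  role_map <- stats::setNames(names(.role_resid), .role_resid)
  data.frame(x = a$x, y = a$y, z = a$z,
             role = unname(role_map[a$resid]),
             fixed = a$b >= 0.5,
             stringsAsFactors = FALSE)
}

#' Write an X-PLOR PSF for a pore model
#'
#' Emits the atom section (id, segment, residue, atom name, type, charge,
#' mass, fixed flag) in the X-PLOR dialect; the model has no bonds.
#'
#' @param model A `pore_model`.
#' @param file Output path.
#' @return Invisibly, the file path.
#' @export
write_psf <- function(model, file) {
  p <- model$particles
  n <- nrow(p)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("PSF", "",
               sprintf("%8d !NTITLE", 1L),
               " REMARKS porelab coarse pore model", ""), con)
  writeLines(sprintf("%8d !NATOM", n), con)
  mass <- ifelse(p$role == "calp", 40.08, 12.011)
  writeLines(sprintf("%8d %-4s %-4d %-4s %-4s %-4s %14.6f %10.4f %11d",
                     seq_len(n), "MODL", seq_len(n),
                     unname(.role_resid[p$role]),
                     ifelse(p$role == "calp", "CAL", "C"),
                     ifelse(p$role == "calp", "CAL", "C"),
                     p$charge, mass, as.integer(p$fixed)), con)
  writeLines(c("", sprintf("%8d !NBOND: bonds", 0L), ""), con)
  invisible(file)
}

#' Read an X-PLOR PSF atom section
#'
#' @param file PSF path.
#' @return Data frame with `id`, `segid`, `resno`, `resid`, `name`, `type`,
#'   `charge`, `mass`, `fixed`.
#' @export
read_psf <- function(file) {
  lines <- readLines(file)
  hdr <- grep("!NATOM", lines)
  if (length(hdr) != 1)
    stop("malformed PSF: no unique !NATOM section", call. = FALSE)
  n <- as.integer(strsplit(trimws(lines[hdr]), "\\s+")[[1]][1])
  rows <- lines[(hdr + 1):(hdr + n)]
  parse_row <- function(i) {
    tok <- strsplit(trimws(rows[i]), "\\s+")[[1]]
    if (length(tok) < 8)
      stop(sprintf("malformed PSF atom record at line %d", hdr + i),
           call. = FALSE)
    data.frame(id = as.integer(tok[1]), segid = tok[2],
               resno = as.integer(tok[3]), resid = tok[4], name = tok[5],
               type = tok[6], charge = as.numeric(tok[7]),
               mass = as.numeric(tok[8]),
               fixed = length(tok) >= 9 && tok[9] == "1",
               stringsAsFactors = FALSE)
  }
  do.call(rbind, lapply(seq_len(n), parse_row))
}

#' Write a complete model directory
#'
#' Writes `model.pdb`, `model.psf`, and `model.yaml` (per-role LJ
#' parameters plus all construction specs) under `dir`; optionally a NAMD
#' configuration template exercising the constant-field mechanism.
#'
#' @param model A `pore_model`.
#' @param dir Output directory (created if missing).
#' @param namd_template Also write `namd_template.conf`.
#' @param voltage Voltage (mV) used in the NAMD template.
#' @return Invisibly, `dir`.
#' @export
write_model <- function(model, dir, namd_template = FALSE, voltage = 500) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_pdb(model, file.path(dir, "model.pdb"))
  write_psf(model, file.path(dir, "model.psf"))
  p <- model$particles
  per_role <- lapply(split(p, p$role), function(d)
    list(rmin = unique(d$rmin), epsilon = unique(d$epsilon),
         charge = unique(d$charge), count = nrow(d)))
  specs <- lapply(model$specs, function(s) if (is.null(s)) NULL else unclass(s))
  yaml::write_yaml(list(label = model$label, parameters = per_role,
                        specs = specs),
                   file.path(dir, "model.yaml"))
  if (namd_template) {
    ls <- model$specs$lattice
    ez <- voltage_to_field(voltage, ls$box_z)
    writeLines(c(
      "# NAMD template: fixed-lattice pore model under a constant field",
      "structure          model.psf",
      "coordinates        model.pdb",
      "fixedAtoms         on",
      "fixedAtomsCol      B",
      "langevin           on",
      "langevinTemp       298",
      "langevinDamping    1.0",
      "cutoff             12.0",
      sprintf("cellBasisVector1   %.1f 0 0", ls$box_x),
      sprintf("cellBasisVector2   0 %.1f 0", ls$box_y),
      sprintf("cellBasisVector3   0 0 %.1f", ls$box_z),
      "eFieldOn           yes",
      sprintf("eField             0 0 %.6f   ;# kcal/(mol A e), dV = %g mV",
              ez * 0.0230609, voltage)),
      file.path(dir, "namd_template.conf"))
  }
  invisible(dir)
}

#' Read a model directory written by [write_model()]
#'
#' @param dir Directory containing `model.pdb`, `model.psf`, `model.yaml`.
#' @return A `pore_model` equivalent to the one written.
#' @export
read_model <- function(dir) {
  tab <- read_pdb(file.path(dir, "model.pdb"))
  psf <- read_psf(file.path(dir, "model.psf"))
  meta <- yaml::read_yaml(file.path(dir, "model.yaml"))
  if (nrow(tab) != nrow(psf))
    stop("PDB/PSF atom count mismatch", call. = FALSE)
  tab$charge <- psf$charge
  pr <- meta$parameters
  tab$rmin <- vapply(tab$role, function(r) pr[[r]]$rmin[1], 0)
  tab$epsilon <- vapply(tab$role, function(r) pr[[r]]$epsilon[1], 0)
  tab <- tab[, c("x", "y", "z", "charge", "rmin", "epsilon", "role", "fixed")]
  rebuild <- function(name, cls) {
    s <- meta$specs[[name]]
    if (is.null(s)) NULL else structure(s, class = cls)
  }
  specs <- list(lattice = rebuild("lattice", "lattice_spec"),
                pore = rebuild("pore", "pore_spec"),
                rings = rebuild("rings", "ring_spec"),
                calps = rebuild("calps", "calp_spec"),
                stretch = rebuild("stretch", "stretch_spec"))
  .new_pore_model(tab, specs, label = meta$label)
}

# ---------------------------------------------------------------------------
# Trajectories

#' Write a trajectory as multi-frame XYZ
#'
#' Ions are one record per frame (`K`, `CL`); each solvent dumbbell is two
#' records (`OW` at the oxygen-equivalent site, `HW` at the opposite site)
#' so dipole vectors survive the round trip. Frame time and box are stored
#' on the comment line.
#'
#' @param traj A `bd_trajectory`.
#' @param file Output path.
#' @return Invisibly, the file path.
#' @export
write_xyz <- function(traj, file) {
  sp <- traj$metadata$species_params
  dip_mag <- if (!is.null(sp)) sp$W$dipole else 0.4893
  d_w <- if (!is.null(sp)) sp$W$d else 1.0
  con <- file(file, "w")
  on.exit(close(con))
  isw <- traj$species == "W"
  n_rec <- sum(!isw) + 2 * sum(isw)
  widx <- cumsum(isw)
  nf <- n_frames(traj)
  for (f in seq_len(nf)) {
    writeLines(sprintf("%d", n_rec), con)
    writeLines(sprintf(
      "time=%.6f box=%.4f,%.4f,%.4f dipole=%.4f d=%.4f frame=%d/%d",
      traj$times[f], traj$box[1], traj$box[2], traj$box[3],
      dip_mag, d_w, f, nf), con)
    for (p in seq_along(traj$species)) {
      xyz <- traj$coords[f, p, ]
      if (!isw[p]) {
        lab <- if (traj$species[p] == "Cl") "CL" else traj$species[p]
        writeLines(sprintf("%-3s %14.6f %14.6f %14.6f", lab,
                           xyz[1], xyz[2], xyz[3]), con)
      } else {
        u <- traj$dipoles[f, widx[p], ] / dip_mag
        h <- xyz + d_w * u
        writeLines(sprintf("%-3s %14.6f %14.6f %14.6f", "OW",
                           xyz[1], xyz[2], xyz[3]), con)
        writeLines(sprintf("%-3s %14.6f %14.6f %14.6f", "HW",
                           h[1], h[2], h[3]), con)
      }
    }
  }
  invisible(file)
}

#' Read a multi-frame XYZ trajectory written by [write_xyz()]
#'
#' @param file XYZ path.
#' @return A `bd_trajectory` (with dipoles if solvent records are present).
#' @export
read_xyz <- function(file) {
  lines <- readLines(file)
  i <- 1L
  frames <- list()
  times <- numeric()
  box <- c(NA_real_, NA_real_, NA_real_)
  dip_mag <- 0.4893; d_w <- 1
  while (i <= length(lines)) {
    n_rec <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n_rec)) stop(sprintf("malformed XYZ at line %d", i),
                           call. = FALSE)
    hdr <- lines[i + 1L]
    gv <- function(key, k = 1) {
      m <- regmatches(hdr, regexpr(paste0(key, "=[^ ]+"), hdr))
      if (length(m) == 0) return(NULL)
      as.numeric(strsplit(sub(paste0(key, "="), "", m), ",")[[1]])
    }
    times <- c(times, gv("time"))
    if (!is.null(gv("box"))) box <- gv("box")
    if (!is.null(gv("dipole"))) dip_mag <- gv("dipole")
    if (!is.null(gv("d"))) d_w <- gv("d")[1]
    rec <- lines[i + 1L + seq_len(n_rec)]
    tok <- strsplit(trimws(rec), "\\s+")
    lab <- vapply(tok, `[`, "", 1)
    xyz <- t(vapply(tok, function(tk) as.numeric(tk[2:4]), numeric(3)))
    frames[[length(frames) + 1L]] <- list(lab = lab, xyz = xyz)
    i <- i + 2L + n_rec
  }
  if (length(frames) == 0)
    return(bd_trajectory(array(numeric(), c(0, 0, 3)), character(),
                         numeric(), c(NA_real_, NA_real_, NA_real_)))
  lab <- frames[[1]]$lab
  is_o <- lab == "OW"; is_h <- lab == "HW"
  keep <- !is_h
  species <- ifelse(lab[keep] == "OW", "W",
                    ifelse(lab[keep] == "CL", "Cl", lab[keep]))
  nf <- length(frames)
  np <- sum(keep)
  nw <- sum(is_o)
  coords <- array(NA_real_, c(nf, np, 3))
  dip <- if (nw > 0) array(NA_real_, c(nf, nw, 3)) else NULL
  for (f in seq_len(nf)) {
    coords[f, , ] <- frames[[f]]$xyz[keep, , drop = FALSE]
    if (nw > 0) {
      o <- frames[[f]]$xyz[is_o, , drop = FALSE]
      h <- frames[[f]]$xyz[is_h, , drop = FALSE]
      dip[f, , ] <- (h - o) / d_w * dip_mag
    }
  }
  bd_trajectory(coords, species, times, box, dipoles = dip)
}

#' Write a trajectory in DCD format
#'
#' Binary CHARMM-style DCD of the trajectory particles (ions and solvent
#' oxygen-equivalent sites; dipoles are not representable in DCD - use
#' [write_xyz()] to preserve them). Pair with [write_traj_pdb()] for the
#' topology.
#'
#' @param traj A `bd_trajectory`.
#' @param file Output path.
#' @return Invisibly, the file path.
#' @export
write_dcd <- function(traj, file) {
  con <- file(file, "wb")
  on.exit(close(con))
  nf <- n_frames(traj)
  natom <- length(traj$species)
  dtf <- if (nf > 1) traj$times[2] - traj$times[1] else 1
  rec <- function(writer) {
    # fortran record: length prefix/suffix in bytes
    raw <- writer()
    writeBin(as.integer(length(raw)), con, size = 4)
    writeBin(raw, con)
    writeBin(as.integer(length(raw)), con, size = 4)
  }
  rec(function() {
    c(charToRaw("CORD"),
      writeBin(as.integer(c(nf, 1, 1, nf, 0, 0, 0, 0, 0)), raw(),
               size = 4),
      writeBin(as.numeric(dtf), raw(), size = 4),
      writeBin(as.integer(c(0, 0, 0, 0, 0, 0, 0, 0, 0, 24)), raw(),
               size = 4))
  })
  rec(function() {
    title <- sprintf("%-80s", "porelab trajectory")
    c(writeBin(1L, raw(), size = 4), charToRaw(title))
  })
  rec(function() writeBin(as.integer(natom), con = raw(), size = 4))
  for (f in seq_len(nf)) {
    for (d in 1:3) {
      rec(function() writeBin(as.numeric(traj$coords[f, , d]), raw(),
                              size = 4))
    }
  }
  invisible(file)
}

#' Read a DCD trajectory
#'
#' Thin wrapper over [bio3d::read.dcd()]; species labels must be supplied
#' (or a topology PDB written by [write_traj_pdb()]).
#'
#' @param file DCD path.
#' @param species Character vector of per-particle species, or `NULL` with
#'   `topology` given.
#' @param topology Optional topology PDB path.
#' @param box Length-3 box (A); defaults to an uninformative large box.
#' @param dt_frame Frame spacing in ps.
#' @return A `bd_trajectory` (no dipoles).
#' @export
read_dcd <- function(file, species = NULL, topology = NULL,
                     box = c(1e4, 1e4, 1e4), dt_frame = 1) {
  xyz <- bio3d::read.dcd(file, verbose = FALSE)
  nf <- nrow(xyz)
  np <- ncol(xyz) / 3
  if (is.null(species)) {
    if (is.null(topology)) stop("give species or a topology PDB",
                                call. = FALSE)
    a <- bio3d::read.pdb(topology)$atom
    species <- ifelse(a$resid == "WAT", "W",
                      ifelse(a$resid == "CLA", "Cl", "K"))
  }
  coords <- array(NA_real_, c(nf, np, 3))
  for (f in seq_len(nf)) coords[f, , ] <- matrix(xyz[f, ], ncol = 3,
                                                 byrow = TRUE)
  bd_trajectory(coords, species, times = (seq_len(nf) - 1) * dt_frame, box)
}

#' Write a topology PDB for a trajectory
#'
#' One atom per trajectory particle (first-frame coordinates); residue
#' names POT/CLA/WAT identify the species.
#'
#' @param traj A `bd_trajectory`.
#' @param file Output path.
#' @return Invisibly, the file path.
#' @export
write_traj_pdb <- function(traj, file) {
  n <- length(traj$species)
  resid <- ifelse(traj$species == "W", "WAT",
                  ifelse(traj$species == "Cl", "CLA", "POT"))
  xyz <- if (n_frames(traj) > 0) traj$coords[1, , , drop = TRUE]
         else matrix(0, n, 3)
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
  bio3d::write.pdb(file = file,
                   xyz = as.vector(t(xyz)),
                   resno = seq_len(n), resid = resid,
                   elety = ifelse(traj$species == "W", "OH2",
                                  traj$species),
                   chain = rep("A", n), segid = rep("MOBL", n),
                   b = rep(0, n), o = rep(1, n))
  invisible(file)
}

# ---------------------------------------------------------------------------
# Configs and reports

#' Write / read a run configuration
#'
#' A run is reproducible from its configuration and seeds alone; the YAML
#' stores the model label, engine settings, field, analysis selections and
#' the seed list.
#'
#' @param config A named list (any nesting of scalars/vectors/lists).
#' @param file YAML path.
#' @return `write_run_config` returns the path invisibly; `read_run_config`
#'   the restored list.
#' @export
write_run_config <- function(config, file) {
  yaml::write_yaml(config, file)
  invisible(file)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(file) yaml::read_yaml(file)

#' Write an analysis report
#'
#' @param x A data frame (CSV) or any list/data frame (JSON).
#' @param file Output path; format chosen by extension (`.csv` or `.json`).
#' @return Invisibly, the file path.
#' @export
write_report <- function(x, file) {
  if (grepl("\\.json$", file, ignore.case = TRUE)) {
    jsonlite::write_json(x, file, auto_unbox = TRUE, digits = NA,
                         na = "null")
  } else {
    utils::write.csv(x, file, row.names = FALSE)
  }
  invisible(file)
}
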