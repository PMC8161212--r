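# Specification objects for model construction. All lengths in Angstrom,
# charges in e. Constructors validate; builders consume.

#' Lattice specification
#'
#' Geometry of the carbon-lattice membrane slab: a body-centred cubic (BCC)
#' array of neutral sp2 carbons filling a slab centred at z = 0, inside a
#' periodic box.
#'
#' @param box_x,box_y,box_z Box edge lengths in Angstrom.
#' @param slab_thickness Thickness of the carbon slab along z (the pore
#'   length). The slab is centred at z = 0.
#' @param spacing Cubic lattice constant in Angstrom.
#' @return An object of class `lattice_spec`.
#' @export
lattice_spec <- function(box_x = 50, box_y = 50, box_z = 130,
                         slab_thickness = 75, spacing = 4) {
  if (spacing <= 0) stop("lattice spacing must be positive", call. = FALSE)
  if (slab_thickness <= 0 || slab_thickness > box_z)
    stop("slab_thickness must be in (0, box_z]", call. = FALSE)
  structure(list(box_x = box_x, box_y = box_y, box_z = box_z,
                 slab_thickness = slab_thickness, spacing = spacing),
            class = "lattice_spec")
}

#' Pore specification
#'
#' A straight cylindrical pore along z through the box centre. The diameter is
#' the centre-to-centre distance between opposite wall carbons.
#'
#' @param diameter Pore diameter in Angstrom (centre-to-centre).
#' @return An object of class `pore_spec`.
#' @export
pore_spec <- function(diameter = 20) {
  if (diameter < 0) stop("diameter must be >= 0", call. = FALSE)
  structure(list(diameter = diameter), class = "pore_spec")
}

#' Charged-ring specification
#'
#' Two rings of pore-wall carbons carry partial charges: -q per atom on the
#' extracellular (+z) side and +q per atom on the cytoplasmic (-z) side, so a
#' calcium-free model is net neutral. Positions default to +/- 0.35 x slab
#' thickness, near the two pore mouths.
#'
#' @param z_extracellular,z_cytoplasmic Ring z positions in Angstrom. `NULL`
#'   means +/- 0.35 x slab thickness of the model being decorated.
#' @param q Charge magnitude per ring atom in e (extracellular ring gets -q,
#'   cytoplasmic +q).
#' @param n_atoms_per_ring Atoms per ring; `NULL` uses every wall atom in the
#'   lattice layer nearest the ring plane (counts are forced equal between the
#'   two rings).
#' @return An object of class `ring_spec`.
#' @export
ring_spec <- function(z_extracellular = NULL, z_cytoplasmic = NULL,
                      q = 0.2, n_atoms_per_ring = NULL) {
  if (q < 0) stop("ring charge magnitude must be >= 0", call. = FALSE)
  structure(list(z_extracellular = z_extracellular,
                 z_cytoplasmic = z_cytoplasmic,
                 q = q, n_atoms_per_ring = n_atoms_per_ring),
            class = "ring_spec")
}

#' Calcium-like particle (CaLP) specification
#'
#' Six fixed point charges on a ring of radius `ring_radius` in the
#' extracellular half of the pore, standing in for the crystallographic ring
#' of bound calcium ions. The default radius 10.5 A gives an opposite-site
#' centre-to-centre distance of 21 A. Allowed charge levels are 0, +0.2,
#' +0.4 and +0.6 e per site (labels X0-X3).
#'
#' @param charge_per_site Charge in e per CaLP site.
#' @param n_sites Number of sites, equally spaced azimuthally.
#' @param ring_radius Ring radius in Angstrom.
#' @param z_position z of the CaLP ring; `NULL` means +0.25 x slab thickness.
#' @param allow_any_charge Permit charges outside \{0, 0.2, 0.4, 0.6\}.
#' @return An object of class `calp_spec`.
#' @export
calp_spec <- function(charge_per_site = 0, n_sites = 6, ring_radius = 10.5,
                      z_position = NULL, allow_any_charge = FALSE) {
  allowed <- c(0, 0.2, 0.4, 0.6)
  if (!allow_any_charge && !any(abs(charge_per_site - allowed) < 1e-9))
    stop("charge_per_site must be one of 0, 0.2, 0.4, 0.6 e ",
         "(or set allow_any_charge = TRUE)", call. = FALSE)
  if (n_sites < 0) stop("n_sites must be >= 0", call. = FALSE)
  lev <- which.min(abs(charge_per_site - allowed)) - 1L
  label <- if (!allow_any_charge || any(abs(charge_per_site - allowed) < 1e-9))
    paste0("X", lev) else sprintf("Xq%.3g", charge_per_site)
  structure(list(n_sites = as.integer(n_sites),
                 charge_per_site = charge_per_site,
                 ring_radius = ring_radius, z_position = z_position,
                 level_label = label),
            class = "calp_spec")
}

#' Pore-stretching specification
#'
#' Wall atoms in a band around the pore mid-height get an enlarged
#' Lennard-Jones `rmin` (the like-pair minimum-energy distance), narrowing the
#' water-accessible pore without moving any atom. `rmin = 4` (the sp2 carbon
#' value) means no stretching.
#'
#' @param rmin Like-pair LJ rmin in Angstrom for the stretch atoms; one of
#'   4 (none), 8, 10, 12, 14, 16 in the standard series, but any value >= 4
#'   is accepted.
#' @param z_half_width Half-width in Angstrom of the z band (centred at z = 0)
#'   whose wall atoms are stretched.
#' @return An object of class `stretch_spec`.
#' @export
stretch_spec <- function(rmin = 4, z_half_width = 4) {
  if (rmin < 4) stop("stretch rmin must be >= 4 A (the sp2 carbon value)",
                     call. = FALSE)
  structure(list(rmin = rmin, z_half_width = z_half_width),
            class = "stretch_spec")
}

# Map the standard rmin series to the effective-diameter labels used for
# model names (measured from the water distribution in the reference series).
.rmin_diameter_label <- function(rmin) {
  map <- c("4" = 17, "8" = 13, "10" = 11, "12" = 9, "14" = 7, "16" = 5)
  key <- as.character(rmin)
  if (key %in% names(map)) paste0("d", map[[key]]) else paste0("rmin", rmin)
}
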