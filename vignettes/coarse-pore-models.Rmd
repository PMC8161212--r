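---
title: "Coarse hemichannel pore models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse hemichannel pore models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Connexin hemichannels are wide, weakly selective channels connecting the
cytoplasm to the extracellular space; extracellular Ca2+ drives them closed.
Two candidate mechanisms are debated: a purely electrostatic block by the
ring of bound calcium ions, and a physical narrowing (stretching) of the
pore. `porelab` implements a minimal-model laboratory for separating the
two: a rigid carbon-lattice "membrane" with a cylindrical pore, decorated
with (i) fixed partial-charge rings reproducing the channel's inner surface
polarity, (ii) a hexagonal ring of fixed "calcium-like particles" (CaLPs)
whose charge can be dialled from 0 to +0.6 e per site, and (iii) a band of
wall atoms with enlarged Lennard-Jones radii that constrict the pore
without moving a single atom. Ions and a coarse dipolar solvent move
through this fixed scaffold under Langevin dynamics and a constant
transmembrane field, and the package measures the quantities that
characterise channel function: permeation events and rates, axial and
radial density profiles, water survival probability, dipole orientation
along the pore axis (DZ), and dipole orientational relaxation.

## Model construction

The membrane is a body-centred cubic lattice of neutral sp2-like carbons
(spacing 4 Å) filling a slab centred at z = 0 inside a periodic box
(default 50 × 50 × 130 Å). The slab thickness is not uniquely dictated by
the biology; the default 75 Å approximates the length of a hemichannel and
is configurable. The pore is "drilled" by deleting every lattice atom
within 10 Å of the z axis. Because no lattice site falls exactly on the
10 Å circle, the measured centre-to-centre diameter of the drilled pore is
20.4 Å rather than exactly 20 Å — within half a lattice spacing, which is
the natural resolution of any lattice construction.

Design choices where the construction was genuinely open:

* **Ring positions.** The charged rings (−0.2 e per atom extracellular,
  +0.2 e cytoplasmic) sit on the wall layer nearest ±0.35 × slab
  thickness, near the two mouths. Equal atom counts per ring are enforced
  so the calcium-free model is exactly neutral.
* **CaLP placement.** Six sites, 60° apart, on a circle of radius 10.5 Å
  (opposite-site distance 21 Å) at +0.25 × slab thickness — in the
  extracellular half, clearly separated from the central stretch band.
  CaLPs carry carbon-like LJ parameters so mobile ions cannot collapse
  onto a bare point charge.
* **Stretch band.** Wall atoms with |z| ≤ 4 Å (one lattice period each
  side of the mid-plane) receive the enlarged `rmin`. `rmin` is read as
  the *like-pair* minimum-energy distance (4 Å for carbon–carbon), with
  Lorentz–Berthelot combination for cross terms.
* **Neutralisation.** CaLP-charged models have net charges of +1.2, +2.4
  or +3.6 e. Whole counterions cannot cancel a fractional charge; the
  solvation plan adds ⌈net⌉ extra Cl− and reports the sub-elementary
  residual rather than rescaling any charge.

Model building involves no randomness: the 24-model grid (4 charge levels
X0–X3 × 6 stretch radii) is bit-for-bit reproducible.

## The dynamics engine

The engine is a desk-scale Langevin integrator, not a molecular dynamics
package: its purpose is to make the model's qualitative physics testable
in minutes on one CPU.

* **Integrator.** BAOAB splitting of Langevin dynamics at T = 298 K with
  friction 1 ps⁻¹; default time step 5 fs. The solvent is a rigid two-site
  dumbbell propagated by a rotational Langevin update of its axis
  (Rodrigues rotations of the unit axis by the angular velocity, which is
  kept perpendicular to the axis).
* **Interactions.** 12-6 Lennard-Jones, truncated at 12 Å with the energy
  shifted to zero at the cutoff, plus shifted-force Coulomb (both the
  potential and the force go continuously to zero at 12 Å). Minimum-image
  periodic boundaries in all three dimensions. No Ewald summation: the
  engine trades long-range accuracy for speed, which is acceptable for
  qualitative trends but is one reason absolute rates are not comparable
  to all-atom results.
* **Coarse solvent.** A net-neutral dumbbell with charges ±0.489 e
  separated by 1 Å (a 2.35 D dipole equivalent), water-like LJ sites
  (σ = 3.15 Å, ε = 0.152 kcal/mol) on both sites and site masses of 9 amu.
  The default number density, 0.0042 dumbbells/Å³, is a deliberately
  coarse mapping (roughly one bead per eight waters by count): it keeps a
  full solvated default system near 700 dumbbells so that equilibrium
  density profiles converge in minutes. At these dilutions the shape of
  the density profile against the pore wall is controlled by the
  wall–solvent potential, not by solvent–solvent packing, which is what
  the effective-diameter measurement needs. The dumbbell does not
  reproduce TIP3P thermodynamics and is not meant to.
* **Ion model.** K+ and Cl− carry their formal ±1 e charges, but two
  corrections standard in coarse and implicit-solvent ion modelling are
  applied: hydrated (Nightingale) radii (rmin/2 = 3.31 and 3.32 Å) in
  place of bare crystallographic radii, and an electronic-continuum
  background dielectric of 1.78 (the optical permittivity of water)
  dividing all charge–charge interactions. Without them, a nonpolarizable
  model with unresolved hydration shells condenses 150 mM KCl into
  permanently bound contact pairs (binding ≈ 60 kT) and there are no free
  carriers at all; with them, ion pairing is reversible and field-driven
  transport exists. `pair_forces()` defaults to `dielectric = 1` so the
  raw Coulomb kernel can be validated against the textbook constant.
* **Control potential.** The ion-exclusion control applies a z-directed
  force of at most 5 kcal/mol/Å at the pore mid-height, decaying linearly
  to zero at the mouths, to ions only. The protocol it reproduces states
  the maximum as "5 kcal/mol" without a length in the denominator; it is
  read here as a force, 5 kcal/mol/Å. Because the ramp vanishes at the
  entrances, ions still sample the outermost 2–3 Å of the vestibules (the
  integrated barrier there is under 1 kT); "excluding ions from the pore"
  means the pore interior, which the control empties completely.
* **Determinism.** Every random number (placement, initial velocities,
  thermostat noise) derives from the single integer seed in
  `engine_config()`; identical seeds give identical trajectories.
  Replicas are three seeds.

## Trajectory statistics

* **Permeation.** A four-state automaton (above / pore / below /
  membrane) on box-folded coordinates counts one event per continuous
  passage that enters at one mouth inside the wall radius and exits at the
  other; events are credited at exit with direction (ext→int is +z to
  −z). Passages through the lattice outside the pore radius, and
  re-entries to the same side, never count. A particle that jumps between
  reservoirs across the periodic z boundary is recognised by its ~Lz
  coordinate jump and is not an event; a same-frame jump *through* the
  slab would indicate frames coarser than the transit and triggers an
  undercount warning. Rates are counts divided by simulation time, with
  the population SD across replicas.
* **Densities.** 0.5 Å bins; axial profiles are per-bin counts averaged
  over frames; radial profiles additionally divide by the cylindrical
  shell volume before normalising (the only reading under which a profile
  in "atoms/Å³" can then be area-normalised). All profiles are normalised
  by the area under the curve to exactly 1.
* **Survival probability.** Multi-time-origin product form: a particle
  contributes at lag t if continuously inside the region for t frames
  after an origin at which it was inside; Q is reported normalised to
  Q(0) = 1 (the fitted decay time is invariant to this).
* **Exponential fits** use Levenberg–Marquardt least squares initialised
  from a log-linear regression, with points below 0.01 × max excluded
  (floor and window are recorded); constant curves flag τ = ∞, rising
  curves flag a fit failure.
* **Dipole statistics.** DZ per 0.5 Å z-bin is Σμz / Σ|μ| over loaded
  solvent and frames; the orientational autocorrelation averages
  ê(t0+t)·ê(t0) over particles loaded at each origin.
* **Effective diameter.** Twice the outermost radius at which the radial
  water density at the constriction still reaches 10% of its peak
  (linearly interpolated between bin centres). The threshold definition
  (rather than, say, a first moment) follows from the "water-accessible
  width" reading; 0.1 is the package default and is configurable.
* **Electrostatic slices** are direct vacuum Coulomb sums of the fixed
  model charges on a 1 Å grid (no periodic images); they map the bare
  model field, so no dielectric correction is applied there.

## What the synthetic fixtures do and do not show

The `gen_*` generators produce trajectories whose ground truth is known in
closed form: scripted crossing counts, geometric residence times
(τ = −Δt/ln(1−p)), aligned/isotropic/rotationally-diffusing dipoles
(τμ = 1/(2 Dr)), and uniform clouds/cylinders for flat density profiles.
They validate the *analysis* operations exactly, independent of the
engine. They do not emulate interacting-particle physics: passing the
fixture suite shows the statistics are computed correctly, not that the
engine's physics matches any particular real system.

## Problem sizes used by the tests and the acceptance script

All study-condition parameters (geometry, charges, temperatures,
densities) are the defaults above. Run lengths and box sizes are scaled to
the package's intended desk-scale budget:

* Effective-diameter runs in the test suite use a compact geometry
  (40 × 40 × 100 Å box, 40 Å slab — identical pore, rings, CaLPs and
  stretch band) with ~8,000 steps per seed, 3 seeds; the acceptance
  script uses the full default geometry with 3 seeds × (10,000
  equilibration + 50,000 production) steps.
* Permeation-trend runs use a thin-slab geometry (40 × 40 × 80 Å box,
  24 Å slab) so that a slab transit takes ~20 ps and events accumulate
  quickly; each condition is 3 seeds × 18,000 steps (90 ps), with counts
  pooled across seeds. The ion-exclusion control comparison is 3 seeds ×
  12,000 steps per arm, evaluated over the equilibrated second half of
  each run.

These sizes are stated here because they are part of the reported
conditions: trends measured at this scale are qualitative, and absolute
rates are not comparable to multi-nanosecond all-atom simulations.

## Known limitations

* Truncated (non-Ewald) electrostatics and the uniform background
  dielectric are crude; electrostatic barrier heights are only
  order-of-magnitude faithful.
* The coarse solvent has no hydrogen-bond network; survival probabilities
  and rotational relaxation times are internally consistent but much
  faster than real confined water.
* Ion currents at 150 mM in a 40 Å box involve ~10 ions of each species;
  trend tests therefore compare pooled counts over seeds, not converged
  single-channel conductances.
* The all-atom calcium-bound hemichannel system, lipid membranes and
  crystallographic modelling are out of scope.
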