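# Internal unit system: length in Angstrom, time in ps, mass in amu,
# energy in kcal/mol, charge in units of the elementary charge e.

#' Physical constants used by porelab
#'
#' A named list of the constants that define the package's unit system:
#' `kB` (Boltzmann constant, kcal/mol/K), `coulomb` (Coulomb constant,
#' kcal.A/(mol.e^2)), `f_conv` (kcal/mol/A to amu.A/ps^2),
#' `emv_per_A` (force on 1 e in a 1 mV/A field, kcal/mol/A) and
#' `avogadro` (1/mol).
#'
#' @export
porelab_constants <- function() {
  list(
    kB       = 0.001987204259,
    coulomb  = 332.0636,
    f_conv   = 418.4,
    emv_per_A = 0.0230609,
    avogadro = 6.02214076e23
  )
}

.kB       <- 0.001987204259
.COULOMB  <- 332.0636
.F_CONV   <- 418.4   # 1 kcal/mol = 418.4 amu A^2/ps^2
.EMV      <- 0.0230609 # 1 e * (1 mV/A) = 0.0230609 kcal/mol/A
.AVOGADRO <- 6.02214076e23
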