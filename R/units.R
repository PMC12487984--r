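#' @keywords internal
"_PACKAGE"

## Canonical internal unit system: Angstrom, femtosecond, amu, kcal/mol.
## Conversions happen only at I/O boundaries.

#' Physical constants of the package unit system
#'
#' The package works in Angstrom / femtosecond / amu / kcal mol^-1 throughout.
#' `kB` is the Boltzmann constant in kcal mol^-1 K^-1, and `acc_unit` converts
#' an acceleration expressed as (kcal mol^-1 A^-1) / amu into A fs^-2.
#'
#' @return Named list with elements `kB` and `acc_unit`.
#' @examples
#' cg_units()$kB * 300  # thermal energy at 300 K in kcal/mol
#' @export
cg_units <- function() {
  list(kB = 1.987204259e-3,  # kcal mol^-1 K^-1
       acc_unit = 4.184e-4)  # (kcal mol^-1 A^-1 / amu) -> A fs^-2
}

.kB <- 1.987204259e-3
.acc_unit <- 4.184e-4
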