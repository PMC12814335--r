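#' Physical constants and unit conversions
#'
#' All internal quantities are in Hartree atomic units (bohr for length,
#' hartree for energy). Wavenumbers (cm^-1) appear only in reported results.
#'
#' @format Named numeric constants:
#' \describe{
#'   \item{bohr_per_angstrom}{1.8897259886 bohr per angstrom (CODATA).}
#'   \item{wavenumber_per_hartree}{219474.6313632 cm^-1 per hartree.}
#' }
#' @name units
NULL

BOHR_PER_ANGSTROM <- 1.8897259886
WAVENUMBER_PER_HARTREE <- 219474.6313632

#' Convert angstrom to bohr
#' @param x length(s) in angstrom
#' @return length(s) in bohr
#' @export
angstrom_to_bohr <- function(x) x * BOHR_PER_ANGSTROM

#' Convert bohr to angstrom
#' @param x length(s) in bohr
#' @return length(s) in angstrom
#' @export
bohr_to_angstrom <- function(x) x / BOHR_PER_ANGSTROM

#' Convert hartree to wavenumbers
#' @param x energy in hartree
#' @return energy in cm^-1
#' @export
hartree_to_wavenumber <- function(x) x * WAVENUMBER_PER_HARTREE
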