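# Physical constants (CODATA 2018) and unit conversions.
#
# Internal unit conventions, used consistently across the package:
#   coordinates   Angstrom
#   energies      Hartree
#   gradients     Hartree/Bohr (conversion happens at the theory boundary)
#   masses        amu (most-abundant isotope by default)
#   charges       elementary charge e
#   dipoles       atomic units (e * Bohr), origin at the Cartesian origin
#   time (MD)     fs at the interface, atomic time units internally

#' Unit conversion constants
#'
#' Named list of the physical constants and conversion factors used
#' throughout the package (CODATA 2018 values).
#'
#' @format A named list:
#' \describe{
#'   \item{bohr_to_ang}{Bohr radius in Angstrom.}
#'   \item{hartree_to_kcalmol}{Hartree in kcal/mol.}
#'   \item{hartree_to_J}{Hartree in Joule.}
#'   \item{hartree_to_cm1}{Hartree in cm^-1.}
#'   \item{amu_to_me}{Atomic mass unit in electron masses.}
#'   \item{kB_hartree}{Boltzmann constant in Hartree/K.}
#'   \item{au_time_fs}{Atomic time unit in fs.}
#'   \item{amu_to_kg, kB_SI, h_SI, NA_SI, c_SI}{SI helpers for thermochemistry.}
#'   \item{ir_kmmol}{IR intensity conversion, km/mol per (e^2/amu).}
#' }
#' @export
units_au <- list(
  bohr_to_ang        = 0.529177210903,
  hartree_to_kcalmol = 627.5094740631,
  hartree_to_J       = 4.3597447222071e-18,
  hartree_to_cm1     = 219474.6313632,
  amu_to_me          = 1822.888486209,
  kB_hartree         = 3.166811563e-6,
  au_time_fs         = 2.4188843265857e-2,
  amu_to_kg          = 1.66053906660e-27,
  kB_SI              = 1.380649e-23,
  h_SI               = 6.62607015e-34,
  NA_SI              = 6.02214076e23,
  c_SI               = 2.99792458e10,   # cm/s
  ir_kmmol           = 974.8801118057   # km/mol per (e^2 amu^-1) dipole-derivative^2
)

#' Convert between Angstrom and Bohr
#'
#' @param x numeric vector/matrix of lengths.
#' @return converted values.
#' @export
ang_to_bohr <- function(x) x / units_au$bohr_to_ang

#' @rdname ang_to_bohr
#' @export
bohr_to_ang <- function(x) x * units_au$bohr_to_ang

#' Convert between Hartree and kcal/mol
#'
#' @param x numeric energies.
#' @return converted values.
#' @export
hartree_to_kcalmol <- function(x) x * units_au$hartree_to_kcalmol

#' @rdname hartree_to_kcalmol
#' @export
kcalmol_to_hartree <- function(x) x / units_au$hartree_to_kcalmol
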