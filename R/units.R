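#' Physical constants and unit conversions
#'
#' All internal quantities are in Hartree atomic units (bohr, hartree, e).
#' Geometry files on disk use angstrom; excitation energies are reported in
#' electron-volt at the output boundary only.
#'
#' @name units
#' @keywords internal
NULL

## CODATA-style factors; fixed once for the whole package.
ANGSTROM_PER_BOHR <- 0.52917721092
EV_PER_HARTREE <- 27.211386245988

#' Convert angstrom to bohr
#' @param x numeric vector/matrix in angstrom.
#' @return same shape, bohr.
#' @export
ang_to_bohr <- function(x) x / ANGSTROM_PER_BOHR

#' Convert bohr to angstrom
#' @param x numeric vector/matrix in bohr.
#' @return same shape, angstrom.
#' @export
bohr_to_ang <- function(x) x * ANGSTROM_PER_BOHR

#' Convert hartree to electron-volt
#' @param x numeric, hartree.
#' @return numeric, eV.
#' @export
hartree_to_ev <- function(x) x * EV_PER_HARTREE

#' Convert electron-volt to hartree
#' @param x numeric, eV.
#' @return numeric, hartree.
#' @export
ev_to_hartree <- function(x) x / EV_PER_HARTREE
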