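#' Unit conversion constants
#'
#' All internal quantities are in atomic units (Hartree, Bohr); kcal/mol and
#' Angstrom appear only at report boundaries. `HARTREE_PER_KCAL` is the inverse
#' of `KCAL_PER_HARTREE` to better than 1e-12 relative.
#'
#' @format Named numeric scalars.
#' @name units
NULL

#' @rdname units
#' @export
KCAL_PER_HARTREE <- 627.509

#' @rdname units
#' @export
ANGSTROM_PER_BOHR <- 0.529177

#' @rdname units
#' @export
EV_PER_HARTREE <- 27.2114

#' Convert Hartree to kcal/mol
#' @param x numeric, Hartree
#' @return numeric, kcal/mol
#' @export
hartree_to_kcal <- function(x) x * KCAL_PER_HARTREE

#' Convert kcal/mol to Hartree
#' @param x numeric, kcal/mol
#' @return numeric, Hartree
#' @export
kcal_to_hartree <- function(x) x / KCAL_PER_HARTREE

#' Convert Bohr to Angstrom
#' @param x numeric, Bohr
#' @return numeric, Angstrom
#' @export
bohr_to_angstrom <- function(x) x * ANGSTROM_PER_BOHR

#' Convert Angstrom to Bohr
#' @param x numeric, Angstrom
#' @return numeric, Bohr
#' @export
angstrom_to_bohr <- function(x) x / ANGSTROM_PER_BOHR

# Round half away from zero (table-matching rounding; base round() ties to even)
#' Round half away from zero
#'
#' Rounding used in table-matching report mode: ties round away from zero,
#' matching how the reference tables print e.g. |v|/G ratios.
#'
#' @param x numeric
#' @param digits integer, decimal places
#' @return numeric
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
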