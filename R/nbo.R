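#' Second-order perturbation stabilization energy
#'
#' NBO donor-to-acceptor hyperconjugation energy
#' `E(2) = n_sigma * F_ij^2 / (eps_acceptor - eps_donor)`, reported as a
#' positive magnitude in kcal/mol (the sign convention of published E(2)
#' tables). Occupancy must lie in (0, 2]; accepted records have the
#' acceptor above the donor, and a degenerate denominator is an error.
#'
#' @param n_sigma donor-orbital occupancy, electrons
#' @param fock Fock matrix element F_ij, a.u.
#' @param eps_donor donor orbital energy, a.u.
#' @param eps_acceptor acceptor orbital energy, a.u.
#' @return E(2), kcal/mol (magnitude)
#' @export
e2_stabilization <- function(n_sigma, fock, eps_donor, eps_acceptor) {
  if (any(n_sigma <= 0) || any(n_sigma > 2)) {
    stop("occupancy must lie in (0, 2]")
  }
  denom <- eps_acceptor - eps_donor
  if (any(denom == 0)) stop("degenerate donor/acceptor energies")
  if (any(denom < 0)) stop("acceptor energy must exceed donor energy")
  hartree_to_kcal(n_sigma * fock^2 / denom)
}
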