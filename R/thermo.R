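#' Bond dissociation enthalpy (HAT mechanism)
#'
#' `BDE = H_Aradical + H_Hradical - H_AH`, converted to kcal/mol. The lowest
#' BDE identifies the O-H group most susceptible to hydrogen-atom transfer.
#'
#' @param ledger an [enthalpy_ledger()]
#' @param site site label, e.g. `"O3H"`
#' @return BDE, kcal/mol
#' @export
bde <- function(ledger, site) {
  hartree_to_kcal(
    ledger_species(ledger, site, "H_Aradical") +
      ledger_reference(ledger, "H_Hradical") -
      ledger_species(ledger, site, "H_AH"))
}

#' Ionization potential (SET-PT, first step)
#'
#' `IP = H_cation + H_electron - H_AH` in kcal/mol.
#'
#' @inheritParams bde
#' @return IP, kcal/mol
#' @export
ip <- function(ledger, site) {
  hartree_to_kcal(
    ledger_species(ledger, site, "H_cation") +
      ledger_reference(ledger, "H_electron") -
      ledger_species(ledger, site, "H_AH"))
}

#' Proton dissociation enthalpy (SET-PT, second step)
#'
#' `PDE = H_Aradical + H_proton - H_cation` in kcal/mol.
#'
#' @inheritParams bde
#' @return PDE, kcal/mol
#' @export
pde <- function(ledger, site) {
  hartree_to_kcal(
    ledger_species(ledger, site, "H_Aradical") +
      ledger_reference(ledger, "H_proton") -
      ledger_species(ledger, site, "H_cation"))
}

#' Proton affinity (SPLET, first step)
#'
#' `PA = H_anion + H_proton - H_AH` in kcal/mol.
#'
#' @inheritParams bde
#' @return PA, kcal/mol
#' @export
pa <- function(ledger, site) {
  hartree_to_kcal(
    ledger_species(ledger, site, "H_anion") +
      ledger_reference(ledger, "H_proton") -
      ledger_species(ledger, site, "H_AH"))
}

#' Electron transfer enthalpy (SPLET, second step)
#'
#' `ETE = H_Aradical + H_electron - H_anion` in kcal/mol.
#'
#' @inheritParams bde
#' @return ETE, kcal/mol
#' @export
ete <- function(ledger, site) {
  hartree_to_kcal(
    ledger_species(ledger, site, "H_Aradical") +
      ledger_reference(ledger, "H_electron") -
      ledger_species(ledger, site, "H_anion"))
}

#' Relative solution enthalpy
#'
#' `dH = H_solution - H_vacuum`, converted to kcal/mol. Applied over a
#' solvent series it tracks the stabilisation of the solute with dielectric
#' constant.
#'
#' @param h_solution enthalpy in solution, Hartree (vectorised)
#' @param h_vacuum enthalpy in vacuum, Hartree
#' @return kcal/mol
#' @export
relative_solution_enthalpy <- function(h_solution, h_vacuum) {
  hartree_to_kcal(h_solution - h_vacuum)
}

#' Percent difference relative to a reference
#'
#' `100 * (value - reference) / reference`. A zero reference is an error.
#'
#' @param value numeric
#' @param reference numeric, same units
#' @return percent
#' @export
percent_difference <- function(value, reference) {
  if (any(reference == 0)) stop("reference must be nonzero")
  100 * (value - reference) / reference
}

#' Explicit-water effect on bond dissociation enthalpies
#'
#' Compares per-site BDEs without and with explicitly coordinated water:
#' per-site percent changes, percent change of the mean, sample (n-1)
#' standard deviations of both vectors and the percent change in SD (the
#' dispersion of site reactivities). The sample convention is deliberate:
#' it is the convention under which the luteolin reference dispersion
#' (5.04 to 5.40 kcal/mol) reproduces.
#'
#' @param bde_no_water numeric vector, kcal/mol (length >= 2)
#' @param bde_water numeric vector, same length and site order
#' @param sites optional site labels
#' @return object of class `water_effect_stats`: list with `per_site_pct`,
#'   `mean_no_water`, `mean_water`, `mean_pct`, `sd_no_water`, `sd_water`,
#'   `sd_pct`
#' @export
water_effect <- function(bde_no_water, bde_water, sites = NULL) {
  if (length(bde_no_water) != length(bde_water)) {
    stop("BDE vectors differ in length")
  }
  if (length(bde_no_water) < 2) stop("need at least two sites")
  per_site <- percent_difference(bde_water, bde_no_water)
  if (!is.null(sites)) names(per_site) <- sites
  m0 <- mean(bde_no_water)
  m1 <- mean(bde_water)
  s0 <- stats::sd(bde_no_water)
  s1 <- stats::sd(bde_water)
  structure(
    list(per_site_pct = per_site,
         mean_no_water = m0, mean_water = m1,
         mean_pct = percent_difference(m1, m0),
         sd_no_water = s0, sd_water = s1,
         sd_pct = percent_difference(s1, s0)),
    class = "water_effect_stats"
  )
}

#' @export
print.water_effect_stats <- function(x, ...) {
  cat(sprintf(
    "<water_effect_stats> mean %.3f -> %.3f kcal/mol (%+.2f%%); SD %.2f -> %.2f (%+.2f%%)\n",
    x$mean_no_water, x$mean_water, x$mean_pct,
    x$sd_no_water, x$sd_water, x$sd_pct))
  invisible(x)
}

#' Mechanism comparison table for one ledger
#'
#' Per-site BDE, IP, PDE, PA, ETE and the summed descriptors IP+PDE and
#' PA+ETE (kcal/mol), plus the preferred abstraction site (argmin BDE) and
#' preferred mechanism: the argmin over the compound minima of
#' \{BDE, IP+PDE, PA+ETE\}, i.e. HAT vs SET-PT vs SPLET on purely enthalpic
#' grounds. Ties resolve to the lowest site index / first mechanism and are
#' flagged.
#'
#' @param ledger an [enthalpy_ledger()]
#' @param sites site labels; default all ledger sites
#' @param tie_tol absolute tolerance for tie detection, kcal/mol
#' @return object of class `mechanism_table`: list with `table`
#'   (data.frame), `preferred_site`, `preferred_mechanism`, `site_tie`,
#'   `mechanism_tie`, `compound`, `environment`
#' @export
mechanism_summary <- function(ledger, sites = ledger_sites(ledger),
                              tie_tol = 1e-9) {
  if (length(sites) == 0) stop("no sites to summarise")
  gaps <- character(0)
  for (s in sites) {
    sv <- ledger$sites[[s]]
    if (is.null(sv)) {
      gaps <- c(gaps, paste0(s, ": site absent"))
      next
    }
    need <- c("H_AH", "H_Aradical", "H_cation", "H_anion")
    miss <- setdiff(need, names(sv))
    if (length(miss)) gaps <- c(gaps, paste0(s, ": ",
                                             paste(miss, collapse = ", ")))
  }
  for (r in c("H_Hradical", "H_proton", "H_electron")) {
    if (!r %in% names(ledger$references)) {
      gaps <- c(gaps, paste0("reference: ", r))
    }
  }
  if (length(gaps)) {
    stop("incomplete ledger for ", ledger$compound, "/",
         ledger$environment, " - ", paste(gaps, collapse = "; "))
  }

  tab <- data.frame(
    site = sites,
    BDE = vapply(sites, function(s) bde(ledger, s), numeric(1)),
    IP = vapply(sites, function(s) ip(ledger, s), numeric(1)),
    PDE = vapply(sites, function(s) pde(ledger, s), numeric(1)),
    PA = vapply(sites, function(s) pa(ledger, s), numeric(1)),
    ETE = vapply(sites, function(s) ete(ledger, s), numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  tab$IP_PDE <- tab$IP + tab$PDE
  tab$PA_ETE <- tab$PA + tab$ETE

  best_site <- which.min(tab$BDE)
  site_tie <- sum(abs(tab$BDE - tab$BDE[best_site]) <= tie_tol) > 1
  mins <- c(HAT = min(tab$BDE), `SET-PT` = min(tab$IP_PDE),
            SPLET = min(tab$PA_ETE))
  best_mech <- which.min(mins)
  mech_tie <- sum(abs(mins - mins[best_mech]) <= tie_tol) > 1

  structure(
    list(table = tab,
         preferred_site = tab$site[best_site],
         preferred_mechanism = names(mins)[best_mech],
         site_tie = site_tie, mechanism_tie = mech_tie,
         compound = ledger$compound, environment = ledger$environment),
    class = "mechanism_table"
  )
}

#' @export
print.mechanism_table <- function(x, ...) {
  cat("<mechanism_table>", x$compound, "/", x$environment, "\n")
  print(x$table, digits = 6)
  cat("preferred site:", x$preferred_site,
      if (x$site_tie) "(tie)" else "", "\n")
  cat("preferred mechanism:", x$preferred_mechanism,
      if (x$mechanism_tie) "(tie)" else "", "\n")
  invisible(x)
}
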