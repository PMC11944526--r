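#' Packaged luteolin reference tables
#'
#' Verbatim numeric transcriptions of the literature reference tables for
#' luteolin: QTAIM topological parameters of luteolin-solvent bond critical
#' points (`qtaim_reference()`), NBO E(2) hyperconjugation energies
#' (`nbo_reference()`), HAT/SET-PT/SPLET thermodynamic descriptors
#' (`mechanism_reference()`), the solvent dielectric series
#' (`solvent_reference()`) and the intramolecular H-bond / ground-state
#' geometry values (`intramolecular_reference()`, returned as a named
#' vector). Printed row labels are preserved, including the duplicated "VI"
#' label in the water block (disambiguated in `bcp_id`).
#'
#' @return data.frames (named numeric vector for
#'   `intramolecular_reference()`)
#' @name reference_tables
NULL

.read_extdata <- function(file) {
  path <- system.file("extdata", file, package = "phenolox",
                      mustWork = TRUE)
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' @rdname reference_tables
#' @export
qtaim_reference <- function() .read_extdata("qtaim_luteolin_solvent.csv")

#' @rdname reference_tables
#' @export
nbo_reference <- function() .read_extdata("nbo_luteolin_solvent.csv")

#' @rdname reference_tables
#' @export
mechanism_reference <- function() .read_extdata("mechanism_reference.csv")

#' @rdname reference_tables
#' @export
solvent_reference <- function() .read_extdata("solvents.csv")

#' @rdname reference_tables
#' @export
intramolecular_reference <- function() {
  tab <- .read_extdata("intramolecular_reference.csv")
  stats::setNames(tab$value, tab$quantity)
}

#' Refit the BE-vs-density calibration from the reference table
#'
#' Ordinary least squares of the tabulated binding energies against the
#' density at the bond critical point over all rows of
#' [qtaim_reference()]. The reference table's BE column was generated with a
#' steeper calibration than the published intramolecular-H-bond coefficients
#' (-223.08, 0.7423): this fit recovers the coefficients the table actually
#' encodes (slope near -334 kcal/mol per a.u.). Both coefficient sets are
#' legitimate inputs to [estimate_be()]; they must not be interchanged.
#'
#' @return list with `slope` (kcal/mol per a.u.), `intercept` (kcal/mol),
#'   `r_squared`, `n`
#' @export
fit_be_coefficients <- function() {
  tab <- qtaim_reference()
  fit <- stats::lm(be_kcal ~ rho, data = tab)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = summary(fit)$r.squared,
       n = nrow(tab))
}

#' Synthetic diatomic promolecular density
#'
#' Two promolecular atoms on the z axis at `-separation/2` and
#' `+separation/2`, with a stored reference bond-critical-point position
#' found independently of the Newton search: by symmetry for equal atoms,
#' by a dense 10^4-point scan of the density minimum along the internuclear
#' axis for unequal ones. Deterministic for fixed arguments.
#'
#' @param elements character length-2
#' @param separation internuclear distance, Bohr (> 0.5)
#' @param params promolecular parameter table; see [promolecular_density()]
#' @param scan_points number of samples in the line-scan oracle
#' @return list with `field` (a `promolecular_density`), `bcp_reference`
#'   (3-vector, Bohr) and `bcp_method` (`"symmetry"` or `"line_scan"`)
#' @export
make_diatomic_density <- function(elements, separation,
                                  params = promolecular_params(),
                                  scan_points = 1e4) {
  stopifnot(length(elements) == 2)
  if (separation <= 0.5) stop("separation must exceed 0.5 Bohr")
  geom <- molecule_geometry(list(
    atom_site(elements[1], c(0, 0, -separation / 2)),
    atom_site(elements[2], c(0, 0, separation / 2))
  ), label = paste0(elements[1], elements[2], "_diatomic"))
  field <- promolecular_density(geom, params)

  i1 <- match(elements[1], params$element)
  i2 <- match(elements[2], params$element)
  same <- params$amplitude[i1] == params$amplitude[i2] &&
    params$decay[i1] == params$decay[i2]
  if (same) {
    ref <- c(0, 0, 0)
    method <- "symmetry"
  } else {
    zs <- seq(-separation / 2 + 1e-3, separation / 2 - 1e-3,
              length.out = scan_points)
    rho <- vapply(zs, function(z) probe_density(field, c(0, 0, z))$value,
                  numeric(1))
    i <- which.min(rho)
    z_min <- zs[i]
    if (i > 1 && i < length(zs)) {
      # parabolic refinement through the three bracketing samples removes
      # the half-spacing quantisation of the dense scan
      denom <- rho[i + 1] - 2 * rho[i] + rho[i - 1]
      if (denom > 0) {
        z_min <- zs[i] - 0.5 * (zs[2] - zs[1]) *
          (rho[i + 1] - rho[i - 1]) / denom
      }
    }
    ref <- c(0, 0, z_min)
    method <- "line_scan"
  }
  list(field = field, bcp_reference = ref, bcp_method = method)
}

#' Inverse-constructed enthalpy ledger with prescribed descriptors
#'
#' Builds an [enthalpy_ledger()] whose BDE, IP and PA evaluate exactly to
#' the requested targets (kcal/mol); PDE and ETE are then fixed by the
#' algebraic identities `IP + PDE = PA + ETE = BDE + offset` with
#' `offset = (H_proton + H_electron - H_Hradical)` in kcal/mol. The
#' closed-shell base enthalpies are drawn from a seeded generator so the
#' ledger is reproducible but not degenerate.
#'
#' @param targets data.frame with columns `site`, `BDE`, `IP`, `PA`
#'   (kcal/mol)
#' @param references named numeric length-3: `H_Hradical`, `H_proton`,
#'   `H_electron` (Hartree)
#' @param seed integer seed for the base enthalpies
#' @param compound,environment ledger labels
#' @return an `enthalpy_ledger`
#' @export
make_ledger <- function(targets, references, seed = 1,
                        compound = "synthetic",
                        environment = "model") {
  stopifnot(is.data.frame(targets),
            all(c("site", "BDE", "IP", "PA") %in% names(targets)),
            all(is.finite(targets$BDE)), all(is.finite(targets$IP)),
            all(is.finite(targets$PA)))
  need <- c("H_Hradical", "H_proton", "H_electron")
  if (!all(need %in% names(references))) {
    stop("references must supply ", paste(need, collapse = ", "))
  }
  old <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  base <- -1000 + stats::rnorm(nrow(targets), sd = 0.05)

  sites <- list()
  for (i in seq_len(nrow(targets))) {
    h_ah <- base[i]
    sites[[targets$site[i]]] <- c(
      H_AH = h_ah,
      H_Aradical = h_ah - references[["H_Hradical"]] +
        kcal_to_hartree(targets$BDE[i]),
      H_cation = h_ah - references[["H_electron"]] +
        kcal_to_hartree(targets$IP[i]),
      H_anion = h_ah - references[["H_proton"]] +
        kcal_to_hartree(targets$PA[i])
    )
  }
  enthalpy_ledger(compound, environment, sites, references[need])
}

#' Synthetic ledger replaying the luteolin reference descriptors
#'
#' Inverse-constructs a ledger whose BDEs equal the tabulated luteolin
#' column (no-water or explicit-water) exactly, with the H+/e-/H* reference
#' enthalpies chosen so that `(PA + ETE) - BDE = 2.989` kcal/mol - the
#' offset the printed PA+ETE column actually shows. The printed IP+PDE
#' column carries a different offset (3.060-3.061) that cannot coexist with
#' PA+ETE in one algebraically consistent ledger; it stays fixture data in
#' [mechanism_reference()]. IP targets are set to the printed
#' `ip_pde - 11` so the SET-PT split is nontrivial but the sums are exact.
#'
#' @param water use the explicit-water BDE column
#' @param seed forwarded to [make_ledger()]
#' @return an `enthalpy_ledger`
#' @export
luteolin_ledger <- function(water = FALSE, seed = 1) {
  ref <- mechanism_reference()
  lut <- ref[ref$compound == "luteolin", ]
  bde_col <- if (water) lut$bde_water else lut$bde_no_water
  offset_kcal <- 2.989
  # H* enthalpy near the exact hydrogen-atom value; H+/e- split arbitrary
  refs <- c(H_Hradical = -0.49765, H_proton = 0.0, H_electron = 0.0)
  refs[["H_proton"]] <- kcal_to_hartree(offset_kcal) -
    refs[["H_electron"]] + refs[["H_Hradical"]]
  targets <- data.frame(
    site = lut$site,
    BDE = bde_col,
    IP = bde_col + offset_kcal - 11,  # PDE = 11 by construction
    PA = lut$pa_ete - 11 + (bde_col - lut$bde_no_water)
  )
  # PA target keeps ETE = printed sum - PA when no-water; with water the
  # sums track the water BDEs through the identity instead
  make_ledger(targets, refs, seed = seed, compound = "luteolin",
              environment = if (water) "explicit-water" else "water")
}
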