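#' Element symbols and nuclear charges
#'
#' Minimal periodic-table lookup covering the elements that occur in phenolic
#' antioxidants and their solvents.
#' @keywords internal
.element_z <- c(
  H = 1, He = 2, Li = 3, Be = 4, B = 5, C = 6, N = 7, O = 8, F = 9, Ne = 10,
  Na = 11, Mg = 12, Al = 13, Si = 14, P = 15, S = 16, Cl = 17, Ar = 18
)

element_to_z <- function(element) {
  z <- .element_z[element]
  if (any(is.na(z))) {
    stop("unknown element symbol(s): ",
         paste(element[is.na(z)], collapse = ", "))
  }
  unname(z)
}

z_to_element <- function(z) {
  idx <- match(z, .element_z)
  if (any(is.na(idx))) {
    stop("unknown nuclear charge(s): ", paste(z[is.na(idx)], collapse = ", "))
  }
  names(.element_z)[idx]
}

#' Create an atomic site
#'
#' An atom with element symbol, nuclear charge Z and Cartesian position in
#' Bohr. Z must match the element symbol and the position must be finite.
#'
#' @param element chemical symbol, e.g. `"O"`
#' @param position numeric length-3, Bohr
#' @param z nuclear charge; defaults to the charge implied by `element`
#' @return object of class `atom_site`
#' @export
atom_site <- function(element, position, z = element_to_z(element)) {
  stopifnot(is.character(element), length(element) == 1)
  position <- as.numeric(position)
  if (length(position) != 3 || !all(is.finite(position))) {
    stop("position must be a finite 3-vector (Bohr)")
  }
  if (z != element_to_z(element)) {
    stop("nuclear charge ", z, " does not match element ", element)
  }
  structure(
    list(element = element, z = as.integer(z), position = position),
    class = "atom_site"
  )
}

#' Create a molecular geometry
#'
#' An ordered collection of [atom_site()]s. At least one atom is required and
#' no two atoms may sit closer than 0.1 Bohr.
#'
#' @param atoms list of `atom_site`
#' @param label text label
#' @return object of class `molecule_geometry`
#' @export
molecule_geometry <- function(atoms, label = "") {
  if (length(atoms) < 1) stop("a geometry needs at least one atom")
  if (!all(vapply(atoms, inherits, logical(1), "atom_site"))) {
    stop("atoms must all be atom_site objects")
  }
  pos <- t(vapply(atoms, `[[`, numeric(3), "position"))
  if (nrow(pos) > 1) {
    d <- as.matrix(stats::dist(pos))
    diag(d) <- Inf
    if (min(d) < 0.1) {
      stop("atoms closer than 0.1 Bohr: geometry rejected")
    }
  }
  structure(list(atoms = atoms, label = label), class = "molecule_geometry")
}

#' @export
print.molecule_geometry <- function(x, ...) {
  cat("<molecule_geometry>", x$label, "-", length(x$atoms), "atoms\n")
  invisible(x)
}

geometry_positions <- function(geom) {
  t(vapply(geom$atoms, `[[`, numeric(3), "position"))
}

geometry_charges <- function(geom) {
  vapply(geom$atoms, `[[`, integer(1), "z")
}

geometry_elements <- function(geom) {
  vapply(geom$atoms, `[[`, character(1), "element")
}

#' Translate a molecular geometry
#'
#' @param geom a `molecule_geometry`
#' @param shift numeric length-3, Bohr
#' @return translated `molecule_geometry`
#' @export
translate_geometry <- function(geom, shift) {
  shift <- as.numeric(shift)
  stopifnot(length(shift) == 3, all(is.finite(shift)))
  atoms <- lapply(geom$atoms, function(a) {
    atom_site(a$element, a$position + shift)
  })
  molecule_geometry(atoms, label = geom$label)
}
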