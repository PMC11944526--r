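#' Load the packaged promolecular radial parameters
#'
#' One single Slater-type exponential per element,
#' `rho_elem(r) = amplitude * exp(-r / decay)`, with amplitude in
#' electrons/Bohr^3 and decay length in Bohr. The numbers are a transparent
#' packaged constant chosen to give chemically sensible relative magnitudes;
#' they are a desk-scale stand-in for self-consistent densities, not fitted
#' physics claims.
#'
#' @return data.frame with columns `element`, `amplitude`, `decay`
#' @export
promolecular_params <- function() {
  path <- system.file("extdata", "promolecular_params.csv",
                      package = "phenolox", mustWork = TRUE)
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Create an analytic promolecular density
#'
#' Sum of spherical single-exponential atomic densities centred on the atoms
#' of `geometry`. Strictly positive everywhere; value, gradient and Hessian
#' are analytic.
#'
#' @param geometry a [molecule_geometry()]
#' @param params data.frame with columns `element`, `amplitude` (e/Bohr^3),
#'   `decay` (Bohr); defaults to the packaged table
#' @return object of class `promolecular_density`
#' @export
promolecular_density <- function(geometry, params = promolecular_params()) {
  stopifnot(inherits(geometry, "molecule_geometry"))
  elems <- geometry_elements(geometry)
  idx <- match(elems, params$element)
  if (any(is.na(idx))) {
    stop("no promolecular parameters for element(s): ",
         paste(unique(elems[is.na(idx)]), collapse = ", "))
  }
  amp <- params$amplitude[idx]
  dec <- params$decay[idx]
  if (any(amp <= 0) || any(dec <= 0)) {
    stop("promolecular amplitudes and decay lengths must be positive")
  }
  structure(
    list(geometry = geometry, centers = geometry_positions(geometry),
         amplitude = amp, decay = dec),
    class = "promolecular_density"
  )
}

#' @export
print.promolecular_density <- function(x, ...) {
  cat("<promolecular_density>", nrow(x$centers), "atomic centres\n")
  invisible(x)
}
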