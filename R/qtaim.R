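#' Topological parameters at a bond critical point
#'
#' Bundle of QTAIM descriptors: density rho, Laplacian, Lagrangian kinetic
#' energy density G, potential energy density v, total energy density
#' h = G + v (exact as computed), and the covalency ratio |v|/G.
#'
#' @param rho density, a.u.
#' @param lap Laplacian of the density, a.u.
#' @param G kinetic energy density, a.u. (must be >= 0)
#' @param v potential energy density, a.u.
#' @return object of class `topological_parameters`
#' @export
topological_parameters <- function(rho, lap, G, v) {
  stopifnot(is.finite(rho), is.finite(lap), is.finite(G), is.finite(v))
  if (G < 0) stop("kinetic energy density G must be >= 0")
  structure(
    list(rho = rho, lap = lap, G = G, v = v, h = G + v,
         ratio = if (G > 0) abs(v) / G else NA_real_),
    class = "topological_parameters"
  )
}

#' Abramov kinetic energy density estimate
#'
#' Density-only closed form
#' `G = (3/10) (3 pi^2)^(2/3) rho^(5/3) + (1/6) lap`, the standard estimate
#' of the Lagrangian kinetic energy density at closed-shell bond critical
#' points when no wavefunction is available. When a reference table supplies
#' G directly, the supplied value takes precedence and this is a cross-check.
#'
#' @param rho density at the BCP, a.u. (>= 0)
#' @param lap Laplacian at the BCP, a.u.
#' @return G, a.u.
#' @export
abramov_g <- function(rho, lap) {
  if (any(rho < 0)) stop("rho must be >= 0")
  (3 / 10) * (3 * pi^2)^(2 / 3) * rho^(5 / 3) + lap / 6
}

#' Potential energy density from the local virial relation
#'
#' `v = (1/4) lap - 2 G`. Exact arithmetic; used when a table does not
#' supply v directly.
#'
#' @param G kinetic energy density, a.u.
#' @param lap Laplacian, a.u.
#' @return v, a.u.
#' @export
virial_v <- function(G, lap) {
  lap / 4 - 2 * G
}

#' Total energy density
#'
#' `h = G + v`; h < 0 signals partial covalency of a closed-shell contact.
#'
#' @param G kinetic energy density, a.u.
#' @param v potential energy density, a.u.
#' @return h, a.u.
#' @export
energy_density_h <- function(G, v) {
  G + v
}

#' Classify a closed- or shared-shell interaction
#'
#' Deterministic rules on the QTAIM descriptors:
#' * `lap > 0`, `h < 0`, `1 < |v|/G < 2` - moderate H-bond with partial
#'   covalent character;
#' * `lap > 0`, `h >= 0`, `|v|/G <= 1`, `rho >= rho_vdw_cutoff` - weak
#'   noncovalent H-bond;
#' * `lap > 0`, `h >= 0`, `rho < rho_vdw_cutoff` - van der Waals contact;
#' * `|v|/G >= 2` or `lap < 0` - covalent (shared shell).
#'
#' The 0.015 a.u. density cutoff and the ratio bounds 1 and 2 are fixed,
#' configurable constants; they reproduce the reference classifications for
#' luteolin (moderate H-bond at rho 0.0425 and a van der Waals contact at
#' rho 0.0121).
#'
#' @param params a [topological_parameters()]
#' @param rho_vdw_cutoff density separating weak H-bond from van der Waals,
#'   a.u.
#' @return one of `"moderate_Hbond_partial_covalent"`,
#'   `"weak_Hbond_noncovalent"`, `"van_der_Waals"`, `"covalent"`
#' @export
classify_interaction <- function(params, rho_vdw_cutoff = 0.015) {
  stopifnot(inherits(params, "topological_parameters"))
  ratio <- params$ratio
  if (is.na(ratio)) ratio <- 0
  if (ratio >= 2 || params$lap < 0) return("covalent")
  if (params$lap > 0 && params$h < 0 && ratio > 1 && ratio < 2) {
    return("moderate_Hbond_partial_covalent")
  }
  if (params$lap > 0 && params$h >= 0 && params$rho >= rho_vdw_cutoff) {
    return("weak_Hbond_noncovalent")
  }
  if (params$lap > 0 && params$h >= 0 && params$rho < rho_vdw_cutoff) {
    return("van_der_Waals")
  }
  # lap > 0, h < 0, ratio <= 1: borderline partial covalency at ratio ~ 1
  "moderate_Hbond_partial_covalent"
}

#' Hydrogen-bond binding energy from the density at the BCP
#'
#' Linear regression `BE = slope * rho + intercept` in kcal/mol. The default
#' coefficients (-223.08, 0.7423) are the published intramolecular-H-bond
#' calibration; at rho = 0.0425 a.u. they give -8.74, i.e. -8.7 at one
#' decimal. Note the luteolin-solvent reference table was generated with a
#' *different* (steeper) calibration: use [fit_be_coefficients()] to recover
#' it. Output from the default coefficients must not be compared against
#' that table's BE column.
#'
#' @param rho density at the BCP, a.u. (>= 0)
#' @param slope kcal/mol per a.u.
#' @param intercept kcal/mol
#' @return BE, kcal/mol
#' @export
estimate_be <- function(rho, slope = -223.08, intercept = 0.7423) {
  if (any(rho < 0)) stop("rho must be >= 0")
  slope * rho + intercept
}

#' Locate a critical point of the electron density
#'
#' Damped Newton iteration on the density gradient from `guess`, converging
#' to `|grad rho| < tol` (default 1e-8 a.u.) within `max_iter` steps. The
#' step is halved whenever it would make the density negative or grow the
#' gradient norm catastrophically. Rank and signature come from the Hessian
#' eigenvalues with magnitude threshold `eigen_tol`. An iterate landing
#' within `nuclear_capture` Bohr of a nucleus is reported as a nuclear
#' attractor (rank 3, signature -3): promolecular densities have cusps
#' there and the Hessian is not meaningful.
#'
#' @param field density field accepted by [probe_density()]
#' @param guess starting point, Bohr
#' @param tol convergence threshold on the gradient norm, a.u.
#' @param max_iter maximum Newton steps
#' @param eigen_tol eigenvalue magnitude threshold for rank counting
#' @param nuclear_capture capture radius around nuclei, Bohr
#' @return object of class `critical_point` with fields `position`, `rho`,
#'   `lap`, `eigenvalues`, `rank`, `signature`, `grad_norm`, `converged`,
#'   `iterations`, `is_nuclear`
#' @export
find_bcp <- function(field, guess, tol = 1e-8, max_iter = 200,
                     eigen_tol = 1e-10, nuclear_capture = 1e-3) {
  x <- as.numeric(guess)
  stopifnot(length(x) == 3, all(is.finite(x)))
  geom <- field$geometry
  nuclei <- geometry_positions(geom)

  nearest_nucleus <- function(p) {
    d2 <- rowSums((nuclei - matrix(p, nrow(nuclei), 3, byrow = TRUE))^2)
    list(index = which.min(d2), dist = sqrt(min(d2)))
  }

  make_record <- function(p, probe, converged, iters, is_nuclear = FALSE) {
    if (is_nuclear) {
      ev <- rep(-Inf, 3)
      rank <- 3L
      signature <- -3L
    } else {
      ev <- sort(eigen(probe$hessian, symmetric = TRUE,
                       only.values = TRUE)$values)
      big <- abs(ev) > eigen_tol
      rank <- sum(big)
      signature <- sum(sign(ev[big]))
    }
    structure(
      list(position = p, rho = probe$value, lap = probe$laplacian,
           eigenvalues = ev, rank = as.integer(rank),
           signature = as.integer(signature),
           grad_norm = sqrt(sum(probe$gradient^2)),
           converged = converged, iterations = iters,
           is_nuclear = is_nuclear),
      class = "critical_point"
    )
  }

  nn <- nearest_nucleus(x)
  if (nn$dist < nuclear_capture) {
    p <- nuclei[nn$index, ]
    probe <- probe_density(field, p + c(nuclear_capture, 0, 0))
    probe$gradient <- numeric(3)  # reported at the attractor itself
    return(make_record(p, probe, converged = TRUE, iters = 0L,
                       is_nuclear = TRUE))
  }

  probe <- probe_density(field, x)
  for (it in seq_len(max_iter)) {
    gn <- sqrt(sum(probe$gradient^2))
    if (gn < tol) {
      rec <- make_record(x, probe, converged = TRUE, iters = it - 1L)
      if (rec$rank < 3) {
        stop("degenerate critical point (rank ", rec$rank, ") at (",
             paste(sprintf("%.6f", x), collapse = ", "), ")")
      }
      return(rec)
    }
    step <- tryCatch(-solve(probe$hessian, probe$gradient),
                     error = function(e) -probe$gradient)
    # damp: halve while the trial point would leave the domain, make the
    # density negative, or blow up the gradient
    lambda <- 1
    repeat {
      trial <- x + lambda * step
      tp <- tryCatch(probe_density(field, trial), error = function(e) NULL)
      if (!is.null(tp) && tp$value > 0 &&
          sqrt(sum(tp$gradient^2)) < 10 * gn) break
      lambda <- lambda / 2
      if (lambda < 1e-10) {
        return(make_record(x, probe, converged = FALSE, iters = it))
      }
    }
    x <- x + lambda * step
    probe <- tp
    nn <- nearest_nucleus(x)
    if (nn$dist < nuclear_capture) {
      p <- nuclei[nn$index, ]
      return(make_record(p, probe, converged = TRUE, iters = it,
                         is_nuclear = TRUE))
    }
  }
  make_record(x, probe, converged = FALSE, iters = max_iter)
}

#' @export
print.critical_point <- function(x, ...) {
  cat(sprintf(
    "<critical_point> (%s)  rho=%.6g  signature=%d%s  |grad|=%.2e\n",
    paste(sprintf("%.4f", x$position), collapse = ", "),
    x$rho, x$signature, if (x$is_nuclear) " [nuclear]" else "", x$grad_norm))
  invisible(x)
}

#' Assemble an interaction record
#'
#' One donor-H...acceptor contact with geometry, topology, binding energy and
#' classification. The category is always recomputed from the parameters so
#' the record stays internally consistent.
#'
#' @param label text, e.g. `"O3-H...Ow"`
#' @param length_angstrom H...acceptor distance, Angstrom
#' @param angle_degree donor angle, degrees
#' @param params a [topological_parameters()]
#' @param be binding energy, kcal/mol; default recomputed via [estimate_be()]
#' @param rho_vdw_cutoff forwarded to [classify_interaction()]
#' @return object of class `interaction_record`
#' @export
interaction_record <- function(label, length_angstrom, angle_degree, params,
                               be = estimate_be(params$rho),
                               rho_vdw_cutoff = 0.015) {
  stopifnot(inherits(params, "topological_parameters"))
  structure(
    list(label = label, length_angstrom = length_angstrom,
         angle_degree = angle_degree, params = params, be = be,
         category = classify_interaction(params, rho_vdw_cutoff)),
    class = "interaction_record"
  )
}

#' Render interaction records as a report table
#'
#' Columns: BCP id, interaction, length (Angstrom), angle (degrees), rho,
#' Laplacian, G, v, h, |v|/G and BE. In `"table"` rounding mode the a.u.
#' columns print at 4 decimals, the ratio at 1 and BE at 2, rounding half
#' away from zero; `"full"` leaves values unrounded.
#'
#' @param records list of [interaction_record()]s
#' @param rounding `"full"` or `"table"`
#' @return data.frame (header-only when `records` is empty)
#' @export
interaction_table <- function(records, rounding = c("full", "table")) {
  rounding <- match.arg(rounding)
  cols <- c("bcp", "interaction", "length_angstrom", "angle_degree",
            "rho", "lap", "G", "v", "h", "ratio", "be_kcal", "category")
  if (length(records) == 0) {
    out <- as.data.frame(stats::setNames(
      c(list(integer(0), character(0)), rep(list(numeric(0)), 9),
        list(character(0))), cols))
    return(out)
  }
  out <- data.frame(
    bcp = seq_along(records),
    interaction = vapply(records, `[[`, character(1), "label"),
    length_angstrom = vapply(records, `[[`, numeric(1), "length_angstrom"),
    angle_degree = vapply(records, `[[`, numeric(1), "angle_degree"),
    rho = vapply(records, function(r) r$params$rho, numeric(1)),
    lap = vapply(records, function(r) r$params$lap, numeric(1)),
    G = vapply(records, function(r) r$params$G, numeric(1)),
    v = vapply(records, function(r) r$params$v, numeric(1)),
    h = vapply(records, function(r) r$params$h, numeric(1)),
    ratio = vapply(records, function(r) r$params$ratio, numeric(1)),
    be_kcal = vapply(records, `[[`, numeric(1), "be"),
    category = vapply(records, `[[`, character(1), "category"),
    stringsAsFactors = FALSE
  )
  if (rounding == "table") {
    for (cc in c("rho", "lap", "G", "v", "h")) {
      out[[cc]] <- round_half_away(out[[cc]], 4)
    }
    out$ratio <- round_half_away(out$ratio, 1)
    out$be_kcal <- round_half_away(out$be_kcal, 2)
  }
  out
}
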