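#' Frontier orbital energies
#'
#' HOMO/LUMO pair in Hartree for one environment. Inputs with
#' `E_HOMO > E_LUMO` are rejected.
#'
#' @param e_homo HOMO energy, Hartree
#' @param e_lumo LUMO energy, Hartree
#' @param environment text, e.g. `"vacuum"`, `"water"`
#' @return object of class `frontier_orbitals`
#' @export
frontier_orbitals <- function(e_homo, e_lumo, environment = "vacuum") {
  stopifnot(is.finite(e_homo), is.finite(e_lumo))
  if (e_homo > e_lumo) stop("E_HOMO must not exceed E_LUMO")
  structure(list(e_homo = e_homo, e_lumo = e_lumo,
                 environment = environment),
            class = "frontier_orbitals")
}

#' Conceptual-DFT reactivity descriptors from frontier orbitals
#'
#' Within the frontier-orbital approximation `I = -E_HOMO`, `A = -E_LUMO`,
#' and the descriptors follow exactly:
#' hardness `eta = (I - A)/2`, chemical potential `mu = -(I + A)/2`,
#' electronegativity `chi = -mu`, gap `I - A`, and global electrophilicity
#' `omega = mu^2 / (2 eta)`. When `I = A` (zero hardness) `omega` is
#' reported as `NA` rather than infinity.
#'
#' @param orbitals a [frontier_orbitals()]
#' @return object of class `reactivity_descriptors` with fields `I`, `A`,
#'   `gap`, `eta`, `mu`, `chi`, `omega` (all a.u.) and `environment`
#' @export
reactivity_descriptors <- function(orbitals) {
  stopifnot(inherits(orbitals, "frontier_orbitals"))
  I <- -orbitals$e_homo
  A <- -orbitals$e_lumo
  eta <- (I - A) / 2
  mu <- -(I + A) / 2
  omega <- if (eta == 0) NA_real_ else mu^2 / (2 * eta)
  structure(
    list(I = I, A = A, gap = I - A, eta = eta, mu = mu, chi = -mu,
         omega = omega, environment = orbitals$environment),
    class = "reactivity_descriptors"
  )
}

#' @export
print.reactivity_descriptors <- function(x, ...) {
  cat(sprintf(
    "<reactivity_descriptors> [%s] I=%.4f A=%.4f gap=%.4f eta=%.4f mu=%.4f omega=%s (a.u.)\n",
    x$environment, x$I, x$A, x$gap, x$eta, x$mu,
    if (is.na(x$omega)) "undefined" else sprintf("%.4f", x$omega)))
  invisible(x)
}

#' Reactivity descriptors in electronvolts
#'
#' @param desc a `reactivity_descriptors`
#' @return named numeric vector in eV
#' @export
descriptors_ev <- function(desc) {
  stopifnot(inherits(desc, "reactivity_descriptors"))
  vapply(c("I", "A", "gap", "eta", "mu", "chi", "omega"),
         function(k) desc[[k]] * EV_PER_HARTREE, numeric(1))
}

#' Molecular electrostatic potential at a set of points
#'
#' `V(r) = sum_a Z_a / |r_a - r| - int rho(r') / |r' - r| dr'`. The nuclear
#' term is an exact Coulomb sum. For a `density_grid` the electronic term is
#' midpoint quadrature over voxels, with the kernel distance floored at 0.6
#' voxel diagonals to regularise the voxel containing the evaluation point.
#' A point-charge electron set (data.frame with `x`, `y`, `z`, `q` in
#' electrons) is summed exactly. Points closer than 0.05 Bohr to a nucleus
#' are rejected with the offending index.
#'
#' @param nuclei list of [atom_site()]s (may be empty)
#' @param density a [density_grid()], a point-charge data.frame, or `NULL`
#'   for no electronic term
#' @param points numeric matrix, one row per evaluation point, Bohr
#' @return object of class `mep_field`: list with `points` and `V` (a.u.)
#' @export
mep_at_points <- function(nuclei, density, points) {
  points <- matrix(as.numeric(points), ncol = 3)
  npt <- nrow(points)
  V <- numeric(npt)

  if (length(nuclei) > 0) {
    pos <- t(vapply(nuclei, `[[`, numeric(3), "position"))
    zs <- vapply(nuclei, function(a) as.numeric(a$z), numeric(1))
    for (p in seq_len(npt)) {
      d <- sqrt(rowSums((pos - matrix(points[p, ], nrow(pos), 3,
                                      byrow = TRUE))^2))
      if (any(d < 0.05)) {
        stop("evaluation point ", p, " is within 0.05 Bohr of nucleus ",
             which(d < 0.05)[1])
      }
      V[p] <- V[p] + sum(zs / d)
    }
  }

  if (inherits(density, "density_grid")) {
    n <- density$counts
    vol <- abs(det(density$axes))
    ii <- seq_len(n[1]) - 1
    jj <- seq_len(n[2]) - 1
    kk <- seq_len(n[3]) - 1
    idx <- as.matrix(expand.grid(i = ii, j = jj, k = kk))
    centers <- matrix(density$origin, nrow(idx), 3, byrow = TRUE) +
      idx %*% density$axes
    rho_flat <- as.numeric(density$values)
    floor_d <- 0.6 * sqrt(sum((density$axes[1, ] + density$axes[2, ] +
                                 density$axes[3, ])^2))
    keep <- rho_flat > 0
    centers <- centers[keep, , drop = FALSE]
    rho_keep <- rho_flat[keep]
    for (p in seq_len(npt)) {
      d <- sqrt(rowSums((centers - matrix(points[p, ], nrow(centers), 3,
                                          byrow = TRUE))^2))
      d <- pmax(d, floor_d)
      V[p] <- V[p] - vol * sum(rho_keep / d)
    }
  } else if (is.data.frame(density)) {
    stopifnot(all(c("x", "y", "z", "q") %in% names(density)))
    pc <- as.matrix(density[, c("x", "y", "z")])
    for (p in seq_len(npt)) {
      d <- sqrt(rowSums((pc - matrix(points[p, ], nrow(pc), 3,
                                     byrow = TRUE))^2))
      if (any(d < 1e-10)) stop("evaluation point ", p,
                               " coincides with a point charge")
      V[p] <- V[p] - sum(density$q / d)
    }
  } else if (!is.null(density)) {
    stop("density must be a density_grid, a point-charge data.frame or NULL")
  }

  structure(list(points = points, V = V), class = "mep_field")
}

#' Extract a density isosurface as a triangle point set
#'
#' Marching-tetrahedra extraction (each voxel split into six tetrahedra,
#' linear interpolation along edges) of the surface `rho = isovalue`.
#' Returns triangle centroids with per-triangle areas, ready for
#' [mpi_polar_area()]. The default isovalue 4e-4 electrons/Bohr^3 is the
#' customary molecular-surface contour.
#'
#' @param grid a [density_grid()]
#' @param isovalue contour level, electrons/Bohr^3
#' @return data.frame with columns `x`, `y`, `z` (centroid, Bohr) and
#'   `area` (Bohr^2)
#' @export
density_isosurface <- function(grid, isovalue = 4e-4) {
  stopifnot(inherits(grid, "density_grid"))
  n <- grid$counts
  v <- grid$values
  # tetrahedral decomposition of the unit cube (6 tets, consistent diagonal)
  corners <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0),
                   c(0, 0, 1), c(1, 0, 1), c(0, 1, 1), c(1, 1, 1))
  tets <- rbind(c(1, 2, 4, 8), c(1, 2, 6, 8), c(1, 5, 6, 8),
                c(1, 3, 4, 8), c(1, 3, 7, 8), c(1, 5, 7, 8))

  tris <- list()
  tcount <- 0
  for (i in seq_len(n[1] - 1)) {
    for (j in seq_len(n[2] - 1)) {
      for (k in seq_len(n[3] - 1)) {
        cvals <- v[cbind(i + corners[, 1], j + corners[, 2],
                         k + corners[, 3])]
        if (all(cvals > isovalue) || all(cvals < isovalue)) next
        base <- c(i - 1, j - 1, k - 1)
        for (t in seq_len(nrow(tets))) {
          tv <- cvals[tets[t, ]]
          above <- tv > isovalue
          ns <- sum(above)
          if (ns == 0 || ns == 4) next
          tc <- corners[tets[t, ], , drop = FALSE]
          edge_pt <- function(a, b) {
            f <- (isovalue - tv[a]) / (tv[b] - tv[a])
            base + tc[a, ] + f * (tc[b, ] - tc[a, ])
          }
          if (ns == 1 || ns == 3) {
            apex <- if (ns == 1) which(above) else which(!above)
            oth <- setdiff(1:4, apex)
            p1 <- edge_pt(apex, oth[1])
            p2 <- edge_pt(apex, oth[2])
            p3 <- edge_pt(apex, oth[3])
            tcount <- tcount + 1
            tris[[tcount]] <- rbind(p1, p2, p3)
          } else {
            hi <- which(above)
            lo <- which(!above)
            q1 <- edge_pt(hi[1], lo[1])
            q2 <- edge_pt(hi[1], lo[2])
            q3 <- edge_pt(hi[2], lo[2])
            q4 <- edge_pt(hi[2], lo[1])
            tcount <- tcount + 1
            tris[[tcount]] <- rbind(q1, q2, q3)
            tcount <- tcount + 1
            tris[[tcount]] <- rbind(q1, q3, q4)
          }
        }
      }
    }
  }
  if (tcount == 0) {
    return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      area = numeric(0)))
  }
  A <- grid$axes
  out <- matrix(0, tcount, 4)
  for (t in seq_len(tcount)) {
    tri_frac <- tris[[t]]
    tri <- tri_frac %*% A +
      matrix(grid$origin, 3, 3, byrow = TRUE)
    cen <- colMeans(tri)
    ar <- 0.5 * sqrt(sum(crossprod3(tri[2, ] - tri[1, ],
                                    tri[3, ] - tri[1, ])^2))
    out[t, ] <- c(cen, ar)
  }
  out <- out[out[, 4] > 0, , drop = FALSE]
  data.frame(x = out[, 1], y = out[, 2], z = out[, 3], area = out[, 4])
}

crossprod3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Molecular polarity index and polar surface fraction
#'
#' The MPI is the area-weighted mean of |V| over a molecular surface,
#' reported in kcal/mol; the polar fraction is the percentage of surface
#' area where |V| meets the polarity threshold. By default the threshold is
#' the surface MPI itself (in a.u.), i.e. the surface-mean |V|.
#'
#' @param V numeric, electrostatic potential at the surface points, a.u.
#' @param areas numeric, per-point areas (> 0)
#' @param polar_threshold |V| threshold in a.u.; default the area-weighted
#'   mean |V|
#' @return list with `mpi_kcal`, `mpi_au`, `polar_fraction` (percent),
#'   `polar_threshold`
#' @export
mpi_polar_area <- function(V, areas, polar_threshold = NULL) {
  if (length(V) == 0) stop("empty surface point set")
  if (length(V) != length(areas)) stop("V and areas differ in length")
  if (any(areas <= 0)) stop("areas must be positive")
  mpi_au <- sum(areas * abs(V)) / sum(areas)
  if (is.null(polar_threshold)) polar_threshold <- mpi_au
  polar <- abs(V) >= polar_threshold
  list(
    mpi_kcal = hartree_to_kcal(mpi_au),
    mpi_au = mpi_au,
    polar_fraction = 100 * sum(areas[polar]) / sum(areas),
    polar_threshold = polar_threshold
  )
}
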