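#' Construct a density probe
#'
#' Value, gradient, Hessian and Laplacian of an electron density at one
#' point. The Laplacian is the trace of the Hessian and the Hessian is
#' symmetrised, so the probe invariants hold by construction.
#'
#' @param value density, electrons/Bohr^3
#' @param gradient numeric length-3
#' @param hessian 3x3 matrix
#' @return object of class `density_probe` with fields `value`, `gradient`,
#'   `hessian`, `laplacian`
#' @export
density_probe <- function(value, gradient, hessian) {
  hessian <- (hessian + t(hessian)) / 2
  structure(
    list(value = value, gradient = as.numeric(gradient), hessian = hessian,
         laplacian = sum(diag(hessian))),
    class = "density_probe"
  )
}

#' @export
print.density_probe <- function(x, ...) {
  cat(sprintf("<density_probe> rho=%.6g  |grad|=%.3g  lap=%.6g\n",
              x$value, sqrt(sum(x$gradient^2)), x$laplacian))
  invisible(x)
}

#' Evaluate a density field at a point
#'
#' Returns a [density_probe()] with value, gradient and Hessian. Promolecular
#' fields are differentiated analytically; grid fields use separable tricubic
#' (Catmull-Rom) interpolation with analytic derivatives of the interpolant.
#' Grid evaluation requires the point to lie at least one voxel inside the
#' grid bounds; extrapolation is refused.
#'
#' @param field a `promolecular_density` or `density_grid`
#' @param point numeric length-3, Bohr
#' @return a `density_probe`
#' @export
probe_density <- function(field, point) UseMethod("probe_density")

#' @export
probe_density.promolecular_density <- function(field, point) {
  point <- as.numeric(point)
  stopifnot(length(point) == 3, all(is.finite(point)))
  val <- 0
  grad <- numeric(3)
  hess <- matrix(0, 3, 3)
  for (a in seq_len(nrow(field$centers))) {
    d <- point - field$centers[a, ]
    r <- sqrt(sum(d^2))
    A <- field$amplitude[a]
    lam <- field$decay[a]
    if (r < 1e-12) {
      # at the nuclear cusp the spherical average of the gradient vanishes;
      # the tangential curvature diverges, so flag via a large negative proxy
      val <- val + A
      hess <- hess + diag(-A / lam^2 * 1e6, 3)
      next
    }
    f <- A * exp(-r / lam)
    fp <- -f / lam          # df/dr
    fpp <- f / lam^2        # d2f/dr2
    u <- d / r
    val <- val + f
    grad <- grad + fp * u
    hess <- hess + fpp * tcrossprod(u) + (fp / r) * (diag(3) - tcrossprod(u))
  }
  density_probe(val, grad, hess)
}

# Catmull-Rom cubic weights and derivatives for fractional offset t in [0,1),
# stencil offsets -1..2. Columns: w, dw/dt, d2w/dt2.
.catmull_rom <- function(t) {
  t2 <- t * t
  t3 <- t2 * t
  w <- c(-0.5 * t + t2 - 0.5 * t3,
         1 - 2.5 * t2 + 1.5 * t3,
         0.5 * t + 2 * t2 - 1.5 * t3,
         -0.5 * t2 + 0.5 * t3)
  dw <- c(-0.5 + 2 * t - 1.5 * t2,
          -5 * t + 4.5 * t2,
          0.5 + 4 * t - 4.5 * t2,
          -t + 1.5 * t2)
  d2w <- c(2 - 3 * t,
           -5 + 9 * t,
           4 - 9 * t,
           -1 + 3 * t)
  list(w = w, dw = dw, d2w = d2w)
}

#' @export
probe_density.density_grid <- function(field, point) {
  point <- as.numeric(point)
  stopifnot(length(point) == 3, all(is.finite(point)))
  # fractional (voxel) coordinates: point = origin + t(axes) %*% u
  u <- solve(t(field$axes), point - field$origin)
  n <- field$counts
  # one-voxel margin: need stencil i0-1 .. i0+2 inside [0, n-1]
  if (any(u < 1) || any(u > n - 2)) {
    stop("point outside grid interpolation domain (one-voxel margin): (",
         paste(sprintf("%.4f", point), collapse = ", "), ") Bohr")
  }
  i0 <- pmin(floor(u), n - 3)  # base index, 0-based; clamp top edge
  tf <- u - i0
  wx <- .catmull_rom(tf[1]); wy <- .catmull_rom(tf[2]); wz <- .catmull_rom(tf[3])
  sten <- field$values[(i0[1] - 1 + 1):(i0[1] + 2 + 1),
                       (i0[2] - 1 + 1):(i0[2] + 2 + 1),
                       (i0[3] - 1 + 1):(i0[3] + 2 + 1)]

  contract <- function(ax, ay, az) {
    # sum_{ijk} ax_i ay_j az_k sten[i,j,k]
    tmp <- apply(sten, c(2, 3), function(v) sum(v * ax))
    tmp2 <- apply(tmp, 2, function(v) sum(v * ay))
    sum(tmp2 * az)
  }

  val <- contract(wx$w, wy$w, wz$w)
  # derivatives in fractional coordinates
  g_u <- c(contract(wx$dw, wy$w, wz$w),
           contract(wx$w, wy$dw, wz$w),
           contract(wx$w, wy$w, wz$dw))
  h_u <- matrix(0, 3, 3)
  h_u[1, 1] <- contract(wx$d2w, wy$w, wz$w)
  h_u[2, 2] <- contract(wx$w, wy$d2w, wz$w)
  h_u[3, 3] <- contract(wx$w, wy$w, wz$d2w)
  h_u[1, 2] <- h_u[2, 1] <- contract(wx$dw, wy$dw, wz$w)
  h_u[1, 3] <- h_u[3, 1] <- contract(wx$dw, wy$w, wz$dw)
  h_u[2, 3] <- h_u[3, 2] <- contract(wx$w, wy$dw, wz$dw)

  # chain rule back to Cartesian: u = solve(t(axes)) (p - origin)
  J <- solve(t(field$axes))   # du/dp
  grad <- as.numeric(t(J) %*% g_u)
  hess <- t(J) %*% h_u %*% J
  density_probe(val, grad, hess)
}

#' Finite-difference probe of a density field
#'
#' Central-difference gradient and Hessian at step `h` (default 1e-3 Bohr),
#' used as the independent check on analytic derivatives.
#'
#' @param field density field accepted by [probe_density()]
#' @param point numeric length-3, Bohr
#' @param h step, Bohr
#' @return list with `gradient` and `hessian`
#' @export
fd_probe <- function(field, point, h = 1e-3) {
  f <- function(p) probe_density(field, p)$value
  g <- numeric(3)
  H <- matrix(0, 3, 3)
  e <- diag(3) * h
  f0 <- f(point)
  for (i in 1:3) {
    g[i] <- (f(point + e[i, ]) - f(point - e[i, ])) / (2 * h)
    H[i, i] <- (f(point + e[i, ]) - 2 * f0 + f(point - e[i, ])) / h^2
    for (j in seq_len(i - 1)) {
      H[i, j] <- H[j, i] <-
        (f(point + e[i, ] + e[j, ]) - f(point + e[i, ] - e[j, ]) -
           f(point - e[i, ] + e[j, ]) + f(point - e[i, ] - e[j, ])) / (4 * h^2)
    }
  }
  list(gradient = g, hessian = H)
}
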