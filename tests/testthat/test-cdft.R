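test_that("reactivity descriptors: hand-evaluated case and identities", {
  d <- reactivity_descriptors(frontier_orbitals(-0.25, -0.05))
  expect_equal(d$I, 0.25)
  expect_equal(d$A, 0.05)
  expect_equal(d$eta, 0.10)
  expect_equal(d$mu, -0.15)
  expect_equal(d$chi, 0.15)
  expect_equal(d$gap, 0.20)
  expect_equal(d$omega, 0.1125)
  # degenerate limit: zero hardness, omega undefined (sentinel, not Inf)
  d0 <- reactivity_descriptors(frontier_orbitals(-0.1, -0.1))
  expect_equal(d0$eta, 0)
  expect_equal(d0$gap, 0)
  expect_true(is.na(d0$omega))
})

test_that("descriptor identities hold to machine precision", {
  set.seed(21)
  for (i in 1:20) {
    eh <- runif(1, -0.5, -0.1)
    el <- eh + runif(1, 0, 0.4)
    d <- reactivity_descriptors(frontier_orbitals(eh, el))
    expect_equal(d$mu + d$chi, 0, tolerance = 1e-15)
    expect_equal(2 * d$eta - (d$I - d$A), 0, tolerance = 1e-15)
    expect_gte(d$gap, 0)
    if (!is.na(d$omega)) {
      expect_equal(d$omega, d$mu^2 / (2 * d$eta), tolerance = 1e-15)
    }
  }
})

test_that("hardness and gap are shift-invariant; mu shifts with the levels", {
  d1 <- reactivity_descriptors(frontier_orbitals(-0.31, -0.07))
  shift <- 0.123
  d2 <- reactivity_descriptors(frontier_orbitals(-0.31 + shift,
                                                 -0.07 + shift))
  expect_equal(d2$eta, d1$eta, tolerance = 1e-12)
  expect_equal(d2$gap, d1$gap, tolerance = 1e-12)
  # mu = (E_HOMO + E_LUMO)/2, so a common upward shift raises mu with it
  expect_equal(d2$mu, d1$mu + shift, tolerance = 1e-12)
})

test_that("descriptors convert to eV with the standard factor", {
  d <- reactivity_descriptors(frontier_orbitals(-0.25, -0.05))
  ev <- descriptors_ev(d)
  expect_equal(ev[["gap"]], 0.20 * 27.2114)
})

test_that("bare nuclear MEP is Coulombic", {
  nuc <- list(atom_site("H", c(0, 0, 0)))
  V <- mep_at_points(nuc, NULL, matrix(c(1, 0, 0), 1))$V
  expect_equal(V, 1.0, tolerance = 1e-12)
  # superposition: two sources add
  nuc2 <- list(atom_site("H", c(0, 0, 0)), atom_site("O", c(3, 0, 0)))
  V2 <- mep_at_points(nuc2, NULL, matrix(c(1, 0, 0), 1))$V
  expect_equal(V2, 1 / 1 + 8 / 2, tolerance = 1e-12)
  # proximity rejection names the offending point
  expect_error(mep_at_points(nuc, NULL, matrix(c(0.01, 0, 0), 1)),
               "within 0.05 Bohr")
})

test_that("point-charge electron sets are summed exactly", {
  pc <- data.frame(x = c(0, 1), y = c(0, 0), z = c(0, 0), q = c(0.5, 0.5))
  V <- mep_at_points(list(), pc, matrix(c(3, 0, 0), 1))$V
  expect_equal(V, -(0.5 / 3 + 0.5 / 2), tolerance = 1e-14)
})

test_that("neutral system potential vanishes at long range", {
  # nucleus Z=1 with a unit Gaussian electron cloud, probed far away
  g <- gaussian_grid(alpha = 1.5, charge = 1, n = 41, half_width = 5)
  V <- mep_at_points(list(atom_site("H", c(0, 0, 0))), g,
                     matrix(c(50, 0, 0), 1))$V
  expect_lt(abs(V), 1e-3)
})

test_that("Gaussian cloud potential matches the erf closed form", {
  alpha <- 1.2
  g <- gaussian_grid(alpha = alpha, charge = 1, n = 61, half_width = 6)
  pts <- rbind(c(3, 0, 0), c(0, 4, 0), c(2.5, 2.5, 0))
  V <- mep_at_points(list(), g, pts)$V
  erf <- function(x) 2 * pnorm(x * sqrt(2)) - 1
  for (i in seq_len(nrow(pts))) {
    r <- sqrt(sum(pts[i, ]^2))
    expect_equal(V[i], -erf(sqrt(alpha) * r) / r, tolerance = 1e-4)
  }
})

test_that("MEP superposition: union of sources equals sum of parts", {
  pc1 <- data.frame(x = 0, y = 0, z = 0, q = 0.7)
  pc2 <- data.frame(x = 2, y = 1, z = 0, q = 0.3)
  pts <- matrix(c(4, 0, 0, 0, 5, 1), ncol = 3, byrow = TRUE)
  V1 <- mep_at_points(list(), pc1, pts)$V
  V2 <- mep_at_points(list(), pc2, pts)$V
  V12 <- mep_at_points(list(), rbind(pc1, pc2), pts)$V
  expect_equal(V12, V1 + V2, tolerance = 1e-12)
})

test_that("MPI: uniform, antisymmetric, and brute-force randomized cases", {
  # uniform V = c over any surface: MPI = |c|
  r <- mpi_polar_area(rep(-0.02, 10), runif(10, 0.5, 2))
  expect_equal(r$mpi_au, 0.02, tolerance = 1e-14)
  # antisymmetric V with equal areas: MPI = |c|; half the area is polar at
  # any threshold below |c|
  r2 <- mpi_polar_area(c(rep(0.03, 5), rep(-0.03, 5)), rep(1, 10),
                       polar_threshold = 0.01)
  expect_equal(r2$mpi_au, 0.03, tolerance = 1e-14)
  expect_equal(r2$polar_fraction, 100)
  # randomized surface vs independent direct summation
  set.seed(99)
  V <- rnorm(200, sd = 0.05)
  areas <- runif(200, 0.1, 1)
  r3 <- mpi_polar_area(V, areas)
  oracle <- sum(areas * abs(V)) / sum(areas)
  expect_equal(r3$mpi_au, oracle, tolerance = 1e-12)
  expect_equal(r3$mpi_kcal, oracle * 627.509, tolerance = 1e-12)
  # scale consistency: doubling all areas leaves MPI unchanged
  expect_equal(mpi_polar_area(V, 2 * areas)$mpi_au, r3$mpi_au,
               tolerance = 1e-14)
  expect_error(mpi_polar_area(numeric(0), numeric(0)), "empty")
})

test_that("isosurface extraction: sphere area and surface-MEP pipeline", {
  # for a Gaussian, rho = iso is a sphere of radius sqrt(log(N/iso)/alpha)
  alpha <- 1
  g <- gaussian_grid(alpha = alpha, charge = 1, n = 41, half_width = 5)
  iso <- 1e-3
  surf <- density_isosurface(g, iso)
  expect_gt(nrow(surf), 100)
  r_expect <- sqrt(log((alpha / pi)^(3 / 2) / iso) / alpha)
  radii <- sqrt(surf$x^2 + surf$y^2 + surf$z^2)
  expect_lt(abs(mean(radii) - r_expect) / r_expect, 0.02)
  expect_lt(abs(sum(surf$area) - 4 * pi * r_expect^2) /
              (4 * pi * r_expect^2), 0.05)
  # end-to-end: MEP on the isosurface feeds the MPI
  V <- mep_at_points(list(atom_site("H", c(0, 0, 0))), g,
                     as.matrix(surf[, c("x", "y", "z")]))$V
  res <- mpi_polar_area(V, surf$area)
  expect_gt(res$mpi_kcal, 0)
  expect_true(res$polar_fraction >= 0 && res$polar_fraction <= 100)
})
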