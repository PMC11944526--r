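test_that("Abramov closed form matches hand-evaluated values", {
  # first term vanishes at rho = 0
  expect_equal(abramov_g(0, 0.06), 0.01, tolerance = 1e-15)
  # extended-precision re-evaluation of the closed form
  rho <- 0.0222
  lap <- 0.0952
  expected <- 0.3 * (3 * pi^2)^(2 / 3) * exp((5 / 3) * log(rho)) + lap / 6
  expect_equal(abramov_g(rho, lap), expected, tolerance = 1e-12)
  expect_error(abramov_g(-0.1, 0), ">= 0")
})

test_that("density-only G estimate tracks the wavefunction value", {
  # reference row O3-H...Ow prints G = 0.0346 from the wavefunction; the
  # density-only estimate at its printed rho and Laplacian lands within 3e-4
  expect_lt(abs(abramov_g(0.0389, 0.1314) - 0.0346), 3e-4)
})

test_that("virial relation v = lap/4 - 2G holds exactly", {
  expect_equal(virial_v(0.06 / 8 * 1, 0.06), virial_v(0.0075, 0.06))
  expect_equal(virial_v(0.0075, 0.06), 0)  # balance point G = lap/8
  # printed G and Laplacian reproduce the printed v within 2e-4
  expect_lt(abs(virial_v(0.0346, 0.1314) - (-0.0363)), 2e-4)
  set.seed(5)
  for (i in 1:25) {
    G <- runif(1, 0, 0.1)
    lap <- runif(1, -0.2, 0.2)
    v <- virial_v(G, lap)
    expect_equal(v + 2 * G - lap / 4, 0, tolerance = 1e-15)
  }
})

test_that("energy density h = G + v on printed rows", {
  expect_equal(energy_density_h(0.0346, -0.0363), -0.0017)
  expect_equal(energy_density_h(0.0429, -0.0484), -0.0055)
  expect_equal(energy_density_h(0.02, -0.02), 0)
})

test_that("every reference table row satisfies h = G + v at print precision", {
  tab <- qtaim_reference()
  expect_identical(nrow(tab), 25L)
  expect_true(all(abs(tab$h - (tab$G + tab$v)) <= 1e-4 + 1e-12))
})

test_that("interaction classification reproduces the reference verdicts", {
  # intramolecular O1-H...O=C: moderate H-bond with partial covalency
  intra <- intramolecular_reference()
  G <- abramov_g(intra[["rho"]], intra[["lap"]])
  params <- topological_parameters(intra[["rho"]], intra[["lap"]],
                                   G, virial_v(G, intra[["lap"]]))
  expect_lt(abs(params$h - intra[["h"]]), 5e-4)
  expect_identical(classify_interaction(params),
                   "moderate_Hbond_partial_covalent")
  # radical row II: rho below the 0.015 cutoff, positive h: van der Waals
  p_vdw <- topological_parameters(0.0121, 0.0457, 0.0102, -0.0090)
  expect_identical(classify_interaction(p_vdw), "van_der_Waals")
  # shared-shell regime
  p_cov <- topological_parameters(0.35, -0.5, 0.1, -0.3)
  expect_identical(classify_interaction(p_cov), "covalent")
  # weak noncovalent H-bond: h >= 0, ratio <= 1, rho above cutoff
  p_weak <- topological_parameters(0.0222, 0.0952, 0.0208, -0.0177)
  expect_identical(classify_interaction(p_weak), "weak_Hbond_noncovalent")
})

test_that("BE regression: default coefficients and monotonicity", {
  expect_equal(estimate_be(0), 0.7423)
  expect_equal(round_half_away(estimate_be(0.0425), 1), -8.7)
  # the published coefficients do NOT reproduce the solvent-table BE column
  expect_equal(estimate_be(0.0222), -4.21, tolerance = 0.005)
  ref <- qtaim_reference()
  expect_gt(abs(estimate_be(0.0222) - ref$be_kcal[1]), 4)
  # strictly decreasing in rho for negative slope
  rho <- seq(0, 0.06, by = 0.005)
  expect_true(all(diff(estimate_be(rho)) < 0))
})

test_that("refit BE coefficients recover the table's calibration", {
  fit <- fit_be_coefficients()
  expect_equal(fit$n, 25L)
  expect_gt(fit$r_squared, 0.999)
  ref <- qtaim_reference()
  pred <- fit$slope * ref$rho + fit$intercept
  expect_lt(max(abs(pred - ref$be_kcal)), 0.1)
  # clearly distinct from the published intramolecular calibration
  expect_lt(fit$slope, -300)
})

test_that("BCP search finds the midpoint saddle of a symmetric diatomic", {
  d <- make_diatomic_density(c("O", "O"), 3.0, params = soft_params())
  cp <- find_bcp(d$field, c(0.1, -0.1, 0.2))
  expect_true(cp$converged)
  expect_lt(cp$grad_norm, 1e-8)
  expect_equal(cp$position, c(0, 0, 0), tolerance = 1e-6)
  expect_identical(cp$signature, -1L)
  expect_identical(cp$rank, 3L)
})

test_that("BCP of homonuclear pairs lies on the bisector plane", {
  for (sep in c(2.0, 2.8, 3.6)) {
    d <- make_diatomic_density(c("H", "H"), sep, params = soft_params())
    cp <- find_bcp(d$field, c(0.15, 0.1, -0.3))
    expect_lt(abs(cp$position[3]), 1e-6)
    expect_identical(cp$signature, -1L)
  }
})

test_that("a guess at a nucleus reports a nuclear attractor, not a BCP", {
  d <- make_diatomic_density(c("O", "O"), 3.0, params = soft_params())
  cp <- find_bcp(d$field, c(0, 0, 1.5))
  expect_true(cp$is_nuclear)
  expect_identical(cp$signature, -3L)
  expect_equal(cp$position, c(0, 0, 1.5), tolerance = 1e-9)
})

test_that("unequal diatomic BCP matches the dense line-scan oracle", {
  params <- soft_params()
  params <- rbind(params,
                  data.frame(element = "N", amplitude = 2 * 0.60,
                             decay = 0.45))
  d <- make_diatomic_density(c("N", "O"), 3.0, params = params)
  expect_identical(d$bcp_method, "line_scan")
  cp <- find_bcp(d$field, c(0.05, -0.02, 0.1))
  expect_lt(abs(cp$position[3] - d$bcp_reference[3]), 1e-4)
  expect_equal(cp$position[1:2], c(0, 0), tolerance = 1e-6)
  expect_identical(cp$signature, -1L)
})

test_that("BCP search works on an interpolated grid field", {
  # sample a symmetric soft diatomic onto a grid and search there
  d <- make_diatomic_density(c("H", "H"), 2.4, params = soft_params())
  n <- 31
  ax <- seq(-3, 3, length.out = n)
  vals <- array(0, dim = c(n, n, n))
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    vals[i, j, k] <- probe_density(d$field, c(ax[i], ax[j], ax[k]))$value
  }
  g <- density_grid(rep(-3, 3), diag(ax[2] - ax[1], 3), vals,
                    d$field$geometry)
  cp <- find_bcp(g, c(0.1, -0.1, 0.15))
  expect_true(cp$converged)
  expect_equal(cp$position, c(0, 0, 0), tolerance = 1e-3)
  expect_identical(cp$signature, -1L)
})

test_that("interaction tables render with table-matching rounding", {
  expect_identical(nrow(interaction_table(list())), 0L)
  params <- topological_parameters(0.0222, 0.0952, 0.0208, -0.0177)
  rec <- interaction_record("O1...H-Ow", 1.92185, 176.9067, params)
  tab <- interaction_table(list(rec), rounding = "table")
  expect_equal(tab$ratio, 0.9)  # 0.851 prints as 0.9 at one decimal
  expect_equal(tab$h, 0.0031)
  full <- interaction_table(list(rec), rounding = "full")
  expect_equal(full$ratio, 0.0177 / 0.0208, tolerance = 1e-12)
})

test_that("G must be nonnegative in topological parameters", {
  expect_error(topological_parameters(0.01, 0.05, -0.001, -0.01),
               ">= 0")
})
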