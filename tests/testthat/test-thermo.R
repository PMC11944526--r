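test_that("BDE arithmetic: hand-evaluated and thermoneutral cases", {
  led <- enthalpy_ledger("toy", "vacuum",
                         sites = list(S = c(H_AH = -1000.0,
                                            H_Aradical = -999.4)),
                         references = c(H_Hradical = -0.5))
  expect_equal(bde(led, "S"), 62.7509, tolerance = 1e-10)
  led0 <- enthalpy_ledger("toy", "vacuum",
                          sites = list(S = c(H_AH = -1000.0,
                                             H_Aradical = -999.5)),
                          references = c(H_Hradical = -0.5))
  expect_equal(bde(led0, "S"), 0, tolerance = 1e-10)
  expect_error(bde(led, "missing"), "no site")
  expect_error(ip(led, "S"), "H_cation")
})

test_that("zero-cost ionization gives IP = 0", {
  led <- enthalpy_ledger("toy", "vacuum",
                         sites = list(S = c(H_AH = -500, H_cation = -500)),
                         references = c(H_electron = 0))
  expect_equal(ip(led, "S"), 0)
})

test_that("mechanism identities hold on random seeded ledgers", {
  offsets <- numeric(0)
  for (seed in 1:100) {
    rl <- random_ledger(seed)
    led <- rl$ledger
    sites <- ledger_sites(led)
    expected_offset <- hartree_to_kcal(
      rl$refs[["H_proton"]] + rl$refs[["H_electron"]] -
        rl$refs[["H_Hradical"]])
    site_offsets <- vapply(sites, function(s) {
      # SET-PT and SPLET sums agree identically
      expect_equal(ip(led, s) + pde(led, s) - pa(led, s) - ete(led, s),
                   0, tolerance = 1e-10)
      ip(led, s) + pde(led, s) - bde(led, s)
    }, numeric(1))
    # (IP+PDE) - BDE is the same reference-only constant on every site
    expect_lt(max(site_offsets) - min(site_offsets), 1e-10)
    expect_equal(site_offsets[[1]], expected_offset, tolerance = 1e-8)
    offsets <- c(offsets, site_offsets[[1]])
  }
  expect_gt(stats::sd(offsets), 0)  # the constant varies across ledgers
})

test_that("ledger inverse construction recovers targets exactly", {
  worst <- 0
  for (seed in 1:100) {
    rl <- random_ledger(seed)
    led <- rl$ledger
    for (i in seq_len(nrow(rl$targets))) {
      s <- rl$targets$site[i]
      worst <- max(worst,
                   abs(bde(led, s) - rl$targets$BDE[i]),
                   abs(ip(led, s) - rl$targets$IP[i]),
                   abs(pa(led, s) - rl$targets$PA[i]))
    }
  }
  expect_lt(worst, 1e-10)
})

test_that("degenerate all-zero targets give a thermoneutral ledger", {
  targets <- data.frame(site = c("A", "B"), BDE = 0, IP = 0, PA = 0)
  refs <- c(H_Hradical = 0, H_proton = 0, H_electron = 0)
  led <- make_ledger(targets, refs, seed = 3)
  for (s in c("A", "B")) {
    expect_equal(bde(led, s), 0, tolerance = 1e-10)
    expect_equal(ip(led, s), 0, tolerance = 1e-10)
    expect_equal(pde(led, s), 0, tolerance = 1e-10)
    expect_equal(pa(led, s), 0, tolerance = 1e-10)
    expect_equal(ete(led, s), 0, tolerance = 1e-10)
  }
})

test_that("relative solution enthalpy is an order-preserving pointwise map", {
  expect_equal(relative_solution_enthalpy(-100, -100), 0)
  expect_equal(relative_solution_enthalpy(-100.001, -100), -0.627509,
               tolerance = 1e-9)
  # solvent series sorted by dielectric constant stays sorted under the map
  h_vac <- -800
  h_sol <- h_vac - seq(0.001, 0.008, by = 0.001)
  dh <- relative_solution_enthalpy(h_sol, h_vac)
  expect_true(all(diff(dh) < 0))
  expect_identical(order(dh), order(h_sol))
})

test_that("percent difference matches the printed site comparisons", {
  expect_equal(percent_difference(83.605, 80.662), 3.649, tolerance = 5e-4)
  expect_equal(percent_difference(88.072, 80.662), 9.187, tolerance = 5e-4)
  expect_equal(percent_difference(5, 5), 0)
  expect_error(percent_difference(1, 0), "nonzero")
})

test_that("water-effect statistics match direct-formula recomputation", {
  set.seed(77)
  for (i in 1:20) {
    n <- sample(3:8, 1)
    a <- runif(n, 70, 100)
    b <- a + rnorm(n, sd = 2)
    w <- water_effect(a, b)
    expect_equal(w$per_site_pct, 100 * (b - a) / a, tolerance = 1e-12)
    expect_equal(w$mean_pct, 100 * (mean(b) - mean(a)) / mean(a),
                 tolerance = 1e-12)
    expect_equal(w$sd_no_water,
                 sqrt(sum((a - mean(a))^2) / (n - 1)), tolerance = 1e-12)
    expect_equal(w$sd_pct,
                 100 * (w$sd_water - w$sd_no_water) / w$sd_no_water,
                 tolerance = 1e-12)
  }
  # identical vectors: all zeros, equal SDs
  v <- c(80, 85, 90)
  w0 <- water_effect(v, v)
  expect_equal(unname(w0$per_site_pct), c(0, 0, 0))
  expect_equal(w0$mean_pct, 0)
  expect_equal(w0$sd_pct, 0)
  expect_error(water_effect(v, v[1:2]), "length")
  expect_error(water_effect(1, 2), "at least two")
})

test_that("sample SD convention is what reproduces the reference dispersion", {
  ref <- mechanism_reference()
  lut <- ref[ref$compound == "luteolin", ]
  w <- water_effect(lut$bde_no_water, lut$bde_water)
  expect_equal(w$sd_no_water, 5.04, tolerance = 0.005)
  expect_equal(w$sd_water, 5.40, tolerance = 0.005)
  # the population convention would give ~4.37 / 4.68 and must not be used
  pop_sd <- sqrt(mean((lut$bde_no_water - mean(lut$bde_no_water))^2))
  expect_lt(pop_sd, 4.5)
})

test_that("mechanism summary replays the luteolin verdicts", {
  led <- luteolin_ledger()
  m <- mechanism_summary(led)
  expect_equal(m$table$BDE, c(88.072, 92.153, 80.662, 83.605),
               tolerance = 1e-9)
  expect_identical(m$preferred_site, "O3H")
  expect_identical(m$preferred_mechanism, "HAT")
  expect_false(m$site_tie)
  expect_false(m$mechanism_tie)
  expect_equal(m$table$IP_PDE, m$table$PA_ETE, tolerance = 1e-10)
  expect_equal(m$table$PA_ETE - m$table$BDE, rep(2.989, 4),
               tolerance = 1e-9)
})

test_that("ties are detected and flagged", {
  targets <- data.frame(site = c("A", "B"), BDE = c(80, 80),
                        IP = c(150, 150), PA = c(300, 300))
  refs <- c(H_Hradical = -0.5, H_proton = 0.26, H_electron = -0.04)
  led <- make_ledger(targets, refs, seed = 9)
  m <- mechanism_summary(led)
  expect_true(m$site_tie)
  expect_identical(m$preferred_site, "A")  # lowest index wins
  # a ledger where all three descriptor minima coincide flags the mechanism:
  # references with H_proton + H_electron = H_Hradical make IP+PDE = BDE
  targets2 <- data.frame(site = "A", BDE = 80, IP = 40, PA = 50)
  refs0 <- c(H_Hradical = -0.5, H_proton = -0.5, H_electron = 0)
  led3 <- make_ledger(targets2, refs0, seed = 11)
  m3 <- mechanism_summary(led3)
  expect_equal(m3$table$IP_PDE, m3$table$BDE, tolerance = 1e-9)
  expect_true(m3$mechanism_tie)
  expect_identical(m3$preferred_mechanism, "HAT")
})

test_that("argmin agrees with exhaustive comparison over seeded ledgers", {
  for (seed in 1:100) {
    rl <- random_ledger(seed + 500)
    m <- mechanism_summary(rl$ledger)
    tab <- m$table
    expect_identical(m$preferred_site, tab$site[order(tab$BDE)[1]])
    mins <- c(HAT = min(tab$BDE), `SET-PT` = min(tab$IP_PDE),
              SPLET = min(tab$PA_ETE))
    expect_identical(m$preferred_mechanism,
                     names(mins)[order(mins)[1]])
  }
})

test_that("incomplete ledgers fail with the gaps listed", {
  led <- enthalpy_ledger("toy", "vacuum",
                         sites = list(S = c(H_AH = -500,
                                            H_Aradical = -499.5)),
                         references = c(H_Hradical = -0.5))
  expect_error(mechanism_summary(led), "H_cation")
  expect_error(mechanism_summary(led), "H_proton")
})
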