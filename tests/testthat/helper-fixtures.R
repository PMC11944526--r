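# Shared fixture builders for the suite. Everything is generated in code;
# no binary fixtures.

# Single spherical Gaussian density rho(r) = N exp(-alpha r^2) sampled on a
# cubic grid; N chosen so the field integrates to `charge` electrons.
gaussian_grid <- function(alpha = 1, charge = 1, n = 21, half_width = 4,
                          center = c(0, 0, 0), element = "H") {
  h <- 2 * half_width / (n - 1)
  ax <- seq(-half_width, half_width, length.out = n)
  norm <- charge * (alpha / pi)^(3 / 2)
  vals <- array(0, dim = c(n, n, n))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      r2 <- (ax[i] - center[1])^2 + (ax[j] - center[2])^2 +
        (ax - center[3])^2
      vals[i, j, ] <- norm * exp(-alpha * r2)
    }
  }
  geom <- molecule_geometry(list(atom_site(element, center)),
                            label = "gaussian fixture")
  density_grid(origin = c(-half_width, -half_width, -half_width) ,
               axes = diag(h, 3), values = vals, geometry = geom)
}

# closed form for the same Gaussian at a point
gaussian_value <- function(p, alpha = 1, charge = 1, center = c(0, 0, 0)) {
  charge * (alpha / pi)^(3 / 2) * exp(-alpha * sum((p - center)^2))
}

# Independent minimal cube parser used as the second-reader oracle: line
# oriented, no shared code with read_cube().
oracle_read_cube_values <- function(path) {
  ln <- readLines(path)
  natoms <- abs(as.integer(strsplit(trimws(ln[3]), "\\s+")[[1]][1]))
  counts <- sapply(4:6, function(i) {
    abs(as.integer(strsplit(trimws(ln[i]), "\\s+")[[1]][1]))
  })
  body <- ln[-(1:(6 + natoms))]
  vals <- as.numeric(unlist(lapply(body, function(l) {
    strsplit(trimws(l), "\\s+")[[1]]
  })))
  list(counts = counts, values = vals)
}

# promolecular parameter table with soft (hydrogen-like) decay for
# derivative-accuracy checks
soft_params <- function() {
  data.frame(element = c("H", "O"),
             amplitude = c(0.2815, 0.60),
             decay = c(0.529, 0.45))
}

random_ledger <- function(seed) {
  set.seed(seed)
  n_sites <- sample(2:5, 1)
  targets <- data.frame(
    site = paste0("S", seq_len(n_sites)),
    BDE = runif(n_sites, 60, 110),
    IP = runif(n_sites, 120, 220),
    PA = runif(n_sites, 280, 380)
  )
  refs <- c(H_Hradical = -0.5 + rnorm(1, sd = 0.01),
            H_proton = rnorm(1, sd = 0.01),
            H_electron = rnorm(1, sd = 0.005))
  list(targets = targets, refs = refs,
       ledger = make_ledger(targets, refs, seed = seed))
}
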