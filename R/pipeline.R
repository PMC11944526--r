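#' Run configuration for the analysis pipeline
#'
#' Validated key-value configuration for [run_qtaim()] and
#' [run_mechanism()]. Unknown keys are rejected; the effective
#' configuration (defaults merged with overrides) is attached to every
#' result so runs are auditable.
#'
#' @param ... configuration overrides; recognised keys:
#'   `rounding` (`"full"` or `"table"`), `seed` (integer),
#'   `qtaim.tolerance` (gradient norm threshold, a.u.),
#'   `qtaim.rho_vdw_cutoff` (a.u.), `qtaim.be_slope`, `qtaim.be_intercept`
#'   (kcal/mol calibration), `qtaim.max_pair_angstrom` and
#'   `qtaim.min_angle_degree` (BCP seeding prescreen), `mep.isovalue`
#'   (electrons/Bohr^3), `mep.polar_threshold` (a.u. or `NA` for
#'   surface-mean), `out_dir` (output directory or `NA` to skip writing)
#' @return object of class `run_config`
#' @export
run_config <- function(...) {
  defaults <- list(
    rounding = "full",
    seed = 1L,
    qtaim.tolerance = 1e-8,
    qtaim.rho_vdw_cutoff = 0.015,
    qtaim.be_slope = -223.08,
    qtaim.be_intercept = 0.7423,
    qtaim.max_pair_angstrom = 3.5,
    qtaim.min_angle_degree = 90,
    mep.isovalue = 4e-4,
    mep.polar_threshold = NA_real_,
    out_dir = NA_character_
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, over)
  if (!cfg$rounding %in% c("full", "table")) {
    stop("rounding must be 'full' or 'table'")
  }
  structure(cfg, class = "run_config")
}

write_outputs <- function(tab, stem, out_dir) {
  if (is.na(out_dir)) return(invisible(NULL))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(out_dir, paste0(stem, ".csv"))
  jsn <- file.path(out_dir, paste0(stem, ".json"))
  utils::write.csv(tab, csv, row.names = FALSE)
  jsonlite::write_json(tab, jsn, dataframe = "rows", digits = NA,
                       na = "null")
  invisible(c(csv, jsn))
}

#' QTAIM analysis stage
#'
#' Two modes. With a density field (`promolecular_density` or
#' `density_grid`): seed the bond-critical-point search at the midpoints of
#' all H...acceptor pairs closer than `qtaim.max_pair_angstrom` with donor
#' angle above `qtaim.min_angle_degree`, run the Newton search, keep
#' signature -1 saddles, and emit an interaction table with topology from
#' the Abramov/virial closed forms, classification and BE. With a BCP
#' parameter table (data.frame shaped like [qtaim_reference()]): ingest
#' supplied G and v (they take precedence over the closed-form estimates),
#' verify `h = G + v` against the printed column, flag ratio and BE cells
#' that differ from the supplied reference, and classify every row.
#'
#' @param input density field or BCP parameter data.frame
#' @param config a [run_config()]
#' @return list with `table` (data.frame) and, in field mode, `bcps`
#'   (list of `critical_point`); in ingest mode `consistency` (data.frame
#'   of h = G + v residuals and mismatch flags). Tables are written to
#'   `config$out_dir` when set.
#' @export
run_qtaim <- function(input, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  if (is.data.frame(input)) {
    out <- qtaim_ingest(input, config)
  } else if (inherits(input, "promolecular_density") ||
             inherits(input, "density_grid")) {
    out <- qtaim_search(input, config)
  } else {
    stop("input must be a density field or a BCP parameter data.frame")
  }
  out$config <- config
  write_outputs(out$table, "qtaim_interactions", config$out_dir)
  if (!is.null(out$consistency)) {
    write_outputs(out$consistency, "qtaim_consistency", config$out_dir)
  }
  out
}

qtaim_ingest <- function(tab, config) {
  need <- c("interaction", "rho", "lap", "G", "v", "h")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("BCP table missing column(s): ",
                         paste(miss, collapse = ", "))
  records <- vector("list", nrow(tab))
  h_resid <- numeric(nrow(tab))
  ratio_flag <- logical(nrow(tab))
  be_flag <- logical(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    params <- topological_parameters(tab$rho[i], tab$lap[i], tab$G[i],
                                     tab$v[i])
    h_resid[i] <- params$h - tab$h[i]
    if ("ratio" %in% names(tab)) {
      ratio_flag[i] <- round_half_away(params$ratio, 1) != tab$ratio[i]
    }
    be_here <- estimate_be(params$rho, config$qtaim.be_slope,
                           config$qtaim.be_intercept)
    if ("be_kcal" %in% names(tab)) {
      # materially different calibration, not printed-rounding noise
      be_flag[i] <- abs(be_here - tab$be_kcal[i]) > 0.1
    }
    records[[i]] <- interaction_record(
      label = tab$interaction[i],
      length_angstrom = if ("length_angstrom" %in% names(tab)) {
        tab$length_angstrom[i]
      } else NA_real_,
      angle_degree = if ("angle_degree" %in% names(tab)) {
        tab$angle_degree[i]
      } else NA_real_,
      params = params, be = be_here,
      rho_vdw_cutoff = config$qtaim.rho_vdw_cutoff)
  }
  consistency <- data.frame(
    interaction = tab$interaction,
    h_printed = tab$h,
    h_recomputed = tab$G + tab$v,
    h_residual = h_resid,
    h_ok = abs(h_resid) <= 1e-4 + 1e-12,
    ratio_differs = ratio_flag,
    be_differs_from_reference = be_flag,
    stringsAsFactors = FALSE
  )
  list(table = interaction_table(records, config$rounding),
       consistency = consistency)
}

qtaim_search <- function(field, config) {
  geom <- field$geometry
  pos <- geometry_positions(geom)
  elems <- geometry_elements(geom)
  max_d <- angstrom_to_bohr(config$qtaim.max_pair_angstrom)

  # geometric prescreen: H...acceptor pairs with a donor heavy atom whose
  # donor angle exceeds the configured minimum
  hyd <- which(elems == "H")
  acc <- which(elems != "H")
  seeds <- list()
  labels <- character(0)
  lengths <- numeric(0)
  angles <- numeric(0)
  for (h in hyd) {
    if (length(acc) == 0) break
    dh <- sqrt(rowSums((pos[acc, , drop = FALSE] -
                          matrix(pos[h, ], length(acc), 3,
                                 byrow = TRUE))^2))
    donor <- acc[which.min(dh)]
    for (ai in seq_along(acc)) {
      a <- acc[ai]
      if (a == donor) next
      if (dh[ai] > max_d) next
      v1 <- pos[donor, ] - pos[h, ]
      v2 <- pos[a, ] - pos[h, ]
      ang <- acos(sum(v1 * v2) /
                    sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
      if (ang < config$qtaim.min_angle_degree) next
      seeds[[length(seeds) + 1]] <- (pos[h, ] + pos[a, ]) / 2
      labels <- c(labels, paste0(elems[donor], donor, "-H", h, "...",
                                 elems[a], a))
      lengths <- c(lengths, bohr_to_angstrom(dh[ai]))
      angles <- c(angles, ang)
    }
  }
  if (length(seeds) == 0 && nrow(pos) == 2) {
    # diatomic: single internuclear seed
    seeds <- list((pos[1, ] + pos[2, ]) / 2)
    labels <- paste0(elems[1], "1...", elems[2], "2")
    lengths <- bohr_to_angstrom(sqrt(sum((pos[1, ] - pos[2, ])^2)))
    angles <- NA_real_
  }
  if (length(seeds) == 0) {
    stop("no H...acceptor pairs satisfy the seeding prescreen")
  }

  records <- list()
  bcps <- list()
  failures <- character(0)
  for (i in seq_along(seeds)) {
    cp <- tryCatch(
      find_bcp(field, seeds[[i]], tol = config$qtaim.tolerance),
      error = function(e) NULL)
    if (is.null(cp) || !cp$converged || cp$signature != -1) {
      failures <- c(failures, sprintf(
        "%s: %s", labels[i],
        if (is.null(cp)) "search error"
        else if (!cp$converged) sprintf("no convergence (|grad|=%.2e)",
                                        cp$grad_norm)
        else sprintf("signature %d, not a BCP", cp$signature)))
      next
    }
    G <- abramov_g(cp$rho, cp$lap)
    v <- virial_v(G, cp$lap)
    params <- topological_parameters(cp$rho, cp$lap, G, v)
    records[[length(records) + 1]] <- interaction_record(
      labels[i], lengths[i], angles[i], params,
      be = estimate_be(cp$rho, config$qtaim.be_slope,
                       config$qtaim.be_intercept),
      rho_vdw_cutoff = config$qtaim.rho_vdw_cutoff)
    bcps[[length(bcps) + 1]] <- cp
  }
  if (length(records) == 0) {
    stop("no BCP found for any seeded pair - ",
         paste(failures, collapse = "; "))
  }
  list(table = interaction_table(records, config$rounding), bcps = bcps,
       failures = failures)
}

#' Mechanism analysis stage
#'
#' Computes the mechanism table for each supplied ledger and, when exactly
#' two ledgers share their site set (a reference and an explicit-water
#' environment), the water-effect statistics block. With a single ledger
#' the statistics are omitted with a warning.
#'
#' @param ledgers an [enthalpy_ledger()] or list of them (reference
#'   environment first)
#' @param config a [run_config()]
#' @return list with `mechanisms` (list of `mechanism_table`), `water`
#'   (`water_effect_stats` or `NULL`) and `config`; tables written to
#'   `config$out_dir` when set
#' @export
run_mechanism <- function(ledgers, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  if (inherits(ledgers, "enthalpy_ledger")) ledgers <- list(ledgers)
  if (!length(ledgers) ||
      !all(vapply(ledgers, inherits, logical(1), "enthalpy_ledger"))) {
    stop("ledgers must be enthalpy_ledger objects")
  }
  mechs <- lapply(ledgers, mechanism_summary)

  water <- NULL
  if (length(ledgers) == 2 &&
      identical(ledger_sites(ledgers[[1]]), ledger_sites(ledgers[[2]]))) {
    water <- water_effect(mechs[[1]]$table$BDE, mechs[[2]]$table$BDE,
                          sites = mechs[[1]]$table$site)
  } else if (length(ledgers) == 1) {
    warning("single environment: water-effect statistics omitted")
  }

  if (!is.na(config$out_dir)) {
    for (m in mechs) {
      tab <- m$table
      if (config$rounding == "table") {
        num <- vapply(tab, is.numeric, logical(1))
        tab[num] <- lapply(tab[num], round_half_away, digits = 3)
      }
      write_outputs(tab, paste0("mechanism_", m$compound, "_",
                                gsub("[^A-Za-z0-9]+", "-",
                                     m$environment)),
                    config$out_dir)
    }
    if (!is.null(water)) {
      stats_tab <- data.frame(
        statistic = c(paste0("pct_change_", names(water$per_site_pct)),
                      "pct_change_mean", "sd_no_water", "sd_water",
                      "pct_change_sd"),
        value = c(unname(water$per_site_pct), water$mean_pct,
                  water$sd_no_water, water$sd_water, water$sd_pct))
      write_outputs(stats_tab, "water_effect", config$out_dir)
    }
  }
  list(mechanisms = mechs, water = water, config = config)
}
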