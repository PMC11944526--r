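#' Build an enthalpy ledger
#'
#' Enthalpies (Hartree) of the closed-shell antioxidant AH, its radical A*,
#' radical cation [AH*]+ and anion [A:]- per abstraction site, plus the
#' H*/H+/e- reference enthalpies, for one compound in one environment. The
#' reference enthalpies are required explicit inputs: no baked-in constants.
#'
#' @param compound text
#' @param environment text (`"vacuum"`, a solvent name, or
#'   `"explicit-water"`)
#' @param sites named list; each element a named numeric vector with any of
#'   `H_AH`, `H_Aradical`, `H_cation`, `H_anion` (Hartree)
#' @param references named numeric vector with any of `H_Hradical`,
#'   `H_proton`, `H_electron` (Hartree)
#' @return object of class `enthalpy_ledger`
#' @export
enthalpy_ledger <- function(compound, environment, sites,
                            references = c()) {
  stopifnot(is.list(sites))
  for (s in names(sites)) {
    v <- sites[[s]]
    bad <- setdiff(names(v), c("H_AH", "H_Aradical", "H_cation", "H_anion"))
    if (length(bad)) stop("unknown species field(s) for site ", s, ": ",
                          paste(bad, collapse = ", "))
    if (any(!is.finite(v))) stop("non-finite enthalpy for site ", s)
  }
  bad <- setdiff(names(references),
                 c("H_Hradical", "H_proton", "H_electron"))
  if (length(bad)) stop("unknown reference field(s): ",
                        paste(bad, collapse = ", "))
  if (any(!is.finite(references))) stop("non-finite reference enthalpy")
  structure(
    list(compound = compound, environment = environment,
         sites = sites, references = references),
    class = "enthalpy_ledger"
  )
}

#' @export
print.enthalpy_ledger <- function(x, ...) {
  cat("<enthalpy_ledger>", x$compound, "/", x$environment, "-",
      length(x$sites), "sites,", length(x$references), "references\n")
  invisible(x)
}

#' Sites present in a ledger
#' @param ledger an `enthalpy_ledger`
#' @return character vector of site labels
#' @export
ledger_sites <- function(ledger) names(ledger$sites)

# fetch one species enthalpy with a descriptive deferred error
ledger_species <- function(ledger, site, species) {
  sv <- ledger$sites[[site]]
  if (is.null(sv)) {
    stop("ledger for ", ledger$compound, "/", ledger$environment,
         " has no site '", site, "'")
  }
  if (!species %in% names(sv)) {
    stop("site '", site, "' of ", ledger$compound, "/", ledger$environment,
         " is missing species enthalpy '", species, "'")
  }
  unname(sv[[species]])
}

ledger_reference <- function(ledger, key) {
  if (!key %in% names(ledger$references)) {
    stop("ledger for ", ledger$compound, "/", ledger$environment,
         " is missing reference enthalpy '", key, "'")
  }
  unname(ledger$references[[key]])
}

#' Load an enthalpy ledger from a long-format table
#'
#' Accepts CSV or JSON with columns `compound`, `environment`, `site`,
#' `species`, `enthalpy_hartree`. Species values: `AH`, `Aradical`,
#' `cation`, `anion` for site rows; reference rows use site `"_reference"`
#' with species `Hradical`, `proton`, `electron`. Duplicate
#' (compound, environment, site, species) rows are an error. Returns one
#' ledger per (compound, environment) pair.
#'
#' @param path CSV (`.csv`) or JSON (`.json`) file
#' @return named list of [enthalpy_ledger()]s, keyed
#'   `"compound|environment"`; empty list for an empty table
#' @export
load_ledger <- function(path) {
  if (!file.exists(path)) stop("ledger file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    tab <- jsonlite::fromJSON(path)
    tab <- as.data.frame(tab, stringsAsFactors = FALSE)
  } else {
    tab <- utils::read.csv(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  }
  if (nrow(tab) == 0) return(list())
  need <- c("compound", "environment", "site", "species",
            "enthalpy_hartree")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    stop("ledger table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  key4 <- paste(tab$compound, tab$environment, tab$site, tab$species,
                sep = "|")
  if (anyDuplicated(key4)) {
    stop("duplicate ledger row(s): ",
         paste(unique(key4[duplicated(key4)]), collapse = "; "))
  }
  species_field <- c(AH = "H_AH", Aradical = "H_Aradical",
                     cation = "H_cation", anion = "H_anion")
  ref_field <- c(Hradical = "H_Hradical", proton = "H_proton",
                 electron = "H_electron")
  out <- list()
  for (keypair in unique(paste(tab$compound, tab$environment, sep = "|"))) {
    parts <- strsplit(keypair, "|", fixed = TRUE)[[1]]
    sub <- tab[tab$compound == parts[1] & tab$environment == parts[2], ]
    refs_rows <- sub[sub$site == "_reference", ]
    site_rows <- sub[sub$site != "_reference", ]
    sites <- list()
    for (s in unique(site_rows$site)) {
      sr <- site_rows[site_rows$site == s, ]
      unknown <- setdiff(sr$species, names(species_field))
      if (length(unknown)) stop("unknown species '", unknown[1],
                                "' for site ", s)
      sites[[s]] <- stats::setNames(sr$enthalpy_hartree,
                                    species_field[sr$species])
    }
    refs <- c()
    if (nrow(refs_rows)) {
      unknown <- setdiff(refs_rows$species, names(ref_field))
      if (length(unknown)) stop("unknown reference species '",
                                unknown[1], "'")
      refs <- stats::setNames(refs_rows$enthalpy_hartree,
                              ref_field[refs_rows$species])
    }
    out[[keypair]] <- enthalpy_ledger(parts[1], parts[2], sites, refs)
  }
  out
}

#' Write an enthalpy ledger to a long-format CSV
#'
#' Inverse of [load_ledger()] for a single ledger.
#'
#' @param ledger an `enthalpy_ledger`
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_ledger <- function(ledger, path) {
  stopifnot(inherits(ledger, "enthalpy_ledger"))
  species_name <- c(H_AH = "AH", H_Aradical = "Aradical",
                    H_cation = "cation", H_anion = "anion")
  ref_name <- c(H_Hradical = "Hradical", H_proton = "proton",
                H_electron = "electron")
  rows <- list()
  for (s in names(ledger$sites)) {
    v <- ledger$sites[[s]]
    rows[[length(rows) + 1]] <- data.frame(
      compound = ledger$compound, environment = ledger$environment,
      site = s, species = unname(species_name[names(v)]),
      enthalpy_hartree = unname(v), stringsAsFactors = FALSE)
  }
  if (length(ledger$references)) {
    rows[[length(rows) + 1]] <- data.frame(
      compound = ledger$compound, environment = ledger$environment,
      site = "_reference",
      species = unname(ref_name[names(ledger$references)]),
      enthalpy_hartree = unname(ledger$references),
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
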