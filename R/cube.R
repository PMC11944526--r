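#' Create a volumetric density grid
#'
#' A scalar field sampled on a regular (possibly non-orthogonal) lattice:
#' origin and axis step vectors in Bohr, values in electrons/Bohr^3 stored as
#' a 3-D array indexed `[i, j, k]` along the three axes. All values must be
#' non-negative and the axis vectors linearly independent.
#'
#' @param origin numeric length-3, Bohr
#' @param axes 3x3 matrix whose *rows* are the per-voxel step vectors, Bohr
#' @param values numeric array `counts[1] x counts[2] x counts[3]`, or a
#'   vector with `counts` supplied
#' @param geometry attached [molecule_geometry()]
#' @param counts integer length-3, required when `values` is not an array
#' @return object of class `density_grid`
#' @export
density_grid <- function(origin, axes, values, geometry, counts = dim(values)) {
  origin <- as.numeric(origin)
  stopifnot(length(origin) == 3, all(is.finite(origin)))
  axes <- matrix(as.numeric(axes), 3, 3)
  if (abs(det(axes)) < 1e-14) stop("axis vectors must be linearly independent")
  counts <- as.integer(counts)
  if (length(counts) != 3 || any(counts < 1)) {
    stop("counts must be 3 positive integers")
  }
  values <- as.numeric(values)
  if (length(values) != prod(counts)) {
    stop("value count ", length(values), " != n1*n2*n3 = ", prod(counts))
  }
  if (any(!is.finite(values))) stop("grid values must be finite")
  if (any(values < 0)) stop("grid values must be >= 0 (electron density)")
  if (!inherits(geometry, "molecule_geometry")) {
    stop("geometry must be a molecule_geometry")
  }
  structure(
    list(origin = origin, axes = axes, counts = counts,
         values = array(values, dim = counts), geometry = geometry),
    class = "density_grid"
  )
}

#' @export
print.density_grid <- function(x, ...) {
  cat("<density_grid>", paste(x$counts, collapse = " x "), "voxels,",
      length(x$geometry$atoms), "atoms\n")
  invisible(x)
}

#' Read a Gaussian-style cube file
#'
#' Supports the common dialect: two comment lines; atom count and origin;
#' three axis records; atom block; values with the third index fastest.
#' Positive voxel counts mean Bohr; negative counts mean Angstrom and are
#' converted to Bohr on read. A negative atom count signals an orbital cube:
#' the single trailing orbital-id record is consumed (only single-orbital
#' cubes are accepted).
#'
#' @param path file path
#' @return a [density_grid()]
#' @export
read_cube <- function(path) {
  if (!file.exists(path)) stop("cube file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 6) stop("cube parse error: header truncated")

  # byte offsets of each line start, for error reporting
  line_bytes <- c(0, cumsum(nchar(lines, type = "bytes") + 1L))

  num_tokens <- function(line, lineno) {
    toks <- strsplit(trimws(line), "[ \t]+")[[1]]
    vals <- suppressWarnings(as.numeric(toks))
    if (any(is.na(vals))) {
      stop("cube parse error: non-numeric token '",
           toks[which(is.na(vals))[1]], "' at line ", lineno,
           " (byte offset ", line_bytes[lineno], ")")
    }
    vals
  }

  hdr <- num_tokens(lines[3], 3)
  if (length(hdr) < 4) stop("cube parse error: bad atom/origin record")
  natoms_raw <- hdr[1]
  orbital_cube <- natoms_raw < 0
  natoms <- abs(as.integer(natoms_raw))
  origin <- hdr[2:4]

  axes <- matrix(0, 3, 3)
  counts <- integer(3)
  angstrom <- logical(3)
  for (i in 1:3) {
    rec <- num_tokens(lines[3 + i], 3 + i)
    if (length(rec) < 4) stop("cube parse error: bad axis record ", i)
    counts[i] <- abs(as.integer(rec[1]))
    angstrom[i] <- rec[1] < 0
    axes[i, ] <- rec[2:4]
  }
  # negative count convention: that axis (and the origin) are in Angstrom
  if (any(angstrom)) {
    axes[angstrom, ] <- angstrom_to_bohr(axes[angstrom, , drop = FALSE])
    origin <- angstrom_to_bohr(origin)
  }

  if (natoms < 1) stop("cube parse error: no atoms in header")
  atom_lines <- lines[seq(7, length.out = natoms)]
  atoms <- vector("list", natoms)
  for (a in seq_len(natoms)) {
    rec <- num_tokens(atom_lines[a], 6 + a)
    if (length(rec) < 5) stop("cube parse error: bad atom record ", a)
    pos <- rec[3:5]
    if (any(angstrom)) pos <- angstrom_to_bohr(pos)
    atoms[[a]] <- atom_site(z_to_element(as.integer(rec[1])), pos)
  }

  first_value_line <- 6 + natoms + 1
  if (orbital_cube) {
    orb <- num_tokens(lines[first_value_line], first_value_line)
    if (orb[1] != 1) {
      stop("cube parse error: multi-orbital cubes are not supported (",
           orb[1], " orbitals)")
    }
    first_value_line <- first_value_line + 1
  }

  nexpect <- prod(counts)
  value_lines <- lines[seq(first_value_line, length.out =
                             max(0, length(lines) - first_value_line + 1))]
  toks <- unlist(strsplit(trimws(value_lines), "[ \t]+"), use.names = FALSE)
  toks <- toks[nzchar(toks)]
  vals <- suppressWarnings(as.numeric(toks))
  if (any(is.na(vals))) {
    stop("cube parse error: non-numeric token '", toks[which(is.na(vals))[1]],
         "' in value block")
  }
  if (length(vals) != nexpect) {
    stop("cube parse error: value block has ", length(vals),
         " values, expected ", nexpect, " (truncated near byte offset ",
         line_bytes[length(line_bytes)], ")")
  }

  geom <- molecule_geometry(atoms, label = trimws(lines[1]))
  # cube order: first index slowest, third fastest
  arr <- aperm(array(vals, dim = rev(counts)), c(3, 2, 1))
  density_grid(origin, axes, arr, geom, counts = counts)
}

#' Write a Gaussian-style cube file
#'
#' Always emits the Bohr dialect (positive voxel counts). Values are written
#' with 17 significant digits so that a read/write round trip is bit-exact.
#'
#' @param grid a [density_grid()]
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_cube <- function(grid, path) {
  stopifnot(inherits(grid, "density_grid"))
  if (length(grid$geometry$atoms) < 1) stop("grid has no atoms")
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("cannot open '", path, "' for writing: ", conditionMessage(e))
  })
  on.exit(close(con))

  label <- grid$geometry$label
  if (!nzchar(label)) label <- "phenolox density grid"
  writeLines(c(label, "electron density (electrons/Bohr^3), Bohr units"), con)
  natoms <- length(grid$geometry$atoms)
  cat(sprintf("%5d %15.10f %15.10f %15.10f\n", natoms,
              grid$origin[1], grid$origin[2], grid$origin[3]), file = con)
  for (i in 1:3) {
    cat(sprintf("%5d %15.10f %15.10f %15.10f\n", grid$counts[i],
                grid$axes[i, 1], grid$axes[i, 2], grid$axes[i, 3]), file = con)
  }
  for (a in grid$geometry$atoms) {
    cat(sprintf("%5d %15.10f %15.10f %15.10f %15.10f\n", a$z, as.numeric(a$z),
                a$position[1], a$position[2], a$position[3]), file = con)
  }
  # third index fastest, 6 per record, line breaks within each (i, j) run
  n3 <- grid$counts[3]
  vals_by_row <- matrix(as.vector(aperm(grid$values, c(3, 2, 1))), nrow = n3)
  # vals_by_row columns enumerate (j within i) in cube order
  for (col in seq_len(ncol(vals_by_row))) {
    v <- vals_by_row[, col]
    for (start in seq(1, length(v), by = 6)) {
      chunk <- v[start:min(start + 5, length(v))]
      cat(paste(sprintf("% .16E", chunk), collapse = " "), "\n",
          sep = "", file = con)
    }
  }
  invisible(path)
}
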