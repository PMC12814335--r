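# Gaussian cube handling. Values are stored flattened in cube order (first
# grid axis slowest, third fastest); grid_points() reproduces the matching
# coordinates so quadrature is a plain Riemann sum over (points, values).

ATOMIC_NUMBERS <- c(H = 1, C = 6, N = 7, O = 8, F = 9, Na = 11, Mg = 12,
                    P = 15, S = 16, Cl = 17)

element_from_z <- function(z) {
  sym <- names(ATOMIC_NUMBERS)[match(z, ATOMIC_NUMBERS)]
  if (anyNA(sym)) {
    stop("unsupported atomic number(s) in cube header: ",
         paste(unique(z[is.na(sym)]), collapse = ", "))
  }
  sym
}

new_density_grid <- function(origin, axes, npoints, values, atoms,
                             negative_tolerance = 1e-4) {
  stopifnot(length(origin) == 3L, is.matrix(axes), all(dim(axes) == c(3L, 3L)),
            length(npoints) == 3L)
  npoints <- as.integer(npoints)
  if (any(npoints < 1L)) stop("all grid dimensions must be >= 1")
  if (length(values) != prod(npoints)) {
    stop("value count ", length(values), " does not match grid ",
         paste(npoints, collapse = "x"))
  }
  if (any(!is.finite(values))) stop("non-finite density values")
  if (min(values) < -abs(negative_tolerance)) {
    stop("density has negative values beyond tolerance (min = ",
         format(min(values)), "); raise negative_tolerance if this is a ",
         "correlated-density artifact")
  }
  structure(list(origin = as.numeric(origin), axes = axes, npoints = npoints,
                 values = as.numeric(values), atoms = atoms),
            class = "density_grid")
}

#' Read a Gaussian cube file
#'
#' Parses the standard cube dialect: two comment lines, an atom-count/origin
#' line, three axis lines, the atom block, then values with the third grid
#' index running fastest. Positive axis counts mean bohr; negative counts
#' (angstrom convention) are converted to bohr on input, so the returned grid
#' is always in atomic units.
#'
#' @param path cube file
#' @param negative_tolerance magnitude of negative density tolerated (cube
#'   files of correlated densities can carry tiny negative values)
#' @return a `density_grid`: origin (bohr), axes (3x3 step vectors, bohr),
#'   npoints, values (electrons/bohr^3, flattened in cube order) and the
#'   header atoms as a data frame
#' @export
read_cube <- function(path, negative_tolerance = 1e-4) {
  if (!file.exists(path)) stop("cannot read cube file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 7L) stop("malformed cube file (too short): ", path)
  nums <- function(i) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    if (anyNA(v)) stop("cube parse error at line ", i, " of ", path)
    v
  }
  hd <- nums(3L)
  natoms <- as.integer(hd[1L])
  if (is.na(natoms)) stop("cube parse error at line 3 of ", path)
  # natoms < 0 flags an extra DSET line after the atom block (orbital cubes)
  has_dset <- natoms < 0L
  natoms <- abs(natoms)
  origin <- hd[2:4]
  npoints <- integer(3)
  axes <- matrix(0, 3, 3)
  for (k in 1:3) {
    ax <- nums(3L + k)
    npoints[k] <- as.integer(ax[1L])
    axes[k, ] <- ax[2:4]
  }
  # negative point counts mark angstrom axes per the cube convention
  ang <- npoints < 0L
  npoints <- abs(npoints)
  if (any(ang)) axes[ang, ] <- angstrom_to_bohr(axes[ang, , drop = FALSE])
  atom_lines <- 7L:(6L + natoms)
  if (max(atom_lines) > length(lines)) stop("cube file truncated: ", path)
  atoms <- do.call(rbind, lapply(atom_lines, function(i) {
    v <- nums(i)
    if (length(v) < 5L) stop("cube parse error at line ", i, " of ", path)
    data.frame(element = element_from_z(as.integer(v[1L])),
               x = v[3L], y = v[4L], z = v[5L], stringsAsFactors = FALSE)
  }))
  body_start <- 6L + natoms + if (has_dset) 1L else 0L
  values <- suppressWarnings(as.numeric(unlist(
    strsplit(trimws(lines[(body_start + 1L):length(lines)]), "\\s+"))))
  values <- values[!is.na(values)]
  new_density_grid(origin, axes, npoints, values, atoms,
                   negative_tolerance = negative_tolerance)
}

#' Write a density grid to a Gaussian cube file
#'
#' @param grid a `density_grid`
#' @param path output file
#' @param comment first comment line
#' @return `path`, invisibly
#' @export
write_cube <- function(grid, path, comment = "density written by clr3disp") {
  stopifnot(inherits(grid, "density_grid"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(comment, "all lengths in bohr"), con)
  fmt <- function(n, v) sprintf("%5d %12.6f %12.6f %12.6f", n, v[1], v[2], v[3])
  writeLines(fmt(nrow(grid$atoms), grid$origin), con)
  for (k in 1:3) writeLines(fmt(grid$npoints[k], grid$axes[k, ]), con)
  for (i in seq_len(nrow(grid$atoms))) {
    z <- ATOMIC_NUMBERS[[grid$atoms$element[i]]]
    writeLines(sprintf("%5d %12.6f %12.6f %12.6f %12.6f", z, as.numeric(z),
                       grid$atoms$x[i], grid$atoms$y[i], grid$atoms$z[i]), con)
  }
  v <- grid$values
  n <- length(v)
  idx <- seq(1L, n, by = 6L)
  for (i in idx) {
    writeLines(paste(sprintf("%13.5e", v[i:min(i + 5L, n)]), collapse = " "),
               con)
  }
  invisible(path)
}

#' Cartesian coordinates of every grid point
#'
#' @param grid a `density_grid`
#' @return an N x 3 matrix (bohr) in the same flattened order as `grid$values`
#' @export
grid_points <- function(grid) {
  n <- grid$npoints
  i1 <- rep(seq_len(n[1]) - 1L, each = n[2] * n[3])
  i2 <- rep(rep(seq_len(n[2]) - 1L, each = n[3]), times = n[1])
  i3 <- rep(seq_len(n[3]) - 1L, times = n[1] * n[2])
  cbind(i1, i2, i3) %*% grid$axes +
    matrix(grid$origin, nrow = n[1] * n[2] * n[3], ncol = 3, byrow = TRUE)
}

#' Volume of one grid voxel (bohr^3)
#' @param grid a `density_grid`
#' @return scalar voxel volume
#' @export
voxel_volume <- function(grid) abs(det(grid$axes))

#' Integral of the density over the grid (electron count)
#' @param grid a `density_grid`
#' @return Riemann-sum integral of the density, electrons
#' @export
density_integral <- function(grid) sum(grid$values) * voxel_volume(grid)

#' @export
print.density_grid <- function(x, ...) {
  cat("density_grid:", paste(x$npoints, collapse = " x "), "points,",
      nrow(x$atoms), "atoms, integral =",
      format(density_integral(x), digits = 6), "e\n")
  invisible(x)
}
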