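# Hirshfeld (stockholder) partitioning of a molecular density on a cube grid
# into atomic volume ratios gamma_A = V_A / V_A^free, the central quantity of
# the volume-scaling dispersion model: effective atomic polarizabilities and
# C6 coefficients scale as gamma and gamma^2.

PROMOLECULE_FLOOR <- 1e-12  # electrons/bohr^3; below it weights are zeroed

#' Hirshfeld weight fields on a density grid
#'
#' At every grid point, atom A's stockholder weight is its free-atom density
#' divided by the promolecule density (the sum of all atoms' free densities):
#' \eqn{w_A(r) = \rho_A^{free}(|r - R_A|) / \sum_B \rho_B^{free}(|r - R_B|)}.
#' Points where the promolecule falls below `floor` are excluded (all weights
#' zero there); on retained points the weights sum to one by construction.
#'
#' @param grid a `density_grid`
#' @param atoms data frame of QM sites (element, x, y, z in bohr); defaults to
#'   the cube header atoms
#' @param free_densities named list of `free_atom_density`, one per atom row
#'   (matched by position, not by name); defaults to packaged models for the
#'   atoms' elements
#' @param floor promolecule density floor, electrons/bohr^3
#' @return N_points x N_atoms matrix of weights (cube flattening order), with
#'   attribute `retained` flagging points above the floor
#' @export
promolecule_weights <- function(grid, atoms = grid$atoms,
                                free_densities = NULL,
                                floor = PROMOLECULE_FLOOR) {
  stopifnot(inherits(grid, "density_grid"), nrow(atoms) >= 1L)
  if (is.null(free_densities)) free_densities <- free_atom_models(atoms$element)
  stopifnot(length(free_densities) == nrow(atoms))
  pts <- grid_points(grid)
  w <- matrix(0, nrow = nrow(pts), ncol = nrow(atoms))
  for (a in seq_len(nrow(atoms))) {
    dr <- sqrt((pts[, 1] - atoms$x[a])^2 + (pts[, 2] - atoms$y[a])^2 +
                 (pts[, 3] - atoms$z[a])^2)
    w[, a] <- free_densities[[a]]$fn(dr)
  }
  promol <- rowSums(w)
  retained <- promol > floor
  if (!any(retained)) {
    stop("promolecule density is zero everywhere: grid does not cover the molecule")
  }
  w[retained, ] <- w[retained, , drop = FALSE] / promol[retained]
  w[!retained, ] <- 0
  attr(w, "retained") <- retained
  w
}

#' Effective atomic volume of one atom in the molecule
#'
#' The r^3-weighted share of the molecular density assigned to atom A:
#' \eqn{V_A = \int |r - R_A|^3 w_A(r) \rho(r) d^3r}, evaluated as a Riemann
#' sum over the cube grid with distances measured from A's own nucleus.
#'
#' @param grid a `density_grid`
#' @param weights weight matrix from [promolecule_weights()]
#' @param atom_index column of `weights` / row of the atom table to evaluate
#' @param atoms atom table the weights were built for
#' @return effective volume, bohr^3 * electron
#' @export
atomic_volume <- function(grid, weights, atom_index, atoms = grid$atoms) {
  stopifnot(inherits(grid, "density_grid"),
            nrow(weights) == length(grid$values),
            atom_index >= 1L, atom_index <= ncol(weights))
  pts <- grid_points(grid)
  r3 <- ((pts[, 1] - atoms$x[atom_index])^2 +
           (pts[, 2] - atoms$y[atom_index])^2 +
           (pts[, 3] - atoms$z[atom_index])^2)^1.5
  sum(r3 * weights[, atom_index] * grid$values) * voxel_volume(grid)
}

#' Atomic volume ratios from a molecular density
#'
#' Computes the per-atom Hirshfeld volume ratio
#' \eqn{\gamma_A = V_A[\rho] / V_A^{free}} for every QM atom: the effective
#' in-molecule volume divided by the free-atom reference volume. Ground- and
#' excited-state densities give state-specific gamma sets; the excited-state
#' set is later rescaled atom-wise (see [scaled_volume_ratios()]).
#'
#' @param grid a `density_grid` holding the molecular density of one state
#' @param atoms QM atom table (element, x, y, z bohr); default cube header
#' @param free_densities per-atom free-atom models (packaged defaults if NULL)
#' @param state_label `"GS"` or an excited-state label (e.g. `"S1"`)
#' @param floor promolecule floor passed to [promolecule_weights()]
#' @return a `volume_ratio_set`: data frame (atom, element, gamma) with state
#'   and quadrature metadata attributes
#' @export
volume_ratios <- function(grid, atoms = grid$atoms, free_densities = NULL,
                          state_label = "GS", floor = PROMOLECULE_FLOOR) {
  if (is.null(free_densities)) free_densities <- free_atom_models(atoms$element)
  w <- promolecule_weights(grid, atoms, free_densities, floor = floor)
  gamma <- vapply(seq_len(nrow(atoms)), function(a) {
    v_mol <- atomic_volume(grid, w, a, atoms)
    v_free <- free_atom_volume(free_densities[[a]])
    v_mol / v_free
  }, numeric(1))
  if (any(!is.finite(gamma)) || any(gamma <= 0)) {
    stop("non-positive volume ratio for atom(s) ",
         paste(which(!is.finite(gamma) | gamma <= 0), collapse = ", "),
         "; the grid may not cover the density")
  }
  new_volume_ratio_set(
    atom = seq_len(nrow(atoms)), element = atoms$element, gamma = gamma,
    state_label = state_label, scaled = FALSE,
    quadrature_meta = list(
      spacing = diag(grid$axes %*% t(grid$axes))^0.5,
      npoints = grid$npoints, floor = floor,
      retained_fraction = mean(attr(w, "retained"))))
}

#' Construct a volume-ratio set from known values
#'
#' Builds a `volume_ratio_set` directly from per-atom gamma values, e.g. from
#' a deposited parametrization or from MM polarizabilities, bypassing the
#' density route of [volume_ratios()].
#'
#' @param gamma positive per-atom volume ratios
#' @param elements element symbol per atom
#' @param state_label electronic-state (or `"MM"`) label
#' @param scaled whether the set already includes excited-state rescaling
#' @return a `volume_ratio_set`
#' @export
volume_ratio_set <- function(gamma, elements, state_label = "GS",
                             scaled = FALSE) {
  stopifnot(length(gamma) == length(elements))
  new_volume_ratio_set(seq_along(gamma), elements, gamma, state_label,
                       scaled = scaled,
                       quadrature_meta = list(source = "user-supplied"))
}

new_volume_ratio_set <- function(atom, element, gamma, state_label,
                                 scaled = FALSE, quadrature_meta = list()) {
  stopifnot(length(atom) == length(gamma), length(element) == length(gamma),
            all(is.finite(gamma)), all(gamma > 0))
  structure(
    data.frame(atom = as.integer(atom), element = element, gamma = gamma,
               stringsAsFactors = FALSE),
    class = c("volume_ratio_set", "data.frame"),
    state_label = state_label, scaled = scaled,
    quadrature_meta = quadrature_meta)
}

#' MM-side volume ratios from MMPol polarizabilities
#'
#' For environment atoms no density is available; their volume ratios are
#' estimated directly from the polarizable force field's isotropic atomic
#' polarizabilities via the TS proportionality between polarizability and
#' volume: \eqn{\gamma_B = \alpha_B^{MM} / \alpha_B^{free}}.
#'
#' @param alpha_mm numeric vector of MM atomic polarizabilities, a.u.
#' @param elements element symbol per MM atom
#' @param params an `element_params` table
#' @return a `volume_ratio_set` labelled `"MM"` (state-independent)
#' @export
gamma_from_mm_polarizability <- function(alpha_mm, elements,
                                         params = load_element_params()) {
  stopifnot(length(alpha_mm) == length(elements))
  if (any(!is.finite(alpha_mm)) || any(alpha_mm <= 0)) {
    stop("MM polarizabilities must be positive and finite")
  }
  alpha_free <- element_lookup(params, elements)$alpha_free
  new_volume_ratio_set(atom = seq_along(alpha_mm), element = elements,
                       gamma = alpha_mm / alpha_free, state_label = "MM",
                       quadrature_meta = list(source = "MMPol polarizabilities"))
}

#' Read / write per-atom volume-ratio tables
#'
#' Delimited text with header `atom element gamma`; comment lines start `#`.
#' The state label is carried in a `# state:` header comment.
#'
#' @param path table file
#' @return a `volume_ratio_set`
#' @export
read_gamma_table <- function(path) {
  if (!file.exists(path)) stop("cannot read gamma table: ", path)
  lines <- readLines(path, warn = FALSE)
  state <- sub("^#\\s*state:\\s*", "", grep("^#\\s*state:", lines, value = TRUE))
  scaled <- any(grepl("^#\\s*scaled:\\s*true", lines))
  tab <- utils::read.table(path, header = TRUE, comment.char = "#",
                           stringsAsFactors = FALSE)
  needed <- c("atom", "element", "gamma")
  if (!all(needed %in% names(tab))) {
    stop("gamma table ", path, " must have columns: ",
         paste(needed, collapse = ", "))
  }
  new_volume_ratio_set(tab$atom, tab$element, tab$gamma,
                       state_label = if (length(state)) state[1] else "GS",
                       scaled = scaled,
                       quadrature_meta = list(source = path))
}

#' @rdname read_gamma_table
#' @param gammas a `volume_ratio_set`
#' @export
write_gamma_table <- function(gammas, path) {
  stopifnot(inherits(gammas, "volume_ratio_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# state: ", attr(gammas, "state_label")),
               if (isTRUE(attr(gammas, "scaled"))) "# scaled: true",
               "atom\telement\tgamma"), con)
  writeLines(sprintf("%d\t%s\t%.12f", gammas$atom, gammas$element,
                     gammas$gamma), con)
  invisible(path)
}
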