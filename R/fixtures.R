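# Seeded synthetic fixtures: model densities on cube grids with analytically
# known volume ratios, toy QM/MM geometries, and parameter/component tables.
# "Excitation" is emulated as a per-atom multiplicative density rescaling --
# in the non-overlapping limit the recovered gamma equals the applied scale
# exactly, giving constructed ground truth without any quantum chemistry.
# No physical realism is claimed for these densities.

#' Model molecular density on a cube grid
#'
#' Superposes scaled free-atom model densities,
#' \eqn{\rho(r) = \sum_A s_A \rho_A^{free}(|r - R_A|)}, on a regular grid
#' enclosing all atoms with the requested padding. With all scales 1 this is
#' exactly the promolecule (every \eqn{\gamma_A = 1}); per-atom scales
#' emulate an electronic-state change with known target
#' \eqn{\gamma_A = s_A} in the limit of non-overlapping atoms.
#'
#' @param recipe data frame (element, x, y, z) in bohr
#' @param scales per-atom multiplicative density factors (default all 1)
#' @param spacing grid spacing, bohr
#' @param padding margin beyond the atom bounding box, bohr
#' @param params an `element_params` table
#' @param origin,npoints optional explicit grid; atoms falling outside it are
#'   an error
#' @return a `density_grid`
#' @export
make_model_density <- function(recipe, scales = NULL, spacing = 0.25,
                               padding = 6, params = load_element_params(),
                               origin = NULL, npoints = NULL) {
  stopifnot(is.data.frame(recipe), nrow(recipe) >= 1L,
            all(c("element", "x", "y", "z") %in% names(recipe)),
            spacing > 0, padding >= 0)
  if (is.null(scales)) scales <- rep(1, nrow(recipe))
  stopifnot(length(scales) == nrow(recipe), all(scales > 0))
  pos <- as.matrix(recipe[, c("x", "y", "z")])
  axes <- diag(spacing, 3L)
  if (is.null(origin) || is.null(npoints)) {
    lo <- apply(pos, 2, min) - padding
    hi <- apply(pos, 2, max) + padding
    origin <- lo
    npoints <- pmax(2L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  } else {
    npoints <- as.integer(npoints)
    hi <- origin + (npoints - 1L) * spacing
    inside <- pos >= matrix(origin, nrow(pos), 3, byrow = TRUE) &
      pos <= matrix(hi, nrow(pos), 3, byrow = TRUE)
    if (!all(inside)) {
      stop("atom(s) ", paste(which(rowSums(inside) < 3L), collapse = ", "),
           " fall outside the requested grid")
    }
  }
  models <- free_atom_models(recipe$element, params = params, scales = scales)
  # reuse grid_points() by building the grid first with zero values
  grid <- new_density_grid(origin, axes, npoints,
                           values = numeric(prod(npoints)),
                           atoms = recipe[, c("element", "x", "y", "z")])
  pts <- grid_points(grid)
  vals <- numeric(nrow(pts))
  for (a in seq_len(nrow(recipe))) {
    dr <- sqrt((pts[, 1] - recipe$x[a])^2 + (pts[, 2] - recipe$y[a])^2 +
                 (pts[, 3] - recipe$z[a])^2)
    vals <- vals + models[[a]]$fn(dr)
  }
  grid$values <- vals
  grid
}

#' Generate a complete toy QM/MM system with ground-truth parameters
#'
#' Builds a seeded random chromophore-plus-environment system and every table
#' the pipeline consumes: geometry (PDB; QM = residue 1 chain Q, MM molecules
#' on chain M), ground/excited QM volume ratios, MM volume ratios, HHS
#' polarizability tables consistent with a known per-atom excited/ground
#' ratio, and a multi-frame component table drawn around known means. All
#' ground truths are recorded in a JSON manifest, so downstream results can
#' be checked against construction.
#'
#' The HHS tables are constructed as \eqn{\alpha^{HHS,GS}_A = \gamma^{GS}_A
#' \alpha^{free}_A} (TS-consistent) and \eqn{\alpha^{HHS,ExS}_A = \rho_A
#' \alpha^{HHS,GS}_A} with a drawn ratio \eqn{\rho_A}, so the true scaling
#' factors are \eqn{\beta_A = (\gamma^{GS}_A / \gamma^{ExS}_A) \rho_A} and
#' the true scaled ratios \eqn{\tilde\gamma_A = \gamma^{GS}_A \rho_A}.
#'
#' @param seed integer RNG seed; identical seeds give identical systems
#' @param n_qm,n_mm atom counts (each >= 1; `n_mm = 0` allowed for the
#'   empty-environment case)
#' @param box cubic box edge, bohr
#' @param min_dist minimum interatomic distance, bohr. The default 4.5 bohr
#'   (~2.4 angstrom) is a typical closest nonbonded H...H approach: toy
#'   environment atoms sit at or outside van der Waals contact with the
#'   chromophore, as in a real protein/solvent shell, rather than
#'   interpenetrating the region where the damping function is switching the
#'   dispersion off
#' @param n_frames frames in the component table
#' @param dir optional output directory; when given, all files plus
#'   `manifest.json` are written there
#' @return list with the in-memory objects (geometry, gamma sets, hhs sets,
#'   component data frame, true beta/scaled gammas) and, if `dir` was given,
#'   the file paths
#' @export
make_toy_system <- function(seed, n_qm = 3, n_mm = 10, box = 15,
                            min_dist = 4.5, n_frames = 5, dir = NULL) {
  stopifnot(n_qm >= 1L, n_mm >= 0L, box > 0, min_dist > 0, n_frames >= 1L)
  n_tot <- n_qm + n_mm
  if (box / min_dist < n_tot^(1 / 3)) {
    stop("box too small to place ", n_tot, " atoms ", min_dist, " bohr apart")
  }
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))

  pos <- matrix(NA_real_, n_tot, 3L)
  placed <- 0L
  attempts <- 0L
  while (placed < n_tot) {
    attempts <- attempts + 1L
    if (attempts > 20000L) {
      stop("box too small to place ", n_tot, " atoms ", min_dist,
           " bohr apart")
    }
    cand <- stats::runif(3, 0, box)
    ok <- placed == 0L ||
      min(sqrt(colSums((t(pos[seq_len(placed), , drop = FALSE]) - cand)^2))) >=
        min_dist
    if (ok) {
      placed <- placed + 1L
      pos[placed, ] <- cand
    }
  }
  elements <- sample(c("H", "C", "N", "O"), n_tot, replace = TRUE)
  mm_group <- if (n_mm > 0) paste0(1L + ceiling(seq_len(n_mm) / 3), "M")
  sites <- data.frame(
    element = elements,
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    subsystem = rep(c("QM", "MM"), c(n_qm, n_mm)),
    group_id = c(rep("1Q", n_qm), mm_group),
    stringsAsFactors = FALSE)
  geometry <- new_system_geometry(sites, "generated in bohr")

  params <- load_element_params()
  qm_el <- elements[seq_len(n_qm)]
  gamma_gs_v <- stats::runif(n_qm, 0.75, 1.10)
  gamma_exs_v <- gamma_gs_v * stats::runif(n_qm, 0.92, 1.08)
  hhs_ratio <- stats::runif(n_qm, 0.85, 1.15)
  alpha_free_qm <- element_lookup(params, qm_el)$alpha_free
  hhs_gs_v <- gamma_gs_v * alpha_free_qm
  hhs_exs_v <- hhs_ratio * hhs_gs_v
  beta_true <- (gamma_gs_v / gamma_exs_v) * hhs_ratio
  gamma_scaled_true <- gamma_gs_v * hhs_ratio

  gamma_gs <- new_volume_ratio_set(seq_len(n_qm), qm_el, gamma_gs_v, "GS")
  gamma_exs <- new_volume_ratio_set(seq_len(n_qm), qm_el, gamma_exs_v, "S1")
  gamma_mm <- if (n_mm > 0) {
    new_volume_ratio_set(seq_len(n_mm), elements[n_qm + seq_len(n_mm)],
                         stats::runif(n_mm, 0.6, 1.2), "MM")
  }
  hhs_gs <- distributed_polarizabilities(hhs_gs_v, qm_el, "GS",
                                         source_meta = "synthetic")
  hhs_exs <- distributed_polarizabilities(hhs_exs_v, qm_el, "S1",
                                          source_meta = "synthetic")

  comp_means <- c(de_gs_pol = 14000, r_ss_pol = -15, r_lr_disp = -650,
                  r_ss_disp = 220)
  comp_sd <- c(80, 4, 40, 25)
  labels <- paste0("site", LETTERS[1:3])
  components <- do.call(rbind, lapply(labels, function(lab) {
    offset <- stats::rnorm(4, 0, c(150, 3, 60, 30))
    data.frame(label = lab, frame = seq_len(n_frames),
               de_gs_pol = stats::rnorm(n_frames, comp_means[1] + offset[1],
                                        comp_sd[1]),
               r_ss_pol = stats::rnorm(n_frames, comp_means[2] + offset[2],
                                       comp_sd[2]),
               r_lr_disp = stats::rnorm(n_frames, comp_means[3] + offset[3],
                                        comp_sd[3]),
               r_ss_disp = stats::rnorm(n_frames, comp_means[4] + offset[4],
                                        comp_sd[4]),
               stringsAsFactors = FALSE)
  }))

  out <- list(geometry = geometry, gamma_qm_gs = gamma_gs,
              gamma_qm_exs_unscaled = gamma_exs, gamma_mm = gamma_mm,
              hhs_gs = hhs_gs, hhs_exs = hhs_exs, components = components,
              beta_true = beta_true, gamma_scaled_true = gamma_scaled_true,
              seed = as.integer(seed))
  if (!is.null(dir)) {
    out$files <- write_toy_system(out, dir)
  }
  out
}

write_toy_system <- function(sys, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  geo <- sys$geometry
  pdb_path <- file.path(dir, "system.pdb")
  resno <- as.integer(sub("[A-Z]$", "", geo$group_id))
  chain <- sub("^[0-9]+", "", geo$group_id)
  bio3d::write.pdb(
    file = pdb_path,
    xyz = as.vector(t(bohr_to_angstrom(geometry_positions(geo)))),
    resno = resno, chain = chain,
    resid = ifelse(geo$subsystem == "QM", "CHR", "ENV"),
    eleno = seq_len(nrow(geo)),
    elety = paste0(geo$element, seq_len(nrow(geo))),
    elesy = geo$element)
  paths <- list(geometry = pdb_path)

  paths$gamma_qm_gs <- file.path(dir, "gamma_qm_gs.tsv")
  write_gamma_table(sys$gamma_qm_gs, paths$gamma_qm_gs)
  paths$gamma_qm_exs <- file.path(dir, "gamma_qm_exs_unscaled.tsv")
  write_gamma_table(sys$gamma_qm_exs_unscaled, paths$gamma_qm_exs)
  if (!is.null(sys$gamma_mm)) {
    paths$gamma_mm <- file.path(dir, "gamma_mm.tsv")
    write_gamma_table(sys$gamma_mm, paths$gamma_mm)
  }

  paths$hhs <- file.path(dir, "hhs.tsv")
  con <- file(paths$hhs, "w")
  writeLines(c("# synthetic HHS-style distributed polarizabilities (a.u.)",
               "atom\telement\talpha_gs\talpha_exs"), con)
  writeLines(sprintf("%d\t%s\t%.12f\t%.12f", sys$hhs_gs$atom,
                     sys$hhs_gs$element, sys$hhs_gs$alpha,
                     sys$hhs_exs$alpha), con)
  close(con)

  paths$components <- file.path(dir, "components.tsv")
  con <- file(paths$components, "w")
  writeLines(c("# units: cm-1",
               "label\tframe\tde_gs_pol\tr_ss_pol\tr_lr_disp\tr_ss_disp"),
             con)
  writeLines(sprintf("%s\t%d\t%.6f\t%.6f\t%.6f\t%.6f",
                     sys$components$label, sys$components$frame,
                     sys$components$de_gs_pol, sys$components$r_ss_pol,
                     sys$components$r_lr_disp, sys$components$r_ss_disp), con)
  close(con)

  paths$manifest <- file.path(dir, "manifest.json")
  manifest <- list(
    seed = sys$seed,
    n_qm = sum(geo$subsystem == "QM"), n_mm = sum(geo$subsystem == "MM"),
    gamma_qm_gs = sys$gamma_qm_gs$gamma,
    gamma_qm_exs_unscaled = sys$gamma_qm_exs_unscaled$gamma,
    gamma_mm = if (!is.null(sys$gamma_mm)) sys$gamma_mm$gamma,
    beta_true = sys$beta_true,
    gamma_scaled_true = sys$gamma_scaled_true,
    files = lapply(paths, basename))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths
}
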