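# Pairwise QM-MM dispersion energies in the volume-scaling scheme:
# E = -sum_{A in QM} sum_{B in MM} f_AB * C6_AB / R_AB^6,
# with effective C6 coefficients built from volume ratios and a Fermi damping
# suppressing the R^-6 divergence at short range. QM-QM and MM-MM pairs are
# never included: only the chromophore-environment interaction shifts the
# excitation energy.

#' Damping specification for the pairwise dispersion sum
#'
#' The default is the Fermi-type damping of the TS scheme,
#' \eqn{f(R) = [1 + \exp(-d (R / (s_r (R^0_A + R^0_B)) - 1))]^{-1}},
#' with steepness `d = 20` and radius scaling `s_r = 0.97`. With
#' `radius_mode = "scaled"` the free-atom vdW radii entering \eqn{R^0} are
#' pre-scaled by \eqn{\gamma^{1/3}}, consistent with the volume scaling of the
#' polarizabilities. All three choices are recorded in every result's
#' metadata because short-range pair energies are sensitive to them.
#'
#' @param d steepness of the Fermi switch (dimensionless, > 0)
#' @param s_r scaling of the vdW-radius sum (dimensionless, > 0)
#' @param radius_mode `"scaled"` (radii scale as gamma^(1/3)) or `"free"`
#' @return a `damping_spec`
#' @export
damping_spec <- function(d = 20, s_r = 0.97,
                         radius_mode = c("scaled", "free")) {
  radius_mode <- match.arg(radius_mode)
  stopifnot(is.finite(d), d > 0, is.finite(s_r), s_r > 0)
  structure(list(form = "fermi", d = d, s_r = s_r, radius_mode = radius_mode),
            class = "damping_spec")
}

#' Fermi damping factor
#'
#' @param r_ab interatomic distance(s), bohr (> 0)
#' @param r0_a,r0_b effective vdW radii of the two atoms, bohr
#' @param spec a `damping_spec`
#' @return damping factor(s) in (0, 1)
#' @export
damping <- function(r_ab, r0_a, r0_b, spec = damping_spec()) {
  stopifnot(inherits(spec, "damping_spec"), all(r_ab > 0))
  1 / (1 + exp(-spec$d * (r_ab / (spec$s_r * (r0_a + r0_b)) - 1)))
}

#' Effective homonuclear C6 and polarizability from volume ratios
#'
#' In the volume-scaling scheme the in-molecule atomic polarizability is
#' \eqn{\alpha^{eff}_A = \gamma_A \alpha^{free}_A} and, because homonuclear
#' C6 goes as the polarizability squared,
#' \eqn{C_{6,AA}^{eff} = \gamma_A^2 C_{6,AA}^{free}}.
#'
#' @param gammas a `volume_ratio_set`
#' @param params an `element_params` table
#' @return data frame (atom, element, gamma, alpha_eff, c6_eff, r0_eff) where
#'   `r0_eff` is the free vdW radius scaled by gamma^(1/3)
#' @export
effective_c6_homonuclear <- function(gammas, params = load_element_params()) {
  stopifnot(inherits(gammas, "volume_ratio_set"))
  ref <- element_lookup(params, gammas$element)
  data.frame(atom = gammas$atom, element = gammas$element,
             gamma = gammas$gamma,
             alpha_eff = gammas$gamma * ref$alpha_free,
             c6_eff = gammas$gamma^2 * ref$c6_free,
             r0_eff = gammas$gamma^(1 / 3) * ref$r_vdw_free,
             r0_free = ref$r_vdw_free,
             stringsAsFactors = FALSE)
}

#' Heteronuclear C6 combination rule
#'
#' \deqn{C_{6,AB} = \frac{2 C_{6,AA} C_{6,BB}}
#'   {\frac{\alpha_B}{\alpha_A} C_{6,AA} + \frac{\alpha_A}{\alpha_B} C_{6,BB}}}
#' Symmetric in A and B and reducing to \eqn{C_{6,AA}} in the homonuclear
#' limit. Vectorized over its arguments.
#'
#' @param c6_aa,c6_bb homonuclear effective C6 of atoms A and B, a.u.
#' @param alpha_a,alpha_b effective polarizabilities, a.u.
#' @return combined C6_AB, a.u.
#' @export
combine_c6 <- function(c6_aa, c6_bb, alpha_a, alpha_b) {
  if (any(c6_aa <= 0) || any(c6_bb <= 0) || any(alpha_a <= 0) ||
        any(alpha_b <= 0)) {
    stop("C6 combination requires positive C6 and polarizabilities")
  }
  2 * c6_aa * c6_bb / ((alpha_b / alpha_a) * c6_aa +
                         (alpha_a / alpha_b) * c6_bb)
}

#' Pairwise QM-MM dispersion energy for one electronic state
#'
#' Sums \eqn{-f_{AB} C_{6,AB} R_{AB}^{-6}} over all QM-MM atom pairs (no
#' QM-QM, no MM-MM), with effective parameters from the state's QM volume
#' ratios and the state-independent MM volume ratios. Pairs beyond `cutoff`
#' are skipped (default: none). Contributions are aggregated per MM group
#' (residue/molecule) for per-residue maps.
#'
#' @param geometry a `system_geometry`
#' @param gamma_qm `volume_ratio_set` for the QM atoms (order = QM atom order
#'   within the geometry); for an excited state pass the scaled set
#' @param gamma_mm `volume_ratio_set` for the MM atoms
#' @param params an `element_params` table
#' @param spec a `damping_spec`
#' @param cutoff optional pair-distance cutoff, bohr (`Inf` = all pairs)
#' @param per_pair keep the full pair-resolved table (memory grows as
#'   N_QM x N_MM)
#' @param r_floor minimum allowed pair distance, bohr; closer pairs are an
#'   error (overlapping atoms)
#' @return a `dispersion_result`: state label, total energy (hartree and
#'   cm^-1), per-group sums, optional per-pair table, parameter metadata
#' @export
dispersion_energy <- function(geometry, gamma_qm, gamma_mm,
                              params = load_element_params(),
                              spec = damping_spec(), cutoff = Inf,
                              per_pair = FALSE, r_floor = 0.1) {
  stopifnot(inherits(geometry, "system_geometry"),
            inherits(gamma_qm, "volume_ratio_set"),
            inherits(gamma_mm, "volume_ratio_set"))
  if (is.null(cutoff) || !is.finite(cutoff)) cutoff <- Inf
  if (cutoff <= 0) stop("cutoff must be positive (got ", cutoff, ")")
  qm <- qm_sites(geometry)
  mm <- mm_sites(geometry)
  if (nrow(qm) != nrow(gamma_qm)) {
    stop("gamma_qm covers ", nrow(gamma_qm), " atoms but geometry has ",
         nrow(qm), " QM sites")
  }
  if (!identical(qm$element, gamma_qm$element)) {
    stop("gamma_qm elements do not match the geometry's QM sites")
  }
  state_label <- attr(gamma_qm, "state_label")
  eff_q <- effective_c6_homonuclear(gamma_qm, params)
  if (nrow(mm) == 0L) {
    return(new_dispersion_result(state_label, energy = 0,
                                 per_group = empty_group_table(),
                                 per_pair_tab = NULL,
                                 meta = result_meta(geometry, spec, cutoff)))
  }
  if (nrow(mm) != nrow(gamma_mm)) {
    stop("gamma_mm covers ", nrow(gamma_mm), " atoms but geometry has ",
         nrow(mm), " MM sites")
  }
  if (!identical(mm$element, gamma_mm$element)) {
    stop("gamma_mm elements do not match the geometry's MM sites")
  }
  eff_m <- effective_c6_homonuclear(gamma_mm, params)
  use_scaled_r0 <- spec$radius_mode == "scaled"
  r0_q <- if (use_scaled_r0) eff_q$r0_eff else eff_q$r0_free
  r0_m <- if (use_scaled_r0) eff_m$r0_eff else eff_m$r0_free

  pq <- geometry_positions(qm)
  pm <- geometry_positions(mm)
  # nQM x nMM distance matrix; systems here are chromophore + local
  # environment, so the dense matrix is affordable
  r2 <- outer(rowSums(pq^2), rowSums(pm^2), `+`) - 2 * pq %*% t(pm)
  r <- sqrt(pmax(r2, 0))
  if (any(r < r_floor)) {
    idx <- which(r < r_floor, arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "QM atom %d and MM atom %d are %.4f bohr apart (< %.2f): overlapping atoms",
      idx[1L], idx[2L], r[idx[1L], idx[2L]], r_floor))
  }
  c6_ab <- combine_c6(outer(eff_q$c6_eff, rep(1, nrow(mm))),
                      outer(rep(1, nrow(qm)), eff_m$c6_eff),
                      outer(eff_q$alpha_eff, rep(1, nrow(mm))),
                      outer(rep(1, nrow(qm)), eff_m$alpha_eff))
  f <- damping(r, outer(r0_q, rep(1, nrow(mm))),
               outer(rep(1, nrow(qm)), r0_m), spec)
  e_pair <- -f * c6_ab / r^6
  e_pair[r > cutoff] <- 0
  total <- sum(e_pair)

  group_sum <- tapply(colSums(e_pair), mm$group_id, sum)
  per_group <- data.frame(group_id = names(group_sum),
                          energy_hartree = as.numeric(group_sum),
                          stringsAsFactors = FALSE)
  per_pair_tab <- NULL
  if (per_pair) {
    per_pair_tab <- data.frame(
      qm_atom = rep(seq_len(nrow(qm)), times = nrow(mm)),
      mm_atom = rep(seq_len(nrow(mm)), each = nrow(qm)),
      r_ab = as.vector(r), energy_hartree = as.vector(e_pair))
  }
  new_dispersion_result(state_label, total, per_group, per_pair_tab,
                        meta = result_meta(geometry, spec, cutoff))
}

empty_group_table <- function() {
  data.frame(group_id = character(0), energy_hartree = numeric(0),
             stringsAsFactors = FALSE)
}

result_meta <- function(geometry, spec, cutoff) {
  pos <- geometry_positions(geometry)
  list(n_qm = sum(geometry$subsystem == "QM"),
       n_mm = sum(geometry$subsystem == "MM"),
       geom_checksum = sum(pos) + sum(pos^2),
       damping = unclass(spec), cutoff = cutoff)
}

new_dispersion_result <- function(state_label, energy, per_group,
                                  per_pair_tab, meta) {
  structure(list(state_label = state_label,
                 total_hartree = energy,
                 total_cm1 = hartree_to_wavenumber(energy),
                 per_group = per_group,
                 per_pair = per_pair_tab,
                 meta = meta),
            class = "dispersion_result")
}

#' @export
print.dispersion_result <- function(x, ...) {
  cat(sprintf("dispersion_result [%s]: %.8f hartree (%.2f cm^-1), %d MM group(s)\n",
              x$state_label, x$total_hartree, x$total_cm1, nrow(x$per_group)))
  invisible(x)
}

#' State-specific dispersion shift
#'
#' The excitation-energy contribution of dispersion is the difference between
#' excited- and ground-state QM-MM dispersion energies,
#' \eqn{R_{SS-disp} = R^{ExS}_{disp} - R^{GS}_{disp}}, reported in cm^-1. A
#' smaller excited-state polarizability (smaller scaled gammas) gives a
#' positive shift (blue), a larger one a negative shift (red). Per-group
#' differences are propagated for residue-contribution maps. Both inputs must
#' come from the same geometry, damping and cutoff (checked via metadata
#' fingerprints).
#'
#' @param result_es excited-state `dispersion_result`
#' @param result_gs ground-state `dispersion_result`
#' @return an `ss_dispersion`: shift in cm^-1 (and hartree) plus per-group
#'   differences
#' @export
state_specific_dispersion <- function(result_es, result_gs) {
  stopifnot(inherits(result_es, "dispersion_result"),
            inherits(result_gs, "dispersion_result"))
  ma <- result_es$meta; mb <- result_gs$meta
  same <- isTRUE(all.equal(ma$geom_checksum, mb$geom_checksum)) &&
    ma$n_qm == mb$n_qm && ma$n_mm == mb$n_mm &&
    identical(ma$damping, mb$damping) && identical(ma$cutoff, mb$cutoff)
  if (!same) {
    stop("GS and ES dispersion results were computed with different ",
         "geometry, damping or cutoff; the difference is not meaningful")
  }
  d_hartree <- result_es$total_hartree - result_gs$total_hartree
  pg <- merge(result_es$per_group, result_gs$per_group, by = "group_id",
              suffixes = c("_es", "_gs"), all = TRUE)
  pg$energy_hartree_es[is.na(pg$energy_hartree_es)] <- 0
  pg$energy_hartree_gs[is.na(pg$energy_hartree_gs)] <- 0
  per_group <- data.frame(
    group_id = pg$group_id,
    shift_cm1 = hartree_to_wavenumber(pg$energy_hartree_es -
                                        pg$energy_hartree_gs),
    stringsAsFactors = FALSE)
  structure(list(r_ss_disp_cm1 = hartree_to_wavenumber(d_hartree),
                 r_ss_disp_hartree = d_hartree,
                 per_group = per_group,
                 es_label = result_es$state_label,
                 meta = ma),
            class = "ss_dispersion")
}

#' @export
print.ss_dispersion <- function(x, ...) {
  cat(sprintf("state-specific dispersion shift [%s - GS]: %.2f cm^-1 (%s)\n",
              x$es_label, x$r_ss_disp_cm1,
              if (x$r_ss_disp_cm1 >= 0) "blue" else "red"))
  invisible(x)
}
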