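# Excited-state rescaling of volume ratios. The TS volume proxy (alpha
# proportional to volume) holds for ground states only: an excited state's
# polarizability carries negative-frequency transition terms with no volume
# analogue. The atom-wise factor beta_A restores the excited/ground atomic
# polarizability ratio obtained from a distributed (HHS-style) decomposition
# of the molecular polarizabilities, whose atomic contributions sum to the
# molecular value.

#' Distributed (HHS-style) atomic polarizability set
#'
#' Plain per-atom isotropic polarizabilities for one electronic state,
#' consumed as input tables (their computation from wavefunctions is out of
#' scope here). Anisotropic 3x3 tensors, if supplied, are reduced to the
#' isotropic mean (trace/3).
#'
#' @param alpha per-atom isotropic polarizability (a.u.), or a list of 3x3
#'   tensors which are reduced to trace/3
#' @param elements element symbol per atom
#' @param state_label electronic-state label
#' @param source_meta free-form provenance note (gas phase vs embedded, frame
#'   id for per-configuration sets)
#' @return a `distributed_polarizability_set` data frame (atom, element, alpha)
#' @export
distributed_polarizabilities <- function(alpha, elements, state_label,
                                         source_meta = "") {
  if (is.list(alpha) && !is.data.frame(alpha)) {
    alpha <- vapply(alpha, function(t) {
      stopifnot(is.matrix(t), all(dim(t) == c(3L, 3L)))
      sum(diag(t)) / 3
    }, numeric(1))
  }
  stopifnot(length(alpha) == length(elements), all(is.finite(alpha)))
  if (identical(state_label, "GS") && any(alpha <= 0)) {
    stop("ground-state HHS polarizabilities must be positive")
  }
  structure(
    data.frame(atom = seq_along(alpha), element = elements, alpha = alpha,
               stringsAsFactors = FALSE),
    class = c("distributed_polarizability_set", "data.frame"),
    state_label = state_label, source_meta = source_meta)
}

#' Read a per-atom HHS polarizability table
#'
#' Delimited text with header `atom element alpha_gs alpha_exs` (comments
#' `#`). Returns ground- and excited-state sets.
#'
#' @param path table file
#' @param excited_state_label label for the excited-state column
#' @return list with elements `gs` and `exs`, each a
#'   `distributed_polarizability_set`
#' @export
read_hhs_table <- function(path, excited_state_label = "ExS") {
  if (!file.exists(path)) stop("cannot read HHS table: ", path)
  tab <- utils::read.table(path, header = TRUE, comment.char = "#",
                           stringsAsFactors = FALSE)
  needed <- c("atom", "element", "alpha_gs", "alpha_exs")
  if (!all(needed %in% names(tab))) {
    stop("HHS table ", path, " must have columns: ",
         paste(needed, collapse = ", "))
  }
  list(gs = distributed_polarizabilities(tab$alpha_gs, tab$element, "GS",
                                         source_meta = path),
       exs = distributed_polarizabilities(tab$alpha_exs, tab$element,
                                          excited_state_label,
                                          source_meta = path))
}

#' Average per-configuration HHS sets
#'
#' Arithmetic per-atom mean over frames (e.g. snapshots of an embedded
#' chromophore); for rigid solutes in isotropic media frame-to-frame changes
#' are small and the mean is an adequate single parametrization.
#'
#' @param sets list of `distributed_polarizability_set` over the same atoms
#' @return one averaged `distributed_polarizability_set`
#' @export
average_hhs_sets <- function(sets) {
  stopifnot(length(sets) >= 1L)
  ref <- sets[[1L]]
  for (s in sets) {
    stopifnot(inherits(s, "distributed_polarizability_set"),
              identical(s$element, ref$element))
  }
  alpha <- Reduce(`+`, lapply(sets, `[[`, "alpha")) / length(sets)
  distributed_polarizabilities(
    alpha, ref$element, attr(ref, "state_label"),
    source_meta = sprintf("mean of %d configurations", length(sets)))
}

#' Atom-wise excited-state rescaling factors
#'
#' The scaled excited-state atomic polarizability must reproduce the HHS
#' excited/ground ratio: since TS atomic polarizabilities are
#' \eqn{\alpha_A = \gamma_A \alpha_A^{free}}, this fixes
#' \deqn{\beta_A = (\gamma_A^{GS} / \gamma_A^{ExS}) \cdot
#'       (\alpha_A^{HHS,ExS} / \alpha_A^{HHS,GS}).}
#' With `mode = "hhs_only"` the volume-ratio change upon excitation is
#' neglected and \eqn{\beta_A} is the bare HHS ratio (the documented
#' alternative parametrization); the default keeps the full
#' density-dependence.
#'
#' A negative excited-state HHS atomic polarizability (possible in principle:
#' excited-state dispersion can turn repulsive) has no volume analogue and is
#' a hard error rather than being clamped.
#'
#' @param gamma_gs ground-state `volume_ratio_set`
#' @param gamma_exs_unscaled excited-state `volume_ratio_set` before scaling
#' @param hhs_gs,hhs_exs `distributed_polarizability_set` for the two states
#' @param mode `"full"` (default, density-dependent) or `"hhs_only"`
#' @return a `scaling_factor_set` data frame (atom, element, beta)
#' @export
compute_beta <- function(gamma_gs, gamma_exs_unscaled, hhs_gs, hhs_exs,
                         mode = c("full", "hhs_only")) {
  mode <- match.arg(mode)
  stopifnot(inherits(gamma_gs, "volume_ratio_set"),
            inherits(gamma_exs_unscaled, "volume_ratio_set"))
  check_same_atoms(gamma_gs, gamma_exs_unscaled, hhs_gs, hhs_exs)
  if (isTRUE(attr(gamma_exs_unscaled, "scaled"))) {
    stop("excited-state gamma set is already scaled; pass the unscaled set")
  }
  if (any(hhs_exs$alpha <= 0)) {
    stop("excited-state HHS polarizability non-positive for atom(s) ",
         paste(hhs_exs$atom[hhs_exs$alpha <= 0], collapse = ", "),
         ": the excited-state dispersion interaction has no volume-ratio ",
         "representation (repulsive-dispersion regime); cannot rescale")
  }
  hhs_ratio <- hhs_exs$alpha / hhs_gs$alpha
  beta <- if (mode == "full") {
    (gamma_gs$gamma / gamma_exs_unscaled$gamma) * hhs_ratio
  } else {
    hhs_ratio
  }
  structure(
    data.frame(atom = gamma_gs$atom, element = gamma_gs$element, beta = beta,
               stringsAsFactors = FALSE),
    class = c("scaling_factor_set", "data.frame"),
    excited_state_label = attr(gamma_exs_unscaled, "state_label"),
    mode = mode)
}

check_same_atoms <- function(...) {
  sets <- list(...)
  n <- vapply(sets, nrow, 1L)
  if (length(unique(n)) != 1L) {
    stop("atom sets differ in size: ", paste(n, collapse = " vs "))
  }
  els <- lapply(sets, `[[`, "element")
  for (e in els[-1L]) {
    if (!identical(e, els[[1L]])) stop("atom sets list different elements")
  }
  invisible(TRUE)
}

#' Apply scaling factors to excited-state volume ratios
#'
#' \eqn{\tilde\gamma_A^{ExS} = \gamma_A[\rho^{ExS}] \cdot \beta_A}. The
#' output is flagged as scaled; scaling an already-scaled set is an error.
#'
#' @param gamma_exs_unscaled excited-state `volume_ratio_set` from the
#'   excited-state density
#' @param beta a `scaling_factor_set` from [compute_beta()]
#' @return the rescaled `volume_ratio_set`
#' @export
scaled_volume_ratios <- function(gamma_exs_unscaled, beta) {
  stopifnot(inherits(gamma_exs_unscaled, "volume_ratio_set"),
            inherits(beta, "scaling_factor_set"))
  if (isTRUE(attr(gamma_exs_unscaled, "scaled"))) {
    stop("volume-ratio set is already scaled")
  }
  check_same_atoms(gamma_exs_unscaled, beta)
  new_volume_ratio_set(
    atom = gamma_exs_unscaled$atom, element = gamma_exs_unscaled$element,
    gamma = gamma_exs_unscaled$gamma * beta$beta,
    state_label = paste0(attr(gamma_exs_unscaled, "state_label"), " (scaled)"),
    scaled = TRUE,
    quadrature_meta = attr(gamma_exs_unscaled, "quadrature_meta"))
}

#' Molecular polarizability as the sum of atomic contributions
#'
#' \eqn{\alpha_{mol} = \sum_A \gamma_A \alpha_A^{free}}: the TS atomic
#' polarizabilities summed over the molecule. Applied to a scaled
#' excited-state set this is the consistency check that the rescaling
#' reproduces the distributed-polarizability molecular values.
#'
#' @param gammas a `volume_ratio_set`
#' @param params an `element_params` table
#' @return scalar molecular polarizability, a.u.
#' @export
molecular_polarizability <- function(gammas, params = load_element_params()) {
  stopifnot(inherits(gammas, "volume_ratio_set"))
  alpha_free <- element_lookup(params, gammas$element)$alpha_free
  sum(gammas$gamma * alpha_free)
}

#' Write scaling factors as a delimited table
#'
#' @param beta a `scaling_factor_set`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_beta_table <- function(beta, path) {
  stopifnot(inherits(beta, "scaling_factor_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# excited state: ", attr(beta, "excited_state_label")),
               paste0("# mode: ", attr(beta, "mode")),
               "atom\telement\tbeta"), con)
  writeLines(sprintf("%d\t%s\t%.12f", beta$atom, beta$element, beta$beta), con)
  invisible(path)
}
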