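# Assembly of the four-component cLR3 excitation energy,
#   dE = dE_GS-pol + R_SS-pol + R_LR-disp + R_SS-disp,
# plus site-energy range analysis and per-residue dispersion reports. The
# first three components come from the polarizable-embedding response solver
# and are consumed as input tables; only R_SS-disp is computed by this
# package's dispersion engine.

COMPONENT_NAMES <- c("de_gs_pol", "r_ss_pol", "r_lr_disp", "r_ss_disp")

#' Bundle the four excitation-energy components (cm^-1)
#'
#' @param de_gs_pol excitation energy with the environment polarization
#'   frozen to the ground state, cm^-1
#' @param r_ss_pol state-specific polarization correction, cm^-1
#' @param r_lr_disp linear-response dispersion correction, cm^-1
#' @param r_ss_disp state-specific dispersion correction, cm^-1
#' @param provenance named character; at minimum `r_ss_disp` must name its
#'   origin (`"clr3disp"` when computed here, else the input file)
#' @return an `energy_components` list
#' @export
energy_components <- function(de_gs_pol, r_ss_pol, r_lr_disp, r_ss_disp,
                              provenance = c(r_ss_disp = "input")) {
  vals <- list(de_gs_pol = de_gs_pol, r_ss_pol = r_ss_pol,
               r_lr_disp = r_lr_disp, r_ss_disp = r_ss_disp)
  missing <- names(vals)[vapply(vals, function(v) {
    is.null(v) || length(v) != 1L || !is.finite(v)
  }, logical(1))]
  if (length(missing) > 0L) {
    stop("missing or non-finite component(s): ", paste(missing, collapse = ", "))
  }
  structure(c(vals, list(provenance = provenance)),
            class = "energy_components")
}

#' Assemble the cLR3 excitation energy
#'
#' Plain arithmetic sum of the four components, in cm^-1. Decomposition and
#' assembly round-trip exactly.
#'
#' @param components an `energy_components`
#' @return total excitation energy, cm^-1
#' @export
assemble_clr3 <- function(components) {
  stopifnot(inherits(components, "energy_components"))
  components$de_gs_pol + components$r_ss_pol + components$r_lr_disp +
    components$r_ss_disp
}

#' Read a component table
#'
#' Delimited text with header columns `label`, optional `frame`, and the four
#' components `de_gs_pol r_ss_pol r_lr_disp r_ss_disp`, all cm^-1 (a
#' `# units:` header comment, if present, must say cm-1).
#'
#' @param path table file
#' @return data frame with one row per (label, frame)
#' @export
read_component_table <- function(path) {
  if (!file.exists(path)) stop("cannot read component table: ", path)
  lines <- readLines(path, warn = FALSE)
  units <- sub("^#\\s*units:\\s*", "",
               grep("^#\\s*units:", lines, value = TRUE))
  if (length(units) > 0L && !grepl("cm", units[1L], ignore.case = TRUE)) {
    stop("component table ", path, " declares units '", units[1L],
         "'; cm^-1 required")
  }
  tab <- utils::read.table(path, header = TRUE, comment.char = "#",
                           stringsAsFactors = FALSE)
  missing <- setdiff(c("label", COMPONENT_NAMES), names(tab))
  if (length(missing) > 0L) {
    stop("component table ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  }
  if (!"frame" %in% names(tab)) tab$frame <- 1L
  tab[c("label", "frame", COMPONENT_NAMES)]
}

#' Average components over frames
#'
#' Componentwise arithmetic mean over MD snapshots, with standard errors.
#'
#' @param frames a list of `energy_components`, or a data frame with the four
#'   component columns (one row per frame)
#' @return an `energy_components` with attributes `n_frames` and `se`
#' @export
average_components <- function(frames) {
  if (is.data.frame(frames)) {
    stopifnot(all(COMPONENT_NAMES %in% names(frames)))
    mat <- as.matrix(frames[COMPONENT_NAMES])
  } else {
    stopifnot(is.list(frames), length(frames) >= 1L)
    mat <- do.call(rbind, lapply(frames, function(f) {
      stopifnot(inherits(f, "energy_components"))
      unlist(f[COMPONENT_NAMES])
    }))
  }
  if (nrow(mat) == 0L) stop("no frames to average")
  m <- colMeans(mat)
  se <- if (nrow(mat) > 1L) {
    apply(mat, 2, stats::sd) / sqrt(nrow(mat))
  } else {
    rep(NA_real_, 4L)
  }
  out <- energy_components(m[["de_gs_pol"]], m[["r_ss_pol"]],
                           m[["r_lr_disp"]], m[["r_ss_disp"]],
                           provenance = c(r_ss_disp = "frame average"))
  attr(out, "n_frames") <- nrow(mat)
  attr(out, "se") <- se
  out
}

#' Build a site-energy table from a component table
#'
#' Frames sharing a label are averaged; each row then carries the four
#' MD-averaged components and the assembled total.
#'
#' @param components data frame as returned by [read_component_table()]
#' @return a `site_energy_table` data frame (label, four components, total,
#'   n_frames)
#' @export
site_energy_table <- function(components) {
  stopifnot(is.data.frame(components),
            all(c("label", COMPONENT_NAMES) %in% names(components)))
  labels <- unique(components$label)
  rows <- lapply(labels, function(lab) {
    sub <- components[components$label == lab, , drop = FALSE]
    avg <- average_components(sub)
    data.frame(label = lab,
               de_gs_pol = avg$de_gs_pol, r_ss_pol = avg$r_ss_pol,
               r_lr_disp = avg$r_lr_disp, r_ss_disp = avg$r_ss_disp,
               total = assemble_clr3(avg), n_frames = attr(avg, "n_frames"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("site_energy_table", "data.frame"))
}

#' Site-energy range and per-component attribution
#'
#' The spread of site energies across environments (max - min of the
#' assembled totals) and, for each component, the fraction of that spread the
#' component alone would produce: (max - min of the component) / range,
#' reported as a percentage. Components can co-vary, so the attributions need
#' not sum to 100%; they are reported as-is, not renormalized.
#'
#' @param table a `site_energy_table` with at least two rows
#' @return list with `range_cm1`, `attribution_pct` (named over the four
#'   components, `NA` when the range is zero) and `note`
#' @export
site_energy_range <- function(table) {
  stopifnot(inherits(table, "site_energy_table"))
  if (nrow(table) < 2L) {
    stop("site-energy range needs at least two rows (got ", nrow(table), ")")
  }
  rng <- max(table$total) - min(table$total)
  if (rng == 0) {
    attribution <- stats::setNames(rep(NA_real_, 4L), COMPONENT_NAMES)
    note <- "all totals identical; attribution not applicable"
  } else {
    attribution <- vapply(COMPONENT_NAMES, function(cn) {
      100 * (max(table[[cn]]) - min(table[[cn]])) / rng
    }, numeric(1))
    note <- paste("component attributions are ranges divided by the total",
                  "range; components co-vary, so they need not sum to 100%")
  }
  list(range_cm1 = rng, attribution_pct = attribution, note = note)
}

#' Per-residue contribution report for the dispersion shift
#'
#' Ranks MM groups (residues/molecules) by their contribution to the total
#' dispersion shift: the state-specific part computed by
#' [state_specific_dispersion()], optionally combined with externally
#' supplied per-group linear-response values.
#'
#' @param result_ss an `ss_dispersion` (per-group SS shifts, cm^-1)
#' @param result_lr optional data frame (group_id, shift_cm1) of per-group LR
#'   dispersion values from the response solver
#' @return data frame (group_id, ss_disp_cm1, lr_disp_cm1, total_cm1) sorted
#'   by decreasing |total|
#' @export
residue_contribution_report <- function(result_ss, result_lr = NULL) {
  stopifnot(inherits(result_ss, "ss_dispersion"))
  tab <- data.frame(group_id = result_ss$per_group$group_id,
                    ss_disp_cm1 = result_ss$per_group$shift_cm1,
                    stringsAsFactors = FALSE)
  if (!is.null(result_lr)) {
    stopifnot(all(c("group_id", "shift_cm1") %in% names(result_lr)))
    tab <- merge(tab, result_lr, by = "group_id", all = TRUE)
    tab$ss_disp_cm1[is.na(tab$ss_disp_cm1)] <- 0
    tab$shift_cm1[is.na(tab$shift_cm1)] <- 0
    names(tab)[names(tab) == "shift_cm1"] <- "lr_disp_cm1"
  } else {
    tab$lr_disp_cm1 <- 0
  }
  tab$total_cm1 <- tab$ss_disp_cm1 + tab$lr_disp_cm1
  tab <- tab[order(-abs(tab$total_cm1)), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
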