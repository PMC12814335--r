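#' Load free-atom element reference parameters
#'
#' Reads the per-element free-atom reference table used throughout the
#' volume-scaling dispersion model: static polarizability \eqn{\alpha^{free}},
#' homonuclear \eqn{C_6} coefficient, van der Waals radius and electron count,
#' all in Hartree atomic units. With no `path`, the packaged Chu--Dalgarno-style
#' Tkatchenko--Scheffler reference set (H, C, N, O, F, Na, Mg, P, S, Cl) is
#' returned. A custom table overrides the packaged defaults element-by-element:
#' elements it lists replace the defaults, all others fall back to them.
#'
#' @param path optional path to a delimited text table with a header line and
#'   columns `symbol`, `alpha_free`, `c6_free`, `r_vdw_free`, `n_electrons`.
#'   Lines starting with `#` are comments. `NULL` means packaged defaults only.
#' @param fallback logical; when a custom `path` is given, keep packaged
#'   defaults for elements the custom table does not list (default `TRUE`).
#' @return a data frame of class `element_params` with one row per element.
#' @export
load_element_params <- function(path = NULL, fallback = TRUE) {
  default_path <- system.file("extdata", "ts_free_atom_reference.tsv",
                              package = "clr3disp", mustWork = TRUE)
  tab <- parse_element_table(default_path)
  if (!is.null(path)) {
    custom <- parse_element_table(path)
    if (fallback) {
      keep <- !(tab$symbol %in% custom$symbol)
      tab <- rbind(custom, tab[keep, , drop = FALSE])
    } else {
      tab <- custom
    }
  }
  rownames(tab) <- NULL
  class(tab) <- c("element_params", "data.frame")
  tab
}

parse_element_table <- function(path) {
  if (!file.exists(path)) stop("element parameter table not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "", comment.char = "#",
                           stringsAsFactors = FALSE)
  needed <- c("symbol", "alpha_free", "c6_free", "r_vdw_free", "n_electrons")
  missing <- setdiff(needed, names(tab))
  if (length(missing) > 0L) {
    stop("element parameter table ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  }
  tab <- tab[needed]
  for (i in seq_len(nrow(tab))) {
    row <- tab[i, ]
    if (is.na(row$symbol) || !nzchar(row$symbol)) {
      stop("element table row ", i, ": missing element symbol")
    }
    vals <- unlist(row[c("alpha_free", "c6_free", "r_vdw_free", "n_electrons")])
    if (any(!is.finite(vals)) || any(vals <= 0)) {
      stop("element table row ", i, " (", row$symbol,
           "): all parameters must be positive and finite")
    }
  }
  if (anyDuplicated(tab$symbol)) {
    stop("element parameter table has duplicated symbols: ",
         paste(unique(tab$symbol[duplicated(tab$symbol)]), collapse = ", "))
  }
  tab$n_electrons <- as.integer(tab$n_electrons)
  tab
}

#' Look up free-atom parameters for one element
#'
#' Elements absent from the table are a hard error: \eqn{C_6} errors grow
#' quadratically in the volume ratio and a silent default would corrupt
#' dispersion energies.
#'
#' @param params an `element_params` table from [load_element_params()]
#' @param symbol element symbol (case-sensitive, e.g. `"Mg"`)
#' @return a one-row data frame
#' @export
element_lookup <- function(params, symbol) {
  stopifnot(inherits(params, "element_params"))
  hit <- match(symbol, params$symbol)
  if (anyNA(hit)) {
    stop("element(s) not in parameter table: ",
         paste(unique(symbol[is.na(hit)]), collapse = ", "))
  }
  params[hit, , drop = FALSE]
}

new_system_geometry <- function(sites, length_unit_note) {
  stopifnot(is.data.frame(sites))
  needed <- c("element", "x", "y", "z", "subsystem", "group_id")
  stopifnot(all(needed %in% names(sites)))
  if (!all(sites$subsystem %in% c("QM", "MM"))) {
    stop("subsystem tag must be 'QM' or 'MM'")
  }
  if (sum(sites$subsystem == "QM") < 1L) {
    stop("geometry must contain at least one QM site")
  }
  pos <- as.matrix(sites[, c("x", "y", "z")])
  if (any(!is.finite(pos))) stop("non-finite coordinates in geometry")
  if (nrow(pos) > 1L) {
    d <- stats::dist(pos)
    if (any(d < 1e-8)) stop("two sites share identical positions")
  }
  rownames(sites) <- NULL
  structure(sites, class = c("system_geometry", "data.frame"),
            length_unit_note = length_unit_note)
}

#' Read a molecular geometry and assign QM/MM subsystems
#'
#' Reads XYZ (standard two-header-line dialect) or PDB coordinates, converts
#' angstrom to bohr, and tags every atom as belonging to the QM chromophore or
#' the MM environment. Three assignment rules are supported: an explicit index
#' list (`qm_indices`), a PDB residue selection (`qm_residues`, matched against
#' `group_id` = resSeq + chain), or two separate files (`path` is all-QM and
#' `mm_path` all-MM).
#'
#' Group identifiers, used for per-residue contribution reports, come from the
#' PDB residue (resSeq + chain) when available; XYZ files get one group per
#' file.
#'
#' @param path geometry file (.xyz or .pdb; format inferred from extension)
#' @param qm_indices integer vector of 1-based atom indices that form the QM
#'   subsystem
#' @param qm_residues character vector of group ids (e.g. `"1A"` or `"1"`)
#'   whose atoms form the QM subsystem (PDB input)
#' @param mm_path optional second geometry file holding the MM subsystem; when
#'   given, all atoms of `path` are QM and assignment arguments are ignored
#' @return a `system_geometry` data frame (element, x, y, z in bohr,
#'   subsystem, group_id)
#' @export
read_geometry <- function(path, qm_indices = NULL, qm_residues = NULL,
                          mm_path = NULL) {
  sites <- read_coordinates(path, group_prefix = "QM")
  if (!is.null(mm_path)) {
    sites$subsystem <- "QM"
    mm <- read_coordinates(mm_path, group_prefix = "MM")
    mm$subsystem <- "MM"
    sites <- rbind(sites, mm)
  } else if (!is.null(qm_indices)) {
    qm_indices <- as.integer(qm_indices)
    if (length(qm_indices) == 0L) stop("empty QM selection")
    if (any(qm_indices < 1L | qm_indices > nrow(sites))) {
      stop("qm_indices out of range 1..", nrow(sites))
    }
    sites$subsystem <- "MM"
    sites$subsystem[qm_indices] <- "QM"
  } else if (!is.null(qm_residues)) {
    sel <- sites$group_id %in% as.character(qm_residues)
    if (!any(sel)) stop("empty QM selection: no atom matches residues ",
                        paste(qm_residues, collapse = ", "))
    sites$subsystem <- ifelse(sel, "QM", "MM")
  } else {
    stop("no subsystem assignment: give qm_indices, qm_residues or mm_path")
  }
  new_system_geometry(
    sites,
    length_unit_note = sprintf(
      "input angstrom, converted to bohr (x %.10f)", BOHR_PER_ANGSTROM))
}

read_coordinates <- function(path, group_prefix = "G") {
  if (!file.exists(path)) stop("cannot read geometry file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "xyz") {
    read_xyz_sites(path, group_prefix)
  } else if (ext %in% c("pdb", "ent")) {
    read_pdb_sites(path)
  } else {
    stop("unsupported geometry format '.", ext, "' (expect .xyz or .pdb)")
  }
}

read_xyz_sites <- function(path, group_prefix) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L) stop("malformed XYZ file (needs 2 header lines): ", path)
  n <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(n) || n < 1L) stop("malformed XYZ atom count in ", path)
  if (length(lines) < 2L + n) stop("XYZ file truncated: ", path)
  body <- lines[3:(2 + n)]
  toks <- strsplit(trimws(body), "\\s+")
  bad <- which(vapply(toks, length, 1L) < 4L)
  if (length(bad) > 0L) stop("malformed XYZ line ", bad[1L] + 2L, " in ", path)
  el <- vapply(toks, `[[`, "", 1L)
  xyz <- t(vapply(toks, function(t) as.numeric(t[2:4]), numeric(3)))
  if (any(!is.finite(xyz))) stop("non-numeric coordinate in ", path)
  grp <- paste0(group_prefix, ":", basename(path))
  data.frame(element = el,
             x = angstrom_to_bohr(xyz[, 1]),
             y = angstrom_to_bohr(xyz[, 2]),
             z = angstrom_to_bohr(xyz[, 3]),
             subsystem = NA_character_, group_id = grp,
             stringsAsFactors = FALSE)
}

read_pdb_sites <- function(path) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  atoms <- pdb$atom
  if (nrow(atoms) == 0L) stop("no ATOM/HETATM records in ", path)
  el <- trimws(atoms$elesy)
  # element column is optional in older files; fall back to the atom name
  fallback <- gsub("[^A-Za-z].*", "", trimws(atoms$elety))
  el <- ifelse(!is.na(el) & nzchar(el), el, fallback)
  el <- paste0(toupper(substr(el, 1, 1)), tolower(substring(el, 2)))
  chain <- ifelse(is.na(atoms$chain), "", atoms$chain)
  data.frame(element = el,
             x = angstrom_to_bohr(atoms$x),
             y = angstrom_to_bohr(atoms$y),
             z = angstrom_to_bohr(atoms$z),
             subsystem = NA_character_,
             group_id = paste0(atoms$resno, chain),
             stringsAsFactors = FALSE)
}

#' Write a geometry to an XYZ file (angstrom)
#'
#' @param geometry a `system_geometry` or any data frame with element/x/y/z
#'   columns in bohr
#' @param path output file
#' @param comment second header line
#' @return `path`, invisibly
#' @export
write_xyz <- function(geometry, path, comment = "written by clr3disp") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(as.character(nrow(geometry)), comment), con)
  for (i in seq_len(nrow(geometry))) {
    writeLines(sprintf("%-3s %18.12f %18.12f %18.12f",
                       geometry$element[i],
                       bohr_to_angstrom(geometry$x[i]),
                       bohr_to_angstrom(geometry$y[i]),
                       bohr_to_angstrom(geometry$z[i])), con)
  }
  invisible(path)
}

geometry_positions <- function(geometry) {
  as.matrix(geometry[, c("x", "y", "z")])
}

qm_sites <- function(geometry) {
  geometry[geometry$subsystem == "QM", , drop = FALSE]
}

mm_sites <- function(geometry) {
  geometry[geometry$subsystem == "MM", , drop = FALSE]
}
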