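# Shared fixtures, built in code. Heavier density grids are created once per
# session and memoized here so individual test files stay fast.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# one hydrogen model atom on a fine grid: gamma and volume known analytically
hydrogen_grid <- function(spacing = 0.25, padding = 8) {
  cached(paste0("Hgrid", spacing, ":", padding), {
    make_model_density(data.frame(element = "H", x = 0, y = 0, z = 0),
                       spacing = spacing, padding = padding)
  })
}

# heteronuclear pair, well separated, with known per-atom density scales
scaled_pair_grid <- function(scales = c(1.0, 0.8)) {
  cached(paste0("pair", paste(scales, collapse = "_")), {
    make_model_density(
      data.frame(element = c("H", "O"), x = c(0, 9), y = c(0, 0), z = c(0, 0)),
      scales = scales, spacing = 0.25, padding = 7)
  })
}

toy_system <- function(seed = 42, n_qm = 5, n_mm = 20) {
  cached(paste0("toy", seed, ":", n_qm, ":", n_mm), {
    make_toy_system(seed = seed, n_qm = n_qm, n_mm = n_mm, box = 25)
  })
}

# one QM atom at the origin and one MM atom at distance r (bohr)
make_pair_geometry <- function(r, elements = c("H", "H")) {
  clr3disp:::new_system_geometry(
    data.frame(element = elements, x = c(0, r), y = 0, z = 0,
               subsystem = c("QM", "MM"), group_id = c("q", "m"),
               stringsAsFactors = FALSE),
    "built in bohr")
}

# independent brute-force oracle for the pairwise dispersion sum: scalar
# arithmetic straight from the formulas, no shared code with the engine
brute_force_dispersion <- function(geometry, gamma_qm, gamma_mm, params,
                                   d = 20, s_r = 0.97) {
  qm <- geometry[geometry$subsystem == "QM", ]
  mm <- geometry[geometry$subsystem == "MM", ]
  total <- 0
  for (a in seq_len(nrow(qm))) {
    pa <- element_lookup(params, qm$element[a])
    ga <- gamma_qm$gamma[a]
    c6a <- ga^2 * pa$c6_free
    ala <- ga * pa$alpha_free
    r0a <- ga^(1 / 3) * pa$r_vdw_free
    for (b in seq_len(nrow(mm))) {
      pb <- element_lookup(params, mm$element[b])
      gb <- gamma_mm$gamma[b]
      c6b <- gb^2 * pb$c6_free
      alb <- gb * pb$alpha_free
      r0b <- gb^(1 / 3) * pb$r_vdw_free
      r <- sqrt((qm$x[a] - mm$x[b])^2 + (qm$y[a] - mm$y[b])^2 +
                  (qm$z[a] - mm$z[b])^2)
      c6ab <- 2 * c6a * c6b / ((alb / ala) * c6a + (ala / alb) * c6b)
      f <- 1 / (1 + exp(-d * (r / (s_r * (r0a + r0b)) - 1)))
      total <- total - f * c6ab / r^6
    }
  }
  total
}

lh2_component_path <- function() {
  system.file("extdata", "lh2_qy_components_cm1.tsv", package = "clr3disp",
              mustWork = TRUE)
}

# published assembled LH2 Q_y site energies (cm^-1), carried alongside the
# component table for cross-checks
lh2_published_totals <- function() {
  tab <- utils::read.table(lh2_component_path(), header = TRUE,
                           comment.char = "#")
  stats::setNames(tab$total_published, tab$label)
}
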