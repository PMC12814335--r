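# Cube handling, free-atom models, Hirshfeld partitioning and volume ratios.
# The packaged hydrogen model density is exactly rho = exp(-2r)/pi, so the
# r^3-weighted volume integral has the closed form
# 4*pi * (1/pi) * Int_0^inf r^5 exp(-2r) dr = 4 * 120 / 2^6 = 7.5 bohr^3*e,
# evaluated symbolically; it anchors the quadrature below.

test_that("model hydrogen density integrates to one electron on the grid", {
  grid <- hydrogen_grid()
  expect_equal(density_integral(grid), 1.0, tolerance = 1e-2)
  expect_equal(nrow(grid$atoms), 1L)
})

test_that("cube write/read round-trips all fields to output precision", {
  grid <- make_model_density(
    data.frame(element = c("H", "O"), x = c(0, 2.1), y = c(0, 0), z = c(0, 0.4)),
    spacing = 0.7, padding = 2.5)
  path <- withr::local_tempfile(fileext = ".cube")
  write_cube(grid, path)
  back <- read_cube(path)
  expect_identical(back$npoints, grid$npoints)
  expect_equal(back$origin, grid$origin, tolerance = 1e-6)
  expect_equal(back$axes, grid$axes, tolerance = 1e-6)
  expect_equal(back$values, grid$values, tolerance = 1e-5)
  expect_identical(back$atoms$element, c("H", "O"))
  expect_equal(nrow(back$atoms), 2L)
})

test_that("angstrom-convention cubes (negative point counts) are normalized", {
  path <- withr::local_tempfile(fileext = ".cube")
  step_ang <- 0.2
  writeLines(c("angstrom cube", "fixture",
               sprintf("%5d %12.6f %12.6f %12.6f", 1, 0, 0, 0),
               sprintf("%5d %12.6f %12.6f %12.6f", -2, step_ang, 0, 0),
               sprintf("%5d %12.6f %12.6f %12.6f", -2, 0, step_ang, 0),
               sprintf("%5d %12.6f %12.6f %12.6f", -2, 0, 0, step_ang),
               sprintf("%5d %12.6f %12.6f %12.6f %12.6f", 1, 1, 0, 0, 0),
               paste(rep("0.1", 8), collapse = " ")), path)
  grid <- read_cube(path)
  expect_identical(grid$npoints, c(2L, 2L, 2L))
  expect_equal(voxel_volume(grid), angstrom_to_bohr(step_ang)^3,
               tolerance = 1e-10)
})

test_that("malformed cubes and out-of-tolerance negative densities error", {
  path <- withr::local_tempfile(fileext = ".cube")
  writeLines(c("comment", "comment", "not a number here",
               "2 0.5 0 0", "2 0 0.5 0", "2 0 0 0.5",
               "1 1.0 0 0 0", "0.1 0.1"), path)
  expect_error(read_cube(path), "line 3")
  expect_error(read_cube(withr::local_tempfile(fileext = ".cube")),
               "cannot read")
  grid <- hydrogen_grid()
  g2 <- grid
  g2$values[1] <- -1
  expect_error(
    new_density_grid(g2$origin, g2$axes, g2$npoints, g2$values, g2$atoms),
    "negative")
})

test_that("free-atom volumes match the symbolic radial integral", {
  fad <- free_atom_density("H")
  expect_equal(free_atom_volume(fad), 7.5, tolerance = 1e-12)
  # tabulated route must agree with the closed form via adaptive quadrature
  r <- seq(0, 30, by = 0.01)
  tab <- data.frame(r = r, rho = exp(-2 * r) / pi)
  fad_tab <- free_atom_density("H", table = tab)
  expect_equal(free_atom_volume(fad_tab), 7.5, tolerance = 1e-3)
  # linearity in the density
  expect_equal(free_atom_volume(free_atom_density("H", scale = 3)),
               3 * 7.5, tolerance = 1e-12)
})

test_that("degenerate free-atom densities are rejected", {
  r <- seq(0, 10, by = 0.1)
  expect_error(free_atom_density("H", table = data.frame(r = r, rho = 0 * r)),
               "zero")
  expect_error(free_atom_density("H",
                                 table = data.frame(r = r, rho = exp(-8 * r))),
               "electrons")
  expect_error(free_atom_density("H", zeta = -1), "zeta")
  expect_error(free_atom_density("Xx"), "Xx")
})

test_that("Hirshfeld weights are a stockholder partition of unity", {
  # single atom: weight 1 wherever the promolecule is above the floor
  grid1 <- hydrogen_grid()
  w1 <- promolecule_weights(grid1)
  retained <- attr(w1, "retained")
  expect_true(all(w1[retained, 1] == 1))
  expect_true(all(w1[!retained, 1] == 0))

  # two different atoms: weights sum to one at every retained point
  grid2 <- scaled_pair_grid()
  w2 <- promolecule_weights(grid2)
  sums <- rowSums(w2)[attr(w2, "retained")]
  expect_lt(max(abs(sums - 1)), 1e-12)
})

test_that("two identical atoms split the midpoint half and half", {
  rec <- data.frame(element = c("H", "H"), x = c(-1.5, 1.5), y = 0, z = 0)
  grid <- make_model_density(rec, spacing = 0.5, padding = 4)
  w <- promolecule_weights(grid)
  pts <- grid_points(grid)
  mid <- which(abs(pts[, 1]) < 1e-9 & abs(pts[, 2]) < 1e-9 &
                 abs(pts[, 3]) < 1e-9)
  expect_gt(length(mid), 0)
  expect_equal(w[mid, 1], 0.5, tolerance = 1e-12)
  expect_equal(w[mid, 2], 0.5, tolerance = 1e-12)
})

test_that("a grid that does not cover the molecule is a hard error", {
  grid <- hydrogen_grid()
  far <- data.frame(element = "H", x = 1e4, y = 1e4, z = 1e4)
  expect_error(promolecule_weights(grid, atoms = far), "does not cover")
})

test_that("atomic volume is linear in the density and matches the oracle", {
  grid <- hydrogen_grid()
  w <- promolecule_weights(grid)
  v <- atomic_volume(grid, w, 1)
  expect_equal(v, 7.5, tolerance = 1e-2)  # symbolic value, Riemann quadrature
  gz <- grid
  gz$values <- 0 * gz$values
  expect_equal(atomic_volume(gz, w, 1), 0)
  gs <- grid
  gs$values <- 2.5 * gs$values
  expect_equal(atomic_volume(gs, w, 1), 2.5 * v, tolerance = 1e-12)
})

test_that("the Hirshfeld partition conserves the electron count", {
  grid <- scaled_pair_grid()
  w <- promolecule_weights(grid)
  per_atom <- colSums(w * grid$values) * voxel_volume(grid)
  expect_equal(sum(per_atom), density_integral(grid), tolerance = 1e-10)
})

test_that("a free atom partitioned against its own density has gamma = 1", {
  g <- volume_ratios(hydrogen_grid())
  expect_equal(g$gamma, 1.0, tolerance = 1e-2)
  expect_identical(attr(g, "state_label"), "GS")
})

test_that("uniform density rescaling rescales every gamma by the same factor", {
  grid <- scaled_pair_grid(scales = c(1, 1))
  g1 <- volume_ratios(grid)
  gs <- grid
  gs$values <- 0.8 * gs$values
  g08 <- volume_ratios(gs)
  expect_equal(g08$gamma / g1$gamma, c(0.8, 0.8), tolerance = 1e-12)
})

test_that("non-overlapping homonuclear diatomic recovers gamma = 1 per atom", {
  rec <- data.frame(element = c("H", "H"), x = c(0, 50), y = 0, z = 0)
  grid <- make_model_density(rec, spacing = 0.35, padding = 8)
  g <- volume_ratios(grid)
  expect_equal(g$gamma, c(1, 1), tolerance = 1e-2)
})

test_that("halving the grid spacing changes gamma by little (convergence)", {
  rec <- data.frame(element = c("H", "O"), x = c(0, 3), y = 0, z = 0)
  coarse <- volume_ratios(make_model_density(rec, spacing = 0.5, padding = 6))
  fine <- volume_ratios(make_model_density(rec, spacing = 0.25, padding = 6))
  expect_lt(max(abs(fine$gamma - coarse$gamma)), 5e-3)
})

test_that("MM volume ratios are elementwise polarizability ratios", {
  params <- load_element_params()
  a_free <- element_lookup(params, c("O", "H", "C"))$alpha_free
  g <- gamma_from_mm_polarizability(a_free, c("O", "H", "C"))
  expect_equal(g$gamma, c(1, 1, 1), tolerance = 1e-14)
  g2 <- gamma_from_mm_polarizability(2 * a_free, c("O", "H", "C"))
  expect_equal(g2$gamma, c(2, 2, 2), tolerance = 1e-14)
  mixed <- c(0.9, 1.3, 0.7) * a_free
  g3 <- gamma_from_mm_polarizability(mixed, c("O", "H", "C"))
  expect_equal(g3$gamma, c(0.9, 1.3, 0.7), tolerance = 1e-12)
  expect_error(gamma_from_mm_polarizability(-1, "H"), "positive")
})

test_that("gamma tables round-trip through the writer and reader", {
  g <- volume_ratio_set(c(0.91, 1.07), c("C", "N"), state_label = "S1",
                        scaled = TRUE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_gamma_table(g, path)
  back <- read_gamma_table(path)
  expect_equal(back$gamma, g$gamma, tolerance = 1e-12)
  expect_identical(back$element, g$element)
  expect_identical(attr(back, "state_label"), "S1")
  expect_true(attr(back, "scaled"))
})
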