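# Effective C6 coefficients, damping, the pairwise QM-MM sum and the
# state-specific dispersion difference.

test_that("homonuclear effective C6 scales quadratically with gamma", {
  params <- load_element_params()
  c6_h <- element_lookup(params, "H")$c6_free
  a_h <- element_lookup(params, "H")$alpha_free
  eff1 <- effective_c6_homonuclear(volume_ratio_set(1, "H"), params)
  expect_equal(eff1$c6_eff, c6_h, tolerance = 1e-14)
  expect_equal(eff1$alpha_eff, a_h, tolerance = 1e-14)
  eff2 <- effective_c6_homonuclear(volume_ratio_set(2, "H"), params)
  expect_equal(eff2$c6_eff, 4 * c6_h, tolerance = 1e-14)
  expect_equal(eff2$alpha_eff, 2 * a_h, tolerance = 1e-14)
  # gamma = 0.8 with C6_free = 10 -> 6.4 (hand evaluation, custom element)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("symbol\talpha_free\tc6_free\tr_vdw_free\tn_electrons",
               "C\t5.0\t10.0\t3.0\t6"), path)
  custom <- load_element_params(path)
  eff08 <- effective_c6_homonuclear(volume_ratio_set(0.8, "C"), custom)
  expect_equal(eff08$c6_eff, 6.4, tolerance = 1e-14)
})

test_that("the C6 combination rule has the homonuclear limit and is symmetric", {
  expect_equal(combine_c6(13.2, 13.2, 4.7, 4.7), 13.2, tolerance = 1e-14)
  # hand evaluation: 2*10*40 / ((2/1)*10 + (1/2)*40) = 800/40 = 20
  expect_equal(combine_c6(10, 40, 1, 2), 20, tolerance = 1e-14)
  set.seed(5)
  for (i in 1:20) {
    v <- runif(4, 0.1, 50)
    expect_equal(combine_c6(v[1], v[2], v[3], v[4]),
                 combine_c6(v[2], v[1], v[4], v[3]), tolerance = 1e-14)
  }
  expect_error(combine_c6(1, 1, 0, 1), "positive")
})

test_that("Fermi damping interpolates between 0 and 1 with midpoint at s_r*R0", {
  spec <- damping_spec(d = 20, s_r = 0.97)
  r0 <- c(3.1, 3.59)
  expect_equal(damping(1e3, r0[1], r0[2], spec), 1, tolerance = 1e-12)
  mid <- spec$s_r * sum(r0)
  expect_equal(damping(mid, r0[1], r0[2], spec), 0.5, tolerance = 1e-14)
  expect_equal(damping(1e-6, r0[1], r0[2], spec), 1 / (1 + exp(20)),
               tolerance = 1e-4)
  expect_error(damping_spec(d = -1), "d > 0")
})

test_that("a single undamped pair reproduces -C6/R^6", {
  # tiny vdW radii push the damping midpoint to ~0, so f ~ 1 at R = 2;
  # equal atoms with gamma 1 give C6_AB = C6_free = 20
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("symbol\talpha_free\tc6_free\tr_vdw_free\tn_electrons",
               "H\t4.5\t20.0\t0.01\t1"), path)
  params <- load_element_params(path)
  geo <- make_pair_geometry(r = 2)
  res <- dispersion_energy(geo, volume_ratio_set(1, "H"),
                           volume_ratio_set(1, "H", "MM"), params = params)
  expect_equal(res$total_hartree, -20 / 2^6, tolerance = 1e-8)
  expect_equal(res$total_cm1, hartree_to_wavenumber(-0.3125), tolerance = 1e-4)
})

test_that("an empty MM subsystem gives exactly zero dispersion", {
  sys <- make_toy_system(seed = 9, n_qm = 3, n_mm = 0, box = 12)
  res <- dispersion_energy(sys$geometry, sys$gamma_qm_gs,
                           volume_ratio_set(numeric(0), character(0), "MM"))
  expect_identical(res$total_hartree, 0)
  expect_equal(nrow(res$per_group), 0L)
})

test_that("the vectorized sum equals an independent brute-force double loop", {
  params <- load_element_params()
  sys <- toy_system(seed = 42, n_qm = 5, n_mm = 20)
  res <- dispersion_energy(sys$geometry, sys$gamma_qm_gs, sys$gamma_mm,
                           params = params, per_pair = TRUE)
  oracle <- brute_force_dispersion(sys$geometry, sys$gamma_qm_gs,
                                   sys$gamma_mm, params)
  expect_equal(res$total_hartree, oracle, tolerance = 1e-12)
  # conservation: pair and group decompositions both sum to the total
  expect_equal(sum(res$per_pair$energy_hartree), res$total_hartree,
               tolerance = 1e-12)
  expect_equal(sum(res$per_group$energy_hartree), res$total_hartree,
               tolerance = 1e-12)
})

test_that("a cutoff beyond the system diameter changes nothing; a short one does", {
  sys <- toy_system(seed = 42, n_qm = 5, n_mm = 20)
  full <- dispersion_energy(sys$geometry, sys$gamma_qm_gs, sys$gamma_mm)
  capped <- dispersion_energy(sys$geometry, sys$gamma_qm_gs, sys$gamma_mm,
                              cutoff = 1e4)
  expect_equal(capped$total_hartree, full$total_hartree, tolerance = 1e-14)
  short <- dispersion_energy(sys$geometry, sys$gamma_qm_gs, sys$gamma_mm,
                             cutoff = 8)
  expect_gt(short$total_hartree, full$total_hartree)  # fewer negative terms
  expect_error(dispersion_energy(sys$geometry, sys$gamma_qm_gs, sys$gamma_mm,
                                 cutoff = 0), "cutoff")
})

test_that("increasing any single gamma deepens the attraction at fixed damping", {
  # fixed (free) damping radii so f does not change with gamma: then C6_AB
  # grows monotonically with each gamma and every pair term deepens. With
  # gamma-scaled radii the damping feeds back and can offset the C6 gain for
  # near-contact pairs, which is why the radii are held fixed here.
  spec <- damping_spec(radius_mode = "free")
  sys <- toy_system(seed = 42, n_qm = 5, n_mm = 20)
  base <- dispersion_energy(sys$geometry, sys$gamma_qm_gs, sys$gamma_mm,
                            spec = spec)
  for (idx in c(1L, 4L)) {
    g_up <- sys$gamma_qm_gs
    g_up$gamma[idx] <- g_up$gamma[idx] * 1.2
    up <- dispersion_energy(sys$geometry, g_up, sys$gamma_mm, spec = spec)
    expect_lt(up$total_hartree, base$total_hartree)
  }
  gm_up <- sys$gamma_mm
  gm_up$gamma[7] <- gm_up$gamma[7] * 1.3
  up_mm <- dispersion_energy(sys$geometry, sys$gamma_qm_gs, gm_up,
                             spec = spec)
  expect_lt(up_mm$total_hartree, base$total_hartree)
})

test_that("pair energy magnitude decays monotonically beyond the damping midpoint", {
  params <- load_element_params()
  spec <- damping_spec()
  r_mid <- spec$s_r * 2 * element_lookup(params, "H")$r_vdw_free
  radii <- seq(r_mid + 0.2, r_mid + 12, length.out = 40)
  energies <- vapply(radii, function(r) {
    dispersion_energy(make_pair_geometry(r), volume_ratio_set(1, "H"),
                      volume_ratio_set(1, "H", "MM"),
                      params = params, spec = spec)$total_hartree
  }, numeric(1))
  expect_true(all(diff(abs(energies)) < 0))
})

test_that("the total energy is invariant under rigid motions", {
  sys <- toy_system(seed = 42, n_qm = 5, n_mm = 20)
  base <- dispersion_energy(sys$geometry, sys$gamma_qm_gs, sys$gamma_mm)
  geo <- sys$geometry
  # rotation about z by 37 degrees plus a translation
  th <- 37 * pi / 180
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  pos <- as.matrix(geo[, c("x", "y", "z")]) %*% rot
  geo$x <- pos[, 1] + 11.3
  geo$y <- pos[, 2] - 4.7
  geo$z <- pos[, 3] + 0.9
  moved <- dispersion_energy(geo, sys$gamma_qm_gs, sys$gamma_mm)
  expect_equal(moved$total_hartree, base$total_hartree, tolerance = 1e-10)
})

test_that("overlapping atoms are reported as an error naming the pair", {
  sys <- toy_system(seed = 42, n_qm = 5, n_mm = 20)
  geo <- sys$geometry
  qm1 <- which(geo$subsystem == "QM")[1]
  mm1 <- which(geo$subsystem == "MM")[1]
  geo$x[mm1] <- geo$x[qm1] + 0.01
  geo$y[mm1] <- geo$y[qm1]
  geo$z[mm1] <- geo$z[qm1]
  expect_error(dispersion_energy(geo, sys$gamma_qm_gs, sys$gamma_mm),
               "overlapping")
})

test_that("state-specific shift is zero for identical states and follows the sign law", {
  sys <- toy_system(seed = 42, n_qm = 5, n_mm = 20)
  gs_default <- dispersion_energy(sys$geometry, sys$gamma_qm_gs, sys$gamma_mm)
  same <- sys$gamma_qm_gs
  attr(same, "state_label") <- "S1"
  es_same <- dispersion_energy(sys$geometry, same, sys$gamma_mm)
  expect_equal(state_specific_dispersion(es_same, gs_default)$r_ss_disp_cm1,
               0, tolerance = 1e-12)
  # the sign law is the C6 mechanism, so damping radii are held fixed here
  # (gamma-scaled radii feed back into f and can invert near-contact pairs)
  spec <- damping_spec(radius_mode = "free")
  gs <- dispersion_energy(sys$geometry, sys$gamma_qm_gs, sys$gamma_mm,
                          spec = spec)
  # smaller excited-state polarizability (gamma) -> blue shift (positive)
  smaller <- volume_ratio_set(0.9 * sys$gamma_qm_gs$gamma,
                              sys$gamma_qm_gs$element, "S1", scaled = TRUE)
  es_small <- dispersion_energy(sys$geometry, smaller, sys$gamma_mm,
                                spec = spec)
  expect_gt(state_specific_dispersion(es_small, gs)$r_ss_disp_cm1, 0)
  # larger -> red shift (negative)
  larger <- volume_ratio_set(1.1 * sys$gamma_qm_gs$gamma,
                             sys$gamma_qm_gs$element, "S1", scaled = TRUE)
  es_large <- dispersion_energy(sys$geometry, larger, sys$gamma_mm,
                                spec = spec)
  expect_lt(state_specific_dispersion(es_large, gs)$r_ss_disp_cm1, 0)
})

test_that("GS/ES results from different setups refuse to combine", {
  sys <- toy_system(seed = 42, n_qm = 5, n_mm = 20)
  gs <- dispersion_energy(sys$geometry, sys$gamma_qm_gs, sys$gamma_mm)
  other <- make_toy_system(seed = 43, n_qm = 5, n_mm = 20, box = 25)
  es <- dispersion_energy(other$geometry, other$gamma_qm_gs, other$gamma_mm)
  expect_error(state_specific_dispersion(es, gs), "different")
  es_damp <- dispersion_energy(sys$geometry, sys$gamma_qm_gs, sys$gamma_mm,
                               spec = damping_spec(d = 10))
  expect_error(state_specific_dispersion(es_damp, gs), "different")
})
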