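test_that("geometry specs validate dimensions and shape constraints", {
  sp <- lv_geometry_spec("symmetric")
  expect_equal(sp$cavity_length, 16.00)
  expect_equal(sp$basal_cavity_width, 13.40)
  expect_equal(sp$wall_thickness, 3.0)
  expect_error(lv_geometry_spec("symmetric", wall_thickness = -1), "positive")
  expect_error(lv_geometry_spec("symmetric", wall_thickness = 7),
               "wall_thickness")
  expect_error(lv_geometry_spec("hemisphere", cavity_length = 10,
                                basal_cavity_width = 30), "hemisphere")
  # hemisphere radius from a 1.504 ml cavity by closed form
  hs <- lv_geometry_spec("hemisphere", target_cavity_volume = 1.504)
  expect_equal(hs$cavity_length, (1504 / ((2 / 3) * pi))^(1 / 3),
               tolerance = 1e-10)
  expect_equal(hs$cavity_length, 8.95, tolerance = 1e-3)
})

test_that("volume-matched family closed forms reproduce the reference volume", {
  vref <- analytic_cavity_volume(lv_geometry_spec("symmetric"))
  for (s in c("hypertrophic", "long", "hemisphere", "wide")) {
    expect_equal(analytic_cavity_volume(lv_geometry_spec(s)), vref,
                 tolerance = 1e-10, label = s)
  }
  lg <- lv_geometry_spec("long")
  expect_equal(lg$cavity_length, 1.5 * 16)
  wd <- lv_geometry_spec("wide")
  expect_lt(wd$cavity_length, wd$basal_cavity_width / 2)  # oblate
})

test_that("generated meshes are valid, conforming, and match spec dimensions", {
  m <- fx_mesh_coarse()
  expect_gt(min(lvhelix:::tet_signed_volume(m$nodes, m$elems[, 1:4])), 0)
  # conformity: every interior triangular face shared by exactly two tets
  f <- rbind(m$elems[, c(1, 2, 3)], m$elems[, c(1, 2, 4)],
             m$elems[, c(2, 3, 4)], m$elems[, c(1, 3, 4)])
  key <- apply(t(apply(f, 1, sort)), 1, paste, collapse = " ")
  expect_true(all(table(key) %in% c(1L, 2L)))
  nbnd <- sum(table(key) == 1L)
  expect_equal(nbnd, sum(vapply(m$faces, nrow, 1L)))
  # dimensions: apex depth = cavity length + wall; equatorial wall thickness
  expect_equal(-min(m$nodes[, 3]), 16 + 3, tolerance = 0.01)
  base_endo <- m$nodes[unique(as.vector(m$faces$endo)), ]
  base_endo <- base_endo[abs(base_endo[, 3]) < 1e-8, ]
  r_endo <- max(sqrt(base_endo[, 1]^2 + base_endo[, 2]^2))
  expect_equal(r_endo, 13.40 / 2, tolerance = 0.01 * 6.7)
  # default resolution reaches the minimum element count
  md <- generate_idealized_lv(lv_geometry_spec("symmetric"))
  expect_gte(nrow(md$elems), 2500)
})

test_that("divergence-theorem cavity volume matches closed forms and converges", {
  # hemisphere with 10 mm cavity radius: (2/3) pi 10^3
  v10 <- (2 / 3) * pi * 1000 / 1000
  hs <- lv_geometry_spec("hemisphere", target_cavity_volume = v10)
  m <- generate_idealized_lv(hs, n_trans = 1, n_long = 6, n_circ = 12)
  expect_equal(compute_cavity_volume(m), v10, tolerance = 5e-3)
  # symmetric half-prolate 16.00 x 6.70: (2/3) pi a b^2 = 1.504 ml
  expect_equal(compute_cavity_volume(fx_mesh_coarse()),
               (2 / 3) * pi * 16 * 6.7^2 / 1000, tolerance = 5e-3)
  # refinement changes the measured volume by < 0.2%
  m2 <- generate_idealized_lv(lv_geometry_spec("symmetric"),
                              n_trans = 2, n_long = 12, n_circ = 20)
  expect_lt(abs(compute_cavity_volume(m2) - compute_cavity_volume(fx_mesh_coarse())) /
              compute_cavity_volume(m2), 0.002)
})

test_that("the five fetal geometries have cavity volumes within 2% of each other", {
  vols <- vapply(c("symmetric", "hypertrophic", "long", "hemisphere", "wide"),
                 function(s) compute_cavity_volume(
                   generate_idealized_lv(lv_geometry_spec(s),
                                         n_trans = 1, n_long = 8, n_circ = 12)),
                 numeric(1))
  expect_lt((max(vols) - min(vols)) / min(vols), 0.02)
})

test_that("asymmetric lean preserves wall volume, labels and element validity", {
  m <- fx_mesh_coarse()
  expect_identical(make_asymmetric_fixture(m, 0), m)
  m2 <- make_asymmetric_fixture(m, 2)
  wall_vol <- function(mm) sum(lvhelix:::tet_signed_volume(mm$nodes, mm$elems[, 1:4]))
  # pure shear: wall volume preserved (well under the 1% contract)
  expect_equal(wall_vol(m2), wall_vol(m), tolerance = 1e-6)
  expect_gt(min(lvhelix:::tet10_min_jacobian(m2$nodes, m2$elems - 1L)), 0)
  expect_identical(m2$faces$endo, m$faces$endo)
  # cavity volume also preserved by the shear
  expect_equal(compute_cavity_volume(m2), compute_cavity_volume(m),
               tolerance = 1e-6)
  expect_error(make_asymmetric_fixture(m, 50), "lean")
})

test_that("mesh write/read round-trips through the Gmsh dialect", {
  m <- generate_idealized_lv(lv_geometry_spec("symmetric"),
                             n_trans = 1, n_long = 4, n_circ = 8)
  tf <- withr::local_tempfile(fileext = ".msh")
  write_lv_mesh(m, tf)
  m2 <- read_lv_mesh(tf)
  expect_equal(m2$nodes, m$nodes, tolerance = 1e-12)
  expect_identical(m2$elems, m$elems)
  for (nm in c("endo", "epi", "base"))
    expect_identical(m2$faces[[nm]], m$faces[[nm]])
})
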