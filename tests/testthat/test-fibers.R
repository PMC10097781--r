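test_that("transmural coordinate honours boundary data and the maximum principle", {
  m <- fx_mesh_coarse()
  e <- fx_transmural()
  expect_true(all(e >= 0 & e <= 1))
  expect_equal(unname(e[unique(as.vector(m$faces$endo))]),
               rep(1, length(unique(as.vector(m$faces$endo)))))
  expect_equal(unname(e[unique(as.vector(m$faces$epi))]),
               rep(0, length(unique(as.vector(m$faces$epi)))))
  bad <- m
  bad$faces$epi <- bad$faces$epi[0, , drop = FALSE]
  expect_error(solve_transmural_coordinate(bad), "labeled")
})

test_that("harmonic coordinate matches the concentric-sphere closed form", {
  # hemispherical shell = half of a concentric-sphere annulus (the base plane
  # is a symmetry plane of the radial solution)
  sp <- lv_geometry_spec("hemisphere")
  m <- generate_idealized_lv(sp, n_trans = 2, n_long = 8, n_circ = 12)
  e <- solve_transmural_coordinate(m)
  qp <- lvhelix:::tet10_scalar_qp(m$nodes, m$elems - 1L, e)
  r <- sqrt(rowSums(qp$x^2))
  r_en <- sp$cavity_length; r_ep <- r_en + sp$wall_thickness
  exact <- (1 / r - 1 / r_ep) / (1 / r_en - 1 / r_ep)
  expect_lt(max(abs(as.numeric(qp$value) - exact)), 0.01)
})

test_that("local frames are orthonormal, right-handed, and apex-regularized", {
  fr <- fx_frames()
  expect_lt(max(abs(rowSums(fr$c * fr$l))), 1e-8)
  expect_lt(max(abs(rowSums(fr$c * fr$t))), 1e-8)
  expect_lt(max(abs(rowSums(fr$l * fr$t))), 1e-8)
  for (nm in c("c", "l", "t"))
    expect_equal(rowSums(fr[[nm]]^2), rep(1, nrow(fr$c)), tolerance = 1e-12)
  # right-handed: c x l = t
  cxl <- cbind(fr$c[, 2] * fr$l[, 3] - fr$c[, 3] * fr$l[, 2],
               fr$c[, 3] * fr$l[, 1] - fr$c[, 1] * fr$l[, 3],
               fr$c[, 1] * fr$l[, 2] - fr$c[, 2] * fr$l[, 1])
  expect_equal(cxl, fr$t, tolerance = 1e-9)
  # circumferential direction is horizontal near the base of a symmetric prolate
  i_base <- which(fx_fibers()$x_qp[, 3] > -1)
  expect_lt(max(abs(fr$c[i_base, 3])), 1e-6)
  # apex-cap points carry finite unit frames
  expect_true(all(is.finite(fr$t)))
  expect_gt(length(fr$degenerate), 0)
})

test_that("helix angle follows the linear transmural rule", {
  cfg <- helix_config(10, 123)
  expect_equal(helix_angle(0, cfg), 10 - 123 / 2)   # epicardium -51.5
  expect_equal(helix_angle(1, cfg), 10 + 123 / 2)   # endocardium +71.5
  expect_equal(helix_angle(0.5, cfg), 10)
  expect_equal(helix_angle(0.5, helix_config(25, -40)), 25)
  expect_warning(helix_config(10, 200), "swept range")
  expect_error(helix_config(NA, 0), "finite")
})

test_that("fiber fields are unit, tangent to the wall, and linear in e", {
  fib <- fx_fibers()
  fr <- fx_frames()
  expect_equal(rowSums(fib$f^2), rep(1, nrow(fib$f)), tolerance = 1e-12)
  expect_lt(max(abs(rowSums(fib$f * fr$t))), 1e-8)  # transverse angle 0
  expect_equal(fib$alpha, 10 + (fib$e_qp - 0.5) * 123, tolerance = 1e-9)
  # tau_diff = 0: uniform angle, no transmural variation
  fib0 <- assign_helix_field(fx_mesh_coarse(), fr, helix_config(35, 0))
  expect_equal(fib0$alpha, rep(35, length(fib0$alpha)))
})

test_that("negating the transmural direction reproduces the negated tau_diff field", {
  fr <- fx_frames()
  m <- fx_mesh_coarse()
  suppressWarnings({
    a_neg <- assign_helix_field(m, fr, helix_config(10, -123))$alpha
  })
  fr_flip <- fr
  fr_flip$e_qp <- 1 - fr$e_qp
  a_flip <- assign_helix_field(m, fr_flip, helix_config(10, 123))$alpha
  expect_equal(a_neg, a_flip, tolerance = 1e-12)
})
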