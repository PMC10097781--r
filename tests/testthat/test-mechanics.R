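test_that("solver configuration enforces its invariants", {
  expect_error(solver_config(steps_per_cycle = 10), "steps_per_cycle")
  expect_error(solver_config(newton_atol = 0), "tolerances")
})

test_that("zero-load volume solve returns (numerically) zero pressure", {
  m <- fx_mesh_coarse()
  model <- fe_model(m, fx_fibers(), passive_params(), NULL, solver_config())
  V0 <- compute_cavity_volume(m)
  res <- inflate_to_volume(model, V0)
  expect_lt(abs(res$p), 0.01)  # mmHg
  expect_equal(res$V, V0, tolerance = 1e-4)
})

test_that("passive pressure-volume relation is strictly increasing", {
  m <- fx_mesh_coarse()
  model <- fe_model(m, fx_fibers(), passive_params(), NULL, solver_config())
  V0 <- compute_cavity_volume(m)
  targets <- V0 * c(1.1, 1.25, 1.4)
  ps <- numeric(0); U <- NULL; p <- 0
  for (v in targets) {
    r <- inflate_to_volume(model, v, U0 = U, p0 = p)
    U <- r$U; p <- r$p
    ps <- c(ps, r$p)
    expect_equal(r$V, v, tolerance = 1e-4)
    # incompressibility at every accepted state
    expect_lt(max(abs(r$detF_range - 1)), 0.01)
  }
  expect_true(all(diff(ps) > 0))
})

test_that("isotropic-limit inflation matches the thick-sphere oracle within 2%", {
  chk <- fx_sphere_check()
  expect_gte(chk$nelem, 1400)
  expect_lt(max(abs(chk$rel_err)), 0.02)
})

test_that("unloaded state at zero EDP is the identity", {
  m <- fx_mesh_coarse()
  unl <- find_unloaded_state(m, helix_config(10, 123), EDP = 0)
  expect_identical(unl$mesh$nodes, m$nodes)
  expect_equal(unl$iterations, 0L)
})

test_that("backward displacement at EDP 5 mmHg round-trips the geometry", {
  m <- fx_mesh_coarse()
  unl <- fx_unloaded_roundtrip()
  expect_lt(abs(unl$V_roundtrip - unl$EDV) / unl$EDV, 0.005)
  x_loaded <- unl$mesh$nodes + matrix(unl$U_inflate, ncol = 3, byrow = TRUE)
  rms <- sqrt(mean(rowSums((x_loaded - m$nodes)^2)))
  cavity_radius <- m$spec$basal_cavity_width / 2
  expect_lt(rms, 0.01 * cavity_radius)
})

test_that("a stiffer wall yields a smaller inverse displacement", {
  # one fixed-point iterate is the inflation displacement itself, whose norm
  # must shrink when C doubles
  m <- fx_mesh_coarse()
  u1 <- suppressWarnings(find_unloaded_state(m, helix_config(10, 123), EDP = 3,
                                             passive = passive_params(C = 2),
                                             max_iter = 1))
  u2 <- suppressWarnings(find_unloaded_state(m, helix_config(10, 123), EDP = 3,
                                             passive = passive_params(C = 4),
                                             max_iter = 1))
  d1 <- sqrt(mean(rowSums((u1$mesh$nodes - m$nodes)^2)))
  d2 <- sqrt(mean(rowSums((u2$mesh$nodes - m$nodes)^2)))
  expect_lt(d2, d1)
})

test_that("the pressure-volume response is objective under rigid rotation", {
  m <- fx_mesh_coarse()
  fib <- fx_fibers()
  model <- fe_model(m, fib, passive_params(), NULL, solver_config())
  V_t <- compute_cavity_volume(m) * 1.25
  p_ref <- inflate_to_volume(model, V_t)$p
  rot <- rotate_mesh_fibers(m, fib, 37)
  model_r <- fe_model(rot$mesh, rot$fib, passive_params(), NULL, solver_config())
  p_rot <- inflate_to_volume(model_r, V_t)$p
  expect_equal(p_rot, p_ref, tolerance = 1e-6)
})
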