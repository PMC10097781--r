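make_pv <- function(v, p) {
  out <- data.frame(time = seq_along(v), pressure = p, volume = v)
  class(out) <- c("pv_loop", "data.frame")
  out
}

test_that("stroke work is the loop area with unit conversion", {
  # counterclockwise rectangle in (V, p): p 0..10 mmHg, V 1..2 ml -> 10 mmHg.ml
  v <- c(1, 2, 2, 1, 1); p <- c(0, 0, 10, 10, 0)
  expect_equal(compute_stroke_work(make_pv(v, p)), 10 * 0.1333224,
               tolerance = 1e-9)
  # degenerate loop at constant volume
  expect_equal(compute_stroke_work(make_pv(rep(1.5, 5), c(0, 5, 10, 5, 0))), 0)
  # reversed traversal: warned, absolute value reported
  expect_warning(sw <- compute_stroke_work(make_pv(rev(v), rev(p))),
                 "clockwise")
  expect_equal(sw, 10 * 0.1333224, tolerance = 1e-9)
  expect_error(compute_stroke_work(make_pv(c(1, 2, 2.5), c(0, 10, 5))),
               "closed")
})

test_that("stroke work agrees with the time integral of p dV", {
  pv <- fx_cycle_active()$pv
  sw <- compute_stroke_work(pv)
  v <- c(pv$volume, pv$volume[1]); p <- c(pv$pressure, pv$pressure[1])
  trap <- -sum(0.5 * (p[-1] + p[-length(p)]) * diff(v)) * 0.1333224
  expect_equal(sw, abs(trap), tolerance = 0.005)
})

test_that("identity motion yields zero strains and uniform scaling the closed form", {
  cyc <- fx_cycle_active()
  still <- cyc
  still$U <- matrix(0, nrow(cyc$U), 3)
  still$i_ed <- 1L; still$i_es <- 2L
  gs <- compute_global_strains(still)
  expect_equal(gs$eps_long, 0, tolerance = 1e-12)
  expect_equal(gs$eps_circ, 0, tolerance = 1e-12)
  # isotropic contraction by lambda = 0.9 between ED and ES:
  # E = (lambda^2 - 1)/2 = -0.095 in every direction
  lam <- 0.9
  scaled <- cyc
  U_es <- as.numeric(t((lam - 1) * cyc$model$mesh$nodes))
  scaled$U <- cbind(numeric(cyc$model$ndof), U_es)
  scaled$i_ed <- 1L; scaled$i_es <- 2L
  gs2 <- compute_global_strains(scaled)
  expect_equal(gs2$eps_long, (lam^2 - 1) / 2, tolerance = 1e-9)
  expect_equal(gs2$eps_circ, (lam^2 - 1) / 2, tolerance = 1e-9)
  # uniform relative strain has zero transmural variance
  expect_equal(compute_transmural_strain_variance(scaled), 0,
               tolerance = 1e-12)
})

test_that("strain error follows the quadratic form and its identities", {
  a <- strain_summary(0.09, 0.10)
  expect_equal(strain_error(a, a), 0)
  b <- strain_summary(0.08, 0.12)
  expect_equal(strain_error(a, b), (0.01)^2 + (0.02)^2, tolerance = 1e-9)
  expect_equal(strain_error(a, b), strain_error(b, a))
  # Case-1-style values as fractions: direct arithmetic
  fe <- strain_summary(0.0898, 0.0905)
  echo <- strain_summary(0.0895, 0.0825)
  expect_equal(strain_error(fe, echo), 6.409e-5, tolerance = 1e-12)
  expect_error(strain_error(strain_summary(8.98, 9.05), echo), "mismatch")
})

test_that("cycle metrics have the right signs, scales and invariances", {
  cyc <- fx_cycle_active()
  met <- compute_biomech_metrics(cyc)
  expect_gt(met$stroke_work, 0)
  expect_gt(met$peak_myofiber_stress, 0)
  expect_gte(met$deform_burden, 0)
  expect_gte(met$strain_variance, 0)
  expect_equal(met$stroke_volume, 1.0, tolerance = 1e-3)
  # compressive global strains at end-systole
  expect_lt(met$eps_circ, 0)
  # doubling C doubles the burden for identical kinematics
  cyc2 <- cyc
  cyc2$model$passive <- passive_params(C = 2 * cyc$model$passive$C)
  expect_equal(compute_deformational_burden(cyc2),
               2 * compute_deformational_burden(cyc), tolerance = 1e-9)
})

test_that("metrics are invariant under rigid rotation of geometry and fibers", {
  cyc <- fx_cycle_active()
  met <- compute_biomech_metrics(cyc)
  rot <- rotate_mesh_fibers(cyc$model$mesh, cyc$model$fibers, 53)
  R <- rot_z(53)
  cyc_r <- cyc
  cyc_r$model$mesh <- rot$mesh
  cyc_r$model$fibers <- rot$fib
  n <- nrow(rot$mesh$nodes)
  for (k in seq_len(ncol(cyc$U))) {
    Um <- matrix(cyc$U[, k], ncol = 3, byrow = TRUE) %*% t(R)
    cyc_r$U[, k] <- as.numeric(t(Um))
  }
  met_r <- compute_biomech_metrics(cyc_r)
  for (nm in c("peak_myofiber_stress", "deform_burden", "strain_variance",
               "eps_long", "eps_circ"))
    expect_equal(met_r[[nm]], met[[nm]], tolerance = 1e-8, label = nm)
})
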