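# Shared fixtures, built once per test run. Meshes are deliberately coarse
# (the mesh generator's structured counts are overridden) so the suite stays
# fast; geometry/constitutive values do not depend on resolution beyond the
# tolerances asserted.

.fx <- new.env(parent = emptyenv())

fx_get <- function(name, build) {
  if (!exists(name, envir = .fx)) assign(name, build(), envir = .fx)
  get(name, envir = .fx)
}

fx_mesh_coarse <- function() fx_get("mesh_coarse", function() {
  generate_idealized_lv(lv_geometry_spec("symmetric"),
                        n_trans = 1, n_long = 6, n_circ = 10)
})

fx_transmural <- function() fx_get("transmural", function() {
  solve_transmural_coordinate(fx_mesh_coarse())
})

fx_frames <- function() fx_get("frames", function() {
  build_local_frames(fx_mesh_coarse(), fx_transmural())
})

fx_fibers <- function(tau_bar = 10, tau_diff = 123) {
  key <- sprintf("fibers_%g_%g", tau_bar, tau_diff)
  fx_get(key, function() {
    assign_helix_field(fx_mesh_coarse(), fx_frames(),
                       helix_config(tau_bar, tau_diff))
  })
}

# one active volume-constrained cycle on the coarse mesh, reused by the
# metrics and driver tests
fx_cycle_active <- function() fx_get("cycle_active", function() {
  run_volume_constrained_cycle(fx_mesh_coarse(), fx_fibers(),
                               passive_params(), active_params(),
                               generate_volume_waveform(waveform_spec()),
                               solver_config(steps_per_cycle = 20))
})

# coupled FE-0D cycle on the coarse mesh (two coupled cycles so the reported
# last cycle is near-periodic)
fx_cycle_coupled <- function() fx_get("cycle_coupled", function() {
  run_coupled_cycle(fx_mesh_coarse(), fx_fibers(0, 120), passive_params(),
                    active_params(), circulation_params(),
                    solver_config(steps_per_cycle = 20),
                    warmup_cycles = 8, coupled_cycles = 2)
})

fx_cycle_passive <- function() fx_get("cycle_passive", function() {
  run_volume_constrained_cycle(fx_mesh_coarse(), fx_fibers(),
                               passive_params(), active_params(T0_LV = 0),
                               generate_volume_waveform(waveform_spec()),
                               solver_config(steps_per_cycle = 20))
})

fx_unloaded_roundtrip <- function() fx_get("unloaded_roundtrip", function() {
  find_unloaded_state(fx_mesh_coarse(), helix_config(10, 123), EDP = 5)
})

# FE inflation of a ~1500-element hemispherical shell in the isotropic
# parameter limit, compared against the 1D radial oracle at two pressures;
# cached because two suites assert on it
fx_sphere_check <- function() fx_get("sphere_check", function() {
  sp <- lv_geometry_spec("hemisphere")
  m <- generate_idealized_lv(sp, n_trans = 2, n_long = 8, n_circ = 16)
  iso <- passive_params(C = 2, b_ff = 8, b_xx = 8, b_fx = 8)
  model <- fe_model(m, build_fiber_field(m, helix_config(0, 0)), iso, NULL,
                    solver_config(epi_spring = 1e-4))
  A <- sp$cavity_length; B <- A + sp$wall_thickness
  U <- NULL
  rel_err <- c()
  for (pm in c(1.5, 3)) {
    U <- inflate_to_pressure(model, pm, U0 = U, nsteps = 3)
    a_eq <- (attr(U, "volume") * 1000 / ((2 / 3) * pi))^(1 / 3)
    p_or <- sphere_oracle_pressure(a_eq, A, B, iso) * lvhelix:::KPA_TO_MMHG
    rel_err[as.character(pm)] <- p_or / pm - 1
  }
  list(nelem = nrow(m$elems), rel_err = rel_err)
})

# 1D oracle for incompressible inflation of a thick spherical shell with the
# isotropic-limit Fung law: total strain energy by radial quadrature,
# pressure as the derivative of energy w.r.t. cavity volume. Half shell
# (hemisphere + base symmetry plane), volumes in mm^3, pressures kPa.
sphere_oracle_pressure <- function(a_inner, A, B, p) {
  stopifnot(p$b_ff == p$b_xx, p$b_xx == p$b_fx)
  b <- p$b_ff
  W <- function(lam) {
    Er <- (lam^-4 - 1) / 2
    Eh <- (lam^2 - 1) / 2
    0.5 * p$C * (exp(b * (Er^2 + 2 * Eh^2)) - 1)
  }
  energy <- function(a) {
    f <- function(R) {
      r <- (R^3 + a^3 - A^3)^(1 / 3)
      vapply(r / R, W, numeric(1)) * 2 * pi * R^2
    }
    integrate(f, A, B, rel.tol = 1e-10)$value
  }
  h <- 1e-4
  (energy(a_inner + h) - energy(a_inner - h)) /
    ((2 / 3) * pi * ((a_inner + h)^3 - (a_inner - h)^3))
}

rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

# rigidly rotate a mesh + fiber field about the long axis
rotate_mesh_fibers <- function(mesh, fib, deg) {
  R <- rot_z(deg)
  mesh$nodes <- mesh$nodes %*% t(R)
  for (nm in c("f", "s", "n")) fib[[nm]] <- fib[[nm]] %*% t(R)
  fib$frames_mat <- cbind(fib$f, fib$s, fib$n)
  fib$cl <- lapply(fib$cl, function(m) m %*% t(R))
  list(mesh = mesh, fib = fib)
}
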