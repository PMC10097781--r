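test_that("passive energy closed forms and symmetries hold", {
  p <- passive_params()
  expect_equal(passive_energy(list(), p), 0)
  e <- 0.1
  expect_equal(passive_energy(list(E_ff = e), p),
               0.5 * p$C * (exp(p$b_ff * e^2) - 1), tolerance = 1e-14)
  # transverse isotropy: swapping sheet and normal components
  expect_equal(passive_energy(list(E_ss = 0.05, E_nn = -0.02), p),
               passive_energy(list(E_ss = -0.02, E_nn = 0.05), p))
  # rotation in the (s, n) plane leaves W invariant
  set.seed(4)
  for (i in 1:10) {
    E <- matrix(rnorm(9, 0, 0.05), 3)
    E <- (E + t(E)) / 2
    th <- runif(1, 0, 2 * pi)
    R <- diag(3)
    R[2:3, 2:3] <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    expect_equal(passive_energy(t(R) %*% E %*% R, p), passive_energy(E, p),
                 tolerance = 1e-12)
  }
  expect_error(passive_energy(list(E_ff = 5), p), "cap")
  expect_error(passive_energy(matrix(c(0, 1, 0, 0, 0, 0, 0, 0, 0), 3), p),
               "symmetric")
})

test_that("passive stress is the strain-energy gradient", {
  p <- passive_params()
  expect_equal(passive_stress(list(), p), matrix(0, 3, 3),
               ignore_attr = TRUE)
  e <- 0.08
  S <- passive_stress(list(E_ff = e), p)
  expect_equal(S[1, 1], p$C * p$b_ff * e * exp(p$b_ff * e^2), tolerance = 1e-14)
  # finite-difference consistency on 100 random small strain states
  set.seed(11)
  worst <- 0
  for (i in 1:100) {
    E <- matrix(rnorm(9, 0, 0.06), 3)
    E <- (E + t(E)) / 2
    S <- passive_stress(E, p)
    h <- 1e-6
    for (k in sample(9, 3)) {
      i1 <- (k - 1) %% 3 + 1; j1 <- (k - 1) %/% 3 + 1
      Ep <- E; Ep[i1, j1] <- Ep[i1, j1] + h; Ep[j1, i1] <- Ep[i1, j1]
      Em <- E; Em[i1, j1] <- Em[i1, j1] - h; Em[j1, i1] <- Em[i1, j1]
      fd <- (passive_energy(Ep, p) - passive_energy(Em, p)) / (2 * h)
      # symmetric perturbation probes S_ij + S_ji
      an <- if (i1 == j1) S[i1, j1] else S[i1, j1] + S[j1, i1]
      worst <- max(worst, abs(fd - an) / max(abs(an), 1e-8))
    }
  }
  expect_lt(worst, 1e-6)
})

test_that("activation time course follows the three-branch law", {
  p <- active_params()
  a0 <- activation_timecourse(0, 2.0, p)
  expect_equal(a0$omega, 0); expect_equal(a0$Ct, 0)
  at0 <- activation_timecourse(p$t0, 2.0, p)
  expect_equal(at0$omega, pi); expect_equal(at0$Ct, 1)
  tr <- p$m * 2.0 + p$b_time
  expect_equal(at0$t_r, tr)
  late <- activation_timecourse(p$t0 + tr + 1, 2.0, p)
  expect_equal(late$Ct, 0)
  # continuity at both branch points
  eps <- 1e-9
  expect_equal(activation_timecourse(p$t0 - eps, 2.0, p)$Ct,
               activation_timecourse(p$t0 + eps, 2.0, p)$Ct, tolerance = 1e-6)
  expect_equal(activation_timecourse(p$t0 + tr - eps, 2.0, p)$Ct,
               activation_timecourse(p$t0 + tr + eps, 2.0, p)$Ct,
               tolerance = 1e-6)
  # peak value 1 attained exactly at t0, bounded in [0, 1] everywhere
  tt <- c(seq(0, p$cycle_length - 1e-9, length.out = 400), p$t0)
  ct <- activation_timecourse(tt, 2.0, p)$Ct
  expect_equal(max(ct), 1)
  expect_equal(tt[which.max(ct)], p$t0)
  expect_true(all(ct >= 0 & ct <= 1))
  # relaxation line example: m = 50 ms/um, l = 2 um, b = 40 ms
  p2 <- active_params(m = 50, b_time = 40)
  expect_equal(activation_timecourse(10, 2.0, p2)$t_r, 140)
  expect_error(activation_timecourse(10, 2.0, active_params(m = 1, b_time = -100)),
               "t_r")
  expect_error(activation_timecourse(500, 2.0, p), "cycle_length")
})

test_that("active tension saturates and is monotone in its drivers", {
  p <- active_params()
  expect_equal(active_stress(0, 2.0, p), 0)
  # Ca0 = ECa50 gives half the saturated tension
  act <- activation_timecourse(p$t0, 2.0, p)
  p_eq <- active_params(Ca0 = act$ECa50)
  expect_equal(active_stress(p$t0, 2.0, p_eq),
               p_eq$T0_LV * activation_timecourse(p$t0, 2.0, p_eq)$Ct / 2,
               tolerance = 1e-12)
  # saturation: very high Ca0 relative to ECa50 approaches T0 * Ct
  p_sat <- active_params(Ca0 = 1e4)
  expect_equal(active_stress(p$t0, 2.0, p_sat), p_sat$T0_LV, tolerance = 1e-4)
  # monotone in Ca0 and T0_LV
  s1 <- active_stress(100, 2.0, active_params(Ca0 = 3))
  s2 <- active_stress(100, 2.0, active_params(Ca0 = 5))
  expect_gt(s2, s1)
  s3 <- active_stress(100, 2.0, active_params(T0_LV = 30))
  s4 <- active_stress(100, 2.0, active_params(T0_LV = 50))
  expect_gt(s4, s3)
  expect_error(active_stress(100, 1.0, p), "ECa50")
})

test_that("the C++ activation kernel matches the R reference law", {
  p <- active_params()
  for (t in c(0, 50, 140.5, 200, 350)) {
    for (lam in c(0.95, 1.0, 1.1)) {
      l <- p$l_ref * lam
      expected <- if (l <= p$l0) 0 else active_stress(t, l, p)
      expect_equal(lvhelix:::active_tension_cpp(lam, lvhelix:::pact_vec(p, t)),
                   expected, tolerance = 1e-12,
                   label = sprintf("t=%g lam=%g", t, lam))
    }
  }
})
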