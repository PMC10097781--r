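test_that("scale factors act on all resistances and compliances only", {
  p <- circulation_params()
  p1 <- apply_scale_factors(p, 1, 1)
  expect_equal(p1[names(p)], p[names(p)])
  p2 <- apply_scale_factors(p, k_R = 2)
  for (nm in grep("^R_", names(p), value = TRUE))
    expect_equal(p2[[nm]], 2 * p[[nm]], label = nm)
  for (nm in grep("^C_", names(p), value = TRUE))
    expect_equal(p2[[nm]], p[[nm]], label = nm)
  p3 <- apply_scale_factors(p, k_C = 0.5)
  for (nm in grep("^C_", names(p), value = TRUE))
    expect_equal(p3[[nm]], 0.5 * p[[nm]], label = nm)
  expect_equal(p3$LV, p$LV)
  expect_error(apply_scale_factors(p, k_R = 0), "positive")
})

test_that("the integrator reproduces analytic RC discharge to 0.1%", {
  R <- 2; C <- 0.5; p0 <- 40
  out <- rc_discharge(p0, R, C, times = seq(0, 3, by = 0.05))
  expect_lt(max(abs(out$pressure - p0 * exp(-out$time / (R * C))) / p0), 1e-3)
})

test_that("closed loop conserves volume and reaches periodic steady state", {
  p <- circulation_params()
  s <- simulate_circulation(p, n_cycles = 12)
  ss <- circulation_steady_state(s, p)
  expect_lt(ss$volume_drift_per_cycle, 1e-6)
  expect_true(all(ss$edv_rel_change < 0.01))
  # valve diodes never run backward
  for (q in c("Q_mv", "Q_av", "Q_tv", "Q_pval", "Q_fo"))
    expect_gte(min(s[[q]]), 0)
  # all states repeat within 1% cycle-to-cycle at the end
  T <- p$cycle_length
  i11 <- which.min(abs(s$time - 10 * T)); i12 <- which.min(abs(s$time - 11 * T))
  vcols <- grep("^V_", names(s), value = TRUE)
  rel <- abs(s[i12, vcols] - s[i11, vcols]) / unlist(s[i11, vcols])
  expect_true(all(rel < 0.01))
})

test_that("fetal defaults give physiological pressures and outputs", {
  p <- circulation_params()
  s <- simulate_circulation(p, n_cycles = 12)
  last <- s[s$cycle == 12, ]
  expect_gt(max(last$p_LV), 30); expect_lt(max(last$p_LV), 60)
  expect_gt(max(last$V_LV), 1.5); expect_lt(max(last$V_LV), 3)
  expect_gt(max(last$V_LV) - min(last$V_LV), 0.5)
  edp <- last$p_LV[1]
  expect_gt(edp, 2); expect_lt(edp, 8)
})

test_that("raising the resistance scale factor lowers systemic output", {
  p <- circulation_params()
  co <- function(kr) {
    s <- simulate_circulation(apply_scale_factors(p, k_R = kr), n_cycles = 8)
    l <- s[s$cycle == 8, ]
    mean(l$Q_ub + l$Q_lb + l$Q_pl_a)
  }
  expect_gt(co(1), co(1.5))
})
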