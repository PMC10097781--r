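test_that("volume-constrained driver tracks the prescribed waveform", {
  cyc <- fx_cycle_active()
  wf <- cyc$waveform
  vol_fun <- attr(wf, "fun")
  expect_lt(max(abs(cyc$pv$volume - vol_fun(cyc$times)) / cyc$pv$volume), 1e-3)
  spec <- attr(wf, "spec")
  sv <- max(cyc$pv$volume) - min(cyc$pv$volume)
  expect_equal(sv, spec$EDV - spec$ESV, tolerance = 1e-3)
  expect_gt(compute_stroke_work(cyc$pv), 0)
  expect_gt(max(cyc$pv$pressure), 20)  # systolic pressures develop
})

test_that("a passive cycle does essentially no net work", {
  sw0 <- compute_stroke_work(fx_cycle_passive()$pv)
  sw1 <- compute_stroke_work(fx_cycle_active()$pv)
  expect_lt(abs(sw0), 0.01 * sw1)
})

test_that("the coupled driver conserves exchanged volume and shows four phases", {
  cyc <- fx_cycle_coupled()
  ve <- cyc$volume_exchange
  expect_lt(max(abs(ve$circ - ve$fe) / ve$circ), 1e-6)
  pv <- cyc$pv
  sv <- max(pv$volume) - min(pv$volume)
  # near-isovolumetric segments while both valves are shut
  dv <- abs(diff(pv$volume))
  expect_gt(sum(dv < 0.01 * sv), 2)
  expect_gt(compute_stroke_work(pv), 0)
  expect_gt(max(pv$pressure), 25)
  # near-periodic: the reported (second coupled) cycle closes
  expect_lt(abs(pv$volume[1] - pv$volume[nrow(pv)]),
            0.02 * diff(range(pv$volume)))
})

test_that("volume-constrained and coupled drivers agree on stroke work", {
  cyc_c <- fx_cycle_coupled()
  # drive the volume-constrained cycle with the coupled loop's own V(t)
  wf <- waveform_from_series(cyc_c$pv$time, cyc_c$pv$volume,
                             cycle_length = 400)
  cyc_v <- run_volume_constrained_cycle(
    fx_mesh_coarse(), fx_fibers(0, 120), passive_params(), active_params(),
    wf, solver_config(steps_per_cycle = 20))
  sw_c <- compute_stroke_work(cyc_c$pv)
  sw_v <- compute_stroke_work(cyc_v$pv)
  expect_equal(sw_v, sw_c, tolerance = 0.10)
})

test_that("maximum-tension calibration recovers a target peak pressure", {
  # monotone bracket premise, asserted on a cheap elastance surrogate where
  # T0 scales the LV elastance
  peak_fn <- function(T0) {
    p <- circulation_params(LV = list(Emax = T0))
    s <- simulate_circulation(p, n_cycles = 6)
    max(s$p_LV[s$cycle == 6])
  }
  lo <- peak_fn(23.9); hi <- peak_fn(59.2)
  expect_gt(hi, lo)
  target <- 0.5 * (lo + hi)
  cal <- calibrate_t0lv(peak_fn, target)
  expect_lt(abs(cal$achieved_peak - target), 0.5)
  expect_gte(cal$T0_LV, 23.9); expect_lte(cal$T0_LV, 59.2)
  expect_error(calibrate_t0lv(peak_fn, 500), "outside")
})
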