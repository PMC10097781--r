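test_that("volume waveforms honour their spec and are smooth and periodic", {
  spec <- waveform_spec(EDV = 2.2, ESV = 1.2, cycle_length = 400)
  wf <- generate_volume_waveform(spec)
  f <- attr(wf, "fun")
  expect_equal(max(wf$volume), 2.2, tolerance = 1e-9)
  expect_equal(min(wf$volume), 1.2, tolerance = 1e-9)
  expect_equal(f(0), f(400), tolerance = 1e-12)
  # C1 across the seam and at phase boundaries
  h <- 1e-5
  slope <- function(t) (f(t + h) - f(t - h)) / (2 * h)
  expect_lt(abs(slope(400) - slope(0)), 1e-6)
  expect_lt(abs(slope(attr(wf, "t_eject"))), 1e-3)
  # no isovolumetric plateaus at the extremes: volume leaves EDV immediately
  expect_lt(f(10), 2.2)
  expect_gt(f(attr(wf, "t_eject") + 10), 1.2)
  # fetal default cycle length
  expect_equal(waveform_spec()$cycle_length, 400)
  expect_equal(waveform_spec_adult()$EDV - waveform_spec_adult()$ESV, 81.8)
  expect_error(waveform_spec(EDV = 1, ESV = 2), "EDV")
  expect_error(waveform_spec(systolic_fraction = 1.2), "fractions")
})

test_that("unload time sits one third into diastole", {
  wf <- generate_volume_waveform(waveform_spec(cycle_length = 400,
                                               systolic_fraction = 0.4))
  expect_equal(waveform_unload_time(wf), 160 + 240 / 3)
})

test_that("synthetic echo strains are exact at zero noise and seed-reproducible", {
  s <- generate_synthetic_echo_strains(0.09, 0.10, sd = 0, seed = 3)
  expect_equal(s$eps_long, 0.09)
  expect_equal(s$eps_circ, 0.10)
  s1 <- generate_synthetic_echo_strains(0.09, 0.10, sd = 0.01, seed = 42)
  s2 <- generate_synthetic_echo_strains(0.09, 0.10, sd = 0.01, seed = 42)
  expect_identical(s1, s2)
  s3 <- generate_synthetic_echo_strains(0.09, 0.10, sd = 0.01, seed = 43)
  expect_false(identical(s1, s3))
  # law of large numbers: sample sd of many draws near the nominal sd
  draws <- vapply(1:1000, function(k)
    generate_synthetic_echo_strains(0, 0, sd = 0.01, seed = k)$eps_long,
    numeric(1))
  expect_lt(abs(sd(draws) - 0.01) / 0.01, 0.10)
  expect_error(generate_synthetic_echo_strains(0, 0, sd = -1), "sd")
})
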