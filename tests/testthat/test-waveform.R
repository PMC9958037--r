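test_that("constant flow integrates to its exact volumes", {
  wf <- generate_waveform(waveform_params(mean_flux = 1, pulse_amplitude = 0),
                          heart_rate = 60, n_phases = 30)
  expect_equal(wf$rr_interval, 1)
  expect_true(all(wf$flux == 1))
  expect_equal(wf$truth$ffv, 1)
  expect_equal(wf$truth$bfv, 0)
  expect_equal(wf$truth$sv, 1)
  expect_equal(wf$truth$asv, 1)
})

test_that("full reflux cancels the stroke volume and doubles the ASV", {
  wf <- generate_waveform(waveform_params(mean_flux = 0.5, pulse_amplitude = 0,
                                          reflux_fraction = 1),
                          heart_rate = 75, n_phases = 30)
  expect_equal(wf$truth$sv, 0)
  expect_equal(wf$truth$asv, 2 * wf$truth$ffv)
  expect_equal(wf$truth$bfv, wf$truth$ffv)
})

test_that("closed-form truth matches dense quadrature of the parametric flux", {
  cases <- list(
    list(mean_flux = 1, pulse_amplitude = 0.4, reflux_fraction = 0),
    list(mean_flux = 0.35, pulse_amplitude = 0.1, reflux_fraction = 0.5),
    list(mean_flux = 2, pulse_amplitude = 1.2, reflux_fraction = 0.25,
         reflux_width = 0.4),
    list(mean_flux = 0.2, pulse_amplitude = 0, reflux_fraction = 0.9))
  for (pars in cases) {
    for (hr in c(55, 70, 96)) {
      wf <- generate_waveform(do.call(waveform_params, pars), heart_rate = hr)
      oracle <- quad_truth(wf)
      for (fld in c("sv", "ffv", "bfv", "asv")) {
        expect_lt(abs(wf$truth[[fld]] - oracle[[fld]]) /
                    max(abs(oracle[[fld]]), 1e-6), 0.001)
      }
    }
  }
})

test_that("truth volumes satisfy the conservation identities exactly", {
  set.seed(11)
  for (i in 1:25) {
    wf <- generate_waveform(
      waveform_params(mean_flux = runif(1, 0.1, 5),
                      pulse_amplitude = runif(1, 0, 2),
                      reflux_fraction = sample(c(0, runif(1)), 1)),
      heart_rate = runif(1, 45, 110), n_phases = sample(20:60, 1))
    expect_identical(wf$truth$sv, wf$truth$ffv - wf$truth$bfv)
    expect_identical(wf$truth$asv, wf$truth$ffv + wf$truth$bfv)
    expect_equal(length(wf$flux), wf$n_phases)
    expect_true(all(diff(wf$phase_times) > 0))
  }
})

test_that("invalid waveform parameters are rejected", {
  expect_error(waveform_params(mean_flux = NaN), "finite")
  expect_error(waveform_params(mean_flux = 1, reflux_fraction = 1.2), "\\[0, 1\\]")
  expect_error(waveform_params(mean_flux = -1), "non-negative")
  expect_error(generate_waveform(waveform_params(1), heart_rate = 0), "positive")
  expect_error(generate_waveform(waveform_params(1), heart_rate = 60,
                                 n_phases = 7), ">= 8")
  # reflux window too coarse at few phases
  expect_error(generate_waveform(
    waveform_params(1, 0, reflux_fraction = 0.5, reflux_width = 0.1),
    heart_rate = 60, n_phases = 20), "4 phase bins")
  # overlapping pulse and reflux windows
  expect_error(generate_waveform(
    waveform_params(1, 0.5, reflux_fraction = 0.5,
                    pulse_start = 0.5, pulse_width = 0.2,
                    reflux_start = 0.55, reflux_width = 0.3),
    heart_rate = 60), "overlap")
})
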