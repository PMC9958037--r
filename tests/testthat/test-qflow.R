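make_curve <- function(flux, rr = 1, area = 1) {
  n <- length(flux)
  structure(tibble::tibble(phase_time = (seq_len(n) - 1) * rr / n, flux = flux),
            rr_interval = rr, roi_area = area)
}

test_that("constant unit flux gives the unit parameter set", {
  q <- compute_qflow(make_curve(rep(1, 30)))
  expect_equal(q$sv, 1)
  expect_equal(q$ffv, 1)
  expect_equal(q$bfv, 0)
  expect_equal(q$rf, 0)
  expect_equal(q$asv, 1)
  expect_equal(q$mf, 1)
  expect_equal(q$sd, 1)
  expect_equal(q$mv, 1)
  expect_equal(q$heart_rate, 60)
})

test_that("a sinusoidal flux splits into the closed-form lobe volumes", {
  n <- 1000
  t <- (seq_len(n) - 1) / n
  q <- compute_qflow(make_curve(sin(2 * pi * t)))
  expect_lt(abs(q$sv), 1e-10)
  expect_lt(rel_err(q$ffv, 1 / pi), 0.01)
  expect_lt(rel_err(q$bfv, 1 / pi), 0.01)
  expect_lt(rel_err(q$asv, 2 / pi), 0.01)
  expect_lt(abs(q$rf - 100), 1)
})

test_that("pure retrograde flow has zero FFV and an undefined RF", {
  q <- compute_qflow(make_curve(rep(-2, 20), rr = 0.5))
  expect_equal(q$ffv, 0)
  expect_equal(q$bfv, 1)
  expect_equal(q$sv, -1)
  expect_true(is.na(q$rf))
})

test_that("the ROI flux curve equals an independent per-pixel summation", {
  set.seed(5)
  cine <- structure(array(rnorm(10 * 12 * 12), c(10, 12, 12)),
                    phase_times = (0:9) / 10, rr_interval = 1,
                    pixel_spacing = 0.2,
                    class = c("velocity_cine", "array"))
  roi <- structure(matrix(runif(144) > 0.6, 12, 12), pixel_spacing = 0.2)
  fc <- compute_flux_curve(cine, roi)
  expect_equal(fc$flux, brute_flux(cine, roi))
})

test_that("conservation and consistency identities hold on random curves", {
  set.seed(6)
  for (i in 1:20) {
    n <- sample(10:50, 1)
    q <- compute_qflow(make_curve(rnorm(n), rr = runif(1, 0.5, 1.5),
                                  area = runif(1, 0.2, 2)))
    expect_identical(q$sv, q$ffv - q$bfv)
    expect_identical(q$asv, q$ffv + q$bfv)
    expect_lt(abs(q$mv * q$roi_area - q$mf) / max(abs(q$mf), 1e-12), 1e-9)
    expect_equal(q$mf, q$sv * q$heart_rate / 60)
  }
})

test_that("scaling all velocities scales the volumes linearly, RF invariant", {
  set.seed(7)
  flux <- rnorm(25, 0.2, 1)
  q1 <- compute_qflow(make_curve(flux, rr = 0.8, area = 0.5))
  c_ <- 3.7
  q2 <- compute_qflow(make_curve(c_ * flux, rr = 0.8, area = 0.5))
  for (fld in c("sv", "ffv", "bfv", "asv", "mf", "sd", "mv")) {
    expect_equal(q2[[fld]], c_ * q1[[fld]])
  }
  expect_equal(q2$rf, q1$rf)
})

test_that("invalid flux-curve inputs are rejected", {
  expect_error(compute_qflow(make_curve(rep(1, 10), rr = -1)), "rr_interval")
  expect_error(compute_qflow(make_curve(rep(1, 10), area = 0)), "roi_area")
  cine <- structure(array(0, c(5, 8, 8)), phase_times = (0:4) / 5,
                    rr_interval = 1, pixel_spacing = 0.2,
                    class = c("velocity_cine", "array"))
  expect_error(compute_flux_curve(cine, matrix(FALSE, 8, 8)), "empty")
  expect_error(compute_flux_curve(cine, matrix(TRUE, 6, 6)), "match")
})

test_that("batch QFlow covers every subject-setpoint of a cohort", {
  co <- generate_cohort(tiny_cfg(noise_sd = 0), seed = 3)
  q <- batch_qflow(co)
  expect_equal(nrow(q), 40L)
  expect_setequal(unique(q$setpoint), c("EIV", "FV", "PV", "GSV"))
  # noise-free measurements recover the generator truth
  for (fld in c("sv", "ffv", "bfv", "asv", "mf", "sd", "mv")) {
    expect_true(all(rel_err(q[[fld]], co[[paste0("truth_", fld)]]) < 0.005 |
                      abs(co[[paste0("truth_", fld)]]) < 1e-9))
  }
})

test_that("phase- and pixel-level splits agree on noise-free cines", {
  co <- generate_cohort(tiny_cfg(noise_sd = 0, n_reflux = 2L, n_control = 1L),
                        seed = 4)
  expect_equal(batch_qflow(co, split = "phase")$ffv,
               batch_qflow(co, split = "pixel")$ffv, tolerance = 1e-10)
})
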