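# Small cohort configuration for fast unit tests (full-size cohorts are
# exercised in test-acceptance.R).
tiny_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_reflux = 6L, n_control = 4L, grid_shape = c(32L, 32L)),
    list(...))
  do.call(cohort_config, args)
}

# Independent per-pixel summation oracle for the ROI flux curve.
brute_flux <- function(cine, roi) {
  d <- dim(cine)
  ps <- attr(roi, "pixel_spacing")
  out <- numeric(d[1])
  for (t in seq_len(d[1])) {
    acc <- 0
    for (r in seq_len(d[2])) {
      for (c in seq_len(d[3])) {
        if (roi[r, c]) acc <- acc + cine[t, r, c] * ps^2
      }
    }
    out[t] <- acc
  }
  out
}

# Dense-quadrature oracle for the truth volumes of a waveform: midpoint rule
# on the continuous parametric flux at n points.
quad_truth <- function(wf, n = 1e4) {
  tt <- (seq_len(n) - 0.5) * wf$rr_interval / n
  q <- waveform_flux_at(wf, tt)
  h <- wf$rr_interval / n
  ffv <- sum(q[q > 0]) * h
  bfv <- -sum(q[q < 0]) * h
  list(sv = ffv - bfv, ffv = ffv, bfv = bfv, asv = ffv + bfv)
}

rel_err <- function(x, ref) abs(x - ref) / pmax(abs(ref), 1e-12)
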