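#' Per-setpoint venous waveform parameters
#'
#' Bundles the parametric description of a single vessel's flux waveform over
#' one cardiac cycle: a constant antegrade baseline (toward-head positive), a
#' smooth antegrade pulse, and, for refluxing great saphenous veins, a
#' retrograde lobe bracketed by one-phase valve-closure tapers.
#'
#' Window positions are expressed as fractions of the cardiac cycle and are
#' snapped to the sampled phase grid when the waveform is generated, so that
#' every flow-direction transition coincides with a sampled phase.
#'
#' @param mean_flux Baseline antegrade flux in mL/s (non-negative).
#' @param pulse_amplitude Peak amplitude of the antegrade pulse in mL/s.
#' @param reflux_fraction Integrated retrograde lobe volume as a fraction of
#'   the integrated antegrade volume, in `[0, 1]`. Zero disables the lobe.
#' @param pulse_start,pulse_width Start and width of the antegrade pulse
#'   window, as fractions of the cycle.
#' @param reflux_start,reflux_width Start and width of the reflux window,
#'   as fractions of the cycle.
#' @return A list of class `waveform_params`.
#' @seealso [generate_waveform()]
#' @export
waveform_params <- function(mean_flux,
                            pulse_amplitude = 0.3 * mean_flux,
                            reflux_fraction = 0,
                            pulse_start = 0.08, pulse_width = 0.2,
                            reflux_start = 0.55, reflux_width = 0.3) {
  p <- list(mean_flux = mean_flux, pulse_amplitude = pulse_amplitude,
            reflux_fraction = reflux_fraction,
            pulse_start = pulse_start, pulse_width = pulse_width,
            reflux_start = reflux_start, reflux_width = reflux_width)
  bad <- !vapply(p, function(x) is.numeric(x) && length(x) == 1L && is.finite(x),
                 logical(1))
  if (any(bad)) {
    stop("waveform parameters must be finite scalars; offending: ",
         paste(names(p)[bad], collapse = ", "), call. = FALSE)
  }
  if (p$mean_flux < 0) stop("mean_flux must be non-negative", call. = FALSE)
  if (p$pulse_amplitude < 0) stop("pulse_amplitude must be non-negative", call. = FALSE)
  if (p$reflux_fraction < 0 || p$reflux_fraction > 1) {
    stop("reflux_fraction must lie in [0, 1]", call. = FALSE)
  }
  structure(p, class = "waveform_params")
}

#' Generate a sampled venous flow waveform with closed-form ground truth
#'
#' Builds the flux curve of one vessel over one R-R interval, sampled at
#' `n_phases` uniformly spaced cardiac phases, together with analytically
#' integrated truth volumes. Flux is signed, positive toward the head.
#'
#' The waveform is piecewise sinusoid-plus-constant: a baseline `mean_flux`,
#' an antegrade half-cycle `sin^2` pulse, and (when `reflux_fraction > 0`) a
#' reflux window in which flow tapers to zero over one phase bin
#' (`cos^2` valve closure), reverses as a `sin^2` retrograde lobe, and tapers
#' back. All window junctions are snapped to the phase grid and every piece
#' has vanishing end derivatives, so the trapezoidal phase-bin integration
#' used by the QFlow stage reproduces the analytic truth volumes essentially
#' to machine precision on noise-free data.
#'
#' The retrograde lobe is scaled so its integrated volume equals
#' `reflux_fraction` times the integrated antegrade volume; hence
#' `truth$bfv = reflux_fraction * truth$ffv` exactly.
#'
#' @param params A [waveform_params()] object (or a list coercible to one).
#' @param heart_rate Heart rate in beats/min; the R-R interval is
#'   `60 / heart_rate` seconds.
#' @param n_phases Number of sampled cardiac phases (at least 8; at least a
#'   4-bin reflux window is required when `reflux_fraction > 0`).
#' @param seed Accepted for interface symmetry with the rendering stage; the
#'   waveform itself is deterministic and the value is ignored.
#' @return An object of class `flow_waveform`: a list with `phase_times`
#'   (seconds, starting at 0), `flux` (mL/s per phase), `rr_interval`
#'   (seconds), and `truth`, a list with analytically integrated `sv`,
#'   `ffv`, `bfv` and `asv` in mL.
#' @examples
#' wf <- generate_waveform(waveform_params(mean_flux = 1, pulse_amplitude = 0),
#'                         heart_rate = 60)
#' wf$truth$sv   # 1 mL: constant 1 mL/s over a 1 s cycle
#' @export
generate_waveform <- function(params, heart_rate, n_phases = 30, seed = NULL) {
  if (!inherits(params, "waveform_params")) params <- do.call(waveform_params, params)
  if (!is.numeric(heart_rate) || length(heart_rate) != 1L || !is.finite(heart_rate) ||
      heart_rate <= 0) {
    stop("heart_rate must be a positive finite scalar", call. = FALSE)
  }
  n <- as.integer(n_phases)
  if (is.na(n) || n < 8L) stop("n_phases must be an integer >= 8", call. = FALSE)

  rr <- 60 / heart_rate
  h <- rr / n
  t <- (seq_len(n) - 1L) * h
  m <- params$mean_flux
  a <- params$pulse_amplitude
  rf <- params$reflux_fraction

  p0 <- round(params$pulse_start * n)
  np <- round(params$pulse_width * n)
  if (a > 0 && np < 2L) stop("pulse window resolves to fewer than 2 phase bins", call. = FALSE)
  r0 <- round(params$reflux_start * n)
  nr <- round(params$reflux_width * n)
  if (rf > 0) {
    if (nr < 4L) {
      stop("reflux window resolves to fewer than 4 phase bins; ",
           "increase n_phases or reflux_width", call. = FALSE)
    }
    if (r0 < 0L || r0 + nr > n) stop("reflux window must lie within the cycle", call. = FALSE)
    if (a > 0 && !(p0 + np <= r0 || r0 + nr <= p0)) {
      stop("pulse and reflux windows overlap", call. = FALSE)
    }
    if (m <= 0) stop("reflux_fraction > 0 requires mean_flux > 0", call. = FALSE)
  }
  if (a > 0 && (p0 < 0L || p0 + np > n)) {
    stop("pulse window must lie within the cycle", call. = FALSE)
  }

  flux <- rep(m, n)
  if (a > 0) {
    j <- 0:(np - 1L)
    flux[p0 + j + 1L] <- flux[p0 + j + 1L] + a * sin(pi * j / np)^2
  }

  pulse_vol <- if (a > 0) a * np * h / 2 else 0
  if (rf > 0) {
    # antegrade volume: baseline outside the window, two half-bin tapers, pulse
    ffv <- m * (rr - nr * h) + m * h + pulse_vol
    lobe_len <- (nr - 2L) * h
    A <- 2 * rf * ffv / lobe_len
    j <- 1:(nr - 1L)
    flux[r0 + j + 1L] <- -A * sin(pi * (j - 1L) / (nr - 2L))^2
    bfv <- rf * ffv
  } else {
    ffv <- m * rr + pulse_vol
    bfv <- 0
    A <- 0
  }

  structure(list(
    phase_times = t, flux = flux, rr_interval = rr, n_phases = n,
    truth = list(sv = ffv - bfv, ffv = ffv, bfv = bfv, asv = ffv + bfv),
    pieces = list(m = m, a = a, A = A, h = h, p0 = p0, np = np, r0 = r0, nr = nr)
  ), class = "flow_waveform")
}

#' Evaluate the continuous-time flux of a generated waveform
#'
#' Evaluates the underlying parametric (continuous-time) flux curve of a
#' [generate_waveform()] result at arbitrary times, independent of the phase
#' sampling. Mainly useful for plotting and for quadrature cross-checks of
#' the closed-form truth volumes.
#'
#' @param waveform A `flow_waveform` object.
#' @param t Times in seconds within `[0, rr_interval)`.
#' @return Flux in mL/s at each time.
#' @export
waveform_flux_at <- function(waveform, t) {
  stopifnot(inherits(waveform, "flow_waveform"))
  pc <- waveform$pieces
  q <- rep(pc$m, length(t))
  if (pc$a > 0) {
    s <- t - pc$p0 * pc$h
    inp <- s >= 0 & s < pc$np * pc$h
    q[inp] <- q[inp] + pc$a * sin(pi * s[inp] / (pc$np * pc$h))^2
  }
  if (pc$A > 0) {
    s <- t - pc$r0 * pc$h
    w <- pc$nr * pc$h
    inw <- s >= 0 & s < w
    sw <- s[inw]
    qq <- numeric(length(sw))
    dn <- sw < pc$h
    up <- sw >= w - pc$h
    mid <- !dn & !up
    qq[dn] <- pc$m * cos(pi * sw[dn] / (2 * pc$h))^2
    qq[up] <- pc$m * cos(pi * (w - sw[up]) / (2 * pc$h))^2
    qq[mid] <- -pc$A * sin(pi * (sw[mid] - pc$h) / ((pc$nr - 2L) * pc$h))^2
    q[inw] <- qq
  }
  q
}

#' @export
print.flow_waveform <- function(x, ...) {
  cat(sprintf(
    "<flow_waveform> %d phases over %.3f s; truth SV %.3f, FFV %.3f, BFV %.3f mL\n",
    x$n_phases, x$rr_interval, x$truth$sv, x$truth$ffv, x$truth$bfv))
  invisible(x)
}
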