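#' Net flux curve of an ROI over the cardiac cycle
#'
#' Sums the phase-shift (velocity) signal over the ROI pixels at every
#' cardiac phase: `flux[t] = sum(velocity[t, pixel] * pixel_area)`, giving
#' mL/s when velocities are cm/s and the pixel area cm^2.
#'
#' @param cine A `velocity_cine` array (`[phase, row, col]`).
#' @param roi A logical ROI mask congruent with the cine frames.
#' @return A `flux_curve` tibble with columns `phase_time` (s) and `flux`
#'   (mL/s, toward-head positive), carrying `rr_interval` and `roi_area`
#'   attributes.
#' @export
compute_flux_curve <- function(cine, roi) {
  d <- dim(cine)
  if (length(d) != 3L) stop("cine must be a [phase, row, col] array", call. = FALSE)
  if (!all(dim(roi) == d[2:3])) {
    stop("ROI mask shape does not match the cine frames", call. = FALSE)
  }
  if (!any(roi)) stop("ROI mask is empty", call. = FALSE)
  ps <- attr(roi, "pixel_spacing") %||% attr(cine, "pixel_spacing")
  if (is.null(ps)) stop("no pixel_spacing attribute on cine or roi", call. = FALSE)
  px_area <- ps^2
  m <- matrix(cine, nrow = d[1])
  flux <- rowSums(m[, as.vector(roi), drop = FALSE]) * px_area
  structure(
    tibble(phase_time = attr(cine, "phase_times"), flux = flux),
    rr_interval = attr(cine, "rr_interval"),
    roi_area = sum(roi) * px_area,
    class = c("flux_curve", class(tibble())))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Cyclic trapezoid weights for phase times over one R-R interval: each phase
# gets half the span between its cyclic neighbours, the last interval closing
# the cycle at rr_interval. Uniform grids get uniform weights rr/n.
phase_weights <- function(phase_times, rr_interval) {
  n <- length(phase_times)
  tn <- c(phase_times, phase_times[1] + rr_interval)
  dt <- diff(tn)
  if (any(dt <= 0)) stop("phase_times must be strictly increasing within the cycle",
                         call. = FALSE)
  (dt + c(dt[n], dt[-n])) / 2
}

#' Eight QFlow hemodynamic parameters from a flux curve
#'
#' Time-integrates the signed ROI flux over one R-R interval by the cyclic
#' trapezoid rule on the phase bins and reports the standard QFlow set:
#' \describe{
#'   \item{sv}{Stroke volume (mL): net volume through the ROI per beat.}
#'   \item{ffv}{Forward flow volume (mL): integral over phases with net
#'     flux toward the head.}
#'   \item{bfv}{Backward flow volume (mL): magnitude of the integral over
#'     phases with net flux toward the feet.}
#'   \item{rf}{Regurgitant fraction (%): `100 * bfv / ffv`; `NA` when
#'     `ffv = 0` (undefined, never silently zero).}
#'   \item{asv}{Absolute stroke volume (mL): `ffv + bfv`.}
#'   \item{mf}{Mean flux (mL/s): `sv * heart_rate / 60`.}
#'   \item{sd}{Stroke distance (cm): net distance blood travels per beat,
#'     `sv / roi_area`.}
#'   \item{mv}{Mean velocity (cm/s): `sd * heart_rate / 60`.}
#' }
#' The forward/backward split is made at the phase level (sign of the net
#' ROI flux per phase); see [batch_qflow()] for the per-pixel alternative.
#'
#' @param flux_curve A [compute_flux_curve()] result, or any tibble with
#'   `phase_time` and `flux` columns plus an `rr_interval` attribute (or an
#'   `rr_interval` argument).
#' @param roi_area ROI area in cm^2; defaults to the curve's attribute.
#' @param rr_interval R-R interval in seconds; defaults to the curve's
#'   attribute.
#' @return A one-row tibble: `sv, ffv, bfv, rf, asv, mf, sd, mv, roi_area,
#'   heart_rate`.
#' @examples
#' fc <- tibble::tibble(phase_time = seq(0, 0.9, 0.1), flux = rep(1, 10))
#' compute_qflow(fc, roi_area = 1, rr_interval = 1)
#' @export
compute_qflow <- function(flux_curve, roi_area = attr(flux_curve, "roi_area"),
                          rr_interval = attr(flux_curve, "rr_interval")) {
  if (is.null(rr_interval) || !is.finite(rr_interval) || rr_interval <= 0) {
    stop("rr_interval must be a positive finite scalar", call. = FALSE)
  }
  if (is.null(roi_area) || !is.finite(roi_area) || roi_area <= 0) {
    stop("roi_area must be a positive finite scalar", call. = FALSE)
  }
  flux <- flux_curve$flux
  if (!all(is.finite(flux))) stop("flux curve contains non-finite values", call. = FALSE)
  vols <- split_volumes(flux, flux_curve$phase_time, rr_interval)
  qflow_from_volumes(vols[["ffv"]], vols[["bfv"]], roi_area, rr_interval)
}

# Vectorized over its four arguments.
qflow_from_volumes <- function(ffv, bfv, roi_area, rr_interval) {
  sv <- ffv - bfv
  hr <- 60 / rr_interval
  sd_ <- sv / roi_area
  tibble(
    sv = sv, ffv = ffv, bfv = bfv,
    rf = ifelse(ffv > 0, 100 * bfv / ffv, NA_real_),
    asv = ffv + bfv,
    mf = sv * hr / 60,
    sd = sd_,
    mv = sd_ * hr / 60,
    roi_area = roi_area,
    heart_rate = hr)
}

# Signed forward/backward volume split of a sampled flux curve (phase level).
split_volumes <- function(flux, phase_times, rr_interval) {
  w <- phase_weights(phase_times, rr_interval)
  c(ffv = sum(w[flux > 0] * flux[flux > 0]),
    bfv = -sum(w[flux < 0] * flux[flux < 0]))
}

# Forward/backward volumes of a cine + mask, with phase- or pixel-level
# direction split; returns c(ffv, bfv, roi_area, rr_interval).
cine_volumes <- function(cine, roi, split = c("phase", "pixel")) {
  split <- match.arg(split)
  d <- dim(cine)
  if (length(d) != 3L) stop("cine must be a [phase, row, col] array", call. = FALSE)
  if (!all(dim(roi) == d[2:3])) {
    stop("ROI mask shape does not match the cine frames", call. = FALSE)
  }
  if (!any(roi)) stop("ROI mask is empty", call. = FALSE)
  ps <- attr(roi, "pixel_spacing") %||% attr(cine, "pixel_spacing")
  px_area <- ps^2
  rr <- attr(cine, "rr_interval")
  w <- phase_weights(attr(cine, "phase_times"), rr)
  m <- matrix(cine, nrow = d[1])[, as.vector(roi), drop = FALSE]
  if (split == "phase") {
    flux <- rowSums(m) * px_area
    vols <- c(sum(w[flux > 0] * flux[flux > 0]),
              -sum(w[flux < 0] * flux[flux < 0]))
  } else {
    pos <- rowSums(m * (m > 0)) * px_area
    neg <- -rowSums(m * (m < 0)) * px_area
    vols <- c(sum(w * pos), sum(w * neg))
  }
  c(ffv = vols[1], bfv = vols[2], roi_area = sum(roi) * px_area,
    rr_interval = rr)
}

qflow_from_cine <- function(cine, roi, split = c("phase", "pixel")) {
  v <- cine_volumes(cine, roi, split)
  qflow_from_volumes(v[["ffv"]], v[["bfv"]], v[["roi_area"]], v[["rr_interval"]])
}

#' QFlow parameter table for a whole cohort
#'
#' Runs the QFlow quantification over every subject-setpoint cine of a
#' cohort, yielding one row per (subject, setpoint) with the eight
#' hemodynamic parameters plus identifying metadata. Cohorts generated with
#' `render = FALSE` are quantified from their sampled waveform flux curves
#' (no spatial rendering, hence no velocity noise).
#'
#' A character `cohort` is taken as a path to a cohort manifest CSV written
#' by [write_cohort()]; unreadable or missing setpoint files are reported
#' with a warning, skipped, and recorded in the `failures` attribute while
#' the run continues.
#'
#' @param cohort A `vein_cohort` tibble from [generate_cohort()] /
#'   [read_cohort()], or a manifest CSV path.
#' @param split Direction split for forward/backward volumes: `"phase"`
#'   (sign of the net ROI flux per phase; default, matching vendor-style
#'   flow curves) or `"pixel"` (per-pixel sign before summation).
#' @return A tibble with columns `subject_id, group, limb, label, setpoint,
#'   sv, ffv, bfv, rf, asv, mf, sd, mv, roi_area, heart_rate`.
#' @export
batch_qflow <- function(cohort, split = c("phase", "pixel")) {
  split <- match.arg(split)
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  stopifnot(is_tibble(cohort))
  failures <- attr(cohort, "failures")
  n <- nrow(cohort)
  wfs <- if ("waveform" %in% names(cohort)) cohort$waveform else
    vector("list", n)
  ffv <- bfv <- area <- rr <- numeric(n)
  for (i in seq_len(n)) {
    cine <- cohort$cine[[i]]
    if (!is.null(cine)) {
      v <- cine_volumes(cine, cohort$roi[[i]], split)
    } else {
      wf <- wfs[[i]]
      v <- c(split_volumes(wf$flux, wf$phase_times, wf$rr_interval),
             roi_area = roi_area(cohort$roi[[i]]), rr_interval = wf$rr_interval)
    }
    ffv[i] <- v[["ffv"]]; bfv[i] <- v[["bfv"]]
    area[i] <- v[["roi_area"]]; rr[i] <- v[["rr_interval"]]
  }
  meta <- as_tibble(cohort)[, intersect(
    c("subject_id", "group", "limb", "label", "setpoint"), names(cohort))]
  attr(meta, "config") <- NULL
  out <- dplyr::bind_cols(meta, qflow_from_volumes(ffv, bfv, area, rr))
  attr(out, "failures") <- failures
  out
}
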