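#' Synthetic cohort configuration
#'
#' Describes the study conditions emulated by the synthetic cine generator:
#' 26 limbs with superficial great-saphenous reflux and 15 healthy-control
#' limbs, each imaged at the four venous setpoints (EIV, FV, PV, GSV), with
#' the between-group effect confined to the GSV segment. Reflux limbs carry a
#' retrograde GSV lobe (drawn reflux fraction) and a moderately dilated-flow
#' GSV baseline; EIV/FV/PV parameters are shared between groups.
#'
#' @param n_reflux,n_control Group sizes (default 26 and 15).
#' @param n_phases Cardiac phases per cine (default 30).
#' @param grid_shape,pixel_spacing Imaging grid (default 64x64 at 0.17 cm,
#'   the 1.7 mm in-plane voxel of lower-limb QFlow protocols).
#' @param noise_sd Velocity noise in cm/s added by the renderer (default 1).
#' @param heart_rate_mean,heart_rate_sd,heart_rate_range Normal(70, 8)
#'   heart-rate distribution truncated to a physiologic 40-120 beats/min.
#' @param setpoints Per-vessel baseline parameters: mean flux (mL/s),
#'   antegrade pulse amplitude (mL/s) and lumen radius (cm) for EIV, FV,
#'   PV, GSV.
#' @param flux_sdlog Log-normal between-subject spread of each vessel's
#'   mean flux (sdlog scale).
#' @param gsv_flux_multiplier Multiplier on the GSV baseline flux of reflux
#'   limbs. A refluxing GSV is a dilated recirculation conduit carrying
#'   well above normal throughput; the default 1.85 yields roughly a 1.35x
#'   antegrade (FFV) volume in expectation once the antegrade flow
#'   suppressed during the reflux window is accounted for, about twice the
#'   control absolute stroke volume, and a clearly reduced net stroke
#'   volume.
#' @param reflux_mean,reflux_sd,reflux_range Truncated-normal distribution
#'   of the reflux fraction in reflux limbs' GSV; controls are always 0.
#' @param pulse_start,pulse_width,reflux_start,reflux_width Waveform window
#'   fractions passed to [waveform_params()].
#' @return A list of class `cohort_config`.
#' @seealso [generate_cohort()], [null_cohort_config()]
#' @export
cohort_config <- function(n_reflux = 26L, n_control = 15L,
                          n_phases = 30L,
                          grid_shape = c(64L, 64L), pixel_spacing = 0.17,
                          noise_sd = 1,
                          heart_rate_mean = 70, heart_rate_sd = 8,
                          heart_rate_range = c(40, 120),
                          setpoints = list(
                            EIV = list(mean_flux = 6.0, pulse_amplitude = 1.8, lumen_radius = 0.60),
                            FV  = list(mean_flux = 4.0, pulse_amplitude = 1.2, lumen_radius = 0.50),
                            PV  = list(mean_flux = 1.3, pulse_amplitude = 0.4, lumen_radius = 0.40),
                            GSV = list(mean_flux = 0.35, pulse_amplitude = 0.10, lumen_radius = 0.35)),
                          flux_sdlog = 0.25,
                          gsv_flux_multiplier = 1.85,
                          reflux_mean = 0.5, reflux_sd = 0.12,
                          reflux_range = c(0.2, 0.8),
                          pulse_start = 0.08, pulse_width = 0.2,
                          reflux_start = 0.55, reflux_width = 0.3) {
  if (n_reflux < 1L || n_control < 1L) {
    stop("group sizes must be at least 1", call. = FALSE)
  }
  stopifnot(identical(sort(names(setpoints)), sort(c("EIV", "FV", "PV", "GSV"))))
  cfg <- as.list(environment())
  cfg$n_reflux <- as.integer(n_reflux)
  cfg$n_control <- as.integer(n_control)
  structure(cfg, class = "cohort_config")
}

#' Zero-effect (null) cohort configuration
#'
#' The default configuration with the GSV effect removed: reflux-group limbs
#' draw their GSV parameters from the same distributions as controls and
#' carry no retrograde lobe. Used for type-I-error calibration of the group
#' comparisons.
#'
#' @param ... Overrides forwarded to [cohort_config()].
#' @return A `cohort_config`.
#' @export
null_cohort_config <- function(...) {
  cohort_config(gsv_flux_multiplier = 1, reflux_mean = 0, reflux_sd = 0,
                reflux_range = c(0, 0), ...)
}

rtrunc_norm <- function(n, mean, sd, range) {
  if (sd <= 0) return(rep(pmin(pmax(mean, range[1]), range[2]), n))
  x <- rnorm(n, mean, sd)
  while (any(bad <- x < range[1] | x > range[2])) {
    x[bad] <- rnorm(sum(bad), mean, sd)
  }
  x
}

#' Generate a synthetic cohort of venous cine velocity maps
#'
#' Draws a seeded cohort under a [cohort_config()]: per subject a heart rate
#' and per-setpoint waveform parameters (log-normal between-subject flux
#' spread; reflux fraction in reflux limbs' GSV only), then the sampled flow
#' waveform with closed-form truth volumes and, when `render = TRUE`, the
#' noisy cine velocity maps and ROI masks. All randomness flows from the
#' single `seed`; identical `(config, seed)` yield identical cohorts.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @param render Render pixel-level cines (`TRUE`, default) or keep only
#'   waveforms and masks (`FALSE`; much faster, used for waveform-level
#'   simulation studies - no velocity noise enters downstream analyses).
#' @return A `vein_cohort` tibble with one row per subject-setpoint
#'   (`n_subjects * 4` rows): identifiers (`subject_id, group, limb,
#'   label, setpoint, heart_rate`), list-columns `waveform`, `cine`, `roi`,
#'   and ground-truth parameter columns `truth_sv, truth_ffv, truth_bfv,
#'   truth_rf, truth_asv, truth_mf, truth_sd, truth_mv, roi_area`. The
#'   config and seed are stored as attributes.
#' @examples
#' co <- generate_cohort(cohort_config(n_reflux = 2, n_control = 2,
#'                                     grid_shape = c(32, 32)), seed = 1)
#' nrow(co)  # 16: 4 subjects x 4 setpoints
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1L, render = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  n_sub <- config$n_reflux + config$n_control
  sp_names <- c("EIV", "FV", "PV", "GSV")

  draws <- withr::with_seed(seed, {
    hr <- rtrunc_norm(n_sub, config$heart_rate_mean, config$heart_rate_sd,
                      config$heart_rate_range)
    limb <- c(sample(c("left", "right"), config$n_reflux, replace = TRUE,
                     prob = c(18, 8) / 26),
              sample(c("left", "right"), config$n_control, replace = TRUE))
    rf <- c(rtrunc_norm(config$n_reflux, config$reflux_mean, config$reflux_sd,
                        config$reflux_range),
            rep(0, config$n_control))
    flux_mult <- matrix(rlnorm(n_sub * 4L, 0, config$flux_sdlog), n_sub, 4L,
                        dimnames = list(NULL, sp_names))
    noise_seeds <- matrix(sample.int(.Machine$integer.max - 1L, n_sub * 4L),
                          n_sub, 4L, dimnames = list(NULL, sp_names))
    list(hr = hr, limb = limb, rf = rf, flux_mult = flux_mult,
         noise_seeds = noise_seeds)
  })

  group <- rep(c("reflux_patient", "healthy_control"),
               c(config$n_reflux, config$n_control))
  subject_id <- c(sprintf("P%02d", seq_len(config$n_reflux)),
                  sprintf("C%02d", seq_len(config$n_control)))
  geoms <- lapply(config$setpoints, function(sp) {
    vessel_geometry(sp$lumen_radius, config$grid_shape, config$pixel_spacing)
  })
  masks <- lapply(geoms, lumen_mask)
  areas <- vapply(masks, roi_area, numeric(1))

  n_rows <- n_sub * 4L
  sub_i <- rep(seq_len(n_sub), each = 4L)
  sp_col <- rep(sp_names, n_sub)
  wf_col <- vector("list", n_rows)
  cine_col <- vector("list", n_rows)
  roi_col <- masks[sp_col]
  sv <- ffv <- bfv <- asv <- numeric(n_rows)
  for (idx in seq_len(n_rows)) {
    i <- sub_i[idx]
    sp <- sp_col[idx]
    base <- config$setpoints[[sp]]
    is_gsv_reflux <- sp == "GSV" && group[i] == "reflux_patient"
    m <- base$mean_flux * draws$flux_mult[i, sp] *
      if (is_gsv_reflux) config$gsv_flux_multiplier else 1
    a <- base$pulse_amplitude * m / base$mean_flux
    rf <- if (is_gsv_reflux) draws$rf[i] else 0
    wf <- generate_waveform(
      waveform_params(mean_flux = m, pulse_amplitude = a, reflux_fraction = rf,
                      pulse_start = config$pulse_start,
                      pulse_width = config$pulse_width,
                      reflux_start = config$reflux_start,
                      reflux_width = config$reflux_width),
      heart_rate = draws$hr[i], n_phases = config$n_phases)
    wf_col[[idx]] <- wf
    if (render) {
      cine_col[[idx]] <- render_velocity_cine(
        wf, geoms[[sp]], config$noise_sd, seed = draws$noise_seeds[i, sp])$cine
    }
    sv[idx] <- wf$truth$sv; ffv[idx] <- wf$truth$ffv
    bfv[idx] <- wf$truth$bfv; asv[idx] <- wf$truth$asv
  }
  hr_col <- draws$hr[sub_i]
  area_col <- unname(areas[sp_col])
  grp_col <- group[sub_i]
  out <- tibble(
    subject_id = subject_id[sub_i], group = grp_col,
    limb = draws$limb[sub_i],
    label = as.integer(grp_col == "reflux_patient"),
    setpoint = sp_col, heart_rate = hr_col,
    waveform = wf_col, cine = cine_col, roi = roi_col,
    truth_sv = sv, truth_ffv = ffv, truth_bfv = bfv,
    truth_rf = ifelse(ffv > 0, 100 * bfv / ffv, NA_real_),
    truth_asv = asv,
    truth_mf = sv * hr_col / 60,
    truth_sd = sv / area_col,
    truth_mv = sv / area_col * hr_col / 60,
    roi_area = area_col)
  structure(out, config = config, seed = seed, rendered = render,
            class = c("vein_cohort", class(out)))
}

#' Subject labels of a cohort
#'
#' @param cohort A `vein_cohort` tibble.
#' @return A tibble with one row per subject: `subject_id`, `group`,
#'   `label` (1 = reflux limb, 0 = healthy-control limb).
#' @export
cohort_labels <- function(cohort) {
  dplyr::distinct(as_tibble(cohort)[, c("subject_id", "group", "label")])
}

#' @export
print.vein_cohort <- function(x, ...) {
  lab <- cohort_labels(x)
  cat(sprintf("<vein_cohort> %d subjects (%d reflux, %d control), %d cines%s\n",
              nrow(lab), sum(lab$label == 1L), sum(lab$label == 0L), nrow(x),
              if (isTRUE(attr(x, "rendered"))) "" else " (waveforms only)"))
  NextMethod()
}
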