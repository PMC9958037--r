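#' Vessel cross-section geometry for cine rendering
#'
#' Describes the circular vessel lumen on the imaging grid used to rasterize
#' a flow waveform into a cine of through-plane velocity maps.
#'
#' @param lumen_radius Lumen radius in cm.
#' @param grid_shape Integer `(rows, cols)` of the imaging grid.
#' @param pixel_spacing Pixel edge length in cm (default 0.17, i.e. the
#'   1.7 mm in-plane voxel size typical of lower-extremity QFlow scans).
#' @param lumen_center Lumen center in pixel coordinates `(row, col)`;
#'   defaults to the grid center.
#' @return A list of class `vessel_geometry`.
#' @export
vessel_geometry <- function(lumen_radius, grid_shape = c(64L, 64L),
                            pixel_spacing = 0.17, lumen_center = NULL) {
  stopifnot(is.numeric(lumen_radius), length(lumen_radius) == 1L,
            is.finite(lumen_radius), lumen_radius > 0,
            length(grid_shape) == 2L, all(grid_shape >= 4),
            is.numeric(pixel_spacing), pixel_spacing > 0)
  grid_shape <- as.integer(grid_shape)
  if (is.null(lumen_center)) lumen_center <- (grid_shape + 1) / 2
  r_px <- lumen_radius / pixel_spacing
  if (lumen_center[1] - r_px < 0.5 || lumen_center[1] + r_px > grid_shape[1] + 0.5 ||
      lumen_center[2] - r_px < 0.5 || lumen_center[2] + r_px > grid_shape[2] + 0.5) {
    stop("lumen does not fit inside the imaging grid", call. = FALSE)
  }
  structure(list(lumen_radius = lumen_radius, grid_shape = grid_shape,
                 pixel_spacing = pixel_spacing, lumen_center = lumen_center),
            class = "vessel_geometry")
}

# Parabolic (Poiseuille) profile values at pixel centers; zero outside lumen.
lumen_profile <- function(geometry) {
  g <- geometry
  rows <- g$grid_shape[1]; cols <- g$grid_shape[2]
  y <- (seq_len(rows) - g$lumen_center[1]) * g$pixel_spacing
  x <- (seq_len(cols) - g$lumen_center[2]) * g$pixel_spacing
  r2 <- outer(y^2, x^2, `+`)
  pmax(1 - r2 / g$lumen_radius^2, 0)
}

#' Binary lumen mask for a vessel geometry
#'
#' @param geometry A [vessel_geometry()] object.
#' @return A logical matrix (`roi_mask`) marking in-lumen pixels, with the
#'   pixel spacing stored as an attribute.
#' @export
lumen_mask <- function(geometry) {
  m <- lumen_profile(geometry) > 0
  structure(m, pixel_spacing = geometry$pixel_spacing, class = c("roi_mask", "matrix"))
}

#' Area of an ROI mask in cm^2
#'
#' @param roi A logical ROI mask carrying a `pixel_spacing` attribute (cm).
#' @return ROI area: number of `TRUE` pixels times the pixel area.
#' @export
roi_area <- function(roi) {
  ps <- attr(roi, "pixel_spacing")
  if (is.null(ps)) stop("roi mask lacks a pixel_spacing attribute", call. = FALSE)
  sum(roi) * ps^2
}

#' Render a flow waveform into a cine of velocity maps
#'
#' Rasterizes a [generate_waveform()] result onto an imaging grid: each phase
#' gets a parabolic through-plane velocity profile inside the lumen, scaled so
#' that the in-lumen pixel flux (velocity times pixel area) sums exactly to
#' the waveform's flux at that phase, plus optional zero-mean Gaussian
#' velocity noise over the whole frame. Outside the lumen the mean velocity
#' is zero. The sign convention is toward-head positive throughout.
#'
#' @param waveform A `flow_waveform`.
#' @param geometry A [vessel_geometry()]; the lumen radius must be at least
#'   two pixel spacings so the profile is resolvable.
#' @param noise_sd Standard deviation of the additive velocity noise in cm/s.
#' @param seed Optional integer seed making the noise reproducible without
#'   disturbing the global RNG state.
#' @return A list with `cine` (a `velocity_cine`: numeric array
#'   `[phase, row, col]` in cm/s with phase times, R-R interval, pixel
#'   spacing and sign convention as attributes) and `roi` (the lumen mask).
#' @export
render_velocity_cine <- function(waveform, geometry, noise_sd = 1, seed = NULL) {
  stopifnot(inherits(waveform, "flow_waveform"), inherits(geometry, "vessel_geometry"))
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || !is.finite(noise_sd) ||
      noise_sd < 0) {
    stop("noise_sd must be a non-negative finite scalar", call. = FALSE)
  }
  if (geometry$lumen_radius < 2 * geometry$pixel_spacing) {
    stop("lumen radius below two pixel spacings: profile unresolvable", call. = FALSE)
  }
  prof <- lumen_profile(geometry)
  px_area <- geometry$pixel_spacing^2
  weights <- prof / (sum(prof) * px_area)  # 1/cm^2; flux * weights = velocity
  n <- waveform$n_phases
  dims <- c(n, geometry$grid_shape)
  cine <- outer(waveform$flux, weights)    # [phase, row, col]
  if (noise_sd > 0) {
    noise <- if (is.null(seed)) rnorm(prod(dims), sd = noise_sd) else
      withr::with_seed(seed, rnorm(prod(dims), sd = noise_sd))
    cine <- cine + array(noise, dims)
  }
  cine <- structure(cine,
                    phase_times = waveform$phase_times,
                    rr_interval = waveform$rr_interval,
                    pixel_spacing = geometry$pixel_spacing,
                    sign_convention = "toward_head_positive",
                    class = c("velocity_cine", "array"))
  list(cine = cine, roi = lumen_mask(geometry))
}

#' @export
print.velocity_cine <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<velocity_cine> %d phases, %dx%d grid, R-R %.3f s, pixel %.2f cm\n",
              d[1], d[2], d[3], attr(x, "rr_interval"), attr(x, "pixel_spacing")))
  invisible(x)
}
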