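#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_hline
#'   geom_jitter geom_tile geom_text labs theme_minimal scale_fill_gradient
#'   facet_wrap geom_raster scale_fill_viridis_c coord_equal
NULL

#' Plot a flow waveform
#'
#' Sampled phase fluxes (points) over the continuous parametric curve
#' (line), with the zero-flow line marking the antegrade/retrograde split.
#'
#' @param object A `flow_waveform`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.flow_waveform <- function(object, ...) {
  tt <- seq(0, object$rr_interval, length.out = 400)
  dense <- tibble(t = tt, flux = waveform_flux_at(object, tt %% object$rr_interval))
  pts <- tibble(t = object$phase_times, flux = object$flux)
  ggplot(dense, aes(x = .data$t, y = .data$flux)) +
    geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    geom_line(colour = "steelblue") +
    geom_point(data = pts, size = 1.4) +
    labs(x = "time within R-R interval (s)", y = "ROI flux (mL/s)",
         title = "Venous flux waveform (toward-head positive)") +
    theme_minimal()
}

#' Plot RBFNN training outputs by class
#'
#' Network outputs for every training subject, jittered by true class, with
#' the decision threshold drawn as a horizontal line - the usual
#' correspondence plot of a training-stage classification report.
#'
#' @param object A fitted `rbfnn`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rbfnn <- function(object, ...) {
  df <- tibble(
    class = factor(ifelse(object$training$labels == 1, "reflux limb",
                          "control limb"),
                   levels = c("control limb", "reflux limb")),
    score = object$training$scores)
  ggplot(df, aes(x = .data$class, y = .data$score, colour = .data$class)) +
    geom_jitter(width = 0.12, height = 0, size = 2, show.legend = FALSE) +
    geom_hline(yintercept = object$threshold, linetype = 2) +
    labs(x = NULL, y = "network output",
         title = sprintf("RBFNN outputs (threshold %.2f)", object$threshold)) +
    theme_minimal()
}

#' Plot the per-segment group comparison
#'
#' Significance map of the 24 segment-by-parameter Student's t tests:
#' tiles shaded by -log10(p) and labelled with the significance tier.
#'
#' @param object A [compare_segments()] table.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.segment_comparison <- function(object, ...) {
  df <- dplyr::mutate(as_tibble(object),
                      neglogp = -log10(pmax(.data$p_value, 1e-16)),
                      parameter = toupper(.data$parameter),
                      segment = factor(.data$segment,
                                       levels = c("EIV", "FV", "PV", "GSV")))
  ggplot(df, aes(x = .data$segment, y = .data$parameter,
                 fill = .data$neglogp)) +
    geom_tile(colour = "white") +
    geom_text(aes(label = .data$tier), size = 3.4) +
    scale_fill_gradient(low = "grey95", high = "firebrick",
                        name = expression(-log[10](p))) +
    labs(x = "venous segment", y = "QFlow parameter",
         title = "Reflux vs control limbs, unpaired Student's t (raw p)") +
    theme_minimal()
}

#' Display one phase of a cine velocity map
#'
#' @param cine A `velocity_cine`.
#' @param phase Phase index to display (default 1).
#' @param roi Optional ROI mask; its outline pixels are overdrawn.
#' @return A ggplot object.
#' @export
plot_cine_frame <- function(cine, phase = 1L, roi = NULL) {
  fr <- unclass(cine)[phase, , ]
  df <- tibble(row = as.vector(row(fr)), col = as.vector(col(fr)),
               v = as.vector(fr))
  p <- ggplot(df, aes(x = .data$col, y = .data$row, fill = .data$v)) +
    geom_raster() +
    scale_fill_viridis_c(name = "v (cm/s)") +
    coord_equal() +
    labs(title = sprintf("velocity map, phase %d / %d", phase, dim(cine)[1]),
         x = NULL, y = NULL) +
    theme_minimal()
  if (!is.null(roi)) {
    edge <- which(roi & !erode_mask(roi), arr.ind = TRUE)
    p <- p + geom_point(data = tibble(row = edge[, 1], col = edge[, 2]),
                        aes(x = .data$col, y = .data$row),
                        inherit.aes = FALSE, size = 0.3, colour = "white")
  }
  p
}

erode_mask <- function(m) {
  n <- matrix(FALSE, nrow(m), ncol(m))
  inner <- 2:(nrow(m) - 1)
  innc <- 2:(ncol(m) - 1)
  n[inner, innc] <- m[inner - 1, innc] & m[inner + 1, innc] &
    m[inner, innc - 1] & m[inner, innc + 1] & m[inner, innc]
  n
}
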