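#' Assemble the six-feature classifier input per subject
#'
#' Builds, for every subject, the six QFlow-derived classifier inputs:
#' GSV stroke volume, forward flow volume, absolute stroke volume and mean
#' flux, plus the GSV/PV ratios of stroke distance and of mean flux (or of
#' mean velocity, see `ratio`). The desired output `label` is 1 for reflux
#' limbs and 0 for healthy-control limbs.
#'
#' Subjects lacking a GSV or PV row, with a zero PV denominator, or with a
#' non-finite feature are excluded with a logged reason (see the
#' `excluded` attribute of the result).
#'
#' @param qflow A [batch_qflow()] table (one row per subject-setpoint).
#' @param labels A tibble with `subject_id` and binary `label`; defaults to
#'   the labels already present in `qflow`.
#' @param ratio Second GSV/PV ratio: `"mf"` (mean flux, default) or `"mv"`
#'   (mean velocity).
#' @return A tibble with `subject_id`, the six feature columns (fixed order:
#'   `sv_gsv, ffv_gsv, asv_gsv, mf_gsv, sd_gsv_pv`, then `mf_gsv_pv` or
#'   `mv_gsv_pv`) and `label`. Feature names are recorded in the
#'   `feature_names` attribute, exclusions in `excluded`.
#' @export
build_features <- function(qflow, labels = NULL, ratio = c("mf", "mv")) {
  ratio <- match.arg(ratio)
  stopifnot(is.data.frame(qflow))
  if (is.null(labels)) {
    if (!"label" %in% names(qflow)) {
      stop("no labels supplied and no label column in qflow", call. = FALSE)
    }
    labels <- dplyr::distinct(as_tibble(qflow)[, c("subject_id", "label")])
  }
  stopifnot(all(c("subject_id", "label") %in% names(labels)),
            all(labels$label %in% c(0L, 1L)))

  den_col <- ratio                      # "mf" or "mv"
  ratio_name <- paste0(ratio, "_gsv_pv")
  feature_names <- c("sv_gsv", "ffv_gsv", "asv_gsv", "mf_gsv",
                     "sd_gsv_pv", ratio_name)

  excluded <- list()
  rows <- lapply(unique(labels$subject_id), function(id) {
    g <- qflow[qflow$subject_id == id & qflow$setpoint == "GSV", , drop = FALSE]
    p <- qflow[qflow$subject_id == id & qflow$setpoint == "PV", , drop = FALSE]
    if (nrow(g) != 1L || nrow(p) != 1L) {
      excluded[[id]] <<- "missing GSV or PV setpoint"
      return(NULL)
    }
    if (p$sd == 0 || p[[den_col]] == 0) {
      excluded[[id]] <<- "zero PV denominator"
      return(NULL)
    }
    x <- c(g$sv, g$ffv, g$asv, g$mf, g$sd / p$sd, g[[den_col]] / p[[den_col]])
    if (!all(is.finite(x))) {
      excluded[[id]] <<- "non-finite feature"
      return(NULL)
    }
    tibble(subject_id = id, !!!setNames(as.list(x), feature_names))
  })
  out <- dplyr::bind_rows(rows)
  if (length(excluded) > 0) {
    message(length(excluded), " subject(s) excluded from the feature table: ",
            paste(names(excluded), unlist(excluded), sep = ": ", collapse = "; "))
  }
  out <- dplyr::left_join(out, as_tibble(labels)[, c("subject_id", "label")],
                          by = "subject_id")
  excl_tbl <- if (length(excluded) > 0) {
    tibble(subject_id = names(excluded), reason = unlist(excluded))
  } else {
    tibble(subject_id = character(), reason = character())
  }
  structure(out, feature_names = feature_names, excluded = excl_tbl)
}

feature_matrix <- function(features, feature_names = NULL) {
  feature_names <- feature_names %||% attr(features, "feature_names") %||%
    setdiff(names(features), c("subject_id", "label"))
  missing <- setdiff(feature_names, names(features))
  if (length(missing) > 0) {
    stop("feature columns absent: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  as.matrix(features[, feature_names, drop = FALSE])
}

#' Fit a feature standardizer (center and scale per component)
#'
#' Learns per-feature mean and population standard deviation (1/n
#' denominator) from a training feature table, so that the transformed
#' training set has componentwise mean 0 and unit dispersion - and hence a
#' shared RBF width [rbf_sigma()] of exactly 1. Standardization matters
#' because the six features mix mL, mL/s and unitless ratios inside one
#' Euclidean distance in the RBF layer.
#'
#' @param features A [build_features()] table (or any tibble of numeric
#'   feature columns; `subject_id`/`label` are ignored).
#' @return A `standardizer` object holding `center`, `scale` and the
#'   feature names.
#' @export
fit_standardizer <- function(features) {
  X <- feature_matrix(features)
  if (nrow(X) < 2L) stop("need at least 2 feature vectors", call. = FALSE)
  center <- colMeans(X)
  scale_ <- sqrt(colMeans(sweep(X, 2, center)^2))
  if (any(scale_ == 0)) {
    stop("zero-dispersion feature component(s): ",
         paste(colnames(X)[scale_ == 0], collapse = ", "), call. = FALSE)
  }
  structure(list(center = center, scale = scale_, feature_names = colnames(X)),
            class = "standardizer")
}

#' Apply or invert a standardizer
#'
#' The transform is affine and invertible:
#' `apply_standardizer(invert_standardizer(x, s), s)` is the identity.
#'
#' @param features A feature table containing the standardizer's columns.
#' @param standardizer A [fit_standardizer()] object.
#' @return The table with the feature columns transformed in place.
#' @export
apply_standardizer <- function(features, standardizer) {
  stopifnot(inherits(standardizer, "standardizer"))
  out <- features
  for (nm in standardizer$feature_names) {
    out[[nm]] <- (features[[nm]] - standardizer$center[[nm]]) /
      standardizer$scale[[nm]]
  }
  out
}

#' @rdname apply_standardizer
#' @export
invert_standardizer <- function(features, standardizer) {
  stopifnot(inherits(standardizer, "standardizer"))
  out <- features
  for (nm in standardizer$feature_names) {
    out[[nm]] <- features[[nm]] * standardizer$scale[[nm]] +
      standardizer$center[[nm]]
  }
  out
}
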