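#' Write a rendered cohort to disk
#'
#' Writes each subject-setpoint cine and ROI mask as NIfTI volumes
#' (`row x col x phase`), a JSON sidecar per cine (R-R interval, phase
#' times, pixel spacing, heart rate, sign convention), a cohort manifest
#' CSV, and a YAML snapshot of the generator configuration and seed.
#'
#' @param cohort A rendered `vein_cohort`.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "vein_cohort"))
  if (!isTRUE(attr(cohort, "rendered"))) {
    stop("cohort was generated with render = FALSE; no cines to write",
         call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    cine <- cohort$cine[[i]]
    stem <- sprintf("%s_%s", cohort$subject_id[i], cohort$setpoint[i])
    cine_path <- file.path(dir, paste0(stem, "_cine.nii"))
    mask_path <- file.path(dir, paste0(stem, "_mask.nii"))
    sidecar_path <- file.path(dir, paste0(stem, ".json"))
    ps <- attr(cine, "pixel_spacing")
    img <- RNifti::asNifti(aperm(unclass(cine), c(2, 3, 1)),
                           pixdim = c(ps, ps, attr(cine, "rr_interval") / dim(cine)[1]))
    RNifti::writeNifti(img, cine_path)
    RNifti::writeNifti(RNifti::asNifti(array(as.integer(cohort$roi[[i]]),
                                             dim = dim(cohort$roi[[i]])),
                                       pixdim = c(ps, ps)),
                       mask_path)
    jsonlite::write_json(list(rr_interval = attr(cine, "rr_interval"),
                              phase_times = attr(cine, "phase_times"),
                              pixel_spacing_cm = ps,
                              heart_rate = cohort$heart_rate[i],
                              sign_convention = attr(cine, "sign_convention")),
                         sidecar_path, auto_unbox = TRUE, digits = NA)
    rows[[i]] <- tibble(subject_id = cohort$subject_id[i],
                        group = cohort$group[i], limb = cohort$limb[i],
                        label = cohort$label[i], setpoint = cohort$setpoint[i],
                        cine_path = basename(cine_path),
                        mask_path = basename(mask_path),
                        sidecar_path = basename(sidecar_path))
  }
  manifest <- dplyr::bind_rows(rows)
  manifest_path <- file.path(dir, "manifest.csv")
  readr::write_csv(manifest, manifest_path)
  cfg <- attr(cohort, "config")
  yaml::write_yaml(list(seed = attr(cohort, "seed"),
                        config = unclass(cfg)),
                   file.path(dir, "config.yaml"))
  invisible(manifest_path)
}

#' Read a cohort from a manifest
#'
#' Loads the cines and masks listed in a [write_cohort()] manifest. A
#' missing or unreadable file is reported with a warning, the row skipped,
#' and the failure recorded in the `failures` attribute; the run continues.
#'
#' @param manifest Path to `manifest.csv`, or to the directory holding it.
#' @return A `vein_cohort`-style tibble with list-columns `cine` and `roi`
#'   (no ground truth: truth exists only generator-side).
#' @export
read_cohort <- function(manifest) {
  if (dir.exists(manifest)) manifest <- file.path(manifest, "manifest.csv")
  man <- readr::read_csv(manifest, show_col_types = FALSE)
  dir <- dirname(manifest)
  failures <- list()
  rows <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    paths <- file.path(dir, c(man$cine_path[i], man$mask_path[i], man$sidecar_path[i]))
    if (!all(file.exists(paths))) {
      warning(sprintf("%s %s: file missing, row skipped",
                      man$subject_id[i], man$setpoint[i]), call. = FALSE)
      failures[[length(failures) + 1L]] <-
        tibble(subject_id = man$subject_id[i], setpoint = man$setpoint[i],
               reason = "file missing")
      next
    }
    side <- jsonlite::read_json(paths[3], simplifyVector = TRUE)
    vol <- RNifti::readNifti(paths[1])
    cine <- structure(aperm(as.array(vol), c(3, 1, 2)),
                      phase_times = side$phase_times,
                      rr_interval = side$rr_interval,
                      pixel_spacing = side$pixel_spacing_cm,
                      sign_convention = side$sign_convention,
                      class = c("velocity_cine", "array"))
    mask <- structure(as.array(RNifti::readNifti(paths[2])) > 0,
                      pixel_spacing = side$pixel_spacing_cm,
                      class = c("roi_mask", "matrix"))
    rows[[i]] <- tibble(subject_id = man$subject_id[i], group = man$group[i],
                        limb = man$limb[i], label = man$label[i],
                        setpoint = man$setpoint[i],
                        heart_rate = side$heart_rate,
                        cine = list(cine), roi = list(mask))
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "failures") <- if (length(failures) > 0) dplyr::bind_rows(failures) else
    tibble(subject_id = character(), setpoint = character(), reason = character())
  attr(out, "rendered") <- TRUE
  class(out) <- c("vein_cohort", class(out))
  out
}

#' Serialize a fitted RBF network to JSON
#'
#' @param model An `rbfnn` model.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_rbfnn <- function(model, path) {
  stopifnot(inherits(model, "rbfnn"))
  obj <- list(
    centers = unname(apply(model$centers, 1, as.numeric, simplify = FALSE)),
    sigma = model$sigma, weights = as.numeric(model$weights),
    threshold = model$threshold, threshold_policy = model$threshold_policy,
    feature_names = model$feature_names, k = model$k,
    eta = model$eta, epochs = model$epochs, seed = model$seed,
    standardizer = if (!is.null(model$standardizer)) list(
      center = as.numeric(model$standardizer$center),
      scale = as.numeric(model$standardizer$scale),
      feature_names = model$standardizer$feature_names),
    training = list(f_measure = model$training$f_measure))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a fitted RBF network from JSON
#'
#' @param path A [write_rbfnn()] file.
#' @return An `rbfnn` model usable with [predict.rbfnn()].
#' @export
read_rbfnn <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  centers <- do.call(rbind, if (is.list(obj$centers)) obj$centers else
    list(obj$centers))
  if (is.matrix(obj$centers)) centers <- obj$centers
  colnames(centers) <- obj$feature_names
  std <- NULL
  if (!is.null(obj$standardizer)) {
    std <- structure(list(
      center = setNames(obj$standardizer$center, obj$standardizer$feature_names),
      scale = setNames(obj$standardizer$scale, obj$standardizer$feature_names),
      feature_names = obj$standardizer$feature_names), class = "standardizer")
  }
  structure(list(centers = centers, sigma = obj$sigma, weights = obj$weights,
                 threshold = obj$threshold, threshold_policy = obj$threshold_policy,
                 standardizer = std, feature_names = obj$feature_names,
                 k = obj$k, eta = obj$eta, epochs = obj$epochs, seed = obj$seed,
                 training = list(f_measure = obj$training$f_measure)),
            class = "rbfnn")
}
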