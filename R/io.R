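## File interchange: NIfTI series with a JSON timing sidecar, integer-label
## ROI masks, TIC and cohort CSV tables, YAML simulation configs, and JSON
## serialization of fitted ComBat models.

#' Write / read a dynamic series as NIfTI plus timing sidecar
#'
#' The pixel array goes to `<prefix>.nii.gz`; the per-frame timestamps,
#' injection offset and pixel spacing go to a `<prefix>.json` sidecar.
#'
#' @param series a [dce_series()].
#' @param prefix file path without extension.
#' @return `write_dce_series` returns the prefix invisibly;
#'   `read_dce_series` returns a [dce_series()].
#' @export
write_dce_series <- function(series, prefix) {
  stopifnot(inherits(series, "dce_series"))
  RNifti::writeNifti(series$pixels, paste0(prefix, ".nii.gz"))
  jsonlite::write_json(
    list(times_s = series$times,
         injection_offset_s = series$injection_offset,
         pixel_spacing_mm = series$pixel_spacing),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(prefix)
}

#' @rdname write_dce_series
#' @export
read_dce_series <- function(prefix) {
  img <- RNifti::readNifti(paste0(prefix, ".nii.gz"))
  pixels <- array(as.numeric(img), dim = dim(img))
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  dce_series(pixels, side$times_s, side$injection_offset_s,
             side$pixel_spacing_mm)
}

#' Write / read ROI masks as one integer-labeled NIfTI volume
#'
#' Masks are burned into a single volume (later masks overwrite earlier
#' ones where they overlap); the label-name mapping goes to a JSON sidecar.
#'
#' @param masks named list of logical matrices.
#' @param prefix file path without extension.
#' @export
write_roi_masks <- function(masks, prefix) {
  lab <- matrix(0L, nrow(masks[[1]]), ncol(masks[[1]]))
  for (i in seq_along(masks)) lab[masks[[i]]] <- i
  RNifti::writeNifti(lab, paste0(prefix, ".nii.gz"))
  jsonlite::write_json(as.list(stats::setNames(seq_along(masks), names(masks))),
                       paste0(prefix, ".json"), auto_unbox = TRUE)
  invisible(prefix)
}

#' @rdname write_roi_masks
#' @export
read_roi_masks <- function(prefix) {
  img <- RNifti::readNifti(paste0(prefix, ".nii.gz"))
  lab <- array(as.integer(img), dim = dim(img)[1:2])
  key <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  out <- lapply(key, function(i) lab == i)
  names(out) <- names(key)
  out
}

#' Write a time-intensity curve as CSV
#'
#' Columns `time_s` and `si`, one row per frame.
#'
#' @param tic a [new_tic()].
#' @param path output CSV path.
#' @export
write_tic_csv <- function(tic, path) {
  utils::write.csv(as.data.frame(tic), path, row.names = FALSE)
  invisible(path)
}

#' Write / read a cohort feature table as CSV
#'
#' List columns (synthesized curves) are dropped on write; the feature
#' table round-trips exactly.
#'
#' @param records cohort data.frame.
#' @param path CSV path.
#' @export
write_cohort_csv <- function(records, path) {
  keep <- !vapply(records, is.list, logical(1))
  utils::write.csv(records[, keep, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read a cohort simulation config from YAML
#'
#' Keys mirror the arguments of [cohort_config()].
#'
#' @param path YAML file.
#' @return a [cohort_config()].
#' @export
read_cohort_config <- function(path) {
  do.call(cohort_config, yaml::read_yaml(path))
}

#' Serialize / restore a fitted ComBat model as JSON
#'
#' @param model a [fit_combat()] model.
#' @param path JSON path.
#' @export
write_combat_model <- function(model, path) {
  stopifnot(inherits(model, "combat_model"))
  payload <- model
  payload$B <- list(values = as.vector(model$B), dim = dim(model$B),
                    rownames = rownames(model$B))
  for (nm in c("gamma_star", "delta_star")) {
    payload[[nm]] <- list(values = as.vector(model[[nm]]),
                          dim = dim(model[[nm]]),
                          rownames = rownames(model[[nm]]))
  }
  jsonlite::write_json(unclass(payload), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_combat_model
#' @export
read_combat_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  rebuild <- function(m, cols) {
    out <- matrix(m$values, nrow = m$dim[1], ncol = m$dim[2])
    rownames(out) <- m$rownames
    colnames(out) <- cols
    out
  }
  p$B <- rebuild(p$B, p$features)
  p$gamma_star <- rebuild(p$gamma_star, p$features)
  p$delta_star <- rebuild(p$delta_star, p$features)
  p$var_pooled <- stats::setNames(unlist(p$var_pooled), p$features)
  class(p) <- "combat_model"
  p
}
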