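#' Read and write dynamic series as NIfTI + JSON sidecar
#'
#' A dynamic series is stored as a 4D NIfTI-1 volume plus a JSON sidecar
#' holding the frame timing: `{"frame_start_s": [...], "frame_duration_s":
#' [...]}`. The round trip is lossless for voxels, spacing and schedule.
#'
#' @param series a [dynamic_series].
#' @param path_nifti path to the `.nii`/`.nii.gz` file.
#' @param path_json path to the JSON sidecar.
#' @return `write_series` returns the paths invisibly; `read_series` returns
#'   a [dynamic_series].
#' @export
write_series <- function(series, path_nifti, path_json) {
  stopifnot(inherits(series, "dynamic_series"))
  img <- RNifti::asNifti(series$voxels)
  RNifti::pixdim(img) <- c(series$spacing_mm, 1)
  RNifti::writeNifti(img, path_nifti)
  jsonlite::write_json(list(frame_start_s = series$schedule$start_s,
                            frame_duration_s = series$schedule$duration_s),
                       path_json, digits = NA)
  invisible(c(path_nifti, path_json))
}

#' @rdname write_series
#' @export
read_series <- function(path_nifti, path_json) {
  img <- RNifti::readNifti(path_nifti)
  arr <- as.array(img)
  stop_if(length(dim(arr)) != 4L, "NIfTI at ", path_nifti, " is not 4D")
  stop_if(!file.exists(path_json), "missing JSON sidecar: ", path_json)
  side <- jsonlite::read_json(path_json, simplifyVector = TRUE)
  for (f in c("frame_start_s", "frame_duration_s")) {
    stop_if(is.null(side[[f]]), "sidecar missing field '", f, "'")
  }
  stop_if(length(side$frame_start_s) != length(side$frame_duration_s),
          "sidecar fields 'frame_start_s' and 'frame_duration_s' differ in length")
  sch <- frame_schedule(side$frame_start_s, side$frame_duration_s)
  spacing <- RNifti::pixdim(img)[1:3]
  dynamic_series(arr, spacing, sch)
}

#' Read and write label masks as NIfTI
#'
#' @param labels integer 3D array (region or segment labels).
#' @param spacing_mm voxel spacing.
#' @param path NIfTI path.
#' @return `read_labels` returns a list with `labels` and `spacing_mm`.
#' @export
write_labels <- function(labels, spacing_mm, path) {
  img <- RNifti::asNifti(labels)
  RNifti::pixdim(img) <- spacing_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  img <- RNifti::readNifti(path)
  list(labels = array(as.integer(round(as.array(img))), dim = dim(img)),
       spacing_mm = RNifti::pixdim(img)[1:3])
}

#' Read and write motion traces as CSV
#'
#' Schema: `frame` (contiguous from 0), `tx_mm`, `ty_mm`, `tz_mm`.
#'
#' @param trace a [motion_trace].
#' @param path CSV path.
#' @return `read_trace` returns a [motion_trace].
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "motion_trace"))
  df <- data.frame(frame = seq_len(nrow(trace)) - 1L,
                   tx_mm = trace[, 1], ty_mm = trace[, 2], tz_mm = trace[, 3])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path)
  need <- c("frame", "tx_mm", "ty_mm", "tz_mm")
  miss <- setdiff(need, names(df))
  stop_if(length(miss) > 0, "trace file missing column(s): ",
          paste(miss, collapse = ", "))
  stop_if(anyDuplicated(df$frame) > 0, "duplicate frame rows in ", path)
  if (nrow(df) > 0) {
    df <- df[order(df$frame), ]
    stop_if(!identical(as.integer(df$frame), seq_len(nrow(df)) - 1L),
            "frame indices must be contiguous from 0")
  }
  m <- as.matrix(df[, c("tx_mm", "ty_mm", "tz_mm")])
  dimnames(m) <- NULL
  motion_trace(m)
}

#' Read and write operator correction tables as CSV
#'
#' Schema: `case_id, site_id, phase, frame, operator, tx_mm, ty_mm, tz_mm`.
#'
#' @param table a [correction_table].
#' @param path CSV path.
#' @return `read_correction_table` returns a [correction_table].
#' @export
write_correction_table <- function(table, path) {
  stopifnot(inherits(table, "correction_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_correction_table
#' @export
read_correction_table <- function(path) {
  correction_table(utils::read.csv(path))
}

#' Read a pipeline/phantom configuration from YAML
#'
#' @param path YAML file.
#' @return named list.
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}
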