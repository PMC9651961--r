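# Readers for the on-disk interchange formats (NIfTI-1 volumes, BIDS-style
# TSV events and motion tables, JSON axis metadata).

#' Read a 4D BOLD run from NIfTI-1
#'
#' @param path `.nii` or `.nii.gz` file with 4 dimensions.
#' @param tr_seconds repetition time; defaults to the 4th pixdim entry of
#'   the header when positive.
#' @return a [bold_run()].
#' @export
read_bold_run <- function(path, tr_seconds = NULL) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 4L)
    eh_stop("expected a 4D NIfTI volume", "ehconn_invalid_input")
  if (is.null(tr_seconds)) {
    pd <- attr(img, "pixdim")
    tr_seconds <- if (!is.null(pd) && length(pd) >= 4 && pd[4] > 0) pd[4]
                  else eh_stop("TR not in header; pass tr_seconds",
                               "ehconn_invalid_input")
  }
  bold_run(array(as.numeric(img), dim = dim(img)), tr_seconds)
}

#' Read an integer ROI label map with its axis metadata
#'
#' @param path NIfTI-1 label volume.
#' @param meta_path JSON sidecar with `legend`, `coronal_axis`,
#'   `mediolateral_axis`, `proximal_direction`; optional (defaults match
#'   the phantom conventions).
#' @return list shaped like [build_phantom_anatomy()] output (without the
#'   ground-truth fields).
#' @export
read_label_map <- function(path, meta_path = NULL) {
  img <- RNifti::readNifti(path)
  labels <- array(as.integer(round(as.numeric(img))), dim = dim(img))
  meta <- if (!is.null(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = TRUE) else list()
  list(labels = labels,
       legend = unlist(meta$legend %||% as.list(ROI_LEGEND)),
       coronal_axis = meta$coronal_axis %||% 2L,
       mediolateral_axis = meta$mediolateral_axis %||% 1L,
       proximal_direction = meta$proximal_direction %||% "+x")
}

#' Read a BIDS-style event table
#'
#' Accepts `trial_type` or `condition` as the condition column.
#'
#' @param path TSV with `onset`, `duration` and a condition column.
#' @return data.frame with `onset`, `duration`, `condition`.
#' @export
read_events <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  cond_col <- intersect(c("trial_type", "condition"), names(df))
  if (!all(c("onset", "duration") %in% names(df)) || !length(cond_col))
    eh_stop("events TSV needs onset, duration and trial_type/condition",
            "ehconn_invalid_input")
  data.frame(onset = df$onset, duration = df$duration,
             condition = df[[cond_col[1]]], stringsAsFactors = FALSE)
}

#' Read a 6-column motion-parameter table
#'
#' @param path TSV with six numeric columns (translations first).
#' @return T x 6 numeric matrix.
#' @export
read_motion <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) != 6L)
    eh_stop("motion TSV must have exactly 6 columns", "ehconn_invalid_input")
  as.matrix(df)
}

#' Write a 3D map as NIfTI-1
#'
#' @param map 3D numeric array.
#' @param path output `.nii` or `.nii.gz` path.
#' @param voxel_size_mm isotropic voxel size stored in the header.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path, voxel_size_mm = 1) {
  img <- RNifti::asNifti(map)
  RNifti::pixdim(img) <- rep(voxel_size_mm, length(dim(map)))
  RNifti::writeNifti(img, path)
  invisible(path)
}
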