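# Transversal segmentation of subiculum (five equal-width bins from the
# proximal to the distal end) and CA1 (three 60-degree sectors around the
# chord connecting the outer borders), per coronal slice, plus extraction
# of per-segment mean estimates averaged along the longitudinal axis.

#' Equal-width transversal bins for one subiculum slice
#'
#' Bins the medial-lateral coordinates of one coronal slice into
#' `n_segments` equal-width intervals:
#' `label = 1 + floor(n * (x - min) / (max - min + 1))`,
#' then orients the labels so that label 1 sits at the proximal end.
#'
#' @param coords_ml numeric vector of medial-lateral voxel coordinates.
#' @param n_segments number of bins (default 5).
#' @param proximal_at `"high"` if the proximal end (adjacent to CA1) lies
#'   at the larger coordinate values, `"low"` otherwise.
#' @return integer vector of segment labels (1 = proximal).
#' @export
segment_subiculum_slice <- function(coords_ml, n_segments = 5L,
                                    proximal_at = c("high", "low")) {
  proximal_at <- match.arg(proximal_at)
  if (length(unique(coords_ml)) < n_segments)
    eh_stop(sprintf("slice has %d distinct coordinates, fewer than %d segments",
                    length(unique(coords_ml)), n_segments),
            "ehconn_slice_error")
  lo <- min(coords_ml)
  hi <- max(coords_ml)
  lab <- 1L + as.integer(floor(n_segments * (coords_ml - lo) / (hi - lo + 1)))
  if (proximal_at == "high") lab <- n_segments + 1L - lab
  lab
}

#' 60-degree sector segmentation for one CA1 slice
#'
#' Implements the geometric rule for the curved CA1 sheet: (1) the two
#' outer borders are the voxel pair at maximum in-plane distance
#' (lexicographic tie-break); (2) they are connected by a chord with
#' midpoint m; (3) each voxel's angle in [0, 180] degrees is measured at m
#' from the direction of the proximal endpoint (the fold onto the
#' half-plane containing the mask is implicit in using the unsigned
#' angle); (4) sectors of `angle_deg` degrees give labels 1 (proximal,
#' angles `[0, 60)`), 2 (`[60, 120)`) and 3 (`[120, 180]`).
#'
#' @param coords two-column matrix of in-plane voxel coordinates; the
#'   first column is the medial-lateral coordinate.
#' @param angle_deg sector width in degrees (default 60).
#' @param proximal_at `"high"` if the proximal chord endpoint has the
#'   larger first coordinate.
#' @return integer vector of sector labels (1 = proximal).
#' @export
segment_ca1_slice <- function(coords, angle_deg = 60,
                              proximal_at = c("high", "low")) {
  proximal_at <- match.arg(proximal_at)
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 3L)
    eh_stop("CA1 slice needs at least 3 voxels", "ehconn_slice_error")
  d2 <- as.matrix(stats::dist(coords))^2
  best <- which(d2 == max(d2), arr.ind = TRUE)
  best <- best[best[, 1] < best[, 2], , drop = FALSE]
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
  e1 <- coords[best[1], ]
  e2 <- coords[best[2], ]
  if (all(e1 == e2))
    eh_stop("degenerate CA1 slice: zero in-plane extent", "ehconn_slice_error")
  # proximal endpoint per axis metadata
  if ((proximal_at == "high") != (e1[1] >= e2[1])) { tmp <- e1; e1 <- e2; e2 <- tmp }
  m <- (e1 + e2) / 2
  d_prox <- e1 - m
  w <- sweep(coords, 2L, m)
  nw <- sqrt(rowSums(w^2))
  if (all(nw < 1e-12))
    eh_stop("degenerate CA1 slice: all voxels at chord midpoint",
            "ehconn_slice_error")
  cosang <- as.vector(w %*% d_prox) / (nw * sqrt(sum(d_prox^2)))
  theta <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  theta[nw < 1e-12] <- 90  # midpoint voxel: middle sector
  n_seg <- as.integer(round(180 / angle_deg))
  lab <- pmin(1L + as.integer(floor(theta / angle_deg)), n_seg)
  lab
}

#' Transversal segmentation of a labelled ROI
#'
#' Applies [segment_subiculum_slice()] (rule `"bins"`) or
#' [segment_ca1_slice()] (rule `"sectors"`) to every coronal slice of the
#' ROI. Slices that cannot be segmented are skipped with a warning.
#'
#' @param anatomy label-map list with `labels`, `coronal_axis`,
#'   `mediolateral_axis`, `proximal_direction` (see
#'   [build_phantom_anatomy()]).
#' @param roi_label integer ROI code to segment.
#' @param rule `"bins"` or `"sectors"`.
#' @param n_segments number of bins for `"bins"` (default 5).
#' @param angle_deg sector width for `"sectors"` (default 60).
#' @return object of class `transversal_segmentation`: `segment` (3D
#'   integer array, 0 outside the ROI), `slice` (3D integer array of
#'   coronal slice indices), `n_segments`, `roi_label`.
#' @export
segment_roi <- function(anatomy, roi_label, rule = c("bins", "sectors"),
                        n_segments = 5L, angle_deg = 60) {
  rule <- match.arg(rule)
  labels <- anatomy$labels
  cor_ax <- anatomy$coronal_axis
  ml_ax <- anatomy$mediolateral_axis
  prox <- if (identical(anatomy$proximal_direction, "+x")) "high" else "low"
  in_plane <- setdiff(1:3, cor_ax)
  # put medial-lateral first among the in-plane axes
  in_plane <- c(ml_ax, setdiff(in_plane, ml_ax))
  seg <- array(0L, dim = dim(labels))
  slc <- array(0L, dim = dim(labels))
  vox <- which(labels == roi_label, arr.ind = TRUE)
  if (nrow(vox) == 0L)
    eh_stop("ROI label not present in label map", "ehconn_invalid_input")
  n_seg_out <- if (rule == "bins") n_segments
               else as.integer(round(180 / angle_deg))
  for (s in sort(unique(vox[, cor_ax]))) {
    rows <- vox[vox[, cor_ax] == s, , drop = FALSE]
    lab <- tryCatch({
      if (rule == "bins")
        segment_subiculum_slice(rows[, in_plane[1]], n_segments,
                                proximal_at = prox)
      else
        segment_ca1_slice(rows[, in_plane, drop = FALSE], angle_deg,
                          proximal_at = prox)
    }, ehconn_slice_error = function(e) {
      warning(sprintf("coronal slice %d skipped: %s", s, conditionMessage(e)))
      NULL
    })
    if (is.null(lab)) next
    idx <- rows[, 1] + (rows[, 2] - 1L) * dim(labels)[1] +
      (rows[, 3] - 1L) * dim(labels)[1] * dim(labels)[2]
    seg[idx] <- lab
    slc[idx] <- s
  }
  structure(list(segment = seg, slice = slc, n_segments = n_seg_out,
                 roi_label = roi_label),
            class = "transversal_segmentation")
}

#' Per-segment profile of a 3D map
#'
#' For each coronal slice, averages the map over each segment's voxels;
#' the per-slice segment means are then averaged (unweighted) across
#' slices.
#'
#' @param map 3D numeric array on the segmentation grid.
#' @param segmentation a [segment_roi()] result.
#' @return numeric vector of length `n_segments` (proximal to distal).
#' @export
extract_segment_profile <- function(map, segmentation) {
  if (!all(dim(map) == dim(segmentation$segment)))
    eh_stop("map grid does not match segmentation grid",
            "ehconn_invalid_input")
  in_seg <- segmentation$segment > 0L
  df <- data.frame(v = map[in_seg],
                   seg = segmentation$segment[in_seg],
                   slice = segmentation$slice[in_seg])
  per_slice <- stats::aggregate(v ~ seg + slice, data = df, FUN = mean)
  prof <- tapply(per_slice$v, per_slice$seg, mean)
  out <- rep(NA_real_, segmentation$n_segments)
  out[as.integer(names(prof))] <- prof
  if (anyNA(out))
    eh_stop(sprintf("segment(s) %s empty on every slice",
                    paste(which(is.na(out)), collapse = ", ")),
            "ehconn_invalid_input")
  out
}

#' Build a subjects x (measure x segment) estimate table
#'
#' @param subject_maps named list: subject id -> named list of 3D maps
#'   (measure -> map), all on the segmentation grid.
#' @param segmentation a [segment_roi()] result.
#' @return long-format data.frame with columns `subject`, `measure`,
#'   `segment`, `value`; one row per subject x measure x segment.
#' @export
build_estimate_table <- function(subject_maps, segmentation) {
  measures <- names(subject_maps[[1]])
  rows <- list()
  for (s in names(subject_maps)) {
    missing <- setdiff(measures, names(subject_maps[[s]]))
    if (length(missing))
      eh_stop(sprintf("subject %s lacks measure(s) %s", s,
                      paste(missing, collapse = ", ")),
              "ehconn_invalid_input")
    for (m in measures) {
      prof <- extract_segment_profile(subject_maps[[s]][[m]], segmentation)
      rows[[paste(s, m)]] <- data.frame(
        subject = s, measure = m,
        segment = seq_along(prof), value = prof,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write or read a segment estimate table as TSV
#'
#' The TSV schema (`subject`, `measure`, `segment`, `value`) is the
#' interchange format of the stats module; externally produced estimate
#' tables with the same columns load identically.
#'
#' @param table long-format estimate table.
#' @param path file path.
#' @return `read_estimate_table` returns the data.frame.
#' @export
write_estimate_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_estimate_table
#' @export
read_estimate_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("subject", "measure", "segment", "value")
  if (!all(need %in% names(df)))
    eh_stop(paste("estimate table must have columns",
                  paste(need, collapse = ", ")),
            "ehconn_invalid_input")
  df
}
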