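# Group-level winner-take-all parcellation of the entorhinal cortex from
# per-subject source-connectivity z-maps.

#' One-sample t-map across subjects
#'
#' Per voxel, `t = mean / (sd / sqrt(n))` with the sample standard
#' deviation across subjects. Voxels with zero variance yield a signed
#' infinity sentinel (0 when the mean is also 0) and are reported in a
#' warning.
#'
#' @param z_maps list of per-subject 3D arrays on a common grid.
#' @param source_name label stored with the map.
#' @return object of class `t_map`: `t_values` (3D array), `df`
#'   (`n_subjects - 1`), `source_name`.
#' @export
one_sample_tmap <- function(z_maps, source_name = "source") {
  n <- length(z_maps)
  if (n < 2L)
    eh_stop("one-sample t-map needs at least 2 subjects",
            "ehconn_invalid_input")
  dims <- dim(z_maps[[1]])
  M <- vapply(z_maps, as.vector, numeric(prod(dims)))
  mu <- rowMeans(M)
  s <- sqrt(rowSums((M - mu)^2) / (n - 1))
  t_vals <- ifelse(s > 0, mu / (s / sqrt(n)),
                   ifelse(mu == 0, 0, sign(mu) * Inf))
  n_degenerate <- sum(s == 0 & mu != 0, na.rm = TRUE)
  if (n_degenerate > 0)
    warning(sprintf("%d voxel(s) with zero variance set to +/-Inf",
                    n_degenerate))
  structure(list(t_values = array(t_vals, dim = dims), df = n - 1L,
                 source_name = source_name),
            class = "t_map")
}

#' Winner-take-all seed assignment from thresholded t-maps
#'
#' Each mask voxel is assigned to the source with the maximum T value,
#' provided that maximum exceeds `t_threshold` (one-sided, positive
#' connectivity); otherwise it stays unassigned. Ties are broken by the
#' fixed source order (RSC, PHC, A35, A36) and reported in a warning.
#'
#' @param tmaps named list of [one_sample_tmap()] results, one per source,
#'   in the fixed source order.
#' @param mask logical 3D array (or integer indices) restricting the
#'   assignment, e.g. the EC mask.
#' @param t_threshold threshold on the winning T (default 3.1).
#' @return object of class `seed_assignment`: `label` (3D integer array,
#'   0 = unassigned, k = index into `sources`), `winning_t` (3D array),
#'   `sources` (source names), `t_threshold`.
#' @export
winner_take_all <- function(tmaps, mask, t_threshold = 3.1) {
  if (is.null(names(tmaps)) || any(!nzchar(names(tmaps))))
    eh_stop("tmaps must be a named list (one entry per source)",
            "ehconn_invalid_input")
  dims <- dim(tmaps[[1]]$t_values)
  idx <- if (is.logical(mask) || length(mask) == prod(dims))
    mask_indices(mask) else as.integer(mask)
  Tm <- matrix(vapply(tmaps, function(tm) tm$t_values[idx],
                      numeric(length(idx))),
               nrow = length(idx))
  winner <- max.col(Tm, ties.method = "first")
  best_t <- Tm[cbind(seq_along(winner), winner)]
  n_ties <- sum(rowSums(Tm == best_t) > 1L & is.finite(best_t))
  if (n_ties > 0)
    warning(sprintf("%d voxel(s) with tied maximum T assigned by source order",
                    n_ties))
  assigned <- best_t > t_threshold
  label <- array(0L, dim = dims)
  label[idx[assigned]] <- winner[assigned]
  wt <- array(NA_real_, dim = dims)
  wt[idx] <- best_t
  structure(list(label = label, winning_t = wt,
                 sources = names(tmaps), t_threshold = t_threshold),
            class = "seed_assignment")
}

#' Equalize per-source seed sizes across hemispheres
#'
#' For each source, finds the minimum assigned-voxel count over
#' hemispheres and keeps, in each hemisphere, only the N voxels with the
#' highest winning T for that source (ties broken by voxel index). With a
#' single hemisphere the assignment is returned unchanged apart from this
#' top-N rule with N equal to the count, i.e. the identity.
#'
#' @param assignments named list of [winner_take_all()] results, one per
#'   hemisphere.
#' @return list of pruned `seed_assignment` objects with matching
#'   per-source counts.
#' @export
equalize_across_hemispheres <- function(assignments) {
  sources <- assignments[[1]]$sources
  counts <- vapply(assignments, function(a)
    vapply(seq_along(sources), function(k) sum(a$label == k), 1L),
    integer(length(sources)))
  counts <- matrix(counts, nrow = length(sources))
  n_keep <- apply(counts, 1L, min)
  for (k in seq_along(sources)) {
    if (n_keep[k] == 0L && any(counts[k, ] > 0L))
      warning(sprintf(
        "source %s has no voxels in one hemisphere; its seed is empty everywhere",
        sources[k]))
    for (h in seq_along(assignments)) {
      a <- assignments[[h]]
      idx <- which(a$label == k)
      if (length(idx) <= n_keep[k]) next
      ord <- order(-a$winning_t[idx], idx)
      drop <- if (n_keep[k] == 0L) idx else idx[ord][-seq_len(n_keep[k])]
      a$label[drop] <- 0L
      assignments[[h]] <- a
    }
  }
  assignments
}

#' Accuracy of a seed assignment against hidden EC sublabels
#'
#' Fraction of assigned EC voxels whose winner-take-all source matches the
#' phantom's generating source.
#'
#' @param assignment a [winner_take_all()] result.
#' @param ec_sublabel 3D array of hidden sublabels (1..4 inside EC).
#' @return list with `accuracy` (fraction correct among assigned voxels),
#'   `n_assigned`, `n_total` (EC voxels).
#' @export
parcellation_accuracy <- function(assignment, ec_sublabel) {
  in_ec <- ec_sublabel > 0L
  assigned <- assignment$label > 0L & in_ec
  list(accuracy = if (any(assigned))
         mean(assignment$label[assigned] == ec_sublabel[assigned]) else NA_real_,
       n_assigned = sum(assigned), n_total = sum(in_ec))
}
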