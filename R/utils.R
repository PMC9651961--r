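# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded helpers do not disturb
#' the caller's RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

#' Derive a per-unit seed from a base seed, kept within 32-bit integer range
#' @noRd
derive_seed <- function(base_seed, index) {
  as.integer((as.numeric(base_seed) * 7919 + 104729 * as.numeric(index)) %%
               2147483647L)
}

#' Stop with a classed error used throughout the package
#' @noRd
eh_stop <- function(msg, class = "ehconn_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Reshape a 4D (x,y,z,t) array to a voxels-by-time matrix
#' @noRd
as_voxel_matrix <- function(arr4d) {
  d <- dim(arr4d)
  matrix(arr4d, nrow = prod(d[1:3]), ncol = d[4])
}

#' Inverse of [as_voxel_matrix()]
#' @noRd
as_4d <- function(vmat, dims3) {
  array(vmat, dim = c(dims3, ncol(vmat)))
}

#' Linear voxel indices for a logical 3D mask
#' @noRd
mask_indices <- function(mask) which(as.logical(mask))
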