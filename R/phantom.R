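# Synthetic BOLD phantom: a group of subjects with four cortical source
# regions (RSC, PHC, A35, A36), an entorhinal cortex containing four hidden
# subregions each driven by one source, and subiculum/CA1 sheets whose
# source weights vary along a transversal (proximal -> distal) coordinate.
# Task responses (scene/object/baseline) are added with a scene bias
# confined to the PHC-driven EC subregion and the distal subiculum.

SOURCE_NAMES <- c("RSC", "PHC", "A35", "A36")

ROI_LEGEND <- c(RSC = 1L, PHC = 2L, A35 = 3L, A36 = 4L, EC = 5L,
                SUB = 6L, CA1 = 7L, WM = 8L, CSF = 9L)

#' Phantom configuration
#'
#' Holds every knob of the synthetic BOLD experiment. Defaults are the
#' desk-scale study conditions: a 24 x 24 x 12 voxel grid, 16 subjects, one
#' run of 240 volumes at TR 2.4 s (the acquisition TR of the emulated
#' protocol; full-scale values of 32 subjects and 2 x 332 volumes remain
#' valid configuration).
#'
#' @param grid_dims integer triple, voxel grid size (each >= 8; the fixed
#'   ROI layout needs at least 24 x 20 x 10).
#' @param n_subjects number of subjects in the group.
#' @param n_volumes_per_run volumes per run (>= 20).
#' @param n_runs runs per subject.
#' @param tr_seconds repetition time in seconds.
#' @param band_hz passband (low, high) in Hz; must satisfy
#'   `low < high < 1/(2 * tr_seconds)`.
#' @param noise_sd standard deviation of i.i.d. Gaussian voxel noise.
#' @param gradient_weights named list `list(SUB = ..., CA1 = ...)`; each a
#'   named list mapping source name to `c(proximal_weight, distal_weight)`.
#'   A voxel at transversal position p gets weight
#'   `w_prox + p * (w_dist - w_prox)` on that source's latent signal.
#' @param condition_amplitudes named list mapping region
#'   (`EC_RSC`, `EC_PHC`, `EC_A35`, `EC_A36`, `SUB`, `CA1`) to a named
#'   vector of amplitudes for `scene`, `object`, `baseline`; each entry may
#'   be a scalar (flat) or length 2 `(proximal, distal)` interpolated along
#'   the transversal coordinate.
#' @param spike_rate per-volume probability of an injected global-intensity
#'   spike (+3 percent on that volume).
#' @param baseline_intensity mean raw signal intensity added to every voxel
#'   so that intensity-based artifact detection and mask thresholding
#'   operate on realistic positive values.
#' @param rng_seed integer master seed.
#' @return object of class `phantom_config`.
#' @export
phantom_config <- function(grid_dims = c(24L, 24L, 12L),
                           n_subjects = 16L,
                           n_volumes_per_run = 240L,
                           n_runs = 1L,
                           tr_seconds = 2.4,
                           band_hz = c(0.01, 0.1),
                           noise_sd = 1,
                           gradient_weights = default_gradient_weights(),
                           condition_amplitudes = default_condition_amplitudes(),
                           spike_rate = 0.02,
                           baseline_intensity = 100,
                           rng_seed = 1L) {
  cfg <- list(grid_dims = as.integer(grid_dims),
              n_subjects = as.integer(n_subjects),
              n_volumes_per_run = as.integer(n_volumes_per_run),
              n_runs = as.integer(n_runs),
              tr_seconds = tr_seconds,
              band_hz = band_hz,
              noise_sd = noise_sd,
              gradient_weights = gradient_weights,
              condition_amplitudes = condition_amplitudes,
              spike_rate = spike_rate,
              baseline_intensity = baseline_intensity,
              rng_seed = as.integer(rng_seed))
  class(cfg) <- "phantom_config"
  validate_phantom_config(cfg)
  cfg
}

#' @noRd
validate_phantom_config <- function(cfg) {
  if (length(cfg$grid_dims) != 3L || any(cfg$grid_dims < 8L))
    eh_stop("grid_dims must be an integer triple with each entry >= 8",
            "ehconn_invalid_config")
  if (cfg$n_volumes_per_run < 20L)
    eh_stop("n_volumes_per_run must be >= 20", "ehconn_invalid_config")
  if (cfg$tr_seconds <= 0)
    eh_stop("tr_seconds must be positive", "ehconn_invalid_config")
  check_band(cfg$band_hz, cfg$tr_seconds)
  if (cfg$noise_sd < 0)
    eh_stop("noise_sd must be nonnegative", "ehconn_invalid_config")
  if (cfg$spike_rate < 0 || cfg$spike_rate > 1)
    eh_stop("spike_rate must lie in [0, 1]", "ehconn_invalid_config")
  invisible(cfg)
}

#' @noRd
check_band <- function(band, tr) {
  nyquist <- 1 / (2 * tr)
  if (length(band) != 2L || band[1] <= 0 || band[1] >= band[2] ||
      band[2] >= nyquist)
    eh_stop(sprintf(
      "band (%.4g, %.4g) must satisfy 0 < low < high < Nyquist = %.4g Hz",
      band[1], band[2], nyquist), "ehconn_invalid_config")
  invisible(band)
}

#' Default transversal gradient weights
#'
#' Encodes the qualitative connectivity topography under study: the
#' PHC-driven weight rises toward the distal subiculum while A35- and
#' RSC-driven weights rise toward the proximal subiculum; in CA1 the
#' RSC-driven weight rises toward the distal end; A36 is flat everywhere.
#' @return nested named list, see [phantom_config()].
#' @export
default_gradient_weights <- function() {
  list(
    SUB = list(RSC = c(0.9, 0.3), PHC = c(0.2, 1.0),
               A35 = c(1.0, 0.2), A36 = c(0.4, 0.4)),
    CA1 = list(RSC = c(0.2, 0.9), PHC = c(0.4, 0.4),
               A35 = c(0.7, 0.3), A36 = c(0.4, 0.4))
  )
}

#' Default task condition amplitudes
#'
#' Scene processing is boosted only in the PHC-driven EC subregion and,
#' via a proximal->distal ramp, in the distal subiculum; the remaining
#' regions respond equally to scenes and objects. Baseline (scrambled
#' images) evokes no response anywhere and is the reference condition.
#' @return nested named list, see [phantom_config()].
#' @export
default_condition_amplitudes <- function() {
  list(
    EC_RSC = list(scene = 0.3, object = 0.3, baseline = 0),
    EC_PHC = list(scene = 1.0, object = 0.2, baseline = 0),
    EC_A35 = list(scene = 0.3, object = 0.3, baseline = 0),
    EC_A36 = list(scene = 0.3, object = 0.3, baseline = 0),
    SUB    = list(scene = c(0.1, 1.0), object = c(0.3, 0.3), baseline = 0),
    CA1    = list(scene = 0.2, object = 0.2, baseline = 0)
  )
}

#' Band-limited latent source signals
#'
#' White Gaussian series are band-limited by zeroing FFT coefficients
#' outside `band` (and the DC term), inverse-transformed, and standardized
#' to zero mean and unit variance. The spectrum is therefore exactly
#' confined to the passband.
#'
#' @param n_time number of time points.
#' @param tr sampling interval in seconds.
#' @param band passband `c(low, high)` in Hz, `high` below Nyquist.
#' @param seed integer seed; output is deterministic given the seed.
#' @param n_sources number of latent rows (default one per cortical source).
#' @return `n_sources` x `n_time` matrix with rownames [SOURCE_NAMES].
#' @export
make_latent_sources <- function(n_time, tr, band, seed,
                                n_sources = length(SOURCE_NAMES)) {
  check_band(band, tr)
  white <- with_seed(seed,
                     matrix(stats::rnorm(n_sources * n_time),
                            nrow = n_sources))
  freqs <- (seq_len(n_time) - 1) / (n_time * tr)
  freqs <- pmin(freqs, 1 / tr - freqs)   # two-sided spectrum folding
  keep <- freqs >= band[1] & freqs <= band[2]
  out <- t(apply(white, 1L, function(x) {
    xf <- stats::fft(x)
    xf[!keep] <- 0
    Re(stats::fft(xf, inverse = TRUE)) / n_time
  }))
  out <- out - rowMeans(out)
  out <- out / sqrt(rowSums(out^2) / n_time)
  if (n_sources == length(SOURCE_NAMES)) rownames(out) <- SOURCE_NAMES
  out
}

# Fixed ROI layout: coordinates are on the first (medial->lateral), second
# ("coronal" slice) and third axes. Larger first-axis coordinates are
# lateral; the proximal ends of both SUB and CA1 sit at the lateral side.
phantom_layout <- function() {
  list(
    RSC = list(x = 1:3,  y = 1:3,   z = 1:2),
    PHC = list(x = 1:3,  y = 5:7,   z = 1:2),
    A35 = list(x = 1:3,  y = 9:11,  z = 1:2),
    A36 = list(x = 1:3,  y = 13:15, z = 1:2),
    EC  = list(x = 6:13, y = 2:9,   z = 4:7),
    SUB = list(x = 6:15, y = 12:19, z = 9:10),
    WM  = list(x = 18:21, y = 2:5,  z = 1:2),
    CSF = list(x = 18:21, y = 7:10, z = 1:2)
  )
}

# CA1 voxels per coronal slice: a semicircular arc (radius 5 around
# (19, 3) in the (medial-lateral, third-axis) plane) so that the 60-degree
# sector rule yields meaningful, roughly equal transversal segments.
ca1_arc <- function() {
  theta <- seq(10, 170, by = 20)
  list(x = round(19 + 5 * cos(theta * pi / 180)),
       z = round(3 + 5 * sin(theta * pi / 180)),
       # transversal position 0 at the proximal (high-x) end of the arc
       pos = (theta - 10) / 160)
}

#' Build the phantom anatomy and ground-truth geometry
#'
#' Places all ROIs disjointly on the grid, assigns each EC voxel a hidden
#' sublabel naming its driving source, gives every SUB/CA1 voxel a
#' transversal position in [0, 1] (0 = proximal, at the lateral end
#' adjacent to CA1 for SUB and at the far-from-SUB end of the arc for CA1),
#' and derives per-voxel source weights from the configured gradients.
#'
#' @param config a [phantom_config()].
#' @return list with elements
#'   `labels` (3D integer array), `legend` (named label codes),
#'   `coronal_axis` (2), `mediolateral_axis` (1), `proximal_direction`
#'   (`"+x"`), `ec_sublabel` (3D array, 1..4 inside EC, 0 elsewhere),
#'   `transversal_position` (3D array, NA outside SUB/CA1),
#'   `weights` (n_voxels x 4 matrix of latent weights, zero outside
#'   source/EC/SUB/CA1 masks).
#' @export
build_phantom_anatomy <- function(config) {
  dims <- config$grid_dims
  if (dims[1] < 24L || dims[2] < 20L || dims[3] < 10L)
    eh_stop("grid too small to place all ROIs disjointly (need >= 24 x 20 x 10)",
            "ehconn_invalid_config")
  labels <- array(0L, dim = dims)
  ecsub <- array(0L, dim = dims)
  tpos <- array(NA_real_, dim = dims)
  lay <- phantom_layout()
  for (roi in names(lay)) {
    b <- lay[[roi]]
    stopifnot(all(labels[b$x, b$y, b$z] == 0L))
    labels[b$x, b$y, b$z] <- ROI_LEGEND[[roi]]
  }
  # hidden EC sublabels: quadrants of the EC block in the (x, y) plane
  ec <- lay$EC
  half_x <- split(ec$x, rep(1:2, each = length(ec$x) / 2))
  half_y <- split(ec$y, rep(1:2, each = length(ec$y) / 2))
  quadrants <- list(list(half_x[[1]], half_y[[1]]),  # RSC
                    list(half_x[[2]], half_y[[1]]),  # PHC
                    list(half_x[[1]], half_y[[2]]),  # A35
                    list(half_x[[2]], half_y[[2]]))  # A36
  for (k in seq_along(quadrants))
    ecsub[quadrants[[k]][[1]], quadrants[[k]][[2]], ec$z] <- k
  # subiculum transversal positions: 0 at lateral (proximal) end
  sub <- lay$SUB
  for (x in sub$x)
    tpos[x, sub$y, sub$z] <- (max(sub$x) - x) / (max(sub$x) - min(sub$x))
  # CA1 arc
  arc <- ca1_arc()
  ca1_y <- lay$SUB$y
  for (i in seq_along(arc$x)) {
    stopifnot(all(labels[arc$x[i], ca1_y, arc$z[i]] == 0L))
    labels[arc$x[i], ca1_y, arc$z[i]] <- ROI_LEGEND[["CA1"]]
    tpos[arc$x[i], ca1_y, arc$z[i]] <- arc$pos[i]
  }
  weights <- phantom_weights(labels, ecsub, tpos, config$gradient_weights)
  list(labels = labels, legend = ROI_LEGEND,
       coronal_axis = 2L, mediolateral_axis = 1L, proximal_direction = "+x",
       ec_sublabel = ecsub, transversal_position = tpos, weights = weights)
}

#' @noRd
phantom_weights <- function(labels, ecsub, tpos, gradient_weights) {
  n_vox <- length(labels)
  W <- matrix(0, nrow = n_vox, ncol = length(SOURCE_NAMES),
              dimnames = list(NULL, SOURCE_NAMES))
  for (k in seq_along(SOURCE_NAMES)) {
    W[labels == ROI_LEGEND[[SOURCE_NAMES[k]]], k] <- 1  # source follows own latent
    W[ecsub == k, k] <- 1                               # EC sublabel k
  }
  for (region in c("SUB", "CA1")) {
    idx <- which(labels == ROI_LEGEND[[region]])
    p <- tpos[idx]
    gw <- gradient_weights[[region]]
    for (k in seq_along(SOURCE_NAMES)) {
      w <- gw[[SOURCE_NAMES[k]]]
      if (length(w) == 1L) w <- c(w, w)
      W[idx, k] <- w[1] + p * (w[2] - w[1])
    }
  }
  W
}

#' Task event table for one run
#'
#' Blocks of ten 3-second scrambled-image (baseline) trials open and close
#' the run; in between, mini-blocks of two 3-second stimuli alternate
#' between the scene and object conditions with a 6-second gap after each
#' mini-block.
#'
#' @param config a [phantom_config()].
#' @param n_blocks number of scene/object mini-blocks; `NULL` fills the
#'   available time, 0 gives a baseline-only run.
#' @return data.frame with columns `onset`, `duration`, `condition`;
#'   onsets strictly increasing.
#' @export
make_event_table <- function(config, n_blocks = NULL) {
  run_len <- config$n_volumes_per_run * config$tr_seconds
  stim <- 3
  base_len <- 10 * stim
  avail <- run_len - 2 * base_len - 12   # gaps flanking the task window
  max_blocks <- max(0L, floor(avail / 12))
  if (is.null(n_blocks)) n_blocks <- max_blocks
  if (n_blocks > max_blocks)
    eh_stop(sprintf("%d mini-blocks do not fit a %.0f s run", n_blocks, run_len),
            "ehconn_invalid_config")
  if (run_len < 2 * base_len)
    eh_stop("run too short for the opening and closing baseline blocks",
            "ehconn_invalid_config")
  onset <- seq(0, by = stim, length.out = 10)
  cond <- rep("baseline", 10)
  if (n_blocks > 0) {
    starts <- base_len + 6 + (seq_len(n_blocks) - 1) * 12
    onset <- c(onset, rbind(starts, starts + stim))
    cond <- c(cond, rep(rep(c("scene", "object"), length.out = n_blocks),
                        each = 2))
  }
  onset <- c(onset, seq(run_len - base_len, by = stim, length.out = 10))
  cond <- c(cond, rep("baseline", 10))
  ev <- data.frame(onset = onset, duration = stim, condition = cond,
                   stringsAsFactors = FALSE)
  stopifnot(all(diff(ev$onset) > 0), all(ev$onset + ev$duration <= run_len))
  ev
}

#' @noRd
region_amplitudes <- function(labels, ecsub, tpos, condition_amplitudes,
                              conditions = c("scene", "object", "baseline")) {
  A <- matrix(0, nrow = length(labels), ncol = length(conditions),
              dimnames = list(NULL, conditions))
  region_idx <- list(
    EC_RSC = which(ecsub == 1L), EC_PHC = which(ecsub == 2L),
    EC_A35 = which(ecsub == 3L), EC_A36 = which(ecsub == 4L),
    SUB = which(labels == ROI_LEGEND[["SUB"]]),
    CA1 = which(labels == ROI_LEGEND[["CA1"]]))
  for (region in names(condition_amplitudes)) {
    idx <- region_idx[[region]]
    if (is.null(idx) || length(idx) == 0L) next
    for (cond in conditions) {
      a <- condition_amplitudes[[region]][[cond]]
      if (is.null(a)) next
      if (length(a) == 2L) {
        p <- tpos[idx]
        p[is.na(p)] <- 0
        A[idx, cond] <- a[1] + p * (a[2] - a[1])
      } else {
        A[idx, cond] <- a
      }
    }
  }
  A
}

#' Synthesize one subject's BOLD runs and nuisance set
#'
#' Each voxel's time series is the weighted sum of the latent source
#' signals, plus HRF-convolved condition regressors scaled by the region's
#' configured amplitude, plus white Gaussian noise, on top of a constant
#' intensity offset. Randomly chosen volumes receive a +3 percent global
#' intensity spike (above the 1.3 percent detection threshold). Six smooth
#' synthetic motion-parameter columns are generated alongside.
#'
#' @param anatomy output of [build_phantom_anatomy()].
#' @param events_by_run list of event tables, one per run.
#' @param config a [phantom_config()].
#' @param subject_seed integer seed for this subject.
#' @return list with `runs` (list of `bold_run`), `nuisance` (list per run:
#'   `motion` T x 6 matrix, `spikes` integer vector of spiked volumes),
#'   `latents` (list per run of the source x time latent matrix).
#' @export
synthesize_subject <- function(anatomy, events_by_run, config, subject_seed) {
  n_t <- config$n_volumes_per_run
  tr <- config$tr_seconds
  A <- region_amplitudes(anatomy$labels, anatomy$ec_sublabel,
                         anatomy$transversal_position,
                         config$condition_amplitudes)
  runs <- vector("list", config$n_runs)
  nuis <- vector("list", config$n_runs)
  lats <- vector("list", config$n_runs)
  for (r in seq_len(config$n_runs)) {
    lat <- make_latent_sources(n_t, tr, config$band_hz,
                               seed = derive_seed(subject_seed, r))
    Y <- anatomy$weights %*% lat
    ev <- events_by_run[[r]]
    for (cond in colnames(A)) {
      reg <- condition_regressor(ev, cond, n_t, tr)
      if (any(reg != 0)) Y <- Y + A[, cond, drop = FALSE] %*% rbind(reg)
    }
    run_seed <- derive_seed(subject_seed, 1000L + r)
    noise_motion <- with_seed(run_seed, {
      noise <- if (config$noise_sd > 0)
        matrix(stats::rnorm(length(Y), sd = config$noise_sd), nrow = nrow(Y))
      else 0
      motion <- apply(matrix(stats::rnorm(n_t * 6, sd = 0.02), ncol = 6),
                      2L, cumsum)
      spikes <- which(stats::runif(n_t) < config$spike_rate)
      spikes <- setdiff(spikes, 1L)
      list(noise = noise, motion = motion, spikes = spikes)
    })
    Y <- Y + noise_motion$noise + config$baseline_intensity
    if (length(noise_motion$spikes))
      Y[, noise_motion$spikes] <- Y[, noise_motion$spikes, drop = FALSE] * 1.03
    runs[[r]] <- bold_run(array(Y, dim = c(config$grid_dims, n_t)), tr)
    nuis[[r]] <- list(motion = noise_motion$motion,
                      spikes = noise_motion$spikes)
    lats[[r]] <- lat
  }
  list(runs = runs, nuisance = nuis, latents = lats)
}

#' Simulate a full phantom group
#'
#' @param config a [phantom_config()].
#' @return list with `config`, `anatomy`, `events` (list per run, shared by
#'   all subjects), and `subjects` (list per subject as returned by
#'   [synthesize_subject()]).
#' @export
simulate_group <- function(config) {
  anatomy <- build_phantom_anatomy(config)
  events <- lapply(seq_len(config$n_runs),
                   function(r) make_event_table(config))
  subjects <- lapply(seq_len(config$n_subjects), function(s) {
    synthesize_subject(anatomy, events, config,
                       subject_seed = derive_seed(config$rng_seed, s))
  })
  list(config = config, anatomy = anatomy, events = events,
       subjects = subjects)
}

#' Write a phantom dataset to disk
#'
#' Writes the label map, hidden EC sublabels and transversal positions as
#' NIfTI-1 volumes, BOLD runs as 4D NIfTI-1, events as BIDS-style TSV
#' (`onset`, `duration`, `trial_type`), motion parameters as 6-column TSV,
#' and axis metadata / spike indices / configuration as JSON.
#'
#' @param group output of [simulate_group()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(group, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  an <- group$anatomy
  vox <- rep(1, 3)  # 1 mm isotropic phantom grid
  write_map(an$labels, file.path(dir, "labels.nii.gz"))
  write_map(an$ec_sublabel, file.path(dir, "ec_sublabels.nii.gz"))
  tp <- an$transversal_position
  tp[is.na(tp)] <- -1
  write_map(tp, file.path(dir, "transversal_position.nii.gz"))
  for (r in seq_along(group$events)) {
    ev <- group$events[[r]]
    utils::write.table(
      data.frame(onset = ev$onset, duration = ev$duration,
                 trial_type = ev$condition),
      file.path(dir, sprintf("run-%02d_events.tsv", r)),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  spikes <- list()
  for (s in seq_along(group$subjects)) {
    subj <- group$subjects[[s]]
    for (r in seq_along(subj$runs)) {
      stem <- sprintf("sub-%02d_run-%02d", s, r)
      img <- RNifti::asNifti(subj$runs[[r]]$data)
      RNifti::pixdim(img) <- c(vox, subj$runs[[r]]$tr)
      RNifti::writeNifti(img, file.path(dir, paste0(stem, "_bold.nii.gz")))
      mp <- as.data.frame(subj$nuisance[[r]]$motion)
      names(mp) <- c("trans_x", "trans_y", "trans_z",
                     "rot_x", "rot_y", "rot_z")
      utils::write.table(mp, file.path(dir, paste0(stem, "_motion.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      spikes[[stem]] <- subj$nuisance[[r]]$spikes
    }
  }
  meta <- list(legend = as.list(an$legend),
               coronal_axis = an$coronal_axis,
               mediolateral_axis = an$mediolateral_axis,
               proximal_direction = an$proximal_direction,
               true_spikes = spikes,
               config = group$config[setdiff(names(group$config),
                                             c("gradient_weights",
                                               "condition_amplitudes"))],
               gradient_weights = group$config$gradient_weights,
               condition_amplitudes = group$config$condition_amplitudes)
  jsonlite::write_json(meta, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
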