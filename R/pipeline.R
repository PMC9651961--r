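# Orchestration: phantom simulation -> subject GLM -> semipartial
# connectivity -> winner-take-all parcellation -> transversal segmentation
# -> estimate tables -> hierarchical gradient and content-bias tests.

#' Pipeline configuration
#'
#' All analysis constants in one place, with the phantom configuration
#' nested under `phantom`.
#'
#' @param t_threshold group T threshold for winner-take-all seed
#'   definition (default 3.1).
#' @param band_hz connectivity passband in Hz (default 0.01-0.1).
#' @param n_sub_segments transversal subiculum bins (default 5).
#' @param ca1_angle_deg CA1 sector width in degrees (default 60, giving
#'   three sectors).
#' @param intensity_k_sd seed-mask intensity exclusion threshold in SDs
#'   (default 2).
#' @param art_intensity_pct spike-detection global intensity threshold in
#'   percent (default 1.3).
#' @param art_motion_mm spike-detection framewise displacement threshold
#'   in mm (default 0.3).
#' @param fwhm_mm Gaussian smoothing FWHM for contrast maps in mm
#'   (default 1.5).
#' @param fdr_q FDR level for all corrected families (default 0.05).
#' @param phantom a [phantom_config()].
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(t_threshold = 3.1,
                            band_hz = c(0.01, 0.1),
                            n_sub_segments = 5L,
                            ca1_angle_deg = 60,
                            intensity_k_sd = 2,
                            art_intensity_pct = 1.3,
                            art_motion_mm = 0.3,
                            fwhm_mm = 1.5,
                            fdr_q = 0.05,
                            phantom = phantom_config()) {
  stopifnot(t_threshold > 0, n_sub_segments >= 2L, ca1_angle_deg > 0,
            art_intensity_pct > 0, art_motion_mm > 0, fwhm_mm >= 0,
            fdr_q > 0)
  structure(list(t_threshold = t_threshold, band_hz = band_hz,
                 n_sub_segments = as.integer(n_sub_segments),
                 ca1_angle_deg = ca1_angle_deg,
                 intensity_k_sd = intensity_k_sd,
                 art_intensity_pct = art_intensity_pct,
                 art_motion_mm = art_motion_mm,
                 fwhm_mm = fwhm_mm, fdr_q = fdr_q, phantom = phantom),
            class = "pipeline_config")
}

#' Null-effect phantom configuration
#'
#' Flat transversal gradients (every source weighted 0.5 everywhere in
#' SUB and CA1) and identical scene/object amplitudes everywhere, so that
#' neither the gradient cascade nor the content test has a true effect.
#' EC sublabels keep their distinct driving sources so parcellation still
#' operates.
#'
#' @param ... passed to [phantom_config()].
#' @return a [phantom_config()].
#' @export
null_phantom_config <- function(...) {
  flat <- list(RSC = c(0.5, 0.5), PHC = c(0.5, 0.5),
               A35 = c(0.5, 0.5), A36 = c(0.5, 0.5))
  amp <- list(scene = 0.3, object = 0.3, baseline = 0)
  phantom_config(
    gradient_weights = list(SUB = flat, CA1 = flat),
    condition_amplitudes = list(EC_RSC = amp, EC_PHC = amp, EC_A35 = amp,
                                EC_A36 = amp, SUB = amp, CA1 = amp),
    ...)
}

#' @noRd
standardize_rows <- function(M) {
  mu <- rowMeans(M)
  s <- sqrt(rowSums((M - mu)^2) / (ncol(M) - 1))
  s[s < 1e-12] <- 1
  (M - mu) / s
}

#' Per-subject GLM stage of the pipeline
#'
#' Detects spike volumes, fits the task GLM per run (conditions, motion,
#' spikes, intercept), averages the smoothed scene/object-versus-baseline
#' contrasts across runs, standardizes the residuals per run and voxel,
#' and concatenates runs in time.
#'
#' @param subject one element of `simulate_group()$subjects`.
#' @param events_by_run list of event tables per run.
#' @param cfg a [pipeline_config()].
#' @param voxels integer vector of voxel indices to carry through (the
#'   labelled analysis voxels); residuals are restricted to these.
#' @param compute_contrasts build the smoothed scene/object contrast maps
#'   (default TRUE).
#' @return list with `res` (voxels x total-time standardized residual
#'   matrix), `motion` (total-time x 6), `spikes` (per-run list),
#'   `contrast_scene`, `contrast_object` (3D arrays, `NULL` when not
#'   computed), `tr`.
#' @export
process_subject <- function(subject, events_by_run, cfg, voxels,
                            compute_contrasts = TRUE) {
  res_blocks <- list()
  motion_blocks <- list()
  spikes <- list()
  sc_maps <- list()
  ob_maps <- list()
  for (r in seq_along(subject$runs)) {
    run <- subject$runs[[r]]
    motion <- subject$nuisance[[r]]$motion
    spk <- detect_spikes(run, motion,
                         intensity_pct = cfg$art_intensity_pct,
                         motion_mm = cfg$art_motion_mm)
    X <- build_design(events_by_run[[r]],
                      list(motion = motion, spikes = spk),
                      n_time = dim(run$data)[4], tr = run$tr)
    fit <- fit_glm(run, X)
    if (compute_contrasts &&
        all(c("scene", "object", "baseline") %in% colnames(X))) {
      sc_maps[[r]] <- glm_contrast(fit, c(scene = 1, baseline = -1),
                                   "scene_gt_baseline")$values
      ob_maps[[r]] <- glm_contrast(fit, c(object = 1, baseline = -1),
                                   "object_gt_baseline")$values
    }
    R <- as_voxel_matrix(fit$residual_run$data)[voxels, , drop = FALSE]
    res_blocks[[r]] <- standardize_rows(R)
    motion_blocks[[r]] <- motion
    spikes[[r]] <- spk
  }
  avg_smooth <- function(maps) {
    if (!length(maps)) return(NULL)
    smooth_volume(Reduce(`+`, maps) / length(maps), cfg$fwhm_mm)
  }
  list(res = do.call(cbind, res_blocks),
       motion = do.call(rbind, motion_blocks),
       spikes = spikes,
       contrast_scene = avg_smooth(sc_maps),
       contrast_object = avg_smooth(ob_maps),
       tr = subject$runs[[1]]$tr)
}

#' @noRd
seed_voxel_sets <- function(anatomy, subject_run, k_sd) {
  # per-source seed voxel indices after intensity exclusion on raw data
  lapply(SOURCE_NAMES, function(src) {
    vox <- which(anatomy$labels == ROI_LEGEND[[src]])
    intensity_exclude(subject_run, vox, k_sd = k_sd)
  }) |> stats::setNames(SOURCE_NAMES)
}

#' Run the full phantom experiment
#'
#' Simulates the group, runs the per-subject GLM and semipartial
#' connectivity stages, derives the entorhinal seeds by winner-take-all
#' parcellation of the group T-maps, segments subiculum and CA1 along the
#' transversal axis, builds the estimate tables, and applies the
#' hierarchical gradient cascade plus (optionally) the content-bias
#' tests.
#'
#' @param cfg a [pipeline_config()].
#' @param do_content also compute contrast-based content tables and tests
#'   (default TRUE).
#' @return list with elements `config`, `anatomy`, `tmaps`, `assignment`,
#'   `accuracy`, `segmentation` (`SUB`, `CA1`), `tables` (`SUB`, `CA1`
#'   connectivity estimate tables), `gradient_report`, `content`
#'   (EC/SUB/CA1 tables and reports, when `do_content`), `group_profiles`
#'   (seed x segment group-mean matrices).
#' @export
run_phantom_pipeline <- function(cfg, do_content = TRUE) {
  pc <- cfg$phantom
  group <- simulate_group(pc)
  anatomy <- group$anatomy
  labels <- anatomy$labels
  avox <- which(labels > 0L)                # all labelled voxels
  col_of <- integer(length(labels))
  col_of[avox] <- seq_along(avox)           # voxel index -> residual row
  tr <- pc$tr_seconds
  band <- cfg$band_hz
  wm_cols <- col_of[which(labels == ROI_LEGEND[["WM"]])]
  csf_cols <- col_of[which(labels == ROI_LEGEND[["CSF"]])]
  ec_vox <- which(labels == ROI_LEGEND[["EC"]])
  sub_vox <- which(labels == ROI_LEGEND[["SUB"]])
  ca1_vox <- which(labels == ROI_LEGEND[["CA1"]])
  target_vox <- c(sub_vox, ca1_vox)

  subjects <- vector("list", pc$n_subjects)
  ec_z <- lapply(SOURCE_NAMES, function(s)
    vector("list", pc$n_subjects)) |> stats::setNames(SOURCE_NAMES)
  for (s in seq_len(pc$n_subjects)) {
    proc <- process_subject(group$subjects[[s]], group$events, cfg, avox,
                            compute_contrasts = do_content)
    Yf <- bandpass(t(proc$res), band, tr)      # time x labelled voxels
    nuis <- cbind(wm = rowMeans(Yf[, wm_cols, drop = FALSE]),
                  csf = rowMeans(Yf[, csf_cols, drop = FALSE]),
                  bandpass(proc$motion, band, tr))
    Yc <- residualize(Yf, nuis)
    src_sets <- seed_voxel_sets(anatomy, group$subjects[[s]]$runs[[1]],
                                cfg$intensity_k_sd)
    src_series <- vapply(SOURCE_NAMES, function(src)
      rowMeans(Yc[, col_of[src_sets[[src]]], drop = FALSE]),
      numeric(nrow(Yc)))
    for (k in seq_along(SOURCE_NAMES)) {
      seed_u <- residualize(src_series[, k],
                            src_series[, -k, drop = FALSE])
      ec_z[[k]][[s]] <- corr_z(Yc[, col_of[ec_vox], drop = FALSE], seed_u)
    }
    subjects[[s]] <- list(Yc = Yc, proc = proc)
  }

  tmaps <- lapply(SOURCE_NAMES, function(src) {
    maps <- lapply(seq_len(pc$n_subjects), function(s) {
      m <- array(NA_real_, dim = pc$grid_dims)
      m[ec_vox] <- ec_z[[src]][[s]]
      m
    })
    one_sample_tmap(maps, source_name = src)
  }) |> stats::setNames(SOURCE_NAMES)
  assignment <- winner_take_all(tmaps, mask = ec_vox,
                                t_threshold = cfg$t_threshold)
  assignment <- equalize_across_hemispheres(list(assignment))[[1]]
  acc <- parcellation_accuracy(assignment, anatomy$ec_sublabel)

  seed_cols <- lapply(seq_along(SOURCE_NAMES), function(k)
    col_of[which(assignment$label == k)])
  empty_seeds <- vapply(seed_cols, length, 1L) == 0L
  if (any(empty_seeds))
    eh_stop(paste("empty entorhinal seed(s):",
                  paste(SOURCE_NAMES[empty_seeds], collapse = ", ")),
            "ehconn_pipeline_error")
  seg_sub <- segment_roi(anatomy, ROI_LEGEND[["SUB"]], "bins",
                         n_segments = cfg$n_sub_segments)
  seg_ca1 <- segment_roi(anatomy, ROI_LEGEND[["CA1"]], "sectors",
                         angle_deg = cfg$ca1_angle_deg)

  subject_maps <- lapply(seq_len(pc$n_subjects), function(s) {
    Yc <- subjects[[s]]$Yc
    seed_series <- vapply(seed_cols, function(cols)
      rowMeans(Yc[, cols, drop = FALSE]), numeric(nrow(Yc)))
    lapply(seq_along(SOURCE_NAMES), function(k) {
      seed_u <- residualize(seed_series[, k],
                            seed_series[, -k, drop = FALSE])
      m <- array(NA_real_, dim = pc$grid_dims)
      m[target_vox] <- corr_z(Yc[, col_of[target_vox], drop = FALSE], seed_u)
      m
    }) |> stats::setNames(paste0("EC_", SOURCE_NAMES))
  }) |> stats::setNames(sprintf("sub%02d", seq_len(pc$n_subjects)))

  tables <- list(SUB = build_estimate_table(subject_maps, seg_sub),
                 CA1 = build_estimate_table(subject_maps, seg_ca1))
  gradient_report <- hierarchical_gradient_test(tables, q = cfg$fdr_q)
  group_profiles <- lapply(tables, function(tbl) {
    agg <- stats::aggregate(value ~ measure + segment, data = tbl,
                            FUN = mean)
    stats::xtabs(value ~ measure + segment, data = agg)
  })

  content <- NULL
  if (do_content && !is.null(subjects[[1]]$proc$contrast_scene)) {
    content <- content_stage(subjects, assignment, seg_sub, seg_ca1,
                             pc, cfg)
  }
  list(config = cfg, anatomy = anatomy, tmaps = tmaps,
       assignment = assignment, accuracy = acc,
       segmentation = list(SUB = seg_sub, CA1 = seg_ca1),
       tables = tables, gradient_report = gradient_report,
       group_profiles = group_profiles, content = content)
}

#' @noRd
corr_z <- function(Y, seed_u) {
  # Fisher-z correlations between the columns of Y and the vector seed_u
  sc <- seed_u - mean(seed_u)
  Yc <- sweep(Y, 2L, colMeans(Y))
  den <- sqrt(colSums(Yc^2)) * sqrt(sum(sc^2))
  r <- ifelse(den > 0, as.vector(crossprod(Yc, sc)) / den, 0)
  fisher_z(r)
}

#' @noRd
content_stage <- function(subjects, assignment, seg_sub, seg_ca1, pc, cfg) {
  subj_ids <- sprintf("sub%02d", seq_along(subjects))
  ec_rows <- list()
  seg_tbls <- list(SUB = list(), CA1 = list())
  for (s in seq_along(subjects)) {
    proc <- subjects[[s]]$proc
    maps <- list(scene = proc$contrast_scene, object = proc$contrast_object)
    for (cond in names(maps)) {
      for (k in seq_along(SOURCE_NAMES)) {
        vox <- which(assignment$label == k)
        ec_rows[[paste(s, cond, k)]] <- data.frame(
          subject = subj_ids[s], condition = cond,
          unit = paste0("EC_", SOURCE_NAMES[k]),
          value = mean(maps[[cond]][vox]), stringsAsFactors = FALSE)
      }
      for (region in c("SUB", "CA1")) {
        seg <- if (region == "SUB") seg_sub else seg_ca1
        prof <- extract_segment_profile(maps[[cond]], seg)
        seg_tbls[[region]][[paste(s, cond)]] <- data.frame(
          subject = subj_ids[s], condition = cond,
          unit = paste0("seg", seq_along(prof)), value = prof,
          stringsAsFactors = FALSE)
      }
    }
  }
  ec_table <- do.call(rbind, ec_rows)
  sub_table <- do.call(rbind, seg_tbls$SUB)
  ca1_table <- do.call(rbind, seg_tbls$CA1)
  rownames(ec_table) <- rownames(sub_table) <- rownames(ca1_table) <- NULL
  list(ec_table = ec_table, sub_table = sub_table, ca1_table = ca1_table,
       ec_report = content_bias_test(ec_table, q = cfg$fdr_q),
       sub_report = content_bias_test(sub_table, q = cfg$fdr_q),
       ca1_report = content_bias_test(ca1_table, q = cfg$fdr_q))
}

#' Group-mean transversal slope per seed
#'
#' Least-squares slope of the group-mean estimate against segment index
#' (proximal to distal), one value per measure. The sign summarizes the
#' direction of the transversal gradient.
#'
#' @param table long estimate table (`subject`, `measure`, `segment`,
#'   `value`).
#' @return named numeric vector of slopes.
#' @export
profile_slopes <- function(table) {
  agg <- stats::aggregate(value ~ measure + segment, data = table,
                          FUN = mean)
  vapply(split(agg, agg$measure), function(d)
    unname(stats::coef(stats::lm(value ~ segment, data = d))[2]),
    numeric(1))
}

#' Run the pipeline from a configuration file
#'
#' Reads a YAML (or JSON) configuration, runs [run_phantom_pipeline()],
#' and writes all artifacts: T-maps and the seed label map as NIfTI-1,
#' segmentations as integer NIfTI label maps, estimate tables as TSV,
#' reports and a provenance record as JSON, and a plain-text log. Rerun
#' with the same configuration is bit-identical.
#'
#' @param config a [pipeline_config()], or the path of a YAML/JSON file
#'   whose top-level keys override [pipeline_config()] defaults (with
#'   `phantom` overriding [phantom_config()] defaults).
#' @param out_dir artifact directory (created if missing).
#' @return the [run_phantom_pipeline()] result, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else load_pipeline_config(config)
  res <- run_phantom_pipeline(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (src in names(res$tmaps)) {
    tv <- res$tmaps[[src]]$t_values
    tv[!is.finite(tv)] <- 0
    write_map(tv, file.path(out_dir, sprintf("tmap_%s.nii.gz", src)))
  }
  write_map(res$assignment$label, file.path(out_dir, "ec_seed_labels.nii.gz"))
  write_map(res$segmentation$SUB$segment,
            file.path(out_dir, "sub_segments.nii.gz"))
  write_map(res$segmentation$CA1$segment,
            file.path(out_dir, "ca1_segments.nii.gz"))
  write_estimate_table(res$tables$SUB,
                       file.path(out_dir, "sub_connectivity_table.tsv"))
  write_estimate_table(res$tables$CA1,
                       file.path(out_dir, "ca1_connectivity_table.tsv"))
  counts <- vapply(seq_along(res$assignment$sources), function(k)
    sum(res$assignment$label == k), 1L)
  jsonlite::write_json(
    list(seed_voxel_counts = as.list(stats::setNames(counts,
                                                     res$assignment$sources)),
         parcellation_accuracy = res$accuracy,
         gradient = report_to_list(res$gradient_report),
         content = if (!is.null(res$content))
           lapply(res$content[c("ec_report", "sub_report", "ca1_report")],
                  content_report_to_list)),
    file.path(out_dir, "reports.json"),
    auto_unbox = TRUE, digits = NA, null = "null")
  jsonlite::write_json(
    list(config_hash = config_hash(cfg),
         rng_seed = cfg$phantom$rng_seed,
         r_version = as.character(getRversion()),
         package_version = as.character(utils::packageVersion("ehconn"))),
    file.path(out_dir, "provenance.json"), auto_unbox = TRUE)
  writeLines(c(res$gradient_report$log,
               if (!is.null(res$content))
                 unlist(lapply(res$content[c("ec_report", "sub_report",
                                             "ca1_report")],
                               function(rp) rp$log))),
             file.path(out_dir, "pipeline.log"))
  invisible(res)
}

#' @noRd
load_pipeline_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
         else yaml::read_yaml(path)
  ph_args <- raw$phantom %||% list()
  if (!is.null(ph_args$grid_dims)) ph_args$grid_dims <-
    as.integer(unlist(ph_args$grid_dims))
  if (!is.null(ph_args$band_hz)) ph_args$band_hz <-
    as.numeric(unlist(ph_args$band_hz))
  phantom <- do.call(phantom_config, ph_args)
  top <- raw[setdiff(names(raw), "phantom")]
  if (!is.null(top$band_hz)) top$band_hz <- as.numeric(unlist(top$band_hz))
  do.call(pipeline_config, c(top, list(phantom = phantom)))
}

#' @noRd
config_hash <- function(cfg) {
  # deterministic digest of the configuration (rlang is available via
  # the tidyverse stack, but a simple checksum avoids the dependency)
  s <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA, force = TRUE)
  sum(utf8ToInt(as.character(s)) * seq_len(nchar(as.character(s)))) %%
    2147483647
}

#' @noRd
report_to_list <- function(rep) {
  list(stage1 = rep$stage1, stage2 = rep$stage2, stage3 = rep$stage3,
       log = rep$log)
}

#' @noRd
content_report_to_list <- function(rep) {
  list(interaction = rep$interaction, posthoc = rep$posthoc, log = rep$log)
}
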