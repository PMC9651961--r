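# Synthetic phantom: latent sources, anatomy, events, subject synthesis.

test_that("latent sources are standardized, band-limited and deterministic", {
  L1 <- make_latent_sources(300, 2.4, c(0.01, 0.1), seed = 1)
  L2 <- make_latent_sources(300, 2.4, c(0.01, 0.1), seed = 1)
  expect_identical(L1, L2)
  expect_equal(dim(L1), c(4L, 300L))
  expect_lt(max(abs(rowMeans(L1))), 1e-10)
  expect_lt(max(abs(rowSums(L1^2) / 300 - 1)), 1e-10)
  # FFT power-ratio oracle: fraction of spectral power inside the band
  x <- L1[1, ]
  pw <- Mod(fft(x))^2
  f <- (seq_along(x) - 1) / (length(x) * 2.4)
  f <- pmin(f, 1 / 2.4 - f)
  in_band <- f >= 0.01 & f <= 0.1
  expect_gte(sum(pw[in_band]) / sum(pw[-1]), 0.95)
  L3 <- make_latent_sources(300, 2.4, c(0.01, 0.1), seed = 2)
  expect_false(identical(L1, L3))
  expect_error(make_latent_sources(300, 2.4, c(0.01, 0.3), seed = 1),
               class = "ehconn_invalid_config")
})

test_that("phantom anatomy places disjoint ROIs with full transversal coverage", {
  an <- build_phantom_anatomy(phantom_config())
  # each labelled voxel belongs to exactly one ROI by construction of the
  # single label array; check expected sizes and presence
  counts <- table(an$labels[an$labels > 0])
  expect_equal(unname(counts[as.character(an$legend[c("RSC", "PHC", "A35", "A36")])]),
               rep(18L, 4), ignore_attr = TRUE)
  expect_equal(unname(counts[as.character(an$legend["EC"])]), 256L,
               ignore_attr = TRUE)
  expect_equal(sum(an$ec_sublabel > 0), 256L)
  expect_equal(as.vector(table(an$ec_sublabel[an$ec_sublabel > 0])),
               rep(64L, 4))
  # every SUB/CA1 voxel carries a transversal position
  for (roi in c("SUB", "CA1")) {
    in_roi <- an$labels == an$legend[[roi]]
    expect_false(anyNA(an$transversal_position[in_roi]))
  }
  # SUB sheet is 10 voxels wide: positions take 10 evenly spaced values
  sub_idx <- which(an$labels == an$legend[["SUB"]], arr.ind = TRUE)
  one_row <- sub_idx[sub_idx[, 2] == sub_idx[1, 2] &
                       sub_idx[, 3] == sub_idx[1, 3], , drop = FALSE]
  pos <- an$transversal_position[one_row]
  expect_equal(sort(pos), seq(0, 1, length.out = 10))
  # weights are finite everywhere
  expect_true(all(is.finite(an$weights)))
  expect_error(build_phantom_anatomy(phantom_config(grid_dims = c(8, 8, 8))),
               class = "ehconn_invalid_config")
})

test_that("event tables alternate scene/object blocks inside baseline brackets", {
  cfg <- phantom_config()
  ev <- make_event_table(cfg)
  expect_true(all(ev$duration == 3.0))
  expect_true(all(diff(ev$onset) > 0))
  expect_true(all(ev$onset + ev$duration <=
                    cfg$n_volumes_per_run * cfg$tr_seconds))
  expect_setequal(unique(ev$condition), c("baseline", "scene", "object"))
  expect_equal(ev$condition[1:10], rep("baseline", 10))
  expect_equal(tail(ev$condition, 10), rep("baseline", 10))
  ev0 <- make_event_table(cfg, n_blocks = 0)
  expect_equal(unique(ev0$condition), "baseline")
  expect_error(make_event_table(cfg, n_blocks = 1000),
               class = "ehconn_invalid_config")
})

test_that("zero-noise voxels reproduce their latent drivers exactly", {
  cfg <- phantom_config(noise_sd = 0, spike_rate = 0, rng_seed = 3)
  an <- build_phantom_anatomy(cfg)
  ev0 <- make_event_table(cfg, n_blocks = 0)   # baseline only, amplitude 0
  subj <- synthesize_subject(an, list(ev0), cfg, subject_seed = 5)
  Y <- matrix(subj$runs[[1]]$data,
              nrow = prod(cfg$grid_dims)) - cfg$baseline_intensity
  for (k in 1:4) {
    vox <- which(an$ec_sublabel == k)[1]
    expect_equal(Y[vox, ], unname(subj$latents[[1]][k, ]), tolerance = 1e-12)
  }
  # distal SUB voxel: PHC weight (1.0) dominates A35 weight (0.2)
  distal <- which(an$labels == an$legend[["SUB"]] &
                    an$transversal_position == 1)[1]
  lat <- subj$latents[[1]]
  expect_gt(cor(Y[distal, ], lat["PHC", ]), cor(Y[distal, ], lat["A35", ]))
})

test_that("noise attenuates latent correlation as w / sqrt(w^2 + 1)", {
  cfg <- phantom_config(noise_sd = 1, spike_rate = 0,
                        n_volumes_per_run = 600, rng_seed = 4)
  an <- build_phantom_anatomy(cfg)
  ev0 <- make_event_table(cfg, n_blocks = 0)
  subj <- synthesize_subject(an, list(ev0), cfg, subject_seed = 9)
  Y <- matrix(subj$runs[[1]]$data, nrow = prod(cfg$grid_dims))
  # EC voxel has unit weight on its own latent: expect r near 1/sqrt(2)
  rs <- sapply(1:4, function(k) {
    vox <- which(an$ec_sublabel == k)[1:5]
    mean(apply(Y[vox, , drop = FALSE], 1L,
               function(y) cor(y, subj$latents[[1]][k, ])))
  })
  expect_true(all(abs(rs - 1 / sqrt(2)) < 0.05))
})

test_that("subject synthesis is bit-identical under a fixed seed", {
  cfg <- phantom_config(n_subjects = 2, n_volumes_per_run = 130,
                        rng_seed = 6)
  g1 <- simulate_group(cfg)
  g2 <- simulate_group(cfg)
  expect_identical(g1$subjects[[1]]$runs[[1]]$data,
                   g2$subjects[[1]]$runs[[1]]$data)
  expect_identical(g1$subjects[[2]]$nuisance, g2$subjects[[2]]$nuisance)
  expect_false(identical(g1$subjects[[1]]$runs[[1]]$data,
                         g1$subjects[[2]]$runs[[1]]$data))
})

test_that("phantom datasets round-trip through the on-disk formats", {
  dir <- withr::local_tempdir()
  cfg <- phantom_config(n_subjects = 1, n_volumes_per_run = 130,
                        rng_seed = 8)
  group <- simulate_group(cfg)
  write_phantom(group, dir)
  lm <- read_label_map(file.path(dir, "labels.nii.gz"),
                       file.path(dir, "ground_truth.json"))
  expect_equal(lm$labels, group$anatomy$labels, ignore_attr = TRUE)
  expect_equal(lm$coronal_axis, 2L)
  run <- read_bold_run(file.path(dir, "sub-01_run-01_bold.nii.gz"))
  expect_equal(run$tr, cfg$tr_seconds, tolerance = 1e-6)
  expect_equal(array(run$data, dim = dim(run$data)),
               group$subjects[[1]]$runs[[1]]$data, tolerance = 1e-6,
               ignore_attr = TRUE)
  ev <- read_events(file.path(dir, "run-01_events.tsv"))
  expect_equal(ev, group$events[[1]], ignore_attr = TRUE)
  mp <- read_motion(file.path(dir, "sub-01_run-01_motion.tsv"))
  expect_equal(unname(mp), unname(group$subjects[[1]]$nuisance[[1]]$motion),
               tolerance = 1e-12)
})
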