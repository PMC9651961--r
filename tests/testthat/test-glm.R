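# Task GLM: HRF, spike detection, design construction, OLS fit,
# contrasts, Gaussian smoothing.

test_that("canonical HRF peaks near 5 s, sums to 1, subsamples consistently", {
  h_fine <- canonical_hrf(0.1, 32)
  t_fine <- seq(0, 32, by = 0.1)
  # dense evaluation of the double-gamma closed form as oracle
  oracle <- dgamma(t_fine, 6, 1) - dgamma(t_fine, 16, 1) / 6
  peak <- t_fine[which.max(oracle)]
  expect_gte(peak, 4.5); expect_lte(peak, 5.5)
  expect_equal(t_fine[which.max(h_fine)], peak)
  expect_equal(sum(h_fine), 1, tolerance = 1e-9)
  # tr = 2.4 kernel proportional to the 0.1 s kernel at matching times
  h_coarse <- canonical_hrf(2.4, 48)
  t_coarse <- seq(0, 48, by = 2.4)
  sub <- canonical_hrf(0.1, 48)[round(t_coarse / 0.1) + 1]
  expect_equal(h_coarse / sum(h_coarse), sub / sum(sub), tolerance = 1e-9)
})

make_run <- function(Y, dims3 = NULL, tr = 2.4) {
  if (is.null(dims3)) dims3 <- c(nrow(Y), 1, 1)
  bold_run(array(Y, dim = c(dims3, ncol(Y))), tr)
}

test_that("spike detection flags intensity and motion outliers only", {
  n_t <- 20
  Y <- matrix(100, nrow = 4, ncol = n_t)
  motion <- matrix(0, n_t, 6)
  expect_identical(detect_spikes(make_run(Y), motion), integer(0))
  Y2 <- Y; Y2[, 7] <- 103  # +3% global mean
  expect_identical(detect_spikes(make_run(Y2), motion), c(7L, 8L))
  # the drop back at volume 8 also crosses the 1.3% threshold
  m2 <- motion; m2[10, 1:2] <- 0.2   # FD at volume 10 = 0.4 mm
  expect_true(10L %in% detect_spikes(make_run(Y), m2))
  expect_true(11L %in% detect_spikes(make_run(Y), m2))  # return jump
  m3 <- motion; m3[10, 1] <- 0.25    # FD 0.25 < 0.3
  expect_identical(detect_spikes(make_run(Y), m3), integer(0))
  expect_error(detect_spikes(make_run(Y[, 1, drop = FALSE]),
                             motion[1, , drop = FALSE]),
               class = "ehconn_invalid_input")
})

test_that("design matrices hold condition, motion, spike and intercept columns", {
  n_t <- 50; tr <- 2.4
  motion <- matrix(rnorm(n_t * 6, sd = 0.01), n_t, 6)
  X0 <- build_design(NULL, list(motion = motion, spikes = integer(0)),
                     n_t, tr)
  expect_equal(colnames(X0), c(paste0("motion", 1:6), "intercept"))
  ev <- data.frame(onset = 12, duration = 3, condition = "scene")
  X1 <- build_design(ev, list(motion = motion, spikes = 7L), n_t, tr)
  expect_equal(X1[, "scene"], condition_regressor(ev, "scene", n_t, tr))
  expect_lt(max(abs(X1[1:5, "scene"])), 1e-12)   # nothing before onset
  expect_gt(max(X1[, "scene"]), 0)
  expect_equal(unname(X1[, "spike7"]), as.numeric(seq_len(n_t) == 7))
  # duplicated motion column makes the design collinear
  bad_motion <- motion; bad_motion[, 2] <- bad_motion[, 1]
  expect_error(build_design(NULL, list(motion = bad_motion,
                                       spikes = integer(0)), n_t, tr),
               class = "ehconn_invalid_input")
})

test_that("OLS fit recovers exact signals and orthogonal residuals", {
  n_t <- 40; tr <- 2.4
  ev <- data.frame(onset = c(12, 48), duration = 3,
                   condition = c("scene", "scene"))
  X <- build_design(ev, list(motion = NULL, spikes = integer(0)), n_t, tr)
  Y <- matrix(rnorm(8 * n_t), nrow = 8)
  Y[1, ] <- 2 * X[, "scene"]
  fit <- fit_glm(make_run(Y, c(2, 2, 2)), X)
  expect_equal(unname(fit$betas[1, "scene"]), 2, tolerance = 1e-10)
  resid <- matrix(fit$residual_run$data, nrow = 8)
  expect_lt(max(abs(resid[1, ])), 1e-10)
  expect_lt(max(abs(resid %*% X)), 1e-8)
  Ybad <- Y; Ybad[3, 5] <- NA
  expect_error(fit_glm(make_run(Ybad, c(2, 2, 2)), X),
               class = "ehconn_invalid_input")
})

test_that("five-timepoint fit matches the normal-equations oracle", {
  X <- cbind(a = c(1, 2, 3, 4, 5), b = c(1, 0, 1, 0, 1))
  Y <- matrix(c(2.3, 1.1, 4.2, 3.3, 6.1,
                0.5, 0.7, 0.2, 0.9, 0.4), nrow = 2, byrow = TRUE)
  fit <- fit_glm(make_run(Y, c(2, 1, 1)), X)
  beta_oracle <- solve(t(X) %*% X, t(X) %*% t(Y))
  expect_equal(unname(fit$betas), unname(t(beta_oracle)), tolerance = 1e-10)
})

test_that("contrasts are linear in the weights", {
  X <- cbind(scene = c(0, 1, 2, 1, 0, 0), baseline = c(1, 0, 0, 0, 1, 0),
             intercept = 1)
  Y <- matrix(rnorm(4 * 6), nrow = 4)
  Y[2, ] <- 2 * X[, "scene"]   # baseline beta 0 at this voxel
  fit <- fit_glm(make_run(Y, c(4, 1, 1)), X)
  cm <- glm_contrast(fit, c(scene = 1, baseline = -1))
  expect_equal(cm$values[2, 1, 1], 2, tolerance = 1e-10)
  expect_equal(glm_contrast(fit, c(scene = 0, baseline = 0))$values,
               array(0, c(4, 1, 1)))
  w1 <- c(scene = 1); w2 <- c(scene = 0.5, baseline = -1)
  expect_equal(glm_contrast(fit, c(scene = 1.5, baseline = -1))$values,
               glm_contrast(fit, w1)$values + glm_contrast(fit, w2)$values,
               tolerance = 1e-12)
  expect_error(glm_contrast(fit, c(nosuch = 1)),
               class = "ehconn_invalid_input")
})

test_that("Gaussian smoothing preserves constants and matches the kernel ratio", {
  vol <- array(rnorm(20^3), dim = c(20, 20, 20))
  expect_identical(smooth_volume(vol, 0), vol)
  const <- array(3.7, dim = c(12, 12, 12))
  expect_equal(smooth_volume(const, 1.5), const, tolerance = 1e-9)
  delta <- array(0, dim = c(15, 15, 15)); delta[8, 8, 8] <- 1
  sm <- smooth_volume(delta, 1.5, voxel_size_mm = 1)
  sigma <- 1.5 / (2 * sqrt(2 * log(2)))   # 0.6370
  expect_equal(sm[9, 8, 8] / sm[8, 8, 8], exp(-1 / (2 * sigma^2)),
               tolerance = 1e-3)
  expect_equal(sum(sm), 1, tolerance = 1e-9)  # interior mass conserved
})

test_that("zero-noise task voxels recover configured amplitudes exactly", {
  # all latent weights zeroed in SUB so its voxels carry task signal only
  zero_w <- lapply(default_gradient_weights(), function(region)
    lapply(region, function(w) c(0, 0)))
  amps <- default_condition_amplitudes()
  amps$SUB <- list(scene = 1.0, object = 0.3, baseline = 0)
  cfg <- phantom_config(noise_sd = 0, spike_rate = 0,
                        gradient_weights = zero_w,
                        condition_amplitudes = amps,
                        n_volumes_per_run = 130, rng_seed = 13)
  an <- build_phantom_anatomy(cfg)
  ev <- make_event_table(cfg)
  subj <- synthesize_subject(an, list(ev), cfg, subject_seed = 3)
  X <- build_design(ev, list(motion = NULL, spikes = integer(0)),
                    cfg$n_volumes_per_run, cfg$tr_seconds)
  fit <- fit_glm(subj$runs[[1]], X)
  cm <- glm_contrast(fit, c(scene = 1, baseline = -1))
  sub_vox <- which(an$labels == an$legend[["SUB"]])
  expect_equal(unname(cm$values[sub_vox]), rep(1.0, length(sub_vox)),
               tolerance = 1e-8)
  cm_ob <- glm_contrast(fit, c(object = 1, baseline = -1))
  expect_equal(unname(cm_ob$values[sub_vox]), rep(0.3, length(sub_vox)),
               tolerance = 1e-8)
})

test_that("a spike regressor zeroes the corrupted volume's residuals", {
  set.seed(14)
  n_t <- 30
  Y <- matrix(rnorm(5 * n_t), nrow = 5)
  Y[, 9] <- Y[, 9] + 50
  run <- bold_run(array(Y, dim = c(5, 1, 1, n_t)), 2.4)
  X <- build_design(NULL, list(motion = NULL, spikes = 9L), n_t, 2.4)
  fit <- fit_glm(run, X)
  resid <- matrix(fit$residual_run$data, nrow = 5)
  expect_lt(max(abs(resid[, 9])), 1e-10)
})
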