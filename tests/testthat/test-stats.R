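# RM-ANOVA, BH-FDR, paired t, hierarchical cascade, content-bias test.

test_that("rm_anova matches the brute-force sums-of-squares oracle", {
  for (seed in 1:4) {
    dims <- list(c(8, 4, 5), c(5, 2, 2), c(6, 3, 4))[[(seed %% 3) + 1]]
    tbl <- random_rm_table(dims[1], dims[2], dims[3], seed = seed)
    got <- rm_anova(tbl, within = c("measure", "segment"))
    oracle <- ss_rm_anova_oracle(tbl, c("measure", "segment"))
    for (e in oracle$effect) {
      g <- got[got$effect == e, ]
      o <- oracle[oracle$effect == e, ]
      expect_equal(g$F, o$F, tolerance = 1e-8)
      expect_equal(c(g$df_num, g$df_den), c(o$df_num, o$df_den),
                   ignore_attr = TRUE)
    }
  }
  # one-way case
  tbl1 <- random_rm_table(7, 5, seed = 9)
  got1 <- rm_anova(tbl1, within = "measure")
  o1 <- ss_rm_anova_oracle(tbl1, "measure")
  expect_equal(got1$F, o1$F, tolerance = 1e-8)
  expect_equal(c(got1$df_num, got1$df_den), c(o1$df_num, o1$df_den),
               ignore_attr = TRUE)
})

test_that("rm_anova handles degenerate and incomplete tables", {
  tbl <- random_rm_table(4, 3, 2, seed = 2)
  tbl$value <- rep(tapply(tbl$value, tbl$subject, mean)[tbl$subject])
  res <- rm_anova(tbl, within = c("measure", "segment"))
  expect_true(all(res$F == 0))
  expect_true(all(res$p == 1))
  expect_error(rm_anova(tbl[-1, ], within = c("measure", "segment")),
               class = "ehconn_invalid_input")
})

test_that("within-subject degrees of freedom match the design sizes", {
  # 4 seeds x 5 segments, n = 32 -> interaction df (12, 372)
  t45 <- random_rm_table(32, 4, 5, seed = 3)
  r45 <- rm_anova(t45, within = c("measure", "segment"))
  i45 <- r45[r45$effect == "measure x segment", ]
  expect_identical(c(i45$df_num, i45$df_den), c(12L, 372L))
  # 4 x 3 -> (6, 186)
  t43 <- random_rm_table(32, 4, 3, seed = 4)
  r43 <- rm_anova(t43, within = c("measure", "segment"))
  i43 <- r43[r43$effect == "measure x segment", ]
  expect_identical(c(i43$df_num, i43$df_den), c(6L, 186L))
  # condition x 4 regions (2 x 4) -> (3, 93)
  t24 <- random_rm_table(32, 2, 4, seed = 5)
  r24 <- rm_anova(t24, within = c("measure", "segment"))
  i24 <- r24[r24$effect == "measure x segment", ]
  expect_identical(c(i24$df_num, i24$df_den), c(3L, 93L))
  # one-way 5 segments, n = 32 -> (4, 124)
  t5 <- random_rm_table(32, 5, seed = 6)
  r5 <- rm_anova(t5, within = "measure")
  expect_identical(c(r5$df_num, r5$df_den), c(4L, 124L))
})

test_that("BH step-up flags match the exhaustive definition", {
  r <- fdr_bh(c(0.01), 0.05)
  expect_true(r$significant)
  r2 <- fdr_bh(c(0.01, 0.02, 0.04, 0.5), 0.05)
  expect_equal(r2$significant, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(fdr_bh(rep(1, 5))$significant, rep(FALSE, 5))
  expect_equal(fdr_bh(numeric(0))$significant, logical(0))
  set.seed(7)
  for (i in 1:25) {
    m <- sample(1:12, 1)
    p <- runif(m)^sample(1:3, 1)
    q <- sample(c(0.01, 0.05, 0.1), 1)
    expect_equal(fdr_bh(p, q)$significant, bh_stepup_oracle(p, q))
  }
  expect_error(fdr_bh(c(0.5, 1.2)), class = "ehconn_invalid_input")
})

test_that("paired t statistics match hand computation on differences", {
  r <- paired_t(c(1, 2, 3), c(0, 1, 1))
  expect_equal(r$t, 4, tolerance = 1e-12)
  expect_equal(r$df, 2)
  expect_equal(r$mean_diff, 4 / 3, tolerance = 1e-12)
  r_swap <- paired_t(c(0, 1, 1), c(1, 2, 3))
  expect_equal(r_swap$t, -r$t)
  expect_equal(r_swap$p, r$p)
  expect_error(paired_t(c(1, 2, 3), c(0, 1, 2)),
               class = "ehconn_degenerate")
  expect_error(paired_t(1, 2), class = "ehconn_invalid_input")
})

gradient_tables <- function(n_sub = 10, effect = 1, seed = 1) {
  # two regions, four seeds x five segments; opposing PHC/A35 gradients
  # of the given effect size in SUB only
  set.seed(seed)
  slopes_sub <- c(EC_RSC = -0.5, EC_PHC = 1, EC_A35 = -1, EC_A36 = 0) *
    effect
  mk <- function(slopes) {
    g <- expand.grid(subject = sprintf("s%02d", seq_len(n_sub)),
                     measure = names(slopes), segment = 1:5,
                     stringsAsFactors = FALSE)
    g$value <- slopes[g$measure] * (g$segment - 3) / 2 +
      rnorm(nrow(g), sd = 0.5)
    g
  }
  list(SUB = mk(slopes_sub), CA1 = mk(slopes_sub * 0))
}

test_that("the cascade finds imposed opposing gradients and stops on null", {
  tbls <- gradient_tables(n_sub = 12, effect = 1, seed = 10)
  rep <- hierarchical_gradient_test(tbls, q = 0.05)
  expect_true(rep$stage1$significant[rep$stage1$region == "SUB"])
  s2 <- rep$stage2$SUB
  expect_true(all(s2$significant[s2$seed %in% c("EC_PHC", "EC_A35")]))
  s3 <- rep$stage3$SUB
  phc_a35 <- s3[(s3$seed_a == "EC_PHC" & s3$seed_b == "EC_A35") |
                  (s3$seed_a == "EC_A35" & s3$seed_b == "EC_PHC"), ]
  expect_true(phc_a35$significant)
  expect_true(length(rep$log) >= 2)
  # single-seed table is rejected
  one_seed <- tbls
  one_seed$SUB <- one_seed$SUB[one_seed$SUB$measure == "EC_PHC", ]
  expect_error(hierarchical_gradient_test(one_seed),
               class = "ehconn_invalid_input")
})

test_that("stage 1 keeps its size under the null across table simulations", {
  hits <- 0
  for (i in 1:100) {
    tbls <- gradient_tables(n_sub = 8, effect = 0, seed = 100 + i)
    rep <- hierarchical_gradient_test(tbls, q = 0.05)
    hits <- hits + any(rep$stage1$significant)
  }
  expect_lte(hits / 100, 0.10)
})

test_that("content test flags scene bias only where imposed", {
  set.seed(11)
  n_sub <- 12
  g <- expand.grid(subject = sprintf("s%02d", seq_len(n_sub)),
                   condition = c("scene", "object"),
                   unit = paste0("seg", 1:5), stringsAsFactors = FALSE)
  bias <- ifelse(g$condition == "scene" & g$unit %in% c("seg4", "seg5"),
                 1, 0)
  g$value <- bias + rnorm(nrow(g), sd = 0.4)
  rep <- content_bias_test(g, q = 0.05)
  expect_lt(rep$interaction$p, 0.05)
  expect_setequal(rep$posthoc$unit[rep$posthoc$scene_gt_object],
                  c("seg4", "seg5"))
  # identical scene and object values: interaction F = 0, no post-hocs
  g0 <- g
  v <- g0$value[g0$condition == "scene"]
  g0$value[g0$condition == "object"] <- v
  rep0 <- content_bias_test(g0, q = 0.05)
  expect_equal(rep0$interaction$F, 0)
  expect_null(rep0$posthoc)
  expect_error(content_bias_test(transform(g, condition = "x")),
               class = "ehconn_invalid_input")
})

test_that("Greenhouse-Geisser correction shrinks the effective df", {
  tbl <- gradient_tables(n_sub = 10, effect = 0.6, seed = 12)$SUB
  plain <- rm_anova(tbl, within = c("measure", "segment"))
  gg <- rm_anova(tbl, within = c("measure", "segment"), gg = TRUE)
  expect_equal(plain$F, gg$F)            # F unchanged, only p corrected
  i_p <- plain[plain$effect == "measure x segment", "p"]
  i_g <- gg[gg$effect == "measure x segment", "p"]
  expect_gte(i_g, i_p)
})
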