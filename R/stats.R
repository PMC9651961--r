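# Hierarchical repeated-measures ANOVA testing cascade on segment
# estimate tables, Benjamini-Hochberg FDR correction, and post-hoc paired
# t-tests for connectivity-gradient and content-bias questions.

#' Repeated-measures ANOVA with one or two within-subject factors
#'
#' Classical univariate within-subject decomposition: each effect is
#' tested against its own subject-by-effect error stratum
#' (`aov(value ~ A * B + Error(subject/(A * B)))`). No sphericity
#' correction is applied by default, so a factors `a x b` design with `n`
#' subjects has interaction degrees of freedom
#' `((a-1)(b-1), (a-1)(b-1)(n-1))`. Effects with zero effect variance
#' return `F = 0`, `p = 1`.
#'
#' @param table long-format data.frame with a subject column, the within
#'   factor columns and a value column; must be complete and balanced
#'   (exactly one value per subject x cell).
#' @param within character vector of one or two factor column names.
#' @param dv value column name (default `"value"`).
#' @param subject subject column name (default `"subject"`).
#' @param gg apply the Greenhouse-Geisser epsilon correction to the
#'   degrees of freedom and p-values (default off, matching the reporting
#'   convention of the emulated analysis).
#' @return data.frame with columns `effect`, `F`, `df_num`, `df_den`, `p`.
#' @export
rm_anova <- function(table, within, dv = "value", subject = "subject",
                     gg = FALSE) {
  stopifnot(length(within) %in% 1:2)
  df <- data.frame(.subj = factor(table[[subject]]),
                   .y = table[[dv]])
  for (i in seq_along(within))
    df[[paste0(".f", i)]] <- factor(table[[within[i]]])
  cells <- table(df[, c(".subj", paste0(".f", seq_along(within)))])
  if (any(cells != 1L))
    eh_stop("table must be complete and balanced: one value per subject x cell",
            "ehconn_invalid_input")
  if (nlevels(df$.subj) < 2L)
    eh_stop("repeated-measures ANOVA needs at least 2 subjects",
            "ehconn_invalid_input")
  fac <- paste0(".f", seq_along(within))
  rhs <- paste(fac, collapse = " * ")
  form <- stats::as.formula(paste0(".y ~ ", rhs, " + Error(.subj/(", rhs, "))"))
  fit <- stats::aov(form, data = df)
  out <- list()
  for (stratum in summary(fit)) {
    tab <- stratum[[1]]
    rn <- trimws(rownames(tab))
    eff_rows <- rn[rn != "Residuals"]
    if (!length(eff_rows)) next
    res_row <- tab[which(rn == "Residuals"), ]
    for (e in eff_rows) {
      row <- tab[which(trimws(rownames(tab)) == e), ]
      ss_eff <- row[["Sum Sq"]]
      ss_err <- res_row[["Sum Sq"]]
      df_num <- as.integer(row[["Df"]])
      df_den <- as.integer(res_row[["Df"]])
      f_val <- if (ss_eff <= 1e-12 * max(1, ss_err)) 0
               else (ss_eff / df_num) / (ss_err / df_den)
      name <- e
      for (i in seq_along(within))
        name <- gsub(paste0(".f", i), within[i], name, fixed = TRUE)
      name <- gsub(":", " x ", name, fixed = TRUE)
      eps <- 1
      if (gg && df_num > 1) {
        eps <- gg_epsilon(df, e, within)
      }
      p_val <- if (f_val == 0) 1 else
        stats::pf(f_val, df_num * eps, df_den * eps, lower.tail = FALSE)
      out[[name]] <- data.frame(effect = name, F = f_val,
                                df_num = df_num, df_den = df_den,
                                p = p_val, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @noRd
gg_epsilon <- function(df, eff, within) {
  # Greenhouse-Geisser epsilon from the covariance of the (possibly
  # collapsed) subject x condition matrix for the given effect
  fac <- trimws(strsplit(eff, ":")[[1]])
  df$.cell <- interaction(df[fac], drop = TRUE)
  wide <- stats::aggregate(.y ~ .subj + .cell, data = df, FUN = mean)
  M <- stats::reshape(wide, idvar = ".subj", timevar = ".cell",
                      direction = "wide")[, -1, drop = FALSE]
  S <- stats::cov(as.matrix(M))
  k <- ncol(S)
  C <- diag(k) - 1 / k
  SC <- C %*% S %*% C
  ev <- Re(eigen(SC, only.values = TRUE)$values)
  ev <- ev[ev > 1e-12]
  sum(ev)^2 / (length(ev) * sum(ev^2))
}

#' Benjamini-Hochberg FDR step-up procedure
#'
#' Rejects the `k` smallest p-values where
#' `k = max { i : p_(i) <= i * q / m }`, and returns the standard
#' cumulative-minimum adjusted p-values.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @param q target false discovery rate (default 0.05).
#' @return list with `significant` (logical, in input order) and `p_adj`.
#' @export
fdr_bh <- function(p_values, q = 0.05) {
  if (length(p_values) == 0L)
    return(list(significant = logical(0), p_adj = numeric(0)))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    eh_stop("p-values must lie in [0, 1]", "ehconn_invalid_input")
  p_adj <- stats::p.adjust(p_values, method = "BH")
  list(significant = p_adj <= q, p_adj = p_adj)
}

#' Paired-samples t-test
#'
#' @param x,y numeric vectors of equal length (>= 2), paired by position.
#' @return list with `t`, `df`, `p` (two-sided), `mean_diff`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L)
    eh_stop("paired_t needs two equal-length vectors of length >= 2",
            "ehconn_invalid_input")
  d <- x - y
  if (stats::sd(d) < 1e-14 * max(1, mean(abs(d))))
    eh_stop("zero-variance differences: paired t statistic undefined",
            "ehconn_degenerate")
  tt <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = unname(tt$estimate))
}

#' Hierarchical gradient testing cascade
#'
#' Stage 1: per target region (e.g. subiculum, CA1), the overall
#' seed x transversal-segment interaction from a two-factor
#' repeated-measures ANOVA; p-values FDR-corrected across regions.
#' Stage 2: within each stage-1-significant region, one-way
#' repeated-measures ANOVAs across segments per seed; FDR-corrected
#' within the region. Stage 3: if at least two seeds survive stage 2,
#' pairwise seed x segment interaction ANOVAs among them (uncorrected;
#' the family for this final confirmatory stage is left as reported).
#'
#' @param tables named list: region -> long estimate table with columns
#'   `subject`, `measure` (seed), `segment`, `value`; at least 2 seeds.
#' @param q FDR level (default 0.05).
#' @return list of class `gradient_test_report`: `stage1` (data.frame with
#'   region, F, dfs, p, p_adj, significant), `stage2` (per-region
#'   data.frame), `stage3` (per-region pairwise data.frame), `log`
#'   (character vector of decisions).
#' @export
hierarchical_gradient_test <- function(tables, q = 0.05) {
  log_lines <- character()
  for (region in names(tables)) {
    if (length(unique(tables[[region]]$measure)) < 2L)
      eh_stop(sprintf("region %s has a single seed; cascade needs >= 2",
                      region),
              "ehconn_invalid_input")
  }
  stage1 <- do.call(rbind, lapply(names(tables), function(region) {
    res <- rm_anova(tables[[region]], within = c("measure", "segment"))
    inter <- res[res$effect == "measure x segment", ]
    data.frame(region = region, F = inter$F, df_num = inter$df_num,
               df_den = inter$df_den, p = inter$p, stringsAsFactors = FALSE)
  }))
  corr <- fdr_bh(stage1$p, q)
  stage1$p_adj <- corr$p_adj
  stage1$significant <- corr$significant
  log_lines <- c(log_lines, sprintf(
    "stage 1: %d region interactions FDR-corrected at q=%.3g; significant: %s",
    nrow(stage1), q,
    paste(stage1$region[stage1$significant], collapse = ", ")))
  stage2 <- list()
  stage3 <- list()
  for (region in stage1$region[stage1$significant]) {
    tbl <- tables[[region]]
    seeds <- unique(tbl$measure)
    s2 <- do.call(rbind, lapply(seeds, function(seed) {
      res <- rm_anova(tbl[tbl$measure == seed, ], within = "segment")
      data.frame(region = region, seed = seed, F = res$F,
                 df_num = res$df_num, df_den = res$df_den, p = res$p,
                 stringsAsFactors = FALSE)
    }))
    corr2 <- fdr_bh(s2$p, q)
    s2$p_adj <- corr2$p_adj
    s2$significant <- corr2$significant
    stage2[[region]] <- s2
    log_lines <- c(log_lines, sprintf(
      "stage 2 (%s): %d per-seed one-way ANOVAs FDR-corrected; significant: %s",
      region, nrow(s2), paste(s2$seed[s2$significant], collapse = ", ")))
    sig_seeds <- s2$seed[s2$significant]
    if (length(sig_seeds) >= 2L) {
      pairs <- utils::combn(sig_seeds, 2L, simplify = FALSE)
      s3 <- do.call(rbind, lapply(pairs, function(pr) {
        sub_tbl <- tbl[tbl$measure %in% pr, ]
        res <- rm_anova(sub_tbl, within = c("measure", "segment"))
        inter <- res[res$effect == "measure x segment", ]
        data.frame(region = region, seed_a = pr[1], seed_b = pr[2],
                   F = inter$F, df_num = inter$df_num,
                   df_den = inter$df_den, p = inter$p,
                   significant = inter$p <= q, stringsAsFactors = FALSE)
      }))
      stage3[[region]] <- s3
      log_lines <- c(log_lines, sprintf(
        "stage 3 (%s): %d pairwise seed x segment interactions (uncorrected)",
        region, nrow(s3)))
    } else {
      log_lines <- c(log_lines, sprintf(
        "stage 3 (%s): skipped, fewer than 2 stage-2-significant seeds",
        region))
    }
  }
  structure(list(stage1 = stage1, stage2 = stage2, stage3 = stage3,
                 q = q, log = log_lines),
            class = "gradient_test_report")
}

#' Content-bias test: condition x region/segment interaction + post-hocs
#'
#' Two-factor repeated-measures ANOVA of scene vs object estimates across
#' regions (or transversal segments). If the interaction is significant at
#' `q`, per-level paired t-tests (scene vs object) are run and
#' FDR-corrected as their own family; levels with a significantly larger
#' scene mean are flagged.
#'
#' @param table long estimate table with columns `subject`, `condition`
#'   (exactly `scene` and `object`), `unit` (region or segment), `value`.
#' @param q FDR level (default 0.05).
#' @return list of class `content_test_report`: `interaction`
#'   (data.frame), `posthoc` (data.frame or NULL), `log`.
#' @export
content_bias_test <- function(table, q = 0.05) {
  conds <- sort(unique(table$condition))
  if (!identical(conds, c("object", "scene")))
    eh_stop("content test needs exactly the conditions scene and object",
            "ehconn_invalid_input")
  res <- rm_anova(table, within = c("condition", "unit"))
  inter <- res[res$effect == "condition x unit", ]
  log_lines <- sprintf("condition x unit interaction: F(%d,%d) = %.4g, p = %.4g",
                       inter$df_num, inter$df_den, inter$F, inter$p)
  posthoc <- NULL
  if (isTRUE(inter$p <= q)) {
    units <- unique(table$unit)
    posthoc <- do.call(rbind, lapply(units, function(u) {
      sub_tbl <- table[table$unit == u, ]
      sc <- sub_tbl[sub_tbl$condition == "scene", ]
      ob <- sub_tbl[sub_tbl$condition == "object", ]
      ord <- order(sc$subject)
      tt <- paired_t(sc$value[ord], ob$value[order(ob$subject)])
      data.frame(unit = u, t = tt$t, df = tt$df, p = tt$p,
                 mean_diff = tt$mean_diff, stringsAsFactors = FALSE)
    }))
    corr <- fdr_bh(posthoc$p, q)
    posthoc$p_adj <- corr$p_adj
    posthoc$significant <- corr$significant
    posthoc$scene_gt_object <- posthoc$significant & posthoc$mean_diff > 0
    log_lines <- c(log_lines, sprintf(
      "post-hoc paired t-tests FDR-corrected; scene > object in: %s",
      paste(posthoc$unit[posthoc$scene_gt_object], collapse = ", ")))
  } else {
    log_lines <- c(log_lines,
                   "interaction not significant; post-hocs skipped")
  }
  structure(list(interaction = inter, posthoc = posthoc, q = q,
                 log = log_lines),
            class = "content_test_report")
}
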