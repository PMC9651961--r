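# Independent oracles used to cross-check the implementation.

# Brute-force classical within-subject sums-of-squares decomposition for
# one or two repeated factors; independent of rm_anova()'s aov() route.
ss_rm_anova_oracle <- function(table, within) {
  y <- table$value
  s <- factor(table$subject)
  g <- mean(y)
  n <- nlevels(s)
  m_s <- tapply(y, s, mean)
  if (length(within) == 1L) {
    a <- factor(table[[within]])
    ka <- nlevels(a)
    m_a <- tapply(y, a, mean)
    m_as <- tapply(y, list(a, s), mean)
    ss_a <- n * sum((m_a - g)^2)
    ss_err <- sum((m_as - outer(m_a, rep(1, n)) -
                     outer(rep(1, ka), m_s) + g)^2)
    df_a <- ka - 1
    df_err <- (ka - 1) * (n - 1)
    return(data.frame(effect = within,
                      F = (ss_a / df_a) / (ss_err / df_err),
                      df_num = df_a, df_den = df_err))
  }
  a <- factor(table[[within[1]]])
  b <- factor(table[[within[2]]])
  ka <- nlevels(a); kb <- nlevels(b)
  m_a <- tapply(y, a, mean); m_b <- tapply(y, b, mean)
  m_ab <- tapply(y, list(a, b), mean)
  m_as <- tapply(y, list(a, s), mean)
  m_bs <- tapply(y, list(b, s), mean)
  arr <- tapply(y, list(a, b, s), mean)
  ss_a <- kb * n * sum((m_a - g)^2)
  ss_b <- ka * n * sum((m_b - g)^2)
  ss_ab <- n * sum(sweep(sweep(m_ab - g, 1, m_a - g), 2, m_b - g)^2)
  ss_as <- kb * sum((m_as - outer(m_a, rep(1, n)) -
                       outer(rep(1, ka), m_s) + g)^2)
  ss_bs <- ka * sum((m_bs - outer(m_b, rep(1, n)) -
                       outer(rep(1, kb), m_s) + g)^2)
  resid <- arr
  for (i in 1:ka) for (j in 1:kb) for (t in 1:n)
    resid[i, j, t] <- arr[i, j, t] - m_ab[i, j] - m_as[i, t] - m_bs[j, t] +
      m_a[i] + m_b[j] + m_s[t] - g
  ss_abs <- sum(resid^2)
  eff <- function(name, ss_e, df_e, ss_r, df_r)
    data.frame(effect = name, F = (ss_e / df_e) / (ss_r / df_r),
               df_num = df_e, df_den = df_r)
  rbind(
    eff(within[1], ss_a, ka - 1, ss_as, (ka - 1) * (n - 1)),
    eff(within[2], ss_b, kb - 1, ss_bs, (kb - 1) * (n - 1)),
    eff(paste(within[1], "x", within[2]), ss_ab, (ka - 1) * (kb - 1),
        ss_abs, (ka - 1) * (kb - 1) * (n - 1)))
}

# Exhaustive evaluation of the Benjamini-Hochberg step-up definition.
bh_stepup_oracle <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  ks <- which(ps <= seq_len(m) * q / m)
  sig <- logical(m)
  if (length(ks)) sig[ord[seq_len(max(ks))]] <- TRUE
  sig
}

# Explicit OLS-residualize-then-correlate oracle for the semipartial
# correlation (seed residualized against controls + nuisance, voxel
# cleaned of nuisance only).
semipartial_oracle <- function(voxel, seed, controls = NULL,
                               nuisance = NULL) {
  res <- function(y, X) {
    if (is.null(X)) return(y)
    stats::resid(stats::lm(y ~ X))
  }
  Xs <- cbind(nuisance, controls)
  cor(res(voxel, nuisance), res(seed, Xs))
}

# Random balanced long-format table for RM-ANOVA fixtures.
random_rm_table <- function(n_sub, levels_a, levels_b = NULL, seed = 1) {
  set.seed(seed)
  if (is.null(levels_b)) {
    g <- expand.grid(subject = sprintf("s%02d", seq_len(n_sub)),
                     measure = paste0("a", seq_len(levels_a)),
                     stringsAsFactors = FALSE)
  } else {
    g <- expand.grid(subject = sprintf("s%02d", seq_len(n_sub)),
                     measure = paste0("a", seq_len(levels_a)),
                     segment = seq_len(levels_b),
                     stringsAsFactors = FALSE)
  }
  g$value <- rnorm(nrow(g))
  g
}

# Small deterministic phantom configuration for fast pipeline tests.
tiny_pipeline_config <- function(n_subjects = 6, n_volumes = 130,
                                 noise_sd = 1, rng_seed = 11,
                                 phantom_fn = phantom_config, ...) {
  pipeline_config(phantom = phantom_fn(
    n_subjects = n_subjects, n_volumes_per_run = n_volumes,
    noise_sd = noise_sd, rng_seed = rng_seed, ...))
}
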