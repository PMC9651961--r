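#!/usr/bin/env Rscript
# Transversal connectivity profiles: EC-seed-to-hippocampus semipartial
# connectivity, five equal-width subiculum bins and three 60-degree CA1
# sectors per coronal slice, and per-segment group means.
#
# Writes the subject-level estimate tables (TSV) and the group profile
# figure under results/.

# run from the repository root: Rscript analysis/03_transversal_profiles.R
source("analysis/00_config.R")
suppressPackageStartupMessages(library(ggplot2))

res <- get_pipeline_result()

tbl_dir <- ensure_dir(file.path(RESULTS_DIR, "tables"))
write_estimate_table(res$tables$SUB,
                     file.path(tbl_dir, "sub_connectivity_table.tsv"))
write_estimate_table(res$tables$CA1,
                     file.path(tbl_dir, "ca1_connectivity_table.tsv"))

cat("Group-mean Fisher-z profiles (proximal -> distal):\n")
cat("Subiculum:\n"); print(round(res$group_profiles$SUB, 3))
cat("CA1:\n"); print(round(res$group_profiles$CA1, 3))
cat("Profile slopes per seed (positive = rising toward distal):\n")
print(round(profile_slopes(res$tables$SUB), 4))

long <- rbind(cbind(res$tables$SUB, region = "Subiculum"),
              cbind(res$tables$CA1, region = "CA1"))
fig <- ggplot(long, aes(segment, value, colour = measure)) +
  stat_summary(fun = mean, geom = "line") +
  stat_summary(fun.data = mean_se, geom = "ribbon", alpha = 0.2,
               aes(fill = measure), colour = NA) +
  facet_wrap(~region, scales = "free_x") +
  labs(x = "transversal segment (proximal to distal)",
       y = "mean semipartial connectivity (Fisher z)",
       colour = "EC seed", fill = "EC seed") +
  theme_minimal()
fig_dir <- ensure_dir(file.path(RESULTS_DIR, "figures"))
ggsave(file.path(fig_dir, "transversal_profiles.png"), fig,
       width = 8, height = 4, dpi = 150)
cat("Wrote", file.path(fig_dir, "transversal_profiles.png"), "\n")
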