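#!/usr/bin/env Rscript
# Content-related activity: scene/object-versus-baseline contrasts from
# the task GLM, averaged within EC seed regions and within transversal
# SUB/CA1 segments, tested with condition x region (or x segment)
# repeated-measures ANOVAs and FDR-corrected post-hoc paired t-tests.
#
# Writes the content tables and reports under results/.

# run from the repository root: Rscript analysis/05_content_bias.R
source("analysis/00_config.R")

res <- get_pipeline_result()
ct <- res$content

show <- function(label, rep) {
  cat("\n", label, ":\n", sep = "")
  cat(sprintf("  interaction F(%d,%d) = %.2f, p = %.3g\n",
              rep$interaction$df_num, rep$interaction$df_den,
              rep$interaction$F, rep$interaction$p))
  if (!is.null(rep$posthoc)) {
    print(transform(rep$posthoc, t = round(t, 2), p = signif(p, 3),
                    p_adj = signif(p_adj, 3),
                    mean_diff = round(mean_diff, 3)))
  } else {
    cat("  interaction not significant; no post-hoc tests\n")
  }
}

show("EC seed regions (condition x region)", ct$ec_report)
show("Subiculum segments (condition x segment)", ct$sub_report)
show("CA1 segments (condition x segment)", ct$ca1_report)

tbl_dir <- ensure_dir(file.path(RESULTS_DIR, "tables"))
write.table(ct$ec_table, file.path(tbl_dir, "ec_content_table.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(ct$sub_table, file.path(tbl_dir, "sub_content_table.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(ct$ca1_table, file.path(tbl_dir, "ca1_content_table.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(
  lapply(ct[c("ec_report", "sub_report", "ca1_report")],
         function(r) list(interaction = r$interaction,
                          posthoc = r$posthoc, log = r$log)),
  file.path(RESULTS_DIR, "content_report.json"),
  auto_unbox = TRUE, digits = NA, null = "null")
cat("\nWrote", file.path(RESULTS_DIR, "content_report.json"), "\n")
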