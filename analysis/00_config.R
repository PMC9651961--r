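# Shared configuration for the analysis scripts. Source this from each
# numbered script. The pipeline result is cached under scratch/ so the
# scripts can be run independently without recomputing earlier stages.

library(ehconn)

ANALYSIS_SEED <- 2026L
RESULTS_DIR <- "results"
SCRATCH_DIR <- "scratch"

analysis_config <- function() {
  pipeline_config(phantom = phantom_config(rng_seed = ANALYSIS_SEED))
}

# Run (or reuse) the full phantom pipeline for the analysis configuration.
get_pipeline_result <- function() {
  dir.create(SCRATCH_DIR, showWarnings = FALSE)
  cache <- file.path(SCRATCH_DIR,
                     sprintf("pipeline_seed%d.rds", ANALYSIS_SEED))
  if (file.exists(cache)) return(readRDS(cache))
  res <- run_phantom_pipeline(analysis_config())
  saveRDS(res, cache)
  res
}

ensure_dir <- function(path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  path
}
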