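# Shared setup for the analysis drivers: the study-scale configuration
# (27 controls, 105 patients, published damage profile, seed 1) and a cached
# full pipeline run so the numbered scripts can be run independently without
# repeating the ~45 s computation.

library(wmdamage)

RESULTS <- "results"
dir.create(RESULTS, showWarnings = FALSE)

study_spec <- function(seed = 1) cohort_spec(seed = seed)

get_run <- function(seed = 1) {
  cache <- file.path(RESULTS, sprintf(".cache_run_seed%d.rds", seed))
  if (file.exists(cache)) return(readRDS(cache))
  res <- run_pipeline(pipeline_config(cohort_spec = study_spec(seed)))
  saveRDS(res, cache)
  res
}

say <- function(...) cat(sprintf(...), "\n")
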