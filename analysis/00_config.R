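# Shared settings for the analysis scripts. Every script re-derives the
# cohort from this seed, so stages can run independently and still
# operate on bit-identical data.
library(ewaspipe)

COHORT_SEED <- 20260927L
RESULTS_DIR <- "results"
dir.create(RESULTS_DIR, showWarnings = FALSE)

load_cohort <- function() simulate_cohort(sim_config(seed = COHORT_SEED))

save_table <- function(df, name) {
  path <- file.path(RESULTS_DIR, name)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  cat("wrote", path, "\n")
  invisible(path)
}
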