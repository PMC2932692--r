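# Shared settings for the numbered analysis scripts.
# Source this first; each script can also be run on its own.
library(chiptile)

SEED <- 1L
CFG <- run_config(sim_config(seed = SEED))
TARGETS <- names(CFG$sim$shape_table)

SCRATCH <- "scratch/sim"   # bulky per-probe tracks (regenerated on demand)
RESULTS <- "results"       # small result tables
dir.create(SCRATCH, recursive = TRUE, showWarnings = FALSE)
dir.create(RESULTS, recursive = TRUE, showWarnings = FALSE)

track_path <- function(target, rep = NULL) {
  if (is.null(rep)) file.path(SCRATCH, sprintf("%s_avg_z.tsv", target))
  else file.path(SCRATCH, sprintf("%s_%s_log2.tsv", target, rep))
}
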