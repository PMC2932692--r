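#!/usr/bin/env Rscript
# Stage 2: per-replicate z-score standardization, replicate averaging and
# concordance. Each replicate's log2 ratios are standardized to mean 0 / SD 1
# over all probes, replicates are averaged per target, and replicate
# concordance is summarized as all-probe Pearson correlations after 250-bp
# median smoothing.

source("analysis/00_config.R")

layout <- make_genome(CFG$sim)$layout
all_tracks <- list()
for (t in TARGETS) {
  reps <- list()
  for (r in paste0("rep", seq_len(CFG$sim$n_replicates))) {
    tr <- read_probe_table(track_path(t, r), layout)
    tr$value <- zscore_standardize(tr$value)
    reps[[paste(t, r, sep = ".")]] <- tr
  }
  avg <- average_replicates(reps)
  write_probe_table(avg, track_path(t))
  all_tracks <- c(all_tracks, reps)
  message(sprintf("%s: averaged %d standardized replicates", t, length(reps)))
}

cors <- pairwise_correlation(all_tracks, span = CFG$smooth_span)
write_tsv(data.frame(track = rownames(cors), round(cors, 3)),
          file.path(RESULTS, "02_replicate_correlations.tsv"))
within_mes4 <- cors[grep("^mes4", rownames(cors)), grep("^mes4", colnames(cors))]
message(sprintf("mean within-target correlation (mes4): %.3f",
                mean(within_mes4[upper.tri(within_mes4)])))
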