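#!/usr/bin/env Rscript
# Stage 3: sliding-window peak calling on the averaged mes4 track (500-bp
# windows, 100-bp steps, Gaussian null from reflected negative scores,
# Bonferroni-adjusted cutoff 1e-20), followed by removal of peaks within one
# step (100 bp) of a mock-IP control peak, and recovery benchmarking against
# the implanted truth.

source("analysis/00_config.R")

genome <- make_genome(CFG$sim)
layout <- genome$layout

call_for <- function(target) {
  tr <- read_probe_table(track_path(target), layout)
  w <- slide_windows(tr, layout, CFG$window, CFG$step, CFG$min_probes)
  w <- window_pvalue(w, estimate_null_sd(tr$value))
  call_peaks(w, tr, CFG$cutoff, id_prefix = target)
}

peaks_raw <- call_for(CFG$chip_target)
ctrl <- call_for(CFG$control_target)
peaks <- subtract_control_peaks(peaks_raw, ctrl, CFG$control_max_gap)
message(sprintf("%d candidate peaks, %d control peaks, %d removed, %d kept",
                nrow(peaks_raw), nrow(ctrl), attr(peaks, "n_removed"),
                nrow(peaks)))
write_peaks_bed(peaks, file.path(RESULTS, "03_peaks_mes4.bed"))
write_peaks_bed(ctrl, file.path(RESULTS, "03_peaks_noab.bed"))

# recovery against the truth table
truth <- genome$truth[genome$truth$amp_mes4 > 0, ]
gene_hit <- vapply(seq_len(nrow(truth)), function(i)
  any(peaks$chrom == truth$chrom[i] & peaks$start < truth$end[i] &
        peaks$end > truth$start[i]), logical(1))
peak_hit <- vapply(seq_len(nrow(peaks)), function(i)
  any(truth$chrom == peaks$chrom[i] & truth$start < peaks$end[i] &
        truth$end > peaks$start[i]), logical(1))
rec <- data.frame(n_true_genes = nrow(truth), n_peaks = nrow(peaks),
                  recall = mean(gene_hit), precision = mean(peak_hit))
write_tsv(rec, file.path(RESULTS, "03_recovery.tsv"))
message(sprintf("recall %.3f, precision %.3f vs %d implanted genes",
                rec$recall, rec$precision, rec$n_true_genes))
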