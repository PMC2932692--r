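#!/usr/bin/env Rscript
# Stage 6: metagene profiles. Genes longer than 2 kb are split into
# expression quintiles; averaged z-score profiles are computed in 50-bp bins
# around the TSS (-1 kb .. +1.5 kb) and TES (-1.5 kb .. +1 kb), plus
# exon-boundary profiles over intron-exon-intron triplets (elements
# >= 300 bp) with and without per-triplet intronic baseline subtraction.

source("analysis/00_config.R")

layout <- make_genome(CFG$sim)$layout
genes <- read_genes_bed12(file.path(SCRATCH, "genes.bed12"))
expr <- read.delim(file.path(RESULTS, "05_gene_expression.tsv"))
genes$expression <- expr$mean_expr[match(genes$gene_id, expr$gene_id)]

groups <- quantile_bin_genes(genes, k = CFG$n_expression_bins)
message(sprintf("%d genes > 2 kb split into %d expression bins",
                nrow(groups), max(groups$group)))

for (t in c("mes4", "pol2", "h3k36me3")) {
  tr <- read_probe_table(track_path(t), layout)
  tss <- metagene_profile(tr, genes, groups, "TSS")
  tes <- metagene_profile(tr, genes, groups, "TES")
  write_tsv(tss, file.path(RESULTS, sprintf("06_profile_tss_%s.tsv", t)))
  write_tsv(tes, file.path(RESULTS, sprintf("06_profile_tes_%s.tsv", t)))
  top <- tss[tss$group == max(tss$group) & !is.na(tss$mean), ]
  message(sprintf("%s: top-quintile TSS profile peaks at %+d bp (mean z %.2f)",
                  t, top$bin_center[which.max(top$mean)], max(top$mean)))
}

tri <- find_exon_triplets(genes, 300)
message(sprintf("%d intron-exon-intron triplets with all elements >= 300 bp",
                nrow(tri)))
tr <- read_probe_table(track_path("mes4"), layout)
for (sub in c(FALSE, TRUE)) {
  prof <- exon_boundary_profile(tr, tri, groups, baseline_subtract = sub)
  tag <- if (sub) "baseline_subtracted" else "raw"
  write_tsv(prof$start,
            file.path(RESULTS, sprintf("06_exon_start_%s.tsv", tag)))
  write_tsv(prof$end,
            file.path(RESULTS, sprintf("06_exon_end_%s.tsv", tag)))
  if (sub && prof$n_skipped > 0)
    message(sprintf("%d triplets skipped (no intronic probes)",
                    prof$n_skipped))
}
message("wrote exon-boundary profile tables")
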