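#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study.
#
# Six 1-Mb chromosomes (five autosomes + an X-like chromosome largely closed
# to germline-expressed gene classes), 200 genes in the six temporal-spatial
# expression classes, 50-bp probe tiling, and replicate ChIP log2-ratio
# tracks for four targets: a gene-body factor with a 5' skew (mes4), a
# TSS/TES-peaked polymerase (pol2), a flat gene-body mark (h3k36me3) and a
# mock-IP control (noab).

source("analysis/00_config.R")

genome <- make_genome(CFG$sim)
message(sprintf("placed %d genes on %d chromosomes",
                nrow(genome$genes), length(genome$layout$lengths)))
print(table(genome$genes$class_label))
message(sprintf("X-like chromosome carries %d genes (%d enriched for mes4)",
                sum(genome$genes$chrom == "chrX"),
                sum(genome$truth$chrom == "chrX" & genome$truth$amp_mes4 > 0)))

write_genes_bed12(genome$genes, file.path(SCRATCH, "genes.bed12"))
write_tsv(genome$truth, file.path(RESULTS, "01_truth.tsv"))
write_tsv(data.frame(gene_id = genome$genes$gene_id,
                     class_label = genome$genes$class_label),
          file.path(RESULTS, "01_gene_classes.tsv"))

for (t in TARGETS) {
  reps <- simulate_chip(genome$genes, genome$layout, CFG$sim, t)
  for (r in names(reps)) write_probe_table(reps[[r]], track_path(t, r))
  message(sprintf("simulated %s: %d replicates x %d probes",
                  t, length(reps), nrow(reps[[1]])))
}

expr <- simulate_expression(genome$genes, CFG$sim)
em <- data.frame(probe_id = rownames(expr$matrix),
                 gene_id = expr$probe_gene, expr$matrix)
write_tsv(em, file.path(SCRATCH, "expression_probes.tsv"))
message(sprintf("simulated expression array: %d probes x %d samples",
                nrow(expr$matrix), ncol(expr$matrix)))
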