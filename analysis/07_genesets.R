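#!/usr/bin/env Rscript
# Stage 7: gene-level statistics. Gene-body mean z-scores per target feed
# class boxplot summaries, the strict high/low threshold selection
# (mes4 & h3k36me3 z > 1, pol2 z < 0), and set-overlap enrichment of
# MES-4-type bound genes against the germline-expressed classes.

source("analysis/00_config.R")

layout <- make_genome(CFG$sim)$layout
genes <- read_genes_bed12(file.path(SCRATCH, "genes.bed12"))
classes <- read_class_labels(file.path(RESULTS, "01_gene_classes.tsv"))
genes$class_label <- classes$class_label[match(genes$gene_id, classes$gene_id)]
expr <- read.delim(file.path(RESULTS, "05_gene_expression.tsv"))
rna_z <- setNames(expr$rna_z, expr$gene_id)

tracks <- lapply(setNames(TARGETS, TARGETS), function(t)
  read_probe_table(track_path(t), layout))
scores <- gene_score_table(genes, tracks, rna_z)
write_tsv(scores, file.path(RESULTS, "07_gene_scores.tsv"))

for (t in c("rna_z", "mes4", "pol2", "h3k36me3")) {
  s <- class_summary(scores, t)
  write_tsv(s, file.path(RESULTS, sprintf("07_class_summary_%s.tsv", t)))
}
s <- class_summary(scores, "mes4")
message("median mes4 z by class: ",
        paste(s$class_label, round(s$p50, 2), sep = "=", collapse = ", "))

selected <- classify_high_low(scores, CFG$high_targets, CFG$low_targets,
                              CFG$high_threshold, CFG$low_threshold)
writeLines(selected, file.path(RESULTS, "07_selected_genes.txt"))
sel_classes <- scores$class_label[scores$gene_id %in% selected]
message(sprintf("%d genes with high mes4/h3k36me3 (z>1) and low pol2 (z<0): %s",
                length(selected),
                paste(names(table(sel_classes)), table(sel_classes),
                      sep = "=", collapse = ", ")))
germline_ids <- scores$gene_id[scores$class_label %in%
                                 c("germline-expressed", "germline-specific",
                                   "ubiquitous")]
if (length(selected)) {
  ev <- evidence_fraction(selected, germline_ids)
  message(sprintf("%d of %d selected genes (%d%%) are germline-expressed",
                  ev$n_evidence, ev$n, ev$percent))
}

bound <- readLines(file.path(RESULTS, "04_bound_genes.txt"))
enr <- overlap_enrichment(bound, germline_ids, scores$gene_id)
write_tsv(data.frame(observed = enr$observed, expected = enr$expected,
                     fold = enr$fold, tail = enr$tail,
                     log10_p = enr$log10_p),
          file.path(RESULTS, "07_overlap_enrichment.tsv"))
message(sprintf(
  "bound genes vs germline classes: %.1f-fold %s (log10 p = %.1f)",
  enr$fold, enr$tail, enr$log10_p))
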