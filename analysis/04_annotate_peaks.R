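#!/usr/bin/env Rscript
# Stage 4: relate peaks to genes (body / 1-kb flank / intergenic, plus the
# exon > intron > 3' > 5' > distal summit hierarchy) and test the
# chromosome distribution against the uniform-by-length null.

source("analysis/00_config.R")

layout <- make_genome(CFG$sim)$layout
genes <- read_genes_bed12(file.path(SCRATCH, "genes.bed12"))
classes <- read_class_labels(file.path(RESULTS, "01_gene_classes.tsv"))
genes$class_label <- classes$class_label[match(genes$gene_id, classes$gene_id)]
peaks <- read_peaks_bed(file.path(RESULTS, "03_peaks_mes4.bed"))

ann <- peaks_to_genes(peaks, genes, CFG$flank)
feat <- assign_summit_feature(peaks, genes, CFG$flank)
message("peak relations: ",
        paste(names(ann$counts), ann$counts, sep = "=", collapse = ", "))
message("summit features: ",
        paste(names(table(feat)), table(feat), sep = "=", collapse = ", "))
message(sprintf("%d genes body-bound, %d touched only through a flank",
                length(ann$bound_genes), length(ann$flank_genes)))
write_tsv(cbind(ann$relations, feature = feat),
          file.path(RESULTS, "04_peak_annotations.tsv"))
writeLines(ann$bound_genes, file.path(RESULTS, "04_bound_genes.txt"))

dist <- chromosome_distribution(peaks, layout)
write_tsv(dist$table, file.path(RESULTS, "04_chrom_distribution.tsv"))
message(sprintf(
  "X-like chromosome: %d observed vs %.1f expected peaks (%s, log10 p = %.1f)",
  dist$table$observed[dist$table$chrom == dist$focal],
  dist$table$expected[dist$table$chrom == dist$focal],
  dist$focal_tail, dist$focal_log10_p))
message(sprintf("left-tip density %.3f vs autosomal %.3f sites/kb",
                peak_density(peaks, "chrX", 0, 3e5),
                sum(dist$table$observed[dist$table$chrom != "chrX"]) /
                  (sum(dist$table$length[dist$table$chrom != "chrX"]) / 1000)))
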