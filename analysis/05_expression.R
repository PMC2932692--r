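#!/usr/bin/env Rscript
# Stage 5: summarize the 3-probe / 4-sample expression array into one value
# per gene: quantile normalization across samples, median-polish
# summarization per gene, cross-sample averaging, and z-scoring across genes.

source("analysis/00_config.R")

em <- read.delim(file.path(SCRATCH, "expression_probes.tsv"))
mat <- as.matrix(em[, grep("^sample", names(em))])
rownames(mat) <- em$probe_id

qn <- quantile_normalize(mat)
per_gene <- summarize_gene(qn, em$gene_id)
rna_z <- average_and_zscore(per_gene)
out <- data.frame(gene_id = rownames(per_gene),
                  round(per_gene, 4),
                  mean_expr = round(rowMeans(per_gene), 4),
                  rna_z = round(unname(rna_z), 4))
write_tsv(out, file.path(RESULTS, "05_gene_expression.tsv"))
message(sprintf("summarized %d genes from %d probes across %d samples",
                nrow(per_gene), nrow(mat), ncol(mat)))
message(sprintf("RNA z range: %.2f .. %.2f", min(rna_z), max(rna_z)))
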