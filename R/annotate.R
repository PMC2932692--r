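# strand-aware flank intervals, 0-based half-open;
# upstream = before the TSS in transcription direction
.flanks <- function(genes, flank) {
  up_start <- ifelse(genes$strand == "+", genes$tx_start - flank, genes$tx_end)
  up_end   <- ifelse(genes$strand == "+", genes$tx_start, genes$tx_end + flank)
  dn_start <- ifelse(genes$strand == "+", genes$tx_end, genes$tx_start - flank)
  dn_end   <- ifelse(genes$strand == "+", genes$tx_end + flank, genes$tx_start)
  list(up_start = pmax(up_start, 0), up_end = pmax(up_end, 0),
       dn_start = pmax(dn_start, 0), dn_end = pmax(dn_end, 0))
}

# GRanges over a shared seqlevel universe (avoids disjoint-level warnings)
.gr <- function(chrom, start0, end0, levels) {
  GenomicRanges::GRanges(factor(chrom, levels = levels),
                         IRanges::IRanges(start0 + 1L, end0))
}

.overlaps_any <- function(qs, qe, ss, se, qchr, schr) {
  # any >=1 bp overlap between half-open query intervals and subject set
  if (!length(ss)) return(rep(FALSE, length(qs)))
  lev <- unique(c(qchr, schr))
  IRanges::overlapsAny(.gr(qchr, qs, qe, lev), .gr(schr, ss, se, lev))
}

#' Mean z-score over probes fully contained in a gene's transcript
#'
#' A probe contributes iff `start >= tx_start` and `end <= tx_end`. Genes
#' with no qualifying probe get `NA` (never zero).
#'
#' @param track a sorted probe table of z-scores.
#' @param genes a gene model table.
#' @return numeric vector of per-gene means, named by `gene_id`.
#' @export
gene_mean_z <- function(track, genes) {
  lev <- unique(c(track$chrom, genes$chrom))
  gr_p <- .gr(track$chrom, track$start, track$end, lev)
  gr_g <- .gr(genes$chrom, genes$tx_start, genes$tx_end, lev)
  hit <- GenomicRanges::findOverlaps(gr_p, gr_g, type = "within")
  sums <- tapply(track$value[S4Vectors::queryHits(hit)],
                 factor(S4Vectors::subjectHits(hit), levels = seq_len(nrow(genes))),
                 sum)
  ns <- tabulate(S4Vectors::subjectHits(hit), nbins = nrow(genes))
  out <- as.numeric(sums) / ns
  out[ns == 0] <- NA_real_
  setNames(out, genes$gene_id)
}

#' Relate peaks to genes and derive the bound-gene set
#'
#' Each peak gets one relation by precedence: `gene-body` (>= 1 bp overlap
#' with some transcript), else `upstream-1kb`, else `downstream-1kb`
#' (strand-aware flanks), else `intergenic`; the counts therefore partition
#' the peak set. Gene-side, the bound set contains genes with >= 1 bp body
#' overlap with any peak; genes touched only through a flank are reported
#' separately.
#'
#' @param peaks a peak table.
#' @param genes a gene model table.
#' @param flank flank width in bp (default 1000).
#' @return a list with `relations` (data.frame peak_id, relation),
#'   `counts` (named relation counts), `bound_genes` and `flank_genes`
#'   (character vectors of gene ids).
#' @export
peaks_to_genes <- function(peaks, genes, flank = 1000) {
  fl <- .flanks(genes, flank)
  body <- .overlaps_any(peaks$start, peaks$end, genes$tx_start, genes$tx_end,
                        peaks$chrom, genes$chrom)
  ok_up <- fl$up_end > fl$up_start
  up <- .overlaps_any(peaks$start, peaks$end,
                      fl$up_start[ok_up], fl$up_end[ok_up],
                      peaks$chrom, genes$chrom[ok_up])
  ok_dn <- fl$dn_end > fl$dn_start
  dn <- .overlaps_any(peaks$start, peaks$end,
                      fl$dn_start[ok_dn], fl$dn_end[ok_dn],
                      peaks$chrom, genes$chrom[ok_dn])
  relation <- ifelse(body, "gene-body",
              ifelse(up, "upstream-1kb",
              ifelse(dn, "downstream-1kb", "intergenic")))
  gene_body_hit <- .overlaps_any(genes$tx_start, genes$tx_end,
                                 peaks$start, peaks$end,
                                 genes$chrom, peaks$chrom)
  gene_up <- rep(FALSE, nrow(genes))
  gene_up[ok_up] <- .overlaps_any(fl$up_start[ok_up], fl$up_end[ok_up],
                                  peaks$start, peaks$end,
                                  genes$chrom[ok_up], peaks$chrom)
  gene_dn <- rep(FALSE, nrow(genes))
  gene_dn[ok_dn] <- .overlaps_any(fl$dn_start[ok_dn], fl$dn_end[ok_dn],
                                  peaks$start, peaks$end,
                                  genes$chrom[ok_dn], peaks$chrom)
  bound <- genes$gene_id[gene_body_hit]
  flank_only <- genes$gene_id[!gene_body_hit & (gene_up | gene_dn)]
  counts <- setNames(tabulate(factor(relation,
                                     levels = c("gene-body", "upstream-1kb",
                                                "downstream-1kb", "intergenic")),
                              nbins = 4),
                     c("gene-body", "upstream-1kb", "downstream-1kb",
                       "intergenic"))
  list(relations = data.frame(peak_id = peaks$peak_id, relation = relation,
                              stringsAsFactors = FALSE),
       counts = counts, bound_genes = bound, flank_genes = flank_only)
}

# does point p (0-based coordinate) fall in half-open [s, e)?
.point_in <- function(p, s, e) p >= s & p < e

#' Assign a peak summit to a genomic feature by hierarchy
#'
#' The summit (maximum-enrichment probe midpoint) is tested against all
#' annotations; the first match in the order exon > intron > 3' flank >
#' 5' flank > distal wins. Flanks are strand-aware windows of `flank` bp
#' past the 3' end / before the 5' end.
#'
#' @param peaks a peak table (uses the `summit` column).
#' @param genes a gene model table with exon structure.
#' @param flank flank width in bp (default 1000).
#' @return character vector of feature labels, one per peak, from
#'   `c("exon", "intron", "3'", "5'", "distal")`.
#' @export
assign_summit_feature <- function(peaks, genes, flank = 1000) {
  ex_chr <- rep(genes$chrom, lengths(genes$exon_starts))
  ex_s <- unlist(genes$exon_starts, use.names = FALSE)
  ex_e <- unlist(genes$exon_ends, use.names = FALSE)
  fl <- .flanks(genes, flank)
  # 5' flank = upstream of TSS; 3' flank = downstream of TES
  vapply(seq_len(nrow(peaks)), function(i) {
    p <- peaks$summit[i]; chr <- peaks$chrom[i]
    in_ex <- any(ex_chr == chr & .point_in(p, ex_s, ex_e))
    if (in_ex) return("exon")
    same <- genes$chrom == chr
    in_body <- same & .point_in(p, genes$tx_start, genes$tx_end)
    if (any(in_body)) return("intron")  # in a gene body but in no exon
    if (any(same & .point_in(p, fl$dn_start, fl$dn_end))) return("3'")
    if (any(same & .point_in(p, fl$up_start, fl$up_end))) return("5'")
    "distal"
  }, character(1))
}

#' Peak counts per chromosome against the uniform-by-length null
#'
#' Expected counts put peaks on chromosomes with probability proportional to
#' length. The focal chromosome gets an exact binomial tail p (lower tail if
#' observed < expected, i.e. depletion; upper tail otherwise), computed in
#' log space; a genome-wide chi-square statistic is reported alongside.
#'
#' @param peaks a peak table.
#' @param layout a [genome_layout].
#' @param focal focal chromosome; defaults to the layout's focal chromosome.
#' @return a list with `table` (chrom, length, observed, expected),
#'   `focal`, `focal_tail` ("depletion"/"enrichment"), `focal_p`,
#'   `focal_log10_p`, `chisq`, `chisq_df`, `chisq_p`, `n_peaks`.
#' @export
chromosome_distribution <- function(peaks, layout, focal = layout$focal) {
  .check_chroms(peaks$chrom, layout, "peaks")
  if (!focal %in% names(layout$lengths)) stop("focal chromosome not in layout")
  chrs <- names(layout$lengths)
  obs <- tabulate(factor(peaks$chrom, levels = chrs), nbins = length(chrs))
  n <- nrow(peaks)
  lens <- as.numeric(layout$lengths)
  p_chr <- lens / sum(lens)
  expd <- n * p_chr
  chisq <- if (n > 0) sum((obs - expd)^2 / expd) else 0
  df <- length(chrs) - 1L
  chisq_p <- if (n > 0) pchisq(chisq, df, lower.tail = FALSE) else 1
  i <- match(focal, chrs)
  if (n == 0) {
    tail <- "depletion"; lg <- 0
  } else if (obs[i] < expd[i]) {
    tail <- "depletion"
    lg <- pbinom(obs[i], n, p_chr[i], lower.tail = TRUE, log.p = TRUE)
  } else {
    tail <- "enrichment"
    lg <- pbinom(obs[i] - 1L, n, p_chr[i], lower.tail = FALSE, log.p = TRUE)
  }
  list(table = data.frame(chrom = chrs, length = lens, observed = obs,
                          expected = expd, stringsAsFactors = FALSE),
       focal = focal, focal_tail = tail,
       focal_p = exp(lg), focal_log10_p = lg / log(10),
       chisq = chisq, chisq_df = df, chisq_p = chisq_p, n_peaks = n)
}

#' Peak density (summits per kb) over a region
#'
#' @param peaks a peak table.
#' @param chrom chromosome name.
#' @param start,end region bounds, 0-based half-open.
#' @return peaks per kb: summits in `[start, end)` divided by the region
#'   length in kb.
#' @export
peak_density <- function(peaks, chrom, start, end) {
  if (start >= end) stop("zero- or negative-length region")
  k <- sum(peaks$chrom == chrom & peaks$summit >= start & peaks$summit < end)
  k / ((end - start) / 1000)
}
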