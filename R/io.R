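#' Construct and validate a per-probe signal table
#'
#' The central data structure of the pipeline: one row per tiling probe with
#' 0-based half-open coordinates and a single numeric value (a log2 ratio or
#' a z-score, depending on pipeline stage). Rows are sorted by
#' (chromosome, start).
#'
#' @param chrom character chromosome names.
#' @param start,end integer probe coordinates, 0-based half-open.
#' @param probe_id character probe identifiers.
#' @param value numeric per-probe values.
#' @return a `data.frame` with columns `chrom`, `start`, `end`, `probe_id`,
#'   `value`, sorted by (chrom, start).
#' @export
probe_table <- function(chrom, start, end, probe_id, value) {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.integer(start), end = as.integer(end),
                   probe_id = as.character(probe_id),
                   value = as.numeric(value),
                   stringsAsFactors = FALSE)
  if (any(df$start >= df$end)) stop("probe start must be < end")
  df[order(df$chrom, df$start, df$end), , drop = FALSE] |> `rownames<-`(NULL)
}

#' Probe midpoints
#'
#' Probes are reduced to a point coordinate (midpoint, rounded down) for
#' window membership, bin assignment and summit reporting.
#'
#' @param probes a probe table (see [probe_table()]).
#' @return integer vector of midpoints.
#' @export
probe_mid <- function(probes) as.integer((probes$start + probes$end) %/% 2L)

#' Read a per-probe signal table from TSV
#'
#' Expects a header line with columns `chrom`, `start`, `end`, `probe_id`,
#' `value`. Records are validated against the layout (coordinates must lie
#' within chromosome bounds; out-of-bounds records are an error, never
#' clamped) and returned sorted by (chrom, start).
#'
#' @param path file path.
#' @param layout a [genome_layout] used for bounds checking.
#' @return a sorted probe table.
#' @export
read_probe_table <- function(path, layout) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "probe_id", "value")
  if (!all(need %in% names(df)))
    stop("probe table must have columns: ", paste(need, collapse = ", "))
  if (nrow(df) == 0)
    return(probe_table(character(), integer(), integer(), character(), numeric()))
  if (!is.numeric(df$start) || !is.numeric(df$end))
    stop("non-numeric coordinates in probe table: ", path)
  if (!is.numeric(df$value)) {
    bad <- which(is.na(suppressWarnings(as.numeric(df$value))))[1]
    stop("non-numeric value at data line ", bad, " of ", path)
  }
  .check_chroms(df$chrom, layout, what = paste0("probe table ", path))
  len <- layout$lengths[df$chrom]
  bad <- which(df$start < 0 | df$end > len)
  if (length(bad))
    stop("probe beyond chromosome end at data line ", bad[1], " of ", path)
  probe_table(df$chrom, df$start, df$end, df$probe_id, df$value)
}

#' Write a per-probe signal table to TSV
#'
#' @param probes a probe table.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_probe_table <- function(probes, path) {
  write.table(probes[, c("chrom", "start", "end", "probe_id", "value")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a signal track as bedGraph
#'
#' @param probes a probe table.
#' @param path output path (`.bedGraph`).
#' @return the path, invisibly.
#' @export
write_bedgraph <- function(probes, path) {
  gr <- GenomicRanges::GRanges(probes$chrom,
                               IRanges::IRanges(probes$start + 1L, probes$end),
                               score = probes$value)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

# ---- gene models -----------------------------------------------------------

#' Construct a gene model table
#'
#' One row per gene: transcript bounds (0-based half-open), strand and exon
#' block structure. Exons are carried as list-columns of genomic start/end
#' vectors; they must be sorted, disjoint and contained in the transcript.
#'
#' @param gene_id character gene identifiers (unique).
#' @param chrom character chromosome names.
#' @param strand `"+"` or `"-"`.
#' @param tx_start,tx_end transcript bounds, 0-based half-open.
#' @param exon_starts,exon_ends lists of integer vectors, one per gene.
#' @param class_label optional character class labels (NA allowed).
#' @param expression optional numeric expression values.
#' @return a `data.frame` with list-columns `exon_starts`, `exon_ends`.
#' @export
gene_table <- function(gene_id, chrom, strand, tx_start, tx_end,
                       exon_starts = NULL, exon_ends = NULL,
                       class_label = NA_character_, expression = NA_real_) {
  n <- length(gene_id)
  if (anyDuplicated(gene_id)) stop("duplicated gene ids")
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  tx_start <- as.integer(tx_start); tx_end <- as.integer(tx_end)
  if (any(tx_start >= tx_end)) stop("tx_start must be < tx_end")
  if (is.null(exon_starts)) exon_starts <- as.list(tx_start)
  if (is.null(exon_ends)) exon_ends <- as.list(tx_end)
  for (i in seq_len(n)) {
    es <- as.integer(exon_starts[[i]]); ee <- as.integer(exon_ends[[i]])
    if (length(es) < 1L || length(es) != length(ee))
      stop("gene ", gene_id[i], ": malformed exon blocks")
    if (any(es >= ee) || is.unsorted(es, strictly = TRUE) ||
        any(es[-1] < ee[-length(ee)]))
      stop("gene ", gene_id[i], ": exons must be sorted and disjoint")
    if (es[1] < tx_start[i] || ee[length(ee)] > tx_end[i])
      stop("gene ", gene_id[i], ": exon outside transcript bounds")
    exon_starts[[i]] <- es; exon_ends[[i]] <- ee
  }
  df <- data.frame(gene_id = as.character(gene_id), chrom = as.character(chrom),
                   strand = strand, tx_start = tx_start, tx_end = tx_end,
                   class_label = rep_len(as.character(class_label), n),
                   expression = rep_len(as.numeric(expression), n),
                   stringsAsFactors = FALSE)
  df$exon_starts <- exon_starts
  df$exon_ends <- exon_ends
  rownames(df) <- NULL
  df
}

#' Read gene models from BED12
#'
#' Exon blocks are reconstructed from `blockStarts`/`blockSizes`. The BED
#' convention is preserved: `tx_start` is always the smaller coordinate
#' regardless of strand. Blocks extending past `chromEnd` are a format error.
#'
#' @param path BED12 file path.
#' @return a gene model table (see [gene_table()]).
#' @export
read_genes_bed12 <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  if (!"blocks" %in% names(S4Vectors::mcols(gr)))
    stop("not a BED12 file (no block structure): ", path)
  blocks <- S4Vectors::mcols(gr)$blocks
  w <- GenomicRanges::width(gr)
  over <- vapply(seq_along(gr),
                 function(i) any(IRanges::end(blocks[[i]]) > w[i]), logical(1))
  if (any(over))
    stop("BED12 block extends past chromEnd for record ", which(over)[1],
         " of ", path)
  tx_start <- GenomicRanges::start(gr) - 1L
  exon_starts <- lapply(seq_along(gr), function(i)
    tx_start[i] + IRanges::start(blocks[[i]]) - 1L)
  exon_ends <- lapply(seq_along(gr), function(i)
    tx_start[i] + IRanges::end(blocks[[i]]))
  gene_table(gene_id = as.character(S4Vectors::mcols(gr)$name),
             chrom = as.character(GenomicRanges::seqnames(gr)),
             strand = as.character(GenomicRanges::strand(gr)),
             tx_start = tx_start,
             tx_end = GenomicRanges::end(gr),
             exon_starts = exon_starts, exon_ends = exon_ends)
}

#' Write gene models as BED12
#'
#' @param genes a gene model table.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_genes_bed12 <- function(genes, path) {
  lines <- vapply(seq_len(nrow(genes)), function(i) {
    es <- genes$exon_starts[[i]]; ee <- genes$exon_ends[[i]]
    paste(genes$chrom[i], genes$tx_start[i], genes$tx_end[i],
          genes$gene_id[i], 0L, genes$strand[i],
          genes$tx_start[i], genes$tx_end[i], "0",
          length(es),
          paste0(paste(ee - es, collapse = ","), ","),
          paste0(paste(es - genes$tx_start[i], collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# ---- peaks -----------------------------------------------------------------

.PEAK_COLS <- c("chrom", "start", "end", "peak_id", "summit", "mean_z", "adj_p")

#' Construct a peak table
#'
#' @param chrom,start,end peak intervals (0-based half-open), sorted.
#' @param peak_id character identifiers.
#' @param summit integer summit coordinates (max-value probe midpoints).
#' @param mean_z mean z of the best merged window.
#' @param adj_p Bonferroni-adjusted p of the best merged window.
#' @return a sorted `data.frame` with the peak columns.
#' @export
peak_table <- function(chrom, start, end, peak_id, summit, mean_z, adj_p) {
  df <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end), peak_id = as.character(peak_id),
                   summit = as.integer(summit), mean_z = as.numeric(mean_z),
                   adj_p = as.numeric(adj_p), stringsAsFactors = FALSE)
  if (any(df$start >= df$end)) stop("peak start must be < end")
  if (any(df$summit < df$start | df$summit >= df$end))
    stop("summit must lie within [start, end)")
  df[order(df$chrom, df$start, df$end), , drop = FALSE] |> `rownames<-`(NULL)
}

#' Write peaks as a headered BED6+ table
#'
#' Columns: chrom, start, end, name, score (mean z scaled by 100 and clamped
#' to the 0-1000 BED range), strand (`.`), then summit, mean_z, adj_p.
#' p-values are written in scientific notation with full precision so that
#' [read_peaks_bed()] recovers them losslessly.
#'
#' @param peaks a sorted peak table.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_peaks_bed <- function(peaks, path) {
  if (is.unsorted(order(peaks$chrom, peaks$start, peaks$end)))
    stop("peaks must be sorted before writing")
  hdr <- paste(c("chrom", "start", "end", "name", "score", "strand",
                 "summit", "mean_z", "adj_p"), collapse = "\t")
  if (nrow(peaks) == 0) { writeLines(hdr, path); return(invisible(path)) }
  score <- pmax(0L, pmin(1000L, as.integer(round(peaks$mean_z * 100))))
  lines <- paste(peaks$chrom, peaks$start, peaks$end, peaks$peak_id, score, ".",
                 peaks$summit,
                 formatC(peaks$mean_z, format = "e", digits = 16),
                 formatC(peaks$adj_p, format = "e", digits = 16),
                 sep = "\t")
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read peaks written by [write_peaks_bed()]
#'
#' @param path file path.
#' @return a peak table.
#' @export
read_peaks_bed <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (nrow(df) == 0)
    return(peak_table(character(), integer(), integer(), character(),
                      integer(), numeric(), numeric()))
  peak_table(df$chrom, df$start, df$end, df$name, df$summit,
             df$mean_z, df$adj_p)
}

# ---- small TSV helpers -----------------------------------------------------

#' Read a two-column gene class-label table (gene_id, class_label)
#' @param path TSV path with header.
#' @return a `data.frame` with columns `gene_id`, `class_label`.
#' @export
read_class_labels <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("gene_id", "class_label") %in% names(df)))
    stop("class label table needs columns gene_id, class_label")
  df[, c("gene_id", "class_label")]
}

#' Write a generic TSV table
#' @param df a data.frame (list-columns are dropped).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_tsv <- function(df, path) {
  keep <- !vapply(df, is.list, logical(1))
  write.table(df[, keep, drop = FALSE], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
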