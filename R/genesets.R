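#' Build the per-gene score table
#'
#' One row per gene with the gene-body mean z-score of each ChIP target
#' (see [gene_mean_z()]), the RNA z-score, class label and chromosome.
#' Missing scores stay missing; nothing is imputed.
#'
#' @param genes a gene model table.
#' @param tracks named list of z-score probe tables (one per ChIP target).
#' @param rna_z optional named numeric vector of per-gene RNA z-scores.
#' @return a data.frame `gene_id`, `chrom`, `class_label`, one column per
#'   target, and `rna_z`.
#' @export
gene_score_table <- function(genes, tracks, rna_z = NULL) {
  out <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                    class_label = genes$class_label, stringsAsFactors = FALSE)
  for (nm in names(tracks)) out[[nm]] <- unname(gene_mean_z(tracks[[nm]], genes))
  out$rna_z <- if (is.null(rna_z)) NA_real_ else
    unname(rna_z[match(genes$gene_id, names(rna_z))])
  out
}

#' Boxplot-style summary of a score by gene class
#'
#' Percentiles 2.5/25/50/75/97.5 (linear interpolation between order
#' statistics) plus the notch half-width `1.57 * IQR / sqrt(n)` used for the
#' 95% confidence interval of the median. Missing values are excluded and
#' counted.
#'
#' @param table a gene score table.
#' @param target column name of the score to summarize.
#' @param classes data.frame `gene_id`, `class_label` defining the groups;
#'   defaults to the table's own `class_label` column.
#' @return a data.frame with one row per class: `class_label`, `n`,
#'   `n_missing`, `p2.5`, `p25`, `p50`, `p75`, `p97.5`, `median_ci95`.
#' @export
class_summary <- function(table, target, classes = NULL) {
  if (!target %in% names(table)) stop("unknown target column: ", target)
  if (is.null(classes))
    classes <- data.frame(gene_id = table$gene_id,
                          class_label = table$class_label,
                          stringsAsFactors = FALSE)
  classes <- classes[!is.na(classes$class_label), , drop = FALSE]
  labs <- unique(classes$class_label)
  rows <- lapply(labs, function(cl) {
    ids <- classes$gene_id[classes$class_label == cl]
    x <- table[[target]][table$gene_id %in% ids]
    if (!length(x)) stop("empty class: ", cl)
    nm <- sum(is.na(x)); x <- x[!is.na(x)]
    if (!length(x)) stop("class has no non-missing scores: ", cl)
    q <- quantile(x, c(0.025, 0.25, 0.5, 0.75, 0.975), type = 7, names = FALSE)
    data.frame(class_label = cl, n = length(x), n_missing = nm,
               p2.5 = q[1], p25 = q[2], p50 = q[3], p75 = q[4], p97.5 = q[5],
               median_ci95 = 1.57 * (q[4] - q[2]) / sqrt(length(x)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Select genes by strict high/low score thresholds
#'
#' A gene is included iff every `high_targets` score is strictly above
#' `high_threshold` and every `low_targets` score strictly below
#' `low_threshold`; genes with any required score missing are excluded.
#'
#' @param table a gene score table.
#' @param high_targets,low_targets character vectors of score column names.
#' @param high_threshold,low_threshold thresholds (defaults 1 and 0).
#' @return character vector of gene ids.
#' @export
classify_high_low <- function(table, high_targets, low_targets,
                              high_threshold = 1, low_threshold = 0) {
  unknown <- setdiff(c(high_targets, low_targets), names(table))
  if (length(unknown))
    stop("unknown target(s): ", paste(unknown, collapse = ", "))
  keep <- rep(TRUE, nrow(table))
  for (t in high_targets) keep <- keep & !is.na(table[[t]]) &
      table[[t]] > high_threshold
  for (t in low_targets) keep <- keep & !is.na(table[[t]]) &
      table[[t]] < low_threshold
  table$gene_id[keep]
}

#' Fold enrichment and hypergeometric p for the overlap of two gene sets
#'
#' Expected overlap under independence is `|A||B|/|U|`; the reported tail is
#' the upper (enrichment) tail when the observed overlap is at least the
#' expectation and the lower (depletion) tail otherwise, computed in log
#' space.
#'
#' @param setA,setB character vectors of gene ids, subsets of `universe`.
#' @param universe character vector of all gene ids considered.
#' @return a list: `observed`, `expected`, `fold`, `tail`, `p`, `log10_p`.
#' @export
overlap_enrichment <- function(setA, setB, universe) {
  if (!length(universe)) stop("empty universe")
  universe <- unique(universe)
  A <- unique(intersect(setA, universe))
  B <- unique(intersect(setB, universe))
  if (length(A) < length(unique(setA)) || length(B) < length(unique(setB)))
    stop("sets must be subsets of the universe")
  obs <- length(intersect(A, B))
  expd <- length(A) * length(B) / length(universe)
  if (obs >= expd) {
    tail <- "enrichment"
    lg <- phyper(obs - 1L, length(A), length(universe) - length(A),
                 length(B), lower.tail = FALSE, log.p = TRUE)
  } else {
    tail <- "depletion"
    lg <- phyper(obs, length(A), length(universe) - length(A),
                 length(B), lower.tail = TRUE, log.p = TRUE)
  }
  list(observed = obs, expected = expd,
       fold = if (expd > 0) obs / expd else NA_real_,
       tail = tail, p = exp(lg), log10_p = lg / log(10))
}

#' Fraction of a gene set carrying an evidence label
#'
#' @param set character vector of gene ids (nonempty).
#' @param evidence_labels character vector of gene ids that carry evidence.
#' @return a list: `n`, `n_evidence`, `fraction`, `percent` (rounded to the
#'   nearest integer percent).
#' @export
evidence_fraction <- function(set, evidence_labels) {
  if (!length(set)) stop("empty gene set")
  n_ev <- sum(unique(set) %in% evidence_labels)
  n <- length(unique(set))
  frac <- n_ev / n
  list(n = n, n_evidence = n_ev, fraction = frac,
       percent = round(100 * frac))
}
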