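#' Assemble and validate a full-run configuration
#'
#' Stage parameters default to the pipeline's canonical settings: 500-bp
#' windows stepped by 100 bp, adjusted-p cutoff 1e-20, 1-kb annotation
#' flank, 50 x 50-bp profile bins, expression quintiles, gene-set thresholds
#' z > 1 / z < 0, 250-bp median smoothing and a 100-bp control-peak gap.
#'
#' @param sim a [sim_config()] describing the synthetic study.
#' @param chip_target target whose peaks are called (default `"mes4"`).
#' @param control_target mock-IP control target (default `"noab"`).
#' @param window,step,cutoff,min_probes peak-caller settings.
#' @param flank annotation flank in bp.
#' @param smooth_span correlation smoothing span in bp.
#' @param control_max_gap control-subtraction gap in bp.
#' @param n_expression_bins metagene expression groups (default 5).
#' @param high_targets,low_targets,high_threshold,low_threshold gene-set
#'   classification settings.
#' @return a validated list of class `run_config`.
#' @export
run_config <- function(sim = sim_config(),
                       chip_target = "mes4", control_target = "noab",
                       window = 500, step = 100, cutoff = 1e-20,
                       min_probes = 1, flank = 1000, smooth_span = 250,
                       control_max_gap = 100, n_expression_bins = 5,
                       high_targets = c("mes4", "h3k36me3"),
                       low_targets = "pol2",
                       high_threshold = 1, low_threshold = 0) {
  validate_sim_config(sim)
  stopifnot(window > 0, step > 0, cutoff > 0, cutoff <= 1, flank >= 0,
            smooth_span >= 0, control_max_gap >= 0, n_expression_bins >= 2)
  targets <- names(sim$shape_table)
  for (t in c(chip_target, control_target, high_targets, low_targets))
    if (!t %in% targets) stop("target not in simulation config: ", t)
  structure(list(sim = sim, chip_target = chip_target,
                 control_target = control_target, window = window,
                 step = step, cutoff = cutoff, min_probes = min_probes,
                 flank = flank, smooth_span = smooth_span,
                 control_max_gap = control_max_gap,
                 n_expression_bins = n_expression_bins,
                 high_targets = high_targets, low_targets = low_targets,
                 high_threshold = high_threshold,
                 low_threshold = low_threshold),
            class = "run_config")
}

#' Read / write a run configuration as YAML
#' @param path YAML file path.
#' @return for the reader, a `run_config`; for the writer, the path.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim %||% list()
  for (nm in c("chrom_lengths", "class_mix", "expression_means"))
    if (!is.null(sim_args[[nm]])) sim_args[[nm]] <- unlist(sim_args[[nm]])
  if (!is.null(sim_args$effect_table))
    sim_args$effect_table <- as.data.frame(lapply(sim_args$effect_table,
                                                  unlist),
                                           stringsAsFactors = FALSE)
  if (!is.null(sim_args$shape_table))
    sim_args$shape_table <- unlist(sim_args$shape_table)
  y$sim <- do.call(sim_config, sim_args)
  do.call(run_config, y)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_run_config
#' @param config a `run_config`.
#' @export
write_run_config <- function(config, path) {
  y <- unclass(config)
  y$sim <- unclass(y$sim)
  y$sim$effect_table <- as.list(y$sim$effect_table)
  # named atomic vectors must become YAML maps, not plain sequences
  for (nm in c("chrom_lengths", "class_mix", "expression_means",
               "shape_table"))
    y$sim[[nm]] <- as.list(y$sim[[nm]])
  yaml::write_yaml(y, path, precision = 15)
  invisible(path)
}

#' Run the full synthetic-study pipeline
#'
#' Executes simulate -> normalize (z-score per replicate, average) ->
#' call peaks (+ control subtraction) -> annotate -> metagene profiles ->
#' expression summarization -> gene-set statistics, writes all artifacts
#' under `out_dir` (TSV/BED; omitted when `out_dir` is `NULL`), and returns
#' a report of per-stage counts. Re-running with the same config reproduces
#' identical artifacts.
#'
#' @param config a [run_config()].
#' @param out_dir output directory, or `NULL` to skip writing.
#' @param quiet suppress progress messages.
#' @return a list (`run_report`): the simulated data, averaged z-score
#'   tracks, peaks, annotations, chromosome distribution, profiles, gene
#'   score table, classified gene set and a `counts` list of bookkeeping
#'   numbers.
#' @export
run_pipeline <- function(config, out_dir = NULL, quiet = TRUE) {
  say <- function(...) if (!quiet) message(...)
  t0 <- Sys.time()
  sim <- config$sim
  say("stage simulate")
  genome <- make_genome(sim)
  genes <- genome$genes; layout <- genome$layout; truth <- genome$truth
  targets <- names(sim$shape_table)
  reps <- lapply(setNames(targets, targets), function(t)
    simulate_chip(genes, layout, sim, t))

  say("stage normalize")
  ztracks <- lapply(reps, function(rl) {
    zs <- lapply(rl, function(tr) { tr$value <- zscore_standardize(tr$value); tr })
    average_replicates(zs)
  })

  say("stage callpeaks")
  track <- ztracks[[config$chip_target]]
  win <- slide_windows(track, layout, config$window, config$step,
                       config$min_probes)
  null_sd <- estimate_null_sd(track$value)
  win <- window_pvalue(win, null_sd)
  peaks_raw <- call_peaks(win, track, config$cutoff,
                          id_prefix = config$chip_target)
  ctrack <- ztracks[[config$control_target]]
  cwin <- window_pvalue(slide_windows(ctrack, layout, config$window,
                                      config$step, config$min_probes),
                        estimate_null_sd(ctrack$value))
  control_peaks <- call_peaks(cwin, ctrack, config$cutoff,
                              id_prefix = config$control_target)
  peaks <- subtract_control_peaks(peaks_raw, control_peaks,
                                  config$control_max_gap)

  say("stage annotate")
  ann <- peaks_to_genes(peaks, genes, config$flank)
  features <- assign_summit_feature(peaks, genes, config$flank)
  chrdist <- chromosome_distribution(peaks, layout)

  say("stage expression")
  expr <- simulate_expression(genes, sim)
  qn <- quantile_normalize(expr$matrix)
  per_gene <- summarize_gene(qn, expr$probe_gene)
  rna_z <- average_and_zscore(per_gene)
  genes$expression <- unname(rowMeans(per_gene)[genes$gene_id])

  say("stage profile")
  groups <- quantile_bin_genes(genes, k = config$n_expression_bins)
  prof_tss <- metagene_profile(track, genes, groups, "TSS")
  prof_tes <- metagene_profile(track, genes, groups, "TES")
  triplets <- find_exon_triplets(genes)

  say("stage genesets")
  scores <- gene_score_table(genes, ztracks, rna_z)
  selected <- classify_high_low(scores, config$high_targets,
                                config$low_targets, config$high_threshold,
                                config$low_threshold)
  # recovery against the implanted truth for the called target
  amp_col <- paste0("amp_", config$chip_target)
  truth_genes <- truth[truth[[amp_col]] != 0, , drop = FALSE]
  hit_gene <- .overlaps_any(truth_genes$start, truth_genes$end,
                            peaks$start, peaks$end,
                            truth_genes$chrom, peaks$chrom)
  hit_peak <- .overlaps_any(peaks$start, peaks$end,
                            truth_genes$start, truth_genes$end,
                            peaks$chrom, truth_genes$chrom)
  recall <- if (nrow(truth_genes)) mean(hit_gene) else NA_real_
  precision <- if (nrow(peaks)) mean(hit_peak) else NA_real_

  counts <- list(n_probes = nrow(track), n_windows = nrow(win),
                 n_peaks_raw = nrow(peaks_raw),
                 n_control_peaks = nrow(control_peaks),
                 n_peaks_removed = attr(peaks, "n_removed"),
                 n_peaks = nrow(peaks),
                 relation_counts = ann$counts,
                 n_bound_genes = length(ann$bound_genes),
                 n_flank_genes = length(ann$flank_genes),
                 n_selected_genes = length(selected),
                 n_triplets = nrow(triplets),
                 recall = recall, precision = precision)
  if (counts$n_peaks_raw - counts$n_peaks_removed != counts$n_peaks)
    stop("internal invariant violated: peak bookkeeping does not balance")
  if (sum(ann$counts) != nrow(peaks))
    stop("internal invariant violated: relations do not partition the peaks")

  report <- list(genes = genes, layout = layout, truth = truth,
                 tracks = ztracks, windows = win, peaks = peaks,
                 control_peaks = control_peaks, relations = ann$relations,
                 summit_features = features, bound_genes = ann$bound_genes,
                 flank_genes = ann$flank_genes, chrom_distribution = chrdist,
                 profiles = list(TSS = prof_tss, TES = prof_tes),
                 triplets = triplets, scores = scores,
                 selected_genes = selected, rna_z = rna_z, counts = counts,
                 elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_genes_bed12(genes, file.path(out_dir, "genes.bed12"))
    write_tsv(truth, file.path(out_dir, "truth.tsv"))
    write_peaks_bed(peaks, file.path(out_dir, "peaks.bed"))
    write_peaks_bed(control_peaks, file.path(out_dir, "control_peaks.bed"))
    write_tsv(cbind(ann$relations, feature = features),
              file.path(out_dir, "peak_annotations.tsv"))
    write_tsv(chrdist$table, file.path(out_dir, "chrom_distribution.tsv"))
    write_tsv(prof_tss, file.path(out_dir, "profile_tss.tsv"))
    write_tsv(prof_tes, file.path(out_dir, "profile_tes.tsv"))
    write_tsv(scores, file.path(out_dir, "gene_scores.tsv"))
    writeLines(selected, file.path(out_dir, "selected_genes.txt"))
  }
  report
}
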