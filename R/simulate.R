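# default class mix: proportions of the six temporal-spatial expression
# classes, proportional to the published class sizes
# (4693 / 169 / 797 / 323 / 2580 / 415 genes)
.DEFAULT_CLASS_SIZES <- c(
  "germline-expressed" = 4693,
  "germline-specific"  = 169,
  "embryo-expressed"   = 797,
  "soma-specific"      = 323,
  "ubiquitous"         = 2580,
  "silent"             = 415
)

.DEFAULT_TARGETS <- c(mes4 = "five-prime-skewed-body",
                      pol2 = "tss-and-tes-peak",
                      h3k36me3 = "flat-body",
                      noab = "flat-body")

.SHAPES <- c("flat-body", "five-prime-skewed-body", "tss-peak",
             "tss-and-tes-peak", "anti-expressed", "promoter-dip")

.default_effect_table <- function() {
  classes <- names(.DEFAULT_CLASS_SIZES)
  tab <- expand.grid(class_label = classes,
                     target = names(.DEFAULT_TARGETS),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tab$amplitude <- 0
  germline <- c("germline-expressed", "germline-specific", "ubiquitous")
  transcribed <- c("germline-expressed", "ubiquitous", "embryo-expressed",
                   "soma-specific")
  tab$amplitude[tab$target %in% c("mes4", "h3k36me3") &
                  tab$class_label %in% germline] <- 5
  tab$amplitude[tab$target == "pol2" & tab$class_label %in% transcribed] <- 5
  tab
}

#' Configuration for the synthetic tiling-array study
#'
#' Bundles and validates every knob of the generator: the toy genome, the
#' gene-class mixture, the probe tiling, the per-(class, target) enrichment
#' amplitudes and per-target profile shapes, the replicate structure and the
#' noise level. Defaults describe the benchmark conditions: six 1-Mb
#' chromosomes (five autosomes plus an X-like chromosome largely closed to
#' germline-expressed gene classes), 200 genes mixed in proportion to the
#' published class sizes, amplitude 5 on the log2 scale, Gaussian probe
#' noise with SD 1, and 3 replicates per target.
#'
#' @param seed master RNG seed (integer).
#' @param chrom_lengths named vector of chromosome lengths (>= 2 chromosomes).
#' @param x_chrom name of the X-like chromosome.
#' @param n_genes number of genes to place.
#' @param class_mix named class proportions summing to 1.
#' @param x_germline_depletion probability that a germline-class gene is
#'   allowed on the X-like chromosome.
#' @param germline_classes classes subject to the X-like depletion.
#' @param probe_length,probe_spacing probe tiling in bp.
#' @param n_replicates replicates per ChIP target.
#' @param noise_sd per-probe Gaussian noise SD (log2 scale).
#' @param effect_table data.frame `class_label`, `target`, `amplitude`; must
#'   cover every class in `class_mix` for every target.
#' @param shape_table named character vector target -> profile shape, one of
#'   `r paste(.SHAPES, collapse=", ")`.
#' @param frac_long fraction of genes drawn longer than 2 kb (metagene
#'   eligibility).
#' @param expression_means named per-class mean expression (log2 scale).
#' @param expr_gene_sd,expr_probe_sd,expr_noise_sd expression-array spread
#'   of gene effects, probe offsets and residual noise.
#' @param n_expr_samples expression-array samples (default 4).
#' @param allow_opposite_overlap permit opposite-strand gene overlap when
#'   placing genes (default FALSE).
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       chrom_lengths = c(chrI = 1e6, chrII = 1e6, chrIII = 1e6,
                                         chrIV = 1e6, chrV = 1e6, chrX = 1e6),
                       x_chrom = "chrX",
                       n_genes = 200L,
                       class_mix = .DEFAULT_CLASS_SIZES /
                         sum(.DEFAULT_CLASS_SIZES),
                       x_germline_depletion = 0.1,
                       germline_classes = c("germline-expressed",
                                            "germline-specific", "ubiquitous"),
                       probe_length = 50L, probe_spacing = 50L,
                       n_replicates = 3L, noise_sd = 1,
                       effect_table = .default_effect_table(),
                       shape_table = .DEFAULT_TARGETS,
                       frac_long = 0.7,
                       expression_means = c("germline-expressed" = 2,
                                            "germline-specific" = 1.5,
                                            "embryo-expressed" = 2,
                                            "soma-specific" = 0.5,
                                            "ubiquitous" = 2.5,
                                            "silent" = 0),
                       expr_gene_sd = 0.5, expr_probe_sd = 0.3,
                       expr_noise_sd = 0.2, n_expr_samples = 4L,
                       allow_opposite_overlap = FALSE) {
  cfg <- list(seed = as.integer(seed), chrom_lengths = chrom_lengths,
              x_chrom = x_chrom, n_genes = as.integer(n_genes),
              class_mix = class_mix,
              x_germline_depletion = x_germline_depletion,
              germline_classes = germline_classes,
              probe_length = as.integer(probe_length),
              probe_spacing = as.integer(probe_spacing),
              n_replicates = as.integer(n_replicates), noise_sd = noise_sd,
              effect_table = effect_table, shape_table = shape_table,
              frac_long = frac_long, expression_means = expression_means,
              expr_gene_sd = expr_gene_sd, expr_probe_sd = expr_probe_sd,
              expr_noise_sd = expr_noise_sd,
              n_expr_samples = as.integer(n_expr_samples),
              allow_opposite_overlap = allow_opposite_overlap)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#' @param cfg a `sim_config` list.
#' @return the config, invisibly; errors describe the violated invariant.
#' @export
validate_sim_config <- function(cfg) {
  if (length(cfg$chrom_lengths) < 2 || is.null(names(cfg$chrom_lengths)))
    stop("need >= 2 named chromosomes")
  if (any(cfg$chrom_lengths <= 0)) stop("all chromosome lengths must be positive")
  if (!cfg$x_chrom %in% names(cfg$chrom_lengths))
    stop("x_chrom must name one of the chromosomes")
  if (abs(sum(cfg$class_mix) - 1) > 1e-9)
    stop("class proportions must sum to 1")
  if (cfg$probe_spacing < 1) stop("probe_spacing must be >= 1")
  if (cfg$probe_length < 1) stop("probe_length must be >= 1")
  if (cfg$x_germline_depletion < 0 || cfg$x_germline_depletion > 1)
    stop("x_germline_depletion must be in [0, 1]")
  if (!all(cfg$shape_table %in% .SHAPES))
    stop("unknown profile shape(s): ",
         paste(setdiff(cfg$shape_table, .SHAPES), collapse = ", "))
  need <- expand.grid(class_label = names(cfg$class_mix),
                      target = names(cfg$shape_table),
                      stringsAsFactors = FALSE)
  key <- paste(cfg$effect_table$class_label, cfg$effect_table$target)
  miss <- !paste(need$class_label, need$target) %in% key
  if (any(miss))
    stop("effect_table misses (class, target) pairs: ",
         paste(paste(need$class_label, need$target)[miss][1], "..."))
  invisible(cfg)
}

# deterministic, well-separated child seed per named stream: a fresh stream
# per (label, index) so adding a target/replicate never perturbs the others
.derive_seed <- function(master, label, index) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.double(master) * 1009 + h * 7919 + index * 104729) %%
               2147483629)
}

.amplitude_lookup <- function(cfg) {
  et <- cfg$effect_table
  setNames(et$amplitude, paste(et$class_label, et$target, sep = "\r"))
}

#' Generate a toy genome: layout, annotated genes and the truth table
#'
#' Draws gene classes from the configured mixture (one multinomial draw via
#' `sample()`), draws transcript lengths so that `frac_long` of genes exceed
#' 2 kb, builds exon/intron structures with blocks long enough to feed the
#' exon-triplet analyses, and places genes without overlap (rejection
#' sampling, chromosomes weighted by length). Germline-class genes are
#' allowed onto the X-like chromosome only with probability
#' `x_germline_depletion`. Fully deterministic for a fixed seed.
#'
#' @param cfg a [sim_config()].
#' @return a list with `layout` (a [genome_layout] with the X-like
#'   chromosome focal), `genes` (a [gene_table()] with class labels) and
#'   `truth` (a data.frame: gene, class, interval, per-target amplitudes and
#'   `enriched` flag, plus attribute `chrom_counts` of implanted enriched
#'   genes per chromosome).
#' @export
make_genome <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(.derive_seed(cfg$seed, "genome", 0L))
  n <- cfg$n_genes
  classes <- sample(names(cfg$class_mix), n, replace = TRUE,
                    prob = cfg$class_mix)
  long <- runif(n) < cfg$frac_long
  len <- integer(n)
  len[long] <- as.integer(round(runif(sum(long), 2400, 6000)))
  len[!long] <- as.integer(round(runif(sum(!long), 800, 2000)))
  strand <- sample(c("+", "-"), n, replace = TRUE)

  chrs <- names(cfg$chrom_lengths)
  autos <- setdiff(chrs, cfg$x_chrom)
  occupied <- list()  # per chromosome: 2-col matrix of [start, end)
  chrom <- character(n); start <- integer(n)
  for (i in seq_len(n)) {
    allowed <- chrs
    if (classes[i] %in% cfg$germline_classes &&
        runif(1) >= cfg$x_germline_depletion)
      allowed <- autos
    placed <- FALSE
    for (try in seq_len(500L)) {
      w <- cfg$chrom_lengths[allowed]
      cand <- sample(allowed, 1, prob = w / sum(w))
      room <- cfg$chrom_lengths[[cand]] - len[i]
      if (room < 0) next
      s <- as.integer(floor(runif(1) * (room + 1)))
      occ <- occupied[[cand]]
      clash <- !is.null(occ) && any(s < occ[, 2] & s + len[i] > occ[, 1])
      if (!clash) {
        chrom[i] <- cand; start[i] <- s
        occupied[[cand]] <- rbind(occ, c(s, s + len[i]))
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      lim <- allowed[which.max(cfg$chrom_lengths[allowed])]
      stop("genome too small to place gene ", i, " without overlap ",
           "(limiting chromosome: ", lim, ")")
    }
  }
  # exon structure: first/last blocks are exons; internal blocks alternate
  # intron/exon with lengths 320-500 bp so triplets >= 300 bp exist
  exon_starts <- vector("list", n); exon_ends <- vector("list", n)
  for (i in seq_len(n)) {
    L <- len[i]; s <- start[i]
    bounds <- integer(0)
    pos <- 0L
    first_ex <- as.integer(round(runif(1, 350, 500)))
    pos <- min(first_ex, L)
    bounds <- c(0L, pos)
    while (L - pos >= 900L) {
      intr <- as.integer(round(runif(1, 320, 450)))
      ex <- as.integer(round(runif(1, 320, 450)))
      if (L - pos - intr - ex < 0L) break
      bounds <- c(bounds, pos + intr, pos + intr + ex)
      pos <- pos + intr + ex
    }
    if (bounds[length(bounds)] < L) {
      if (L - bounds[length(bounds)] >= 520L) {
        intr <- as.integer(round(runif(1, 320, min(450, L - bounds[length(bounds)] - 200L))))
        bounds <- c(bounds, bounds[length(bounds)] + intr, L)
      } else {
        bounds[length(bounds)] <- L  # extend the last exon to the end
      }
    }
    es <- bounds[seq(1, length(bounds), by = 2)]
    ee <- bounds[seq(2, length(bounds), by = 2)]
    exon_starts[[i]] <- s + es
    exon_ends[[i]] <- s + ee
  }
  ids <- sprintf("gene_%04d", seq_len(n))
  genes <- gene_table(ids, chrom, strand, start, start + len,
                      exon_starts, exon_ends, class_label = classes)
  amp <- .amplitude_lookup(cfg)
  truth <- data.frame(gene_id = ids, class_label = classes, chrom = chrom,
                      start = start, end = start + len,
                      stringsAsFactors = FALSE)
  for (t in names(cfg$shape_table))
    truth[[paste0("amp_", t)]] <- unname(amp[paste(classes, t, sep = "\r")])
  amp_cols <- paste0("amp_", names(cfg$shape_table))
  truth$enriched <- rowSums(abs(as.matrix(truth[, amp_cols, drop = FALSE]))) > 0
  attr(truth, "chrom_counts") <-
    tapply(truth$enriched, factor(truth$chrom, levels = chrs), sum,
           default = 0L)
  layout <- genome_layout(cfg$chrom_lengths, focal = cfg$x_chrom)
  list(layout = layout, genes = genes, truth = truth)
}

#' Tile probes across a genome layout
#'
#' Probe starts run 0, spacing, 2*spacing, ... while a full probe fits, so
#' each chromosome contributes `floor((length - probe_length)/spacing) + 1`
#' probes.
#'
#' @param layout a [genome_layout].
#' @param probe_length,probe_spacing tiling parameters in bp.
#' @return a probe table with `value = 0`.
#' @export
tile_probes <- function(layout, probe_length = 50, probe_spacing = 50) {
  parts <- lapply(names(layout$lengths), function(chr) {
    k <- (layout$lengths[[chr]] - probe_length) %/% probe_spacing + 1
    if (k < 1) return(NULL)
    s <- as.integer(probe_spacing * (seq_len(k) - 1))
    data.frame(chrom = chr, start = s, end = s + as.integer(probe_length),
               probe_id = sprintf("%s_p%07d", chr, seq_len(k)),
               value = 0, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

# noiseless per-probe signal for one target.
# Gene-body shapes take exactly the probes fully contained in the
# transcript; promoter/terminator shapes extend 500 bp beyond it.
.chip_signal <- function(genes, probes, cfg, target) {
  shape <- cfg$shape_table[[target]]
  if (is.null(shape)) stop("unknown target: ", target)
  amp <- .amplitude_lookup(cfg)
  sig <- numeric(nrow(probes))
  mids <- probe_mid(probes)
  for (i in seq_len(nrow(genes))) {
    a <- unname(amp[paste(genes$class_label[i], target, sep = "\r")])
    if (is.na(a) || a == 0) next
    s <- genes$tx_start[i]; e <- genes$tx_end[i]; L <- e - s
    plus <- genes$strand[i] == "+"
    tss <- if (plus) s else e
    tes <- if (plus) e else s
    support_pad <- if (shape %in% c("tss-peak", "tss-and-tes-peak",
                                    "promoter-dip")) 500L else 0L
    idx <- which(probes$chrom == genes$chrom[i] &
                   probes$start >= s - support_pad &
                   probes$end <= e + support_pad)
    if (!length(idx)) next
    d <- if (plus) mids[idx] - tss else tss - mids[idx]  # bp into the body
    in_body <- probes$start[idx] >= s & probes$end[idx] <= e
    f <- switch(shape,
      "flat-body" = as.numeric(in_body),
      "anti-expressed" = as.numeric(in_body),
      "five-prime-skewed-body" = ifelse(in_body,
        ifelse(d < 500, 0.4 + 0.6 * d / 500,
               1 - 0.3 * (d - 500) / max(L - 500, 1)), 0),
      "tss-peak" = exp(-(mids[idx] - tss)^2 / (2 * 250^2)),
      "tss-and-tes-peak" = {
        tes_off <- if (plus) tes + 150 else tes - 150
        exp(-(mids[idx] - tss)^2 / (2 * 200^2)) +
          0.8 * exp(-(mids[idx] - tes_off)^2 / (2 * 200^2)) +
          0.3 * as.numeric(in_body)
      },
      "promoter-dip" = ifelse(in_body,
        1 - 0.8 * exp(-(mids[idx] - tss)^2 / (2 * 150^2)), 0))
    sig[idx] <- sig[idx] + a * f
  }
  sig
}

#' Simulate replicate ChIP log2-ratio tracks for one target
#'
#' Probe value = shape(gene, position) x amplitude(class, target) +
#' Gaussian(0, noise_sd). Replicates share the noiseless signal and differ
#' only in noise; each (target, replicate) pair draws from its own seeded
#' stream, so adding targets or replicates never perturbs the others.
#'
#' @param genes gene model table from [make_genome()].
#' @param layout the matching [genome_layout].
#' @param cfg the [sim_config()].
#' @param target target name (must be in `cfg$shape_table`).
#' @return a named list of probe tables, one per replicate
#'   (`rep1`, `rep2`, ...).
#' @export
simulate_chip <- function(genes, layout, cfg, target) {
  validate_sim_config(cfg)
  if (!target %in% names(cfg$shape_table)) stop("unknown target: ", target)
  probes <- tile_probes(layout, cfg$probe_length, cfg$probe_spacing)
  sig <- .chip_signal(genes, probes, cfg, target)
  reps <- lapply(seq_len(cfg$n_replicates), function(r) {
    set.seed(.derive_seed(cfg$seed, paste0("chip:", target), r))
    out <- probes
    out$value <- sig + rnorm(nrow(probes), 0, cfg$noise_sd)
    out
  })
  names(reps) <- paste0("rep", seq_len(cfg$n_replicates))
  reps
}

#' Simulate a multi-probe expression array
#'
#' Three probes per gene, `n_expr_samples` samples; probe value =
#' gene effect + probe offset + Gaussian noise, with the gene effect drawn
#' around the configured class mean. Deterministic per seed.
#'
#' @param genes gene model table from [make_genome()].
#' @param cfg the [sim_config()].
#' @param probes_per_gene probes per gene (default 3).
#' @return a list: `matrix` (probes x samples, log2 scale), `probe_gene`
#'   (row -> gene id map), `true_gene_effect` (named vector).
#' @export
simulate_expression <- function(genes, cfg, probes_per_gene = 3L) {
  validate_sim_config(cfg)
  miss <- setdiff(unique(genes$class_label), names(cfg$expression_means))
  if (length(miss))
    stop("no configured mean expression for class(es): ",
         paste(miss, collapse = ", "))
  set.seed(.derive_seed(cfg$seed, "expression", 0L))
  n <- nrow(genes)
  gene_eff <- cfg$expression_means[genes$class_label] +
    rnorm(n, 0, cfg$expr_gene_sd)
  probe_gene <- rep(genes$gene_id, each = probes_per_gene)
  probe_off <- rnorm(n * probes_per_gene, 0, cfg$expr_probe_sd)
  m <- matrix(rep(gene_eff, each = probes_per_gene) + probe_off,
              nrow = n * probes_per_gene, ncol = cfg$n_expr_samples)
  m <- m + matrix(rnorm(length(m), 0, cfg$expr_noise_sd), nrow = nrow(m))
  rownames(m) <- sprintf("%s_ep%d", probe_gene,
                         rep(seq_len(probes_per_gene), times = n))
  colnames(m) <- paste0("sample", seq_len(cfg$n_expr_samples))
  list(matrix = m, probe_gene = probe_gene,
       true_gene_effect = setNames(unname(gene_eff), genes$gene_id))
}
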