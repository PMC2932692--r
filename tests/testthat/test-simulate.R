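small_cfg <- function(...) {
  args <- list(seed = 101,
               chrom_lengths = c(chrI = 2e5, chrII = 2e5, chrX = 2e5),
               n_genes = 30)
  args <- utils::modifyList(args, list(...))
  do.call(sim_config, args)
}

test_that("the generator is deterministic and conserves probe counts", {
  cfg <- small_cfg()
  g1 <- make_genome(cfg)
  g2 <- make_genome(cfg)
  expect_identical(g1, g2)
  r1 <- simulate_chip(g1$genes, g1$layout, cfg, "mes4")
  r2 <- simulate_chip(g2$genes, g2$layout, cfg, "mes4")
  expect_identical(r1, r2)

  # probe conservation: floor((L - probe_len)/spacing) + 1 per chromosome
  pr <- tile_probes(g1$layout, cfg$probe_length, cfg$probe_spacing)
  want <- sum((cfg$chrom_lengths - cfg$probe_length) %/% cfg$probe_spacing + 1)
  expect_equal(nrow(pr), want)
  cfg2 <- small_cfg(probe_spacing = 37L, probe_length = 60L)
  pr2 <- tile_probes(g1$layout, 60L, 37L)
  expect_equal(nrow(pr2), sum((cfg2$chrom_lengths - 60) %/% 37 + 1))
  expect_true(all(pr2$end <= cfg2$chrom_lengths[pr2$chrom]))
})

test_that("class draws reproduce the seeded multinomial stream", {
  cfg <- sim_config(seed = 7, n_genes = 200)
  g <- make_genome(cfg)
  # independent re-draw from the same derived stream
  set.seed(chiptile:::.derive_seed(7L, "genome", 0L))
  want <- sample(names(cfg$class_mix), 200, replace = TRUE,
                 prob = cfg$class_mix)
  expect_equal(g$genes$class_label, want)
  expect_equal(as.vector(table(g$genes$class_label)),
               as.vector(table(want)))
})

test_that("germline-class genes avoid the X-like chromosome when depleted", {
  cfg <- small_cfg(class_mix = c("germline-specific" = 1),
                   x_germline_depletion = 0)
  g <- make_genome(cfg)
  expect_equal(sum(g$genes$chrom == "chrX"), 0)
  # with depletion 1 the X is open again
  cfg2 <- small_cfg(class_mix = c("germline-specific" = 1),
                    x_germline_depletion = 1)
  g2 <- make_genome(cfg2)
  expect_gt(sum(g2$genes$chrom == "chrX"), 0)
  # non-germline classes are never restricted
  cfg3 <- small_cfg(class_mix = c("silent" = 1), x_germline_depletion = 0)
  g3 <- make_genome(cfg3)
  expect_gt(sum(g3$genes$chrom == "chrX"), 0)
})

test_that("genes never overlap and stay within chromosome bounds", {
  cfg <- small_cfg(n_genes = 60)
  g <- make_genome(cfg)
  expect_true(all(g$genes$tx_end <= cfg$chrom_lengths[g$genes$chrom]))
  for (chr in unique(g$genes$chrom)) {
    sub <- g$genes[g$genes$chrom == chr, ]
    sub <- sub[order(sub$tx_start), ]
    if (nrow(sub) > 1)
      expect_true(all(sub$tx_start[-1] >= sub$tx_end[-nrow(sub)]))
  }
  # an impossible request names the limiting chromosome
  tiny <- sim_config(seed = 1, chrom_lengths = c(chrA = 5000, chrX = 5000),
                     n_genes = 50)
  expect_error(make_genome(tiny), "limiting chromosome")
})

test_that("noiseless flat-body signal equals the amplitude on contained probes", {
  cfg <- small_cfg(noise_sd = 0, n_replicates = 1,
                   class_mix = c("germline-expressed" = 1),
                   frac_long = 1)
  g <- make_genome(cfg)
  tr <- simulate_chip(g$genes, g$layout, cfg, "h3k36me3")$rep1  # flat-body, amp 5
  genes <- g$genes
  contained <- rep(FALSE, nrow(tr))
  for (i in seq_len(nrow(genes))) {
    contained <- contained | (tr$chrom == genes$chrom[i] &
                                tr$start >= genes$tx_start[i] &
                                tr$end <= genes$tx_end[i])
  }
  expect_true(all(tr$value[contained] == 5))
  expect_true(all(tr$value[!contained] == 0))
  # truth-consistency: every enriched interval overlies amplitude-value probes
  truth <- g$truth[g$truth$enriched, ]
  for (i in seq_len(nrow(truth))) {
    sel <- tr$chrom == truth$chrom[i] & tr$start >= truth$start[i] &
      tr$end <= truth$end[i]
    expect_equal(mean(tr$value[sel]), truth$amp_h3k36me3[i])
  }
})

test_that("tss-peak shapes put their maximum at the probe nearest the TSS", {
  cfg <- small_cfg(noise_sd = 0, n_replicates = 1, n_genes = 5,
                   class_mix = c("germline-expressed" = 1),
                   shape_table = c(mes4 = "tss-peak", pol2 = "tss-and-tes-peak",
                                   h3k36me3 = "flat-body", noab = "flat-body"))
  g <- make_genome(cfg)
  tr <- simulate_chip(g$genes, g$layout, cfg, "mes4")$rep1
  mids <- probe_mid(tr)
  for (i in seq_len(nrow(g$genes))) {
    tss <- if (g$genes$strand[i] == "+") g$genes$tx_start[i] else
      g$genes$tx_end[i]
    near <- which(tr$chrom == g$genes$chrom[i] & abs(mids - tss) <= 2000)
    best <- near[which.max(tr$value[near])]
    expect_lte(abs(mids[best] - tss), min(abs(mids[near] - tss)) + 50)
  }
})

test_that("replicates share signal and differ only in seeded noise", {
  cfg <- small_cfg(noise_sd = 0.5, n_replicates = 3)
  g <- make_genome(cfg)
  reps <- simulate_chip(g$genes, g$layout, cfg, "mes4")
  expect_equal(length(reps), 3)
  d12 <- reps$rep1$value - reps$rep2$value
  expect_gt(sd(d12), 0)   # noise differs
  # background probes average near zero (CLT bound at 3 sigma / sqrt(n))
  bg <- rep(TRUE, nrow(reps$rep1))
  for (i in seq_len(nrow(g$genes)))
    bg <- bg & !(reps$rep1$chrom == g$genes$chrom[i] &
                   reps$rep1$start >= g$genes$tx_start[i] - 500 &
                   reps$rep1$end <= g$genes$tx_end[i] + 500)
  n_bg <- sum(bg)
  expect_gt(n_bg, 1000)
  expect_lt(abs(mean(reps$rep1$value[bg])), 3 * 0.5 / sqrt(n_bg))
  # adding a replicate must not perturb earlier ones
  cfg4 <- small_cfg(noise_sd = 0.5, n_replicates = 4)
  reps4 <- simulate_chip(g$genes, g$layout, cfg4, "mes4")
  expect_identical(reps4$rep2, reps$rep2)
})

test_that("expression arrays follow gene effect + probe offset + noise", {
  cfg <- small_cfg(expr_gene_sd = 0, expr_probe_sd = 0, expr_noise_sd = 0)
  g <- make_genome(cfg)
  ex <- simulate_expression(g$genes, cfg)
  expect_equal(dim(ex$matrix), c(3 * nrow(g$genes), 4))
  means <- cfg$expression_means[g$genes$class_label]
  for (j in 1:4)
    expect_equal(unname(ex$matrix[, j]), rep(unname(means), each = 3))
  # class-mean ordering is preserved in the noiseless output
  silent <- ex$matrix[ex$probe_gene %in%
                        g$genes$gene_id[g$genes$class_label == "silent"], 1]
  ubiq <- ex$matrix[ex$probe_gene %in%
                      g$genes$gene_id[g$genes$class_label == "ubiquitous"], 1]
  if (length(silent) && length(ubiq)) expect_lt(max(silent), min(ubiq))

  # seeded noisy run: per-gene means match independent recomputation
  cfg2 <- small_cfg()
  ex2 <- simulate_expression(g$genes, cfg2)
  ex3 <- simulate_expression(g$genes, cfg2)
  expect_identical(ex2, ex3)
  gm <- tapply(rowMeans(ex2$matrix), ex2$probe_gene, mean)
  for (gid in g$genes$gene_id[1:5])
    expect_equal(unname(gm[gid]),
                 mean(rowMeans(ex2$matrix[ex2$probe_gene == gid, ])))
})
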