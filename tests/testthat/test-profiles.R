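test_that("expression binning splits eligible genes into equal stable groups", {
  genes <- gene_table(sprintf("g%02d", 1:12), rep("chrA", 12), rep("+", 12),
                      seq(0, by = 10000, length.out = 12),
                      seq(0, by = 10000, length.out = 12) +
                        c(rep(3000, 10), 1500, 1500),
                      expression = c(10:1, 99, 98))
  grp <- quantile_bin_genes(genes, k = 5)
  expect_equal(nrow(grp), 10)           # the two short genes are excluded
  expect_equal(unname(table(grp$group)), rep(2L, 5), ignore_attr = TRUE)
  # lowest expression in group 1: g10 has expression 1
  expect_equal(sort(grp$gene_id[grp$group == 1]), c("g09", "g10"))
  expect_equal(sort(grp$gene_id[grp$group == 5]), c("g01", "g02"))

  # all-equal expression: stable gene-id order partition
  tied <- genes
  tied$expression <- rep(1, 12)
  gt <- quantile_bin_genes(tied, k = 5)
  expect_equal(gt$gene_id, sprintf("g%02d", 1:10))
  expect_equal(gt$group, rep(1:5, each = 2))

  # seeded fixture equals an independent sort-and-slice oracle
  fx <- random_fixture(31)
  grp <- quantile_bin_genes(fx$genes, k = 4)
  elig <- fx$genes[fx$genes$tx_end - fx$genes$tx_start > 2000, ]
  ord <- order(elig$expression, elig$gene_id)
  want <- ceiling(seq_along(ord) * 4 / length(ord))
  expect_equal(grp$gene_id, elig$gene_id[ord])
  expect_equal(grp$group, want)
  expect_error(quantile_bin_genes(genes[1:3, ], k = 5), "fewer than k")
})

test_that("metagene bins assign probes to the nearest center, ties left", {
  layout <- genome_layout(c(chrA = 2e4), focal = "chrA")
  genes <- gene_table("g1", "chrA", "+", 5000, 10000)
  groups <- data.frame(gene_id = "g1", group = 1L)
  one <- toy_track(5000, 4, chrom = "chrA")   # midpoint 5025 -> bin +0..+50
  pr <- metagene_profile(one, genes, groups, "TSS")
  hit <- pr[!is.na(pr$mean), ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$bin_center, 25)
  expect_equal(hit$mean, 4)
  expect_equal(hit$n_probes, 1)

  # constant track: every covered bin mean is the constant with zero CI
  tr <- tiled_track(layout, values = rep(2.2, 400))
  pr <- metagene_profile(tr, genes, groups, "TSS")
  expect_true(all(pr$mean == 2.2))
  expect_true(all(pr$ci95 == 0))
  expect_equal(nrow(pr), 50)
})

test_that("metagene matrices equal the brute-force oracle, both anchors", {
  fx <- random_fixture(41, chrom_len = 1.2e5)
  groups <- quantile_bin_genes(fx$genes, k = 3, min_len = 1500)
  for (anchor in c("TSS", "TES")) {
    win <- if (anchor == "TSS") c(-1000, 1500) else c(-1500, 1000)
    got <- metagene_profile(fx$track, fx$genes, groups, anchor)
    want <- oracle_metagene(fx$track, fx$genes, groups, anchor, win)
    expect_equal(got$mean, want$mean, tolerance = 1e-12)
    expect_equal(got$ci95, want$ci95, tolerance = 1e-12)
    expect_equal(got$n_probes, want$n_probes)
  }
  # the alternative TSS window is honored
  alt <- metagene_profile(fx$track, fx$genes, groups, "TSS",
                          tss_window = c(-1500, 1000))
  want <- oracle_metagene(fx$track, fx$genes, groups, "TSS", c(-1500, 1000))
  expect_equal(alt$mean, want$mean, tolerance = 1e-12)
})

test_that("profiles are invariant under mirroring the whole genome", {
  fx <- random_fixture(43, chrom_len = 1e5)
  groups <- quantile_bin_genes(fx$genes, k = 3, min_len = 1500)
  fwd_tss <- metagene_profile(fx$track, fx$genes, groups, "TSS")
  fwd_tes <- metagene_profile(fx$track, fx$genes, groups, "TES")
  mg <- mirror_genes(fx$genes, fx$layout)
  mt <- mirror_track(fx$track, fx$layout)
  expect_equal(metagene_profile(mt, mg, groups, "TSS"), fwd_tss)
  expect_equal(metagene_profile(mt, mg, groups, "TES"), fwd_tes)
})

test_that("exon triplets require internal exons with long flanking introns", {
  single <- gene_table("s", "chrA", "+", 0, 2000)
  expect_equal(nrow(find_exon_triplets(single)), 0)

  # exons 400/400/400 with introns 350/350: exactly the middle exon
  g <- gene_table("t", "chrA", "+", 1000, 2900,
                  list(c(1000, 1750, 2500)), list(c(1400, 2150, 2900)))
  tri <- find_exon_triplets(g, 300)
  expect_equal(nrow(tri), 1)
  expect_equal(tri$exon_start, 1750)
  expect_equal(tri$exon_end, 2150)
  expect_equal(tri$intron_left_start, 1400)
  expect_equal(tri$intron_right_end, 2500)
  # a short intron disqualifies the exon
  g2 <- gene_table("t2", "chrA", "+", 1000, 2750,
                   list(c(1000, 1600, 2350)), list(c(1400, 2000, 2750)))
  expect_equal(nrow(find_exon_triplets(g2, 300)), 0)

  # exhaustive enumeration oracle on a random fixture
  fx <- random_fixture(47)
  tri <- find_exon_triplets(fx$genes, 300)
  want <- 0L
  for (i in seq_len(nrow(fx$genes))) {
    es <- fx$genes$exon_starts[[i]]; ee <- fx$genes$exon_ends[[i]]
    if (length(es) < 3) next
    for (j in 2:(length(es) - 1)) {
      if (ee[j] - es[j] >= 300 && es[j] - ee[j - 1] >= 300 &&
          es[j + 1] - ee[j] >= 300) want <- want + 1L
    }
  }
  expect_equal(nrow(tri), want)
})

test_that("exon-boundary profiles subtract the intronic baseline per triplet", {
  # plus-strand triplet: intron 600, exon 600, intron 600
  g <- gene_table("t", "chrA", "+", 0, 2400,
                  list(c(0, 900, 2100)), list(c(300, 1500, 2400)))
  tri <- find_exon_triplets(g, 300)
  expect_equal(nrow(tri), 1)
  groups <- data.frame(gene_id = "t", group = 1L)
  # exonic value 3, intronic value 1 (step function), probes every 50 bp
  layout <- genome_layout(c(chrA = 2400), focal = "chrA")
  tr <- tiled_track(layout)
  mids <- probe_mid(tr)
  tr$value <- ifelse(mids >= 900 & mids < 1500, 3, 1)
  prof <- exon_boundary_profile(tr, tri, groups, baseline_subtract = TRUE)
  expect_equal(prof$n_skipped, 0)
  st <- prof$start
  exonic <- st$bin_center > 0
  expect_equal(st$mean[exonic], rep(2, sum(exonic)))      # e - i
  expect_equal(st$mean[!exonic], rep(0, sum(!exonic)))    # introns -> 0
  en <- prof$end
  expect_equal(en$mean[en$bin_center < 0], rep(2, sum(en$bin_center < 0)))
  expect_equal(en$mean[en$bin_center > 0], rep(0, sum(en$bin_center > 0)))

  # constant track with subtraction: everything zero
  tr0 <- tr; tr0$value <- 5
  p0 <- exon_boundary_profile(tr0, tri, groups, baseline_subtract = TRUE)
  expect_true(all(p0$start$mean == 0))
  expect_true(all(p0$end$mean == 0))

  # mirroring invariance holds for boundary profiles too
  mg <- mirror_genes(g, layout)
  mtri <- find_exon_triplets(mg, 300)
  mtr <- mirror_track(tr, layout)
  mp <- exon_boundary_profile(mtr, mtri, groups, baseline_subtract = TRUE)
  expect_equal(mp$start$mean, prof$start$mean)
  expect_equal(mp$end$mean, prof$end$mean)
})
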