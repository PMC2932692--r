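test_that("gene-body mean z averages fully contained probes only", {
  genes <- gene_table("g1", "chrA", "+", 100, 1000)
  tr <- toy_track(c(40, 100, 900, 960), c(9, 2, 4, 9), chrom = "chrA")
  # probe [40,90) outside; [100,150) and [900,950) inside; [960,1010) crosses
  expect_equal(gene_mean_z(tr, genes), c(g1 = 3))
  one <- toy_track(200, 2, chrom = "chrA")
  expect_equal(gene_mean_z(one, genes), c(g1 = 2))
  # gene shorter than the probe length cannot contain any probe
  short <- gene_table("tiny", "chrA", "+", 100, 130)
  expect_equal(gene_mean_z(tr, short), c(tiny = NA_real_))

  fx <- random_fixture(17)
  expect_equal(gene_mean_z(fx$track, fx$genes),
               oracle_gene_mean(fx$track, fx$genes))
})

test_that("peak relations follow the body > upstream > downstream precedence", {
  genes <- gene_table(c("plus", "minus"), c("chrA", "chrA"), c("+", "-"),
                      c(10000, 30000), c(12000, 32000))
  # peak inside a gene body
  inside <- peak_table("chrA", 10500, 11000, "pk1", 10700, 3, 1e-30)
  r <- peaks_to_genes(inside, genes)
  expect_equal(r$relations$relation, "gene-body")
  expect_equal(r$bound_genes, "plus")
  # 500 bp upstream of a minus-strand gene means right of its tx_end
  up_minus <- peak_table("chrA", 32400, 32700, "pk2", 32500, 3, 1e-30)
  expect_equal(peaks_to_genes(up_minus, genes)$relations$relation,
               "upstream-1kb")
  # the same interval left of the minus gene is downstream
  dn_minus <- peak_table("chrA", 29300, 29700, "pk3", 29500, 3, 1e-30)
  expect_equal(peaks_to_genes(dn_minus, genes)$relations$relation,
               "downstream-1kb")
  far <- peak_table("chrA", 50000, 50500, "pk4", 50200, 3, 1e-30)
  rf <- peaks_to_genes(far, genes)
  expect_equal(rf$relations$relation, "intergenic")
  expect_equal(length(rf$bound_genes), 0)
})

test_that("relation counts partition a hand-enumerated 12-peak toy", {
  genes <- gene_table(c("g1", "g2", "g3", "g4"),
                      rep("chrA", 4), c("+", "-", "+", "-"),
                      c(5000, 20000, 40000, 60000),
                      c(8000, 24000, 43000, 63000))
  s <- c(5500,  7900, 19000, 24500,  4200,  8200, 39500, 43500,
         50000, 55000, 62000, 63500)
  e <- s + 400
  pk <- peak_table(rep("chrA", 12), s, e, sprintf("pk%02d", 1:12),
                   s + 200, rep(3, 12), rep(1e-30, 12))
  r <- peaks_to_genes(pk, genes)
  # hand enumeration:
  # 5500,7900 in g1 body; 24500 in g2 up-flank (minus); 19000 g2 dn-flank;
  # 4200 g1 up; 8200 g1 dn; 39500 g3 up; 43500 g3 dn; 62000 g4 body;
  # 63500 g4 up; 50000/55000 intergenic
  expect_equal(unname(r$counts),
               c(3L, 4L, 3L, 2L))
  expect_equal(sum(r$counts), 12)
  expect_setequal(r$bound_genes, c("g1", "g4"))
  expect_setequal(r$flank_genes, c("g2", "g3"))
})

test_that("summit features follow the exon > intron > 3' > 5' hierarchy", {
  genes <- gene_table("g1", "chrA", "+", 1000, 4000,
                      list(c(1000, 2000, 3500)), list(c(1500, 2500, 4000)))
  mk <- function(summit) peak_table("chrA", summit - 100, summit + 100, "p",
                                    summit, 3, 1e-30)
  expect_equal(assign_summit_feature(mk(1200), genes), "exon")
  expect_equal(assign_summit_feature(mk(1700), genes), "intron")
  expect_equal(assign_summit_feature(mk(4500), genes), "3'")
  expect_equal(assign_summit_feature(mk(500), genes), "5'")
  expect_equal(assign_summit_feature(mk(8000), genes), "distal")
  # an exon of one gene inside the flank of a neighbor is still "exon"
  two <- gene_table(c("g1", "g2"), c("chrA", "chrA"), c("+", "+"),
                    c(1000, 4200), c(4000, 6000))
  expect_equal(assign_summit_feature(mk(3800), two), "exon")

  # randomized fixture vs a literal rule-by-rule checker
  fx <- random_fixture(23)
  set.seed(23)
  summits <- sort(sample(2e5 - 1, 40)) # peak tables sort by start
  pk <- peak_table(rep("chrA", 40), pmax(summits - 100, 0), summits + 100,
                   sprintf("p%02d", 1:40), summits, rep(3, 40),
                   rep(1e-30, 40))
  got <- assign_summit_feature(pk, fx$genes)
  fl <- 1000
  want <- vapply(summits, function(p) {
    g <- fx$genes[fx$genes$chrom == "chrA", ]
    in_ex <- FALSE; in_body <- FALSE; in3 <- FALSE; in5 <- FALSE
    for (i in seq_len(nrow(g))) {
      for (j in seq_along(g$exon_starts[[i]]))
        if (p >= g$exon_starts[[i]][j] && p < g$exon_ends[[i]][j])
          in_ex <- TRUE
      if (p >= g$tx_start[i] && p < g$tx_end[i]) in_body <- TRUE
      if (g$strand[i] == "+") {
        if (p >= g$tx_end[i] && p < g$tx_end[i] + fl) in3 <- TRUE
        if (p >= g$tx_start[i] - fl && p < g$tx_start[i]) in5 <- TRUE
      } else {
        if (p >= g$tx_start[i] - fl && p < g$tx_start[i]) in3 <- TRUE
        if (p >= g$tx_end[i] && p < g$tx_end[i] + fl) in5 <- TRUE
      }
    }
    if (in_ex) "exon" else if (in_body) "intron" else if (in3) "3'"
    else if (in5) "5'" else "distal"
  }, character(1))
  expect_equal(got, want)
})

test_that("chromosome distribution reports exact expectations and tails", {
  layout <- genome_layout(c(chrA = 1e6, chrB = 1e6), focal = "chrB")
  s <- c(sample(seq(1000, 9e5, by = 100), 5), sample(seq(1000, 9e5, by = 100), 5))
  pk <- peak_table(rep(c("chrA", "chrB"), each = 5), s, s + 500,
                   sprintf("p%02d", 1:10), s + 250, rep(3, 10), rep(1e-30, 10))
  d <- chromosome_distribution(pk, layout)
  expect_equal(d$table$expected, c(5, 5))
  expect_equal(d$chisq, 0)
  expect_gt(d$focal_p, 0.5)
  expect_equal(sum(d$table$expected), d$n_peaks)

  # depletion tail equals the exact binomial sum on a small instance
  pk2 <- pk[pk$chrom == "chrA", ]
  d2 <- chromosome_distribution(pk2, layout)
  expect_equal(d2$focal_tail, "depletion")
  expect_equal(d2$focal_p, sum(dbinom(0, 5, 0.5)))
})

test_that("binomial tails agree with high-precision summation in log space", {
  # depletion of a 1/6-length chromosome: exact sum over the support
  n <- 5000; p <- 1 / 6; obs <- 600
  lsum <- sum(dbinom(0:obs, n, p))
  layout <- genome_layout(setNames(c(rep(1e6, 5), 1e6), paste0("c", 1:6)),
                          focal = "c6")
  pk <- peak_table(c(rep("c1", n - obs), rep("c6", obs)),
                   seq_len(n) * 10, seq_len(n) * 10 + 5,
                   sprintf("p%04d", seq_len(n)), seq_len(n) * 10 + 2,
                   rep(3, n), rep(1e-30, n))
  d <- chromosome_distribution(pk, layout)
  expect_equal(d$focal_log10_p, log10(lsum), tolerance = 0.01)
})

test_that("peak density counts summits per kb within a half-open region", {
  s <- seq(1000, by = 1000, length.out = 25)
  pk <- peak_table(rep("chrX", 25), s, s + 500, sprintf("p%02d", 1:25),
                   s + 100, rep(3, 25), rep(1e-30, 25))
  expect_equal(peak_density(pk, "chrX", 0, 300000), 25 / 300)
  expect_equal(round(peak_density(pk, "chrX", 0, 300000), 2), 0.08)
  expect_equal(peak_density(pk, "chrX", 5e5, 6e5), 0)
  expect_error(peak_density(pk, "chrX", 100, 100), "region")
})
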