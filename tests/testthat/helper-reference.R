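# Peak sets reconstructed from the study's printed per-chromosome counts:
# 5391 final peaks of which 100 on chrX (25 in the leftmost 300 kb, 75 on
# the remaining ~17.4 Mb) and 5291 on the autosomes in proportion to length.
reference_peak_set <- function(layout = ws170_layout()) {
  lens <- layout$lengths
  autos <- setdiff(names(lens), "chrX")
  n_auto <- 5291
  share <- lens[autos] / sum(lens[autos])
  counts <- floor(n_auto * share)
  rem <- n_auto - sum(counts)
  top_up <- order(n_auto * share - counts, decreasing = TRUE)[seq_len(rem)]
  counts[top_up] <- counts[top_up] + 1
  chrom <- character(0); summit <- numeric(0)
  for (chr in autos) {
    k <- counts[[chr]]
    summit <- c(summit, round(seq(5000, lens[[chr]] - 5000, length.out = k)))
    chrom <- c(chrom, rep(chr, k))
  }
  sx_tip <- round(seq(5000, 295000, length.out = 25))
  sx_rest <- round(seq(400000, 17000000, length.out = 75))
  chrom <- c(chrom, rep("chrX", 100))
  summit <- c(summit, sx_tip, sx_rest)
  summit <- as.integer(summit)
  peak_table(chrom, summit - 250L, summit + 250L,
             sprintf("ref_%04d", seq_along(chrom)), summit,
             rep(3, length(chrom)), rep(1e-30, length(chrom)))
}

# 5408 candidate peaks and 38 mock-IP control peaks placed so that exactly
# 17 candidates lie within 100 bp of a control.
control_subtraction_fixture <- function() {
  n_cand <- 5408
  cand_start <- 3000 * (seq_len(n_cand) - 1)
  cand <- peak_table(rep("chrI", n_cand), cand_start, cand_start + 500,
                     sprintf("cand_%04d", seq_len(n_cand)), cand_start + 250,
                     rep(3, n_cand), rep(1e-30, n_cand))
  # 17 controls at a 50-bp gap from the first 17 candidates ...
  near_start <- cand_start[1:17] + 550
  # ... and 21 well beyond the last candidate, > 100 bp from everything
  far_start <- max(cand_start) + 2000 + 500 * (0:20)
  ctrl_start <- c(near_start, far_start)
  ctrl <- peak_table(rep("chrI", 38), ctrl_start, ctrl_start + 100,
                     sprintf("ctrl_%02d", 1:38), ctrl_start + 50,
                     rep(2, 38), rep(1e-25, 38))
  list(candidates = cand, controls = ctrl)
}
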