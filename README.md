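# chiptile

Analysis of two-channel tiling-microarray ChIP (ChIP-chip) for chromatin
factors and histone marks that cover gene bodies, written for the kind of
study that mapped the H3K36 methyltransferase MES-4 and its marks across
the *C. elegans* genome in early embryos. The package takes per-probe
log2(IP/input) ratios on a 50-bp tiling and answers, reproducibly:

* **Where is the factor?** z-score normalization per replicate
  (`log2_ratio()`, `zscore_standardize()`, `average_replicates()`,
  `anchored_normalize()` for knockdown samples, `smooth_median()` +
  `pairwise_correlation()` for concordance), then ChIPOTle-style peak
  calling: 500-bp windows stepped by 100 bp, a Gaussian null with
  `sigma0 = sqrt(mean(v^2 | v < 0))` estimated from reflected negative
  scores, upper-tail window p-values `P(mean > m | Normal(0, sigma0/sqrt(n)))`
  with Bonferroni correction over evaluated windows, merge at
  `adj_p <= 1e-20`, and subtraction of peaks within 100 bp of a mock-IP
  control peak (`slide_windows()`, `window_pvalue()`, `call_peaks()`,
  `subtract_control_peaks()`).
* **Which genes?** Peak relations with precedence gene-body >
  upstream-1kb > downstream-1kb > intergenic, the summit feature hierarchy
  exon > intron > 3′ > 5′ > distal, and gene-body mean z-scores over fully
  contained probes (`peaks_to_genes()`, `assign_summit_feature()`,
  `gene_mean_z()`).
* **Which chromosomes?** Uniform-by-length expectations
  `E_c = N * L_c / sum(L)`, an exact log-space binomial tail for the focal
  chromosome and a genome-wide chi-square (`chromosome_distribution()`,
  `peak_density()`), with WS170/ce4 lengths bundled (`ws170_layout()`).
* **How does signal run across genes?** Metagene profiles in 50-bp bins
  around the TSS (−1 kb..+1.5 kb) and TES (−1.5 kb..+1 kb) for expression
  quintiles, and exon-boundary profiles over intron-exon-intron triplets
  with optional intronic-baseline subtraction (`quantile_bin_genes()`,
  `metagene_profile()`, `find_exon_triplets()`, `exon_boundary_profile()`).
* **How does binding relate to expression class?** Boxplot summaries,
  strict threshold selection (z > 1 on the high targets, z < 0 on the low
  ones), hypergeometric set-overlap enrichment and evidence fractions
  (`class_summary()`, `classify_high_low()`, `overlap_enrichment()`,
  `evidence_fraction()`), fed by expression arrays summarized with quantile
  normalization + median polish (`quantile_normalize()`,
  `summarize_gene()`, `average_and_zscore()`).

A synthetic-data generator (`sim_config()`, `make_genome()`,
`simulate_chip()`, `simulate_expression()`) emulates the whole study —
tiled log-ratio tracks with gene-body enrichment domains, class-dependent
amplitudes, replicate structure, Gaussian probe noise and an X-like
chromosome depleted of germline-expressed gene classes — and provides a
truth table so peak recovery can be benchmarked exactly.
`run_pipeline(run_config(sim_config(seed = 1)))` runs everything end to
end; the numbered scripts under `analysis/` do the same as a narrated
workflow writing tables under `results/`.

## Worked example

```r
library(chiptile)
rep <- run_pipeline(run_config(sim_config(seed = 1)))
rep$counts[c("n_peaks", "recall", "precision")]
#> $n_peaks
#> [1] 167
#> $recall
#> [1] 1
#> $precision
#> [1] 1
rep$chrom_distribution$focal_log10_p
#> [1] -13.22327
head(rep$peaks, 3)
#>   chrom start   end   peak_id summit   mean_z        adj_p
#> 1  chrI 16800 18500 mes4_0001  18025 2.786510 2.247164e-70
#> 2  chrI 19800 22200 mes4_0002  20275 2.727271 2.641098e-67
#> 3  chrI 49700 52200 mes4_0003  50175 2.744773 3.323233e-68
```

On the default synthetic study (six 1-Mb chromosomes, 200 genes, enrichment
amplitude 5, noise SD 1, 3 replicates) the caller finds 167 peaks, every
implanted enriched gene is recovered and every peak overlaps an implanted
gene (recall = precision = 1), and the X-like chromosome is significantly
depleted of peaks under the uniform-by-length null (log10 p ≈ −13) because
germline-expressed gene classes are largely excluded from it. Running the
`analysis/` scripts in order narrates the same run: the top expression
quintile's mes4 profile peaks ~500 bp into the gene body while pol2 peaks
at the TSS, and the strict z > 1 / z < 0 selection recovers exactly the
germline-specific gene that carries the factor without polymerase.

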