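# Fixture builders and independent brute-force oracles used across tests.

# a probe table from parallel vectors, default 50-bp probes on one chromosome
toy_track <- function(starts, values, chrom = "chrI", len = 50L) {
  probe_table(rep(chrom, length(starts)), starts, starts + len,
              sprintf("p%04d", seq_along(starts)), values)
}

# evenly tiled track over a layout with supplied or generated values
tiled_track <- function(layout, values = NULL, spacing = 50L, len = 50L) {
  pr <- tile_probes(layout, len, spacing)
  if (!is.null(values)) pr$value <- values
  pr
}

# O(n^2) windowed-median oracle
oracle_smooth_median <- function(track, span) {
  out <- track
  mids <- probe_mid(track)
  for (i in seq_len(nrow(track))) {
    sel <- track$chrom == track$chrom[i] & abs(mids - mids[i]) <= span / 2
    out$value[i] <- median(track$value[sel])
  }
  out
}

# brute-force containment mean per gene
oracle_gene_mean <- function(track, genes) {
  sapply(seq_len(nrow(genes)), function(i) {
    sel <- track$chrom == genes$chrom[i] &
      track$start >= genes$tx_start[i] & track$end <= genes$tx_end[i]
    if (!any(sel)) NA_real_ else mean(track$value[sel])
  }) |> setNames(genes$gene_id)
}

# exhaustive sliding-window peak caller: plain loops over every window on
# the step grid, Gaussian upper tail, Bonferroni over evaluated windows,
# then a literal merge of overlapping/bookended significant windows
oracle_call_peaks <- function(track, layout, window = 500, step = 100,
                              min_probes = 1, cutoff = 1e-20) {
  mids <- probe_mid(track)
  null_sd <- sqrt(mean(track$value[track$value < 0]^2))
  wins <- list()
  for (chr in names(layout$lengths)) {
    s <- 0
    while (s < layout$lengths[[chr]]) {
      member <- which(track$chrom == chr & mids >= s & mids < s + window)
      if (length(member) >= min_probes) {
        m <- mean(track$value[member])
        wins[[length(wins) + 1]] <- data.frame(
          chrom = chr, start = s, end = s + window, n = length(member),
          mean_z = m, stringsAsFactors = FALSE)
      }
      s <- s + step
    }
  }
  wins <- do.call(rbind, wins)
  if (is.null(wins)) return(NULL)
  lp <- pnorm(wins$mean_z, 0, null_sd / sqrt(wins$n),
              lower.tail = FALSE, log.p = TRUE)
  sig <- wins[lp + log(nrow(wins)) <= log(cutoff), , drop = FALSE]
  if (nrow(sig) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), summit = integer()))
  sig <- sig[order(sig$chrom, sig$start), ]
  peaks <- list()
  cur <- sig[1, ]
  flush <- function(cur) {
    member <- which(track$chrom == cur$chrom & mids >= cur$start &
                      mids < cur$end)
    summit <- mids[member[which.max(track$value[member])]]
    data.frame(chrom = cur$chrom, start = cur$start, end = cur$end,
               summit = summit, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(sig))[-1]) {
    if (sig$chrom[i] == cur$chrom && sig$start[i] <= cur$end) {
      cur$end <- max(cur$end, sig$end[i])
    } else {
      peaks[[length(peaks) + 1]] <- flush(cur)
      cur <- sig[i, ]
    }
  }
  peaks[[length(peaks) + 1]] <- flush(cur)
  out <- do.call(rbind, peaks)
  rownames(out) <- NULL
  out
}

# literal nearest-bin-center assignment (tie -> left), pooled bin stats
oracle_metagene <- function(track, genes, groups, anchor,
                            win, bin_width = 50) {
  a <- win[1]; b <- win[2]
  nbin <- (b - a) / bin_width
  centers <- a + bin_width / 2 + bin_width * (seq_len(nbin) - 1)
  mids <- probe_mid(track)
  acc <- list()
  for (i in seq_len(nrow(genes))) {
    g <- groups$group[match(genes$gene_id[i], groups$gene_id)]
    if (is.na(g)) next
    anc <- if (anchor == "TSS") {
      if (genes$strand[i] == "+") genes$tx_start[i] else genes$tx_end[i]
    } else {
      if (genes$strand[i] == "+") genes$tx_end[i] else genes$tx_start[i]
    }
    for (j in which(track$chrom == genes$chrom[i])) {
      rel <- if (genes$strand[i] == "+") mids[j] - anc else anc - mids[j]
      if (rel < a || rel > b) next
      d <- abs(centers - rel)
      bin <- which(d == min(d))[1]  # tie -> left (smaller center)
      acc[[length(acc) + 1]] <- c(group = g, bin = bin,
                                  value = track$value[j])
    }
  }
  m <- do.call(rbind, acc)
  stats <- expand.grid(bin_center = centers, group = sort(unique(groups$group)))
  stats$mean <- NA_real_; stats$ci95 <- NA_real_; stats$n_probes <- 0L
  for (r in seq_len(nrow(stats))) {
    bin <- match(stats$bin_center[r], centers)
    sel <- !is.null(m) & m[, "group"] == stats$group[r] & m[, "bin"] == bin
    v <- m[sel, "value"]
    stats$n_probes[r] <- length(v)
    if (length(v)) {
      stats$mean[r] <- mean(v)
      stats$ci95[r] <- if (length(v) == 1) 0 else
        1.96 * sd(v) / sqrt(length(v))
    }
  }
  stats
}

# literal per-triplet recomputation of the exon-boundary profiles
oracle_exon_profile <- function(track, triplets, groups, baseline_subtract,
                                start_window = c(-300, 200),
                                end_window = c(-200, 300), bin_width = 50) {
  mids <- probe_mid(track)
  one_window <- function(win, which_end) {
    nbin <- (win[2] - win[1]) / bin_width
    centers <- win[1] + bin_width / 2 + bin_width * (seq_len(nbin) - 1)
    acc <- list()
    for (i in seq_len(nrow(triplets))) {
      g <- groups$group[match(triplets$gene_id[i], groups$gene_id)]
      if (is.na(g)) next
      on_chr <- which(track$chrom == triplets$chrom[i])
      v <- track$value[on_chr]
      if (baseline_subtract) {
        intronic <- (mids[on_chr] >= triplets$intron_left_start[i] &
                       mids[on_chr] < triplets$intron_left_end[i]) |
          (mids[on_chr] >= triplets$intron_right_start[i] &
             mids[on_chr] < triplets$intron_right_end[i])
        if (!any(intronic)) next
        v <- v - mean(v[intronic])
      }
      plus <- triplets$strand[i] == "+"
      anchor <- if (which_end == "start") {
        if (plus) triplets$exon_start[i] else triplets$exon_end[i]
      } else {
        if (plus) triplets$exon_end[i] else triplets$exon_start[i]
      }
      for (jj in seq_along(on_chr)) {
        rel <- if (plus) mids[on_chr[jj]] - anchor else anchor - mids[on_chr[jj]]
        if (rel < win[1] || rel > win[2]) next
        d <- abs(centers - rel)
        acc[[length(acc) + 1]] <- c(g, which(d == min(d))[1], v[jj])
      }
    }
    m <- do.call(rbind, acc)
    stats <- expand.grid(bin_center = centers,
                         group = sort(unique(groups$group)))
    stats$mean <- NA_real_; stats$ci95 <- NA_real_; stats$n_probes <- 0L
    for (r in seq_len(nrow(stats))) {
      bin <- match(stats$bin_center[r], centers)
      v <- m[m[, 1] == stats$group[r] & m[, 2] == bin, 3]
      stats$n_probes[r] <- length(v)
      if (length(v)) {
        stats$mean[r] <- mean(v)
        stats$ci95[r] <- if (length(v) == 1) 0 else
          1.96 * sd(v) / sqrt(length(v))
      }
    }
    stats
  }
  list(start = one_window(start_window, "start"),
       end = one_window(end_window, "end"))
}

# reflect a genome: coordinates x -> L - x per chromosome, strands flipped
mirror_genes <- function(genes, layout) {
  L <- layout$lengths[genes$chrom]
  gene_table(genes$gene_id, genes$chrom,
             ifelse(genes$strand == "+", "-", "+"),
             L - genes$tx_end, L - genes$tx_start,
             lapply(seq_len(nrow(genes)),
                    function(i) rev(L[i] - genes$exon_ends[[i]])),
             lapply(seq_len(nrow(genes)),
                    function(i) rev(L[i] - genes$exon_starts[[i]])),
             class_label = genes$class_label,
             expression = genes$expression)
}

mirror_track <- function(track, layout) {
  L <- layout$lengths[track$chrom]
  probe_table(track$chrom, L - track$end, L - track$start,
              track$probe_id, track$value)
}

# a small random annotated genome for oracle comparisons
random_fixture <- function(seed, n_genes = 40, chrom_len = 2e5,
                           chroms = c("chrA", "chrB")) {
  set.seed(seed)
  layout <- genome_layout(setNames(rep(chrom_len, length(chroms)), chroms),
                          focal = chroms[1])
  genes <- list()
  for (chr in chroms) {
    pos <- 0
    while (pos < chrom_len - 8000 && length(genes) < n_genes) {
      gap <- round(runif(1, 200, 2000))
      len <- round(runif(1, 1200, 6000))
      s <- pos + gap
      if (s + len > chrom_len) break
      nex <- sample(1:4, 1)
      cuts <- sort(sample(seq(200, len - 200, by = 50), 2 * (nex - 1)))
      es <- s + c(0, cuts[seq_along(cuts) %% 2 == 0])
      ee <- s + c(cuts[seq_along(cuts) %% 2 == 1], len)
      genes[[length(genes) + 1]] <- list(
        chrom = chr, strand = sample(c("+", "-"), 1), s = s, e = s + len,
        es = es, ee = ee)
      pos <- s + len
    }
  }
  gt <- gene_table(sprintf("g%03d", seq_along(genes)),
                   vapply(genes, `[[`, character(1), "chrom"),
                   vapply(genes, `[[`, character(1), "strand"),
                   vapply(genes, `[[`, numeric(1), "s"),
                   vapply(genes, `[[`, numeric(1), "e"),
                   lapply(genes, `[[`, "es"), lapply(genes, `[[`, "ee"),
                   expression = rnorm(length(genes)))
  track <- tiled_track(layout)
  track$value <- rnorm(nrow(track))
  list(layout = layout, genes = gt, track = track)
}
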