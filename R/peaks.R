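#' Estimate the Gaussian null SD from reflected negative values
#'
#' The peak caller's background model assumes probe scores of unenriched
#' regions are symmetric about zero, so the negative scores (which carry no
#' enrichment) are reflected about 0 to reconstruct the null distribution:
#' sigma0 = sqrt(mean(v^2)) over the strictly negative values v.
#'
#' @param values numeric vector of probe scores; must contain at least one
#'   strictly negative value.
#' @return the null standard deviation (a positive scalar).
#' @export
estimate_null_sd <- function(values) {
  neg <- values[values < 0]
  if (!length(neg))
    stop("no negative values: cannot estimate a null from signal-only input")
  sqrt(mean(neg^2))
}

#' Tile sliding windows over a track and score their mean signal
#'
#' Windows start at coordinate 0 on every chromosome and advance by `step`;
#' a probe belongs to a window iff its midpoint lies in `[start, end)`.
#' Windows holding fewer than `min_probes` probes are dropped. A chromosome
#' shorter than the window still yields its (truncated-coverage) windows.
#'
#' @param track a sorted probe table of z-scores.
#' @param layout a [genome_layout] giving chromosome lengths.
#' @param window window size in bp (default 500).
#' @param step step size in bp (default 100).
#' @param min_probes minimum probes per evaluated window (default 1).
#' @return a `data.frame` with columns `chrom`, `start`, `end`, `n_probes`,
#'   `mean_z`, sorted by (chrom, start).
#' @export
slide_windows <- function(track, layout, window = 500, step = 100,
                          min_probes = 1) {
  min_probes <- max(1L, as.integer(min_probes))
  .check_chroms(track$chrom, layout, "track")
  res <- lapply(names(layout$lengths), function(chr) {
    idx <- which(track$chrom == chr)
    if (!length(idx)) return(NULL)
    mids <- probe_mid(track[idx, ])
    if (is.unsorted(mids)) stop("probes must be sorted within chromosome")
    v <- track$value[idx]
    cs <- cumsum(v)
    starts <- seq.int(0L, by = step,
                      length.out = max(1L, ceiling(layout$lengths[[chr]] / step)))
    starts <- starts[starts < layout$lengths[[chr]]]
    # probes with start <= mid < start + window, via counts of mids < x
    lo <- findInterval(starts, mids, left.open = TRUE)
    hi <- findInterval(starts + window, mids, left.open = TRUE)
    n <- hi - lo
    keep <- n >= min_probes
    if (!any(keep)) return(NULL)
    sums <- cs[hi[keep]] - ifelse(lo[keep] > 0, cs[pmax(lo[keep], 1L)], 0)
    data.frame(chrom = chr, start = starts[keep],
               end = starts[keep] + as.integer(window),
               n_probes = n[keep], mean_z = sums / n[keep],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(chrom = character(), start = integer(), end = integer(),
                      n_probes = integer(), mean_z = numeric())
  rownames(out) <- NULL
  out
}

#' Upper-tail window p-values under the Gaussian null, Bonferroni-adjusted
#'
#' The mean of `n` null probes is Normal(0, sigma0/sqrt(n)); each window's
#' raw p is the upper tail of that distribution at its observed mean,
#' computed in log space so extreme tails do not underflow prematurely.
#' The Bonferroni factor is the number of evaluated windows genome-wide.
#'
#' @param windows output of [slide_windows()].
#' @param null_sd per-probe null SD (see [estimate_null_sd()]).
#' @param n_windows Bonferroni multiplier; defaults to `nrow(windows)`.
#' @return `windows` with columns `raw_p`, `adj_p` and `log10_adj_p` added.
#' @export
window_pvalue <- function(windows, null_sd, n_windows = nrow(windows)) {
  if (!is.numeric(null_sd) || null_sd <= 0) stop("null_sd must be positive")
  if (n_windows < 1) stop("n_windows must be >= 1")
  if (any(windows$n_probes < 1)) stop("window with zero probes")
  log_p <- pnorm(windows$mean_z, mean = 0,
                 sd = null_sd / sqrt(windows$n_probes),
                 lower.tail = FALSE, log.p = TRUE)
  log_adj <- pmin(0, log_p + log(n_windows))
  windows$raw_p <- exp(log_p)
  windows$adj_p <- exp(log_adj)
  windows$log10_adj_p <- log_adj / log(10)
  windows
}

#' Merge significant windows into peaks
#'
#' Windows with adjusted p at or below the cutoff (boundary inclusive) are
#' selected; on each chromosome, overlapping or bookended significant
#' windows (gap <= 0 under half-open arithmetic) merge into one peak
#' spanning their union. The peak summit is the midpoint of the maximum-value
#' probe inside the peak (leftmost on ties); `mean_z` and `adj_p` are taken
#' from the best (smallest adjusted p) merged window.
#'
#' @param windows scored windows from [window_pvalue()].
#' @param track the probe table the windows were computed from (for summits).
#' @param cutoff adjusted-p cutoff (default 1e-20).
#' @param id_prefix prefix for generated peak ids.
#' @return a peak table (see [peak_table()]); empty if nothing is significant.
#' @export
call_peaks <- function(windows, track, cutoff = 1e-20, id_prefix = "peak") {
  log_cut <- log10(cutoff)
  sig <- windows[windows$log10_adj_p <= log_cut, , drop = FALSE]
  if (nrow(sig) == 0)
    return(peak_table(character(), integer(), integer(), character(),
                      integer(), numeric(), numeric()))
  sig <- sig[order(sig$chrom, sig$start), , drop = FALSE]
  # assign merge groups with a linear scan (runs share a chromosome and
  # each window starts at or before the running maximum end)
  grp <- integer(nrow(sig)); g <- 0L; run_end <- -Inf; run_chr <- ""
  for (i in seq_len(nrow(sig))) {
    if (sig$chrom[i] != run_chr || sig$start[i] > run_end) {
      g <- g + 1L; run_chr <- sig$chrom[i]; run_end <- sig$end[i]
    } else run_end <- max(run_end, sig$end[i])
    grp[i] <- g
  }
  mids <- probe_mid(track)
  pk <- lapply(split(seq_len(nrow(sig)), grp), function(ii) {
    chr <- sig$chrom[ii[1]]
    s <- min(sig$start[ii]); e <- max(sig$end[ii])
    best <- ii[order(sig$log10_adj_p[ii], -sig$mean_z[ii])][1]
    in_pk <- which(track$chrom == chr & mids >= s & mids < e)
    if (length(in_pk)) {
      summit <- mids[in_pk[which.max(track$value[in_pk])]]
    } else summit <- s  # no probe midpoint inside (possible at chrom edges)
    list(chrom = chr, start = s, end = e, summit = summit,
         mean_z = sig$mean_z[best], adj_p = sig$adj_p[best])
  })
  df <- do.call(rbind, lapply(pk, as.data.frame))
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  peak_table(df$chrom, df$start, df$end,
             sprintf("%s_%04d", id_prefix, seq_len(nrow(df))),
             df$summit, df$mean_z, df$adj_p)
}

#' Remove peaks lying within a gap of any control peak
#'
#' A peak is eliminated iff its edge-to-edge gap to some control peak on the
#' same chromosome is at most `max_gap` bp (overlap counts as gap 0).
#' Survivors keep their identifiers.
#'
#' @param peaks,control_peaks sorted peak tables.
#' @param max_gap maximum gap in bp (default 100, i.e. one caller step).
#' @return the filtered peak table, with attribute `n_removed`.
#' @export
subtract_control_peaks <- function(peaks, control_peaks, max_gap = 100) {
  if (nrow(peaks) == 0 || nrow(control_peaks) == 0) {
    attr(peaks, "n_removed") <- 0L
    return(peaks)
  }
  lev <- unique(c(peaks$chrom, control_peaks$chrom))
  gr_p <- GenomicRanges::GRanges(factor(peaks$chrom, levels = lev),
                                 IRanges::IRanges(peaks$start + 1L, peaks$end))
  gr_c <- GenomicRanges::GRanges(factor(control_peaks$chrom, levels = lev),
                                 IRanges::IRanges(control_peaks$start + 1L,
                                                  control_peaks$end))
  hit <- GenomicRanges::distanceToNearest(gr_p, gr_c)
  drop <- rep(FALSE, nrow(peaks))
  drop[S4Vectors::queryHits(hit)] <- S4Vectors::mcols(hit)$distance <= max_gap
  out <- peaks[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(drop)
  out
}
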