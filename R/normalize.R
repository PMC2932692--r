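#' Per-probe log2 ratio of sample over reference channel
#'
#' @param sample_intensity,reference_intensity positive numeric vectors of
#'   equal length (one entry per probe).
#' @return numeric vector `log2(sample / reference)`.
#' @export
log2_ratio <- function(sample_intensity, reference_intensity) {
  if (length(sample_intensity) != length(reference_intensity))
    stop("channel vectors must have equal length")
  bad <- which(sample_intensity <= 0 | reference_intensity <= 0)
  if (length(bad))
    stop("nonpositive intensity at probe ", bad[1])
  log2(sample_intensity / reference_intensity)
}

# population standard deviation (divide by n)
.pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Standardize values to mean 0 and population SD 1 (z-scores)
#'
#' The per-array enrichment score: log2 ratios standardized over all probes
#' of an array. The population SD (divide by n) is used, so `c(-1, 1)` is a
#' fixed point; the function is idempotent.
#'
#' @param values numeric vector, length >= 2, with nonzero dispersion.
#' @return standardized numeric vector.
#' @export
zscore_standardize <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values to standardize")
  s <- .pop_sd(values)
  if (s == 0) stop("zero variance: cannot standardize a constant vector")
  (values - mean(values)) / s
}

#' Rescale a track so a reference chromosome matches a reference track
#'
#' Estimates the affine map `v -> a*v + b` that makes the mean and
#' population SD of the adjusted track over the anchor chromosome's probes
#' equal those of the reference track over the same probes, then applies the
#' map genome-wide. This is the normalization used for knockdown samples,
#' anchored on the chromosome least affected by the knockdown.
#'
#' @param track_to_adjust,reference_track probe tables over the identical
#'   probe set (same chrom/start/end in the same order).
#' @param anchor_chrom chromosome supplying the anchor probes.
#' @return the adjusted probe table.
#' @export
anchored_normalize <- function(track_to_adjust, reference_track, anchor_chrom) {
  .check_same_probes(list(track_to_adjust, reference_track))
  on_anchor <- track_to_adjust$chrom == anchor_chrom
  if (sum(on_anchor) < 2L)
    stop("anchor chromosome '", anchor_chrom, "' has fewer than 2 probes")
  v <- track_to_adjust$value[on_anchor]
  r <- reference_track$value[on_anchor]
  sv <- .pop_sd(v)
  if (sv == 0) stop("zero dispersion on anchor chromosome: cannot rescale")
  a <- .pop_sd(r) / sv
  b <- mean(r) - a * mean(v)
  out <- track_to_adjust
  out$value <- a * out$value + b
  out
}

#' Windowed median smoothing of a signal track
#'
#' Replaces each probe's value by the median over probes of the same
#' chromosome whose midpoints lie within +/- span/2 of its own midpoint
#' (window closed on both ends). A lone probe maps to itself.
#'
#' @param track a sorted probe table.
#' @param span window width in bp (default 250).
#' @return the smoothed probe table.
#' @export
smooth_median <- function(track, span = 250) {
  out <- track
  half <- span / 2
  for (chr in unique(track$chrom)) {
    idx <- which(track$chrom == chr)
    mids <- probe_mid(track[idx, ])
    if (is.unsorted(mids)) stop("probes must be sorted within chromosome")
    v <- track$value[idx]
    lo <- findInterval(mids - half, mids, left.open = TRUE) + 1L
    hi <- findInterval(mids + half, mids)
    out$value[idx] <- vapply(seq_along(idx),
                             function(i) median(v[lo[i]:hi[i]]), numeric(1))
  }
  out
}

# contract check: identical probe coordinates across tracks
.check_same_probes <- function(tracks) {
  ref <- tracks[[1]]
  for (t in tracks[-1]) {
    if (nrow(t) != nrow(ref) ||
        !identical(t$chrom, ref$chrom) || !identical(t$start, ref$start) ||
        !identical(t$end, ref$end))
      stop("tracks are not aligned to the same probe set")
  }
  invisible(TRUE)
}

#' Average replicate tracks probe-by-probe
#'
#' @param tracks list of probe tables over the identical probe set.
#' @return a probe table whose value is the per-probe arithmetic mean.
#' @export
average_replicates <- function(tracks) {
  if (!length(tracks)) stop("need at least one track")
  .check_same_probes(tracks)
  out <- tracks[[1]]
  out$value <- rowMeans(vapply(tracks, `[[`, numeric(nrow(out)), "value"))
  out
}

#' Pairwise Pearson correlations between tracks after median smoothing
#'
#' The replicate/target concordance statistic: all-probe Pearson correlation
#' of z-score tracks after 250-bp median smoothing.
#'
#' @param tracks named list (>= 2) of probe tables over one probe set.
#' @param span smoothing span in bp applied before correlating; 0 disables.
#' @return a symmetric correlation matrix with unit diagonal.
#' @export
pairwise_correlation <- function(tracks, span = 250) {
  if (length(tracks) < 2L) stop("need at least 2 tracks")
  .check_same_probes(tracks)
  vals <- vapply(tracks, function(t) {
    if (span > 0) smooth_median(t, span)$value else t$value
  }, numeric(nrow(tracks[[1]])))
  if (any(apply(vals, 2, .pop_sd) == 0))
    stop("zero-variance track: correlation undefined")
  m <- cor(vals)
  if (!is.null(names(tracks))) dimnames(m) <- list(names(tracks), names(tracks))
  m
}
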