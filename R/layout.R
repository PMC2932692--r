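#' Genome layout: chromosome names, lengths and a focal chromosome
#'
#' A layout is the minimal description of a genome the pipeline needs: an
#' ordered set of chromosome lengths plus one designated "focal" chromosome
#' (the X in the worm genome) used for anchored normalization and for the
#' uniform-by-length depletion test.
#'
#' @param lengths named numeric vector of chromosome lengths in bp; names are
#'   chromosome names, lengths must be positive.
#' @param focal name of the focal chromosome; must appear in `lengths`.
#' @return an object of class `genome_layout`: a list with elements
#'   `lengths` (named integer-valued numeric) and `focal` (character).
#' @examples
#' genome_layout(c(chrI = 1e6, chrX = 1e6), focal = "chrX")
#' @export
genome_layout <- function(lengths, focal = "chrX") {
  if (is.null(names(lengths)) || anyNA(names(lengths)) || any(names(lengths) == ""))
    stop("chromosome lengths must be named")
  if (anyDuplicated(names(lengths)))
    stop("duplicated chromosome names in layout")
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("all chromosome lengths must be positive and finite")
  if (!focal %in% names(lengths))
    stop("focal chromosome '", focal, "' not present in layout")
  structure(list(lengths = lengths, focal = focal), class = "genome_layout")
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("genome_layout:", length(x$lengths), "chromosomes,",
      format(sum(x$lengths), big.mark = ","), "bp; focal =", x$focal, "\n")
  invisible(x)
}

# C. elegans WS170/ce4 nuclear chromosome lengths (UCSC ce4 chromInfo).
.WS170_LENGTHS <- c(
  chrI   = 15080483,
  chrII  = 15279308,
  chrIII = 13783313,
  chrIV  = 17493791,
  chrV   = 20922231,
  chrX   = 17718849
)

#' WS170 (ce4) chromosome lengths as a genome layout
#'
#' Nuclear chromosome lengths of the *C. elegans* WS170 (ce4) assembly, the
#' coordinate system of the tiling arrays this pipeline targets. Bundled so
#' that the uniform-by-length expectations (e.g. the expected number of peaks
#' on the X) can be reproduced without external files.
#'
#' @return a [genome_layout] with chromosomes chrI-chrV and chrX
#'   (focal = `"chrX"`).
#' @examples
#' ws170_layout()
#' @export
ws170_layout <- function() genome_layout(.WS170_LENGTHS, focal = "chrX")

# internal: check chrom values of a table against a layout
.check_chroms <- function(chrom, layout, what = "record") {
  bad <- setdiff(unique(chrom), names(layout$lengths))
  if (length(bad))
    stop("unknown chromosome(s) in ", what, ": ", paste(bad, collapse = ", "))
  invisible(TRUE)
}
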