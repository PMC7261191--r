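#' Construct a validated table of genomic intervals
#'
#' Intervals follow the BED convention throughout the package: 0-based,
#' half-open \code{[start, end)}. Strand is one of \code{"+"}, \code{"-"} or
#' \code{"."}.
#'
#' @param chrom Character vector of chromosome identifiers.
#' @param start Integer vector, 0-based inclusive start positions.
#' @param end Integer vector, exclusive end positions.
#' @param strand Character vector recycled to length; defaults to ".".
#' @param name Optional identifiers; autogenerated when NULL.
#'
#' @return A \code{data.frame} with columns chrom, start, end, name, strand.
#' @export
genomic_intervals <- function(chrom, start, end, strand = ".", name = NULL) {
  n <- length(chrom)
  start <- as.integer(start)
  end <- as.integer(end)
  strand <- rep_len(as.character(strand), n)
  if (is.null(name)) name <- paste0("iv", seq_len(n))
  bad <- which(!(start >= 0L & start < end))
  if (length(bad) > 0L) {
    stop(sprintf("invalid interval at record %d: start=%d end=%d (need 0 <= start < end)",
                 bad[1], start[bad[1]], end[bad[1]]))
  }
  if (!all(strand %in% c("+", "-", "."))) {
    stop("strand must be one of '+', '-', '.'")
  }
  data.frame(chrom = as.character(chrom), start = start, end = end,
             name = as.character(name), strand = strand,
             stringsAsFactors = FALSE)
}

#' Interval lengths in nucleotides
#' @param intervals A data.frame from \code{\link{genomic_intervals}}.
#' @return Integer vector end - start.
#' @export
interval_length <- function(intervals) intervals$end - intervals$start

#' Transcription start sites of a bidirectional enhancer
#'
#' FANTOM5 transcribed enhancers are divergently transcribed: the reverse-strand
#' TSS is placed at the interval start and the forward-strand TSS at end - 1.
#' The midpoint used for directionality windows is floor((start + end) / 2).
#'
#' @param intervals Enhancer intervals.
#' @return data.frame with columns tss_rev, tss_fwd, mid.
#' @export
enhancer_tss <- function(intervals) {
  data.frame(tss_rev = intervals$start,
             tss_fwd = intervals$end - 1L,
             mid = (intervals$start + intervals$end) %/% 2L)
}

#' Promoter regions for binding-density analysis
#'
#' Builds the region spanning 500 nt upstream and 200 nt downstream of the TSS
#' on the element's strand, i.e. relative \code{[-500, +200)}, length 700 nt.
#'
#' @param tss Integer vector of absolute TSS positions (0-based).
#' @param strand Strand vector ("+" or "-").
#' @param chrom Chromosome vector.
#' @param upstream,downstream Extents in nt.
#' @return Interval data.frame.
#' @export
promoter_regions <- function(tss, strand, chrom, upstream = 500L, downstream = 200L) {
  tss <- as.integer(tss)
  fwd <- strand == "+"
  start <- ifelse(fwd, tss - upstream, tss - downstream + 1L)
  end <- ifelse(fwd, tss + downstream, tss + upstream + 1L)
  start <- pmax(start, 0L)
  genomic_intervals(chrom, start, end, strand,
                    name = paste0("promreg", seq_along(tss)))
}
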