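# Overlap helpers use IRanges internally; package coordinates are BED
# half-open [start, end), so the 1-based closed IRanges is (start+1, end).
iranges_of <- function(x) IRanges::IRanges(start = x$start + 1L, end = x$end)

# hits between regions and peaks, chromosome-aware; returns a data.frame
# (region_idx, peak_idx)
overlap_pairs <- function(regions, peaks) {
  out <- list()
  for (ch in unique(regions$chrom)) {
    ri <- which(regions$chrom == ch)
    pi <- which(peaks$chrom == ch)
    if (length(pi) == 0L) next
    hits <- IRanges::findOverlaps(iranges_of(regions[ri, , drop = FALSE]),
                                  iranges_of(peaks[pi, , drop = FALSE]))
    if (length(hits) == 0L) next
    out[[ch]] <- data.frame(region_idx = ri[S4Vectors::queryHits(hits)],
                            peak_idx = pi[S4Vectors::subjectHits(hits)])
  }
  if (length(out) == 0L) {
    return(data.frame(region_idx = integer(0), peak_idx = integer(0)))
  }
  do.call(rbind, out)
}

#' Maximum peak signal per element
#'
#' A peak overlaps an element when their half-open intervals share at least
#' one base. The maximum \code{signal} over all overlapping peaks (pooled
#' across any number of peak files) is reported per element.
#'
#' @param regions Interval data.frame (elements).
#' @param peaks narrowPeak data.frame (may be several files rbind-ed).
#' @return data.frame element_id (= regions$name), overlapped, n_peaks,
#'   max_signal (NA when no peak overlaps).
#' @export
max_signal <- function(regions, peaks) {
  pr <- overlap_pairs(regions, peaks)
  out <- data.frame(element_id = regions$name, overlapped = FALSE,
                    n_peaks = 0L, max_signal = NA_real_,
                    stringsAsFactors = FALSE)
  if (nrow(pr) > 0L) {
    agg <- stats::aggregate(peaks$signal[pr$peak_idx],
                            by = list(region_idx = pr$region_idx),
                            FUN = max)
    cnt <- table(pr$region_idx)
    out$overlapped[agg$region_idx] <- TRUE
    out$max_signal[agg$region_idx] <- agg$x
    out$n_peaks[as.integer(names(cnt))] <- as.integer(cnt)
  }
  out
}

#' Binding-event density per region
#'
#' Counts the narrowPeak records whose interval intersects each region by at
#' least one base and reports the density per 1000 nt of region length.
#'
#' @param regions Interval data.frame (promoter regions [-500,+200), enhancer
#'   bodies, or CGI spans).
#' @param peaks narrowPeak data.frame.
#' @return data.frame element_id, n_peaks, region_length, density_per_kb.
#' @export
binding_density <- function(regions, peaks) {
  len <- interval_length(regions)
  if (any(len <= 0L)) stop("zero-length region")
  pr <- overlap_pairs(regions, peaks)
  n <- integer(nrow(regions))
  if (nrow(pr) > 0L) {
    cnt <- table(pr$region_idx)
    n[as.integer(names(cnt))] <- as.integer(cnt)
  }
  data.frame(element_id = regions$name, n_peaks = n, region_length = len,
             density_per_kb = 1000 * n / len, stringsAsFactors = FALSE)
}

#' Rank-based comparison of two groups of values
#'
#' Two-sided Mann-Whitney U test: exact when both groups are small (< 50) and
#' tie-free, otherwise the normal approximation with continuity and tie
#' correction. Reports medians and means per group.
#'
#' @param x,y Numeric vectors (both nonempty).
#' @param label_x,label_y Group labels for the report.
#' @return data.frame with one row: labels, n, medians, means, U statistic, p.
#' @export
compare_groups <- function(x, y, label_x = "group1", label_y = "group2") {
  if (length(x) == 0L || length(y) == 0L) stop("both groups must be nonempty")
  exact <- length(x) < 50L && length(y) < 50L && !any(duplicated(c(x, y)))
  wt <- stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                           correct = TRUE)
  data.frame(group_x = label_x, group_y = label_y,
             n_x = length(x), n_y = length(y),
             median_x = stats::median(x), median_y = stats::median(y),
             mean_x = mean(x), mean_y = mean(y),
             U = unname(wt$statistic), p = wt$p.value,
             stringsAsFactors = FALSE)
}
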