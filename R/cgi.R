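#' Composition of a single CpG-island scan window
#'
#' Counts C, G and overlapping CpG dinucleotides and returns the GC percentage
#' and the CpG observed/expected ratio \code{(n_cpg * L) / (n_c * n_g)}
#' (Gardiner-Garden/Frommer convention; 0 when the window has no C or no G).
#' Windows containing N fail both thresholds downstream: their composition is
#' computed over the literal characters, so N never counts as C or G.
#'
#' @param seq Nucleotide string of exactly the window length.
#' @param window Expected window length (default 100).
#' @return List with gc_percent, cpg_obs_exp, n_c, n_g, n_cpg.
#' @export
window_composition <- function(seq, window = 100L) {
  L <- nchar(seq)
  if (L != window) stop("window_composition: sequence length ", L,
                        " != window size ", window)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n_c <- sum(ch == "C")
  n_g <- sum(ch == "G")
  n_cpg <- if (L > 1L) sum(ch[-L] == "C" & ch[-1L] == "G") else 0L
  oe <- if (n_c > 0L && n_g > 0L) (n_cpg * L) / (n_c * n_g) else 0
  list(gc_percent = 100 * (n_c + n_g) / L, cpg_obs_exp = oe,
       n_c = n_c, n_g = n_g, n_cpg = n_cpg)
}

# Per-window C/G/CpG counts for every window start, via cumulative sums.
# Returns a data.frame with one row per window start (0-based offset in seq).
window_stats_vec <- function(seq, window = 100L) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(ch)
  if (L < window) {
    return(data.frame(start = integer(0), gc = numeric(0), oe = numeric(0)))
  }
  isC <- as.integer(ch == "C")
  isG <- as.integer(ch == "G")
  isCpG <- c(as.integer(ch[-L] == "C" & ch[-1L] == "G"), 0L)
  csC <- cumsum(c(0L, isC)); csG <- cumsum(c(0L, isG)); csD <- cumsum(c(0L, isCpG))
  starts <- 0:(L - window)                       # 0-based
  i <- starts + 1L
  nC <- csC[i + window] - csC[i]
  nG <- csG[i + window] - csG[i]
  # CpG dinucleotides fully inside the window: pair start in [i, i+window-2]
  nD <- csD[i + window - 1L] - csD[i]
  oe <- ifelse(nC > 0L & nG > 0L, (nD * window) / (nC * nG), 0)
  data.frame(start = starts, gc = 100 * (nC + nG) / window, oe = oe,
             n_c = nC, n_g = nG, n_cpg = nD)
}

#' Call CpG islands on a sequence by the sliding-window rule
#'
#' A window of \code{window} nt is shifted in \code{step}-bp intervals. Each
#' maximal run of consecutive qualifying windows (GC-content >= min_gc and
#' CpG observed/expected >= min_obs_exp) whose spanned region (first window
#' start to last window end) is at least \code{min_region} nt is emitted as
#' one CpG island call.
#'
#' @param seq Nucleotide string (or an \code{anchored_seq}, in which case
#'   coordinates in the result are relative to the anchor).
#' @param window,step,min_gc,min_obs_exp,min_region Caller parameters; the
#'   defaults are the 100 nt / >=50\% GC / >=0.6 obs-exp / >=200 bp rule.
#' @return data.frame with columns start, end (0-based, half-open; offsets in
#'   the input sequence, or anchor-relative for an anchored_seq), mean_gc,
#'   mean_obs_exp. Zero rows when nothing qualifies.
#' @export
call_cgis <- function(seq, window = 100L, step = 1L, min_gc = 50,
                      min_obs_exp = 0.6, min_region = 200L) {
  offset <- 0L
  if (inherits(seq, "anchored_seq")) {
    offset <- seq$rel_start
    seq <- seq$seq
  }
  if (nchar(seq) < window) {
    stop("call_cgis: sequence shorter than window size")
  }
  ws <- window_stats_vec(seq, window)
  if (step > 1L) ws <- ws[ws$start %% step == 0L, ]
  ok <- ws$gc >= min_gc & ws$oe >= min_obs_exp
  if (!any(ok)) {
    return(data.frame(start = integer(0), end = integer(0),
                      mean_gc = numeric(0), mean_obs_exp = numeric(0)))
  }
  r <- rle(ok)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  keep <- which(r$values)
  out <- lapply(keep, function(k) {
    idx <- run_start[k]:run_end[k]
    s <- ws$start[idx[1]]
    e <- ws$start[idx[length(idx)]] + window
    if (e - s < min_region) return(NULL)
    data.frame(start = s + offset, end = e + offset,
               mean_gc = mean(ws$gc[idx]), mean_obs_exp = mean(ws$oe[idx]))
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      mean_gc = numeric(0), mean_obs_exp = numeric(0)))
  }
  do.call(rbind, out)
}

#' CGI association of a promoter
#'
#' Scans the window spanning relative positions [-200, +200] around the TSS
#' and reports association if at least one CpG island call is found anywhere
#' in that span.
#'
#' @param anchored An \code{anchored_seq} covering at least [-200, +200].
#' @param ... Passed to \code{\link{call_cgis}}.
#' @return List with \code{associated} (logical) and \code{calls} (data.frame,
#'   anchor-relative coordinates).
#' @export
associate_promoter_cgi <- function(anchored, ...) {
  if (anchored$rel_start > -200L || anchored$rel_end < 200L) {
    stop("promoter span must cover [-200, +200] around the TSS")
  }
  calls <- call_cgis(anchored, ...)
  list(associated = nrow(calls) > 0L, calls = calls)
}

#' CGI association of a bidirectional enhancer
#'
#' Scans [-200, +200] around each of the two enhancer TSSs (reverse-strand TSS
#' at interval start, forward-strand TSS at end - 1) and reports association
#' if a CpG island call contains at least one of the TSS bases.
#'
#' @param enhancer One-row interval data.frame.
#' @param genome Named character vector of chromosome sequences.
#' @param ... Passed to \code{\link{call_cgis}}.
#' @return Logical scalar.
#' @export
associate_enhancer_cgi <- function(enhancer, genome, ...) {
  tss <- enhancer_tss(enhancer)
  for (pos in c(tss$tss_rev[1], tss$tss_fwd[1])) {
    a <- extract_anchored(genome, enhancer$chrom[1], pos, "+",
                          upstream = 200L, downstream = 200L)
    calls <- call_cgis(a, ...)
    if (any(calls$start <= 0L & calls$end > 0L)) return(TRUE)
  }
  FALSE
}
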