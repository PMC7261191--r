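#' Localized overrepresentation test for one CPE
#'
#' Partitions elements into CPE+ (a hit starting inside the functional window,
#' i.e. within two nucleotides of the expected location) and CPE-. The
#' background is obtained by shifting a 5-nucleotide window in 1 bp intervals
#' across the scan range, recording per location the number of elements whose
#' hit start falls inside the window, and taking the mean and standard
#' deviation over all window locations that do not overlap the functional
#' window. Significance is assessed with both a Gaussian upper-tail p on the
#' standard score and an upper-tail binomial p with success probability
#' mu / n_elements; both must fall below alpha.
#'
#' @param hits Hit table for one CPE (columns element_id, start).
#' @param n_elements Number of elements scanned.
#' @param pwm The \code{cpe_pwm} (supplies the functional window).
#' @param alpha Significance level (default 0.001).
#' @param range Inclusive scan range, default c(-500, 200); background windows
#'   run from [range1, range1+5) to (range2-5, range2].
#' @return List: cpe_name, n_plus, mu, sigma, z, p_gaussian, p_binomial,
#'   significant, degenerate (TRUE when sigma = 0).
#' @export
overrepresentation_test <- function(hits, n_elements, pwm, alpha = 0.001,
                                    range = c(-500L, 200L)) {
  fw <- functional_window(pwm)
  win <- 5L
  wstarts <- range[1]:(range[2] - win + 1L)
  u <- unique(hits[, c("element_id", "start")])
  n_plus <- length(unique(u$element_id[u$start >= fw[1] & u$start <= fw[2]]))
  # per-window counts of distinct elements with a hit start inside the window
  counts <- integer(length(wstarts))
  if (nrow(u) > 0L) {
    # a hit at position s lies in windows with start in [s-4, s]
    lo <- pmax(u$start - (win - 1L), range[1])
    hi <- pmin(u$start, range[2] - win + 1L)
    keep <- lo <= hi
    if (any(keep)) {
      reps <- hi[keep] - lo[keep] + 1L
      wpos <- unlist(mapply(seq.int, lo[keep], hi[keep], SIMPLIFY = FALSE))
      eid <- rep(u$element_id[keep], reps)
      pair <- unique(data.frame(eid = eid, w = wpos))
      tab <- table(factor(pair$w, levels = wstarts))
      counts <- as.integer(tab)
    }
  }
  bg <- !(wstarts + win - 1L >= fw[1] & wstarts <= fw[2])
  mu <- mean(counts[bg])
  sigma <- stats::sd(counts[bg])
  degenerate <- !is.finite(sigma) || sigma == 0
  if (degenerate) {
    z <- NA_real_
    p_gaussian <- if (n_plus > mu) 0 else 1
  } else {
    z <- (n_plus - mu) / sigma
    p_gaussian <- stats::pnorm(z, lower.tail = FALSE)
  }
  p0 <- min(max(mu / n_elements, 0), 1)
  p_binomial <- stats::pbinom(n_plus - 1L, n_elements, p0, lower.tail = FALSE)
  list(cpe_name = pwm$name, n_plus = n_plus, mu = mu, sigma = sigma, z = z,
       p_gaussian = p_gaussian, p_binomial = p_binomial,
       significant = is.finite(p_gaussian) && p_gaussian < alpha &&
         p_binomial < alpha && !degenerate,
       degenerate = degenerate)
}

#' CPE presence matrix: which elements carry which CPE in its functional window
#'
#' @param hits Hit table from \code{\link{scan_elements}} (all CPEs).
#' @param element_ids All scanned element ids.
#' @param pwms Named list of \code{cpe_pwm}.
#' @return Logical matrix, elements x CPEs.
#' @export
cpe_presence <- function(hits, element_ids, pwms) {
  m <- matrix(FALSE, nrow = length(element_ids), ncol = length(pwms),
              dimnames = list(element_ids, names(pwms)))
  for (nm in names(pwms)) {
    fw <- functional_window(pwms[[nm]])
    h <- hits[hits$cpe_name == nm & hits$start >= fw[1] & hits$start <= fw[2], ]
    m[unique(h$element_id), nm] <- TRUE
  }
  m
}
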