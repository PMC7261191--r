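# Log-space hypergeometric machinery shared by the co-occurrence tails and
# the two-sided Fisher test. All sums are formed with log-sum-exp over
# lchoose terms so that p-values remain accurate far below 1e-300 (returned
# both in linear space, which may underflow to 0, and as log10).

logsumexp <- function(lx) {
  lx <- lx[is.finite(lx) | lx == -Inf]
  m <- max(lx)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(lx - m)))
}

# log P(X = x) for the 2x2 table with cell a = x and fixed margins
# rows (a+b, c+d), first column a+c, in log space.
log_dhyper_table <- function(x, r1, r2, c1) {
  N <- r1 + r2
  lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(N, c1)
}

#' One-sided co-occurrence tail probabilities for a 2x2 table
#'
#' For counts a = |CPE1+ n CPE2+|, b = |CPE1+ n CPE2-|, c = |CPE1- n CPE2+|,
#' d = |CPE1- n CPE2-|, computes the tail sum for overrepresentation of
#' co-occurrence,
#' \code{p_co = sum_i C(a+b, a+i) C(c+d, c-i) / C(N, a+c)} over
#' \code{i = 0..min(N-a, b, c, N-d)}, and the opposite tail
#' \code{p_anti = sum_i C(c+d, c+i) C(a+b, a-i) / C(N, a+c)} over
#' \code{i = 0..min(a, N-b, N-c, d)}. Arithmetic is carried out in log space.
#'
#' @param a,b,c,d Non-negative cell counts.
#' @return List with p_co, p_anti, log10_p_co, log10_p_anti.
#' @export
cooccurrence_tail <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("negative cell count")
  N <- a + b + c + d
  if (N <= 0) stop("empty table")
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  i_co <- 0:min(N - a, b, c, N - d)
  l_co <- log_dhyper_table(a + i_co, r1, r2, c1)
  i_an <- 0:min(a, N - b, N - c, d)
  l_an <- log_dhyper_table(a - i_an, r1, r2, c1)
  lco <- logsumexp(l_co)
  lan <- logsumexp(l_an)
  list(p_co = exp(lco), p_anti = exp(lan),
       log10_p_co = lco / log(10), log10_p_anti = lan / log(10))
}

#' Pairwise CPE co-occurrence tests with Bonferroni correction
#'
#' Builds the 2x2 table for every pair of distinct CPEs from the presence
#' matrix and computes both one-sided tail probabilities. The Bonferroni
#' threshold is alpha / (k(k-1)/2) for k CPEs (0.05 / 66 for twelve).
#'
#' @param presence Logical matrix, elements x CPEs
#'   (see \code{\link{cpe_presence}}).
#' @param alpha Family-wise level before correction (default 0.05).
#' @return List with \code{pairs} (data.frame: cpe1, cpe2, a, b, c, d, p_co,
#'   p_anti, log10_p_co, log10_p_anti, significant_co, significant_anti),
#'   \code{n_tests} and \code{alpha_corrected}.
#' @export
cooccurrence_tests <- function(presence, alpha = 0.05) {
  k <- ncol(presence)
  n_tests <- k * (k - 1L) / 2L
  alpha_c <- alpha / n_tests
  cpes <- colnames(presence)
  rows <- list()
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    p1 <- presence[, i]; p2 <- presence[, j]
    a <- sum(p1 & p2); b <- sum(p1 & !p2)
    cc <- sum(!p1 & p2); d <- sum(!p1 & !p2)
    tl <- cooccurrence_tail(a, b, cc, d)
    rows[[length(rows) + 1L]] <- data.frame(
      cpe1 = cpes[i], cpe2 = cpes[j], a = a, b = b, c = cc, d = d,
      p_co = tl$p_co, p_anti = tl$p_anti,
      log10_p_co = tl$log10_p_co, log10_p_anti = tl$log10_p_anti,
      significant_co = tl$p_co < alpha_c,
      significant_anti = tl$p_anti < alpha_c,
      stringsAsFactors = FALSE)
  }
  list(pairs = do.call(rbind, rows), n_tests = n_tests,
       alpha_corrected = alpha_c)
}

#' Two-sided Fisher's exact test in log space
#'
#' Sums, over all admissible tables with the observed margins, the
#' probabilities not exceeding that of the observed table (with the standard
#' (1 + 1e-7) tolerance), using log-space combinatorics so the p-value is
#' reported accurately (as log10) even when it underflows linear doubles.
#'
#' @param a,b,c,d Non-negative cell counts.
#' @return List with p (may underflow to 0), log10_p, odds_ratio
#'   ((a d)/(b c); Inf when b c = 0 and a d > 0, NaN when both products are 0),
#'   or_defined flag.
#' @export
association_test <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("negative cell count")
  N <- a + b + c + d
  if (N <= 0) stop("empty table")
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == N) {
    return(list(p = 1, log10_p = 0, odds_ratio = NA_real_, or_defined = FALSE))
  }
  supp <- max(0, c1 - r2):min(r1, c1)
  lp <- log_dhyper_table(supp, r1, r2, c1)
  lobs <- log_dhyper_table(a, r1, r2, c1)
  keep <- lp <= lobs + log(1 + 1e-7)
  l2 <- logsumexp(lp[keep])
  l2 <- min(l2, 0)
  or <- (a * d) / (b * c)
  list(p = exp(l2), log10_p = l2 / log(10), odds_ratio = or,
       or_defined = is.finite(or))
}

#' Bonferroni-corrected significance threshold for k pairwise tests
#' @param k Number of CPEs.
#' @param alpha Family-wise level.
#' @return List with n_tests = k(k-1)/2 and alpha_corrected.
#' @export
bonferroni_pairs <- function(k, alpha = 0.05) {
  n_tests <- as.integer(k * (k - 1) / 2)
  list(n_tests = n_tests, alpha_corrected = alpha / n_tests)
}
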