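# Independent brute-force oracles used across the suite. These deliberately
# avoid the vectorized code paths of the package implementation.

# literal per-window CGI scan: loops window starts, counts by slicing the
# character vector, then assembles maximal qualifying runs
oracle_call_cgis <- function(seq, window = 100L, min_gc = 50,
                             min_obs_exp = 0.6, min_region = 200L) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(ch)
  starts <- 0:(L - window)
  ok <- logical(length(starts))
  gc <- oe <- numeric(length(starts))
  for (k in seq_along(starts)) {
    w <- ch[(starts[k] + 1L):(starts[k] + window)]
    nc <- sum(w == "C"); ng <- sum(w == "G")
    ncpg <- sum(w[-window] == "C" & w[-1L] == "G")
    gc[k] <- 100 * (nc + ng) / window
    oe[k] <- if (nc > 0 && ng > 0) ncpg * window / (nc * ng) else 0
    ok[k] <- gc[k] >= min_gc && oe[k] >= min_obs_exp
  }
  calls <- list()
  k <- 1L
  while (k <= length(ok)) {
    if (ok[k]) {
      j <- k
      while (j < length(ok) && ok[j + 1L]) j <- j + 1L
      s <- starts[k]; e <- starts[j] + window
      if (e - s >= min_region) {
        calls[[length(calls) + 1L]] <-
          data.frame(start = s, end = e, mean_gc = mean(gc[k:j]),
                     mean_obs_exp = mean(oe[k:j]))
      }
      k <- j + 1L
    } else k <- k + 1L
  }
  if (length(calls) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      mean_gc = numeric(0), mean_obs_exp = numeric(0)))
  }
  do.call(rbind, calls)
}

# quadratic interval-overlap counter (half-open coordinates)
oracle_overlap_counts <- function(regions, peaks) {
  vapply(seq_len(nrow(regions)), function(i) {
    sum(peaks$chrom == regions$chrom[i] &
          peaks$start < regions$end[i] & regions$start[i] < peaks$end)
  }, integer(1))
}

random_seq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# small deterministic PWM used in motif tests: consensus TATAAA
test_pwm <- function(cutoff_frac = 1, expected_position = -30L,
                     requires = NULL, name = "TATAtest") {
  cons <- c("T", "A", "T", "A", "A", "A")
  fr <- sapply(cons, function(b) {
    f <- setNames(rep(0.05, 4), c("A", "C", "G", "T")); f[b] <- 0.85; f
  })
  w <- pwm_from_frequencies(fr)
  cpe_pwm(name, w, cutoff_frac * pwm_max_score(w), expected_position,
          requires = requires)
}
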