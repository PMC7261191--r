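test_that("pwm_from_frequencies computes log-odds weights", {
  fr <- matrix(c(1, 0, 0, 0), 4, 1, dimnames = list(c("A", "C", "G", "T"), NULL))
  w <- pwm_from_frequencies(fr, pseudocount = 0.01)
  expect_equal(unname(w["A", 1]), log2((1 + 0.01 * 0.25) / 1.01 / 0.25),
               tolerance = 1e-12)
  expect_equal(round(unname(w["A", 1]), 3), 1.989)

  u <- matrix(0.25, 4, 1, dimnames = list(c("A", "C", "G", "T"), NULL))
  expect_equal(unname(pwm_from_frequencies(u)), matrix(0, 4, 1))

  expect_error(pwm_from_frequencies(fr, pseudocount = 0), "infinite")
  bad <- matrix(c(0.5, 0.1, 0.1, 0.1), 4, 1,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  expect_error(pwm_from_frequencies(bad), "sum to 1")
})

test_that("consensus score equals the sum of column maxima and cutoffs respect it", {
  pwms <- load_pwms()
  expect_length(pwms, 12)
  for (pwm in pwms) {
    cons <- pwm_consensus(pwm)
    a <- structure(list(seq = cons, rel_start = 0L, rel_end = nchar(cons) - 1L,
                        anchor = 0L, strand = "+", chrom = "x",
                        clipped = FALSE), class = "anchored_seq")
    hits <- scan_pwm(a, pwm)
    expect_equal(nrow(hits), 1L)
    expect_equal(hits$score, pwm_max_score(pwm), tolerance = 1e-12)
    expect_lte(pwm$cutoff, pwm_max_score(pwm))
  }
})

test_that("scan finds a planted consensus exactly at its location", {
  pwm <- test_pwm(cutoff_frac = 1, expected_position = -30L)
  set.seed(3)
  bg <- random_seq(701, gc = 0.5)
  seq <- bg
  # relative coordinates -500..+200; position -30 is offset 470
  substr(seq, 471, 476) <- "TATAAA"
  a <- structure(list(seq = seq, rel_start = -500L, rel_end = 200L,
                      anchor = 0L, strand = "+", chrom = "x", clipped = FALSE),
                 class = "anchored_seq")
  hits <- scan_pwm(a, pwm)
  # cutoff = max score: only exact TATAAA matches; the planted one must be there
  expect_true(-30L %in% hits$start)
  other <- gregexpr("TATAAA", seq)[[1]]
  expect_setequal(hits$start, as.integer(other) - 1L - 500L)

  # unreachable cutoff: no hits
  pwm2 <- pwm
  pwm2$cutoff <- pwm_max_score(pwm) + 1
  expect_equal(nrow(scan_pwm(a, pwm2)), 0L)
})

test_that("windows containing N never match", {
  pwm <- test_pwm()
  a <- structure(list(seq = "TANAAATATAAA", rel_start = 0L, rel_end = 11L,
                      anchor = 0L, strand = "+", chrom = "x", clipped = FALSE),
                 class = "anchored_seq")
  hits <- scan_pwm(a, pwm)
  expect_equal(hits$start, 6L)
})

test_that("dependent CPEs are reported only alongside their partner", {
  inr <- test_pwm(expected_position = -2L, name = "InrT")
  dpe <- test_pwm(expected_position = 28L, requires = "InrT", name = "DPET")
  mk <- function(seq) structure(
    list(seq = seq, rel_start = -500L, rel_end = 200L, anchor = 0L,
         strand = "+", chrom = "x", clipped = FALSE), class = "anchored_seq")
  set.seed(9)
  base <- gsub("TATAAA", "CCCCCC", random_seq(701, 0.5))
  with_both <- base; substr(with_both, 499, 504) <- "TATAAA"  # offset 498 -> -2
  substr(with_both, 529, 534) <- "TATAAA"                     # offset 528 -> +28
  with_dpe_only <- base; substr(with_dpe_only, 529, 534) <- "TATAAA"
  hits <- scan_elements(list(e1 = mk(with_both), e2 = mk(with_dpe_only)),
                        list(InrT = inr, DPET = dpe))
  expect_true(any(hits$element_id == "e1" & hits$cpe_name == "DPET"))
  expect_false(any(hits$element_id == "e2" & hits$cpe_name == "DPET"))
  # the partner itself is reported regardless
  expect_true(any(hits$element_id == "e1" & hits$cpe_name == "InrT"))
})

test_that("positional profile counts distinct elements per start position", {
  hits <- data.frame(element_id = c("a", "a", "b", "b"),
                     cpe_name = "X", start = c(0L, 0L, -30L, 5L),
                     score = 1)
  p <- positional_profile(hits, n_elements = 2)
  expect_equal(p$counts[p$positions == 0], 1L)
  expect_equal(p$counts[p$positions == -30], 1L)
  expect_equal(sum(p$counts), 3L)
  expect_true(all(p$counts <= 2L))
})

test_that("overrepresentation test flags planted motifs and not uniform noise", {
  pwm <- test_pwm(expected_position = -30L)
  n <- 1000L
  set.seed(17)
  # planted: 20% of elements hit inside the functional window, sparse background
  planted <- data.frame(
    element_id = sprintf("e%d", 1:200),
    cpe_name = "TATAtest",
    start = sample((-32L):(-28L), 200, replace = TRUE), score = 1)
  bgels <- sample(1000, 60)
  background <- data.frame(
    element_id = sprintf("e%d", bgels), cpe_name = "TATAtest",
    start = sample(c(-500L:(-40L), -20L:195L), 60, replace = TRUE), score = 1)
  r <- overrepresentation_test(rbind(planted, background), n, pwm,
                               alpha = 0.001)
  expect_true(r$significant)
  expect_gte(r$n_plus, 200L)

  # uniform: every element one hit anywhere
  unif <- data.frame(element_id = sprintf("e%d", 1:n), cpe_name = "TATAtest",
                     start = sample(-500L:196L, n, replace = TRUE), score = 1)
  r2 <- overrepresentation_test(unif, n, pwm, alpha = 0.001)
  expect_false(r2$significant)
  expect_lt(abs(r2$z), 4)

  r3 <- overrepresentation_test(planted[0, ], n, pwm)
  expect_equal(r3$n_plus, 0L)
  expect_false(r3$significant)
})

test_that("co-occurrence tails match the hypergeometric and are monotone", {
  tl <- cooccurrence_tail(5, 1, 1, 5)
  expect_equal(tl$p_co, phyper(4, 6, 6, 6, lower.tail = FALSE),
               tolerance = 1e-12)
  # a = N single-term case
  expect_equal(cooccurrence_tail(7, 0, 0, 0)$p_co, 1)

  # monotone: increasing a with fixed margins (rows 10/10, first column 10)
  # shrinks the co-occurrence tail
  prev <- Inf
  for (a in 5:10) {
    p <- cooccurrence_tail(a, 10 - a, 10 - a, a)$p_co
    expect_lte(p, prev + 1e-12)
    prev <- p
  }
})

test_that("co-occurrence test table assembles pairs with Bonferroni threshold", {
  set.seed(31)
  pres <- matrix(runif(300) < 0.3, 100, 3,
                 dimnames = list(sprintf("e%d", 1:100), c("A", "B", "C")))
  # force a strong positive pair
  pres[, 2] <- pres[, 1]
  res <- cooccurrence_tests(pres)
  expect_equal(res$n_tests, 3L)
  expect_equal(res$alpha_corrected, 0.05 / 3)
  ab <- res$pairs[res$pairs$cpe1 == "A" & res$pairs$cpe2 == "B", ]
  expect_true(ab$significant_co)
  expect_true(all(res$pairs$p_co >= 0 & res$pairs$p_co <= 1 + 1e-12))
  expect_true(all(res$pairs$p_anti >= 0 & res$pairs$p_anti <= 1 + 1e-12))
})

test_that("two-sided Fisher agrees with fisher.test and brackets the one-sided tails", {
  set.seed(41)
  for (k in 1:50) {
    tb <- as.integer(rmultinom(1, sample(8:40, 1), runif(4, 0.05, 1)))
    a <- tb[1]; b <- tb[2]; cc <- tb[3]; d <- tb[4]
    mine <- association_test(a, b, cc, d)
    ref <- fisher.test(matrix(c(a, cc, b, d), 2))$p.value
    expect_equal(mine$p, ref, tolerance = 1e-9)
    tl <- cooccurrence_tail(a, b, cc, d)
    m <- min(tl$p_co, tl$p_anti)
    expect_lte(m, mine$p + 1e-12)
    expect_lte(mine$p, min(1, 2 * m) + 1e-9)
  }
})

test_that("log-space Fisher p-values stay finite far below double underflow", {
  r <- association_test(5000, 100, 100, 5000)
  expect_true(is.finite(r$log10_p))
  expect_lt(r$log10_p, -1000)
})
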