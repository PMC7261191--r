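test_that("dispersion index matches closed forms", {
  expect_equal(dispersion_index(0L, 10L), 0)
  expect_equal(dispersion_index(c(-50L, 50L), c(1L, 1L)), 50)
  expect_equal(dispersion_index(-50:50, rep(1L, 101)), sqrt(850))
  expect_true(is.na(dispersion_index(c(-60L, 60L), c(1L, 1L))))
})

test_that("dispersion is invariant under joint shift of tags and window", {
  set.seed(19)
  for (k in 1:20) {
    pos <- sample(-50:50, 12)
    cnt <- rpois(12, 5) + 1L
    shift <- sample(-30:30, 1)
    s0 <- dispersion_index(pos, cnt)
    s1 <- dispersion_index(pos + shift, cnt, window = c(-50L, 50L) + shift)
    expect_identical(s0, s1)
  }
})

test_that("sharp/broad classification uses the inclusive 2.5 threshold", {
  expect_equal(classify_sharpness(c(0, 0, 5))$label, "sharp")
  expect_equal(classify_sharpness(c(0, 0, 5))$mean_dispersion, 5 / 3)
  expect_equal(classify_sharpness(2.5)$label, "sharp")
  expect_equal(classify_sharpness(2.5 + 1e-9)$label, "broad")
  expect_equal(classify_sharpness(numeric(0))$label, "unclassified")
  expect_equal(classify_sharpness(c(NA_real_, NA_real_))$label, "unclassified")
  expect_equal(classify_sharpness(c(1, NA_real_))$label, "sharp")
})

test_that("group expression: TPM, group mean, windowed sum, log2(1+x)", {
  tags <- data.frame(element_id = c("p1", "p1", "p1"),
                     library_id = "L1", strand = "+",
                     rel_position = c(0L, 50L, 150L),
                     count = c(3L, 4L, 993L))
  libmap <- data.frame(library_id = "L1", group = "g1", class = "tissue")
  m <- group_expression(tags, libmap, "p1")
  # library total 1000 -> windowed TPM = 7/1000 * 1e6 = 7000; x1000, log2(1+)
  expect_equal(unname(m["p1", "g1"]), log2(1 + 7000 * 1000))
  # element with no in-window tags
  m2 <- group_expression(tags[3, ], libmap, c("p1", "p2"))
  expect_equal(unname(m2["p2", "g1"]), 0)
  expect_equal(unname(m2["p1", "g1"]), 0)   # only tag is outside [-100, 100]
})

test_that("tau matches closed forms and is scale invariant and monotone", {
  expect_equal(tau(c(1, 0, 0, 0))$tau, 1)
  expect_equal(tau(c(3, 3, 3, 3))$tau, 0)
  expect_equal(tau(c(8, 4, 2, 1))$tau, 17 / 24)
  expect_false(tau(c(0, 0))$defined)
  expect_error(tau(5), "2 groups")

  set.seed(29)
  for (k in 1:30) {
    x <- runif(10, 0, 5)
    lambda <- runif(1, 0.1, 20)
    expect_equal(tau(x)$tau, tau(lambda * x)$tau, tolerance = 1e-12)
    # concentration: move mass from a non-maximal group onto the maximum
    i_max <- which.max(x)
    i_other <- sample(setdiff(seq_along(x), i_max), 1)
    delta <- runif(1, 0, x[i_other])
    y <- x
    y[i_max] <- y[i_max] + delta
    y[i_other] <- y[i_other] - delta
    expect_gte(tau(y)$tau, tau(x)$tau - 1e-12)
  }
})

test_that("top-group selection is deterministic with lexicographic tie-break", {
  m <- matrix(c(10, 5, 1), 1, 3, dimnames = list("e", c("gB", "gA", "gC")))
  expect_equal(select_top_groups(m, 2), c("gB", "gA"))
  ties <- matrix(c(4, 4, 4), 1, 3, dimnames = list("e", c("gC", "gA", "gB")))
  expect_equal(select_top_groups(ties, 2), c("gA", "gB"))
  expect_warning(sel <- select_top_groups(ties, 5), "available")
  expect_length(sel, 3)
})

test_that("directionality matches the (F - R)/(F + R) definition", {
  mk <- function(F, R) data.frame(
    strand = c(rep("+", length(F)), rep("-", length(R))),
    rel_position = c(F, R), count = 1L)
  expect_equal(directionality(mk(rep(10L, 10), rep(-10L, 10)))$directionality, 0)
  expect_equal(directionality(mk(rep(5L, 25), integer(0)))$directionality, 1)
  d <- directionality(mk(rep(3L, 30), rep(-3L, 10)))
  expect_equal(d$directionality, 0.5)
  expect_equal(d$F, 30)
  expect_equal(d$R, 10)
  # window boundaries: forward [0, 200] inclusive, reverse [-200, 0) exclusive 0
  expect_equal(directionality(mk(c(0L, 200L, 201L), c(-200L, -201L)))$F, 2)
  expect_equal(directionality(mk(c(0L, 200L, 201L), c(-200L, -201L)))$R, 1)
  empty <- data.frame(strand = character(0), rel_position = integer(0),
                      count = integer(0))
  expect_false(directionality(empty)$defined)
})

test_that("directionality is antisymmetric under strand swap", {
  set.seed(37)
  for (k in 1:20) {
    tags <- data.frame(
      strand = sample(c("+", "-"), 30, replace = TRUE),
      rel_position = sample(-200:200, 30, replace = TRUE),
      count = rpois(30, 3) + 1L)
    d1 <- directionality(tags)$directionality
    sw <- tags
    sw$strand <- ifelse(tags$strand == "+", "-", "+")
    sw$rel_position <- -tags$rel_position
    d2 <- directionality(sw)$directionality
    if (is.na(d1)) { expect_true(is.na(d2)); next }
    expect_true(abs(d1) <= 1)
    # the midpoint base flips side under the swap (half-open convention),
    # so compare after removing position-0/negated-0 edge tags
    if (!any(tags$rel_position == 0 | tags$rel_position == -200 |
               tags$rel_position == 200)) {
      expect_equal(d1, -d2, tolerance = 1e-12)
    }
  }
})

test_that("directionality_table aggregates per element and flags undefined", {
  tags <- data.frame(element_id = c("e1", "e1", "e2"),
                     library_id = "pool",
                     strand = c("+", "-", "+"),
                     rel_position = c(10L, -10L, 300L),
                     count = c(30L, 10L, 5L))
  d <- directionality_table(tags, c("e1", "e2", "e3"))
  expect_equal(d$directionality[d$element_id == "e1"], 0.5)
  expect_false(d$defined[d$element_id == "e2"])  # tag outside window
  expect_false(d$defined[d$element_id == "e3"])  # no tags at all
})
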