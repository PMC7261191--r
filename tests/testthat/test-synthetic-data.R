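cfg_small <- function(seed = 5, ...) {
  sim_config(seed = seed, n_promoters = 40L, n_enhancers = 60L, ...)
}

test_that("generators are byte-identical under a fixed seed", {
  run_once <- function() {
    cfg <- cfg_small()
    sim <- simulate_peaks(cfg, simulate_cage(cfg, simulate_motifs(
      cfg, simulate_genome(cfg))))
    d <- withr::local_tempdir()
    write_simulation(sim, d)
    lapply(sort(list.files(d)), function(f) readLines(file.path(d, f)))
  }
  expect_identical(run_once(), run_once())
})

test_that("cgi_fraction 0 gives an empty truth set", {
  cfg <- cfg_small(cgi_fraction_promoters = 0, cgi_fraction_enhancers = 0)
  sim <- simulate_genome(cfg)
  expect_equal(nrow(sim$cgi_truth), 0L)
  expect_false(any(sim$promoters$cgi_true))
})

test_that("planted CGI blocks satisfy the calling definition in every window", {
  set.seed(71)
  for (len in c(250L, 613L, 1200L)) {
    block <- enhancerCGI:::make_cgi_block(len)
    ws <- enhancerCGI:::window_stats_vec(block)
    expect_true(all(ws$gc >= 50))
    expect_true(all(ws$oe >= 0.6))
  }
})

test_that("planted CGIs are recovered by the caller at high sensitivity", {
  cfg <- sim_config(seed = 11, n_promoters = 50L, n_enhancers = 50L,
                    cgi_fraction_promoters = 1, cgi_fraction_enhancers = 1)
  sim <- simulate_genome(cfg)
  prom_found <- vapply(seq_len(nrow(sim$promoters)), function(i) {
    a <- extract_anchored(sim$genome, "simP", sim$promoters$tss[i],
                          sim$promoters$strand[i], 200L, 200L)
    associate_promoter_cgi(a)$associated
  }, logical(1))
  expect_gte(mean(prom_found), 48 / 50)
  enh_found <- vapply(seq_len(nrow(sim$enhancers)), function(i) {
    associate_enhancer_cgi(sim$enhancers[i, , drop = FALSE], sim$genome)
  }, logical(1))
  expect_gte(mean(enh_found), 48 / 50)
})

test_that("motif planting respects rates and the Inr dependency", {
  pwms <- load_pwms()
  cfg <- cfg_small(seed = 13, motif_plant_rates = list(
    TATA = list(rate = 1, jitter_sd = 0),
    Inr = list(rate = 0, jitter_sd = 0),
    DPE = list(rate = 1, jitter_sd = 0)))
  sim <- simulate_motifs(cfg, simulate_genome(cfg), pwms)
  tt <- sim$motif_truth
  # TATA planted everywhere at exactly the expected position
  tata <- tt[tt$cpe_name == "TATA", ]
  expect_equal(nrow(tata), cfg$n_promoters)
  expect_true(all(tata$rel_start == pwms$TATA$expected_position))
  # DPE requires Inr: rate 1 but Inr rate 0 -> nothing planted
  expect_equal(sum(tt$cpe_name == "DPE"), 0L)

  # scanning recovers the planted TATA in its functional window
  hits <- scan_elements(
    setNames(lapply(seq_len(nrow(sim$promoters)), function(i) {
      extract_anchored(sim$genome, "simP", sim$promoters$tss[i],
                       sim$promoters$strand[i], 500L, 200L)
    }), sim$promoters$name), pwms["TATA"])
  fw <- functional_window(pwms$TATA)
  in_fw <- unique(hits$element_id[hits$start >= fw[1] & hits$start <= fw[2]])
  expect_equal(sort(in_fw), sort(sim$promoters$name))

  cfg0 <- cfg_small(seed = 13, motif_plant_rates = list(
    TATA = list(rate = 0, jitter_sd = 0)))
  sim0 <- simulate_motifs(cfg0, simulate_genome(cfg0), pwms)
  expect_equal(nrow(sim0$motif_truth), 0L)
})

test_that("simulated CAGE recovers sharpness, specificity and directionality", {
  cfg <- sim_config(seed = 21, n_promoters = 60L, n_enhancers = 80L,
                    sharp_prob_cgi = 0.5, sharp_prob_noncgi = 0.5)
  sim <- simulate_cage(cfg, simulate_genome(cfg))
  strand_map <- setNames(sim$promoters$strand, sim$promoters$name)
  cl <- classify_elements(sim$promoter_tags, sim$promoters$name, strand_map)
  classified <- cl$label != "unclassified"
  acc <- mean((cl$label[classified] == "sharp") ==
                sim$promoters$sharp_true[match(cl$element_id[classified],
                                               sim$promoters$name)])
  expect_gte(acc, 0.95)

  expr <- group_expression(sim$promoter_tags, sim$library_map,
                           sim$promoters$name, strand_map)
  tis <- unique(sim$library_map$group[sim$library_map$class == "tissue"])
  taus <- tau_table(expr, select_top_groups(expr[, tis, drop = FALSE]))
  spec_tau <- taus$tau[sim$promoters$specific_true[match(taus$element_id,
                                                         sim$promoters$name)]]
  ubiq_tau <- taus$tau[!sim$promoters$specific_true[match(taus$element_id,
                                                          sim$promoters$name)]]
  # specific elements may miss all 15 top tissues entirely (NA tau)
  expect_gte(min(spec_tau, na.rm = TRUE), 0.9)
  expect_lte(max(ubiq_tau, na.rm = TRUE), 0.2)

  dirs <- directionality_table(sim$enhancer_tags, sim$enhancers$name)
  ok <- dirs$defined
  expect_lt(sqrt(mean((dirs$directionality[ok] -
                         sim$enhancers$directionality_true[ok])^2)), 0.15)
})

test_that("peak simulation: zero density is empty; densities are recovered", {
  cfg0 <- cfg_small(peak_density_by_group = c(promoter_cgi = 0,
                                              promoter_noncgi = 0,
                                              enhancer_cgi = 0,
                                              enhancer_noncgi = 0))
  sim0 <- simulate_peaks(cfg0, simulate_genome(cfg0))
  expect_equal(nrow(sim0$peaks), 0L)

  cfg <- sim_config(seed = 33, n_promoters = 400L, n_enhancers = 400L)
  sim <- simulate_peaks(cfg, simulate_genome(cfg))
  d <- binding_density(sim$peak_regions, sim$peaks)
  d$group <- sim$peak_regions$group
  means <- tapply(d$density_per_kb, d$group, mean)
  truth <- cfg$peak_density_by_group
  for (g in names(truth)) {
    if (truth[[g]] > 0) {
      expect_lt(abs(means[[g]] - truth[[g]]) / truth[[g]], 0.25)
    }
  }
})
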