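#' Run the full analysis pipeline on simulated inputs
#'
#' Executes the stages in order: synthetic-data generation (genome with
#' planted CGIs, CPE motifs, CAGE tags, ChIP-seq peaks), CGI association of
#' promoters and enhancers, CPE scanning with localized-overrepresentation
#' and pairwise co-occurrence tests, sharp/broad classification, tau tissue
#' specificity, enhancer directionality, peak overlap metrics, and the group
#' comparisons (CGI vs non-CGI lengths, tau, |directionality|, densities,
#' sharp/broad contingency with Fisher's exact test).
#'
#' @param config A \code{\link{sim_config}}.
#' @param pwms Named list of \code{cpe_pwm} (default: shipped asset).
#' @param outdir Optional directory; when given, inputs and result tables are
#'   written there as TSV/BED/FASTA.
#' @param scan_promoters_max Cap on the number of promoters scanned for CPEs
#'   (scanning is the slowest stage); NULL = all.
#' @return A report list: \code{elements} (per-element annotation),
#'   \code{overrepresentation}, \code{cooccurrence}, \code{comparisons},
#'   \code{contingency}, \code{recovery} (truth-recovery diagnostics),
#'   \code{config}.
#' @export
run_pipeline <- function(config, pwms = load_pwms(), outdir = NULL,
                         scan_promoters_max = NULL) {
  sim <- simulate_genome(config)
  sim <- simulate_motifs(config, sim, pwms)
  sim <- simulate_cage(config, sim)
  sim <- simulate_peaks(config, sim)

  pr <- sim$promoters
  en <- sim$enhancers
  genome <- sim$genome

  # --- CGI association ------------------------------------------------------
  prom_cgi <- vapply(seq_len(nrow(pr)), function(i) {
    a <- extract_anchored(genome, "simP", pr$tss[i], pr$strand[i],
                          upstream = 200L, downstream = 200L)
    associate_promoter_cgi(a)$associated
  }, logical(1))
  enh_cgi <- vapply(seq_len(nrow(en)), function(i) {
    associate_enhancer_cgi(en[i, , drop = FALSE], genome)
  }, logical(1))

  # --- CPE scanning ---------------------------------------------------------
  scan_idx <- seq_len(nrow(pr))
  if (!is.null(scan_promoters_max)) {
    scan_idx <- scan_idx[seq_len(min(length(scan_idx), scan_promoters_max))]
  }
  frames <- lapply(scan_idx, function(i) {
    extract_anchored(genome, "simP", pr$tss[i], pr$strand[i],
                     upstream = 500L, downstream = 200L)
  })
  names(frames) <- pr$name[scan_idx]
  hits <- scan_elements(frames, pwms)
  overrep <- do.call(rbind, lapply(pwms, function(pwm) {
    h <- hits[hits$cpe_name == pwm$name, , drop = FALSE]
    r <- overrepresentation_test(h, length(frames), pwm)
    data.frame(cpe_name = r$cpe_name, n_plus = r$n_plus, mu = r$mu,
               sigma = r$sigma, z = r$z, p_gaussian = r$p_gaussian,
               p_binomial = r$p_binomial, significant = r$significant,
               stringsAsFactors = FALSE)
  }))
  rownames(overrep) <- NULL
  presence <- cpe_presence(hits, names(frames), pwms)
  cooc <- cooccurrence_tests(presence)

  # --- CAGE metrics ---------------------------------------------------------
  strand_map <- stats::setNames(pr$strand, pr$name)
  sharp <- classify_elements(sim$promoter_tags, pr$name, strand_map)
  expr <- group_expression(sim$promoter_tags, sim$library_map, pr$name,
                           strand_map)
  tis <- unique(sim$library_map$group[sim$library_map$class == "tissue"])
  top_tis <- select_top_groups(expr[, tis, drop = FALSE])
  taus <- tau_table(expr, top_tis)
  dirs <- directionality_table(sim$enhancer_tags, en$name)

  # --- Peak overlap ---------------------------------------------------------
  dens <- binding_density(sim$peak_regions, sim$peaks)
  dens$group <- sim$peak_regions$group
  msig <- max_signal(rbind(
    stats::setNames(pr[, c("chrom", "start", "end", "name", "strand")],
                    c("chrom", "start", "end", "name", "strand")),
    en[, c("chrom", "start", "end", "name", "strand")]), sim$peaks)

  # --- Element annotation table --------------------------------------------
  elements <- rbind(
    data.frame(element_id = pr$name, kind = "promoter", cgi = prom_cgi,
               length = interval_length(pr), stringsAsFactors = FALSE),
    data.frame(element_id = en$name, kind = "enhancer", cgi = enh_cgi,
               length = interval_length(en), stringsAsFactors = FALSE))
  elements$sharp_label <- sharp$label[match(elements$element_id,
                                            sharp$element_id)]
  elements$tau <- taus$tau[match(elements$element_id, taus$element_id)]
  elements$directionality <- dirs$directionality[match(elements$element_id,
                                                       dirs$element_id)]
  elements$density_per_kb <- dens$density_per_kb[match(elements$element_id,
                                                       dens$element_id)]
  elements$max_signal <- msig$max_signal[match(elements$element_id,
                                               msig$element_id)]

  # --- Comparisons ----------------------------------------------------------
  ecgi <- elements$kind == "enhancer" & elements$cgi
  enon <- elements$kind == "enhancer" & !elements$cgi
  comparisons <- rbind(
    cbind(test = "enhancer_length_by_cgi",
          compare_groups(elements$length[ecgi], elements$length[enon],
                         "CGI", "non-CGI")),
    cbind(test = "enhancer_absdir_by_cgi",
          compare_groups(abs(stats::na.omit(elements$directionality[ecgi])),
                         abs(stats::na.omit(elements$directionality[enon])),
                         "CGI", "non-CGI")),
    cbind(test = "promoter_tau_by_cgi",
          compare_groups(stats::na.omit(elements$tau[elements$kind == "promoter" &
                                                       elements$cgi]),
                         stats::na.omit(elements$tau[elements$kind == "promoter" &
                                                       !elements$cgi]),
                         "CGI", "non-CGI")),
    cbind(test = "promoter_density_by_cgi",
          compare_groups(elements$density_per_kb[elements$kind == "promoter" &
                                                   elements$cgi],
                         elements$density_per_kb[elements$kind == "promoter" &
                                                   !elements$cgi],
                         "CGI", "non-CGI")))

  # sharp/broad x CGI contingency for classified promoters (Fisher)
  cl <- elements$kind == "promoter" & elements$sharp_label != "unclassified"
  ct <- c(a = sum(cl & elements$sharp_label == "sharp" & elements$cgi),
          b = sum(cl & elements$sharp_label == "sharp" & !elements$cgi),
          c = sum(cl & elements$sharp_label == "broad" & elements$cgi),
          d = sum(cl & elements$sharp_label == "broad" & !elements$cgi))
  fish <- association_test(ct[["a"]], ct[["b"]], ct[["c"]], ct[["d"]])
  contingency <- list(table = ct, p = fish$p, log10_p = fish$log10_p,
                      odds_ratio = fish$odds_ratio)

  # --- Truth recovery diagnostics ------------------------------------------
  recovery <- list(
    cgi_promoter_sensitivity = mean(prom_cgi[pr$cgi_true]),
    cgi_promoter_specificity = mean(!prom_cgi[!pr$cgi_true]),
    cgi_enhancer_sensitivity = if (any(en$cgi_true)) mean(enh_cgi[en$cgi_true])
                               else NA_real_,
    cgi_enhancer_specificity = mean(!enh_cgi[!en$cgi_true]),
    sharp_accuracy = {
      clk <- sharp$label != "unclassified"
      truth_k <- pr$sharp_true[match(sharp$element_id[clk], pr$name)]
      mean((sharp$label[clk] == "sharp") == truth_k)
    },
    directionality_rmse = sqrt(mean((dirs$directionality -
                                       en$directionality_true)^2, na.rm = TRUE)))

  report <- list(elements = elements, overrepresentation = overrep,
                 cooccurrence = cooc, comparisons = comparisons,
                 contingency = contingency, recovery = recovery,
                 hits = hits, expr = expr, density = dens,
                 sim = sim, config = config)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    meta <- c(pipeline = "enhancerCGI", seed = config$seed)
    write_simulation(sim, file.path(outdir, "inputs"), meta)
    write_tsv_report(elements, file.path(outdir, "elements.tsv"), meta)
    write_tsv_report(overrep, file.path(outdir, "overrepresentation.tsv"), meta)
    write_tsv_report(cooc$pairs, file.path(outdir, "cooccurrence.tsv"), meta)
    write_tsv_report(comparisons, file.path(outdir, "comparisons.tsv"), meta)
  }
  report
}

#' Mann-Whitney comparison of enhancer lengths by CGI status
#'
#' @param lengths Numeric vector of enhancer lengths.
#' @param cgi Logical vector of CGI-association flags.
#' @return One-row data.frame from \code{\link{compare_groups}} with group
#'   means, medians and the two-sided p-value.
#' @export
length_comparison <- function(lengths, cgi) {
  compare_groups(lengths[cgi], lengths[!cgi], "CGI", "non-CGI")
}
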