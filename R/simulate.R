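#' Simulation configuration
#'
#' Defaults mirror the proportions and effect directions of the FANTOM5 /
#' EPDnew study system: ~59\% of promoters and ~5.7\% of transcribed enhancers
#' CGI-associated; CGI elements longer, more broadly expressed, more
#' directional and denser in ChIP-seq peaks than non-CGI elements; 29 tissue
#' and 36 primary-cell groups; CAGE depth 200 tags per informative library.
#'
#' @param seed Integer seed; all generators are fully deterministic given it.
#' @param n_promoters,n_enhancers Element counts.
#' @param cgi_fraction_promoters,cgi_fraction_enhancers Probability that an
#'   element carries a planted CGI.
#' @param motif_plant_rates Named list per CPE: list(rate=, jitter_sd=).
#'   CPEs absent from the list are not planted.
#' @param sharp_prob_cgi,sharp_prob_noncgi Probability that a promoter is
#'   sharp-type given CGI status (CGI promoters are mostly broad).
#' @param specific_prob_cgi,specific_prob_noncgi Probability that a promoter
#'   is expressed in a single group rather than ubiquitously.
#' @param tag_depth Expected CAGE tags per informative library per element.
#' @param n_tissues,n_primary_cells,n_libraries_per_group Library structure.
#' @param directionality_beta Per-group Beta shape pairs (mapped to [-1,1]);
#'   flatter shapes for CGI enhancers give them higher |directionality|.
#' @param enhancer_length CGI/non-CGI mean and common sd of enhancer lengths.
#' @param peak_density_by_group Mean peaks per kb for promoter/enhancer x
#'   CGI-status groups.
#' @param peak_signal_meanlog_by_group Lognormal meanlog of peak signal.
#' @param gc_background Background GC fraction of the simulated genome.
#' @param spacing Distance between consecutive element slots (nt).
#' @return List of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1L,
                       n_promoters = 200L,
                       n_enhancers = 300L,
                       cgi_fraction_promoters = 0.586,
                       cgi_fraction_enhancers = 0.057,
                       motif_plant_rates = list(
                         TATA = list(rate = 0.25, jitter_sd = 1),
                         Inr = list(rate = 0.40, jitter_sd = 1),
                         DPE = list(rate = 0.25, jitter_sd = 1),
                         TCT = list(rate = 0.10, jitter_sd = 1)),
                       sharp_prob_cgi = 0.03,
                       sharp_prob_noncgi = 0.20,
                       specific_prob_cgi = 0.20,
                       specific_prob_noncgi = 0.80,
                       tag_depth = 200L,
                       n_tissues = 29L,
                       n_primary_cells = 36L,
                       n_libraries_per_group = 1L,
                       directionality_beta = list(cgi = c(0.8, 0.8),
                                                  noncgi = c(4, 4)),
                       enhancer_length = list(mean_cgi = 384,
                                              mean_noncgi = 289.2,
                                              sd = 100, min = 150),
                       peak_density_by_group = c(promoter_cgi = 5.06,
                                                 promoter_noncgi = 1.89,
                                                 enhancer_cgi = 3.26,
                                                 enhancer_noncgi = 1.15),
                       peak_signal_meanlog_by_group = c(cgi = log(5000),
                                                        noncgi = log(2500)),
                       gc_background = 0.41,
                       spacing = 4000L) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_promoters > 0L, cfg$n_enhancers > 0L,
            cfg$cgi_fraction_promoters >= 0, cfg$cgi_fraction_promoters <= 1,
            cfg$cgi_fraction_enhancers >= 0, cfg$cgi_fraction_enhancers <= 1,
            cfg$gc_background > 0, cfg$gc_background < 1)
  structure(cfg, class = "sim_config")
}

# A CpG-island block built from randomized 20-nt tiles, each with exactly
# 13 G/C and three CpG dinucleotides. Any 100-nt window of the block then
# contains >= 52 GC (>= 50%) and >= 12 CpGs against a worst-case
# observed/expected threshold count of ~9, so every window of the planted
# truth provably satisfies the calling definition.
make_cgi_block <- function(len) {
  n_tiles <- ceiling(len / 20L)
  tiles <- vapply(seq_len(n_tiles), function(i) {
    tile <- character(20L)
    cg_starts <- sample(c(1L, 4L, 7L, 10L, 13L, 16L, 19L), 3L)
    for (s in cg_starts) { tile[s] <- "C"; tile[s + 1L] <- "G" }
    rest <- which(tile == "")
    fill <- sample(c(sample(c("C", "G"), 7L, replace = TRUE),
                     sample(c("A", "T"), 7L, replace = TRUE)))
    tile[rest] <- fill
    paste(tile, collapse = "")
  }, character(1))
  substr(paste(tiles, collapse = ""), 1L, len)
}

random_dna <- function(n, gc) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

plant_block <- function(seqstr, start, block) {
  substr(seqstr, start + 1L, start + nchar(block)) <- block
  seqstr
}

#' Simulate a genome with planted CpG islands
#'
#' Two chromosomes are generated: \code{simP} carrying promoter slots and
#' \code{simE} carrying enhancer slots, spaced \code{spacing} nt apart over an
#' i.i.d. background with the configured GC content. CGI-positive elements
#' receive a planted block (length Uniform[250, 1200] nt) overlapping the
#' designated TSS: for promoters the annotated TSS, for enhancers one of the
#' two divergent TSSs chosen at random (both with probability 0.2).
#'
#' @param config A \code{\link{sim_config}}.
#' @return List with \code{genome} (named character vector), \code{promoters}
#'   and \code{enhancers} (interval data.frames with tss / cgi_true columns)
#'   and \code{cgi_truth} (interval data.frame of planted blocks).
#' @export
simulate_genome <- function(config) {
  set.seed(config$seed)
  sp <- config$spacing
  np <- config$n_promoters; ne <- config$n_enhancers
  chrP <- random_dna(np * sp + sp, config$gc_background)
  chrE <- random_dna(ne * sp + sp, config$gc_background)
  truth <- list()

  tssP <- sp * (seq_len(np) - 1L) + sp %/% 2L
  strandP <- sample(c("+", "-"), np, replace = TRUE)
  cgiP <- stats::runif(np) < config$cgi_fraction_promoters
  for (i in which(cgiP)) {
    len <- as.integer(round(stats::runif(1, 250, 1200)))
    # block centered near the TSS so the [-200,+200] scan always sees it
    start <- tssP[i] - len %/% 2L + as.integer(round(stats::runif(1, -40, 40)))
    chrP <- plant_block(chrP, start, make_cgi_block(len))
    truth[[length(truth) + 1L]] <- data.frame(chrom = "simP", start = start,
                                              end = start + len)
  }
  promoters <- genomic_intervals("simP", tssP - 500L, tssP + 501L, strandP,
                                 name = sprintf("prom%04d", seq_len(np)))
  promoters$tss <- tssP
  promoters$cgi_true <- cgiP

  cgiE <- stats::runif(ne) < config$cgi_fraction_enhancers
  mu <- ifelse(cgiE, config$enhancer_length$mean_cgi,
               config$enhancer_length$mean_noncgi)
  lenE <- pmax(config$enhancer_length$min,
               as.integer(round(stats::rnorm(ne, mu, config$enhancer_length$sd))))
  startE <- sp * (seq_len(ne) - 1L) + sp %/% 2L
  enhancers <- genomic_intervals("simE", startE, startE + lenE, ".",
                                 name = sprintf("enh%04d", seq_len(ne)))
  enhancers$cgi_true <- cgiE
  etss <- enhancer_tss(enhancers)
  which_tss <- character(ne)
  for (i in which(cgiE)) {
    u <- stats::runif(1)
    which_tss[i] <- if (u < 0.4) "rev" else if (u < 0.8) "fwd" else "both"
    targets <- switch(which_tss[i],
                      rev = etss$tss_rev[i], fwd = etss$tss_fwd[i],
                      both = c(etss$tss_rev[i], etss$tss_fwd[i]))
    for (tpos in targets) {
      len <- as.integer(round(stats::runif(1, 250, 1200)))
      start <- tpos - len %/% 2L + as.integer(round(stats::runif(1, -40, 40)))
      chrE <- plant_block(chrE, start, make_cgi_block(len))
      truth[[length(truth) + 1L]] <- data.frame(chrom = "simE", start = start,
                                                end = start + len)
    }
  }
  enhancers$cgi_tss <- which_tss
  cgi_truth <- if (length(truth) > 0L) do.call(rbind, truth) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0))
  list(genome = c(simP = chrP, simE = chrE), promoters = promoters,
       enhancers = enhancers, cgi_truth = cgi_truth)
}

#' Plant CPE consensus motifs around promoter TSSs
#'
#' For each promoter and each configured CPE, with the configured rate, the
#' consensus oligonucleotide is written into the genome at
#' expected_position + round(Normal(0, jitter_sd)) in the promoter's strand
#' frame. Overlapping plants within one element are resolved by priority
#' TATA > Inr > DPE > others (the later plant is skipped). DPE is planted only
#' in elements where Inr was planted.
#'
#' @param config A \code{\link{sim_config}}.
#' @param sim Result of \code{\link{simulate_genome}}.
#' @param pwms Named list of \code{cpe_pwm} (defines consensus and positions).
#' @return \code{sim} with mutated genome and a \code{motif_truth} data.frame
#'   (element_id, cpe_name, rel_start).
#' @export
simulate_motifs <- function(config, sim, pwms = load_pwms()) {
  set.seed(config$seed + 101L)
  rates <- config$motif_plant_rates
  order_names <- c(intersect(c("TATA", "Inr", "DPE"), names(rates)),
                   setdiff(names(rates), c("TATA", "Inr", "DPE")))
  genome <- sim$genome
  truth <- list()
  pr <- sim$promoters
  for (i in seq_len(nrow(pr))) {
    occupied <- matrix(numeric(0), ncol = 2)
    planted <- character(0)
    for (nm in order_names) {
      if (!nm %in% names(pwms)) stop("unknown CPE in motif_plant_rates: ", nm)
      pwm <- pwms[[nm]]
      if (!is.null(pwm$requires) && !pwm$requires %in% planted) next
      if (stats::runif(1) >= rates[[nm]]$rate) next
      pos <- pwm$expected_position +
        as.integer(round(stats::rnorm(1, 0, rates[[nm]]$jitter_sd)))
      oligo <- pwm_consensus(pwm)
      l <- nchar(oligo)
      if (nrow(occupied) > 0L &&
          any(pos < occupied[, 2] & pos + l > occupied[, 1])) next
      tss <- pr$tss[i]
      if (pr$strand[i] == "+") {
        genome[["simP"]] <- plant_block(genome[["simP"]], tss + pos, oligo)
      } else {
        genome[["simP"]] <- plant_block(genome[["simP"]], tss - pos - l + 1L,
                                        revcomp(oligo))
      }
      occupied <- rbind(occupied, c(pos, pos + l))
      planted <- c(planted, nm)
      truth[[length(truth) + 1L]] <- data.frame(element_id = pr$name[i],
                                                cpe_name = nm, rel_start = pos)
    }
  }
  sim$genome <- genome
  sim$motif_truth <- if (length(truth) > 0L) do.call(rbind, truth) else
    data.frame(element_id = character(0), cpe_name = character(0),
               rel_start = integer(0))
  sim
}

#' Simulate CAGE tag tables and the library map
#'
#' Promoter tags: sharp elements draw tag positions from a point mass at the
#' TSS with +/-1 nt noise; broad elements from Normal(0, 20) truncated to
#' [-50, 50]. Sharpness and tissue breadth depend on CGI status per the
#' configured conditional probabilities. Specific elements are expressed in a
#' single random group, ubiquitous elements in all groups; each informative
#' library contributes Poisson(tag_depth) tags on the promoter strand.
#' Enhancer tags (positions relative to the midpoint): per enhancer a
#' directionality value is drawn from the group's Beta shapes mapped to
#' [-1, 1]; forward tags land at Normal(+60, 30) clipped to [0, 200] on "+",
#' reverse tags at Normal(-60, 30) clipped to [-200, -1] on "-".
#'
#' @param config A \code{\link{sim_config}}.
#' @param sim Result of \code{\link{simulate_genome}}.
#' @return \code{sim} plus \code{library_map}, \code{promoter_tags},
#'   \code{enhancer_tags}, and truth columns \code{sharp_true},
#'   \code{specific_true} (promoters) and \code{directionality_true}
#'   (enhancers).
#' @export
simulate_cage <- function(config, sim) {
  set.seed(config$seed + 202L)
  groups <- data.frame(
    group = c(sprintf("tissue%02d", seq_len(config$n_tissues)),
              sprintf("pcell%02d", seq_len(config$n_primary_cells))),
    class = c(rep("tissue", config$n_tissues),
              rep("primary_cell", config$n_primary_cells)),
    stringsAsFactors = FALSE)
  lib <- do.call(rbind, lapply(seq_len(config$n_libraries_per_group),
                               function(k) {
    data.frame(library_id = sprintf("%s_L%02d", groups$group, k),
               group = groups$group, class = groups$class,
               stringsAsFactors = FALSE)
  }))

  pr <- sim$promoters
  np <- nrow(pr)
  sharp_true <- stats::runif(np) <
    ifelse(pr$cgi_true, config$sharp_prob_cgi, config$sharp_prob_noncgi)
  specific_true <- stats::runif(np) <
    ifelse(pr$cgi_true, config$specific_prob_cgi, config$specific_prob_noncgi)
  home_group <- sample(groups$group, np, replace = TRUE)

  rows <- list()
  for (i in seq_len(np)) {
    active_libs <- if (specific_true[i]) {
      lib$library_id[lib$group == home_group[i]]
    } else lib$library_id
    for (lb in active_libs) {
      nt <- stats::rpois(1, config$tag_depth)
      if (nt == 0L) next
      pos <- if (sharp_true[i]) {
        sample(-1L:1L, nt, replace = TRUE, prob = c(0.15, 0.7, 0.15))
      } else {
        pmax(-50L, pmin(50L, as.integer(round(stats::rnorm(nt, 0, 20)))))
      }
      tb <- table(pos)
      rows[[length(rows) + 1L]] <- data.frame(
        element_id = pr$name[i], library_id = lb, strand = pr$strand[i],
        rel_position = as.integer(names(tb)), count = as.integer(tb),
        stringsAsFactors = FALSE)
    }
  }
  promoter_tags <- do.call(rbind, rows)

  en <- sim$enhancers
  ne <- nrow(en)
  shp <- config$directionality_beta
  d_true <- numeric(ne)
  for (i in seq_len(ne)) {
    p <- if (en$cgi_true[i]) shp$cgi else shp$noncgi
    d_true[i] <- 2 * stats::rbeta(1, p[1], p[2]) - 1
  }
  erows <- list()
  for (i in seq_len(ne)) {
    nt <- stats::rpois(1, config$tag_depth)
    if (nt == 0L) next
    nf <- stats::rbinom(1, nt, (1 + d_true[i]) / 2)
    nr <- nt - nf
    if (nf > 0L) {
      pos <- pmax(0L, pmin(200L, as.integer(round(stats::rnorm(nf, 60, 30)))))
      tb <- table(pos)
      erows[[length(erows) + 1L]] <- data.frame(
        element_id = en$name[i], library_id = "pool", strand = "+",
        rel_position = as.integer(names(tb)), count = as.integer(tb),
        stringsAsFactors = FALSE)
    }
    if (nr > 0L) {
      pos <- pmax(-200L, pmin(-1L, as.integer(round(stats::rnorm(nr, -60, 30)))))
      tb <- table(pos)
      erows[[length(erows) + 1L]] <- data.frame(
        element_id = en$name[i], library_id = "pool", strand = "-",
        rel_position = as.integer(names(tb)), count = as.integer(tb),
        stringsAsFactors = FALSE)
    }
  }
  enhancer_tags <- do.call(rbind, erows)

  sim$library_map <- lib
  sim$promoter_tags <- promoter_tags
  sim$enhancer_tags <- enhancer_tags
  sim$promoters$sharp_true <- sharp_true
  sim$promoters$specific_true <- specific_true
  sim$promoters$home_group <- home_group
  sim$enhancers$directionality_true <- d_true
  sim
}

#' Simulate ChIP-seq narrowPeak records over promoter and enhancer regions
#'
#' Per region, the peak count is Poisson(density x length / 1000) with the
#' group-specific density (promoter/enhancer x CGI status); peak lengths are
#' Normal(491.5, 222.4) truncated at 50 nt, placed uniformly so each peak
#' overlaps its region by at least one base; signal is lognormal with a
#' group-specific meanlog.
#'
#' @param config A \code{\link{sim_config}}.
#' @param sim Result of \code{\link{simulate_cage}} (or earlier stage).
#' @return \code{sim} plus \code{peaks} (narrowPeak data.frame) and
#'   \code{peak_regions} (the regions used, with group and true density).
#' @export
simulate_peaks <- function(config, sim) {
  set.seed(config$seed + 303L)
  pregions <- promoter_regions(sim$promoters$tss, sim$promoters$strand, "simP")
  pregions$name <- sim$promoters$name
  pregions$group <- ifelse(sim$promoters$cgi_true, "promoter_cgi",
                           "promoter_noncgi")
  eregions <- sim$enhancers[, c("chrom", "start", "end", "name", "strand")]
  eregions$group <- ifelse(sim$enhancers$cgi_true, "enhancer_cgi",
                           "enhancer_noncgi")
  regions <- rbind(pregions[, c("chrom", "start", "end", "name", "strand", "group")],
                   eregions)
  dens <- config$peak_density_by_group
  regions$true_density <- as.numeric(dens[regions$group])

  rows <- list()
  for (i in seq_len(nrow(regions))) {
    len <- regions$end[i] - regions$start[i]
    n <- stats::rpois(1, regions$true_density[i] * len / 1000)
    if (n == 0L) next
    plen <- pmax(50L, as.integer(round(stats::rnorm(n, 491.5, 222.4))))
    pstart <- regions$start[i] - plen + 1L +
      as.integer(floor(stats::runif(n) * (len + plen - 1L)))
    pstart <- pmax(pstart, 0L)
    grp <- if (grepl("_cgi$", regions$group[i])) "cgi" else "noncgi"
    sig <- stats::rlnorm(n, config$peak_signal_meanlog_by_group[[grp]], 0.5)
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = regions$chrom[i], start = pstart, end = pstart + plen,
      name = sprintf("%s_pk%d", regions$name[i], seq_len(n)),
      score = 0L, strand = ".", signal = round(sig, 3),
      pvalue_log = -1, qvalue_log = -1, summit_offset = plen %/% 2L,
      stringsAsFactors = FALSE)
  }
  sim$peaks <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               name = character(0), score = integer(0), strand = character(0),
               signal = numeric(0), pvalue_log = numeric(0),
               qvalue_log = numeric(0), summit_offset = integer(0))
  sim$peak_regions <- regions
  sim
}

#' Write all simulated inputs to a directory as plain-text files
#' @param sim Full simulation state.
#' @param outdir Output directory (created if needed).
#' @param meta Metadata lines for TSV headers.
#' @return outdir, invisibly.
#' @export
write_simulation <- function(sim, outdir, meta = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(sim$genome, file.path(outdir, "genome.fa"))
  write_bed(sim$promoters, file.path(outdir, "promoters.bed"))
  write_bed(sim$enhancers, file.path(outdir, "enhancers.bed"))
  if (nrow(sim$cgi_truth) > 0L) {
    ct <- genomic_intervals(sim$cgi_truth$chrom, sim$cgi_truth$start,
                            sim$cgi_truth$end)
    ct$score <- 0L
    write_bed(ct, file.path(outdir, "cgi_truth.bed"))
  }
  if (!is.null(sim$promoter_tags)) {
    write_tsv_report(sim$promoter_tags, file.path(outdir, "promoter_tags.tsv"),
                     meta)
    write_tsv_report(sim$enhancer_tags, file.path(outdir, "enhancer_tags.tsv"),
                     meta)
    write_tsv_report(sim$library_map, file.path(outdir, "library_map.tsv"),
                     meta)
  }
  if (!is.null(sim$peaks)) {
    write_bed(sim$peaks, file.path(outdir, "peaks.narrowPeak"),
              kind = "narrowPeak")
  }
  invisible(outdir)
}
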