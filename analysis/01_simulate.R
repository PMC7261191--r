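#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs with known ground truth.
# Emits FASTA genome with planted CpG islands and CPE motifs, promoter and
# enhancer BED files, CAGE tag tables, the library map and narrowPeak files
# under results/inputs/.

library(enhancerCGI)

seed <- as.integer(Sys.getenv("ENHANCERCGI_SEED", "1"))
cfg <- sim_config(seed = seed)
sim <- simulate_genome(cfg)
sim <- simulate_motifs(cfg, sim)
sim <- simulate_cage(cfg, sim)
sim <- simulate_peaks(cfg, sim)

dir.create("results", showWarnings = FALSE)
write_simulation(sim, "results/inputs",
                 meta = c(pipeline = "enhancerCGI", seed = seed))
# downstream stages regenerate the same state from the seed; the files above
# are the archival plain-text record of the inputs

cat(sprintf("simulated %d promoters (%d CGI-true) and %d enhancers (%d CGI-true)\n",
            nrow(sim$promoters), sum(sim$promoters$cgi_true),
            nrow(sim$enhancers), sum(sim$enhancers$cgi_true)))
cat(sprintf("planted %d motifs; %d CAGE tag rows; %d peaks\n",
            nrow(sim$motif_truth),
            nrow(sim$promoter_tags) + nrow(sim$enhancer_tags),
            nrow(sim$peaks)))
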