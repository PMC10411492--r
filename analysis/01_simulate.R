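#!/usr/bin/env Rscript
# Stage 1: generate the faster-X demonstration data set.
#
# 16 taxa, 200 autosomal + 15 X-linked 600-bp loci on one species tree;
# X loci evolve 3x faster with strongly saturated third codon positions;
# a few cross-contaminants and long-branch paralogs are injected, male X
# depth is halved, and male X sequences are enriched for missing data.
# Everything planted is recorded in truth tables.

suppressMessages(library(phyloconflict))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 7L

cfg <- sim_config(contamination_n = 4, long_branch_n = 4, seed = seed)
sim <- simulate_locus_set(cfg)
link <- setNames(sim$truth$linkage$linkage, sim$truth$linkage$locus)
cov <- simulate_coverage(cfg, link, sim$sex)

dir.create("results", showWarnings = FALSE)
fixdir <- "results/fixture"
unlink(fixdir, recursive = TRUE)
write_fixture_dir(sim, fixdir, coverage = cov)
write_manifest("results/manifest_simulate.json", seed = seed, config = cfg,
               files = c(file.path(fixdir, "species_tree.nwk"),
                         file.path(fixdir, "genetrees.nwk"),
                         file.path(fixdir, "coverage.tsv")))

cat(sprintf("wrote %d loci (%d X-linked) to %s\n", length(sim$records),
            sum(link == "X"), fixdir))
cat(sprintf("planted: %d contaminants, %d long-branch paralogs, %d masked male-X sequences\n",
            NROW(sim$truth$contaminants), NROW(sim$truth$long_branches),
            NROW(sim$truth$missing)))
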